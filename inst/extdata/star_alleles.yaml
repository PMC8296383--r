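# CYP2A6 star-allele definitions resolvable on the shipped SNP panel.
# One panel SNP discriminates one allele (the panel was designed so that each
# SNP, or set of SNPs, corresponds to a single allele).  Assignments marked
# "anchored" follow the standard PharmVar variant-to-allele assignment; the
# remaining single-SNP assignments are synthetic placeholders completing the
# published function groups and are expected to be edited against a full
# allele-definition table.  *10 is intentionally absent: its defining variants
# are the *7 and *8 SNPs, so it cannot be discriminated under the
# one-SNP-one-allele design.  rs1137115 is deliberately unassigned (a
# non-specific marker of decreased-function alleles).
alleles:
  "*1":
    function: normal
    snps: []            # reference allele: no panel minor alleles
  "*2":
    function: loss_of_function
    snps: [rs1801272]   # anchored (L160H)
  "*5":
    function: loss_of_function
    snps: [rs5031017]   # anchored (G479V)
  "*7":
    function: decreased
    snps: [rs5031016]   # anchored (I471T)
  "*8":
    function: normal
    snps: [rs28399468]  # anchored (codon 485 missense)
  "*9":
    function: decreased
    snps: [rs28399433]  # anchored (TATA-box promoter variant)
  "*13":
    function: decreased
    snps: [rs28399434]  # anchored (G5R)
  "*15":
    function: decreased
    snps: [rs199916117] # synthetic placeholder (K194E)
  "*19":
    function: decreased
    snps: [rs1809810]   # synthetic placeholder (Y392F)
  "*21":
    function: decreased
    snps: [rs6413474]   # anchored (K476R)
  "*38":
    function: decreased
    snps: [rs148166815] # synthetic placeholder
  "*18":
    function: unknown
    snps: [rs143731390] # synthetic placeholder (N438Y)
  "*36":
    function: unknown
    snps: [rs8192720]   # synthetic placeholder (L8L)
  "*37":
    function: unknown
    snps: [rs2431413]   # synthetic placeholder (intronic)
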