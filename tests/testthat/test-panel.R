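test_that("shipped panel has the full 31-SNP composition", {
  panel <- load_panel()
  expect_s3_class(panel, "snp_panel")
  expect_equal(nrow(panel), 31L)
  counts <- table(panel$gene)
  expect_equal(unname(counts["CYP2A6"]), 14L)
  expect_equal(unname(counts["NRXN1"]), 4L)
  expect_equal(unname(counts["DRD4"]), 1L)
  expect_equal(unname(counts["HTR2A"]), 2L)
  expect_equal(unname(counts["CHRNA3"]), 4L)
  expect_equal(unname(counts["CHRNA5"]), 5L)
  expect_equal(unname(counts["intergenic"]), 1L)
  expect_false(anyDuplicated(panel$rsid) > 0)
  expect_true(all(panel$major %in% c("A", "C", "G", "T")))
  expect_true(all(panel$major != panel$minor))
  expect_true(all(panel$pos > 0))
  expect_true(all(panel$maf >= 0 & panel$maf <= 1))
  # spot-check a catalogued row
  rs <- panel[panel$rsid == "rs28399433", ]
  expect_equal(rs$pos, 40850474L)
  expect_equal(rs$major, "A")
  expect_equal(rs$minor, "C")
})

test_that("panel parsing accepts 'X > Y' allele notation and rejects malformed rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tgene\tchrom\tpos\talleles\tconsequence\tmaf",
               "rs1\tG1\tchr1\t100\tA > C\tintron\t0.1"), tmp)
  p <- load_panel(tmp)
  expect_equal(p$major, "A")
  expect_equal(p$minor, "C")

  writeLines(c("rsid\tgene\tchrom\tpos\talleles\tconsequence\tmaf",
               "rs1\tG1\tchr1\t100\tA-C\tintron\t0.1"), tmp)
  expect_error(load_panel(tmp), "malformed allele change.*rs1")

  writeLines(c("rsid\tgene\tchrom\tpos\talleles\tconsequence\tmaf",
               "rs1\tG1\tchr1\t100\tA > C\tweird\t0.1"), tmp)
  expect_error(load_panel(tmp), "unknown consequence")

  writeLines(c("rsid\tgene\tchrom\tpos\talleles\tconsequence\tmaf",
               "rs1\tG1\tchr1\t100\tA > C\tintron\t0.1",
               "rs1\tG1\tchr1\t200\tA > G\tintron\t0.2"), tmp)
  expect_error(load_panel(tmp), "duplicate rsID")
})

test_that("an empty panel file yields an empty panel with a warning", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rsid\tgene\tchrom\tpos\tmajor\tminor\tconsequence\tmaf", tmp)
  expect_warning(p <- load_panel(tmp), "no SNPs")
  expect_equal(nrow(p), 0L)
})

test_that("strand normalization maps either strand onto panel alleles and is an involution", {
  # published labels for rs28399433 are on the opposite strand (T/G vs A/C)
  expect_equal(normalize_call("TG", "A", "C"), "AC")
  expect_equal(normalize_call("TT", "A", "C"), "AA")
  expect_equal(normalize_call("GG", "A", "C"), "CC")
  expect_equal(normalize_call("CA", "A", "C"), "AC")  # minor-first reordered
  expect_true(is.na(normalize_call("XY", "A", "C")))
  expect_true(is.na(normalize_call("./.", "A", "C")))
  # involution over all well-formed pairs for several allele systems
  for (al in list(c("A", "C"), c("T", "C"), c("T", "A"), c("G", "A"))) {
    pairs <- c(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
    once <- normalize_call(pairs, al[1], al[2])
    twice <- normalize_call(once, al[1], al[2])
    expect_identical(once, twice)
  }
})

test_that("genotype TSV round-trips through write and load", {
  gm <- published_gm()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, tmp)
  gm2 <- load_genotypes(tmp, gm$snps, gm$subjects, format = "tsv")
  expect_identical(gm2$calls, gm$calls)
  expect_identical(gm2$subjects$subject_id, gm$subjects$subject_id)
})

test_that("genotype loading validates subjects and SNPs and flags unknown alleles", {
  panel <- tiny_panel()
  demo <- data.frame(subject_id = c("s1", "s2"), cohort = "e-Dec",
                     stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("subject_id\trsA\trsB", "s1\tAG\tCC", "s3\tAA\tCT"), tmp)
  expect_error(load_genotypes(tmp, panel, demo), "absent from demographics.*s3")

  writeLines(c("subject_id\trsA\trsZ", "s1\tAG\tCC"), tmp)
  expect_error(load_genotypes(tmp, panel, demo), "not in the panel.*rsZ")

  writeLines(c("subject_id\trsA\trsB", "s1\tXY\tCC", "s2\t./.\tCT"), tmp)
  expect_warning(gm <- load_genotypes(tmp, panel, demo), "neither panel strand")
  expect_true(is.na(gm$calls["s1", "rsA"]))
  expect_true(is.na(gm$calls["s2", "rsA"]))
  expect_equal(gm$calls["s2", "rsB"], "CT")
})

test_that("VCF genotypes load and agree with the equivalent TSV", {
  skip_if_not_installed("vcfR")
  panel <- tiny_panel()
  demo <- data.frame(subject_id = c("s1", "s2"), cohort = "e-Dec",
                     stringsAsFactors = FALSE)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t0/0\t./."
  ), vcf)
  gm <- load_genotypes(vcf, panel, demo, format = "vcf")
  expect_equal(gm$calls["s1", "rsA"], "AG")
  expect_equal(gm$calls["s2", "rsA"], "GG")
  expect_equal(gm$calls["s1", "rsB"], "CC")
  expect_true(is.na(gm$calls["s2", "rsB"]))
})

test_that("shipped star-allele config encodes the published function groups", {
  defs <- load_allele_definitions(panel = load_panel())
  expect_s3_class(defs, "star_allele_defs")
  fun <- setNames(defs$function_class, defs$name)
  expect_equal(unname(fun["*1"]), "normal")
  expect_equal(unname(fun["*8"]), "normal")
  expect_equal(unname(fun["*2"]), "loss_of_function")
  expect_equal(unname(fun["*5"]), "loss_of_function")
  for (a in c("*7", "*9", "*13", "*15", "*19", "*21", "*38")) {
    expect_equal(unname(fun[a]), "decreased")
  }
  for (a in c("*18", "*36", "*37")) {
    expect_equal(unname(fun[a]), "unknown")
  }
  # reference allele has no defining SNPs; every other allele has some
  lens <- vapply(defs$defining_snps, length, 1L)
  expect_equal(lens[defs$name == "*1"], 0L)
  expect_true(all(lens[defs$name != "*1"] > 0))
  # one SNP discriminates at most one allele
  expect_false(anyDuplicated(unlist(defs$defining_snps)) > 0)
  # the excluded non-specific marker is not claimed by any allele
  expect_false("rs1137115" %in% unlist(defs$defining_snps))
})

test_that("allele-definition config errors are caught", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("alleles:", "  \"*2\":", "    function: turbo", "    snps: [rs1801272]"), tmp)
  expect_error(load_allele_definitions(tmp), "function class")

  writeLines(c("alleles:",
               "  \"*2\": {function: loss_of_function, snps: [rs1801272]}",
               "  \"*9\": {function: decreased, snps: [rs1801272]}"), tmp)
  expect_error(load_allele_definitions(tmp), "more than one star allele")

  writeLines(c("alleles:",
               "  \"*9\": {function: decreased, snps: []}"), tmp)
  expect_error(load_allele_definitions(tmp), "only for the reference")
})
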