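---
title: "Methods: pharmacogenetic comparison of two smoking-cessation cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacogenetic comparison of two smoking-cessation cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxsmoke)
```

## The study design this package implements

Two groups of daily smokers entered smoking-cessation interventions: a
mobile text-message program ("e-Dec", n = 38) and an on-site institutional
clinic program (n = 94).  Both cohorts were genotyped on a 31-SNP candidate
panel — 14 SNPs inside *CYP2A6* (the liver enzyme that clears 70–80% of
nicotine to cotinine) chosen so that each SNP, or set of SNPs,
discriminates a single named star allele, plus 17 SNPs in *NRXN1*, *DRD4*,
*HTR2A*, *CHRNA3*, *CHRNA5* and one intergenic site near *CYP2A6*
previously associated with smoking behaviour in Mexican-mestizo smokers.

The analysis is cross-sectional: per-cohort genotype and allele
frequencies, cohort comparison by contingency tests under an explicit
test-selection rule, CYP2A6 metabolizer phenotyping, and nonparametric
comparison of demographic and consumption variables.

## Data model and strand handling

A `genotype_matrix` couples a subject table (ID, cohort, demographics), a
`snp_panel` and a subjects × SNPs matrix of unphased diploid calls.  Calls
are stored on a single canonical strand per SNP — the strand of the panel's
allele-change notation — with the major allele written first.

The published summary tables report several SNPs on the opposite strand
from the panel's catalogue notation (all 14 *CYP2A6* SNPs, and six of the
other loci).  The panel therefore carries a per-SNP `genotype_strand` flag:
input calls written on either strand are complemented onto the canonical
alleles at load time, and report output is re-emitted on the published
display strand.  Normalization is an involution, so normalizing an already
canonical call is a no-op.  For palindromic SNPs (A/T or C/G) the strand
cannot be inferred from the letters at all; there the declared
`genotype_strand` is authoritative, which is why reconstruction from
published labels maps categories through the display labels rather than
guessing.

Three orientation choices deserve mention because the catalogue notation
and the observed tables disagree: for rs1137115, rs680244 and rs985919 the
cohort-major allele is the one annotated as the global minor (or the "X >
Y" order is inverted relative to the catalogued frequency).  The shipped
panel stores the *cohort-major* allele as major so that the
hom-major/het/hom-minor row order of the published tables is reproduced;
the catalogued global frequency is retained in the `maf` column.
rs12914385's printed "C > A" change contradicts its own genotypes and
catalogued T frequency and is treated as a typo for C > T.

## Frequencies, missing data and rounding

Counting is per-SNP complete-case: a subject missing one SNP's call is
excluded from that SNP's statistics only.  Exact fractions are kept
internally; the report layer rounds percentages half-away-from-zero to two
decimals, matching the published rendering.  When comparing against
published percentages, a cell is accepted if either round-half-up or
truncation at the printed precision reproduces it — the published tables
demonstrably mix both renderings (24.468 appears as 24.47 but 57.446 as
57.44).

Six published allele-frequency cells contradict their own genotype rows
(printed allele counts that are not 2×hom + het, apparently copied from
neighbouring rows).  `frequency_concordance()` flags these as
`count_consistent = FALSE` and reports them; all 224 internally consistent
cells reproduce exactly.

## The association battery and its selection rule

The genotype-level rule mirrors the source analysis: all-zero genotype
columns are dropped; with three categories present the uncorrected Pearson
chi-square (df = 2) is used, with exactly two the Fisher exact test, and a
SNP monomorphic in both cohorts is flagged `NS` without a test.  At the
allele level the 2×2 chi-square uses the Yates continuity correction by
default: recomputation shows the published allele p-values (0.0437,
0.0499, 0.0009, 0.0589, …) match the corrected, not the uncorrected,
statistic.  The uncorrected test remains available (`yates = FALSE`), and
an exact route (`exact = TRUE`) substitutes Fisher/Freeman–Halton.

Both exact tests are full enumerations over tables with fixed margins,
defining the two-sided p as the total probability of tables no more likely
than the observed one (with a 1 + 1e-7 relative guard against ties lost to
floating point).  The Freeman–Halton implementation accepts 2×k tables up
to k = 3 and n = 500; beyond that it refuses and advises the asymptotic
test.

Not every published p-value reproduces under any standard test we
implemented.  The genotype-level values for several 2×3 tables (e.g.
0.0311, 0.0161, 0.9709) match neither plain Pearson nor the exact test,
and the source software is described inconsistently; one printed allele
bound ("<0.0001" beside frequencies of 72.4% vs 65.4%) is arithmetically
implausible.  These stay in the *soft* concordance report
(`pvalue_concordance()`, `hard = FALSE`): computed and printed values are
listed side by side without assertion.  The 18 values that do reproduce
deterministically — all count-consistent Yates allele p-values, the two
collapsed-table Fisher values quoted in the text (0.181, 0.287), and the
"<0.0001" bounds — are asserted at one unit of printed precision (never
tighter than 0.0005).  No multiple-testing correction is applied, matching
the source analysis; a Bonferroni column can be added trivially by the
user via `p.adjust`.

## CYP2A6 metabolizer phenotyping

Two classifiers are provided and reported side by side.

The **minor-allele-count rule** (the headline classifier) totals minor
alleles across five polymorphic *CYP2A6* SNPs (rs28399433, rs28399434,
rs8192720, rs2431413, rs5031017): 0 = normal, 1 = intermediate, ≥2 = slow.
rs1137115 is excluded by design as a non-specific marker of
decreased-function alleles.  A subject with missing calls is classified
only when the missing genotypes could not change the class.

The **allele-function rule** first calls an unphased star-allele pair by
greedy dose accounting — each minor-allele copy at a defining SNP
contributes one copy of its star allele, remaining slots fill with the
reference *1, and more than two copies total is a diagnostic failure —
then translates the pair's function classes: normal+normal = normal,
normal+decreased = intermediate, and the four combinations involving
loss-of-function or two decreased alleles = slow.  Unknown-function
alleles yield `unclassified`.  With minor alleles at two different
defining SNPs the two star alleles are placed in trans (the parsimony
assumption for unphased data); `on_ambiguity = "unclassified"` refuses
instead.

The shipped allele-definition YAML anchors the assignments that are
standard in the PharmVar catalogue (*2 = rs1801272, *5 = rs5031017,
*7 = rs5031016, *8 = rs28399468, *9 = rs28399433, *13 = rs28399434,
*21 = rs6413474); the remaining single-SNP assignments complete the
published function groups but are labelled synthetic placeholders in the
file and are user-editable, because the full SNP-to-allele figure is not
printed in the source text.  *10 is deliberately absent: its defining
variants coincide with the *7 and *8 SNPs, so a one-SNP-per-allele panel
cannot discriminate it.  The published headline group sizes (19/39/48)
depend on individual-level data that were never deposited, so they are a
documented non-target; the reconstruction assigns genotypes to subjects
independently per SNP and cannot recover cross-SNP joint structure.

## Nonparametric cohort comparison and matching

`mann_whitney()` uses midranks throughout.  Below 8 observations per group
the two-sided p is exact by enumeration of all group labellings (ties
included); at 8+ it switches to the normal approximation with
tie-corrected variance and a 0.5 continuity correction.  The threshold is
a cost choice: enumeration below 8 per group is at most C(14,7) = 3432
labellings and removes all approximation error where it matters most.
`kruskal_wallis()` delegates to the standard tie-corrected H statistic.

Age/gender matching (the design of the published sub-analysis, whose
algorithm is unstated) is greedy nearest-neighbour within exact gender
strata: each reference-cohort subject selects up to `ratio` nearest-age
comparison subjects without replacement, ties broken by subject ID for
determinism.  Reference subjects are never dropped.  Optimal matching is
out of scope; greedy matching is the simplest reproducible choice and its
balance is verified empirically by the returned post-matching age and
gender p-values.

## Synthetic data: what it emulates and what it does not

`reconstruct_from_counts()` rebuilds individual-level genotype vectors
exactly from the published per-SNP genotype counts (order: hom-major
block, then het, then hom-minor, per cohort).  Re-counting reproduces
every published count; this is the fixture for all frequency and
association checks.  Because only marginal counts are published, the
reconstruction is column-independent — it preserves every per-SNP
statistic but implies nothing about haplotypes, linkage or the joint
distribution across SNPs, which is precisely why metabolizer group sizes
are not a reproduction target.

`simulate_hwe_cohort()` draws minor-allele doses Binomial(2, maf),
independently across subjects and SNPs — Hardy–Weinberg equilibrium with
no linkage disequilibrium, no genotyping error and no missingness.
`simulate_demographics()` draws bounded triangular variables at the
published per-cohort median/min/max (ages 20–60 vs 20–40, etc.) with the
published gender split, and derives the tobacco index as cigarettes/day ×
years / 20 — a simulation convention for pack-years, not a formula stated
by the source.  Passing tests on these generators therefore demonstrate
correctness of the statistical machinery under idealized sampling, not
robustness to the artefacts of real genotyping data.

The default generator seed (20210619) gives reproducible fixtures; every
simulation-based check runs under an explicit seed.

## Numerical choices and problem sizes

Exact-test ties are compared with a relative guard of 1e-7; enumeration
oracles in the test suite use independent factorial-formula code paths and
agree to 1e-12.  The test suite sizes its sweeps as follows: the Fisher
oracle sweep is exhaustive over all 2×2 tables with n ≤ 40 (132,470
tables); Freeman–Halton is checked on 150 random 2×3 tables with n ≤ 60;
HWE calibration uses 400 simulated SNPs at n = 200 and expects the
rejection rate at α = 0.05 inside a 3-SE binomial band (exact tests are
conservative, so rates a little below 5% are the norm); Kruskal–Wallis
power uses 200 replicates of three groups of 30 at a one-SD shift.

## Known limitations

* Unphased data throughout: no phasing, imputation, liftover or
  copy-number alleles (the *CYP2A6* deletion/duplication alleles are
  outside a SNP-only panel).
* The star-allele map beyond the anchored assignments is a placeholder;
  users with a full allele-definition table should replace the YAML.
* Published genotype-level p-values from the source software could not be
  reproduced exactly for several 2×3 tables and are tracked as soft
  concordance entries rather than assertions.
* Group-level published numbers that require individual-level data
  (demographic p-values, metabolizer group sizes, matched-subset
  membership) are out of reach by construction and are replaced by
  property-based checks of the corresponding machinery.
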