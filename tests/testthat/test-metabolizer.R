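# panel restricted to the five SNPs of the minor-count rule
five_snp_panel <- function() {
  panel <- load_panel()
  p <- panel[panel$rsid %in% pgxsmoke:::MINOR_COUNT_SNPS, ]
  class(p) <- c("snp_panel", "data.frame")
  p
}

test_that("minor-count rule maps total dose to phenotype", {
  panel <- five_snp_panel()
  doses <- rbind(
    c(0, 0, 0, 0, 0),  # normal
    c(1, 0, 0, 0, 0),  # intermediate (het at one SNP)
    c(2, 0, 0, 0, 0),  # slow (hom minor)
    c(1, 1, 0, 0, 0),  # slow (two hets)
    c(2, 2, 1, 0, 0)   # slow
  )
  gm <- gm_from_doses(doses, panel)
  calls <- classify_by_minor_count(gm)
  expect_equal(calls$phenotype,
               c("normal", "intermediate", "slow", "slow", "slow"))
  expect_equal(calls$minor_count, c(0L, 1L, 2L, 2L, 5L))
  expect_true(all(calls$rule == "minor_allele_count"))
})

test_that("the default SNP set excludes rs1137115 and non-panel SNPs error", {
  expect_false("rs1137115" %in% pgxsmoke:::MINOR_COUNT_SNPS)
  expect_setequal(pgxsmoke:::MINOR_COUNT_SNPS,
                  c("rs28399433", "rs28399434", "rs8192720", "rs2431413", "rs5031017"))
  gm <- gm_from_doses(rbind(c(0, 0)), tiny_panel())
  expect_error(classify_by_minor_count(gm, c("rsA", "rsNope")), "non-panel")
})

test_that("missing genotypes unclassify only when they could change the class", {
  panel <- five_snp_panel()
  doses <- rbind(
    c(2, NA, 0, 0, 0),  # already slow: missing cannot change it
    c(0, NA, 0, 0, 0),  # could be 0, 1 or 2 -> unclassified
    c(1, NA, 0, 0, 0)   # could be intermediate or slow -> unclassified
  )
  gm <- gm_from_doses(doses, panel)
  calls <- classify_by_minor_count(gm)
  expect_equal(calls$phenotype, c("slow", "unclassified", "unclassified"))
})

test_that("adding a minor allele never moves the class toward normal", {
  panel <- five_snp_panel()
  rank <- c(normal = 0, intermediate = 1, slow = 2)
  # exhaustively enumerate dose vectors over two active SNPs
  grid <- expand.grid(a = 0:2, b = 0:2)
  doses <- cbind(grid$a, grid$b, 0, 0, 0)
  gm <- gm_from_doses(doses, panel)
  calls <- classify_by_minor_count(gm)
  for (i in seq_len(nrow(grid))) {
    for (j in 1:2) {
      if (doses[i, j] < 2) {
        bumped <- doses[i, ]; bumped[j] <- bumped[j] + 1
        k <- which(grid$a == bumped[1] & grid$b == bumped[2])
        expect_gte(rank[calls$phenotype[k]], rank[calls$phenotype[i]])
      }
    }
  }
})

test_that("star-allele calling assigns doses greedily and conserves them", {
  panel <- load_panel()
  defs <- load_allele_definitions(panel = panel)
  gm <- published_gm()
  star <- call_star_alleles(gm, defs)
  expect_equal(nrow(star), 132L)

  # dose conservation: copies of non-*1 alleles equal total minor dose at
  # defining SNPs, for every classified subject
  def_snps <- setNames(
    vapply(defs$defining_snps, function(s) if (length(s)) s[1] else NA_character_, ""),
    defs$name)
  doses <- sapply(def_snps[!is.na(def_snps)], function(rs) minor_dose(gm, rs))
  total_dose <- rowSums(doses)
  called <- !is.na(star$allele1)
  n_star <- (star$allele1 != "*1") + (star$allele2 != "*1")
  expect_equal(n_star[called], unname(total_dose[called]))
  # unclassified iff dose exceeds two haplotype slots (no missing calls here)
  expect_equal(!called, unname(total_dose > 2))
})

test_that("star-allele calls match the dose-accounting oracle on small genotypes", {
  panel <- five_snp_panel()  # includes rs28399433 (*9) and rs5031017 (*5)
  defs <- load_allele_definitions(panel = load_panel())
  # restrict to alleles resolvable on the reduced panel
  resolvable <- vapply(defs$defining_snps, function(s) all(s %in% panel$rsid), TRUE)
  defs <- defs[resolvable, ]
  idx9 <- which(panel$rsid == "rs28399433")
  idx5 <- which(panel$rsid == "rs5031017")
  grid <- expand.grid(d9 = 0:2, d5 = 0:2)
  doses <- matrix(0L, nrow(grid), 5)
  doses[, idx9] <- grid$d9; doses[, idx5] <- grid$d5
  gm <- gm_from_doses(doses, panel)
  star <- call_star_alleles(gm, defs)
  for (i in seq_len(nrow(grid))) {
    expected <- c(rep("*9", grid$d9[i]), rep("*5", grid$d5[i]))
    if (length(expected) > 2) {
      expect_true(is.na(star$allele1[i]))
      expect_match(star$diagnostic[i], "exceeds 2")
    } else {
      expected <- sort(c(expected, rep("*1", 2 - length(expected))))
      expect_equal(sort(c(star$allele1[i], star$allele2[i])), expected)
    }
  }
  # trans resolution can be refused
  het2 <- matrix(0L, 1, 5); het2[idx9] <- 1L; het2[idx5] <- 1L
  gm2 <- gm_from_doses(het2, panel)
  strict <- call_star_alleles(gm2, defs, on_ambiguity = "unclassified")
  expect_true(is.na(strict$allele1))
  # missing genotype at a defining SNP unclassifies
  miss <- matrix(0L, 1, 5); miss[idx9] <- NA
  gm3 <- gm_from_doses(miss, panel)
  expect_match(call_star_alleles(gm3, defs)$diagnostic, "missing genotype")
})

test_that("function-pair translation implements the six published combinations", {
  defs <- load_allele_definitions()
  cases <- list(
    list(pair = c("*1", "*1"), phen = "normal"),        # normal + normal
    list(pair = c("*1", "*8"), phen = "normal"),
    list(pair = c("*1", "*9"), phen = "intermediate"),  # normal + decreased
    list(pair = c("*1", "*2"), phen = "slow"),          # normal + LOF
    list(pair = c("*9", "*2"), phen = "slow"),          # decreased + LOF
    list(pair = c("*9", "*7"), phen = "slow"),          # decreased + decreased
    list(pair = c("*2", "*5"), phen = "slow"),          # LOF + LOF
    list(pair = c("*1", "*18"), phen = "unclassified")  # unknown function
  )
  for (cs in cases) {
    expect_equal(classify_by_function(cs$pair, defs)$phenotype, cs$phen)
    # order invariance
    expect_equal(classify_by_function(rev(cs$pair), defs)$phenotype, cs$phen)
  }
})

test_that("phenotype counts partition the cohort and feed the group comparison", {
  gm <- published_gm()
  calls <- classify_by_minor_count(gm)
  counts <- table(calls$phenotype)
  expect_equal(sum(counts), 132L)
  expect_equal(sum(counts[setdiff(names(counts), "unclassified")]) +
                 sum(calls$phenotype == "unclassified"), 132L)
})

test_that("the smoking comparison detects a cigarettes/day shift in slow metabolizers", {
  panel <- five_snp_panel()
  n_per <- 35
  detect <- 0
  n_sim <- 60
  for (s in seq_len(n_sim)) {
    set.seed(1000 + s)
    doses <- matrix(0L, 3 * n_per, 5)
    doses[seq_len(n_per) + n_per, 1] <- 1L       # intermediates
    doses[seq_len(n_per) + 2 * n_per, 1] <- 2L   # slow
    gm <- gm_from_doses(doses, panel)
    calls <- classify_by_minor_count(gm)
    cpd <- round(rnorm(3 * n_per, mean = 10, sd = 3))
    cpd[calls$phenotype == "slow"] <- cpd[calls$phenotype == "slow"] + 2
    subjects <- data.frame(subject_id = gm$subjects$subject_id,
                           cigarettes_per_day = pmax(cpd, 1))
    res <- phenotype_vs_smoking(calls, subjects, "cigarettes_per_day")
    expect_equal(sort(res$summary$phenotype),
                 c("intermediate", "normal", "slow"))
    if (res$p_value < 0.05) detect <- detect + 1
  }
  expect_gt(detect / n_sim, 0.5)

  # type-I calibration: no shift -> roughly uniform p (coarse band)
  set.seed(99)
  ps <- replicate(60, {
    doses <- matrix(0L, 3 * n_per, 5)
    doses[seq_len(n_per) + n_per, 1] <- 1L
    doses[seq_len(n_per) + 2 * n_per, 1] <- 2L
    gm <- gm_from_doses(doses, panel)
    calls <- classify_by_minor_count(gm)
    subjects <- data.frame(subject_id = gm$subjects$subject_id,
                           cigarettes_per_day = round(rnorm(3 * n_per, 10, 3)))
    phenotype_vs_smoking(calls, subjects, "cigarettes_per_day")$p_value
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps < 0.05), 0.2)

  # single phenotype group only: error path
  doses1 <- matrix(0L, 10, 5)
  gm1 <- gm_from_doses(doses1, panel)
  calls1 <- classify_by_minor_count(gm1)
  subjects1 <- data.frame(subject_id = gm1$subjects$subject_id,
                          cigarettes_per_day = 10)
  expect_error(phenotype_vs_smoking(calls1, subjects1, "cigarettes_per_day"),
               "at least two")
})
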