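#' Round half away from zero
#'
#' Report-layer rounding used for printed percentages (so that e.g. 62.765
#' prints as 62.77).  Exact fractions are kept internally; only formatted
#' output is rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-cohort genotype and allele counts for one SNP
#'
#' Subjects missing this SNP's call are excluded (per-SNP complete-case);
#' genotype categories are ordered hom-major, het, hom-minor.
#'
#' @param gm A `genotype_matrix`.
#' @param rsid Panel SNP identifier.
#' @return A `freq_table`: list with `rsid`, allele labels, cohort names,
#'   `genotype_counts` (2 x 3 matrix), `allele_counts` (2 x 2 matrix),
#'   `n` per cohort, plus exact `genotype_freq`/`allele_freq` fractions.
#' @examples
#' gm <- reconstruct_published()
#' ft <- count_genotypes(gm, "rs28399433")
#' ft$allele_freq["e-Dec", "major"] * 100   # 88.16
#' @export
count_genotypes <- function(gm, rsid) {
  if (!(rsid %in% gm$snps$rsid)) {
    stop("SNP '", rsid, "' not in panel", call. = FALSE)
  }
  snp <- gm$snps[match(rsid, gm$snps$rsid), ]
  cohorts <- unique(gm$subjects$cohort)
  dose <- minor_dose(gm, rsid)
  gc <- matrix(0L, nrow = length(cohorts), ncol = 3,
               dimnames = list(cohorts, c("hom_major", "het", "hom_minor")))
  for (co in cohorts) {
    d <- dose[gm$subjects$cohort == co]
    d <- d[!is.na(d)]
    if (length(d) == 0) {
      stop("no non-missing '", rsid, "' calls in cohort '", co, "'", call. = FALSE)
    }
    gc[co, ] <- c(sum(d == 0L), sum(d == 1L), sum(d == 2L))
  }
  n <- rowSums(gc)
  ac <- cbind(major = 2L * gc[, "hom_major"] + gc[, "het"],
              minor = 2L * gc[, "hom_minor"] + gc[, "het"])
  structure(list(
    rsid = rsid,
    major = snp$major, minor = snp$minor,
    genotype_strand = snp$genotype_strand,
    cohorts = cohorts,
    n = n,
    genotype_counts = gc,
    allele_counts = ac,
    genotype_freq = gc / n,
    allele_freq = ac / (2 * n)
  ), class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table for", x$rsid, "(major", x$major, "/ minor", x$minor, ")\n")
  show <- cbind(x$genotype_counts,
                round_half_up(100 * x$genotype_freq, 2))
  colnames(show)[4:6] <- paste0(colnames(show)[1:3], "_pct")
  print(show)
  invisible(x)
}

#' Genotype labels on the published (display) strand
#'
#' @param freq A `freq_table`.
#' @return Character vector of the three genotype labels (hom-major, het,
#'   hom-minor) as they appear in the published tables, plus the two allele
#'   labels as an attribute `alleles`.
#' @export
display_labels <- function(freq) {
  maj <- freq$major; min_ <- freq$minor
  if (identical(freq$genotype_strand, "complement")) {
    maj <- complement_base(maj); min_ <- complement_base(min_)
  }
  structure(c(paste0(maj, maj), paste0(maj, min_), paste0(min_, min_)),
            alleles = c(maj, min_))
}

#' SNPs polymorphic in at least one cohort
#'
#' Retains SNPs with two or more distinct observed genotypes in at least one
#' cohort — the filter applied before the published association battery.
#'
#' @param gm A `genotype_matrix`.
#' @param snps rsIDs to screen (default: all SNPs in `gm`).
#' @return Character vector of retained rsIDs.
#' @export
polymorphic_filter <- function(gm, snps = gm$snps$rsid) {
  keep <- vapply(snps, function(rs) {
    ft <- count_genotypes(gm, rs)
    any(rowSums(ft$genotype_counts > 0) >= 2)
  }, TRUE)
  snps[keep]
}

#' Build a cohort-by-category contingency table
#'
#' @param freq A `freq_table`.
#' @param level `"genotype"` (2 x up-to-3) or `"allele"` (2 x 2; allele
#'   counts are the linear transform 2 x hom + het of genotype counts).
#' @param drop_empty Drop all-zero genotype columns (default `TRUE`).
#' @return Integer matrix with cohort rows and category columns.
#' @export
to_contingency <- function(freq, level = c("genotype", "allele"), drop_empty = TRUE) {
  level <- match.arg(level)
  tab <- if (level == "genotype") freq$genotype_counts else freq$allele_counts
  if (level == "genotype" && drop_empty) {
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
  }
  if (any(rowSums(tab) == 0)) {
    stop("contingency table has an all-zero row (empty cohort)", call. = FALSE)
  }
  tab
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test conditional on the observed allele counts: enumerates every
#' possible heterozygote count with the correct parity, computes its
#' probability under random mating, and sums the probabilities of
#' configurations no more probable than the observed one.
#'
#' @param freq A `freq_table`, or a length-3 integer vector of genotype
#'   counts (hom-major, het, hom-minor).
#' @param cohort Cohort name when `freq` is a `freq_table`.
#' @return Exact p-value.
#' @examples
#' hwe_exact(c(25, 50, 25))   # 1 region: most probable configuration
#' hwe_exact(c(50, 0, 50))    # ~0: maximal disequilibrium
#' @export
hwe_exact <- function(freq, cohort = NULL) {
  counts <- if (inherits(freq, "freq_table")) {
    if (is.null(cohort)) stop("cohort must be given with a freq_table", call. = FALSE)
    freq$genotype_counts[cohort, ]
  } else {
    as.integer(freq)
  }
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 0)) {
    stop("genotype counts must be three non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("no subjects: cannot test HWE on an empty cohort", call. = FALSE)
  n_minor <- 2L * counts[3] + counts[2]
  n_major <- 2L * n - n_minor
  rare <- min(n_minor, n_major)
  if (rare == 0) return(1)
  # heterozygote count shares the parity of the rare-allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  hom_rare <- (rare - hets) / 2
  hom_common <- n - hets - hom_rare
  lp <- lgamma(n + 1) - lgamma(hom_common + 1) - lgamma(hets + 1) - lgamma(hom_rare + 1) +
    hets * log(2) + lgamma(n_minor + 1) + lgamma(n_major + 1) - lgamma(2 * n + 1)
  p_all <- exp(lp - max(lp))
  p_all <- p_all / sum(p_all)
  obs_het <- counts[2]
  p_obs <- p_all[match(obs_het, hets)]
  if (is.na(p_obs)) stop("internal error: observed heterozygote count has wrong parity")
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-9)]))
}
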