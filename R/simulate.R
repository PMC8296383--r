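# Demographic generator defaults: the two study cohorts' published
# median (min-max) summaries and gender splits.
DEFAULT_DEMOGRAPHICS <- list(
  "e-Dec" = list(n = 38L, male_frac = 24 / 38,
                 age = c(35, 20, 60), cigarettes_per_day = c(9, 2, 30),
                 years_smoking = c(12, 2, 44), onset_age = c(20.5, 12, 50)),
  "on-site" = list(n = 94L, male_frac = 57 / 94,
                   age = c(36, 20, 40), cigarettes_per_day = c(10, 1, 60),
                   years_smoking = c(16, 1, 43), onset_age = c(17.5, 9, 50))
)

#' Simulation configuration
#'
#' Bundles the seed, cohort sizes, per-SNP minor allele frequencies and
#' demographic distributions used by [simulate_hwe_cohort()] and
#' [simulate_demographics()].  Defaults reproduce the study conditions:
#' cohorts of 38 and 94 subjects and the published demographic
#' median/range per cohort.
#'
#' @param seed Integer seed.
#' @param n_per_cohort Named integer vector of cohort sizes.
#' @param maf Named numeric vector of minor allele frequencies in `[0, 1]`
#'   (defaults to the shipped panel's catalogued frequencies).
#' @param demographics Per-cohort list of `n`, `male_frac` and
#'   `c(median, min, max)` triples per variable.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 20210619,
                       n_per_cohort = c("e-Dec" = 38L, "on-site" = 94L),
                       maf = NULL,
                       demographics = DEFAULT_DEMOGRAPHICS) {
  if (is.null(maf)) {
    panel <- load_panel()
    maf <- stats::setNames(panel$maf, panel$rsid)
  }
  if (any(maf < 0 | maf > 1, na.rm = TRUE)) stop("maf must lie in [0, 1]", call. = FALSE)
  if (any(n_per_cohort <= 0)) stop("cohort sizes must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), n_per_cohort = n_per_cohort,
                 maf = maf, demographics = demographics),
            class = "sim_config")
}

#' Rebuild individual-level genotypes from published genotype counts
#'
#' Deterministic reconstruction: for each SNP and cohort the first
#' hom-major subjects are assigned the hom-major genotype, then the
#' heterozygotes, then the hom-minor subjects, in fixed subject order.
#' Re-counting the result reproduces every input count exactly.  SNP
#' columns are reconstructed independently: the published tables give only
#' marginal counts, so no within-subject haplotype structure across SNPs is
#' implied.
#'
#' @param counts Long-format `data.frame` with columns `rsid`, `cohort`,
#'   `category` (genotype label on the published strand) and `count`.
#' @param panel A `snp_panel` covering every `rsid` in `counts`.
#' @param demographics Optional demographics for the reconstructed subjects;
#'   defaults to bare subject records (IDs and cohort labels only).
#' @return A `genotype_matrix`.
#' @export
reconstruct_from_counts <- function(counts, panel, demographics = NULL) {
  needed <- c("rsid", "cohort", "category", "count")
  if (!all(needed %in% names(counts))) {
    stop("counts need columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  counts$count <- as.integer(counts$count)
  rsids <- unique(counts$rsid)
  off <- setdiff(rsids, panel$rsid)
  if (length(off)) stop("counts reference non-panel SNP(s): ", paste(off, collapse = ", "),
                        call. = FALSE)
  cohorts <- unique(counts$cohort)
  # cohort sizes: the common per-SNP total within each cohort
  n_cohort <- stats::setNames(integer(length(cohorts)), cohorts)
  for (co in cohorts) {
    per_snp <- tapply(counts$count[counts$cohort == co],
                      counts$rsid[counts$cohort == co], sum)
    if (length(unique(per_snp)) != 1) {
      bad <- names(per_snp)[per_snp != stats::median(per_snp)][1]
      stop("genotype counts for SNP ", bad, " in cohort '", co,
           "' sum to ", per_snp[bad], ", inconsistent with the cohort size",
           call. = FALSE)
    }
    n_cohort[co] <- per_snp[1]
    if (n_cohort[co] == 0) {
      stop("cohort '", co, "' has zero subjects (all-zero counts)", call. = FALSE)
    }
  }
  subj_id <- unlist(lapply(cohorts, function(co) {
    sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", co), seq_len(n_cohort[co]))
  }))
  subjects <- data.frame(subject_id = subj_id,
                         cohort = rep(cohorts, n_cohort[cohorts]),
                         stringsAsFactors = FALSE)
  if (!is.null(demographics)) {
    subjects <- merge(subjects, demographics,
                      by = intersect(names(subjects), names(demographics)),
                      all.x = TRUE, sort = FALSE)
  }
  subjects <- check_demographics(subjects)

  sub_panel <- panel[match(rsids, panel$rsid), , drop = FALSE]
  class(sub_panel) <- c("snp_panel", "data.frame")
  calls <- matrix(NA_character_, nrow = nrow(subjects), ncol = length(rsids))
  for (j in seq_along(rsids)) {
    snp <- sub_panel[j, ]
    labels <- c(paste0(snp$major, snp$major), paste0(snp$major, snp$minor),
                paste0(snp$minor, snp$minor))
    disp <- labels
    if (snp$genotype_strand == "complement") {
      disp <- vapply(strsplit(complement_base(labels), ""), function(x)
        paste(x, collapse = ""), "")
    }
    for (co in cohorts) {
      rows <- counts[counts$rsid == rsids[j] & counts$cohort == co, ]
      # map published labels through the panel's genotype_strand: for
      # palindromic (A/T, C/G) SNPs the strand cannot be inferred from the
      # letters, so the declared display strand is authoritative
      cat_idx <- match(rows$category, disp)
      if (anyNA(cat_idx)) {
        stop("unrecognized genotype label '", rows$category[is.na(cat_idx)][1],
             "' for SNP ", rsids[j], " (expected ", paste(disp, collapse = "/"),
             ")", call. = FALSE)
      }
      k <- rows$count[match(seq_along(labels), cat_idx)]
      k[is.na(k)] <- 0L
      idx <- which(subjects$cohort == co)
      calls[idx, j] <- rep(labels, k)
    }
  }
  new_genotype_matrix(subjects, sub_panel, calls)
}

#' Reconstruct the full published study data set
#'
#' Convenience wrapper: loads the shipped panel and published genotype
#' count tables (23 tabled SNPs plus the 8 monomorphic CYP2A6 SNPs) and
#' reconstructs the 132-subject genotype matrix (38 + 94).
#'
#' @return A `genotype_matrix` with 132 subjects and 31 SNPs.
#' @export
reconstruct_published <- function() {
  panel <- load_panel()
  pub <- published_counts()
  geno <- pub[pub$level == "genotype", c("rsid", "cohort", "category", "count")]
  reconstruct_from_counts(geno, panel)
}

#' Published genotype/allele count tables shipped with the package
#'
#' @return `data.frame` with `rsid`, `level`, `category`, `cohort`, `count`
#'   and the published percentage as printed (`published_pct`, character;
#'   `NA` for SNPs reported only as monomorphic).
#' @export
published_counts <- function() {
  df <- read.delim(pgx_file("published_genotype_tables.tsv"),
                   stringsAsFactors = FALSE,
                   colClasses = c(published_pct = "character"))
  df$count <- as.integer(df$count)
  df$published_pct[df$published_pct == "NA"] <- NA_character_
  df
}

#' Published association p-values shipped with the package
#'
#' @return `data.frame` with `rsid`, `level`, `published_p` (as printed:
#'   numeric string, `"<0.0001"` or `"NS"`) and `hard` (whether the value
#'   reproduces under a documented standard test and is asserted, as
#'   opposed to reported in the soft concordance only).
#' @export
published_pvalues <- function() {
  read.delim(pgx_file("published_pvalues.tsv"), stringsAsFactors = FALSE,
             colClasses = c(published_p = "character"))
}

rtriangular <- function(n, med, lo, hi) {
  if (lo > med || med > hi) stop("inconsistent bounds: need min <= median <= max", call. = FALSE)
  if (lo == hi) return(rep(lo, n))
  u <- stats::runif(n)
  fc <- (med - lo) / (hi - lo)
  ifelse(u < fc,
         lo + sqrt(u * (hi - lo) * (med - lo)),
         hi - sqrt((1 - u) * (hi - lo) * (hi - med)))
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Per subject and SNP the minor-allele dose is drawn Binomial(2, maf),
#' independently across subjects and SNPs.
#'
#' @param config A `sim_config`; its `seed` makes the draw reproducible.
#' @param panel Optional `snp_panel`; defaults to generic biallelic SNPs
#'   (A major / G minor) named after `config$maf`.
#' @return A `genotype_matrix`.
#' @export
simulate_hwe_cohort <- function(config = sim_config(), panel = NULL) {
  set.seed(config$seed)
  maf <- config$maf
  if (is.null(panel)) {
    panel <- data.frame(
      rsid = if (!is.null(names(maf))) names(maf) else sprintf("snp%03d", seq_along(maf)),
      gene = "simulated", chrom = "chr1", pos = seq_along(maf),
      major = "A", minor = "G", consequence = "intergenic",
      maf = unname(maf), genotype_strand = "same", stringsAsFactors = FALSE)
    class(panel) <- c("snp_panel", "data.frame")
  } else {
    maf <- maf[panel$rsid]
  }
  n_co <- config$n_per_cohort
  cohorts <- names(n_co) %||% paste0("cohort", seq_along(n_co))
  subjects <- data.frame(
    subject_id = sprintf("sim_%04d", seq_len(sum(n_co))),
    cohort = rep(cohorts, n_co), stringsAsFactors = FALSE)
  subjects <- check_demographics(subjects)
  n <- nrow(subjects)
  calls <- matrix(NA_character_, n, nrow(panel))
  for (j in seq_len(nrow(panel))) {
    dose <- stats::rbinom(n, 2, maf[j])
    g <- c(paste0(panel$major[j], panel$major[j]),
           paste0(panel$major[j], panel$minor[j]),
           paste0(panel$minor[j], panel$minor[j]))
    calls[, j] <- g[dose + 1L]
  }
  new_genotype_matrix(subjects, panel, calls)
}

#' Simulate per-subject demographics
#'
#' Ages, consumption and smoking history are drawn from bounded triangular
#' distributions with the configured median and range per cohort; gender is
#' Bernoulli at the configured male fraction.  The tobacco index is derived
#' as cigarettes/day x years / 20 — a simulation convention for pack-years,
#' not a reported formula.
#'
#' @param config A `sim_config`.
#' @param shift Optional named list of per-cohort additive shifts, e.g.
#'   `list("on-site" = c(years_smoking = 4))`, for power experiments.
#' @return Demographics `data.frame` (one row per subject).
#' @export
simulate_demographics <- function(config = sim_config(), shift = NULL) {
  set.seed(config$seed + 1L)
  out <- lapply(names(config$demographics), function(co) {
    d <- config$demographics[[co]]
    sh <- if (!is.null(shift) && !is.null(shift[[co]])) shift[[co]] else c()
    get_shift <- function(v) if (v %in% names(sh)) sh[[v]] else 0
    draw <- function(v, integer = TRUE) {
      tri <- d[[v]] + get_shift(v)
      x <- rtriangular(d$n, tri[1], tri[2], tri[3])
      if (integer) round(x) else x
    }
    cpd <- draw("cigarettes_per_day")
    yrs <- draw("years_smoking")
    data.frame(
      subject_id = sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", co), seq_len(d$n)),
      cohort = co,
      age = draw("age"),
      gender = ifelse(stats::runif(d$n) < d$male_frac, "male", "female"),
      cigarettes_per_day = cpd,
      years_smoking = yrs,
      onset_age = draw("onset_age"),
      tobacco_index = cpd * yrs / 20,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
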