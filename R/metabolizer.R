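# Default SNP set for the minor-allele-count metabolizer rule: the five
# CYP2A6 panel SNPs polymorphic in the study cohorts.  rs1137115 is excluded
# by design (a non-specific marker of decreased-function alleles).
MINOR_COUNT_SNPS <- c("rs28399433", "rs28399434", "rs8192720", "rs2431413", "rs5031017")

phenotype_from_dose <- function(dose) {
  ifelse(dose == 0, "normal", ifelse(dose == 1, "intermediate", "slow"))
}

#' Metabolizer phenotype from total minor-allele count
#'
#' Simplified CYP2A6 phenotyping rule: total the minor-allele copies a
#' subject carries across a set of activity-altering SNPs; 0 copies =
#' normal, 1 = intermediate, 2 or more = slow metabolizer.  A subject with
#' missing genotypes is classified only when the missing calls could not
#' change the class (otherwise `unclassified`).
#'
#' @param gm A `genotype_matrix`.
#' @param snp_set rsIDs entering the count; defaults to the five polymorphic
#'   CYP2A6 SNPs (`rs28399433`, `rs28399434`, `rs8192720`, `rs2431413`,
#'   `rs5031017`).
#' @return A `data.frame` of class `metabolizer_calls`: `subject_id`,
#'   `rule`, `phenotype`, `minor_count`, `evidence` (per-SNP doses).
#' @export
classify_by_minor_count <- function(gm, snp_set = MINOR_COUNT_SNPS) {
  off <- setdiff(snp_set, gm$snps$rsid)
  if (length(off)) {
    stop("snp_set contains non-panel rsID(s): ", paste(off, collapse = ", "),
         call. = FALSE)
  }
  doses <- sapply(snp_set, function(rs) minor_dose(gm, rs))
  if (is.null(dim(doses))) doses <- matrix(doses, nrow = 1, dimnames = list(NULL, snp_set))
  known <- ifelse(is.na(doses), 0L, doses)
  dose_min <- rowSums(known)
  dose_max <- dose_min + 2L * rowSums(is.na(doses))
  lo <- phenotype_from_dose(dose_min)
  hi <- phenotype_from_dose(dose_max)
  phen <- ifelse(lo == hi, lo, "unclassified")
  evid <- apply(doses, 1, function(d) {
    paste(sprintf("%s=%s", snp_set, ifelse(is.na(d), ".", d)), collapse = ";")
  })
  out <- data.frame(subject_id = gm$subjects$subject_id,
                    rule = "minor_allele_count",
                    phenotype = phen,
                    minor_count = ifelse(phen == "unclassified", NA_integer_, dose_min),
                    evidence = evid,
                    stringsAsFactors = FALSE)
  class(out) <- c("metabolizer_calls", "data.frame")
  out
}

#' Call unphased CYP2A6 star-allele pairs
#'
#' Greedy dose accounting: each minor-allele copy observed at an allele's
#' defining SNP contributes one copy of that star allele (for multi-SNP
#' definitions, the dose is the minimum across defining SNPs); the remaining
#' haplotype slots are filled with the reference allele *1.  When minor
#' alleles at two different defining SNPs are seen, the two star alleles are
#' placed on opposite haplotypes (trans) — the parsimony assumption; set
#' `on_ambiguity = "unclassified"` to refuse instead.  Subjects whose total
#' star-allele dose exceeds the two haplotype slots, or who miss a call at a
#' defining SNP, are unclassified with a diagnostic.
#'
#' @param gm A `genotype_matrix`.
#' @param defs `star_allele_defs` from [load_allele_definitions()].
#' @param on_ambiguity `"trans"` (default) or `"unclassified"`.
#' @return `data.frame` with `subject_id`, `allele1`, `allele2` (`NA` when
#'   unclassified) and `diagnostic`.
#' @export
call_star_alleles <- function(gm, defs, on_ambiguity = c("trans", "unclassified")) {
  on_ambiguity <- match.arg(on_ambiguity)
  named <- defs[vapply(defs$defining_snps, length, 1L) > 0, , drop = FALSE]
  off <- setdiff(unlist(named$defining_snps), gm$snps$rsid)
  if (length(off)) {
    stop("allele definitions reference SNP(s) absent from the panel: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  n_sub <- nrow(gm$subjects)
  allele1 <- allele2 <- rep(NA_character_, n_sub)
  diagnostic <- rep(NA_character_, n_sub)
  dose_mat <- sapply(seq_len(nrow(named)), function(i) {
    d <- sapply(named$defining_snps[[i]], function(rs) minor_dose(gm, rs))
    if (is.null(dim(d))) d <- matrix(d, ncol = 1)
    apply(d, 1, function(x) if (anyNA(x)) NA_integer_ else min(x))
  })
  if (is.null(dim(dose_mat))) dose_mat <- matrix(dose_mat, nrow = n_sub)
  colnames(dose_mat) <- named$name
  for (i in seq_len(n_sub)) {
    d <- dose_mat[i, ]
    if (anyNA(d)) {
      diagnostic[i] <- paste("missing genotype for allele(s):",
                             paste(named$name[is.na(d)], collapse = ","))
      next
    }
    total <- sum(d)
    if (total > 2) {
      diagnostic[i] <- sprintf("minor-allele dose %d exceeds 2 haplotype slots", total)
      next
    }
    carried <- rep(named$name, d)
    if (length(carried) == 2 && carried[1] != carried[2] && on_ambiguity == "unclassified") {
      diagnostic[i] <- "ambiguous phase for two distinct star alleles"
      next
    }
    pair <- c(carried, rep("*1", 2 - length(carried)))
    allele1[i] <- pair[1]; allele2[i] <- pair[2]
  }
  data.frame(subject_id = gm$subjects$subject_id,
             allele1 = allele1, allele2 = allele2,
             diagnostic = diagnostic, stringsAsFactors = FALSE)
}

#' Metabolizer phenotype from a star-allele pair
#'
#' Function-class translation of an unphased diplotype: two normal-function
#' alleles = normal; one normal + one decreased = intermediate; slow covers
#' normal + loss-of-function, decreased + loss-of-function, two decreased,
#' and two loss-of-function.  A pair involving an allele of unknown function
#' is unclassified.  The mapping is symmetric in the two alleles.
#'
#' @param pair Character vector of two star-allele names, or a data.frame
#'   from [call_star_alleles()] (classified row-wise).
#' @param defs `star_allele_defs`.
#' @return For a single pair, a one-row `data.frame` (`rule`, `phenotype`,
#'   `evidence`); for a call table, one row per subject with `subject_id`.
#' @export
classify_by_function <- function(pair, defs) {
  lookup <- stats::setNames(defs$function_class, defs$name)
  classify_one <- function(a1, a2) {
    if (is.na(a1) || is.na(a2)) return(c("unclassified", "no diplotype"))
    f <- sort(unname(lookup[c(a1, a2)]))
    if (anyNA(f)) return(c("unclassified", "allele without function class"))
    if (any(f == "unknown")) return(c("unclassified", "allele of unknown function"))
    key <- paste(f, collapse = "+")
    phen <- switch(key,
      "normal+normal" = "normal",
      "decreased+normal" = "intermediate",
      "loss_of_function+normal" = "slow",
      "decreased+loss_of_function" = "slow",
      "decreased+decreased" = "slow",
      "loss_of_function+loss_of_function" = "slow",
      "unclassified")
    c(phen, key)
  }
  if (is.data.frame(pair)) {
    res <- t(mapply(classify_one, pair$allele1, pair$allele2))
    out <- data.frame(subject_id = pair$subject_id,
                      rule = "allele_function",
                      phenotype = unname(res[, 1]),
                      evidence = paste0(pair$allele1, "/", pair$allele2, " [", res[, 2], "]"),
                      stringsAsFactors = FALSE)
    class(out) <- c("metabolizer_calls", "data.frame")
    return(out)
  }
  stopifnot(length(pair) == 2)
  res <- classify_one(pair[1], pair[2])
  data.frame(rule = "allele_function", phenotype = res[1],
             evidence = paste0(pair[1], "/", pair[2], " [", res[2], "]"),
             stringsAsFactors = FALSE)
}

#' Compare a smoking variable across metabolizer phenotypes
#'
#' Per-phenotype median and interquartile range plus an omnibus
#' Kruskal-Wallis p-value across the non-empty phenotype groups
#' (unclassified subjects are excluded).
#'
#' @param calls A `metabolizer_calls` table.
#' @param subjects Demographics `data.frame` with `subject_id`.
#' @param variable Name of the numeric column to compare
#'   (e.g. `"cigarettes_per_day"`).
#' @return List with `summary` (per-group n, median, q1, q3) and `p_value`.
#' @export
phenotype_vs_smoking <- function(calls, subjects, variable) {
  if (!(variable %in% names(subjects))) {
    stop("variable '", variable, "' not in subjects", call. = FALSE)
  }
  merged <- merge(calls, subjects, by = "subject_id")
  merged <- merged[merged$phenotype != "unclassified" & !is.na(merged[[variable]]), ]
  groups <- split(merged[[variable]], merged$phenotype)
  empty <- vapply(groups, length, 1L) == 0L
  if (any(empty)) {
    warning("dropping empty phenotype group(s): ", paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  if (length(groups) < 2) {
    stop("need at least two non-empty phenotype groups", call. = FALSE)
  }
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(phenotype = g, n = length(x), median = stats::median(x),
               q1 = unname(stats::quantile(x, 0.25)), q3 = unname(stats::quantile(x, 0.75)),
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, p_value = kruskal_wallis(groups)$p_value)
}
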