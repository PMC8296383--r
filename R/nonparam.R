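#' Two-sided Mann-Whitney U test
#'
#' U statistic computed from midranks.  Below 8 observations per group the
#' two-sided p-value is exact, by full enumeration of all group labellings
#' of the pooled sample (ties handled through the midranks themselves); at
#' 8 or more per group a normal approximation with tie-corrected variance
#' and a 0.5 continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Per-group size at and below which enumeration is used.
#' @return List with `U` (for `x`), `p_value`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value   # exact 2/20 = 0.1
#' @export
mann_whitney <- function(x, y, exact_max = 7) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(pooled)) == 1) {
    warning("all values identical in both samples; p = 1")
    return(list(U = U, p_value = 1, method = "degenerate"))
  }
  if (nx <= exact_max && ny <= exact_max) {
    # enumerate every assignment of nx pooled ranks to group x
    combs <- utils::combn(nx + ny, nx)
    Us <- colSums(matrix(r[combs], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p_value = p, method = "exact_enumeration"))
  }
  n <- nx + ny
  mu <- nx * ny / 2
  ties <- table(pooled)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       method = "normal_approx_tie_corrected")
}

#' Kruskal-Wallis rank test across k groups
#'
#' Tie-corrected H statistic referred to chi-square with k - 1 df
#' (delegates to [stats::kruskal.test()]).
#'
#' @param groups List of 2 or more non-empty numeric samples.
#' @return List with `H`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 1L) == 0L)) {
    stop("all groups must be non-empty", call. = FALSE)
  }
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(values)) == 1) {
    return(list(H = 0, df = length(groups) - 1L, p_value = 1))
  }
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p_value = kt$p.value)
}

#' Median (min-max) summary of a demographic variable per group
#'
#' @param subjects Demographics `data.frame`.
#' @param variable Numeric column name.
#' @param grouping Grouping column (default `"cohort"`).
#' @return `data.frame` with per-group `n`, `median`, `min`, `max`, `q1`,
#'   `q3` and a formatted `"median (min-max)"` label.
#' @export
summarize_subjects <- function(subjects, variable, grouping = "cohort") {
  if (!(variable %in% names(subjects))) {
    stop("variable '", variable, "' not in subjects", call. = FALSE)
  }
  vals <- split(as.numeric(subjects[[variable]]), subjects[[grouping]])
  vals <- lapply(vals, function(v) v[!is.na(v)])
  empty <- vapply(vals, length, 1L) == 0L
  if (any(empty)) {
    warning("omitting empty group(s): ", paste(names(vals)[empty], collapse = ", "))
    vals <- vals[!empty]
  }
  out <- do.call(rbind, lapply(names(vals), function(g) {
    v <- vals[[g]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75))
    data.frame(group = g, variable = variable, n = length(v),
               median = unname(q[2]), min = min(v), max = max(v),
               q1 = unname(q[1]), q3 = unname(q[3]),
               label = sprintf("%s (%s-%s)", format(unname(q[2])),
                               format(min(v)), format(max(v))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Match cohorts by gender strata and nearest age
#'
#' Within each gender stratum, every reference-cohort subject greedily
#' selects up to `ratio` nearest-age comparison subjects, without
#' replacement, ties broken by subject_id order.  Reference subjects are
#' never dropped.  The balance report gives post-matching Mann-Whitney p for
#' age and a chi-square/Fisher p for gender.
#'
#' @param subjects Demographics with `cohort`, `gender`, `age`.
#' @param reference Cohort whose subjects are all kept (default `"e-Dec"`).
#' @param ratio Maximum comparison subjects matched per reference subject.
#' @return List with `matched` (retained subjects), `balance`
#'   (age/gender p-values) and per-cohort sizes.
#' @export
match_cohorts <- function(subjects, reference = "e-Dec", ratio = 1L) {
  cohorts <- unique(subjects$cohort)
  if (length(cohorts) != 2) stop("exactly two cohorts required", call. = FALSE)
  other <- setdiff(cohorts, reference)
  ref <- subjects[subjects$cohort == reference, , drop = FALSE]
  cmp <- subjects[subjects$cohort == other, , drop = FALSE]
  picked <- character(0)
  for (sex in unique(ref$gender)) {
    ref_s <- ref[ref$gender == sex, , drop = FALSE]
    ref_s <- ref_s[order(ref_s$subject_id), , drop = FALSE]
    pool <- cmp[cmp$gender == sex, , drop = FALSE]
    if (nrow(pool) == 0) {
      warning("no comparison candidates in gender stratum '", sex, "'; stratum skipped")
      next
    }
    for (round in seq_len(ratio)) {
      for (i in seq_len(nrow(ref_s))) {
        avail <- pool[!(pool$subject_id %in% picked), , drop = FALSE]
        if (nrow(avail) == 0) break
        d <- abs(avail$age - ref_s$age[i])
        best <- avail$subject_id[order(d, avail$subject_id)][1]
        picked <- c(picked, best)
      }
    }
  }
  matched <- rbind(ref, cmp[cmp$subject_id %in% picked, , drop = FALSE])
  rownames(matched) <- NULL
  age_p <- mann_whitney(matched$age[matched$cohort == reference],
                        matched$age[matched$cohort == other])$p_value
  gender_tab <- table(matched$cohort, matched$gender)
  gender_p <- if (all(dim(gender_tab) == c(2, 2)) && all(gender_tab > 0)) {
    tryCatch(pearson_chi2(unclass(gender_tab), yates = TRUE)$p_value,
             error = function(e) fisher_2x2(unclass(gender_tab))$p_value)
  } else {
    NA_real_
  }
  list(matched = matched,
       balance = c(age_p = age_p, gender_p = gender_p),
       n = c(stats::setNames(nrow(ref), reference),
             stats::setNames(sum(matched$cohort == other), other)))
}
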