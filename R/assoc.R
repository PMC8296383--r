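new_assoc_result <- function(rsid = NA_character_, level = NA_character_,
                             method, statistic = NA_real_, df = NA_integer_,
                             p_value = NA_real_, table = NULL, note = NA_character_) {
  structure(list(rsid = rsid, level = level, method = method,
                 statistic = statistic, df = df, p_value = p_value,
                 table = table, note = note),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result [%s]%s%s: p = %s",
              x$method,
              if (!is.na(x$rsid)) paste0(" ", x$rsid) else "",
              if (!is.na(x$level)) paste0(" (", x$level, ")") else "",
              format(x$p_value, digits = 4)))
  if (!is.na(x$statistic)) cat(sprintf("  [stat = %.4f, df = %d]", x$statistic, x$df))
  if (!is.na(x$note)) cat("  --", x$note)
  cat("\n")
  invisible(x)
}

check_2xk <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2) stop("contingency table must have 2 rows (cohorts)", call. = FALSE)
  if (ncol(table) < 2) stop("contingency table must have at least 2 columns", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("contingency table must hold non-negative integer counts", call. = FALSE)
  }
  if (any(colSums(table) == 0)) stop("contingency table has an all-zero column", call. = FALSE)
  if (any(rowSums(table) == 0)) stop("contingency table has an all-zero row", call. = FALSE)
  table
}

#' Pearson chi-square test on a 2 x k table
#'
#' Statistic sum((O - E)^2 / E) referred to a chi-square distribution with
#' k - 1 degrees of freedom.  With `yates = TRUE` and a 2 x 2 table,
#' |O - E| is reduced by 0.5 (continuity correction) before squaring.
#'
#' @param table 2 x k integer matrix, k >= 2.
#' @param yates Apply the Yates continuity correction (2 x 2 only).
#' @return An `assoc_result`.
#' @examples
#' pearson_chi2(rbind(c(56, 20), c(112, 76)), yates = TRUE)$p_value  # ~0.0437
#' @export
pearson_chi2 <- function(table, yates = FALSE) {
  table <- check_2xk(table)
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(E == 0)) {
    stop("a cell has expected count 0; use an exact test (fisher_2x2/freeman_halton)",
         call. = FALSE)
  }
  dev <- abs(table - E)
  if (yates && ncol(table) == 2) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  df <- ncol(table) - 1L
  new_assoc_result(method = if (yates && ncol(table) == 2) "pearson_chi2_yates" else "pearson_chi2",
                   statistic = stat, df = df,
                   p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                   table = table)
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided p-value by summing, over every table with the observed margins,
#' the hypergeometric probabilities not exceeding that of the observed table.
#'
#' @param table 2 x 2 integer matrix.
#' @return An `assoc_result` (no statistic: the test is exact).
#' @examples
#' fisher_2x2(rbind(c(0, 5), c(5, 0)))$p_value   # 2/252
#' @export
fisher_2x2 <- function(table) {
  table <- check_2xk(table)
  if (ncol(table) != 2) stop("fisher_2x2 requires a 2 x 2 table", call. = FALSE)
  m <- sum(table[, 1]); n2 <- sum(table[, 2]); k <- sum(table[1, ])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(table[1, 1], m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  new_assoc_result(method = "fisher_2x2", p_value = min(1, p), table = table)
}

# All first rows (a_1..a_k) of 2xk tables with row sum r1 and column sums cs.
enumerate_first_rows <- function(r1, cs) {
  k <- length(cs)
  acc <- matrix(seq.int(max(0, r1 - sum(cs[-1])), min(r1, cs[1])), ncol = 1)
  if (k == 1) return(acc)
  for (j in 2:k) {
    out <- list()
    for (i in seq_len(nrow(acc))) {
      used <- sum(acc[i, ])
      rest_cap <- if (j < k) sum(cs[(j + 1):k]) else 0
      lo <- max(0, r1 - used - rest_cap)
      hi <- min(r1 - used, cs[j])
      if (hi < lo) next
      vals <- lo:hi
      out[[length(out) + 1]] <- cbind(acc[rep(i, length(vals)), , drop = FALSE], vals)
    }
    acc <- do.call(rbind, out)
  }
  unname(acc[rowSums(acc) == r1, , drop = FALSE])
}

#' Freeman-Halton exact test on a 2 x k table
#'
#' Fisher-type exact test generalized to 2 x k tables (k <= 3): enumerates
#' every table with the observed margins, computes its conditional
#' probability, and sums probabilities not exceeding the observed table's.
#' On a 2 x 2 table it coincides with [fisher_2x2()].
#'
#' @param table 2 x k integer matrix, k <= 3, total n <= 500.
#' @return An `assoc_result`.
#' @export
freeman_halton <- function(table) {
  table <- check_2xk(table)
  if (ncol(table) > 3) stop("freeman_halton supports at most 3 columns", call. = FALSE)
  n <- sum(table)
  if (n > 500) {
    stop("table total ", n, " too large for exact enumeration; use pearson_chi2",
         call. = FALSE)
  }
  cs <- colSums(table)
  r1 <- sum(table[1, ])
  rows <- enumerate_first_rows(r1, cs)
  # P(table | margins) = prod_j C(cs_j, a_j) / C(n, r1)
  lden <- lchoose(n, r1)
  lp <- rowSums(lchoose(matrix(cs, nrow(rows), length(cs), byrow = TRUE), rows)) - lden
  probs <- exp(lp)
  obs_lp <- sum(lchoose(cs, table[1, ])) - lden
  p_obs <- exp(obs_lp)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  new_assoc_result(method = "freeman_halton", p_value = min(1, p), table = table)
}

#' Published test-selection rule for one SNP
#'
#' Genotype level: all-zero genotype columns are dropped; with three
#' remaining genotype categories the (uncorrected) Pearson chi-square is
#' used, with exactly two the Fisher exact test, and with one (monomorphic
#' in both cohorts) no test is run and the result is flagged `NS`.
#' Allele level: 2 x 2 chi-square with the Yates continuity correction by
#' default (the correction reproduces the published allele p-values);
#' monomorphic SNPs are again flagged.
#'
#' @param freq A `freq_table` from [count_genotypes()].
#' @param level `"genotype"` or `"allele"`.
#' @param yates Continuity correction for the allele-level 2 x 2 test.
#' @param exact Use [freeman_halton()] instead of Pearson at genotype level.
#' @return An `assoc_result`; degenerate inputs give `method = "none"` with
#'   an `NA` p-value and an explanatory note.
#' @export
select_test <- function(freq, level = c("genotype", "allele"),
                        yates = TRUE, exact = FALSE) {
  level <- match.arg(level)
  if (level == "genotype") {
    tab <- freq$genotype_counts
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) {
      return(new_assoc_result(freq$rsid, level, method = "none",
                              note = "monomorphic in both cohorts: NS, no test run"))
    }
    res <- if (ncol(tab) == 2) {
      fisher_2x2(tab)
    } else if (exact) {
      freeman_halton(tab)
    } else {
      pearson_chi2(tab, yates = FALSE)
    }
  } else {
    tab <- freq$allele_counts
    if (any(colSums(tab) == 0)) {
      return(new_assoc_result(freq$rsid, level, method = "none",
                              note = "monomorphic in both cohorts: NS, no test run"))
    }
    res <- if (exact) fisher_2x2(tab) else pearson_chi2(tab, yates = yates)
  }
  res$rsid <- freq$rsid
  res$level <- level
  res
}
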