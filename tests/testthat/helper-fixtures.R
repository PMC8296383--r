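# Shared fixtures, built in code at test time.

panel_fixture <- function() load_panel()

published_gm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reconstruct_published()
    cache
  }
})

# minimal two-SNP panel for synthetic matrices
tiny_panel <- function() {
  df <- data.frame(
    rsid = c("rsA", "rsB"),
    gene = c("GENE1", "GENE2"),
    chrom = c("chr1", "chr1"),
    pos = c(100L, 200L),
    major = c("A", "C"),
    minor = c("G", "T"),
    consequence = c("intron", "missense"),
    maf = c(0.2, 0.1),
    genotype_strand = c("same", "same"),
    stringsAsFactors = FALSE
  )
  class(df) <- c("snp_panel", "data.frame")
  df
}

# genotype matrix built directly from dose vectors (one per SNP)
gm_from_doses <- function(doses, panel = tiny_panel(), cohort = "e-Dec") {
  doses <- as.matrix(doses)
  stopifnot(ncol(doses) == nrow(panel))
  n <- nrow(doses)
  subjects <- data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    cohort = rep(cohort, length.out = n),
    stringsAsFactors = FALSE
  )
  calls <- matrix(NA_character_, n, nrow(panel))
  for (j in seq_len(nrow(panel))) {
    g <- c(paste0(panel$major[j], panel$major[j]),
           paste0(panel$major[j], panel$minor[j]),
           paste0(panel$minor[j], panel$minor[j]))
    calls[, j] <- ifelse(is.na(doses[, j]), NA_character_, g[doses[, j] + 1L])
  }
  pgxsmoke:::new_genotype_matrix(subjects, panel, calls)
}

# independent brute-force two-sided Fisher p for a 2x2 table, via direct
# factorial enumeration of every table with the observed margins
fisher_bruteforce <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  lprob <- function(a) {
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (b < 0 || c < 0 || d < 0) return(-Inf)
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(n - c1) -
      lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(c) - lfactorial(d)
  }
  as_ <- 0:min(r1, c1)
  lp <- vapply(as_, lprob, 0)
  p <- exp(lp)
  sum(p[p <= exp(lprob(tab[1, 1])) * (1 + 1e-7)])
}

# independent brute-force Freeman-Halton p for a 2x3 table
freeman_bruteforce <- function(tab) {
  cs <- colSums(tab); r1 <- sum(tab[1, ]); n <- sum(tab)
  lprob <- function(a1, a2, a3) {
    rows <- c(a1, a2, a3); rows2 <- cs - rows
    if (any(rows < 0) || any(rows2 < 0)) return(-Inf)
    sum(lfactorial(cs)) + lfactorial(r1) + lfactorial(n - r1) - lfactorial(n) -
      sum(lfactorial(rows)) - sum(lfactorial(rows2))
  }
  ps <- c()
  for (a1 in 0:min(r1, cs[1])) for (a2 in 0:min(r1 - a1, cs[2])) {
    a3 <- r1 - a1 - a2
    if (a3 >= 0 && a3 <= cs[3]) ps <- c(ps, exp(lprob(a1, a2, a3)))
  }
  p_obs <- exp(lprob(tab[1, 1], tab[1, 2], tab[1, 3]))
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}
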