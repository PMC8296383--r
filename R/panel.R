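#' @importFrom utils read.delim write.table
NULL

VALID_CONSEQUENCES <- c("missense", "synonymous", "intron", "upstream_2kb", "intergenic")
VALID_FUNCTIONS <- c("normal", "decreased", "loss_of_function", "unknown")
BASES <- c("A", "C", "G", "T")

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Load a SNP panel definition table
#'
#' Reads a tab-separated panel table with one row per SNP.  Alleles may be
#' given either as explicit `major`/`minor` columns or as a single `alleles`
#' column in `"X > Y"` notation (major first).  An optional `genotype_strand`
#' column (`"same"` or `"complement"`) records the strand on which published
#' genotype labels for that SNP are written relative to the panel alleles;
#' it defaults to `"same"`.
#'
#' @param path Path to the panel TSV. Defaults to the shipped 31-SNP panel.
#' @return A `data.frame` of class `snp_panel` with columns `rsid`, `gene`,
#'   `chrom`, `pos`, `major`, `minor`, `consequence`, `maf`,
#'   `genotype_strand`.
#' @examples
#' panel <- load_panel()
#' nrow(panel)                     # 31
#' table(panel$gene)["CYP2A6"]     # 14
#' @export
load_panel <- function(path = pgx_file("snp_panel.tsv")) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0) {
    warning("panel file '", path, "' contains no SNPs")
    empty <- data.frame(
      rsid = character(), gene = character(), chrom = character(),
      pos = integer(), major = character(), minor = character(),
      consequence = character(), maf = numeric(),
      genotype_strand = character(), stringsAsFactors = FALSE
    )
    class(empty) <- c("snp_panel", "data.frame")
    return(empty)
  }
  if (!("major" %in% names(df)) && "alleles" %in% names(df)) {
    m <- regmatches(df$alleles, regexec("^\\s*([ACGT])\\s*>\\s*([ACGT])\\s*$", df$alleles))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad)) {
      stop("malformed allele change '", df$alleles[which(bad)[1]], "' in panel row ",
           which(bad)[1], " (", df$rsid[which(bad)[1]], "); expected \"X > Y\"",
           call. = FALSE)
    }
    df$major <- vapply(m, `[`, "", 2L)
    df$minor <- vapply(m, `[`, "", 3L)
  }
  required <- c("rsid", "chrom", "pos", "major", "minor", "consequence")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("panel file lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$gene)) df$gene <- "intergenic"
  if (is.null(df$maf)) df$maf <- NA_character_
  if (is.null(df$genotype_strand)) df$genotype_strand <- "same"
  df$pos <- as.integer(df$pos)
  df$maf <- as.numeric(df$maf)

  dup <- duplicated(df$rsid)
  if (any(dup)) {
    stop("duplicate rsID(s) in panel: ", paste(unique(df$rsid[dup]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!(row$major %in% BASES) || !(row$minor %in% BASES)) {
      stop("panel row ", i, " (", row$rsid, "): alleles must be single bases A/C/G/T",
           call. = FALSE)
    }
    if (row$major == row$minor) {
      stop("panel row ", i, " (", row$rsid, "): major and minor allele are identical",
           call. = FALSE)
    }
    if (is.na(row$pos) || row$pos <= 0) {
      stop("panel row ", i, " (", row$rsid, "): position must be a positive integer",
           call. = FALSE)
    }
    if (!(row$consequence %in% VALID_CONSEQUENCES)) {
      stop("panel row ", i, " (", row$rsid, "): unknown consequence '",
           row$consequence, "' (expected one of ",
           paste(VALID_CONSEQUENCES, collapse = ", "), ")", call. = FALSE)
    }
    if (!is.na(row$maf) && (row$maf < 0 || row$maf > 1)) {
      stop("panel row ", i, " (", row$rsid, "): maf must lie in [0, 1]", call. = FALSE)
    }
    if (!(row$genotype_strand %in% c("same", "complement"))) {
      stop("panel row ", i, " (", row$rsid, "): genotype_strand must be 'same' or 'complement'",
           call. = FALSE)
    }
  }
  rownames(df) <- df$rsid
  df <- df[, c("rsid", "gene", "chrom", "pos", "major", "minor",
               "consequence", "maf", "genotype_strand")]
  class(df) <- c("snp_panel", "data.frame")
  df
}

#' Normalize a raw genotype call against a panel SNP
#'
#' Maps a two-letter unphased call, written on either strand, onto the
#' panel's canonical alleles.  The call is accepted as-is when both letters
#' belong to the SNP's allele set, complemented when the complemented pair
#' does, and set missing otherwise.  Normalization is an involution: applying
#' it to its own output changes nothing.
#'
#' @param call Character vector of two-letter calls (e.g. `"TG"`), `"./."`
#'   or `NA` for missing.
#' @param major,minor The SNP's canonical alleles.
#' @return Character vector of normalized calls (major allele written first),
#'   `NA` where the call could not be interpreted.
#' @export
normalize_call <- function(call, major, minor) {
  out <- rep(NA_character_, length(call))
  ok <- !is.na(call) & call != "./." & call != ".." & nchar(call) == 2L
  if (!any(ok)) return(out)
  a1 <- substr(call[ok], 1, 1)
  a2 <- substr(call[ok], 2, 2)
  valid <- c(major, minor)
  on_panel <- a1 %in% valid & a2 %in% valid
  c1 <- complement_base(a1)
  c2 <- complement_base(a2)
  on_comp <- !on_panel & c1 %in% valid & c2 %in% valid
  a1[on_comp] <- c1[on_comp]
  a2[on_comp] <- c2[on_comp]
  good <- on_panel | on_comp
  # canonical order: major allele first
  swap <- good & a1 == minor & a2 == major
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  res <- rep(NA_character_, sum(ok))
  res[good] <- paste0(a1[good], a2[good])
  out[ok] <- res
  out
}

new_genotype_matrix <- function(subjects, panel, calls) {
  stopifnot(nrow(calls) == nrow(subjects), ncol(calls) == nrow(panel))
  rownames(calls) <- subjects$subject_id
  colnames(calls) <- panel$rsid
  structure(list(subjects = subjects, snps = panel, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "subjects x", ncol(x$calls), "SNPs\n")
  cat("cohorts:", paste(sprintf("%s (n=%d)", names(table(x$subjects$cohort)),
                                as.integer(table(x$subjects$cohort))), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

check_demographics <- function(demo) {
  required <- c("subject_id", "cohort")
  missing_cols <- setdiff(required, names(demo))
  if (length(missing_cols)) {
    stop("demographics lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  opt <- c("age", "gender", "cigarettes_per_day", "years_smoking",
           "onset_age", "tobacco_index")
  for (v in setdiff(opt, names(demo))) demo[[v]] <- NA
  num <- c("age", "cigarettes_per_day", "years_smoking", "onset_age", "tobacco_index")
  for (v in num) {
    demo[[v]] <- as.numeric(demo[[v]])
    if (any(!is.na(demo[[v]]) & demo[[v]] < 0)) {
      stop("negative values in demographics column '", v, "'", call. = FALSE)
    }
  }
  # age < onset_age is implausible but data may disagree: flag, don't reject
  odd <- !is.na(demo$age) & !is.na(demo$onset_age) & demo$age < demo$onset_age
  if (any(odd)) {
    warning(sum(odd), " subject(s) with age < onset age (flagged, kept): ",
            paste(utils::head(demo$subject_id[odd], 5), collapse = ", "))
  }
  demo
}

#' Load an individual-level genotype matrix
#'
#' Reads diploid genotype calls for the panel SNPs, either from a wide TSV
#' (one subject per row, one SNP per column, cells as two-letter allele pairs
#' or `"./."`) or from a VCF 4.2 file with `GT` fields (requires the vcfR
#' package).  Calls are strand-normalized against the panel; letters that
#' match neither panel strand become missing with a warning.
#'
#' @param path Genotype file.
#' @param panel A `snp_panel` from [load_panel()].
#' @param demographics Path to a demographics TSV (columns `subject_id`,
#'   `cohort`, `age`, `gender`, `cigarettes_per_day`, `years_smoking`,
#'   `onset_age`, `tobacco_index`) or an equivalent `data.frame`.
#' @param format `"tsv"` or `"vcf"`.
#' @return A `genotype_matrix`: list with `subjects` (demographics),
#'   `snps` (panel subset) and `calls` (character matrix, canonical strand).
#' @export
load_genotypes <- function(path, panel, demographics, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  demo <- if (is.character(demographics)) {
    read.delim(demographics, stringsAsFactors = FALSE)
  } else {
    as.data.frame(demographics, stringsAsFactors = FALSE)
  }
  demo <- check_demographics(demo)

  if (format == "tsv") {
    raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                      check.names = FALSE)
    if (!("subject_id" %in% names(raw))) {
      stop("genotype TSV must have a 'subject_id' column", call. = FALSE)
    }
    ids <- raw$subject_id
    snp_cols <- setdiff(names(raw), "subject_id")
    calls_raw <- as.matrix(raw[, snp_cols, drop = FALSE])
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("VCF input requires the 'vcfR' package", call. = FALSE)
    }
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    snp_cols <- fix[, "ID"]
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ids <- colnames(gt)
    ref <- fix[, "REF"]
    alt <- fix[, "ALT"]
    calls_raw <- matrix(NA_character_, nrow = length(ids), ncol = length(snp_cols))
    for (j in seq_along(snp_cols)) {
      g <- gt[j, ]
      g <- gsub("|", "/", g, fixed = TRUE)
      alleles <- c(ref[j], alt[j])
      parts <- strsplit(g, "/", fixed = TRUE)
      calls_raw[, j] <- vapply(parts, function(p) {
        if (length(p) != 2 || any(p == ".") || any(is.na(p))) return(NA_character_)
        idx <- as.integer(p) + 1L
        if (any(is.na(idx)) || any(idx > length(alleles))) return(NA_character_)
        paste0(alleles[idx[1]], alleles[idx[2]])
      }, "")
    }
  }

  unknown_snp <- setdiff(snp_cols, panel$rsid)
  if (length(unknown_snp)) {
    stop("genotype file contains SNP(s) not in the panel: ",
         paste(unknown_snp, collapse = ", "), call. = FALSE)
  }
  unknown_subj <- setdiff(ids, demo$subject_id)
  if (length(unknown_subj)) {
    stop("subject(s) in genotype file absent from demographics: ",
         paste(unknown_subj, collapse = ", "), call. = FALSE)
  }
  sub_panel <- panel[match(snp_cols, panel$rsid), , drop = FALSE]
  class(sub_panel) <- c("snp_panel", "data.frame")
  subjects <- demo[match(ids, demo$subject_id), , drop = FALSE]
  rownames(subjects) <- NULL

  calls <- matrix(NA_character_, nrow = length(ids), ncol = length(snp_cols))
  n_bad <- 0L
  for (j in seq_along(snp_cols)) {
    norm <- normalize_call(calls_raw[, j], sub_panel$major[j], sub_panel$minor[j])
    was_called <- !is.na(calls_raw[, j]) & !(calls_raw[, j] %in% c("./.", ".."))
    n_bad <- n_bad + sum(was_called & is.na(norm))
    calls[, j] <- norm
  }
  if (n_bad > 0) {
    warning(n_bad, " call(s) used alleles matching neither panel strand; set to missing")
  }
  new_genotype_matrix(subjects, sub_panel, calls)
}

#' Write a genotype matrix to a wide TSV
#'
#' Inverse of the TSV path of [load_genotypes()]: a round trip through
#' [write_genotypes()] and [load_genotypes()] preserves every call.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  out <- data.frame(subject_id = gm$subjects$subject_id, stringsAsFactors = FALSE)
  calls <- gm$calls
  calls[is.na(calls)] <- "./."
  out <- cbind(out, as.data.frame(calls, stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minor-allele dose for one SNP
#'
#' @param gm A `genotype_matrix`.
#' @param rsid SNP identifier.
#' @return Integer vector (0, 1, 2 or `NA`) per subject.
#' @export
minor_dose <- function(gm, rsid) {
  if (!(rsid %in% colnames(gm$calls))) {
    stop("SNP '", rsid, "' not in genotype matrix", call. = FALSE)
  }
  minor <- gm$snps$minor[match(rsid, gm$snps$rsid)]
  calls <- gm$calls[, rsid]
  dose <- (substr(calls, 1, 1) == minor) + (substr(calls, 2, 2) == minor)
  as.integer(dose)
}

#' Load CYP2A6 star-allele definitions
#'
#' Reads a YAML config mapping star-allele names to their defining panel
#' SNPs (minor allele required at each) and a function class.  The shipped
#' default encodes the published function grouping: normal = \{*1, *8\},
#' loss-of-function = \{*2, *5\}, decreased = \{*7, *9, *13, *15, *19, *21,
#' *38\}, unknown = \{*18, *36, *37\}.
#'
#' @param path YAML file; defaults to the shipped config.
#' @param panel Optional `snp_panel`; when given, every defining SNP must be
#'   a panel rsID.
#' @return A `data.frame` of class `star_allele_defs` with columns `name`,
#'   `function_class` and list-column `defining_snps`.
#' @export
load_allele_definitions <- function(path = pgx_file("star_alleles.yaml"), panel = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$alleles) || !length(cfg$alleles)) {
    stop("allele definition config has no 'alleles' section", call. = FALSE)
  }
  names_ <- names(cfg$alleles)
  if (anyDuplicated(names_)) {
    stop("duplicate star-allele name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "), call. = FALSE)
  }
  fun <- vapply(cfg$alleles, function(a) as.character(a[["function"]] %||% NA_character_), "")
  bad_fun <- is.na(fun) | !(fun %in% VALID_FUNCTIONS)
  if (any(bad_fun)) {
    stop("allele ", names_[which(bad_fun)[1]], ": function class must be one of ",
         paste(VALID_FUNCTIONS, collapse = ", "), call. = FALSE)
  }
  snps <- lapply(cfg$alleles, function(a) as.character(unlist(a[["snps"]])))
  empty <- vapply(snps, length, 1L) == 0L
  if (any(empty & names_ != "*1")) {
    stop("allele ", names_[which(empty & names_ != "*1")[1]],
         ": defining SNP set may be empty only for the reference allele *1",
         call. = FALSE)
  }
  all_snps <- unlist(snps)
  if (anyDuplicated(all_snps)) {
    stop("SNP(s) claimed by more than one star allele: ",
         paste(unique(all_snps[duplicated(all_snps)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(panel)) {
    off <- setdiff(all_snps, panel$rsid)
    if (length(off)) {
      stop("defining SNP(s) not in panel: ", paste(off, collapse = ", "), call. = FALSE)
    }
  }
  defs <- data.frame(name = names_, function_class = fun, stringsAsFactors = FALSE)
  defs$defining_snps <- unname(snps)
  rownames(defs) <- NULL
  class(defs) <- c("star_allele_defs", "data.frame")
  defs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
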