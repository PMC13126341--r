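#' Summary-statistics tables
#'
#' GWAS/pQTL/metabolite-QTL summary statistics are carried as plain data
#' frames with one row per variant and the columns `snp_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#' `n`. `eaf` may be `NA` (palindromic variants without frequency
#' information are later excluded by [harmonize()]); all other fields are
#' mandatory. Betas are per-allele effects, on the log-odds scale for
#' binary traits.
#'
#' @param x A data frame to validate.
#' @param strict If `TRUE`, rows violating the per-variant invariants
#'   raise an error; otherwise they are dropped with a warning naming the
#'   reason (the default, mirroring how ragged public summary files are
#'   usually ingested).
#' @return The validated (possibly row-filtered) data frame, with
#'   attribute `"dropped"` holding a data frame of removed rows and
#'   reasons.
#' @export
validate_sumstats <- function(x, strict = FALSE) {
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  x <- x[, req]
  if (anyDuplicated(x$snp_id))
    stop("duplicate snp_id: ",
         paste(unique(x$snp_id[duplicated(x$snp_id)]), collapse = ", "))
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))

  bad_reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, reason) {
    cond[is.na(cond)] <- TRUE
    bad_reason[is.na(bad_reason) & cond] <<- reason
  }
  flag(!(x$effect_allele %in% c("A", "C", "G", "T")) |
         !(x$other_allele %in% c("A", "C", "G", "T")), "invalid_allele")
  flag(x$effect_allele == x$other_allele, "identical_alleles")
  flag(!is.finite(x$beta), "missing_beta")
  flag(!is.finite(x$se) | x$se <= 0, "nonpositive_se")
  flag(!is.finite(x$pval) | x$pval < 0 | x$pval > 1, "invalid_pval")
  flag(!is.finite(x$n) | x$n <= 0, "invalid_n")
  flag(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "invalid_eaf")

  bad <- !is.na(bad_reason)
  if (any(bad)) {
    if (strict)
      stop("invalid summary-statistics row(s): ",
           paste(sprintf("%s (%s)", x$snp_id[bad], bad_reason[bad]),
                 collapse = ", "))
    warning(sum(bad), " row(s) dropped on ingest (",
            paste(unique(bad_reason[bad]), collapse = ", "), ")")
  }
  # warn-only consistency check: pval should track |beta/se| under the
  # normal approximation (public files are often truncated/rounded)
  ok <- !bad & x$pval > 1e-300 & x$pval < 1
  if (any(ok)) {
    implied <- 2 * pnorm(-abs(x$beta[ok] / x$se[ok]))
    rel <- abs(log(pmax(implied, 1e-300)) - log(x$pval[ok])) /
      pmax(abs(log(x$pval[ok])), 1)
    if (any(rel > 0.1))
      warning(sum(rel > 0.1),
              " row(s) have p-values inconsistent with beta/se (>10% on",
              " the log scale); kept as-is")
  }
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(snp_id = x$snp_id[bad],
                                     reason = bad_reason[bad],
                                     stringsAsFactors = FALSE)
  out
}

#' Read a summary-statistics table from a tab-delimited file
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Optional named character vector mapping the standard
#'   column names (names of the vector) to the names used in the file
#'   (values), e.g. `c(snp_id = "rsid", pval = "p")`.
#' @param strict Passed to [validate_sumstats()].
#' @return A validated summary-statistics data frame.
#' @export
read_sumstats <- function(path, column_map = NULL, strict = FALSE) {
  x <- read.delim(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      if (!src %in% names(x))
        stop("column_map refers to absent column: ", src)
      names(x)[names(x) == src] <- std
    }
  }
  validate_sumstats(x, strict = strict)
}

#' Write a summary-statistics table
#'
#' @param x Summary-statistics data frame.
#' @param path Output path (tab-delimited, header, no quoting).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' LD reference panels
#'
#' A panel is a symmetric correlation matrix over variants, keyed by
#' variant id, as exported from an external reference cohort (e.g. a
#' European 1000 Genomes subset). [ld_panel()] validates and wraps a
#' matrix; [read_ld_matrix()]/[write_ld_matrix()] exchange the square TSV
#' form (variant ids as header row and first column).
#'
#' @param r Square numeric matrix of pairwise correlations (not r^2),
#'   with variant ids as dimnames.
#' @param ids Optional variant ids overriding `dimnames(r)`.
#' @param tol Symmetry tolerance.
#' @return An object of class `ld_panel` (a list with elements `ids` and
#'   `r`).
#' @export
ld_panel <- function(r, ids = NULL, tol = 1e-12) {
  r <- as.matrix(r)
  if (is.null(ids)) ids <- rownames(r)
  if (is.null(ids)) stop("LD panel needs variant ids")
  if (nrow(r) != ncol(r) || nrow(r) != length(ids))
    stop("LD matrix must be square with one row/column per id")
  if (any(abs(r - t(r)) > tol)) stop("LD matrix not symmetric")
  if (any(abs(diag(r) - 1) > tol)) stop("LD matrix diagonal must be 1")
  if (any(abs(r) > 1 + tol)) stop("|r| must be <= 1")
  dimnames(r) <- list(ids, ids)
  structure(list(ids = as.character(ids), r = r), class = "ld_panel")
}

#' @rdname ld_panel
#' @param path Path to a square LD TSV.
#' @export
read_ld_matrix <- function(path) {
  x <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                  check.names = FALSE)
  ld_panel(as.matrix(x))
}

#' @rdname ld_panel
#' @param panel An `ld_panel`.
#' @export
write_ld_matrix <- function(panel, path) {
  write.table(panel$r, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}
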