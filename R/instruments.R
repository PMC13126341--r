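#' Instrument-selection criteria
#'
#' Defaults are the conventional genome-wide pipeline settings: variants
#' at genome-wide significance (p < 5e-8), minor-allele frequency above
#' 0.01, greedy LD clumping at r^2 < 0.1 within a 10,000 kb window, and
#' per-variant instrument strength F >= 10.
#'
#' @param p_threshold Significance threshold on the exposure p-value.
#' @param r2_threshold Squared-correlation threshold for clumping.
#' @param clump_window Clumping window in base pairs (default 1e7 =
#'   10,000 kb).
#' @param maf_min Minimum minor-allele frequency.
#' @param f_min Minimum per-variant F statistic.
#' @param strict_panel If `TRUE`, variants absent from the LD panel are
#'   dropped; the default retains them as independent with a warning.
#' @return An object of class `instrument_criteria`.
#' @export
instrument_criteria <- function(p_threshold = 5e-8, r2_threshold = 0.1,
                                clump_window = 1e7, maf_min = 0.01,
                                f_min = 10, strict_panel = FALSE) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold >= 0, r2_threshold <= 1,
            clump_window > 0, maf_min >= 0, maf_min < 0.5, f_min >= 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 clump_window = clump_window, maf_min = maf_min,
                 f_min = f_min, strict_panel = strict_panel),
            class = "instrument_criteria")
}

#' Per-variant instrument strength
#'
#' The summary-data approximation F = (beta/se)^2, i.e. the squared Wald
#' statistic of the variant-exposure association.
#'
#' @param beta,se Effect estimate and its standard error (vectors
#'   recycle); `se` must be positive.
#' @return Numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("se must be positive")
  (beta / se)^2
}

#' Greedy LD clumping
#'
#' Sorts variants by ascending p-value and repeatedly takes the best
#' remaining variant as an index, discarding every other variant within
#' `clump_window` base pairs of it whose squared correlation with it is
#' at least `r2_threshold`. Ties on p are broken by ascending position,
#' then lexicographic variant id, so the result is deterministic and
#' independent of input row order. Variants absent from the panel are
#' treated as independent (with a warning) unless `strict_panel`.
#'
#' @param stats Summary-statistics data frame (needs `snp_id`, `chrom`,
#'   `pos`, `pval`).
#' @param panel An [ld_panel()] or `NULL` (all variants treated as
#'   independent).
#' @param criteria An [instrument_criteria()].
#' @return Character vector of retained (index) variant ids.
#' @export
ld_clump <- function(stats, panel = NULL, criteria = instrument_criteria()) {
  if (nrow(stats) == 0) {
    warning("no variants to clump")
    return(character(0))
  }
  ord <- order(stats$pval, stats$pos, stats$snp_id)
  s <- stats[ord, , drop = FALSE]
  in_panel <- if (is.null(panel)) rep(FALSE, nrow(s)) else
    s$snp_id %in% panel$ids
  if (!is.null(panel) && any(!in_panel)) {
    if (criteria$strict_panel) {
      warning(sum(!in_panel), " variant(s) absent from LD panel dropped",
              " (strict mode)")
      s <- s[in_panel, , drop = FALSE]
      in_panel <- rep(TRUE, nrow(s))
    } else {
      warning(sum(!in_panel), " variant(s) absent from LD panel retained",
              " as independent")
    }
  }
  keep <- character(0)
  alive <- rep(TRUE, nrow(s))
  while (any(alive)) {
    i <- which(alive)[1]
    keep <- c(keep, s$snp_id[i])
    alive[i] <- FALSE
    if (!is.null(panel) && in_panel[i]) {
      cand <- which(alive & in_panel &
                      s$chrom == s$chrom[i] &
                      abs(s$pos - s$pos[i]) <= criteria$clump_window)
      if (length(cand)) {
        r2 <- panel$r[s$snp_id[i], s$snp_id[cand]]^2
        alive[cand[r2 >= criteria$r2_threshold]] <- FALSE
      }
    }
  }
  keep
}

#' Select instrumental variables for one exposure
#'
#' Applies, in order: the significance filter, the minor-allele-frequency
#' filter (effect-allele frequency folded to the minor-allele scale),
#' greedy LD clumping, and the instrument-strength filter. Every input
#' variant ends up either selected or in the exclusion log under the
#' first rule that removed it; nothing is silently lost. Variants with
#' missing EAF pass the MAF filter (frequency-based exclusion is the
#' harmonization stage's job).
#'
#' @inheritParams ld_clump
#' @return List with `selected` (character vector of instrument ids, in
#'   the table's order) and `log` (data frame `snp_id`, `rule`, `value`
#'   for every excluded variant; rules are `p_threshold`, `maf`, `clump`,
#'   `f_stat`). Zero survivors is a valid result (the caller marks the
#'   exposure untestable), not an error.
#' @export
select_instruments <- function(stats, panel = NULL,
                               criteria = instrument_criteria()) {
  lg <- data.frame(snp_id = character(0), rule = character(0),
                   value = numeric(0), stringsAsFactors = FALSE)
  note <- function(ids, rule, value) {
    if (length(ids))
      lg <<- rbind(lg, data.frame(snp_id = ids, rule = rule, value = value,
                                  stringsAsFactors = FALSE))
  }
  s <- stats
  drop <- s$pval >= criteria$p_threshold
  note(s$snp_id[drop], "p_threshold", s$pval[drop])
  s <- s[!drop, , drop = FALSE]

  maf <- pmin(s$eaf, 1 - s$eaf)
  drop <- !is.na(maf) & maf < criteria$maf_min
  note(s$snp_id[drop], "maf", maf[drop])
  s <- s[!drop, , drop = FALSE]

  if (nrow(s)) {
    kept <- ld_clump(s, panel, criteria)
    drop <- !(s$snp_id %in% kept)
    note(s$snp_id[drop], "clump", NA_real_)
    s <- s[!drop, , drop = FALSE]
  }

  f <- if (nrow(s)) f_statistic(s$beta, s$se) else numeric(0)
  drop <- f < criteria$f_min
  note(s$snp_id[drop], "f_stat", f[drop])
  s <- s[!drop, , drop = FALSE]

  list(selected = s$snp_id, log = lg)
}
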