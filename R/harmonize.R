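allele_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every shared variant to the exposure's effect allele. For
#' non-palindromic variants: identical alleles are kept; swapped alleles
#' flip the outcome beta's sign (and complement its EAF); strand
#' complements are tried before a pair is declared incompatible.
#' Palindromic (A/T, C/G) variants cannot be resolved from alleles, so
#' allele frequencies decide: a variant is dropped if either EAF is
#' missing or falls inside the ambiguity band around 0.5; otherwise EAFs
#' on the same side of 0.5 keep the pair and opposite sides flip it.
#'
#' @param exposure,outcome Summary-statistics data frames (see
#'   [validate_sumstats()]).
#' @param ambiguity_band Half-width of the frequency band around 0.5
#'   inside which a palindromic variant is considered unresolvable
#'   (default 0.08, i.e. EAF in \[0.42, 0.58\] is ambiguous).
#' @return A data frame of class `harmonized_pairs`, one row per shared
#'   variant id, with exposure/outcome betas, SEs, EAFs, p-values and
#'   sample sizes, an `action` column (`kept`, `flipped`, `dropped`) and
#'   a `drop_reason` (`incompatible_alleles`, `palindromic_no_freq`,
#'   `palindromic_ambiguous`, or `""`). Rows with `action == "dropped"`
#'   never reach the estimators ([mr_fit()] subsets them away).
#' @export
harmonize <- function(exposure, outcome, ambiguity_band = 0.08) {
  stopifnot(ambiguity_band >= 0, ambiguity_band < 0.5)
  if (anyDuplicated(exposure$snp_id) || anyDuplicated(outcome$snp_id))
    stop("duplicate snp_id on ingest")
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0) {
    warning("exposure and outcome share no variant ids")
    shared <- character(0)
  }
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]
  k <- length(shared)

  action <- rep("kept", k)
  reason <- rep("", k)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  for (i in seq_len(k)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (pal[i]) {
      # palindromic in the exposure: outcome alleles must be the same
      # (or complemented == swapped) pair, else incompatible
      if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        action[i] <- "dropped"; reason[i] <- "incompatible_alleles"
        next
      }
      fx <- ex$eaf[i]; fy <- ou$eaf[i]
      if (is.na(fx) || is.na(fy)) {
        action[i] <- "dropped"; reason[i] <- "palindromic_no_freq"
        next
      }
      lo <- 0.5 - ambiguity_band; hi <- 0.5 + ambiguity_band
      if ((fx >= lo && fx <= hi) || (fy >= lo && fy <= hi)) {
        action[i] <- "dropped"; reason[i] <- "palindromic_ambiguous"
        next
      }
      if ((fx > 0.5) != (fy > 0.5)) {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    } else {
      same <- function(a, b) a[1] == b[1] && a[2] == b[2]
      x <- c(ea_x, oa_x)
      y <- c(ea_y, oa_y)
      yc <- allele_complement(y)
      if (same(y, x) || same(yc, x)) {
        # aligned (directly or after strand complement): keep
      } else if (same(rev(y), x) || same(rev(yc), x)) {
        action[i] <- "flipped"
        beta_out[i] <- -beta_out[i]
        if (!is.na(eaf_out[i])) eaf_out[i] <- 1 - eaf_out[i]
      } else {
        action[i] <- "dropped"; reason[i] <- "incompatible_alleles"
      }
    }
  }

  out <- data.frame(
    snp_id = shared,
    chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exp = ex$beta, se_exp = ex$se, pval_exp = ex$pval,
    eaf_exp = ex$eaf, n_exp = ex$n,
    beta_out = beta_out, se_out = ou$se, pval_out = ou$pval,
    eaf_out = eaf_out, n_out = ou$n,
    action = action, drop_reason = reason,
    stringsAsFactors = FALSE)
  class(out) <- c("harmonized_pairs", "data.frame")
  out
}

#' Write the harmonization audit trail
#'
#' @param pairs A `harmonized_pairs` data frame from [harmonize()].
#' @param path Output TSV path (`snp_id`, `action`, `drop_reason`).
#' @return `path`, invisibly.
#' @export
write_harmonization_audit <- function(pairs, path) {
  write.table(pairs[, c("snp_id", "action", "drop_reason")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# rows usable by estimators
usable_pairs <- function(pairs) {
  p <- pairs[pairs$action != "dropped", , drop = FALSE]
  rownames(p) <- NULL
  p
}
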