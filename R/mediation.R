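#' Two-step MR mediation with delta-method inference
#'
#' Decomposes a total causal effect (beta_all) into the indirect path
#' through a mediator: beta12 = beta1 * beta2 (exposure -> mediator times
#' mediator -> outcome), with the first-order delta-method standard error
#' sqrt(beta1^2 se2^2 + beta2^2 se1^2), a two-sided normal p-value, and
#' the mediation proportion beta12 / beta_all (reported as a percentage
#' by `print`). The two legs are treated as independent, matching the
#' two-sample design where they come from different instrument sets and
#' cohorts.
#'
#' The proportion CI divides the beta12 CI by a fixed beta_all by
#' default; `proportion_ci = "full_delta"` instead propagates se_all
#' through the ratio (first-order, independent estimates). The variance
#' of the product can include the exact second-order term with
#' `exact_product = TRUE`.
#'
#' @param beta_all,se_all Total-effect estimate and SE.
#' @param beta1,se1 Exposure -> mediator estimate and SE.
#' @param beta2,se2 Mediator -> outcome estimate and SE.
#' @param exposure,mediator,outcome Optional identifiers.
#' @param proportion_ci `"fixed_total"` (default) or `"full_delta"`.
#' @param exact_product Include the se1^2 se2^2 term in var(beta12).
#' @param level Confidence level.
#' @return Object of class `mr_mediation` (also a one-row data frame):
#'   `beta_all`, `se_all`, `beta1`, `se1`, `beta2`, `se2`, `beta12`,
#'   `se12`, `ci12_low`, `ci12_high`, `p12`, `proportion`,
#'   `proportion_ci_low`, `proportion_ci_high`. With `beta_all = 0` the
#'   mediation effect is still returned and the proportion is `NA`.
#' @examples
#' # a worked decomposition: total 0.131, legs 0.208 and 0.113
#' m <- mr_mediation(0.131, 0.03, 0.208, 0.05, 0.113, 0.03)
#' m$proportion * 100  # percent mediated
#' @export
mr_mediation <- function(beta_all, se_all, beta1, se1, beta2, se2,
                         exposure = NA_character_,
                         mediator = NA_character_,
                         outcome = NA_character_,
                         proportion_ci = c("fixed_total", "full_delta"),
                         exact_product = FALSE, level = 0.95) {
  proportion_ci <- match.arg(proportion_ci)
  stopifnot(se_all > 0, se1 > 0, se2 > 0)
  z <- qnorm(1 - (1 - level) / 2)
  beta12 <- beta1 * beta2
  v12 <- beta1^2 * se2^2 + beta2^2 * se1^2
  if (exact_product) v12 <- v12 + se1^2 * se2^2
  se12 <- sqrt(v12)
  p12 <- if (se12 == 0) as.numeric(beta12 != 0) else
    2 * pnorm(-abs(beta12 / se12))
  if (beta12 == 0) p12 <- 1
  ci12 <- beta12 + c(-1, 1) * z * se12
  if (beta_all != 0) {
    proportion <- beta12 / beta_all
    if (proportion_ci == "fixed_total") {
      pci <- sort(ci12 / beta_all)
    } else {
      se_prop <- sqrt(v12 / beta_all^2 +
                        beta12^2 * se_all^2 / beta_all^4)
      pci <- proportion + c(-1, 1) * z * se_prop
    }
  } else {
    proportion <- NA_real_
    pci <- c(NA_real_, NA_real_)
  }
  out <- data.frame(exposure_id = exposure, mediator_id = mediator,
                    outcome_id = outcome,
                    beta_all = beta_all, se_all = se_all,
                    beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                    beta12 = beta12, se12 = se12,
                    ci12_low = ci12[1], ci12_high = ci12[2], p12 = p12,
                    proportion = proportion,
                    proportion_ci_low = pci[1], proportion_ci_high = pci[2],
                    stringsAsFactors = FALSE)
  class(out) <- c("mr_mediation", "data.frame")
  out
}

#' @export
print.mr_mediation <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    lab <- if (!is.na(x$exposure_id[i]))
      sprintf("%s -[%s]-> %s", x$exposure_id[i], x$mediator_id[i],
              x$outcome_id[i]) else "mediation"
    cat(sprintf(
      "%s: beta_all %.3f, beta1 %.3f, beta2 %.3f, beta12 %.4f (se %.4f)\n",
      lab, x$beta_all[i], x$beta1[i], x$beta2[i], x$beta12[i], x$se12[i]))
    if (is.na(x$proportion[i])) {
      cat("  proportion mediated: undefined (total effect is zero),")
    } else {
      cat(sprintf("  proportion mediated: %.1f%% (%.1f%%, %.1f%%),",
                  100 * x$proportion[i], 100 * x$proportion_ci_low[i],
                  100 * x$proportion_ci_high[i]))
    }
    cat(sprintf(" p = %.3f\n", x$p12[i]))
  }
  invisible(x)
}

#' Screen mediation results
#'
#' Keeps results with mediation p below `p_max` and mediation proportion
#' above `proportion_min` (so negative-proportion results - inconsistent
#' mediation - never pass), ordered by ascending p.
#'
#' @param results An `mr_mediation` frame (rows stackable via `rbind`).
#' @param p_max Maximum mediation p-value (default 0.05).
#' @param proportion_min Minimum mediation proportion (default 0.15).
#' @return The retained rows, ordered by `p12`.
#' @export
screen_mediators <- function(results, p_max = 0.05, proportion_min = 0.15) {
  keep <- !is.na(results$p12) & results$p12 < p_max &
    !is.na(results$proportion) & results$proportion > proportion_min
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$p12), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a mediation results table
#'
#' @param results `mr_mediation` rows.
#' @param path Output TSV path.
#' @export
write_mediation_table <- function(results, path) {
  tab <- data.frame(
    exposure = results$exposure_id, mediator = results$mediator_id,
    beta_all = results$beta_all, beta1 = results$beta1,
    beta2 = results$beta2,
    proportion = sprintf("%.1f%%", 100 * results$proportion),
    proportion_ci = sprintf("(%.1f%%, %.1f%%)",
                            100 * results$proportion_ci_low,
                            100 * results$proportion_ci_high),
    p = results$p12, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
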