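#' Cochran's Q heterogeneity test
#'
#' Q = sum of w_i (ratio_i - beta_FE)^2 over per-variant Wald ratios,
#' with first-order inverse-variance weights and the fixed-effect IVW
#' estimate as centre; chi-square on nsnp - 1 df under homogeneity.
#'
#' @param pairs Harmonized pairs (>= 2 usable rows; a single variant
#'   returns an NA record rather than an error).
#' @return List `q_stat`, `q_df`, `q_pval`.
#' @export
cochran_q <- function(pairs) {
  p <- pairs_in(pairs, 1, "cochran_q")
  if (nrow(p) < 2)
    return(list(q_stat = NA_real_, q_df = 0L, q_pval = NA_real_))
  rs <- ratio_stats(p)
  w <- 1 / rs$se^2
  beta_fe <- sum(w * rs$ratio) / sum(w)
  q <- sum(w * (rs$ratio - beta_fe)^2)
  df <- nrow(p) - 1L
  list(q_stat = q, q_df = df, q_pval = pchisq(q, df, lower.tail = FALSE))
}

#' Egger intercept test for directional pleiotropy
#'
#' Exposes the intercept of the MR-Egger fit as a test: p > 0.05 is read
#' as no detected directional pleiotropy.
#'
#' @param pairs Harmonized pairs (>= 3 usable rows).
#' @return List `intercept`, `se`, `p`.
#' @export
egger_intercept <- function(pairs) {
  e <- mr_egger(pairs)
  list(intercept = e$egger_intercept, se = e$egger_intercept_se,
       p = e$egger_intercept_p)
}

# leave-one-out IVW slopes and weighted squared residuals for bx fixed,
# arbitrary outcome-beta matrix Y (rows = replicates); returns per-variant
# residual contributions D (replicates x k) under the LOO fit
presso_rss_parts <- function(bx, Y, w) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  wb <- w * bx
  S2 <- sum(w * bx^2)
  S1 <- Y %*% wb                          # replicates x 1
  num <- sweep(Y, 2, wb, `*`)             # w_i bx_i y_i
  beta_loo <- (as.vector(S1) - num) / rep(S2 - wb * bx, each = nrow(Y))
  resid <- Y - sweep(beta_loo, 2, bx, `*`)
  sweep(resid^2, 2, w, `*`)
}

#' MR-PRESSO: residual-sum-of-squares outlier detection
#'
#' Global test: the observed weighted residual sum of squares of the
#' leave-one-out IVW fits is compared against its null distribution from
#' `n_sim` parametric simulations of the outcome betas under the fitted
#' model (exposure betas held fixed - the conditional model under which
#' the statistic is exactly calibrated for the weights used). Outlier
#' test: each variant's observed squared residual against its simulated
#' null, thresholded Bonferroni-style at `outlier_p_threshold` (default
#' 0.05 / nsnp). When outliers are found the IVW estimate is recomputed
#' without them, and a distortion test compares the shift against the
#' distribution of shifts from removing equally many variants at random.
#'
#' @param pairs Harmonized pairs (>= 4 usable rows; fewer returns an NA
#'   record marked not-applicable).
#' @param n_sim Number of null simulations (>= 1000).
#' @param outlier_p_threshold Per-variant outlier p threshold; `NULL`
#'   (default) means 0.05 / nsnp.
#' @param seed Integer seed; results are deterministic given seed and
#'   `n_sim`.
#' @return List `global_p`, `outlier_ids`, `corrected` (one-row IVW
#'   estimate frame or `NULL`), `distortion_p`, `outlier_pvals`.
#' @export
mr_presso <- function(pairs, n_sim = 5000, outlier_p_threshold = NULL,
                      seed = 1L) {
  p <- pairs_in(pairs, 1, "mr_presso")
  k <- nrow(p)
  if (k < 4)
    return(list(global_p = NA_real_, outlier_ids = character(0),
                corrected = NULL, distortion_p = NA_real_,
                outlier_pvals = setNames(rep(NA_real_, k), p$snp_id),
                rss_obs = NA_real_, applicable = FALSE))
  if (n_sim < 1000) stop("n_sim must be >= 1000")
  if (is.null(outlier_p_threshold)) outlier_p_threshold <- 0.05 / k
  bx <- p$beta_exp
  by <- p$beta_out
  w <- 1 / p$se_out^2
  if (sd(by) == 0 && sd(bx) == 0)
    stop("degenerate zero-variance input")

  D_obs <- drop(presso_rss_parts(bx, by, w))
  rss_obs <- sum(D_obs)

  # LOO fitted means for the null simulations
  wb <- w * bx
  S2 <- sum(w * bx^2)
  S1 <- sum(wb * by)
  beta_loo <- (S1 - wb * by) / (S2 - wb * bx)
  mu <- beta_loo * bx

  res <- with_seed(seed, {
    Y <- matrix(rnorm(n_sim * k, mean = rep(mu, each = n_sim),
                      sd = rep(p$se_out, each = n_sim)), nrow = n_sim)
    D_sim <- presso_rss_parts(bx, Y, w)
    rss_sim <- rowSums(D_sim)
    global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    out_p <- (1 + colSums(D_sim >= rep(D_obs, each = n_sim))) / (n_sim + 1)
    list(global_p = global_p, out_p = out_p)
  })
  out_p <- setNames(res$out_p, p$snp_id)
  outlier <- out_p < outlier_p_threshold
  corrected <- NULL
  distortion_p <- NA_real_
  if (any(outlier) && sum(!outlier) >= 1) {
    corrected <- mr_ivw(p[!outlier, , drop = FALSE])
    orig <- mr_ivw(p)
    d_obs <- (orig$beta - corrected$beta) / abs(corrected$beta)
    distortion_p <- with_seed(child_seed(seed, 1L), {
      n_keep <- sum(!outlier)
      num_i <- w * bx * by
      den_i <- w * bx^2
      d_sim <- vapply(seq_len(n_sim), function(s) {
        idx <- sample.int(k, n_keep)
        b <- sum(num_i[idx]) / sum(den_i[idx])
        (orig$beta - b) / abs(b)
      }, numeric(1))
      (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
    })
  }
  list(global_p = res$global_p, outlier_ids = p$snp_id[outlier],
       corrected = corrected, distortion_p = distortion_p,
       outlier_pvals = out_p, rss_obs = rss_obs, applicable = TRUE)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against
#' the outcome. Per-variant r^2 is recovered from the Wald t statistic,
#' r^2 = t^2 / (t^2 + n - 2) (for binary outcomes the same form applied
#' to the log-odds Wald statistic, a liability-scale approximation);
#' instrument r^2 are summed per trait. The direction is TRUE when the
#' exposure sum exceeds the outcome sum; the p-value is a two-sided z
#' test on the difference of Fisher-transformed pooled correlations.
#'
#' @param pairs Harmonized pairs with `n_exp`/`n_out` columns, or supply
#'   `n_exp`/`n_out` scalars.
#' @param n_exp,n_out Per-trait sample sizes (default: medians of the
#'   table's columns).
#' @return List `direction` (logical), `p`, `r2_exp`, `r2_out`.
#' @export
steiger_test <- function(pairs, n_exp = NULL, n_out = NULL) {
  p <- pairs_in(pairs, 1, "steiger")
  n_exp <- n_exp %||% (if (!is.null(p$n_exp)) median(p$n_exp) else
    stop("sample_size_required: supply n_exp"))
  n_out <- n_out %||% (if (!is.null(p$n_out)) median(p$n_out) else
    stop("sample_size_required: supply n_out"))
  if (!is.finite(n_exp) || !is.finite(n_out))
    stop("sample_size_required: missing sample size")
  r2_of <- function(beta, se, n) {
    t2 <- (beta / se)^2
    t2 / (t2 + n - 2)
  }
  r2x <- min(sum(r2_of(p$beta_exp, p$se_exp, n_exp)), 0.999)
  r2y <- min(sum(r2_of(p$beta_out, p$se_out, n_out)), 0.999)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(direction = r2x > r2y, p = 2 * pnorm(-abs(z)),
       r2_exp = r2x, r2_out = r2y)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the (random-effects) IVW slope omitting each variant in
#' turn and flags omissions that change the estimate's sign or move it
#' across the 0.05 significance boundary.
#'
#' @param pairs Harmonized pairs (>= 3 usable rows).
#' @return Data frame with one row per omitted variant: `snp_id`, `beta`,
#'   `se`, `pval`, `sign_change`, `significance_change`.
#' @export
leave_one_out <- function(pairs) {
  p <- pairs_in(pairs, 3, "leave_one_out")
  full <- mr_ivw(p)
  rows <- lapply(seq_len(nrow(p)), function(i) {
    e <- mr_ivw(p[-i, , drop = FALSE])
    data.frame(snp_id = p$snp_id[i], beta = e$beta, se = e$se,
               pval = e$pval,
               sign_change = sign(e$beta) != sign(full$beta),
               significance_change = (e$pval < 0.05) != (full$pval < 0.05),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full sensitivity report for an MR fit
#'
#' Bundles Cochran's Q, the Egger intercept test, MR-PRESSO, the Steiger
#' directionality test and the leave-one-out table into one report.
#'
#' @param fit An [mr_fit()] object, or a harmonized pairs data frame.
#' @param n_exp,n_out Sample sizes for the Steiger test (defaults from
#'   the pairs table when present).
#' @param presso_n_sim,presso_seed MR-PRESSO settings.
#' @param run_presso Set `FALSE` to skip the (simulation-based) PRESSO
#'   stage.
#' @return An object of class `mr_sensitivity`.
#' @export
mr_sensitivity <- function(fit, n_exp = NULL, n_out = NULL,
                           presso_n_sim = 5000, presso_seed = 1L,
                           run_presso = TRUE) {
  p <- if (inherits(fit, "mr_fit")) fit$data else fit
  p <- if (!is.null(p$action)) usable_pairs(p) else p
  k <- nrow(p)
  q <- cochran_q(p)
  eg <- if (k >= 3) egger_intercept(p) else
    list(intercept = NA_real_, se = NA_real_, p = NA_real_)
  pr <- if (run_presso) mr_presso(p, n_sim = presso_n_sim,
                                  seed = presso_seed) else
    list(global_p = NA_real_, outlier_ids = character(0), corrected = NULL,
         distortion_p = NA_real_, rss_obs = NA_real_, applicable = FALSE)
  st <- tryCatch(steiger_test(p, n_exp, n_out),
                 error = function(e) list(direction = NA, p = NA_real_,
                                          r2_exp = NA_real_,
                                          r2_out = NA_real_))
  loo <- if (k >= 3) leave_one_out(p) else NULL
  structure(list(nsnp = k, q = q, egger_intercept = eg, presso = pr,
                 steiger = st, loo = loo,
                 lead_snp = p$snp_id[which.min(p$pval_exp)] %||% NA),
            class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("MR sensitivity report (", x$nsnp, " instruments)\n", sep = "")
  cat(sprintf("  Cochran Q: %.3f on %d df, p = %.3g\n",
              x$q$q_stat, x$q$q_df, x$q$q_pval))
  cat(sprintf("  Egger intercept: %.4g, p = %.3g\n",
              x$egger_intercept$intercept, x$egger_intercept$p))
  if (isTRUE(x$presso$applicable)) {
    cat(sprintf("  MR-PRESSO global p = %.3g; outliers: %s\n",
                x$presso$global_p,
                if (length(x$presso$outlier_ids))
                  paste(x$presso$outlier_ids, collapse = ", ") else "none"))
  }
  cat(sprintf("  Steiger direction: %s (p = %.3g)\n",
              x$steiger$direction, x$steiger$p))
  invisible(x)
}

#' Sensitivity gate configuration and evaluation
#'
#' The pipeline retains an exposure when (each criterion individually
#' switchable): heterogeneity is absent (Q p > alpha) or a
#' random-effects IVW absorbs it; the Egger intercept p > alpha; the
#' PRESSO global p > alpha or the outlier-corrected estimate agrees in
#' sign with the original; and the Steiger direction is TRUE.
#'
#' @param heterogeneity,pleiotropy,presso,steiger Logical switches.
#' @param alpha Significance level for the component tests.
#' @export
gate_config <- function(heterogeneity = TRUE, pleiotropy = TRUE,
                        presso = TRUE, steiger = TRUE, alpha = 0.05) {
  structure(list(heterogeneity = heterogeneity, pleiotropy = pleiotropy,
                 presso = presso, steiger = steiger, alpha = alpha),
            class = "gate_config")
}

#' @rdname gate_config
#' @param report An `mr_sensitivity` report.
#' @param config A `gate_config`.
#' @param ivw_model The IVW model used by the fit (`"random"` satisfies
#'   the heterogeneity criterion by construction).
#' @param ivw_beta The IVW point estimate (for PRESSO sign concordance).
#' @return Logical: does the report pass the gate?
#' @export
sensitivity_gate <- function(report, config = gate_config(),
                             ivw_model = "random", ivw_beta = NA_real_) {
  ok <- TRUE
  if (config$heterogeneity) {
    het_ok <- ivw_model == "random" ||
      (!is.na(report$q$q_pval) && report$q$q_pval > config$alpha) ||
      is.na(report$q$q_pval)
    ok <- ok && het_ok
  }
  if (config$pleiotropy) {
    pk <- report$egger_intercept$p
    ok <- ok && (is.na(pk) || pk > config$alpha)
  }
  if (config$presso && isTRUE(report$presso$applicable)) {
    pg <- report$presso$global_p
    presso_ok <- (!is.na(pg) && pg > config$alpha) ||
      (!is.null(report$presso$corrected) && !is.na(ivw_beta) &&
         sign(report$presso$corrected$beta) == sign(ivw_beta))
    ok <- ok && presso_ok
  }
  if (config$steiger)
    ok <- ok && isTRUE(report$steiger$direction)
  ok
}

#' Write the sensitivity table for a set of fitted edges
#'
#' One row per exposure/outcome pair: lead instrument (smallest exposure
#' p), Steiger direction and p, heterogeneity p, pleiotropy p.
#'
#' @param reports Named list of `mr_sensitivity` objects.
#' @param path Output TSV path.
#' @export
write_sensitivity_table <- function(reports, path) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(pair = nm, snp = r$lead_snp,
               steiger_direction = r$steiger$direction,
               steiger_p = r$steiger$p,
               heterogeneity_p = r$q$q_pval,
               pleiotropy_p = r$egger_intercept$p,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
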