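#' Fit two-sample Mendelian randomization estimators
#'
#' The package's central fitting function. Takes harmonized
#' exposure/outcome pairs (from [harmonize()] or [simulate_sumstats()])
#' and computes the requested causal-effect estimators: inverse-variance
#' weighted (the primary method), MR-Egger, weighted median, and the
#' simple and weighted mode. Returns a classed object with the usual
#' modelling methods (`print`, `summary`, `coef`, `confint`, `plot`,
#' `residuals`, `simulate`).
#'
#' @param pairs Harmonized pairs data frame (columns `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`; rows with `action == "dropped"` are
#'   ignored).
#' @param methods Estimators to fit. Estimators whose minimum instrument
#'   count exceeds the data are skipped with a note in `$skipped` rather
#'   than failing the whole fit.
#' @param ivw_model `"random"` (multiplicative random-effects SE, the
#'   default) or `"fixed"`.
#' @param bandwidth_factor,n_boot,seed Passed to the bootstrap/mode
#'   estimators; the seed makes all bootstrap results bit-reproducible.
#' @param exposure,outcome Optional trait labels carried into printed
#'   output.
#' @return An object of class `mr_fit`: list with `estimates` (stacked
#'   one-row estimate frames), `data` (the usable pairs), `nsnp`,
#'   `skipped`, `call`.
#' @examples
#' pairs <- simulate_sumstats(n_snps = 20, theta = 0.15, seed = 7)
#' fit <- mr_fit(pairs, seed = 7)
#' coef(fit)
#' @export
mr_fit <- function(pairs,
                   methods = c("ivw", "egger", "weighted_median",
                               "simple_mode", "weighted_mode"),
                   ivw_model = c("random", "fixed"),
                   bandwidth_factor = 1, n_boot = 1000, seed = 1L,
                   exposure = NULL, outcome = NULL) {
  ivw_model <- match.arg(ivw_model)
  methods <- match.arg(methods, several.ok = TRUE)
  p <- if (!is.null(pairs$action)) usable_pairs(pairs) else pairs
  if (nrow(p) == 0) stop("no usable variants to fit")
  est <- list()
  skipped <- character(0)
  try_est <- function(name, min_n, fun) {
    if (nrow(p) < min_n) {
      skipped <<- c(skipped, name)
    } else {
      est[[length(est) + 1]] <<- fun()
    }
  }
  if ("ivw" %in% methods)
    try_est("ivw", 1, function() mr_ivw(p, model = ivw_model))
  if ("egger" %in% methods)
    try_est("egger", 3, function() mr_egger(p))
  if ("weighted_median" %in% methods)
    try_est("weighted_median", 3,
            function() mr_weighted_median(p, n_boot = n_boot, seed = seed))
  if (any(c("simple_mode", "weighted_mode") %in% methods)) {
    if (nrow(p) < 3) {
      skipped <- c(skipped, intersect(methods,
                                      c("simple_mode", "weighted_mode")))
    } else {
      md <- mr_mode(p, bandwidth_factor = bandwidth_factor,
                    n_boot = n_boot, seed = seed)
      est[[length(est) + 1]] <-
        md[md$method %in% methods, , drop = FALSE]
    }
  }
  estimates <- do.call(rbind, est)
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, data = p, nsnp = nrow(p),
                 skipped = skipped, exposure = exposure, outcome = outcome,
                 ivw_model = ivw_model, seed = seed,
                 call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  hdr <- "Two-sample MR fit"
  if (!is.null(x$exposure) || !is.null(x$outcome))
    hdr <- sprintf("%s: %s -> %s", hdr, x$exposure %||% "exposure",
                   x$outcome %||% "outcome")
  cat(hdr, sprintf("(%d instruments)\n", x$nsnp))
  e <- x$estimates
  tab <- data.frame(method = e$method, nsnp = e$nsnp,
                    beta = signif(e$beta, digits),
                    se = signif(e$se, digits),
                    p = signif(e$pval, digits),
                    OR = round(e$or, 3),
                    `OR 95% CI` = sprintf("(%.2f, %.2f)", e$or_ci_low,
                                          e$or_ci_high),
                    check.names = FALSE)
  print(tab, row.names = FALSE)
  if (length(x$skipped))
    cat("skipped (too few instruments):",
        paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  e <- object$estimates
  ci <- cbind(e$beta - z * e$se, e$beta + z * e$se)
  dimnames(ci) <- list(e$method,
                       sprintf("%.1f %%", c((1 - level) / 2,
                                            1 - (1 - level) / 2) * 100))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Summarize an MR fit with its sensitivity diagnostics
#'
#' Attaches Cochran's Q and the Egger intercept test to the estimate
#' table.
#'
#' @param object An `mr_fit`.
#' @param ... Unused.
#' @export
summary.mr_fit <- function(object, ...) {
  q <- if (object$nsnp >= 2) cochran_q(object$data) else NULL
  eg <- if (object$nsnp >= 3) egger_intercept(object$data) else NULL
  structure(list(fit = object, q = q, egger_intercept = eg),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$q))
    cat(sprintf("Heterogeneity: Q = %.3f on %d df, p = %.3g\n",
                x$q$q_stat, x$q$q_df, x$q$q_pval))
  if (!is.null(x$egger_intercept))
    cat(sprintf("Egger intercept: %.4g (se %.3g), p = %.3g\n",
                x$egger_intercept$intercept, x$egger_intercept$se,
                x$egger_intercept$p))
  invisible(x)
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  b <- object$estimates$beta[object$estimates$method == method]
  if (!length(b)) stop("method not in fit: ", method)
  if (method == "egger") {
    flip <- ifelse(object$data$beta_exp < 0, -1, 1)
    a <- object$estimates$egger_intercept[object$estimates$method == "egger"]
    return(setNames(object$data$beta_out * flip -
                      (a + b * object$data$beta_exp * flip),
                    object$data$snp_id))
  }
  setNames(object$data$beta_out - b * object$data$beta_exp,
           object$data$snp_id)
}

#' Simulate outcome betas under a fitted IVW model
#'
#' Parametric simulation used for diagnostics: outcome betas drawn from
#' Normal(beta_ivw * beta_exp, se_out), exposure betas held fixed.
#'
#' @param object An `mr_fit`.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of `nsim` pairs data frames.
#' @export
simulate.mr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  b <- object$estimates$beta[object$estimates$method == "ivw"]
  if (!length(b)) stop("simulate needs an ivw estimate in the fit")
  d <- object$data
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      d2 <- d
      d2$beta_out <- rnorm(nrow(d), b * d$beta_exp, d$se_out)
      d2
    })
  })
}

#' Scatter plot of an MR fit
#'
#' Outcome betas against exposure betas with +-1.96 SE bars and one
#' fitted line per estimator (Egger with its intercept, all others
#' through the origin).
#'
#' @param x An `mr_fit`.
#' @param ... Passed to `plot()`.
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  flip <- ifelse(d$beta_exp < 0, -1, 1)
  bx <- d$beta_exp * flip
  by <- d$beta_out * flip
  plot(bx, by, xlab = "effect on exposure", ylab = "effect on outcome",
       pch = 19, ...)
  segments(bx, by - 1.96 * d$se_out, bx, by + 1.96 * d$se_out,
           col = "grey60")
  segments(bx - 1.96 * d$se_exp, by, bx + 1.96 * d$se_exp, by,
           col = "grey60")
  e <- x$estimates
  cols <- seq_len(nrow(e)) + 1
  for (i in seq_len(nrow(e))) {
    if (e$method[i] == "egger")
      abline(a = e$egger_intercept[i], b = e$beta[i], col = cols[i])
    else abline(a = 0, b = e$beta[i], col = cols[i])
  }
  legend("topleft", legend = e$method, col = cols, lty = 1, bty = "n")
  invisible(x)
}
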