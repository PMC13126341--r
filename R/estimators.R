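# All estimators consume harmonized pairs: a data frame with columns
# beta_exp, se_exp, beta_out, se_out (dropped rows are removed first when
# an action column is present). Each returns a one-row data frame in the
# common estimate layout so mr_fit() can stack them.

estimate_row <- function(method, nsnp, beta, se,
                         pval = 2 * pnorm(-abs(beta / se)),
                         intercept = NA_real_, intercept_se = NA_real_,
                         intercept_p = NA_real_) {
  orx <- or_from_beta(beta, se)
  data.frame(method = method, nsnp = as.integer(nsnp),
             beta = beta, se = se, pval = pval,
             or = orx$or, or_ci_low = orx$ci_low, or_ci_high = orx$ci_high,
             egger_intercept = intercept, egger_intercept_se = intercept_se,
             egger_intercept_p = intercept_p,
             stringsAsFactors = FALSE)
}

pairs_in <- function(pairs, min_n, method) {
  if (!is.null(pairs$action)) pairs <- usable_pairs(pairs)
  if (nrow(pairs) < min_n)
    stop("insufficient_instruments: ", method, " needs >= ", min_n,
         " variants, got ", nrow(pairs))
  if (any(pairs$se_out <= 0) || any(pairs$se_exp < 0))
    stop("standard errors must be positive")
  pairs
}

#' Odds-ratio transform of a log-odds estimate
#'
#' @param beta Log odds ratio.
#' @param se Its standard error (> 0).
#' @param level Confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high` (`exp(beta +- z * se)`).
#' @export
or_from_beta <- function(beta, se, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  list(or = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se))
}

#' Wald ratio for a single variant
#'
#' The per-variant causal estimate beta_out / beta_exp with the
#' first-order standard error se_out / |beta_exp| (the second-order term
#' is negligible at the instrument strengths, F >= 10, the selection
#' stage guarantees).
#'
#' @param pairs Harmonized pairs (one usable row).
#' @return One-row estimate data frame (`method = "wald_ratio"`).
#' @export
wald_ratio <- function(pairs) {
  p <- pairs_in(pairs, 1, "wald_ratio")
  if (nrow(p) != 1) stop("wald_ratio takes exactly one variant")
  if (p$beta_exp == 0) stop("beta_exp is zero; Wald ratio undefined")
  estimate_row("wald_ratio", 1L, p$beta_out / p$beta_exp,
               p$se_out / abs(p$beta_exp))
}

# first-order Wald-ratio variances; used as weights by the median/mode
# estimators and Cochran's Q
ratio_stats <- function(p) {
  list(ratio = p$beta_out / p$beta_exp,
       se = p$se_out / abs(p$beta_exp))
}

#' Inverse-variance-weighted estimator
#'
#' The slope of the zero-intercept regression of outcome betas on
#' exposure betas with weights 1/se_out^2 - equivalently the
#' inverse-variance-weighted mean of per-variant Wald ratios. The default
#' standard error uses a multiplicative random-effects residual scale
#' floored at 1 (underdispersion never shrinks the SE); `"fixed"` gives
#' the fixed-effect SE. A single variant delegates to the Wald ratio but
#' is still reported as `ivw`.
#'
#' @param pairs Harmonized pairs (>= 1 usable row).
#' @param model `"random"` (default) or `"fixed"`.
#' @return One-row estimate data frame.
#' @export
mr_ivw <- function(pairs, model = c("random", "fixed")) {
  model <- match.arg(model)
  p <- pairs_in(pairs, 1, "ivw")
  if (all(p$beta_exp == 0)) stop("all exposure betas are zero")
  k <- nrow(p)
  if (k == 1) {
    w <- wald_ratio(p)
    w$method <- "ivw"
    return(w)
  }
  w <- 1 / p$se_out^2
  s2 <- sum(w * p$beta_exp^2)
  beta <- sum(w * p$beta_exp * p$beta_out) / s2
  se <- sqrt(1 / s2)
  if (model == "random") {
    sigma2 <- sum(w * (p$beta_out - beta * p$beta_exp)^2) / (k - 1)
    se <- se * sqrt(max(1, sigma2))
  }
  estimate_row("ivw", k, beta, se)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights 1/se_out^2), after orienting all exposure betas
#' non-negative. The slope is the pleiotropy-adjusted causal estimate;
#' the intercept estimates directional pleiotropy. Slope inference uses
#' the multiplicative random-effects scale floored at 1 and a t
#' distribution on nsnp - 2 df; the intercept test is the exact weighted
#' least-squares t-test (an exactly calibrated hypothesis test), with a
#' perfect-fit guard: data lying exactly on a line give intercept p = 1.
#'
#' @param pairs Harmonized pairs (>= 3 usable rows).
#' @return One-row estimate data frame with the intercept columns filled.
#' @export
mr_egger <- function(pairs) {
  p <- pairs_in(pairs, 3, "egger")
  k <- nrow(p)
  flip <- ifelse(p$beta_exp < 0, -1, 1)
  bx <- p$beta_exp * flip
  by <- p$beta_out * flip
  w <- 1 / p$se_out^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  cf <- sm$coefficients
  sigma <- sm$sigma
  slope <- cf[2, 1]
  slope_se <- cf[2, 2] / min(1, sigma)
  slope_p <- 2 * pt(-abs(slope / slope_se), k - 2)
  int <- cf[1, 1]
  int_se <- cf[1, 2]
  scale_y <- max(abs(by), 1e-300)
  if (sigma < 1e-8 * scale_y) {
    int_p <- 1  # numerically exact fit: no evidence of pleiotropy
  } else {
    int_p <- cf[1, 4]
  }
  estimate_row("egger", k, slope, slope_se, slope_p,
               intercept = int, intercept_se = int_se, intercept_p = int_p)
}

# interpolated weighted median of x with weights w (sums to 1):
# cumulative weight minus half each point's own, linear interpolation at 0.5
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  j <- max(which(cw < 0.5))
  x[j] + (x[j + 1] - x[j]) * (0.5 - cw[j]) / (cw[j + 1] - cw[j])
}

#' Weighted-median estimator
#'
#' Interpolated weighted median of the per-variant Wald ratios with
#' inverse-variance weights; consistent when at least half the weight
#' comes from valid instruments. The SE comes from a seeded parametric
#' bootstrap (per-variant betas resampled from their normal
#' distributions); the p-value is the normal approximation beta/se.
#'
#' @param pairs Harmonized pairs (>= 3 usable rows).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row estimate data frame.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = 1L) {
  p <- pairs_in(pairs, 3, "weighted_median")
  rs <- ratio_stats(p)
  w <- 1 / rs$se^2
  beta <- weighted_median_point(rs$ratio, w)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(nrow(p), p$beta_exp, p$se_exp)
      by <- rnorm(nrow(p), p$beta_out, p$se_out)
      bx[bx == 0] <- .Machine$double.eps
      r <- by / bx
      weighted_median_point(r, bx^2 / p$se_out^2)
    }, numeric(1))
  })
  estimate_row("weighted_median", nrow(p), beta, sd(boot))
}

# weighted-kernel-density mode of ratios
density_mode <- function(r, w, bandwidth_factor = 1, n_grid = 512) {
  if (length(unique(r)) == 1) return(r[1])
  s <- min(sd(r), IQR(r) / 1.349)
  if (s <= 0) s <- sd(r)
  h <- bandwidth_factor * 0.9 * s * length(r)^(-1 / 5)
  if (h <= 0) return(median(r))
  d <- density(r, weights = w / sum(w), bw = h, n = n_grid)
  d$x[which.max(d$y)]
}

#' Mode-based estimators
#'
#' Simple and weighted mode of the smoothed empirical density of the
#' per-variant Wald ratios (Gaussian kernel; bandwidth =
#' `bandwidth_factor` x 0.9 x min(SD, IQR/1.349) x k^(-1/5)). The simple
#' mode weights ratios equally; the weighted mode uses inverse-variance
#' weights. SEs come from a shared seeded parametric bootstrap; p-values
#' from the normal approximation.
#'
#' @param pairs Harmonized pairs (>= 3 usable rows).
#' @param bandwidth_factor Multiplier on the default bandwidth.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return Two-row estimate data frame (`simple_mode`, `weighted_mode`).
#' @export
mr_mode <- function(pairs, bandwidth_factor = 1, n_boot = 1000, seed = 1L) {
  p <- pairs_in(pairs, 3, "mode")
  k <- nrow(p)
  rs <- ratio_stats(p)
  w_iv <- 1 / rs$se^2
  simple <- density_mode(rs$ratio, rep(1, k), bandwidth_factor)
  weighted <- density_mode(rs$ratio, w_iv, bandwidth_factor)
  boots <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      bx <- rnorm(k, p$beta_exp, p$se_exp)
      by <- rnorm(k, p$beta_out, p$se_out)
      bx[bx == 0] <- .Machine$double.eps
      r <- by / bx
      wb <- bx^2 / p$se_out^2
      out[b, 1] <- density_mode(r, rep(1, k), bandwidth_factor, n_grid = 256)
      out[b, 2] <- density_mode(r, wb, bandwidth_factor, n_grid = 256)
    }
    out
  })
  rbind(estimate_row("simple_mode", k, simple, max(sd(boots[, 1]), 1e-300)),
        estimate_row("weighted_mode", k, weighted,
                     max(sd(boots[, 2]), 1e-300)))
}
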