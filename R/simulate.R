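#' Configure a three-trait summary-statistics simulation
#'
#' Describes a genotype -> exposure -> mediator -> outcome causal chain.
#' `n_snps` variants act as direct instruments for the exposure; the
#' mediator and outcome receive genetic effects only through the chain
#' (plus optional horizontal pleiotropy directly on the outcome). The
#' ground-truth total exposure->outcome effect implied by a configuration
#' is `direct_effect + theta1 * theta2`.
#'
#' @param n_snps Number of variants.
#' @param n_exposure,n_mediator,n_outcome Individuals per trait cohort.
#'   The three cohorts are simulated independently (disjoint individuals),
#'   honouring the two-sample design.
#' @param maf_range Range the per-variant minor-allele frequencies are
#'   drawn from, within (0, 1).
#' @param instrument_effect_sd SD of the per-variant effects on the
#'   exposure (the gamma scale).
#' @param theta1 Exposure -> mediator causal effect.
#' @param theta2 Mediator -> outcome causal effect.
#' @param direct_effect Exposure -> outcome effect not through the
#'   mediator.
#' @param pleiotropy_fraction Fraction of variants given a direct
#'   (horizontal pleiotropic) effect on the outcome.
#' @param pleiotropy_mean,pleiotropy_sd Location and scale of those
#'   pleiotropic effects (mean 0 = balanced, nonzero = directional).
#' @param n_outliers,outlier_multiplier Number of variants whose outcome
#'   beta is multiplied by `outlier_multiplier` after simulation (via
#'   [inject_artifacts()]).
#' @param palindromic_fraction Fraction of variants assigned A/T or C/G
#'   allele pairs.
#' @param noise_sd Length-3 positive vector: residual SD of exposure,
#'   mediator, outcome.
#' @param outcome_type `"continuous"` or `"binary"`. Binary outcomes are
#'   generated from a logistic liability and analysed by per-variant
#'   logistic regression, so outcome betas are log odds ratios.
#' @param case_fraction Approximate case fraction for binary outcomes.
#' @param ld Optional list `list(block_size =, rho =)` switching on
#'   block-correlated genotypes; [simulate_cohort()] then also emits a
#'   matching empirical [ld_panel()].
#' @param seed Integer seed; one global seed fans out to per-stage child
#'   seeds so stages are independently reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_snps = 30,
                       n_exposure = 5000, n_mediator = 5000, n_outcome = 5000,
                       maf_range = c(0.05, 0.5),
                       instrument_effect_sd = 0.15,
                       theta1 = 0.2, theta2 = 0.15, direct_effect = 0,
                       pleiotropy_fraction = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       n_outliers = 0, outlier_multiplier = 1,
                       palindromic_fraction = 0,
                       noise_sd = c(1, 1, 1),
                       outcome_type = c("continuous", "binary"),
                       case_fraction = 0.1,
                       ld = NULL,
                       seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  cfg <- list(n_snps = as.integer(n_snps),
              n_exposure = as.integer(n_exposure),
              n_mediator = as.integer(n_mediator),
              n_outcome = as.integer(n_outcome),
              maf_range = as.numeric(maf_range),
              instrument_effect_sd = instrument_effect_sd,
              theta1 = theta1, theta2 = theta2,
              direct_effect = direct_effect,
              pleiotropy_fraction = pleiotropy_fraction,
              pleiotropy_mean = pleiotropy_mean,
              pleiotropy_sd = pleiotropy_sd,
              n_outliers = as.integer(n_outliers),
              outlier_multiplier = outlier_multiplier,
              palindromic_fraction = palindromic_fraction,
              noise_sd = as.numeric(noise_sd),
              outcome_type = outcome_type,
              case_fraction = case_fraction,
              ld = ld,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_snps < 1) stop("n_snps must be >= 1")
    if (min(n_exposure, n_mediator, n_outcome) < 100)
      stop("cohort sizes below 100 give unstable standard errors; rejected")
    if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range >= 1) ||
        maf_range[1] > maf_range[2])
      stop("maf_range must be an increasing pair within (0, 1)")
    if (pleiotropy_fraction < 0 || pleiotropy_fraction > 1)
      stop("pleiotropy_fraction must be in [0, 1]")
    if (palindromic_fraction < 0 || palindromic_fraction > 1)
      stop("palindromic_fraction must be in [0, 1]")
    if (instrument_effect_sd < 0 || pleiotropy_sd < 0)
      stop("effect SDs must be non-negative")
    if (n_outliers < 0 || n_outliers > n_snps)
      stop("n_outliers must be in [0, n_snps]")
    if (length(noise_sd) != 3 || any(noise_sd <= 0))
      stop("noise_sd must be three positive values")
    if (case_fraction <= 0 || case_fraction >= 1)
      stop("case_fraction must be in (0, 1)")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Three-trait simulation config:", x$n_snps, "SNPs;",
      "n =", x$n_exposure, "/", x$n_mediator, "/", x$n_outcome, "\n")
  cat(sprintf("  theta1 = %g, theta2 = %g, direct = %g (total = %g)\n",
              x$theta1, x$theta2, x$direct_effect,
              x$direct_effect + x$theta1 * x$theta2))
  cat(sprintf("  pleiotropy: fraction %g, mean %g, sd %g; outcome: %s\n",
              x$pleiotropy_fraction, x$pleiotropy_mean, x$pleiotropy_sd,
              x$outcome_type))
  invisible(x)
}

# draw an allele pair; palindromic = A/T or C/G
draw_alleles <- function(n, palindromic = rep(FALSE, n)) {
  pal <- list(c("A", "T"), c("C", "G"))
  nonpal <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  ea <- oa <- character(n)
  for (i in seq_len(n)) {
    p <- if (palindromic[i]) pal[[sample.int(2, 1)]] else
      nonpal[[sample.int(8, 1)]]
    if (palindromic[i] && runif(1) < 0.5) p <- rev(p)
    ea[i] <- p[1]; oa[i] <- p[2]
  }
  list(effect = ea, other = oa)
}

# genotype matrix: independent Binomial(2, maf), or block-correlated
# haplotypes via a Gaussian copula when ld is given
draw_genotypes <- function(n, maf, ld = NULL) {
  m <- length(maf)
  if (is.null(ld)) {
    matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  } else {
    bs <- ld$block_size
    rho <- ld$rho
    block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
    hap <- function() {
      # per-individual block factor + idiosyncratic part (Gaussian copula)
      u <- matrix(rnorm(n * max(block)), n)[, block, drop = FALSE]
      z <- sqrt(rho) * u + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
      t(t(z) < qnorm(maf)) + 0
    }
    hap() + hap()
  }
}

# vectorised per-variant simple regression of y on each genotype column
marginal_stats <- function(G, y) {
  n <- length(y)
  gbar <- colMeans(G)
  Sxx <- colSums(G^2) - n * gbar^2
  ybar <- mean(y)
  Sxy <- colSums(G * y) - n * gbar * ybar
  Syy <- sum((y - ybar)^2)
  beta <- Sxy / Sxx
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- sqrt(rss / (n - 2) / Sxx)
  tval <- beta / se
  data.frame(eaf = gbar / 2, beta = beta, se = se,
             pval = 2 * pt(-abs(tval), n - 2), n = n)
}

marginal_stats_binary <- function(G, y) {
  m <- ncol(G)
  beta <- se <- pval <- numeric(m)
  for (j in seq_len(m)) {
    fit <- suppressWarnings(glm(y ~ G[, j], family = binomial()))
    cf <- summary(fit)$coefficients
    beta[j] <- cf[2, 1]; se[j] <- cf[2, 2]; pval[j] <- cf[2, 4]
  }
  data.frame(eaf = colMeans(G) / 2, beta = beta, se = se,
             pval = pval, n = length(y))
}

#' Simulate three-trait two-sample summary statistics with known truth
#'
#' Generates per-variant marginal association statistics for the
#' exposure, mediator and outcome of a known causal chain, each from its
#' own independently simulated cohort (two-sample design). Betas, SEs and
#' p-values come from simple per-variant regression of the simulated
#' trait on the simulated genotype (logistic regression for binary
#' outcomes).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result` with elements `exposure`,
#'   `mediator`, `outcome` (summary-statistics data frames), `truth`
#'   (a `sim_truth` list holding every generating parameter, see
#'   [sim_truth_json()]) and, in LD mode, `panel` (an [ld_panel()]
#'   estimated from a dedicated reference cohort).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  m <- cfg$n_snps

  shared <- with_seed(child_seed(cfg$seed, 0L), {
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    gamma <- rnorm(m, 0, cfg$instrument_effect_sd)
    n_pleio <- round(cfg$pleiotropy_fraction * m)
    pleio_idx <- if (n_pleio > 0) sample.int(m, n_pleio) else integer(0)
    alpha <- numeric(m)
    alpha[pleio_idx] <- rnorm(n_pleio, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    n_pal <- round(cfg$palindromic_fraction * m)
    pal <- rep(FALSE, m)
    if (n_pal > 0) pal[sample.int(m, n_pal)] <- TRUE
    al <- draw_alleles(m, pal)
    list(maf = maf, gamma = gamma, alpha = alpha, pal = pal, alleles = al)
  })

  ids <- sprintf("rs%06d", seq_len(m))
  base <- data.frame(snp_id = ids, chrom = "1", pos = seq_len(m) * 100000L,
                     effect_allele = shared$alleles$effect,
                     other_allele = shared$alleles$other,
                     stringsAsFactors = FALSE)

  traits_of <- function(G) {
    n <- nrow(G)
    x <- drop(G %*% shared$gamma) + rnorm(n, 0, cfg$noise_sd[1])
    md <- cfg$theta1 * x + rnorm(n, 0, cfg$noise_sd[2])
    liab <- cfg$direct_effect * x + cfg$theta2 * md +
      drop(G %*% shared$alpha) + rnorm(n, 0, cfg$noise_sd[3])
    list(x = x, m = md, liab = liab)
  }

  one_cohort <- function(n, which, k) {
    with_seed(child_seed(cfg$seed, k), {
      G <- draw_genotypes(n, shared$maf, cfg$ld)
      tr <- traits_of(G)
      if (which == "outcome" && cfg$outcome_type == "binary") {
        y <- rbinom(n, 1L, plogis(qlogis(cfg$case_fraction) + tr$liab))
        st <- marginal_stats_binary(G, y)
      } else {
        y <- switch(which, exposure = tr$x, mediator = tr$m,
                    outcome = tr$liab)
        st <- marginal_stats(G, y)
      }
      cbind(base, st[, c("eaf", "beta", "se", "pval", "n")])
    })
  }

  exposure <- one_cohort(cfg$n_exposure, "exposure", 1L)
  mediator <- one_cohort(cfg$n_mediator, "mediator", 2L)
  outcome <- one_cohort(cfg$n_outcome, "outcome", 3L)

  total <- cfg$direct_effect + cfg$theta1 * cfg$theta2
  truth <- structure(list(
    snp_id = ids,
    instrument_effects = shared$gamma,
    pleiotropic_effects = shared$alpha,
    maf = shared$maf,
    true_theta1 = cfg$theta1, true_theta2 = cfg$theta2,
    true_direct = cfg$direct_effect, true_total = total,
    true_proportion = if (total != 0) cfg$theta1 * cfg$theta2 / total else NA,
    outlier_snp_ids = character(0),
    palindromic_snp_ids = ids[shared$pal],
    seed = cfg$seed), class = "sim_truth")

  out <- list(exposure = exposure, mediator = mediator, outcome = outcome,
              truth = truth)
  if (!is.null(cfg$ld)) {
    out$panel <- with_seed(child_seed(cfg$seed, 4L), {
      Gref <- draw_genotypes(2000L, shared$maf, cfg$ld)
      r <- suppressWarnings(stats::cor(Gref))
      r[!is.finite(r)] <- 0
      diag(r) <- 1
      r <- (r + t(r)) / 2
      dimnames(r) <- list(ids, ids)
      ld_panel(r)
    })
  }
  if (cfg$n_outliers > 0) {
    inj <- inject_artifacts(out[c("exposure", "mediator", "outcome")],
                            truth = out$truth,
                            palindromic_fraction = 0,
                            n_outliers = cfg$n_outliers,
                            outlier_multiplier = cfg$outlier_multiplier,
                            seed = child_seed(cfg$seed, 5L))
    out[c("exposure", "mediator", "outcome")] <- inj$tables
    out$truth <- inj$truth
  }
  class(out) <- "sim_result"
  out
}

#' Inject palindromic variants and outcome-beta outliers into tables
#'
#' Post-hoc corruption of simulated summary statistics: a stated fraction
#' of variants is rewritten with A/T or C/G allele pairs (a sub-fraction
#' of those losing their outcome allele frequency), and `n_outliers`
#' variants get their outcome beta multiplied by `outlier_multiplier` -
#' the failure modes the harmonization and outlier-detection stages are
#' designed to catch.
#'
#' @param tables Named list of summary-statistics data frames sharing
#'   variant ids; the element named `"outcome"` (else the last) receives
#'   the beta outliers and EAF removals.
#' @param truth Optional `sim_truth` to update with affected ids.
#' @param palindromic_fraction Fraction of variants rewritten as
#'   palindromic (in every table, consistently).
#' @param missing_eaf_fraction Fraction of the rewritten palindromic
#'   variants whose outcome EAF is set missing.
#' @param n_outliers,outlier_multiplier Outlier count and multiplier.
#' @param seed Integer seed.
#' @return List with elements `tables` and `truth`.
#' @export
inject_artifacts <- function(tables, truth = NULL,
                             palindromic_fraction = 0,
                             missing_eaf_fraction = 0.5,
                             n_outliers = 0, outlier_multiplier = 10,
                             seed = 1L) {
  if (is.data.frame(tables)) tables <- list(outcome = tables)
  ids <- tables[[1]]$snp_id
  m <- length(ids)
  if (n_outliers > m) stop("n_outliers exceeds number of variants")
  out_tab <- if ("outcome" %in% names(tables)) "outcome" else
    length(tables)

  with_seed(seed, {
    n_pal <- round(palindromic_fraction * m)
    pal_idx <- if (n_pal > 0) sample.int(m, n_pal) else integer(0)
    if (n_pal > 0) {
      al <- draw_alleles(n_pal, palindromic = rep(TRUE, n_pal))
      for (k in seq_along(tables)) {
        tables[[k]]$effect_allele[pal_idx] <- al$effect
        tables[[k]]$other_allele[pal_idx] <- al$other
      }
      n_miss <- round(missing_eaf_fraction * n_pal)
      if (n_miss > 0) {
        miss_idx <- pal_idx[sample.int(n_pal, n_miss)]
        tables[[out_tab]]$eaf[miss_idx] <- NA_real_
      }
    }
    outlier_idx <- if (n_outliers > 0) sample.int(m, n_outliers) else
      integer(0)
    if (n_outliers > 0)
      tables[[out_tab]]$beta[outlier_idx] <-
        tables[[out_tab]]$beta[outlier_idx] * outlier_multiplier

    if (!is.null(truth)) {
      truth$outlier_snp_ids <- union(truth$outlier_snp_ids, ids[outlier_idx])
      truth$palindromic_snp_ids <- union(truth$palindromic_snp_ids,
                                         ids[pal_idx])
    }
    list(tables = tables, truth = truth)
  })
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth A `sim_truth` object from [simulate_cohort()].
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
sim_truth_json <- function(truth, path = NULL) {
  js <- jsonlite::toJSON(unclass(truth), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Fast summary-statistic-level simulation of one exposure/outcome pair
#'
#' Draws harmonized exposure/outcome betas directly on the summary scale:
#' exposure betas around their true instrument effects, outcome betas
#' conditionally normal around `theta * beta_exp + alpha`. Under this
#' conditional model Cochran's Q is exactly chi-square and the Egger
#' intercept t-test exactly calibrated, which is what makes this the
#' appropriate null generator for error-calibration studies (the
#' individual-level [simulate_cohort()] is the generator for
#' parameter-recovery and end-to-end studies).
#'
#' @param n_snps Number of instruments.
#' @param theta True causal effect.
#' @param gamma_mean,gamma_sd Instrument-effect distribution (signs are
#'   randomised).
#' @param se_exp Exposure beta SE (small = strong instruments).
#' @param se_out_range Range the per-variant outcome SEs are drawn from.
#' @param pleiotropy_mean,pleiotropy_sd Direct-effect (intercept-scale)
#'   pleiotropy added to outcome betas.
#' @param n_exp,n_out Nominal per-trait sample sizes carried into the
#'   table (used by the Steiger test).
#' @param seed Integer seed.
#' @return A harmonized-pairs data frame (columns `snp_id`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `n_exp`, `n_out`, `action`) ready
#'   for [mr_fit()].
#' @export
simulate_sumstats <- function(n_snps = 20, theta = 0,
                              gamma_mean = 0.15, gamma_sd = 0.05,
                              se_exp = 0.005, se_out_range = c(0.01, 0.03),
                              pleiotropy_mean = 0, pleiotropy_sd = 0,
                              n_exp = 20000, n_out = 20000,
                              seed = 1L) {
  with_seed(seed, {
    gamma <- rnorm(n_snps, gamma_mean, gamma_sd) *
      sample(c(-1, 1), n_snps, replace = TRUE)
    bx <- gamma + rnorm(n_snps, 0, se_exp)
    sey <- runif(n_snps, se_out_range[1], se_out_range[2])
    alpha <- if (pleiotropy_sd > 0 || pleiotropy_mean != 0)
      rnorm(n_snps, pleiotropy_mean, pleiotropy_sd) else numeric(n_snps)
    by <- theta * bx + alpha + rnorm(n_snps, 0, sey)
    data.frame(snp_id = sprintf("rs%06d", seq_len(n_snps)),
               beta_exp = bx, se_exp = se_exp,
               beta_out = by, se_out = sey,
               n_exp = n_exp, n_out = n_out,
               action = "kept", stringsAsFactors = FALSE)
  })
}
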