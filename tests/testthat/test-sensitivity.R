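test_that("Cochran's Q is zero under homogeneity and matches hand computation", {
  p <- make_pairs(c(0.2, 0.4, 0.5), 0.01, c(0.1, 0.2, 0.25), 0.05)
  q <- cochran_q(p)  # all ratios exactly 0.5
  expect_equal(q$q_stat, 0, tolerance = 1e-12)
  expect_equal(q$q_pval, 1)
  expect_equal(q$q_df, 2)

  # two hand-set pairs
  p2 <- make_pairs(c(0.5, 0.25), 0.01, c(0.1, 0.1), c(0.05, 0.1))
  r <- c(0.2, 0.4); se_r <- c(0.1, 0.4); w <- 1 / se_r^2
  b <- sum(w * r) / sum(w)
  q_hand <- sum(w * (r - b)^2)
  q2 <- cochran_q(p2)
  expect_equal(q2$q_stat, q_hand, tolerance = 1e-12)
  expect_equal(q2$q_pval, pchisq(q_hand, 1, lower.tail = FALSE))

  # single pair: not applicable, not an error
  expect_true(is.na(cochran_q(p[1, ])$q_pval))
})

test_that("Egger intercept detects directional pleiotropy", {
  # exact line through a nonzero intercept
  bx <- c(0.1, 0.2, 0.3, 0.4)
  p <- make_pairs(bx, 0.001, 0.05 + 0.2 * bx + rnorm(4, 0, 1e-4), 0.03)
  ei <- egger_intercept(p)
  expect_equal(ei$intercept, 0.05, tolerance = 0.01)
  # directional pleiotropy (+0.05 on every oriented instrument):
  # intercept estimate positive in >= 90/100 seeds
  pos <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    bx <- abs(rnorm(30, 0.2, 0.03))
    sey <- runif(30, 0.01, 0.03)
    by <- 0.1 * bx + 0.05 + rnorm(30, 0, sey)
    egger_intercept(make_pairs(bx, 0.005, by, sey))$intercept > 0
  }, logical(1))
  expect_gte(mean(pos), 0.9)
})

test_that("MR-PRESSO RSS equals a brute-force leave-one-out loop", {
  set.seed(161)
  p <- make_pairs(runif(5, 0.2, 0.5), 0.01,
                  rnorm(5, 0.1, 0.05), runif(5, 0.03, 0.08))
  pres <- mr_presso(p, n_sim = 1000, seed = 3)
  rss_oracle <- 0
  for (i in 1:5) {
    sub <- p[-i, ]
    w <- 1 / sub$se_out^2
    b_loo <- sum(w * sub$beta_exp * sub$beta_out) /
      sum(w * sub$beta_exp^2)
    rss_oracle <- rss_oracle +
      (p$beta_out[i] - b_loo * p$beta_exp[i])^2 / p$se_out[i]^2
  }
  expect_equal(pres$rss_obs, rss_oracle, tolerance = 1e-10)
})

test_that("MR-PRESSO is deterministic and clean data rarely alarm", {
  set.seed(171)
  p <- simulate_sumstats(n_snps = 20, theta = 0.15, seed = 4)
  a <- mr_presso(p, n_sim = 1000, seed = 7)
  b <- mr_presso(p, n_sim = 1000, seed = 7)
  expect_identical(a, b)
  clean <- vapply(1:20, function(s) {
    d <- simulate_sumstats(n_snps = 20, theta = 0.15, seed = 3000 + s)
    mr_presso(d, n_sim = 1000, seed = s)$global_p > 0.05
  }, logical(1))
  expect_gte(mean(clean), 0.9)
  # fewer than 4 variants: not applicable
  expect_false(mr_presso(p[1:3, ], n_sim = 1000, seed = 1)$applicable)
})

test_that("an injected outlier is flagged and correction restores the estimate", {
  # a strong causal effect so the tenfold corruption is a real signal
  hits <- corrected_better <- logical(10)
  for (s in 1:10) {
    d <- simulate_sumstats(n_snps = 30, theta = 0.5, seed = 5000 + s)
    j <- 1 + (s %% 30)
    d$beta_out[j] <- d$beta_out[j] * 10
    pres <- mr_presso(d, n_sim = 2000, seed = s)
    hits[s] <- d$snp_id[j] %in% pres$outlier_ids
    if (!is.null(pres$corrected)) {
      raw <- mr_ivw(d)$beta
      corrected_better[s] <-
        abs(pres$corrected$beta - 0.5) < abs(raw - 0.5)
    }
  }
  expect_gte(mean(hits), 0.9)
  expect_gte(mean(corrected_better), 0.9)
})

test_that("Steiger direction follows explained variance and is antisymmetric", {
  # strong exposure instruments, null outcome associations
  p <- make_pairs(rep(0.3, 10), 0.01, rnorm(10, 0, 0.01), 0.05)
  st <- steiger_test(p, n_exp = 5000, n_out = 5000)
  expect_true(st$direction)
  expect_lt(st$p, 1e-10)
  # swapping the roles flips the direction
  swapped <- make_pairs(p$beta_out, p$se_out, p$beta_exp, p$se_exp)
  expect_false(steiger_test(swapped, n_exp = 5000, n_out = 5000)$direction)
  # invariant to rescaling a trait's betas and SEs
  scaled <- make_pairs(p$beta_exp * 4, p$se_exp * 4, p$beta_out, p$se_out)
  st2 <- steiger_test(scaled, n_exp = 5000, n_out = 5000)
  expect_equal(st2$r2_exp, st$r2_exp, tolerance = 1e-12)
  expect_error(steiger_test(p[, setdiff(names(p), c("n_exp", "n_out"))]),
               "sample_size_required")
})

test_that("Steiger r2 matches correlations from individual-level data", {
  set.seed(181)
  n <- 4000
  g <- rbinom(n, 2, 0.3)
  x <- 0.3 * g + rnorm(n)
  y <- 0.1 * x + rnorm(n)
  cf_x <- summary(lm(x ~ g))$coefficients
  cf_y <- summary(lm(y ~ g))$coefficients
  p <- make_pairs(cf_x[2, 1], cf_x[2, 2], cf_y[2, 1], cf_y[2, 2],
                  n_exp = n, n_out = n)
  st <- steiger_test(p)
  expect_equal(st$r2_exp, cor(g, x)^2, tolerance = 0.05 * cor(g, x)^2)
  expect_equal(st$r2_out, cor(g, y)^2,
               tolerance = 0.05 * cor(g, y)^2 + 1e-4)
})

test_that("leave-one-out is exchangeable, complete, and finds the outlier", {
  p3 <- make_pairs(c(0.3, 0.3, 0.3), 0.01, c(0.15, 0.15, 0.15), 0.05)
  loo3 <- leave_one_out(p3)
  expect_equal(nrow(loo3), 3)
  expect_equal(length(unique(loo3$beta)), 1)

  d <- simulate_sumstats(n_snps = 15, theta = 0.15, seed = 8)
  d$beta_out[4] <- d$beta_out[4] * 8
  loo <- leave_one_out(d)
  expect_equal(nrow(loo), 15)
  full <- mr_ivw(d)$beta
  shift <- abs(loo$beta - full)
  expect_equal(which.max(shift), 4)
})

test_that("the sensitivity gate combines its switchable criteria", {
  d <- simulate_sumstats(n_snps = 20, theta = 0.2, seed = 9)
  rep_ok <- mr_sensitivity(d, presso_n_sim = 1000, presso_seed = 1)
  expect_true(sensitivity_gate(rep_ok, gate_config(),
                               ivw_model = "random",
                               ivw_beta = mr_ivw(d)$beta))
  # failing Steiger alone trips the gate, and switching it off restores
  rep_bad <- rep_ok
  rep_bad$steiger$direction <- FALSE
  expect_false(sensitivity_gate(rep_bad, gate_config()))
  expect_true(sensitivity_gate(rep_bad, gate_config(steiger = FALSE),
                               ivw_model = "random"))
  expect_output(print(rep_ok), "Steiger direction")
})
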