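test_that("Wald ratio and its first-order SE", {
  p <- make_pairs(0.5, 0.01, 0.25, 0.1)
  w <- wald_ratio(p)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(wald_ratio(make_pairs(0.5, 0.01, 0, 0.1))$beta, 0)
  expect_error(wald_ratio(make_pairs(0, 0.01, 0.1, 0.1)), "zero")
})

test_that("Wald SE matches a Monte-Carlo ratio SD for strong instruments", {
  # |bx/sex| = 50 >> 10: first-order delta should be within 2%
  set.seed(81)
  bx <- 0.5; sex <- 0.01; by <- 0.25; sey <- 0.1
  draws <- rnorm(1e6, by, sey) / rnorm(1e6, bx, sex)
  expect_equal(wald_ratio(make_pairs(bx, sex, by, sey))$se, sd(draws),
               tolerance = 0.02)
})

test_that("IVW equals the closed-form weighted mean of Wald ratios", {
  bx <- c(0.2, 0.35, 0.5); sey <- c(0.05, 0.08, 0.04)
  by <- c(0.05, 0.02, 0.09)
  p <- make_pairs(bx, 0.01, by, sey)
  fe <- mr_ivw(p, model = "fixed")
  expect_equal(fe$beta, oracle_ivw(bx, by, sey), tolerance = 1e-10)
  expect_equal(fe$se, sqrt(1 / sum(bx^2 / sey^2)), tolerance = 1e-10)
  # single pair reduces to the Wald ratio, reported as ivw
  one <- mr_ivw(p[1, ])
  expect_equal(one$method, "ivw")
  expect_equal(one$beta, wald_ratio(p[1, ])$beta)
  expect_equal(one$se, wald_ratio(p[1, ])$se)
})

test_that("random-effects IVW floors the residual scale at 1", {
  set.seed(91)
  p <- make_pairs(runif(10, 0.1, 0.5), 0.01,
                  runif(10, 0.1, 0.5) * 0.2 + rnorm(10, 0, 0.2), 0.05)
  fe <- mr_ivw(p, model = "fixed")
  re <- mr_ivw(p, model = "random")
  expect_equal(re$beta, fe$beta)
  expect_gte(re$se, fe$se - 1e-15)
  # underdispersed data: the floor keeps random == fixed
  p2 <- make_pairs(c(0.2, 0.3, 0.4), 0.01,
                   c(0.2, 0.3, 0.4) * 0.1 + c(1e-5, -1e-5, 0), 0.1)
  expect_equal(mr_ivw(p2, "random")$se, mr_ivw(p2, "fixed")$se)
})

test_that("Egger recovers an exact line and matches the WLS closed form", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  p_exact <- make_pairs(bx, 0.01, 0.37 * bx, c(0.04, 0.05, 0.06, 0.03))
  e <- mr_egger(p_exact)
  expect_lt(abs(e$egger_intercept), 1e-10)
  expect_equal(e$beta, 0.37, tolerance = 1e-10)
  expect_equal(e$egger_intercept_p, 1)

  set.seed(101)
  by <- 0.02 + 0.3 * bx + rnorm(4, 0, 0.03)
  sey <- c(0.04, 0.05, 0.06, 0.03)
  p4 <- make_pairs(bx, 0.01, by, sey)
  e4 <- mr_egger(p4)
  o <- oracle_wls(bx, by, 1 / sey^2)
  expect_equal(e4$egger_intercept, o[1], tolerance = 1e-10)
  expect_equal(e4$beta, o[2], tolerance = 1e-10)
})

test_that("Egger orients exposure betas non-negative before fitting", {
  set.seed(111)
  bx <- c(0.2, -0.3, 0.4, -0.25)
  by <- 0.01 + 0.3 * bx * sign(bx) * sign(bx) # through-origin-ish
  by <- 0.3 * bx + rnorm(4, 0, 0.02)
  p <- make_pairs(bx, 0.01, by, 0.05)
  e <- mr_egger(p)
  o <- oracle_wls(abs(bx), by * sign(bx), rep(1 / 0.05^2, 4))
  expect_equal(e$beta, o[2], tolerance = 1e-10)
  expect_equal(e$egger_intercept, o[1], tolerance = 1e-10)
})

test_that("fixed-effect IVW equals Egger with the intercept forced to zero", {
  set.seed(121)
  bx <- runif(6, 0.1, 0.5)
  by <- 0.2 * bx + rnorm(6, 0, 0.03)
  sey <- runif(6, 0.03, 0.08)
  p <- make_pairs(bx, 0.01, by, sey)
  # zero-intercept WLS closed form (the Egger design without intercept)
  slope0 <- sum((1 / sey^2) * bx * by) / sum((1 / sey^2) * bx^2)
  expect_equal(mr_ivw(p, "fixed")$beta, slope0, tolerance = 1e-10)
})

test_that("weighted median interpolates cumulative weights", {
  # equal weights on ratios 1,2,3 -> plain median 2
  p <- make_pairs(c(1, 1, 1), 1e-6, c(1, 2, 3), 1)
  expect_equal(mr_weighted_median(p, n_boot = 50, seed = 1)$beta, 2)
  # stated unequal weights on 5 ratios vs the brute-force oracle
  bx <- c(1, 1, 1, 1, 1)
  by <- c(0.8, 1.0, 1.4, 2.0, 3.1)
  sey <- c(0.5, 0.2, 0.1, 0.4, 0.25)
  p5 <- make_pairs(bx, 1e-6, by, sey)
  expect_equal(mr_weighted_median(p5, n_boot = 50, seed = 1)$beta,
               oracle_weighted_median(by / bx, bx^2 / sey^2),
               tolerance = 1e-12)
})

test_that("bootstrap estimators are bit-reproducible under a fixed seed", {
  set.seed(131)
  p <- make_pairs(runif(8, 0.1, 0.4), 0.02,
                  rnorm(8, 0.05, 0.03), runif(8, 0.03, 0.08))
  a <- mr_weighted_median(p, n_boot = 200, seed = 42)
  b <- mr_weighted_median(p, n_boot = 200, seed = 42)
  expect_identical(a, b)
  m1 <- mr_mode(p, n_boot = 200, seed = 42)
  m2 <- mr_mode(p, n_boot = 200, seed = 42)
  expect_identical(m1, m2)
})

test_that("mode estimators find density peaks", {
  # degenerate: all ratios identical
  pd <- make_pairs(rep(1, 4), 1e-8, rep(0.7, 4), 1e-8)
  md <- mr_mode(pd, n_boot = 100, seed = 2)
  expect_equal(md$beta, c(0.7, 0.7), tolerance = 1e-6)
  expect_lt(max(md$se), 1e-6)
  # bimodal {1,1,1,5,5}: simple mode sits on the majority cluster
  pb <- make_pairs(rep(1, 5), 1e-6, c(1, 1, 1, 5, 5), 0.3)
  mb <- mr_mode(pb, n_boot = 100, seed = 3)
  simple <- mb$beta[mb$method == "simple_mode"]
  expect_lt(abs(simple - 1), 0.5)
  # dominant weight on the minority cluster pulls the weighted mode there
  pw <- make_pairs(rep(1, 5), 1e-6, c(1, 1, 1, 5, 5),
                   c(1, 1, 1, 0.01, 0.01))
  mw <- mr_mode(pw, n_boot = 100, seed = 4)
  weighted <- mw$beta[mw$method == "weighted_mode"]
  expect_lt(abs(weighted - 5), 0.5)
  # grid oracle: mode equals the argmax of the weighted kernel density
  r <- c(1, 1, 1, 5, 5); w <- 1 / c(1, 1, 1, 0.01, 0.01)^2 # 1/se^2
  s <- min(sd(r), IQR(r) / 1.349); h <- 0.9 * s * 5^(-1 / 5)
  grid <- seq(-2, 8, length.out = 4000)
  dens <- vapply(grid, function(g)
    sum(w / sum(w) * dnorm(g, r, h)), numeric(1))
  expect_equal(weighted, grid[which.max(dens)], tolerance = 0.05)
})

test_that("odds-ratio transform matches the published rows", {
  expect_equal(round(or_from_beta(0.208, 0.05)$or, 3), 1.231)
  expect_equal(round(or_from_beta(0.131, 0.065)$or, 3), 1.140)
  nullcase <- or_from_beta(0, 0.1)
  expect_equal(nullcase$or, 1)
  expect_equal(log(nullcase$ci_low), -log(nullcase$ci_high))
})

test_that("estimators are scale- and sign-equivariant", {
  set.seed(141)
  bx <- runif(8, 0.1, 0.5)
  by <- 0.25 * bx + rnorm(8, 0, 0.03)
  sey <- runif(8, 0.03, 0.08)
  p <- make_pairs(bx, 0.01, by, sey)
  cc <- 3.7
  p_scaled <- make_pairs(bx, 0.01, cc * by, cc * sey)
  for (fn in list(function(q) mr_ivw(q),
                  function(q) mr_egger(q),
                  function(q) mr_weighted_median(q, n_boot = 100, seed = 5))) {
    a <- fn(p); b <- fn(p_scaled)
    expect_equal(b$beta, cc * a$beta, tolerance = 1e-8)
    expect_equal(b$se, cc * a$se, tolerance = 0.15 * cc * a$se + 1e-12)
  }
  p_neg <- make_pairs(-bx, 0.01, by, sey)
  expect_equal(mr_ivw(p_neg)$beta, -mr_ivw(p)$beta, tolerance = 1e-12)
})

test_that("mr_fit bundles estimators with working S3 methods", {
  set.seed(151)
  pairs <- simulate_sumstats(n_snps = 15, theta = 0.2, seed = 6)
  fit <- mr_fit(pairs, seed = 6)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$estimates$method,
                  c("ivw", "egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
  expect_named(coef(fit), fit$estimates$method)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  expect_length(residuals(fit), 15)
  expect_output(print(fit), "ivw")
  expect_output(print(summary(fit)), "Egger intercept")
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_length(sims, 3)
  expect_identical(simulate(fit, nsim = 3, seed = 9), sims)
  # two instruments: slope-only estimators fit, the rest are skipped
  small <- mr_fit(pairs[1:2, ], seed = 1)
  expect_equal(small$estimates$method, "ivw")
  expect_true("egger" %in% small$skipped)
})
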