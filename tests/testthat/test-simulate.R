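test_that("noise-free single-SNP limit returns the generating effect", {
  cfg <- sim_config(n_snps = 1, n_exposure = 2000, n_mediator = 2000,
                    n_outcome = 2000, noise_sd = rep(1e-8, 3), seed = 11)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$exposure$beta, sim$truth$instrument_effects,
               tolerance = 1e-6)
})

test_that("per-SNP marginal statistics match a per-variant lm oracle", {
  set.seed(21)
  n <- 400
  G <- matrix(rbinom(n * 6, 2, 0.3), n)
  y <- drop(G %*% rnorm(6, 0, 0.2)) + rnorm(n)
  st <- mraxis:::marginal_stats(G, y)
  for (j in 1:6) {
    fit <- summary(lm(y ~ G[, j]))$coefficients
    expect_equal(st$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(st$se[j], fit[2, 2], tolerance = 1e-10)
    expect_equal(st$pval[j], fit[2, 4], tolerance = 1e-10)
  }
})

test_that("config invariant: total effect = direct + theta1 * theta2", {
  cfg <- sim_config(theta1 = 0.2, theta2 = 0.15, direct_effect = 0.1,
                    n_exposure = 500, n_mediator = 500, n_outcome = 500,
                    seed = 1)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$truth$true_total, 0.13)
  expect_equal(sim$truth$true_proportion, 0.2 * 0.15 / 0.13,
               tolerance = 1e-12)
})

test_that("identical config and seed give identical tables", {
  cfg <- sim_config(n_snps = 10, n_exposure = 500, n_mediator = 500,
                    n_outcome = 500, seed = 33)
  expect_identical(simulate_cohort(cfg)[c("exposure", "mediator", "outcome")],
                   simulate_cohort(cfg)[c("exposure", "mediator", "outcome")])
})

test_that("doubling the cohort size shrinks the median SE by about sqrt(2)", {
  cfg1 <- sim_config(n_snps = 40, n_exposure = 2000, n_mediator = 500,
                     n_outcome = 500, seed = 5)
  cfg2 <- sim_config(n_snps = 40, n_exposure = 4000, n_mediator = 500,
                     n_outcome = 500, seed = 6)
  r <- median(simulate_cohort(cfg1)$exposure$se) /
    median(simulate_cohort(cfg2)$exposure$se)
  expect_gt(r, sqrt(2) * 0.9)
  expect_lt(r, sqrt(2) * 1.1)
})

test_that("the three cohorts are simulated independently", {
  cfg <- sim_config(n_snps = 15, n_exposure = 500, n_mediator = 500,
                    n_outcome = 500, noise_sd = rep(1e-6, 3), seed = 9)
  sim <- simulate_cohort(cfg)
  # same trait model, disjoint individuals: the genotype draws (hence
  # EAF estimates) cannot coincide across cohorts
  expect_false(all(sim$exposure$eaf == sim$mediator$eaf))
  expect_false(all(sim$exposure$eaf == sim$outcome$eaf))
  expect_false(all(sim$mediator$eaf == sim$outcome$eaf))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_exposure = 50), "100")
  expect_error(sim_config(pleiotropy_fraction = 1.5), "pleiotropy_fraction")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(n_outliers = 99, n_snps = 10), "n_outliers")
})

test_that("inject_artifacts with zero settings is the identity", {
  cfg <- sim_config(n_snps = 8, n_exposure = 500, n_mediator = 500,
                    n_outcome = 500, seed = 2)
  sim <- simulate_cohort(cfg)
  tabs <- sim[c("exposure", "mediator", "outcome")]
  out <- inject_artifacts(tabs, sim$truth, palindromic_fraction = 0,
                          n_outliers = 0, seed = 4)
  expect_identical(out$tables, tabs)
})

test_that("inject_artifacts records exactly the injected artifacts", {
  cfg <- sim_config(n_snps = 20, n_exposure = 500, n_mediator = 500,
                    n_outcome = 500, seed = 3)
  sim <- simulate_cohort(cfg)
  tabs <- sim[c("exposure", "mediator", "outcome")]
  out <- inject_artifacts(tabs, sim$truth, palindromic_fraction = 0.3,
                          missing_eaf_fraction = 0.5,
                          n_outliers = 2, outlier_multiplier = 10, seed = 8)
  expect_length(out$truth$outlier_snp_ids, 2)
  pal <- out$truth$palindromic_snp_ids
  expect_length(pal, 6)
  for (tab in out$tables) {
    sub <- tab[tab$snp_id %in% pal, ]
    expect_true(all(paste(sub$effect_allele, sub$other_allele) %in%
                      c("A T", "T A", "C G", "G C")))
  }
  expect_equal(sum(is.na(out$tables$outcome$eaf)), 3)
  mult <- out$tables$outcome$beta / tabs$outcome$beta
  expect_equal(sort(out$tables$outcome$snp_id[abs(mult - 10) < 1e-12]),
               sort(out$truth$outlier_snp_ids))
  expect_error(inject_artifacts(tabs, n_outliers = 99), "exceeds")
})

test_that("binary outcomes are simulated on the log-odds scale", {
  cfg <- sim_config(n_snps = 10, n_exposure = 500, n_mediator = 500,
                    n_outcome = 4000, outcome_type = "binary",
                    case_fraction = 0.3, theta1 = 1, theta2 = 1,
                    seed = 14)
  sim <- simulate_cohort(cfg)
  expect_true(all(is.finite(sim$outcome$beta)))
  expect_true(all(sim$outcome$se > 0))
  # log-odds betas attenuate but correlate with the instrument effects
  expect_gt(cor(sim$outcome$beta, sim$truth$instrument_effects), 0)
})

test_that("block-LD mode emits a panel consistent with the genotypes", {
  cfg <- sim_config(n_snps = 12, n_exposure = 1000, n_mediator = 500,
                    n_outcome = 500, maf_range = c(0.2, 0.5),
                    ld = list(block_size = 4, rho = 0.95),
                    seed = 19)
  sim <- simulate_cohort(cfg)
  expect_s3_class(sim$panel, "ld_panel")
  r <- sim$panel$r
  within_block <- r[1, 2]^2
  across_block <- r[1, 6]^2
  expect_gt(within_block, 0.2)
  expect_lt(across_block, 0.1)
})

test_that("truth serializes to JSON and back", {
  cfg <- sim_config(n_snps = 4, n_exposure = 500, n_mediator = 500,
                    n_outcome = 500, seed = 7)
  sim <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  sim_truth_json(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$true_total, sim$truth$true_total)
  expect_equal(back$instrument_effects, sim$truth$instrument_effects)
})
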