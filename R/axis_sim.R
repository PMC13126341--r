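#' Simulate a four-trait regulatory-axis data set
#'
#' Generates summary statistics for an upstream protein (U), a
#' downstream protein (M), a metabolite and a disease outcome (Y) under
#' the chain U -> M -> metabolite -> Y, with each of U, M and the
#' metabolite carrying its own direct instruments so every mediation leg
#' is estimable by two-sample MR. Each trait is measured in its own
#' independently simulated cohort. Optional direct effects U -> Y and
#' M -> Y (not through the metabolite) control the true mediation
#' proportions.
#'
#' Defaults are chosen so that per-trait instruments are genome-wide
#' significant while cross-trait leakage (e.g. U's variants acting on M
#' through the chain) stays far below the significance threshold: causal
#' effects of 0.2 between molecular traits mean a leaked variant would
#' need a direct effect about four standard deviations above the
#' instrument-effect scale to reach p < 5e-8 in the downstream trait, so
#' every leg's selected instruments estimate that leg's total effect
#' without bias from the direct (bypass) effects.
#'
#' @param n_snps_per_trait Direct instruments per molecular trait (three
#'   traits; the outcome has none).
#' @param n_per_cohort Individuals per cohort.
#' @param maf_range Minor-allele-frequency range.
#' @param instrument_effect_sd SD of direct instrument effects.
#' @param theta_um U -> M causal effect.
#' @param theta_mmet M -> metabolite causal effect.
#' @param effect_met_y Metabolite -> Y causal effect.
#' @param direct_u_y,direct_m_y Direct effects on Y bypassing the chain.
#' @param noise_sd Residual SD shared by all traits.
#' @param seed Integer seed.
#' @return List with summary-statistics tables `upstream`, `downstream`,
#'   `metabolite`, `outcome` and a `truth` list holding the generating
#'   effects and the implied true mediation quantities (`upstream_prop`,
#'   `downstream_prop`, totals per leg).
#' @export
simulate_axis <- function(n_snps_per_trait = 30, n_per_cohort = 5000,
                          maf_range = c(0.1, 0.5),
                          instrument_effect_sd = 0.25,
                          theta_um = 0.2, theta_mmet = 0.2,
                          effect_met_y = 0.5,
                          direct_u_y = 0.1, direct_m_y = 0.15,
                          noise_sd = 1, seed = 1L) {
  kpt <- n_snps_per_trait
  m <- 3L * kpt
  shared <- with_seed(child_seed(seed, 0L), {
    maf <- runif(m, maf_range[1], maf_range[2])
    g <- rnorm(m, 0, instrument_effect_sd)
    al <- draw_alleles(m)
    list(maf = maf, g = g, al = al)
  })
  # effect vectors per trait over all m variants
  idx_u <- seq_len(kpt)
  idx_m <- kpt + seq_len(kpt)
  idx_t <- 2L * kpt + seq_len(kpt)
  gamma_u <- gamma_m <- gamma_t <- numeric(m)
  gamma_u[idx_u] <- shared$g[idx_u]
  gamma_m[idx_m] <- shared$g[idx_m]
  gamma_t[idx_t] <- shared$g[idx_t]

  ids <- sprintf("rs%06d", seq_len(m))
  base <- data.frame(snp_id = ids, chrom = "1", pos = seq_len(m) * 100000L,
                     effect_allele = shared$al$effect,
                     other_allele = shared$al$other,
                     stringsAsFactors = FALSE)
  traits_of <- function(G) {
    n <- nrow(G)
    u <- drop(G %*% gamma_u) + rnorm(n, 0, noise_sd)
    md <- theta_um * u + drop(G %*% gamma_m) + rnorm(n, 0, noise_sd)
    met <- theta_mmet * md + drop(G %*% gamma_t) + rnorm(n, 0, noise_sd)
    y <- direct_u_y * u + direct_m_y * md + effect_met_y * met +
      rnorm(n, 0, noise_sd)
    list(upstream = u, downstream = md, metabolite = met, outcome = y)
  }
  one <- function(which, k) {
    with_seed(child_seed(seed, k), {
      G <- draw_genotypes(n_per_cohort, shared$maf)
      st <- marginal_stats(G, traits_of(G)[[which]])
      cbind(base, st[, c("eaf", "beta", "se", "pval", "n")])
    })
  }
  my_total <- direct_m_y + theta_mmet * effect_met_y
  uy_total <- direct_u_y + theta_um * my_total
  truth <- list(
    snp_id = ids,
    instrument_effects = list(upstream = gamma_u[idx_u],
                              downstream = gamma_m[idx_m],
                              metabolite = gamma_t[idx_t]),
    theta_um = theta_um, theta_mmet = theta_mmet,
    effect_met_y = effect_met_y,
    direct_u_y = direct_u_y, direct_m_y = direct_m_y,
    uy_total = uy_total, my_total = my_total,
    upstream_prop = theta_um * my_total / uy_total,
    downstream_prop = theta_mmet * effect_met_y / my_total,
    seed = seed)
  list(upstream = one("upstream", 1L),
       downstream = one("downstream", 2L),
       metabolite = one("metabolite", 3L),
       outcome = one("outcome", 4L),
       truth = truth)
}
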