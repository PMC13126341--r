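# builders for small summary-statistics fixtures, all generated in code

make_assoc <- function(snp_id, beta, se,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, pval = 2 * pnorm(-abs(beta / se)),
                       chrom = "1", pos = seq_along(snp_id) * 1e5,
                       n = 5000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

make_pairs <- function(beta_exp, se_exp, beta_out, se_out,
                       snp_id = sprintf("rs%03d", seq_along(beta_exp)),
                       n_exp = 5000, n_out = 5000) {
  data.frame(snp_id = snp_id,
             beta_exp = beta_exp, se_exp = se_exp,
             pval_exp = 2 * pnorm(-abs(beta_exp / se_exp)),
             beta_out = beta_out, se_out = se_out,
             n_exp = n_exp, n_out = n_out,
             action = "kept", drop_reason = "",
             stringsAsFactors = FALSE)
}

# independent closed-form oracles used across test files
oracle_ivw <- function(bx, by, sey) {
  sum(bx * by / sey^2) / sum(bx^2 / sey^2)
}

oracle_wls <- function(bx, by, w) {
  # weighted least squares with intercept via normal equations;
  # returns c(intercept, slope)
  X <- cbind(1, bx)
  unname(drop(solve(t(X) %*% (w * X), t(X) %*% (w * by))))
}

oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  j <- max(which(cw < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - cw[j]) / (cw[j + 1] - cw[j])
}
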