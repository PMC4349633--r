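# Internal posterior-moment and divergence helpers shared by the variational
# updates and the ELBO. All gamma distributions use the shape/rate
# parameterisation; an inverse-gamma posterior on a variance is carried as the
# gamma posterior of the corresponding precision.

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# KL(Gamma(a, b) || Gamma(a0, b0)), shape/rate
gamma_kl <- function(a, b, a0, b0) {
  (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
}

# KL(Beta(a, b) || Beta(a0, b0))
beta_kl <- function(a, b, a0, b0) {
  lbeta(a0, b0) - lbeta(a, b) +
    (a - a0) * digamma(a) + (b - b0) * digamma(b) +
    (a0 - a + b0 - b) * digamma(a + b)
}

# KL(N(m, v) || N(0, v0))
gauss_kl0 <- function(m, v, v0) {
  0.5 * (v / v0 + m^2 / v0 - 1 + log(v0) - log(v))
}

# Expectations of the structured subject-map posterior: first and second
# moments of P = q * slab weight.
map_moments <- function(subj) {
  list(EP = subj$q_prob * subj$slab_mean,
       EP2 = subj$q_prob * (subj$slab_mean^2 + subj$slab_var))
}

# Expectations of the group spike-slab means
group_mu_moments <- function(group) {
  list(Emu = group$rho_prob * group$mu_mean,
       Emu2 = group$rho_prob * (group$mu_mean^2 + group$mu_var))
}

# Time-course posterior per run: q(A_m) = N(mean_m, cov_m) with
# cov_m = (alpha_at * K^{-1} + c_m I)^{-1}, stored in factored form as the
# scalars (alpha_at, c_m) plus the shared eigendecomposition of K. The
# reconstruction below is exact.
tc_cov_eigvals <- function(tc, prior, m) {
  1 / (tc$alpha_at / prior$eig$values + tc$c[m])
}

tc_cov <- function(tc, prior, m) {
  w <- tc_cov_eigvals(tc, prior, m)
  U <- prior$eig$vectors
  U %*% (w * t(U))
}

# Summary moments needed by the updates/ELBO for every mode of one run:
#   trcov      tr(cov_m)
#   trKinv     tr(K^{-1} cov_m)
#   quadKinv   mean_m' K^{-1} mean_m
#   logdetcov  log |cov_m|
#   sumEA2     sum_t E[A_mt^2] = ||mean_m||^2 + tr(cov_m)
#   sumEAmean2 sum_t E[A_mt]^2
tc_moments <- function(tc, prior) {
  M <- nrow(tc$mean)
  Ut <- t(prior$eig$vectors)
  out <- list(trcov = numeric(M), trKinv = numeric(M), quadKinv = numeric(M),
              logdetcov = numeric(M), sumEA2 = numeric(M),
              sumEAmean2 = numeric(M))
  for (m in seq_len(M)) {
    w <- tc_cov_eigvals(tc, prior, m)
    z <- Ut %*% tc$mean[m, ]
    out$trcov[m] <- sum(w)
    out$trKinv[m] <- sum(w / prior$eig$values)
    out$quadKinv[m] <- sum(z^2 / prior$eig$values)
    out$logdetcov[m] <- sum(log(w))
    out$sumEAmean2[m] <- sum(tc$mean[m, ]^2)
    out$sumEA2[m] <- out$sumEAmean2[m] + out$trcov[m]
  }
  out
}

# Expected squared Frobenius residual E||D - nu 1' - P A||^2 for one run,
# using full second moments of P and A (never just squared means).
expected_residual <- function(D, EP, EP2, EA, tcm, nu_mean, nu_var) {
  R0 <- D - EP %*% EA - nu_mean
  S2P <- colSums(EP2)
  SP2 <- colSums(EP^2)
  sum(R0^2) + ncol(D) * sum(nu_var) +
    sum(S2P * tcm$sumEA2 - SP2 * tcm$sumEAmean2)
}
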