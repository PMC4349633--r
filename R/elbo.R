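# Evidence lower bound for the full model. The bound decomposes as the
# expected complete-data log likelihood plus, for every factor of the
# variational posterior, the expected log prior minus the posterior's
# (negative) entropy; equivalently likelihood terms minus KL terms. Every
# conjugate coordinate update in this package maximises this bound exactly
# with the other factors held fixed, so the trace over full sweeps is
# non-decreasing up to floating-point error.

#' Evidence lower bound of a model state
#'
#' @param state A \code{pfm_state} (see \code{\link{pfm_fit}}).
#' @param data The \code{pfm_dataset} the state was fitted to.
#' @param by_term If \code{TRUE}, return the named per-term breakdown instead
#'   of the scalar sum (useful for diagnosing non-finite bounds).
#' @return Scalar ELBO, or a named numeric vector when \code{by_term}.
#' @export
compute_elbo <- function(state, data, by_term = FALSE) {
  hyper <- state$hyper
  group <- state$group
  M <- state$M
  terms <- c(data_lik = 0, tc_prior = 0, alpha = 0, maps = 0, group_mu = 0,
             group_pi = 0, group_sigma = 0, noise_psi = 0, noise_nu = 0)

  Ealpha <- state$alpha$shape / state$alpha$rate
  Elogalpha <- digamma(state$alpha$shape) - log(state$alpha$rate)
  mom <- lapply(state$subjects, map_moments)

  for (k in names(data$runs)) {
    D <- data$runs[[k]]
    s <- data$run_subject[match(k, names(data$runs))]
    tc <- state$tc[[k]]
    prior <- state$priors[[as.character(ncol(D))]]
    nz <- state$noise[[k]]
    V <- nrow(D); T_ <- ncol(D)
    tcm <- tc_moments(tc, prior)

    Epsi <- nz$psi_shape / nz$psi_rate
    Elogpsi <- digamma(nz$psi_shape) - log(nz$psi_rate)
    resid <- expected_residual(D, mom[[s]]$EP, mom[[s]]$EP2, tc$mean, tcm,
                               nz$nu_mean, nz$nu_var)
    terms["data_lik"] <- terms["data_lik"] +
      V * T_ / 2 * (Elogpsi - log(2 * pi)) - Epsi * resid / 2

    terms["tc_prior"] <- terms["tc_prior"] +
      sum(T_ / 2 * Elogalpha - prior$logdet / 2 -
            Ealpha / 2 * (tcm$quadKinv + tcm$trKinv) +
            tcm$logdetcov / 2 + T_ / 2)

    terms["noise_psi"] <- terms["noise_psi"] -
      gamma_kl(nz$psi_shape, nz$psi_rate, hyper$psi_shape0, hyper$psi_rate0)
    terms["noise_nu"] <- terms["noise_nu"] -
      sum(gauss_kl0(nz$nu_mean, nz$nu_var, hyper$nu_var0))
  }

  terms["alpha"] <- -gamma_kl(state$alpha$shape, state$alpha$rate,
                              hyper$alpha_shape0, hyper$alpha_rate0)

  # spatial hierarchy
  Esiginv <- group$sigma_shape / group$sigma_rate
  Elogsig <- log(group$sigma_rate) - digamma(group$sigma_shape)
  gm <- group_mu_moments(group)
  Elogpi <- digamma(group$pi_a) - digamma(group$pi_a + group$pi_b)
  Elog1mpi <- digamma(group$pi_b) - digamma(group$pi_a + group$pi_b)
  for (s in names(state$subjects)) {
    sb <- state$subjects[[s]]
    q <- sb$q_prob
    equad <- sb$slab_mean^2 + sb$slab_var -
      2 * sb$slab_mean * gm$Emu + gm$Emu2
    terms["maps"] <- terms["maps"] + sum(
      q * (Elogpi - 0.5 * Elogsig - 0.5 * Esiginv * equad +
             0.5 * log(sb$slab_var) + 0.5) +
        (1 - q) * Elog1mpi - xlogx(q) - xlogx(1 - q))
  }

  gam <- matrix(group$gamma_prec, nrow(group$mu_mean), M, byrow = TRUE)
  rho <- group$rho_prob
  lam <- group$lambda
  slab_term <- rho * (log(lam) + 0.5 * log(gam) -
                        0.5 * gam * (group$mu_mean^2 + group$mu_var) +
                        0.5 * log(group$mu_var) + 0.5)
  slab_term[rho == 0] <- 0          # lambda = 0 guard
  spike_term <- if (lam >= 1) 0 else (1 - rho) * log1p(-lam)
  terms["group_mu"] <- sum(slab_term + spike_term -
                             xlogx(rho) - xlogx(1 - rho))

  terms["group_pi"] <- -sum(beta_kl(group$pi_a, group$pi_b,
                                    hyper$pi_a0, hyper$pi_b0))
  terms["group_sigma"] <- -sum(gamma_kl(group$sigma_shape, group$sigma_rate,
                                        hyper$sigma_shape0,
                                        hyper$sigma_rate0))

  if (by_term) return(terms)
  out <- sum(terms)
  if (!is.finite(out)) {
    warning("non-finite ELBO; per-term breakdown follows")
    print(terms)
  }
  out
}
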