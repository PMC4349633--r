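# Variational updates for the per-run white-noise model: voxelwise means nu
# and the run's scalar precision psi. The mean update precedes the precision
# update within a run's sweep.

#' Variational update of one run's noise posterior
#'
#' Conjugate update of the Gaussian posterior on the run's voxel means
#' (regressing out the expected mode contribution) followed by the gamma
#' update of the run's noise precision. The precision rate uses the full
#' expected squared residual, i.e. second moments of both the spatial weights
#' and the time courses, never squared means.
#'
#' @param D V x T data matrix for the run.
#' @param EP,EP2 V x M spatial moment matrices for the run's subject.
#' @param tc The run's time-course posterior.
#' @param prior The run's temporal prior.
#' @param psi_mean Current posterior mean of the run's noise precision (used
#'   in the mean update).
#' @param psi_shape0,psi_rate0 Gamma hyperprior on the precision.
#' @param nu_var0 Prior variance of the voxel means (prior mean 0).
#' @return List with \code{psi_shape}, \code{psi_rate}, \code{nu_mean},
#'   \code{nu_var}.
#' @export
update_noise <- function(D, EP, EP2, tc, prior, psi_mean,
                         psi_shape0 = 1e-3, psi_rate0 = 1e-3,
                         nu_var0 = 1e4) {
  V <- nrow(D); T_ <- ncol(D)
  if (nrow(EP) != V || ncol(tc$mean) != T_)
    stop("noise update dimension mismatch", call. = FALSE)
  fit <- EP %*% tc$mean
  R0 <- D - fit
  nu_prec <- 1 / nu_var0 + T_ * psi_mean
  nu_var <- rep(1 / nu_prec, V)
  nu_mean <- psi_mean * rowSums(R0) / nu_prec
  tcm <- tc_moments(tc, prior)
  resid <- expected_residual(D, EP, EP2, tc$mean, tcm, nu_mean, nu_var)
  list(psi_shape = psi_shape0 + V * T_ / 2,
       psi_rate = psi_rate0 + resid / 2,
       nu_mean = nu_mean, nu_var = nu_var)
}
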