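# Variational updates for the temporal side of the model: per-run mode time
# courses under the HRF autocorrelation prior, and the shared precision
# hyperparameter on those time courses.

#' Variational update of one run's mode time courses
#'
#' Coordinate-ascent update of the Gaussian posteriors q(A_m) for every mode
#' of a single run, factorised across modes. Each mode's posterior precision
#' is \code{E[alpha] K^{-1} + E[psi] E[P_m' P_m] I}; its mean is the standard
#' Gaussian linear-model update on the data with the voxel means and the other
#' modes' current mean contributions subtracted. Modes are swept sequentially
#' so that every single-mode update is an exact ELBO coordinate maximisation.
#'
#' @param D V x T data matrix for the run.
#' @param EP,EP2 V x M first and second posterior moments of the subject's
#'   spatial weights (see \code{map_moments}).
#' @param nu_mean Length-V posterior mean of the run's voxel means.
#' @param psi_mean Posterior mean of the run's noise precision.
#' @param alpha_mean Posterior mean of the temporal precision.
#' @param prior A \code{\link{build_temporal_prior}} object with
#'   \code{prior$T == ncol(D)}.
#' @param mean_init Optional M x T matrix of current time-course means used to
#'   residualise the other modes; defaults to zeros.
#' @return A time-course posterior for the run: list with \code{mean} (M x T),
#'   \code{c} (length-M data precisions), \code{alpha_at} (the E[alpha] the
#'   covariances were computed at). The mode-m covariance is
#'   \code{(alpha_at * K^{-1} + c[m] I)^{-1}}, reconstructable with
#'   \code{tc_cov}.
#' @export
update_time_courses <- function(D, EP, EP2, nu_mean, psi_mean, alpha_mean,
                                prior, mean_init = NULL) {
  if (!inherits(prior, "temporal_prior"))
    stop("'prior' must be a temporal_prior", call. = FALSE)
  V <- nrow(D); T_ <- ncol(D); M <- ncol(EP)
  if (prior$T != T_) stop("prior/time-point mismatch", call. = FALSE)
  if (nrow(EP) != V || !all(dim(EP2) == dim(EP)))
    stop("map moment dimensions do not match the data", call. = FALSE)
  Dc <- D - nu_mean
  G <- crossprod(EP)                 # E[P]'E[P]; off-diagonal of E[P'P]
  S2P <- colSums(EP2)                # diagonal of E[P'P]
  B <- crossprod(EP, Dc)             # M x T
  A <- if (is.null(mean_init)) matrix(0, M, T_) else mean_init
  cvec <- numeric(M)
  U <- prior$eig$vectors
  e <- prior$eig$values
  for (m in seq_len(M)) {
    rhs <- B[m, ]
    if (M > 1) {
      oth <- setdiff(seq_len(M), m)
      rhs <- rhs - drop(G[m, oth, drop = FALSE] %*% A[oth, , drop = FALSE])
    }
    rhs <- psi_mean * rhs
    cvec[m] <- psi_mean * S2P[m]
    w <- 1 / (alpha_mean / e + cvec[m])
    A[m, ] <- U %*% (w * crossprod(U, rhs))
  }
  list(mean = A, c = cvec, alpha_at = alpha_mean)
}

#' Variational update of the temporal precision
#'
#' Conjugate gamma update for the precision alpha shared by all mode time
#' courses: shape grows by half the total number of time-course elements and
#' the rate accumulates the expected prior quadratic forms
#' \code{E[A K^{-1} A']}.
#'
#' @param tcs Named list of run time-course posteriors
#'   (\code{\link{update_time_courses}} output).
#' @param priors Named list mapping \code{as.character(T)} to the
#'   \code{temporal_prior} used for runs of that length (or a single prior).
#' @param shape0,rate0 Gamma hyperprior parameters.
#' @return List with \code{shape} and \code{rate} of the gamma posterior.
#' @export
update_temporal_precision <- function(tcs, priors, shape0 = 1e-3,
                                      rate0 = 1e-3) {
  shape <- shape0
  rate <- rate0
  for (tc in tcs) {
    T_ <- ncol(tc$mean)
    prior <- if (inherits(priors, "temporal_prior")) priors
             else priors[[as.character(T_)]]
    tcm <- tc_moments(tc, prior)
    shape <- shape + nrow(tc$mean) * T_ / 2
    rate <- rate + sum(tcm$quadKinv + tcm$trKinv) / 2
  }
  list(shape = shape, rate = rate)
}
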