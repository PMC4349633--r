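# Variational updates for the spatial hierarchy: subject-level delta-Gaussian
# map posteriors and the group-level spike-slab means, variances and mixture
# weights. All log-odds use exact conjugate-exponential expectations
# (digamma forms), never plug-in means.

#' Variational update of one subject's spatial map posterior
#'
#' Updates the structured Bernoulli-gated Gaussian posterior over each
#' voxel-mode weight, pooling the likelihood evidence over all of the
#' subject's runs weighted by each run's expected noise precision, and
#' combining it with the group prior N(E[mu], E[sigma^2]). The slab membership
#' probability comes from the exact log-odds of the slab versus the delta
#' hypothesis, including E[log pi] - E[log(1 - pi)].
#'
#' @param run_evidence List with one element per run of the subject, each a
#'   list with \code{D} (V x T), \code{tc} (time-course posterior),
#'   \code{prior} (its temporal prior), \code{psi_mean} and \code{nu_mean}.
#' @param EP Current V x M first moments of this subject's maps (used to
#'   residualise the other modes; updated in place as modes are swept).
#' @param group Group spatial posterior (see \code{\link{pfm_fit}} state).
#' @return List with \code{slab_mean}, \code{slab_var}, \code{q_prob}
#'   (all V x M).
#' @export
update_subject_maps <- function(run_evidence, EP, group) {
  V <- nrow(EP); M <- ncol(EP)
  Esiginv <- group$sigma_shape / group$sigma_rate
  Elogsig <- log(group$sigma_rate) - digamma(group$sigma_shape)
  gm <- group_mu_moments(group)
  Elogpi <- digamma(group$pi_a) - digamma(group$pi_a + group$pi_b)
  Elog1mpi <- digamma(group$pi_b) - digamma(group$pi_a + group$pi_b)

  # Pooled likelihood pieces across runs: beta_m (curvature, voxel-constant)
  # and the voxelwise linear terms
  beta_m <- numeric(M)
  Bsum <- matrix(0, V, M)          # sum_r psi_r * Dc EA'
  Hsum <- matrix(0, M, M)          # sum_r psi_r * E[A A'] (means off-diag)
  for (ev in run_evidence) {
    if (nrow(ev$D) != V) stop("run/map dimension mismatch", call. = FALSE)
    tcm <- tc_moments(ev$tc, ev$prior)
    beta_m <- beta_m + ev$psi_mean * tcm$sumEA2
    Dc <- ev$D - ev$nu_mean
    Bsum <- Bsum + ev$psi_mean * tcrossprod(Dc, ev$tc$mean)
    Hsum <- Hsum + ev$psi_mean * tcrossprod(ev$tc$mean)
  }

  slab_mean <- matrix(0, V, M)
  slab_var <- matrix(1, V, M)
  q_prob <- matrix(0, V, M)
  for (m in seq_len(M)) {
    h <- Bsum[, m]
    if (M > 1) {
      oth <- setdiff(seq_len(M), m)
      h <- h - EP[, oth, drop = FALSE] %*% Hsum[oth, m]
    }
    v1 <- 1 / (beta_m[m] + Esiginv[, m])
    m1 <- v1 * (h + Esiginv[, m] * gm$Emu[, m])
    logit <- Elogpi[, m] - Elog1mpi[, m] +
      m1^2 / (2 * v1) + 0.5 * log(v1) -
      0.5 * Elogsig[, m] - 0.5 * Esiginv[, m] * gm$Emu2[, m]
    q <- stats::plogis(logit)
    slab_mean[, m] <- m1
    slab_var[, m] <- v1
    q_prob[, m] <- q
    EP[, m] <- q * m1
  }
  list(slab_mean = slab_mean, slab_var = slab_var, q_prob = q_prob)
}

#' Variational update of the group spike-slab means
#'
#' Spike-slab posterior per voxel-mode for the group mean maps: the slab
#' combines the prior N(0, 1/gamma_m) with each subject's slab evidence,
#' weighted by its slab membership probability and the expected precision
#' E[1/sigma^2]; the non-zero probability comes from the log-odds including
#' log(lambda) - log(1 - lambda).
#'
#' @param subjects List of subject map posteriors.
#' @param group Group spatial posterior (supplies \code{sigma_shape},
#'   \code{sigma_rate}, \code{gamma_prec}, \code{lambda}).
#' @return List with \code{rho_prob}, \code{mu_mean}, \code{mu_var} (V x M).
#' @export
update_group_means <- function(subjects, group) {
  if (length(subjects) < 1) stop("need at least one subject", call. = FALSE)
  Esiginv <- group$sigma_shape / group$sigma_rate
  Sq <- Reduce(`+`, lapply(subjects, `[[`, "q_prob"))
  Sqm <- Reduce(`+`, lapply(subjects, function(s) s$q_prob * s$slab_mean))
  gam <- matrix(group$gamma_prec, nrow(Sq), ncol(Sq), byrow = TRUE)
  beta_mu <- Esiginv * Sq
  vv <- 1 / (gam + beta_mu)
  mm <- vv * (Esiginv * Sqm)
  lam <- group$lambda
  if (lam >= 1) {
    rho <- matrix(1, nrow(Sq), ncol(Sq))
  } else {
    logit <- log(lam) - log1p(-lam) + mm^2 / (2 * vv) + 0.5 * log(vv * gam)
    rho <- stats::plogis(logit)
  }
  list(rho_prob = rho, mu_mean = mm, mu_var = vv)
}

#' Variational update of the group slab variances
#'
#' Conjugate inverse-gamma update per voxel-mode: the shape grows by half the
#' total slab membership across subjects and the rate accumulates half the
#' expected squared deviations of subject slab weights from the group mean.
#'
#' @param subjects List of subject map posteriors.
#' @param group Group spatial posterior (supplies the mu moments).
#' @param shape0,rate0 Inverse-gamma hyperprior parameters.
#' @return List with \code{sigma_shape}, \code{sigma_rate} (V x M).
#' @export
update_group_variances <- function(subjects, group, shape0 = 1e-3,
                                   rate0 = 1e-3) {
  if (length(subjects) < 1) stop("need at least one subject", call. = FALSE)
  gm <- group_mu_moments(group)
  Sq <- Reduce(`+`, lapply(subjects, `[[`, "q_prob"))
  dev <- Reduce(`+`, lapply(subjects, function(s) {
    s$q_prob * (s$slab_mean^2 + s$slab_var - 2 * s$slab_mean * gm$Emu)
  }))
  list(sigma_shape = shape0 + Sq / 2,
       sigma_rate = rate0 + (dev + Sq * gm$Emu2) / 2)
}

#' Variational update of the mixture weights
#'
#' Conjugate beta update of the voxelwise slab probabilities pi from the
#' subjects' slab membership posteriors.
#'
#' @param subjects List of subject map posteriors.
#' @param a0,b0 Beta hyperprior parameters.
#' @return List with \code{pi_a}, \code{pi_b} (V x M).
#' @export
update_mixture_weights <- function(subjects, a0 = 1, b0 = 1) {
  if (length(subjects) < 1) stop("need at least one subject", call. = FALSE)
  Sq <- Reduce(`+`, lapply(subjects, `[[`, "q_prob"))
  list(pi_a = a0 + Sq, pi_b = b0 + length(subjects) - Sq)
}

#' Marginal posterior mean of the group spatial maps
#'
#' The reported group map is the posterior mean of the whole spike-slab
#' distribution, \code{rho * mu}, not the slab means alone.
#'
#' @param group Group spatial posterior.
#' @return V x M matrix.
#' @export
group_map_point_estimate <- function(group) {
  group$rho_prob * group$mu_mean
}
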