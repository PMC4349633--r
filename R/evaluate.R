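# Scoring of decompositions against ground truth or against each other:
# uncentered correlation, Hungarian mode matching with joint sign handling,
# per-mode accuracy summaries, netmat RMS errors, test-retest reliability,
# Fisher-z group statistics, partial correlations, and the dual-regression
# baseline.

#' Uncentered correlation coefficient
#'
#' The sample Pearson correlation without mean removal:
#' \code{sum(x*y) / sqrt(sum(x^2) * sum(y^2))}. Matrix factorisations are not
#' invariant to shifts in the means, so means are deliberately kept.
#'
#' @param x,y Numeric vectors of equal length, neither all-zero.
#' @return Scalar in [-1, 1].
#' @export
uncentered_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0)
    stop("uncentered correlation undefined for a zero vector", call. = FALSE)
  max(-1, min(1, sum(x * y) / sqrt(sx * sy)))
}

# NA instead of an error for zero vectors; scores treat these as missing
ucor_safe <- function(x, y) {
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  max(-1, min(1, sum(x * y) / sqrt(sx * sy)))
}

# all pairwise uncentered correlations between columns of A and B
ucor_matrix <- function(A, B) {
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  na[na == 0] <- NA; nb[nb == 0] <- NA
  crossprod(A, B) / outer(na, nb)
}

#' Match estimated modes to reference modes
#'
#' Solves the assignment maximising the summed pair scores with the Hungarian
#' algorithm. Each candidate pair is scored at its better joint sign: the
#' pair score is |spatial + temporal correlation| with one sign flip applied
#' jointly to a mode's map and time course. When the mode counts differ the
#' excess modes are left unmatched.
#'
#' @param est,ref Lists with \code{maps} (V x M columns are modes) and
#'   optionally \code{tcs} (M x T rows are modes; both sets must have them or
#'   neither).
#' @return Object of class \code{pfm_match}: data frame-like list with
#'   \code{permutation} (ref index per matched est mode, NA if unmatched),
#'   \code{sign_flips}, \code{pair_scores} (matrix with spatial/temporal
#'   columns, at the chosen sign).
#' @export
match_modes <- function(est, ref) {
  if (is.null(est$maps) || is.null(ref$maps) ||
      ncol(est$maps) == 0 || ncol(ref$maps) == 0)
    stop("both mode sets must be non-empty", call. = FALSE)
  Me <- ncol(est$maps); Mr <- ncol(ref$maps)
  Cs <- ucor_matrix(est$maps, ref$maps)
  Ct <- if (!is.null(est$tcs) && !is.null(ref$tcs))
    ucor_matrix(t(est$tcs), t(ref$tcs)) else matrix(0, Me, Mr)
  tot <- Cs + Ct
  tot[is.na(tot)] <- 0
  score <- abs(tot)
  n <- max(Me, Mr)
  S <- matrix(0, n, n)
  S[seq_len(Me), seq_len(Mr)] <- score
  a <- solve_assignment(-S)
  perm <- rep(NA_integer_, Me)
  sgn <- rep(NA_real_, Me)
  ps <- matrix(NA_real_, Me, 2, dimnames = list(NULL,
                                                c("spatial", "temporal")))
  for (i in seq_len(Me)) {
    j <- a[i]
    if (j <= Mr) {
      perm[i] <- j
      sgn[i] <- if (tot[i, j] < 0) -1 else 1
      ps[i, ] <- sgn[i] * c(Cs[i, j], Ct[i, j])
    }
  }
  structure(list(permutation = perm, sign_flips = sgn, pair_scores = ps,
                 total_score = sum(S[cbind(seq_len(Me), a[seq_len(Me)])])),
            class = "pfm_match")
}

#' @export
print.pfm_match <- function(x, ...) {
  cat(sprintf("Mode matching: %d estimated modes, %d matched, total score %.3f\n",
              length(x$permutation), sum(!is.na(x$permutation)),
              x$total_score))
  invisible(x)
}

#' Score a decomposition against ground truth
#'
#' Per matched mode: the mean over subjects of the uncentered correlation
#' between estimated and true subject-specific maps (at the matched sign),
#' and the mean over runs of the time-course correlations. Group-level
#' methods without subject maps can be scored by passing the group map
#' replicated per subject (the ground-truth-group convention). Unmatched
#' modes are reported as NA, never as zero.
#'
#' @param est List with \code{subject_maps} (named list of V x M matrices),
#'   \code{timecourses} (named list per run of M x T) and \code{run_subject}
#'   (subject id per run, aligned with \code{timecourses} names).
#' @param truth Same structure (a simulator truth object works directly:
#'   \code{subject_maps}, \code{bold_tc}, \code{run_subject}).
#' @param match A \code{pfm_match} from group-level summaries of the same
#'   sets.
#' @return Object of class \code{pfm_scores}: list with \code{spatial}
#'   (per-est-mode mean map accuracy), \code{temporal} (per-est-mode mean
#'   time-course accuracy), \code{match}.
#' @export
score_decomposition <- function(est, truth, match) {
  truth_maps <- truth$subject_maps
  truth_tcs <- if (!is.null(truth$bold_tc)) truth$bold_tc else truth$timecourses
  Me <- length(match$permutation)
  spatial <- rep(NA_real_, Me)
  temporal <- rep(NA_real_, Me)
  nsub <- length(est$subject_maps)
  for (i in seq_len(Me)) {
    j <- match$permutation[i]
    if (is.na(j)) next
    sgn <- match$sign_flips[i]
    cs <- vapply(seq_len(nsub), function(s)
      ucor_safe(sgn * est$subject_maps[[s]][, i], truth_maps[[s]][, j]),
      numeric(1))
    spatial[i] <- mean(cs, na.rm = TRUE)
    if (!is.null(est$timecourses) && !is.null(truth_tcs)) {
      keys <- names(est$timecourses)
      ct <- vapply(keys, function(k)
        ucor_safe(sgn * est$timecourses[[k]][i, ], truth_tcs[[k]][j, ]),
        numeric(1))
      temporal[i] <- mean(ct, na.rm = TRUE)
    }
  }
  structure(list(spatial = spatial, temporal = temporal, match = match),
            class = "pfm_scores")
}

#' RMS error of the recovered inter-mode correlation structure
#'
#' Per subject, mode-by-mode correlation matrices are computed from the
#' subject maps (spatial) and the subject's concatenated run time courses
#' (temporal), on the matched modes with sign flips applied. The elementwise
#' error versus the ground-truth matrices is averaged over subjects, and the
#' RMS is taken over off-diagonal elements.
#'
#' @inheritParams score_decomposition
#' @return List with \code{spatial_rmse} and \code{temporal_rmse}.
#' @export
netmat_rmse <- function(est, truth, match) {
  keep <- which(!is.na(match$permutation))
  if (length(keep) < 2) return(list(spatial_rmse = NA_real_,
                                    temporal_rmse = NA_real_))
  perm <- match$permutation[keep]
  sgn <- match$sign_flips[keep]
  nsub <- length(est$subject_maps)
  subs <- names(truth$subject_maps)
  if (is.null(subs)) subs <- seq_len(nsub)
  err_s <- 0; err_t <- 0; has_t <- !is.null(est$timecourses)
  truth_tcs <- if (!is.null(truth$bold_tc)) truth$bold_tc else truth$timecourses
  for (s in seq_len(nsub)) {
    Ce <- stats::cor(est$subject_maps[[s]][, keep, drop = FALSE] %*%
                       diag(sgn, length(keep)))
    Ct <- stats::cor(truth$subject_maps[[s]][, perm, drop = FALSE])
    err_s <- err_s + (Ce - Ct)
    if (has_t) {
      rs <- names(est$timecourses)[est$run_subject ==
                                     unique(est$run_subject)[s]]
      Ae <- do.call(cbind, lapply(est$timecourses[rs], function(a)
        t(a[keep, , drop = FALSE])))
      At <- do.call(cbind, lapply(truth_tcs[rs], function(a)
        t(a[perm, , drop = FALSE])))
      Ce2 <- stats::cor(t(Ae) * sgn) ; Ct2 <- stats::cor(t(At))
      err_t <- err_t + (Ce2 - Ct2)
    }
  }
  off <- upper.tri(err_s) | lower.tri(err_s)
  list(spatial_rmse = sqrt(mean((err_s[off] / nsub)^2)),
       temporal_rmse = if (has_t) sqrt(mean((err_t[off] / nsub)^2))
                       else NA_real_)
}

#' Test-retest reliability of two decompositions
#'
#' Matches the mode sets of two fits of the same data (typically from
#' different random initialisations) and reports the per-pair group-map
#' correlation, together with the normalised map-strength statistic: each
#' analysis's per-mode map standard deviations are normalised by the largest
#' (the global component), and the maximum over the pair is reported. Pairs
#' whose normalised strength is close to zero have been eliminated by the
#' Bayesian model regularisation.
#'
#' @param a,b Lists with \code{maps} (V x M) and optionally \code{tcs}, or
#'   \code{pfm_state} objects.
#' @param threshold Elimination threshold on the normalised strength.
#' @return Data frame with \code{mode_a}, \code{mode_b}, \code{correlation},
#'   \code{strength} (max normalised sd of the pair), \code{eliminated}.
#' @export
test_retest <- function(a, b, threshold = 0.05) {
  as_modes <- function(x) {
    if (inherits(x, "pfm_state"))
      list(maps = group_map_point_estimate(x$group))
    else x
  }
  a <- as_modes(a); b <- as_modes(b)
  mt <- match_modes(a, b)
  norm_strength <- function(maps) {
    s <- apply(maps, 2, stats::sd)
    if (max(s) > 0) s / max(s) else s
  }
  sa <- norm_strength(a$maps); sb <- norm_strength(b$maps)
  keep <- which(!is.na(mt$permutation))
  cors <- vapply(keep, function(i)
    mt$sign_flips[i] * ucor_safe(a$maps[, i],
                                 b$maps[, mt$permutation[i]]), numeric(1))
  strength <- pmax(sa[keep], sb[mt$permutation[keep]])
  data.frame(mode_a = keep, mode_b = mt$permutation[keep],
             correlation = cors, strength = strength,
             eliminated = strength < threshold)
}

#' Group z-statistics of Fisher-transformed correlations
#'
#' Each subject's mode-by-mode correlation matrix is Fisher (atanh)
#' transformed; a one-sample t-test across subjects is performed on every
#' off-diagonal element, and the t value (S - 1 degrees of freedom) is
#' converted to a standard-normal-equivalent z by two-sided tail matching,
#' preserving sign.
#'
#' @param mats List of >= 3 subject correlation matrices (M x M).
#' @return M x M matrix of z statistics (diagonal 0).
#' @export
fisher_group_zstats <- function(mats) {
  S <- length(mats)
  if (S < 3) stop("need at least 3 subjects", call. = FALSE)
  M <- nrow(mats[[1]])
  zr <- lapply(mats, function(C) {
    if (any(abs(C[upper.tri(C) | lower.tri(C)]) >= 1))
      warning("correlation of magnitude 1 clipped before atanh")
    C <- pmin(pmax(C, -1 + 1e-12), 1 - 1e-12)
    atanh(C)
  })
  out <- matrix(0, M, M)
  for (i in seq_len(M)) for (j in seq_len(M)) {
    if (i == j) next
    x <- vapply(zr, `[`, numeric(1), i, j)
    sdx <- stats::sd(x)
    if (sdx == 0) {
      out[i, j] <- if (mean(x) == 0) 0 else sign(mean(x)) * Inf
      next
    }
    tval <- mean(x) / (sdx / sqrt(S))
    logp <- stats::pt(abs(tval), df = S - 1, lower.tail = FALSE,
                      log.p = TRUE)
    out[i, j] <- sign(tval) *
      stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  }
  out
}

#' Partial correlations of a subset of modes
#'
#' Computes the full partial correlation matrix from the inverse of the
#' correlation matrix of the complete mode set, then returns the requested
#' subset block: the subset's correlations after orthogonalisation with
#' respect to all remaining modes.
#'
#' @param x Numeric matrix with observations in rows and modes in columns
#'   (e.g. transposed time courses, or spatial maps with voxels as rows).
#' @param subset Integer indices of the modes to report.
#' @param reg_tol Condition-number threshold above which the correlation
#'   matrix is ridge-regularised (with a warning).
#' @return \code{length(subset)} square matrix, unit diagonal.
#' @export
partial_correlations <- function(x, subset = seq_len(ncol(x)),
                                 reg_tol = 1e8) {
  R <- stats::cor(x)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > reg_tol) {
    warning("ill-conditioned correlation matrix; ridge-regularising")
    R <- R + diag(max(ev) / reg_tol, ncol(R))
    R <- stats::cov2cor(R)
  }
  P <- -stats::cov2cor(solve(R))
  diag(P) <- 1
  P[subset, subset, drop = FALSE]
}

#' Dual regression
#'
#' Stage 1 regresses a run's data on the group maps to give mode time
#' courses; stage 2 regresses the data on those time courses to give
#' subject-specific maps.
#'
#' @param group_maps V x M matrix of full column rank.
#' @param run_data V x T data matrix.
#' @return List with \code{timecourses} (M x T) and \code{subject_maps}
#'   (V x M).
#' @export
dual_regression <- function(group_maps, run_data) {
  qrG <- qr(group_maps)
  if (qrG$rank < ncol(group_maps)) {
    bad <- sort(qrG$pivot[seq(qrG$rank + 1, ncol(group_maps))])
    stop("group maps are rank deficient; offending modes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  A <- qr.coef(qrG, run_data)                       # M x T
  qrA <- qr(t(A))
  P <- t(qr.coef(qrA, t(run_data)))                 # V x M
  list(timecourses = A, subject_maps = P)
}
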