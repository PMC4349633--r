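# Ground-truth simulator for multi-subject resting-state fMRI. The pipeline:
# a 1-D hard parcellation is drawn and smoothly warped per subject; sparse
# signed mode weights over parcels (with spatial clumping) define group and
# subject mode maps; low-frequency-enriched, inter-correlated neural time
# courses are amplitude-thresholded, convolved with per-parcel HRFs drawn
# from a small basis, passed through a compressive saturation, expanded to
# voxel space and buried in white noise at a controlled SNR.

#' Simulation configuration
#'
#' Defaults describe the reference simulated study: 30 subjects scanned 4
#' times for 1200 time points at a TR of 0.72 s, 12,500 voxels carved into
#' 200 parcels carrying 25 modes, with mode sparsities beta-distributed
#' (mean 0.08, variance 7.5e-4), subject atlas warps bounded by 1.5 mean
#' parcel widths, the smallest 80% of neural samples thresholded to zero,
#' and an overall SNR of -10 dB.
#'
#' @param ... Overrides for any field.
#' @return Named list of class \code{sim_config}.
#' @export
sim_config <- function(...) {
  cfg <- list(
    V = 12500L, N = 200L, M = 25L, S = 30L, runs_per_subject = 4L,
    T = 1200L, tr = 0.72, dt_neural = 0.1,
    sparsity_mean = 0.08, sparsity_var = 7.5e-4,
    zero_fraction = 0.8, snr_db = -10,
    max_shift_ratio = 1.5,
    adjacency_strength = 2, weight_ar = 0.7,
    subject_deviation_sparsity = 0.1, deviation_scale = 0.3,
    n_corr_factors = 8L, subject_corr_jitter = 0.15, run_corr_jitter = 0.08,
    lowfreq_gain = 3, lowfreq_knee = 0.1,
    saturation_c = 0.25,
    snr_scope = "dataset",
    hrf_per_voxel = FALSE,
    keep_neural = TRUE,
    seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$V >= 1, cfg$N >= 1, cfg$M >= 1, cfg$S >= 1,
            cfg$runs_per_subject >= 1, cfg$T >= 2,
            cfg$zero_fraction > 0, cfg$zero_fraction < 1,
            cfg$sparsity_mean > 0, cfg$sparsity_mean < 1,
            cfg$max_shift_ratio >= 0)
  structure(cfg, class = "sim_config")
}

#' Random contiguous 1-D parcellation
#'
#' Tiles the line of \code{V} voxels with \code{N} contiguous, disjoint
#' parcels with Dirichlet-distributed widths (minimum width 2 voxels).
#'
#' @param V,N Voxel and parcel counts (N <= V/2).
#' @param seed Integer seed.
#' @return Integer vector of length V with labels 1..N, non-decreasing.
#' @export
generate_atlas <- function(V, N, seed = 1L) {
  if (N > V / 2) stop("need N <= V/2 for minimum parcel width 2",
                      call. = FALSE)
  set.seed(as.integer(seed))
  w <- stats::rgamma(N, 1)             # Dirichlet(1,...,1) up to scale
  extra <- V - 2L * N
  add <- if (extra > 0) stats::rmultinom(1, extra, w / sum(w))[, 1] else 0L
  widths <- 2L + add
  rep.int(seq_len(N), widths)
}

# interior boundary positions (last voxel of parcels 1..N-1)
atlas_boundaries <- function(labels) {
  cumsum(tabulate(labels))[-max(labels)]
}

labels_from_boundaries <- function(bnd, V, N) {
  rep.int(seq_len(N), diff(c(0L, bnd, V)))
}

#' Smooth monotone warp of a parcellation
#'
#' Applies a low-pass-filtered Gaussian displacement field to the parcel
#' boundaries, rescaled so the maximum displacement does not exceed
#' \code{max_shift_ratio} mean parcel widths and so that the warp stays
#' monotone. Parcel count, order and contiguity are preserved.
#'
#' @param labels Atlas label vector (from \code{\link{generate_atlas}}).
#' @param max_shift_ratio Displacement bound in units of V/N.
#' @param seed Integer seed.
#' @param smooth_sd Gaussian smoothing of the displacement field, voxels.
#' @return Warped label vector with the same invariants.
#' @export
warp_atlas <- function(labels, max_shift_ratio = 1.5, seed = 1L,
                       smooth_sd = NULL) {
  V <- length(labels)
  N <- max(labels)
  if (max_shift_ratio == 0) return(labels)
  set.seed(as.integer(seed))
  if (is.null(smooth_sd)) smooth_sd <- max(4, V / 25)
  half <- ceiling(3 * smooth_sd)
  kern <- stats::dnorm(seq(-half, half), sd = smooth_sd)
  kern <- kern / sum(kern)
  x <- stats::rnorm(V + 2 * half)
  d <- stats::filter(x, kern, sides = 2)[(half + 1):(half + V)]
  bound <- max_shift_ratio * V / N
  d <- d / max(abs(d)) * 0.98 * bound
  # keep the map v -> v + d(v) monotone: limit the (negative) slope of d
  slope <- max(abs(diff(d)))
  if (slope > 0.9) d <- d * 0.9 / slope
  bnd <- atlas_boundaries(labels)
  nb <- bnd + d[bnd]
  nb <- round(nb)
  # clean up rounding collisions while keeping boundaries in range
  nb <- pmin(pmax(nb, seq_len(N - 1) * 2), V - 2 * (N - 1:(N - 1)))
  nb <- as.integer(cummax(nb))
  for (i in seq_len(N - 1)[-1])
    if (nb[i] <= nb[i - 1] + 1) nb[i] <- nb[i - 1] + 2L
  for (i in rev(seq_len(N - 1)[-(N - 1)]))
    if (nb[i] >= nb[i + 1] - 1) nb[i] <- nb[i + 1] - 2L
  labels_from_boundaries(nb, V, N)
}

# beta parameters by moment matching
beta_from_moments <- function(mean, var) {
  if (var >= mean * (1 - mean))
    stop("invalid beta moments: need var < mean*(1-mean)", call. = FALSE)
  t <- mean * (1 - mean) / var - 1
  c(a = mean * t, b = (1 - mean) * t)
}

#' Draw per-mode sparsities
#'
#' The beta distribution of the fraction of parcels carrying non-zero weight
#' in each mode, parameterised by its moments.
#'
#' @param M Number of modes.
#' @param sparsity_mean,sparsity_var Beta moments.
#' @param seed Integer seed.
#' @return Length-M vector of sparsities in (0, 1).
#' @export
sample_mode_sparsities <- function(M, sparsity_mean = 0.08,
                                   sparsity_var = 7.5e-4, seed = 1L) {
  ab <- beta_from_moments(sparsity_mean, sparsity_var)
  set.seed(as.integer(seed))
  stats::rbeta(M, ab["a"], ab["b"])
}

#' Sparse signed group mode weights over parcels
#'
#' Each mode selects \code{ceiling(s_m * N)} parcels, with the per-mode
#' sparsity s_m drawn from the beta distribution matched to the configured
#' mean and variance. Selection is Markovian: each new parcel is drawn with
#' probability proportional to 1 + adjacency_strength * (number of already
#' selected neighbours), producing spatially clumped modes. Selected parcels
#' receive signed Gaussian weights from an AR(1) process along the parcel
#' line, so adjacent selected parcels have correlated signs and magnitudes.
#'
#' @param N,M Parcel and mode counts.
#' @param sparsity_mean,sparsity_var Beta moments of the mode sparsities.
#' @param adjacency_strength Clumping strength (0 = exchangeable selection).
#' @param weight_ar AR(1) coefficient of the weight process.
#' @param seed Integer seed.
#' @return N x M matrix of signed weights, sparse by construction.
#' @export
sample_mode_weights <- function(N, M, sparsity_mean = 0.08,
                                sparsity_var = 7.5e-4,
                                adjacency_strength = 2, weight_ar = 0.7,
                                seed = 1L) {
  sp <- sample_mode_sparsities(M, sparsity_mean, sparsity_var, seed)
  set.seed(as.integer(seed) + 1L)
  W <- matrix(0, N, M)
  for (m in seq_len(M)) {
    k <- min(N, max(1L, ceiling(sp[m] * N)))
    sel <- logical(N)
    for (j in seq_len(k)) {
      if (!any(sel)) {
        pick <- sample.int(N, 1)
      } else {
        nb <- c(sel[-1], FALSE) + c(FALSE, sel[-N])
        w <- (1 + adjacency_strength * nb) * !sel
        pick <- sample.int(N, 1, prob = w)
      }
      sel[pick] <- TRUE
    }
    z <- numeric(N)
    z[1] <- stats::rnorm(1)
    for (i in 2:N)
      z[i] <- weight_ar * z[i - 1] +
        sqrt(1 - weight_ar^2) * stats::rnorm(1)
    W[sel, m] <- z[sel]
  }
  W
}

#' Subject-specific mode weights
#'
#' Adds a sparse set of Gaussian deviations around the group weights:
#' each entry is perturbed independently with probability
#' \code{deviation_sparsity}, by N(0, deviation_scale^2).
#'
#' @param group_weights N x M group weight matrix.
#' @param S Number of subjects.
#' @param deviation_sparsity Bernoulli probability of perturbing an entry.
#' @param deviation_scale Standard deviation of a perturbation.
#' @param seed Integer seed.
#' @return List of S matrices (N x M).
#' @export
sample_subject_weights <- function(group_weights, S,
                                   deviation_sparsity = 0.1,
                                   deviation_scale = 0.3, seed = 1L) {
  set.seed(as.integer(seed))
  N <- nrow(group_weights); M <- ncol(group_weights)
  lapply(seq_len(S), function(s) {
    mask <- matrix(stats::rbinom(N * M, 1, deviation_sparsity), N, M)
    group_weights + mask * matrix(stats::rnorm(N * M, sd = deviation_scale),
                                  N, M)
  })
}

#' Random group inter-mode correlation matrix
#'
#' Low-rank-plus-diagonal factor construction giving non-trivial positive and
#' negative correlations between modes.
#'
#' @param M Mode count.
#' @param n_factors Number of latent factors.
#' @param seed Integer seed.
#' @return M x M correlation matrix.
#' @export
make_group_correlation <- function(M, n_factors = max(2L, M %/% 3L),
                                   seed = 1L) {
  set.seed(as.integer(seed))
  B <- matrix(stats::rnorm(M * n_factors), M, n_factors)
  C <- tcrossprod(B) + diag(0.5 * n_factors, M)
  stats::cov2cor(C)
}

#' Perturb a correlation matrix
#'
#' Adds symmetric Gaussian jitter to the off-diagonal and repairs positive
#' definiteness by eigenvalue clipping (with a warning when a repair was
#' needed), renormalising to unit diagonal.
#'
#' @param C Correlation matrix.
#' @param jitter Standard deviation of the elementwise perturbation.
#' @param seed Integer seed.
#' @return Perturbed correlation matrix.
#' @export
perturb_correlation <- function(C, jitter, seed = 1L) {
  set.seed(as.integer(seed))
  M <- nrow(C)
  E <- matrix(stats::rnorm(M * M, sd = jitter), M, M)
  E <- (E + t(E)) / 2
  diag(E) <- 0
  C2 <- C + E
  eg <- eigen(C2, symmetric = TRUE)
  if (min(eg$values) <= 1e-8) {
    warning("perturbed correlation matrix not positive definite; clipping")
    vals <- pmax(eg$values, 1e-6)
    C2 <- eg$vectors %*% (vals * t(eg$vectors))
  }
  stats::cov2cor(C2)
}

#' Correlated, low-frequency-enriched, amplitude-thresholded neural series
#'
#' Draws Gaussian series with the target instantaneous inter-mode
#' correlation, boosts spectral power below the knee frequency by filtering
#' every mode with the same zero-phase low-pass-plus-passthrough filter
#' (which preserves the instantaneous correlations of temporally white
#' input), and finally sets the smallest \code{zero_fraction} of each mode's
#' samples, by absolute amplitude, exactly to zero.
#'
#' @param C M x M target correlation matrix.
#' @param T_high Number of high-resolution samples.
#' @param dt Sample spacing in seconds.
#' @param lowfreq_gain Gain of the low-pass branch.
#' @param lowfreq_knee Knee frequency in Hz.
#' @param zero_fraction Proportion of samples zeroed per mode.
#' @param seed Integer seed.
#' @return M x T_high matrix.
#' @export
sample_neural_timecourses <- function(C, T_high, dt = 0.1, lowfreq_gain = 3,
                                      lowfreq_knee = 0.1, zero_fraction = 0.8,
                                      seed = 1L) {
  stopifnot(zero_fraction > 0, zero_fraction < 1)
  set.seed(as.integer(seed))
  M <- nrow(C)
  L <- chol(C)
  X <- crossprod(L, matrix(stats::rnorm(M * T_high), M, T_high))
  if (lowfreq_gain > 0) {
    bf <- signal::butter(2, min(0.999, lowfreq_knee / (0.5 / dt)))
    X <- t(apply(X, 1, function(x) {
      x + lowfreq_gain * signal::filtfilt(bf, x)
    }))
    if (M == 1) X <- matrix(X, 1, T_high)
  }
  X <- X / apply(X, 1, stats::sd)
  nzero <- round(zero_fraction * T_high)
  for (m in seq_len(M)) {
    idx <- order(abs(X[m, ]))[seq_len(nzero)]
    X[m, idx] <- 0
  }
  X
}

#' HRF basis for the simulator
#'
#' Three double-gamma kernels: the canonical one and two temporal-dispersion
#' perturbations, all unit peak.
#'
#' @param dt Sample spacing in seconds.
#' @param duration Kernel length in seconds.
#' @return List of three \code{hrf_kernel}s.
#' @export
hrf_basis <- function(dt, duration = 32) {
  list(canonical_hrf(dt, duration),
       canonical_hrf(dt, duration, peak_disp = 0.85, undershoot_disp = 0.85),
       canonical_hrf(dt, duration, peak_disp = 1.2, undershoot_disp = 1.2))
}

#' Convolve neural series with HRFs and resample to the TR grid
#'
#' Causally convolves each row with its assigned kernel and samples the
#' result at times k*tr (linear interpolation between high-resolution
#' samples; exact when tr is an integer multiple of dt).
#'
#' @param series R x T_high matrix of neural series.
#' @param kernels List of \code{hrf_kernel}s sampled at \code{dt}.
#' @param assign Length-R integer vector mapping rows to kernels.
#' @param dt High-resolution spacing, seconds.
#' @param tr Output spacing, seconds (>= dt).
#' @param T_out Number of output samples.
#' @return R x T_out matrix.
#' @export
apply_haemodynamics <- function(series, kernels, assign, dt, tr, T_out) {
  if (tr < dt - 1e-12) stop("'tr' must be >= dt", call. = FALSE)
  R <- nrow(series); T_high <- ncol(series)
  if (length(assign) != R) stop("'assign' must have one entry per row",
                                call. = FALSE)
  tt <- (seq_len(T_out) - 1) * tr / dt + 1
  if (max(tt) > T_high)
    stop("series too short for the requested output length", call. = FALSE)
  lo <- floor(tt); frac <- tt - lo
  hi <- pmin(lo + 1, T_high)
  nh <- max(vapply(kernels, function(k) length(k$samples), 0L))
  nfft <- stats::nextn(T_high + nh - 1L, c(2L, 3L, 5L))
  Hf <- lapply(kernels, function(k) {
    stats::fft(c(k$samples, rep(0, nfft - length(k$samples))))
  })
  out <- matrix(0, R, T_out)
  for (r in seq_len(R)) {
    # causal FFT convolution: y_t = sum_i h_i x_{t-i+1}
    xf <- stats::fft(c(series[r, ], rep(0, nfft - T_high)))
    y <- Re(stats::fft(xf * Hf[[assign[r]]], inverse = TRUE))[seq_len(T_high)] /
      nfft
    out[r, ] <- y[lo] * (1 - frac) + y[hi] * frac
  }
  out
}

#' Compressive saturation nonlinearity
#'
#' Odd, monotone, compressive map y = x - c * x * |x| for |x| <= 1/(2c),
#' continued at its extremum value 1/(4c) beyond; the identity when c = 0.
#'
#' @param x Numeric input (any shape).
#' @param saturation_c Curvature c >= 0.
#' @return Same shape as \code{x}.
#' @export
apply_saturation <- function(x, saturation_c = 0.25) {
  if (saturation_c < 0) stop("'saturation_c' must be >= 0", call. = FALSE)
  if (saturation_c == 0) return(x)
  lim <- 1 / (2 * saturation_c)
  y <- x - saturation_c * x * abs(x)
  y[x > lim] <- 1 / (4 * saturation_c)
  y[x < -lim] <- -1 / (4 * saturation_c)
  y
}

#' Add white Gaussian noise at an exact SNR
#'
#' The drawn noise is rescaled post hoc so that the realised
#' 10*log10(P_signal / P_noise) equals \code{snr_db} exactly.
#'
#' @param clean Numeric matrix of clean signal (non-zero power).
#' @param snr_db Target SNR in decibels.
#' @param seed Integer seed.
#' @param noise_power Optional externally fixed noise power (variance); used
#'   to share one noise level across the runs of a dataset.
#' @return List with \code{data} and \code{noise}.
#' @export
add_noise <- function(clean, snr_db, seed = 1L, noise_power = NULL) {
  ps <- mean(clean^2)
  if (is.null(noise_power)) {
    if (ps <= 0) stop("'clean' has zero power", call. = FALSE)
    noise_power <- ps / 10^(snr_db / 10)
  }
  set.seed(as.integer(seed))
  nz <- matrix(stats::rnorm(length(clean)), nrow(clean), ncol(clean))
  nz <- nz * sqrt(noise_power / mean(nz^2))
  list(data = clean + nz, noise = nz)
}

#' Simulate a full multi-subject dataset with ground truth
#'
#' Composes all simulation stages. With defaults this yields 30 subjects x 4
#' runs x 1200 time points x 12,500 voxels (4800 time points per subject,
#' 144,000 in total). Fully reproducible from \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{data} (a \code{pfm_dataset}) and \code{truth}
#'   (group/subject weights, subject atlases and maps, neural and BOLD mode
#'   time courses per run, clean signal and noise per run, the group
#'   correlation matrix and the config echo).
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  sd0 <- as.integer(cfg$seed)
  T_high <- ceiling(((cfg$T - 1) * cfg$tr + cfg$tr) / cfg$dt_neural) +
    length(canonical_hrf(cfg$dt_neural, 32)$samples) + 2L

  atlas <- generate_atlas(cfg$V, cfg$N, seed = sd0)
  sub_atlas <- lapply(seq_len(cfg$S), function(s)
    warp_atlas(atlas, cfg$max_shift_ratio, seed = sd0 + 1000L + s))
  W <- sample_mode_weights(cfg$N, cfg$M, cfg$sparsity_mean, cfg$sparsity_var,
                           cfg$adjacency_strength, cfg$weight_ar,
                           seed = sd0 + 2L)
  Ws <- sample_subject_weights(W, cfg$S, cfg$subject_deviation_sparsity,
                               cfg$deviation_scale, seed = sd0 + 3L)
  Cg <- make_group_correlation(cfg$M, cfg$n_corr_factors, seed = sd0 + 4L)
  basis <- hrf_basis(cfg$dt_neural)
  hrf_canon <- list(basis[[1]])

  subject_maps <- lapply(seq_len(cfg$S), function(s)
    Ws[[s]][sub_atlas[[s]], , drop = FALSE])

  runs <- list(); clean <- list(); noise <- list()
  neural <- list(); bold <- list()
  subj_ids <- sprintf("sub%02d", seq_len(cfg$S))
  for (s in seq_len(cfg$S)) {
    Cs <- perturb_correlation(Cg, cfg$subject_corr_jitter,
                              seed = sd0 + 5000L + s)
    hrf_assign <- {
      set.seed(sd0 + 7000L + s)
      sample.int(length(basis), cfg$N, replace = TRUE)
    }
    for (r in seq_len(cfg$runs_per_subject)) {
      key <- paste(subj_ids[s], sprintf("run%d", r), sep = "/")
      Csr <- perturb_correlation(Cs, cfg$run_corr_jitter,
                                 seed = sd0 + 9000L + s * 10L + r)
      ntc <- sample_neural_timecourses(Csr, T_high, cfg$dt_neural,
                                       cfg$lowfreq_gain, cfg$lowfreq_knee,
                                       cfg$zero_fraction,
                                       seed = sd0 + 20000L + s * 50L + r)
      parcel_neural <- Ws[[s]] %*% ntc            # N x T_high
      parcel_bold <- apply_haemodynamics(parcel_neural, basis, hrf_assign,
                                         cfg$dt_neural, cfg$tr, cfg$T)
      parcel_bold <- apply_saturation(parcel_bold, cfg$saturation_c)
      clean[[key]] <- parcel_bold[sub_atlas[[s]], , drop = FALSE]
      if (cfg$keep_neural) neural[[key]] <- ntc
      bold[[key]] <- apply_haemodynamics(ntc, hrf_canon,
                                         rep(1L, cfg$M),
                                         cfg$dt_neural, cfg$tr, cfg$T)
    }
  }

  noise_power <- if (identical(cfg$snr_scope, "dataset")) {
    mean(vapply(clean, function(x) mean(x^2), 0)) / 10^(cfg$snr_db / 10)
  } else NULL
  i <- 0L
  for (key in names(clean)) {
    i <- i + 1L
    an <- add_noise(clean[[key]], cfg$snr_db, seed = sd0 + 40000L + i,
                    noise_power = noise_power)
    runs[[key]] <- an$data
    noise[[key]] <- an$noise
  }

  data <- multi_run_dataset(runs, tr = cfg$tr)
  truth <- list(group_weights = W, subject_weights = Ws,
                group_atlas = atlas, subject_atlases = sub_atlas,
                subject_maps = subject_maps,
                group_maps = W[atlas, , drop = FALSE],
                neural_tc = neural, bold_tc = bold,
                clean = clean, noise = noise,
                group_correlation = Cg,
                run_subject = data$run_subject,
                config = cfg)
  list(data = data, truth = truth)
}
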