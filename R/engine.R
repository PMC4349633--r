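# Coordinate-ascent variational inference engine: model configuration,
# initialisation, and the full-sweep fitting loop.

#' Default model configuration
#'
#' Collects every tunable hyperparameter and sweep control in one list.
#' Hyperprior values: flat beta(1, 1) on the slab probabilities pi; broad
#' gamma(1e-3, 1e-3) hyperpriors on the temporal and noise precisions and on
#' the slab precisions 1/sigma^2; unit precision gamma_m on the group slab;
#' group sparsity lambda defaulting to 5/M (kept above 1/M so that spatially
#' distributed, overlapping modes are not penalised away); vague N(0, 1e4)
#' prior on the voxel means.
#'
#' @param M Mode count, used only to resolve the default \code{lambda}.
#' @param ... Overrides for any element of the returned list.
#' @return Named list of configuration values.
#' @export
pfm_config <- function(M = 25, ...) {
  cfg <- list(
    lambda = min(5 / M, 0.75),
    gamma_prec = 1,
    pi_a0 = 1, pi_b0 = 1,
    sigma_shape0 = 1e-3, sigma_rate0 = 1e-3,
    alpha_shape0 = 1e-3, alpha_rate0 = 1e-3,
    psi_shape0 = 1e-3, psi_rate0 = 1e-3,
    nu_var0 = 1e4,
    hrf_duration = 32,
    hrf_peak_delay = 6, hrf_undershoot_delay = 16,
    hrf_peak_disp = 1, hrf_undershoot_disp = 1,
    hrf_undershoot_ratio = 1 / 6,
    normalise = TRUE,
    warmup_sweeps = 10,
    max_iter = 1000,
    tol = 1e-8, tol_sweeps = 5,
    init = "svd",
    elimination_threshold = 0.05,
    verbose = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

make_hyper <- function(cfg, M) {
  list(pi_a0 = cfg$pi_a0, pi_b0 = cfg$pi_b0,
       sigma_shape0 = cfg$sigma_shape0, sigma_rate0 = cfg$sigma_rate0,
       alpha_shape0 = cfg$alpha_shape0, alpha_rate0 = cfg$alpha_rate0,
       psi_shape0 = cfg$psi_shape0, psi_rate0 = cfg$psi_rate0,
       nu_var0 = cfg$nu_var0,
       gamma_prec = rep(cfg$gamma_prec, length.out = M),
       lambda = cfg$lambda)
}

# variance-normalise each voxel of each run; zero-variance voxels untouched
normalise_dataset <- function(data) {
  for (k in names(data$runs)) {
    sdv <- apply(data$runs[[k]], 1, stats::sd)
    sdv[sdv == 0] <- 1
    data$runs[[k]] <- data$runs[[k]] / sdv
  }
  data
}

# voxels with zero variance in every run carry no evidence; their slab
# probabilities are pinned to zero rather than left to produce NaNs
degenerate_voxels <- function(data) {
  vv <- Reduce(`+`, lapply(data$runs, function(D) {
    rs <- rowSums((D - rowMeans(D))^2)
    as.numeric(rs > 0)
  }))
  which(vv == 0)
}

#' Initialise a model state
#'
#' Builds a reproducible starting state for \code{\link{pfm_fit}}. The
#' \code{"random"} scheme draws subject slab means from N(0, 1) with slab
#' probabilities at \code{lambda}; the \code{"svd"} scheme seeds the group and
#' subject means from the top-M left singular vectors of the concatenated
#' demeaned data. In both schemes the run time courses are then initialised by
#' ridge regression of each run on the initial maps, and the noise precisions
#' from the residual variance.
#'
#' @param data A \code{pfm_dataset}.
#' @param M Number of modes (1 <= M < min(V, total T)).
#' @param seed Integer RNG seed; the state is a deterministic function of
#'   (data, M, seed, scheme).
#' @param scheme \code{"svd"} or \code{"random"}.
#' @param config A \code{\link{pfm_config}} list.
#' @return A \code{pfm_state}.
#' @export
pfm_init <- function(data, M, seed = 1L, scheme = c("svd", "random"),
                     config = pfm_config(M)) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(data, "pfm_dataset"))
  Ts <- vapply(data$runs, ncol, 0L)
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M >= min(data$V, sum(Ts)))
    stop("'M' must satisfy 1 <= M < min(V, total T)", call. = FALSE)
  M <- as.integer(M)
  V <- data$V
  set.seed(as.integer(seed))

  hrf_tr <- canonical_hrf(data$tr, config$hrf_duration,
                          peak_delay = config$hrf_peak_delay,
                          undershoot_delay = config$hrf_undershoot_delay,
                          peak_disp = config$hrf_peak_disp,
                          undershoot_disp = config$hrf_undershoot_disp,
                          undershoot_ratio = config$hrf_undershoot_ratio)
  priors <- list()
  for (T_ in unique(Ts))
    priors[[as.character(T_)]] <- build_temporal_prior(T_, data$tr,
                                                       hrf = hrf_tr)
  hyper <- make_hyper(config, M)

  if (scheme == "svd") {
    X <- do.call(cbind, lapply(data$runs, function(D) D - rowMeans(D)))
    sv <- svd(X, nu = M, nv = 0)
    maps <- sv$u %*% diag(sv$d[seq_len(M)] / sqrt(ncol(X)), M)
  } else {
    maps <- matrix(stats::rnorm(V * M), V, M)
  }

  group <- list(
    pi_a = matrix(1, V, M), pi_b = matrix(1, V, M),
    rho_prob = matrix(if (scheme == "svd") 1 else hyper$lambda, V, M),
    mu_mean = if (scheme == "svd") maps else matrix(0, V, M),
    mu_var = matrix(1, V, M),
    sigma_shape = matrix(1, V, M), sigma_rate = matrix(1, V, M),
    gamma_prec = hyper$gamma_prec, lambda = hyper$lambda)

  subjects <- list()
  for (s in data$subjects) {
    sm <- if (scheme == "svd") {
      # seed-dependent start: group means are the singular vectors, subject
      # slab means are perturbed around them at the scale of the maps
      sds <- apply(maps, 2, stats::sd)
      maps + matrix(stats::rnorm(V * M), V, M) %*% diag(sds, M)
    } else {
      matrix(stats::rnorm(V * M), V, M)
    }
    subjects[[s]] <- list(slab_mean = sm,
                          slab_var = matrix(1, V, M),
                          q_prob = matrix(hyper$lambda, V, M))
  }

  alpha <- list(shape = 1, rate = 1)
  tc <- list(); noise <- list()
  for (k in names(data$runs)) {
    D <- data$runs[[k]]
    s <- data$run_subject[match(k, names(data$runs))]
    EP <- subjects[[s]]$q_prob * subjects[[s]]$slab_mean
    G <- crossprod(EP)
    ridge <- max(1e-8, 1e-6 * sum(diag(G)) / M)
    A <- solve(G + diag(ridge, M), crossprod(EP, D - rowMeans(D)))
    tc[[k]] <- list(mean = A, c = rep(1, M), alpha_at = 1)
    R <- D - rowMeans(D) - EP %*% A
    psi0 <- length(R) / max(sum(R^2), 1e-12)
    noise[[k]] <- list(psi_shape = hyper$psi_shape0 + length(R) / 2,
                       psi_rate = (hyper$psi_shape0 + length(R) / 2) / psi0,
                       nu_mean = rowMeans(D),
                       nu_var = rep(hyper$nu_var0 /
                                      (1 + hyper$nu_var0), V))
  }

  structure(list(M = M, V = V, tr = data$tr, hyper = hyper,
                 priors = priors, group = group, subjects = subjects,
                 tc = tc, alpha = alpha, noise = noise,
                 elbo_trace = numeric(0), rng_seed = as.integer(seed),
                 scheme = scheme, config = config,
                 degenerate = degenerate_voxels(data)),
            class = "pfm_state")
}

#' @export
print.pfm_state <- function(x, ...) {
  cat(sprintf("PFM model state: %d modes, %d voxels, %d subjects, %d runs\n",
              x$M, x$V, length(x$subjects), length(x$tc)))
  if (length(x$elbo_trace))
    cat(sprintf("  %d sweeps, final ELBO %.6g\n",
                length(x$elbo_trace), x$elbo_trace[length(x$elbo_trace)]))
  invisible(x)
}

# One coordinate-ascent sweep, in the fixed order: subject maps ->
# group means -> group variances -> mixture weights -> time courses ->
# temporal precision -> noise. During warm-up sweeps (warm = TRUE) the
# precision updates (group variances, temporal precision, noise) are held at
# their broad initial values so that maps and time courses can locate the
# signal subspace before shrinkage engages; every update performed is still
# an exact coordinate maximisation, so the ELBO never decreases either way.
pfm_sweep <- function(state, data, warm = FALSE) {
  hyper <- state$hyper
  runs_of <- split(names(data$runs), data$run_subject)

  # --- subject maps
  for (s in names(state$subjects)) {
    ev <- lapply(runs_of[[s]], function(k) {
      nz <- state$noise[[k]]
      list(D = data$runs[[k]], tc = state$tc[[k]],
           prior = state$priors[[as.character(ncol(data$runs[[k]]))]],
           psi_mean = nz$psi_shape / nz$psi_rate, nu_mean = nz$nu_mean)
    })
    sb <- state$subjects[[s]]
    upd <- update_subject_maps(ev, sb$q_prob * sb$slab_mean, state$group)
    if (length(state$degenerate)) {
      upd$q_prob[state$degenerate, ] <- 0
      upd$slab_mean[state$degenerate, ] <- 0
    }
    state$subjects[[s]] <- upd
  }

  # --- group hierarchy
  gu <- update_group_means(state$subjects, state$group)
  state$group[names(gu)] <- gu
  if (!warm) {
    sv <- update_group_variances(state$subjects, state$group,
                                 hyper$sigma_shape0, hyper$sigma_rate0)
    state$group[names(sv)] <- sv
  }
  pw <- update_mixture_weights(state$subjects, hyper$pi_a0, hyper$pi_b0)
  state$group[names(pw)] <- pw

  # --- time courses
  Ealpha <- state$alpha$shape / state$alpha$rate
  for (k in names(data$runs)) {
    s <- data$run_subject[match(k, names(data$runs))]
    mm <- map_moments(state$subjects[[s]])
    nz <- state$noise[[k]]
    prior <- state$priors[[as.character(ncol(data$runs[[k]]))]]
    state$tc[[k]] <- update_time_courses(
      data$runs[[k]], mm$EP, mm$EP2, nz$nu_mean,
      nz$psi_shape / nz$psi_rate, Ealpha, prior,
      mean_init = state$tc[[k]]$mean)
  }

  # --- temporal precision
  if (!warm)
    state$alpha <- update_temporal_precision(state$tc, state$priors,
                                             hyper$alpha_shape0,
                                             hyper$alpha_rate0)
  if (warm) return(state)

  # --- noise
  for (k in names(data$runs)) {
    s <- data$run_subject[match(k, names(data$runs))]
    mm <- map_moments(state$subjects[[s]])
    nz <- state$noise[[k]]
    prior <- state$priors[[as.character(ncol(data$runs[[k]]))]]
    state$noise[[k]] <- update_noise(
      data$runs[[k]], mm$EP, mm$EP2, state$tc[[k]], prior,
      nz$psi_shape / nz$psi_rate,
      hyper$psi_shape0, hyper$psi_rate0, hyper$nu_var0)
  }
  state
}

#' Fit probabilistic functional modes by variational Bayes
#'
#' Runs full coordinate-ascent sweeps over all variational factors until the
#' relative ELBO change stays below \code{config$tol} for
#' \code{config$tol_sweeps} consecutive sweeps, or \code{config$max_iter}
#' sweeps have run. The ELBO trace is non-decreasing up to numerical
#' tolerance.
#'
#' @param data A \code{pfm_dataset}.
#' @param M Number of modes to infer.
#' @param config A \code{\link{pfm_config}} list.
#' @param seed Integer seed controlling the initialisation.
#' @param state Optional pre-built state (overrides \code{seed}/init scheme).
#' @return The fitted \code{pfm_state}, with \code{elbo_trace}.
#' @export
pfm_fit <- function(data, M, config = pfm_config(M), seed = 1L,
                    state = NULL) {
  stopifnot(inherits(data, "pfm_dataset"))
  if (isTRUE(config$normalise)) data <- normalise_dataset(data)
  if (is.null(state))
    state <- pfm_init(data, M, seed = seed, scheme = config$init,
                      config = config)
  trace <- state$elbo_trace
  streak <- 0L
  warmup <- max(0L, as.integer(config$warmup_sweeps))
  for (it in seq_len(config$max_iter)) {
    state <- pfm_sweep(state, data, warm = it <= warmup)
    el <- compute_elbo(state, data)
    if (!is.finite(el)) {
      print(compute_elbo(state, data, by_term = TRUE))
      stop("non-finite ELBO at sweep ", it, call. = FALSE)
    }
    trace <- c(trace, el)
    if (isTRUE(config$verbose))
      message(sprintf("sweep %4d  ELBO %.8g", it, el))
    n <- length(trace)
    if (n > 1) {
      rel <- abs(trace[n] - trace[n - 1]) / max(abs(trace[n]), 1)
      streak <- if (rel < config$tol) streak + 1L else 0L
      if (streak >= config$tol_sweeps) break
    }
  }
  state$elbo_trace <- trace
  state
}

#' Normalised mode strengths and elimination flags
#'
#' For each mode, the standard deviation of the group point-estimate map,
#' normalised by the largest such standard deviation across modes (the
#' strongest mode plays the role of the global component). Modes whose
#' normalised strength falls below the elimination threshold have effectively
#' been removed by the Bayesian model regularisation.
#'
#' When \code{data} is supplied the normalisation is instead by the pooled
#' data standard deviation, which is the right yardstick for checking that a
#' noise-only fit shrank every mode away (by the strongest-mode yardstick the
#' strongest mode is 1 by construction).
#'
#' @param state A fitted \code{pfm_state}.
#' @param threshold Elimination threshold on the normalised strength.
#' @param data Optional \code{pfm_dataset}; normalise by its pooled sd.
#' @return Data frame with \code{mode}, \code{strength} (raw map sd),
#'   \code{normalised}, \code{eliminated}.
#' @export
mode_strengths <- function(state, threshold = state$config$elimination_threshold,
                           data = NULL) {
  maps <- group_map_point_estimate(state$group)
  s <- apply(maps, 2, stats::sd)
  ref <- if (is.null(data)) max(s)
         else stats::sd(unlist(lapply(data$runs, as.numeric)))
  norm <- if (ref > 0) s / ref else s
  data.frame(mode = seq_len(state$M), strength = s, normalised = norm,
             eliminated = norm < threshold)
}
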