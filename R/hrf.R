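#' Canonical double-gamma haemodynamic response function
#'
#' Evaluates the canonical double-gamma HRF (a positive gamma response minus a
#' scaled gamma undershoot) on a regular time grid and rescales it to unit
#' peak. The default shape parameters are the widely used ones: response
#' peaking near 5-6 s, undershoot near 16 s, unit dispersions, undershoot
#' ratio 1/6.
#'
#' @param dt Sample spacing in seconds (> 0).
#' @param duration Kernel length in seconds (>= 2*dt).
#' @param peak_delay Delay of the positive response in seconds.
#' @param undershoot_delay Delay of the undershoot in seconds.
#' @param peak_disp,undershoot_disp Dispersions (scale parameters) in seconds.
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @return An object of class \code{hrf_kernel}: a list with \code{samples}
#'   (amplitudes at \code{k*dt}, k = 0..round(duration/dt)-1, max exactly 1),
#'   \code{dt} and \code{duration}.
#' @examples
#' h <- canonical_hrf(0.72, 32)
#' length(h$samples)  # 44
#' @export
canonical_hrf <- function(dt, duration,
                          peak_delay = 6, undershoot_delay = 16,
                          peak_disp = 1, undershoot_disp = 1,
                          undershoot_ratio = 1 / 6) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration < 2 * dt)
    stop("'duration' must be a single number >= 2*dt", call. = FALSE)
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  # dgamma parameterisation: shape = delay/dispersion, scale = dispersion
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    undershoot_ratio *
      stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                    scale = undershoot_disp)
  h <- h / max(h)
  structure(list(samples = h, dt = dt, duration = duration),
            class = "hrf_kernel")
}

#' Autocovariance of an HRF kernel
#'
#' The raw (uncentered) autocovariance sequence of the kernel: element
#' \code{lag + 1} is \code{sum_tau h(tau) h(tau - lag)}. For white neural
#' input this is, up to scale, the autocorrelation induced in the observed
#' BOLD signal, which is what the temporal prior encodes.
#'
#' @param h An \code{hrf_kernel} or a numeric vector of kernel samples.
#' @param max_lag Largest lag (in samples); must be < length of the kernel.
#' @return Numeric vector of length \code{max_lag + 1}, lags 0..max_lag.
#' @export
hrf_autocovariance <- function(h, max_lag) {
  x <- if (inherits(h, "hrf_kernel")) h$samples else as.numeric(h)
  n <- length(x)
  if (!is.numeric(max_lag) || length(max_lag) != 1L || max_lag < 0 ||
      max_lag >= n)
    stop("'max_lag' must be in [0, length(h) - 1]", call. = FALSE)
  max_lag <- as.integer(max_lag)
  vapply(0:max_lag, function(lag) {
    sum(x[(1 + lag):n] * x[1:(n - lag)])
  }, numeric(1))
}

#' Temporal prior covariance from the HRF autocorrelation
#'
#' Builds the T x T prior covariance for mode time courses: a Toeplitz matrix
#' whose band is the autocovariance of the canonical HRF sampled at the
#' repetition time, rescaled to unit diagonal so that the precision
#' hyperparameter is interpretable as the marginal time-course precision, and
#' ridge-regularised until positive definite.
#'
#' @param T_ Number of time points (>= 2).
#' @param tr Repetition time in seconds (> 0).
#' @param hrf Optional \code{hrf_kernel} sampled at \code{tr}; defaults to
#'   \code{canonical_hrf(tr, 32)}.
#' @param covariance Optional explicit T x T covariance (symmetric positive
#'   definite after regularisation); overrides the HRF construction. Used for
#'   reductions such as an identity prior.
#' @param ridge_rel Relative ridge added (repeatedly, doubling) until the
#'   smallest eigenvalue is positive; fraction of the largest eigenvalue.
#' @return An object of class \code{temporal_prior}: list with \code{K}
#'   (covariance), \code{T}, \code{tr}, \code{eig} (eigendecomposition with
#'   \code{values}, \code{vectors}), and \code{logdet}.
#' @export
build_temporal_prior <- function(T_, tr = 1, hrf = NULL, covariance = NULL,
                                 ridge_rel = 1e-6) {
  if (!is.numeric(T_) || length(T_) != 1L || T_ < 2)
    stop("'T_' must be >= 2", call. = FALSE)
  T_ <- as.integer(T_)
  if (is.null(covariance)) {
    if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
      stop("'tr' must be a single positive number", call. = FALSE)
    if (is.null(hrf)) hrf <- canonical_hrf(tr, 32)
    nh <- length(hrf$samples)
    band <- numeric(T_)
    ml <- min(T_ - 1L, nh - 1L)
    band[seq_len(ml + 1L)] <- hrf_autocovariance(hrf, ml)
    K <- stats::toeplitz(band / band[1])
  } else {
    K <- (covariance + t(covariance)) / 2
    if (!all(dim(K) == c(T_, T_)))
      stop("'covariance' must be T x T", call. = FALSE)
  }
  eg <- eigen(K, symmetric = TRUE)
  ridge <- ridge_rel * max(eg$values)
  while (min(eg$values) + ridge <= 0) ridge <- 2 * ridge
  K <- K + diag(ridge, T_)
  eg$values <- eg$values + ridge
  structure(list(K = K, T = T_, tr = tr, eig = eg,
                 logdet = sum(log(eg$values)), ridge = ridge),
            class = "temporal_prior")
}

#' @export
print.temporal_prior <- function(x, ...) {
  cat(sprintf("Temporal prior covariance: %d x %d (tr = %g s, ridge = %.3g)\n",
              x$T, x$T, x$tr, x$ridge))
  invisible(x)
}

#' Write / read an HRF kernel as two-column CSV
#'
#' Columns are \code{time_s} (k*dt) and \code{amplitude}.
#' @param h An \code{hrf_kernel}.
#' @param path File path.
#' @return \code{write_hrf}: the path, invisibly. \code{read_hrf}: an
#'   \code{hrf_kernel}.
#' @export
write_hrf <- function(h, path) {
  stopifnot(inherits(h, "hrf_kernel"))
  d <- data.frame(time_s = (seq_along(h$samples) - 1) * h$dt,
                  amplitude = h$samples)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hrf
#' @export
read_hrf <- function(path) {
  d <- utils::read.csv(path)
  dt <- if (nrow(d) > 1) d$time_s[2] - d$time_s[1] else 1
  structure(list(samples = d$amplitude, dt = dt,
                 duration = nrow(d) * dt), class = "hrf_kernel")
}
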