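# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; nothing is read from disk.

# small multi-subject dataset with planted modes
make_planted_dataset <- function(V = 60, T_ = 40, M = 2, S = 2,
                                 runs_per_subject = 2, noise_sd = 1,
                                 seed = 42, tr = 0.72) {
  set.seed(seed)
  maps <- matrix(0, V, M)
  block <- floor(V / M)
  for (m in seq_len(M)) {
    idx <- ((m - 1) * block + 1):min(V, m * block + floor(block / 2))
    maps[idx, m] <- stats::rnorm(length(idx))
  }
  runs <- list(); tcs <- list()
  for (s in seq_len(S)) for (r in seq_len(runs_per_subject)) {
    A <- matrix(stats::rnorm(M * T_), M, T_)
    key <- sprintf("s%d/r%d", s, r)
    tcs[[key]] <- A
    runs[[key]] <- maps %*% A + matrix(stats::rnorm(V * T_, sd = noise_sd),
                                       V, T_)
  }
  list(data = multi_run_dataset(runs, tr = tr), maps = maps, tcs = tcs)
}

# pure-noise dataset
make_noise_dataset <- function(V = 200, T_ = 60, S = 3, runs_per_subject = 1,
                               seed = 1, tr = 0.72) {
  set.seed(seed)
  runs <- list()
  for (s in seq_len(S)) for (r in seq_len(runs_per_subject))
    runs[[sprintf("s%d/r%d", s, r)]] <-
      matrix(stats::rnorm(V * T_), V, T_)
  multi_run_dataset(runs, tr = tr)
}

# estimate structure (maps / subject maps / time courses) from a pfm_state
state_estimates <- function(st) {
  list(maps = group_map_point_estimate(st$group),
       subject_maps = lapply(st$subjects, function(s) s$q_prob * s$slab_mean),
       timecourses = lapply(st$tc, function(t) t$mean),
       run_subject = sub("/.*$", "", names(st$tc)))
}

concat_tcs <- function(l) do.call(cbind, l)

# exhaustive assignment maximiser for small score matrices
brute_force_match <- function(S) {
  n <- nrow(S)
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  pm <- perms(seq_len(n))
  vals <- apply(pm, 1, function(p) sum(S[cbind(seq_len(n), p)]))
  list(best = max(vals), perm = pm[which.max(vals), ])
}

# central finite-difference ELBO gradient with a parameter get/set pair
elbo_fd_grad <- function(state, data, get, set, eps = 1e-5) {
  x0 <- get(state)
  g <- numeric(length(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- x0[i] + eps
    xm <- x0; xm[i] <- x0[i] - eps
    g[i] <- (compute_elbo(set(state, xp), data) -
               compute_elbo(set(state, xm), data)) / (2 * eps)
  }
  g
}
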