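test_that("uncentered correlation: hand cases and errors", {
  expect_equal(uncentered_correlation(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(uncentered_correlation(c(1, 0), c(0, 1)), 0)
  expect_equal(uncentered_correlation(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_equal(uncentered_correlation(c(1, 2), c(-1, -2)), -1)
  # means are deliberately not removed
  expect_gt(uncentered_correlation(c(5, 6), c(6, 5)), 0.9)
  expect_error(uncentered_correlation(c(0, 0), c(1, 1)), "zero vector")
  expect_error(uncentered_correlation(1:3, 1:4), "length")
})

test_that("assignment solver agrees with exhaustive search up to M = 6", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    S <- matrix(rnorm(n * n), n)
    a <- solve_assignment(-S)
    expect_true(all(sort(a) == 1:n))
    got <- sum(S[cbind(1:n, a)])
    expect_equal(got, brute_force_match(S)$best, tolerance = 1e-10)
  }
  expect_error(solve_assignment(matrix(0, 2, 3)), "square")
})

test_that("mode matching recovers permutations and joint sign flips", {
  set.seed(50)
  V <- 60; T_ <- 40; M <- 3
  maps <- matrix(rnorm(V * M), V, M)
  tcs <- matrix(rnorm(M * T_), M, T_)
  ref <- list(maps = maps, tcs = tcs)
  # identity
  mt <- match_modes(ref, ref)
  expect_equal(mt$permutation, 1:M)
  expect_equal(mt$sign_flips, rep(1, M))
  expect_equal(unname(mt$pair_scores[, "spatial"]), rep(1, M))
  # swap modes 1 and 2 and negate mode 1 (map and time course jointly)
  est <- list(maps = maps[, c(2, 1, 3)], tcs = tcs[c(2, 1, 3), ])
  est$maps[, 2] <- -est$maps[, 2]
  est$tcs[2, ] <- -est$tcs[2, ]
  mt2 <- match_modes(est, ref)
  expect_equal(mt2$permutation, c(2, 1, 3))
  expect_equal(mt2$sign_flips, c(1, -1, 1))
  # differing mode counts: extra modes stay unmatched
  est3 <- list(maps = cbind(maps, matrix(rnorm(V * 2), V, 2)),
               tcs = rbind(tcs, matrix(rnorm(2 * T_), 2, T_)))
  mt3 <- match_modes(est3, ref)
  expect_equal(mt3$permutation[1:3], 1:3)
  expect_equal(sum(!is.na(mt3$permutation)), 3)
  expect_error(match_modes(list(maps = NULL), ref), "non-empty")
})

test_that("scoring a decomposition against itself gives unit accuracies", {
  set.seed(51)
  V <- 40; T_ <- 30; M <- 3; S <- 2
  truth <- list(subject_maps = lapply(1:S, function(s)
                  matrix(rnorm(V * M), V, M)),
                bold_tc = list("s1/r1" = matrix(rnorm(M * T_), M, T_),
                               "s2/r1" = matrix(rnorm(M * T_), M, T_)),
                run_subject = c("s1", "s2"))
  est <- list(subject_maps = truth$subject_maps,
              timecourses = truth$bold_tc,
              run_subject = truth$run_subject)
  gm <- Reduce(`+`, truth$subject_maps) / S
  mt <- match_modes(list(maps = gm, tcs = concat_tcs(truth$bold_tc)),
                    list(maps = gm, tcs = concat_tcs(truth$bold_tc)))
  sc <- score_decomposition(est, truth, mt)
  expect_equal(sc$spatial, rep(1, M), tolerance = 1e-12)
  expect_equal(sc$temporal, rep(1, M), tolerance = 1e-12)
})

test_that("additive map noise attenuates accuracy as the analytic prediction", {
  set.seed(52)
  V <- 4000; M <- 2; S <- 4
  truth_maps <- lapply(1:S, function(s) matrix(rnorm(V * M), V, M))
  sig <- 0.8
  est_maps <- lapply(truth_maps, function(m)
    m + matrix(rnorm(V * M, sd = sig), V, M))
  truth <- list(subject_maps = truth_maps)
  est <- list(subject_maps = est_maps)
  gm_t <- Reduce(`+`, truth_maps) / S
  gm_e <- Reduce(`+`, est_maps) / S
  mt <- match_modes(list(maps = gm_e), list(maps = gm_t))
  sc <- score_decomposition(est, truth, mt)
  atten <- sqrt(1 / (1 + sig^2))
  expect_equal(mean(sc$spatial), atten, tolerance = 0.02)
})

test_that("scores are invariant to a consistent subject permutation", {
  set.seed(53)
  V <- 30; M <- 2; S <- 3
  truth_maps <- lapply(1:S, function(s) matrix(rnorm(V * M), V, M))
  est_maps <- lapply(truth_maps, function(m) m + 0.3 * rnorm(V * M))
  mt <- match_modes(list(maps = est_maps[[1]]), list(maps = truth_maps[[1]]))
  s1 <- score_decomposition(list(subject_maps = est_maps),
                            list(subject_maps = truth_maps), mt)
  perm <- c(3, 1, 2)
  s2 <- score_decomposition(list(subject_maps = est_maps[perm]),
                            list(subject_maps = truth_maps[perm]), mt)
  expect_equal(s1$spatial, s2$spatial, tolerance = 1e-12)
})

test_that("netmat RMSE: exact recovery, one-element case, sign invariance", {
  set.seed(54)
  V <- 50; T_ <- 60; M <- 3
  sm <- list(matrix(rnorm(V * M), V, M))
  tc <- list("s1/r1" = matrix(rnorm(M * T_), M, T_))
  truth <- list(subject_maps = sm, bold_tc = tc, run_subject = "s1")
  est <- list(subject_maps = sm, timecourses = tc, run_subject = "s1")
  mt <- match_modes(list(maps = sm[[1]], tcs = tc[[1]]),
                    list(maps = sm[[1]], tcs = tc[[1]]))
  nm <- netmat_rmse(est, truth, mt)
  expect_equal(nm$spatial_rmse, 0, tolerance = 1e-12)
  expect_equal(nm$temporal_rmse, 0, tolerance = 1e-12)

  # single subject, 2 modes: est correlation 0.5 vs truth 0.3 -> 0.2
  mk2 <- function(r, n = 10000) {
    L <- chol(matrix(c(1, r, r, 1), 2))
    set.seed(1)
    matrix(rnorm(2 * n), n, 2) %*% L
  }
  Xe <- mk2(0.5); Xt <- mk2(0.3)
  este <- list(subject_maps = list(Xe))
  trte <- list(subject_maps = list(Xt))
  mt2 <- structure(list(permutation = 1:2, sign_flips = c(1, 1)),
                   class = "pfm_match")
  nm2 <- netmat_rmse(este, trte, mt2)
  r_e <- stats::cor(Xe)[1, 2]; r_t <- stats::cor(Xt)[1, 2]
  expect_equal(nm2$spatial_rmse, abs(r_e - r_t), tolerance = 1e-10)

  # joint sign flip of mode 1 leaves the error unchanged
  est_f <- list(subject_maps = list(cbind(-sm[[1]][, 1], sm[[1]][, 2:3])),
                timecourses = list("s1/r1" = rbind(-tc[[1]][1, ],
                                                   tc[[1]][2:3, ])),
                run_subject = "s1")
  mtf <- match_modes(list(maps = est_f$subject_maps[[1]],
                          tcs = est_f$timecourses[[1]]),
                     list(maps = sm[[1]], tcs = tc[[1]]))
  expect_equal(mtf$sign_flips, c(-1, 1, 1))
  nmf <- netmat_rmse(est_f, truth, mtf)
  expect_equal(nmf$spatial_rmse, 0, tolerance = 1e-12)
  expect_equal(nmf$temporal_rmse, 0, tolerance = 1e-12)
})

test_that("test-retest of identical and unrelated mode sets behaves as expected", {
  set.seed(55)
  maps <- matrix(rnorm(200 * 3), 200, 3)
  rr <- test_retest(list(maps = maps), list(maps = maps))
  expect_equal(rr$correlation, rep(1, 3), tolerance = 1e-12)
  expect_false(any(rr$eliminated))

  # independent noise-only map sets: scores bounded by a permutation null
  a <- list(maps = matrix(rnorm(500 * 4), 500, 4))
  b <- list(maps = matrix(rnorm(500 * 4), 500, 4))
  rr2 <- test_retest(a, b)
  null_scores <- replicate(200, {
    i <- sample(500)
    max(abs(pfmodes:::ucor_matrix(a$maps[i, , drop = FALSE], b$maps)))
  })
  expect_lte(max(abs(rr2$correlation)),
             stats::quantile(null_scores, 0.95) + 0.05)

  # a mode shrunk to near zero in both runs is flagged as eliminated
  a3 <- list(maps = cbind(maps, rnorm(200, sd = 1e-4)))
  b3 <- list(maps = cbind(maps, rnorm(200, sd = 1e-4)))
  rr3 <- test_retest(a3, b3)
  expect_true(rr3$eliminated[rr3$mode_a == 4])
})

test_that("Fisher-z group statistics match the closed form and its symmetries", {
  # S = 4 subjects with atanh(r) = [0.1, 0.2, 0.3, 0.2] for element (1,2)
  zvals <- c(0.1, 0.2, 0.3, 0.2)
  mats <- lapply(zvals, function(z) {
    C <- diag(2); C[1, 2] <- C[2, 1] <- tanh(z); C
  })
  Z <- fisher_group_zstats(mats)
  tval <- mean(zvals) / (stats::sd(zvals) / sqrt(4))
  zexp <- sign(tval) * qnorm(pt(abs(tval), df = 3, lower.tail = FALSE),
                             lower.tail = FALSE)
  expect_equal(Z[1, 2], zexp, tolerance = 1e-10)
  expect_equal(Z[2, 1], zexp, tolerance = 1e-10)
  expect_equal(diag(Z), c(0, 0))

  # all-zero correlations give z = 0
  mats0 <- lapply(1:4, function(i) {
    C <- diag(2); C[1, 2] <- C[2, 1] <- c(-.1, .1, -.05, .05)[i]; C
  })
  Zs <- fisher_group_zstats(mats0)
  matsn <- lapply(mats0, function(C) { C[1, 2] <- -C[1, 2]
                                       C[2, 1] <- -C[2, 1]; C })
  Zn <- fisher_group_zstats(matsn)
  expect_equal(Zn[1, 2], -Zs[1, 2], tolerance = 1e-10)  # antisymmetry
  expect_error(fisher_group_zstats(mats0[1:2]), "3 subjects")
  # |r| = 1 is clipped with a warning
  mats1 <- mats
  mats1[[1]][1, 2] <- mats1[[1]][2, 1] <- 1
  expect_warning(fisher_group_zstats(mats1), "clipped")
})

test_that("partial correlations: independent modes, Gaussian chain, diagonal", {
  set.seed(56)
  n <- 20000
  # two independent modes: partials equal full correlations
  X <- matrix(rnorm(n * 2), n, 2)
  P <- partial_correlations(X)
  expect_equal(P[1, 2], stats::cor(X)[1, 2], tolerance = 1e-10)
  expect_equal(diag(P), c(1, 1))

  # chain x -> y -> z: partial r(x,z | y) ~ 0 while full r(x,z) is not
  x <- rnorm(n); y <- 0.8 * x + rnorm(n, sd = 0.6)
  z <- 0.8 * y + rnorm(n, sd = 0.6)
  Xc <- cbind(x, y, z)
  expect_gt(abs(stats::cor(x, z)), 0.3)
  Pc <- partial_correlations(Xc)
  expect_lt(abs(Pc[1, 3]), 0.03)
  # analytic chain values: r_xz.y = 0
  # subset block equals the corresponding block of the full partial matrix
  Ps <- partial_correlations(Xc, subset = c(1, 3))
  expect_equal(Ps, Pc[c(1, 3), c(1, 3)])
})

test_that("dual regression recovers exact linear models and improves with T", {
  set.seed(57)
  V <- 100; M <- 3
  G <- matrix(rnorm(V * M), V, M)
  A <- matrix(rnorm(M * 50), M, 50)
  D <- G %*% A
  dr <- dual_regression(G, D)
  expect_equal(dr$timecourses, A, tolerance = 1e-8)
  expect_equal(dr$subject_maps, G, tolerance = 1e-6)

  # orthonormal maps: stage 1 equals simple projections
  Q <- qr.Q(qr(G))
  drq <- dual_regression(Q, D)
  expect_equal(drq$timecourses, crossprod(Q, D), tolerance = 1e-8)

  # with noise, subject-map error decreases as T grows
  err <- vapply(c(50, 500), function(T_) {
    A <- matrix(rnorm(M * T_), M, T_)
    D <- G %*% A + matrix(rnorm(V * T_), V, T_)
    mean((dual_regression(G, D)$subject_maps - G)^2)
  }, numeric(1))
  expect_lt(err[2], err[1])

  expect_error(dual_regression(cbind(G, G[, 1]), D), "rank deficient")
})

test_that("scores are invariant to joint sign flips and mode relabelling", {
  set.seed(58)
  V <- 40; T_ <- 30; M <- 3
  sm <- list(matrix(rnorm(V * M), V, M))
  tc <- list("s1/r1" = matrix(rnorm(M * T_), M, T_))
  truth <- list(subject_maps = sm, bold_tc = tc, run_subject = "s1")
  base_mt <- match_modes(list(maps = sm[[1]], tcs = tc[[1]]),
                         list(maps = sm[[1]], tcs = tc[[1]]))
  base <- score_decomposition(list(subject_maps = sm, timecourses = tc,
                                   run_subject = "s1"), truth, base_mt)
  perm <- c(2, 3, 1); flip <- c(-1, 1, -1)
  est <- list(subject_maps = list(sm[[1]][, perm] %*% diag(flip)),
              timecourses = list("s1/r1" = diag(flip) %*% tc[[1]][perm, ]),
              run_subject = "s1")
  mt <- match_modes(list(maps = est$subject_maps[[1]],
                         tcs = est$timecourses[[1]]),
                    list(maps = sm[[1]], tcs = tc[[1]]))
  sc <- score_decomposition(est, truth, mt)
  expect_equal(sort(sc$spatial), sort(base$spatial), tolerance = 1e-12)
  expect_equal(sc$spatial[order(mt$permutation)], base$spatial,
               tolerance = 1e-12)
})
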