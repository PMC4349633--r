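# Linear assignment by the shortest-augmenting-path (Jonker-Volgenant style)
# algorithm, O(n^3). Used for matching estimated modes to reference modes.

#' Solve a linear assignment problem
#'
#' Finds the row-to-column assignment of a square cost matrix minimising the
#' total cost.
#'
#' @param cost Square numeric matrix of finite costs.
#' @return Integer vector \code{a} with \code{a[i]} the column assigned to
#'   row \code{i}.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop("'cost' must be square", call. = FALSE)
  if (!all(is.finite(cost))) stop("'cost' must be finite", call. = FALSE)
  if (n == 1L) return(1L)
  u <- numeric(n)
  v <- numeric(n + 1L)       # column n+1 is the virtual source column
  p <- integer(n + 1L)       # p[j]: row currently matched to column j
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    way <- integer(n)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      u[p[n + 1L]] <- u[p[n + 1L]] + delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(n)) a[p[j]] <- j
  a
}
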