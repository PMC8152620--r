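# Hungarian (Jonker-Volgenant shortest augmenting path) solver for the
# rectangular linear sum assignment problem, minimizing total cost.
# O(n^2 m) with n rows <= m columns; every row receives exactly one column.

#' Solve a linear sum assignment problem
#'
#' @param cost numeric matrix (rows <= columns, all finite); entry `[i, j]`
#'   is the cost of assigning row i to column j.
#' @return integer vector `a` of length `nrow(cost)`: row i is assigned to
#'   column `a[i]`; attribute `"cost"` holds the minimal total cost.
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("cost matrix must have nrow <= ncol (pad with dummy columns)")
  if (any(!is.finite(cost))) stop("cost matrix must be finite")

  u <- numeric(n)
  v <- numeric(m + 1L)            # v[1] is the virtual column 0
  p <- integer(m + 1L)            # p[j+1] = row currently assigned to col j
  way <- integer(m + 1L)

  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- !used[-1L]
      cur <- cost[i0, ] - u[i0] - v[-1L]
      upd <- free & (cur < minv)
      if (any(upd)) {
        minv[upd] <- cur[upd]
        way[which(upd) + 1L] <- j0
      }
      cand <- which(free)
      j1 <- cand[which.min(minv[cand])]
      delta <- minv[j1]
      # update potentials
      uj <- which(used)           # indices j+1
      rows <- p[uj]
      u[rows[rows > 0L]] <- u[rows[rows > 0L]] + delta
      v[uj] <- v[uj] - delta
      minv[!used[-1L]] <- minv[!used[-1L]] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  total <- sum(cost[cbind(seq_len(n), assign)])
  structure(assign, cost = total)
}
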