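# Minimum-cost perfect assignment on a square cost matrix, by shortest
# augmenting paths with dual potentials (Jonker-Volgenant scheme, O(n^3)).
# Used by the trajectory linker; "forbidden" pairs are encoded by the caller
# as very large finite costs so a perfect matching always exists.

solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  if (ncol(cost) != n) abort("cost matrix must be square")
  if (any(!is.finite(cost))) abort("cost matrix must be finite")
  BIG <- .Machine$double.xmax / 4

  # Offset index space: 1 is a virtual start column, j + 1 is column j.
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1L)   # column potentials (v[1] virtual)
  p <- integer(n + 1L)   # p[j + 1] = row matched to column j (0 = none)

  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(BIG, n + 1L)
    way <- integer(n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used)  # all >= 2 once the virtual column is consumed
      cur <- cost[i0, free - 1L] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        idx <- free[upd]
        minv[idx] <- cur[upd]
        way[idx] <- j0
      }
      k <- which.min(minv[free])
      delta <- minv[free][k]
      j1 <- free[k]
      u[p[used]] <- u[p[used]] + delta
      v[used] <- v[used] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }

  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}
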