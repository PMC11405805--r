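# Jonker-Volgenant style shortest-augmenting-path solver for the square
# linear assignment problem. Costs must be finite; use a large penalty
# (not Inf) for forbidden pairs. Deterministic for a given cost matrix.
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost), all(is.finite(cost)))
  if (n == 0) return(integer(0))
  # u, v: dual potentials; p[j+1]: row matched to column j (0 = free)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)
  way <- integer(n + 1)
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- !used[cols + 1]
      cur <- cost[i0, ] - u[i0 + 1] - v[cols + 1]
      upd <- free & cur < minv
      minv[upd] <- cur[upd]
      way[which(upd) + 1] <- j0
      j1 <- which(free)[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used) - 1L          # column indices (0-based)
      ur <- p[usedj + 1]
      u[ur + 1] <- u[ur + 1] + delta
      v[usedj + 1] <- v[usedj + 1] - delta
      minv[!used[cols + 1]] <- minv[!used[cols + 1]] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match_of_row <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0L) match_of_row[p[j + 1]] <- j
  match_of_row
}
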