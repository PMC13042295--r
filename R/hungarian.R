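# Optimal linear assignment (Hungarian algorithm, O(n^3) potential/augmenting
# path formulation). No assignment solver ships with the pre-installed
# stack, so this is implemented here and cross-checked against brute-force
# enumeration in the test suite.

#' Solve the linear assignment problem
#'
#' Minimizes the total cost of a one-to-one assignment of rows to columns.
#' Rectangular matrices are padded internally with a constant, so with more
#' rows than columns some rows stay unassigned (`NA`).
#'
#' @param cost Numeric cost matrix (rows = workers, columns = tasks).
#' @return List with `assignment` (for each row, the assigned column or
#'   `NA`) and `cost` (sum over assigned real cells).
#' @export
hungarian_solve <- function(cost) {
  stopifnot(is.matrix(cost), is.numeric(cost))
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L)
    return(list(assignment = rep(NA_integer_, n), cost = 0))
  N <- max(n, m)
  pad <- if (any(is.finite(cost))) max(cost[is.finite(cost)]) + 1 else 1
  C <- matrix(pad, N, N)
  C[seq_len(n), seq_len(m)] <- cost
  C[!is.finite(C)] <- pad * N + 1

  # columns indexed 1..N, virtual column stored at position N + 1
  INF <- Inf
  u <- numeric(N); v <- numeric(N + 1)
  p <- integer(N + 1)          # p[j] = row currently assigned to column j
  way <- integer(N + 1)
  for (i in seq_len(N)) {
    p[N + 1] <- i
    j0 <- N + 1L
    minv <- rep(INF, N)
    used <- rep(FALSE, N + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(N)) {
        if (used[j]) next
        cur <- C[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(N + 1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= N) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == N + 1L) break
    }
  }
  assignment <- rep(NA_integer_, n)
  for (j in seq_len(N)) {
    if (p[j] >= 1L && p[j] <= n && j <= m) assignment[p[j]] <- j
  }
  total <- sum(cost[cbind(which(!is.na(assignment)),
                          assignment[!is.na(assignment)])])
  list(assignment = assignment, cost = total)
}
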