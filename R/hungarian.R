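#' Optimal residue assignment (Kuhn-Munkres)
#'
#' Solves the rectangular minimum-cost assignment problem exactly: selects
#' `min(n, m)` one-to-one pairs whose summed cost is the global minimum over
#' all injective assignments. Implemented as the O(n^3) shortest augmenting
#' path form of the Hungarian algorithm. Ties between equal-cost optima are
#' broken deterministically in favour of the lexicographically smallest pair
#' list over the smaller dimension.
#'
#' @param cost Numeric `n x m` matrix of finite costs (here: predicted or
#'   actual Calpha-Calpha distances, Angstrom).
#' @param tie_break Resolve equal-cost optima lexicographically (default).
#'   Disable only for speed when any optimum is acceptable.
#' @param tol Absolute tolerance used when testing whether a forced pair
#'   preserves optimality during tie-breaking.
#' @return Tibble with columns `i` (row), `j` (column), `cost`, one row per
#'   assigned pair, sorted by the smaller dimension; attribute `total_cost`
#'   carries the minimised sum.
#' @export
optimal_assignment <- function(cost, tie_break = TRUE, tol = 1e-9) {
  cost <- as.matrix(cost)
  if (length(cost) == 0) abort("empty cost matrix")
  if (!all(is.finite(cost))) abort("cost matrix must be finite")
  n <- nrow(cost); m <- ncol(cost)
  transposed <- n > m
  M <- if (transposed) t(cost) else cost

  assign_cols <- if (tie_break) .lap_lex(M, tol) else .lap_solve(M)
  i <- seq_len(nrow(M)); j <- assign_cols
  if (transposed) { tmp <- i; i <- j; j <- tmp }
  out <- tibble(i = as.integer(i), j = as.integer(j),
                cost = cost[cbind(i, j)])
  out <- out[order(if (transposed) out$j else out$i), ]
  attr(out, "total_cost") <- sum(out$cost)
  out
}

# shortest-augmenting-path LAP for n <= m; returns, for each row, its column
.lap_solve <- function(a) {
  n <- nrow(a); m <- ncol(a)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)        # p[j+1]: row matched to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, m + 1)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      jfree <- which(!used[-1])              # candidate columns 1..m
      cur <- a[i0, jfree] - u[i0 + 1] - v[jfree + 1]
      upd <- cur < minv[jfree + 1]
      minv[jfree + 1][upd] <- cur[upd]
      way[jfree + 1][upd] <- j0
      j1 <- jfree[which.min(minv[jfree + 1])]
      delta <- minv[j1 + 1]
      su <- which(used)                       # shift potentials
      u[p[su] + 1] <- u[p[su] + 1] + delta
      v[su] <- v[su] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

.lap_cost <- function(a) {
  if (nrow(a) == 0) return(0)
  cols <- .lap_solve(a)
  sum(a[cbind(seq_len(nrow(a)), cols)])
}

# lexicographically smallest optimal assignment: fix rows in order, and for
# each row accept the smallest column that keeps the optimum attainable
.lap_lex <- function(a, tol = 1e-9) {
  n <- nrow(a); m <- ncol(a)
  base <- .lap_cost(a)
  rows_left <- seq_len(n)
  cols_left <- seq_len(m)
  fixed_cost <- 0
  ans <- integer(n)
  for (i in seq_len(n)) {
    rows_rest <- rows_left[rows_left != i]
    assigned <- FALSE
    for (j in cols_left) {
      rest <- .lap_cost(a[rows_rest, cols_left[cols_left != j], drop = FALSE])
      total <- fixed_cost + a[i, j] + rest
      if (total <= base + tol * max(1, abs(base))) {
        ans[i] <- j
        fixed_cost <- fixed_cost + a[i, j]
        rows_left <- rows_rest
        cols_left <- cols_left[cols_left != j]
        assigned <- TRUE
        break
      }
    }
    if (!assigned) abort("internal error: no column preserves optimality")
  }
  ans
}
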