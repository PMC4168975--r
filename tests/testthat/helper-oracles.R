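# Independent oracles and tiny fixtures shared across the suite.
# Everything here is deliberately brute-force / closed-form and never
# calls the code path it is used to check.

rmsdp <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

# --- assignment: exhaustive enumeration over all injections ------------
brute_assignment_cost <- function(M) {
  n <- nrow(M); m <- ncol(M)
  if (n > m) return(brute_assignment_cost(t(M)))
  best <- Inf
  rec <- function(row, used, acc) {
    if (acc >= best) return()
    if (row > n) { best <<- acc; return() }
    for (j in seq_len(m)) {
      if (!used[j]) { used[j] <- TRUE; rec(row + 1, used, acc + M[row, j])
        used[j] <- FALSE }
    }
  }
  rec(1, logical(m), 0)
  best
}

# --- MCS: maximum connected common induced subgraph via the modular
# product graph and igraph's exact clique enumeration -------------------
brute_mcs_size <- function(lig_a, lig_b) {
  bm <- function(l) {
    n <- nrow(l$atoms)
    M <- matrix(0L, n, n)
    if (nrow(l$bonds)) {
      M[cbind(l$bonds$from, l$bonds$to)] <- as.integer(l$bonds$order)
      M[cbind(l$bonds$to, l$bonds$from)] <- as.integer(l$bonds$order)
    }
    M
  }
  A <- bm(lig_a); B <- bm(lig_b)
  na <- nrow(A); nb <- nrow(B)
  verts <- which(outer(lig_a$atoms$elem, lig_b$atoms$elem, "=="),
                 arr.ind = TRUE)
  nv <- nrow(verts)
  if (nv == 0) return(0L)
  adj <- matrix(FALSE, nv, nv)
  for (p in seq_len(nv)) {
    for (q in seq_len(nv)) {
      if (p == q) next
      a1 <- verts[p, 1]; b1 <- verts[p, 2]
      a2 <- verts[q, 1]; b2 <- verts[q, 2]
      if (a1 == a2 || b1 == b2) next
      if (A[a1, a2] == B[b1, b2]) adj[p, q] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  best <- 0L
  for (cl in igraph::max_cliques(g)) {
    rows <- verts[as.integer(cl), , drop = FALSE]
    # connectivity of the mapped subgraph in molecule A
    sub <- A[rows[, 1], rows[, 1], drop = FALSE] > 0
    gg <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    comp <- igraph::components(gg)
    best <- max(best, max(comp$csize))
  }
  best
}

# --- Needleman-Wunsch with affine gaps, direct dynamic programme -------
nw_identity_oracle <- function(a, b, go = 1, ge = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)   # X: gap in B, Y: gap in A
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + ge) - ge * (i - 1)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + ge) - ge * (j - 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- as.numeric(A[i] == B[j])
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge)
    }
  }
  # traceback for identity / alignment length
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  len <- 0; ident <- 0
  while (i > 0 || j > 0) {
    len <- len + 1
    if (state == 1 && i > 0 && j > 0) {
      s <- as.numeric(A[i] == B[j])
      ident <- ident + (A[i] == B[j])
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2 && i > 0) {
      up <- c(M[i, j + 1] - go - ge, X[i, j + 1] - ge)
      state <- if (which.max(up) == 1) 1 else 2
      i <- i - 1
    } else {
      lf <- c(M[i + 1, j] - go - ge, Y[i + 1, j] - ge)
      state <- if (which.max(lf) == 1) 1 else 3
      j <- j - 1
    }
  }
  list(identity = ident / len, length = len,
       score = max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
}

# --- Kendall tau-b by O(n^2) pair counting -----------------------------
kendall_oracle <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (p in 1:(n - 1)) {
    for (q in (p + 1):n) {
      dx <- sign(x[p] - x[q]); dy <- sign(y[p] - y[q])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) nc <- nc + 1
      else nd <- nd + 1
    }
  }
  (nc - nd) / sqrt((nc + nd + tx) * (nc + nd + ty))
}

# --- simple fixtures ---------------------------------------------------

# a hand-sized pocket with deterministic geometry and annotations
toy_pocket <- function(n = 5, seed = 1) {
  set.seed(seed)
  aa <- sample(c("A", "R", "D", "F", "K", "I", "S", "W"), n, replace = TRUE)
  ca <- matrix(rnorm(3 * n, sd = 4), n, 3)
  new_pocket(tibble::tibble(
    chain = "A", resseq = seq_len(n) * 2, icode = "", aa = aa,
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    cb_x = ca[, 1] + 1.5, cb_y = ca[, 2], cb_z = ca[, 3],
    sc_x = ca[, 1] + 2.4, sc_y = ca[, 2] + 0.3, sc_z = ca[, 3],
    binding_prob = runif(n, 0.4, 1),
    ss_h = 0.6, ss_e = 0.2, ss_c = 0.2,
    profile = lapply(aa, function(a) {
      v <- rep(0.4 / 19, 20); names(v) <- pocketalign:::AA20
      v[a] <- 0.6; v
    })))
}

# a tiny branched ligand for chem tests: C-C(-O)-C-N chain
toy_ligand <- function(shift = 0) {
  new_ligand(
    tibble::tibble(elem = c("C", "C", "O", "C", "N"),
                   x = c(0, 1.5, 2.1, 2.3, 3.6) + shift,
                   y = c(0, 0.2, 1.4, -1.1, -1.0),
                   z = c(0, 0, 0.3, 0.5, 0.8)),
    tibble::tibble(from = c(1, 2, 2, 4), to = c(2, 3, 4, 5),
                   order = c(1, 1, 1, 1)),
    name = "toy")
}

rot_z <- function(th) matrix(c(cos(th), -sin(th), 0,
                               sin(th), cos(th), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)

apply_rt <- function(X, R, t) t(R %*% t(X) + t)

# planted-function data: rows carry realistic feature marginals but the
# target is an exact known function of the features
planted_data <- function(n_pairs = 40, rows_per_pair = 50, seed = 1,
                         noise = 0) {
  set.seed(seed)
  rows <- lapply(seq_len(n_pairs), function(k) {
    n <- rows_per_pair
    tibble::tibble(
      pair_id = paste0("pp", k),
      ligand_group = paste0("G", (k - 1) %% 6 + 1),
      i = seq_len(n), j = seq_len(n),
      s_prof = runif(n, 0, 0.6), s_ss = runif(n, 0, 1.4),
      s_hp = runif(n, -1, 1), s_prob = runif(n, 0, 0.3),
      s_nbr = abs(rnorm(n)), s_entr = runif(n, 0, 2),
      s_lig = runif(n, 0, 15))
  })
  d <- dplyr::bind_rows(rows)
  d$target_dist <- 10 * (1 - d$s_hp) + rnorm(nrow(d), 0, noise)
  d$match <- as.integer(d$target_dist < quantile(d$target_dist, 0.2))
  d
}


# a small distance model trained once on synthetic positives and shared
# by alignment/similarity tests (memoised across files)
.shared_env <- new.env()
shared_distance_model <- function() {
  if (is.null(.shared_env$model)) {
    prs <- lapply(1:4, function(k) {
      c(make_pair(synth_config(seed = 200 + k, family = (k - 1) %% 3 + 1,
                               size_range = c(8, 10)), "positive"),
        list(pair_id = paste0("p", k),
             ligand_group = paste0("G", (k - 1) %% 3 + 1)))
    })
    ts <- make_training_set(prs)
    .shared_env$model <- train_distance_model(ts, "regression", seed = 1)
  }
  .shared_env$model
}
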