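#' Maximum common substructure atom map
#'
#' Finds a largest connected common induced subgraph between two molecular
#' graphs by a deterministic branch-and-bound build-up search: mappings grow
#' one atom pair at a time, candidate pairs must match element labels, agree
#' with every mapped pair on bond presence and order, and stay connected to
#' the mapped core. Among maximum-size solutions the lexicographically
#' smallest atom-index pairing is returned, so results are reproducible.
#'
#' @param lig_a,lig_b `ligand` objects.
#' @param node_budget Maximum number of search-tree nodes; the search stops
#'   expanding (deterministically) once exhausted. The default is ample for
#'   molecules of a few dozen atoms.
#' @return An object of class `atom_map`: a list with `pairs` (tibble with
#'   columns `a`, `b` of 1-based atom indices) and `tanimoto` (fingerprint
#'   Tanimoto coefficient of the two whole molecules). `pairs` has zero rows
#'   when the molecules share no atom type.
#' @export
mcs_atom_map <- function(lig_a, lig_b, node_budget = 2e5) {
  na <- nrow(lig_a$atoms); nb <- nrow(lig_b$atoms)
  A <- .bond_matrix(lig_a); B <- .bond_matrix(lig_b)
  ea <- lig_a$atoms$elem; eb <- lig_b$atoms$elem

  cand <- which(outer(ea, eb, "=="), arr.ind = TRUE)
  tan <- tanimoto(ligand_fp(lig_a), ligand_fp(lig_b))
  if (nrow(cand) == 0) {
    return(structure(list(pairs = tibble(a = integer(), b = integer()),
                          tanimoto = tan), class = "atom_map"))
  }
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]

  best_pairs <- NULL
  best_size <- 0L
  nodes <- 0L

  lex_less <- function(p, q) {
    # p, q: 2-column matrices sorted by first column; TRUE if p < q
    k <- min(nrow(p), nrow(q))
    for (r in seq_len(k)) {
      if (p[r, 1] != q[r, 1]) return(p[r, 1] < q[r, 1])
      if (p[r, 2] != q[r, 2]) return(p[r, 2] < q[r, 2])
    }
    nrow(p) < nrow(q)
  }

  consider <- function(map) {
    m <- map[order(map[, 1]), , drop = FALSE]
    if (nrow(m) > best_size ||
        (nrow(m) == best_size && !is.null(best_pairs) && lex_less(m, best_pairs))) {
      best_pairs <<- m
      best_size <<- nrow(m)
    }
  }

  extend <- function(map, used_a, used_b, banned) {
    nodes <<- nodes + 1L
    if (nodes > node_budget) return()
    consider(map)
    if (nrow(map) + min(na - sum(used_a), nb - sum(used_b)) < best_size) return()
    # candidates: label-matched, unused, induced-consistent, connected
    cset <- cand[!used_a[cand[, 1]] & !used_b[cand[, 2]], , drop = FALSE]
    if (nrow(cset) == 0) return()
    keep <- logical(nrow(cset))
    for (r in seq_len(nrow(cset))) {
      a2 <- cset[r, 1]; b2 <- cset[r, 2]
      if (banned[a2, b2]) next
      ok <- TRUE; conn <- FALSE
      for (m in seq_len(nrow(map))) {
        oa <- A[a2, map[m, 1]]; ob <- B[b2, map[m, 2]]
        if (oa != ob) { ok <- FALSE; break }
        if (oa > 0) conn <- TRUE
      }
      keep[r] <- ok && conn
    }
    cset <- cset[keep, , drop = FALSE]
    if (nrow(cset) == 0) return()
    local_ban <- banned
    for (r in seq_len(nrow(cset))) {
      a2 <- cset[r, 1]; b2 <- cset[r, 2]
      ua <- used_a; ub <- used_b; ua[a2] <- TRUE; ub[b2] <- TRUE
      extend(rbind(map, c(a2, b2)), ua, ub, local_ban)
      local_ban[a2, b2] <- TRUE  # later siblings may not re-add this pair
      if (nodes > node_budget) return()
    }
  }

  banned0 <- matrix(FALSE, na, nb)
  for (r in seq_len(nrow(cand))) {
    a1 <- cand[r, 1]; b1 <- cand[r, 2]
    ua <- logical(na); ub <- logical(nb); ua[a1] <- TRUE; ub[b1] <- TRUE
    extend(matrix(c(a1, b1), 1, 2), ua, ub, banned0)
    banned0[a1, b1] <- TRUE  # solutions containing (a1,b1) fully explored
    if (nodes > node_budget) break
    if (best_size == min(na, nb)) break  # cannot improve
  }
  structure(list(pairs = tibble(a = as.integer(best_pairs[, 1]),
                                b = as.integer(best_pairs[, 2])),
                 tanimoto = tan),
            class = "atom_map")
}

#' @export
print.atom_map <- function(x, ...) {
  cat(sprintf("<atom_map> %d pair(s), fingerprint Tanimoto %.3f\n",
              nrow(x$pairs), x$tanimoto))
  invisible(x)
}

.bond_matrix <- function(l) {
  n <- nrow(l$atoms)
  M <- matrix(0L, n, n)
  if (nrow(l$bonds)) {
    M[cbind(l$bonds$from, l$bonds$to)] <- as.integer(l$bonds$order)
    M[cbind(l$bonds$to, l$bonds$from)] <- as.integer(l$bonds$order)
  }
  M
}
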