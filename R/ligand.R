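#' Construct a small-molecule ligand
#'
#' Ligands are labelled molecular graphs with 3D coordinates in the frame of
#' the protein that owns them. Only heavy atoms are represented.
#'
#' @param atoms Tibble with columns `elem` (element symbol), `x`, `y`, `z`
#'   (Angstrom).
#' @param bonds Tibble with columns `from`, `to` (1-based atom indices) and
#'   `order` (integer bond order). May have zero rows.
#' @param props Optional named 5-vector (`mw`, `logp`, `psa`, `hbd`, `hba`);
#'   computed from the graph when missing.
#' @param name Molecule name.
#' @return An object of class `ligand`.
#' @export
new_ligand <- function(atoms, bonds = NULL, props = NULL, name = "ligand") {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("elem", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) < 3) abort("a ligand needs at least 3 heavy atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    abort("non-finite ligand coordinates")
  bonds <- if (is.null(bonds)) tibble(from = integer(), to = integer(),
                                      order = integer()) else as_tibble(bonds)
  if (nrow(bonds) && (max(bonds$from, bonds$to) > nrow(atoms) ||
                      min(bonds$from, bonds$to) < 1))
    abort("bond indices outside atom table")
  props <- props %||% ligand_props(atoms)
  names(props) <- c("mw", "logp", "psa", "hbd", "hba")
  structure(list(atoms = atoms, bonds = bonds, props = props, name = name),
            class = "ligand")
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf("<ligand> %s: %d heavy atoms, %d bonds\n",
              x$name, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

ligand_coords <- function(l) unname(as.matrix(l$atoms[, c("x", "y", "z")]))

# coarse graph-derived descriptors, adequate for abstract scaffolds:
# additive mass, a carbon-vs-heteroatom logP proxy, heteroatom-count PSA
# proxy, and N/O counts for donors/acceptors
ligand_props <- function(atoms) {
  elem <- atoms$elem
  mass <- sum(AA_MASS[elem], na.rm = TRUE)
  n_c <- sum(elem == "C")
  n_n <- sum(elem == "N")
  n_o <- sum(elem == "O")
  het <- sum(!elem %in% "C")
  c(mw = mass, logp = 0.5 * n_c - 0.6 * het, psa = 20 * (n_n + n_o),
    hbd = n_n, hba = n_n + n_o)
}

transform_ligand <- function(l, transform) {
  xyz <- ligand_coords(l)
  xyz <- t(transform$rotation %*% t(xyz) + transform$translation)
  l$atoms$x <- xyz[, 1]; l$atoms$y <- xyz[, 2]; l$atoms$z <- xyz[, 3]
  l
}

# deterministic polynomial string hash (31-adic, mod a Mersenne prime),
# identical across platforms because it stays in double-safe integer range
.hash_string <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Path-based molecular fingerprint
#'
#' Hashes all simple linear paths of up to `max_len` atoms (element and
#' bond-order labelled, direction-canonicalised) into a fixed-length bit
#' vector. Deterministic for a given connection table; a bond-free molecule
#' still sets its single-atom bits.
#'
#' @param ligand A `ligand`.
#' @param nbits Fingerprint length in bits.
#' @param max_len Maximum path length in atoms.
#' @return A logical vector of length `nbits`.
#' @export
fingerprint <- function(ligand, nbits = 1024, max_len = 7) {
  n <- nrow(ligand$atoms)
  elem <- ligand$atoms$elem
  adj <- vector("list", n)
  ord <- matrix(0L, n, n)
  if (nrow(ligand$bonds)) {
    for (r in seq_len(nrow(ligand$bonds))) {
      i <- ligand$bonds$from[r]; j <- ligand$bonds$to[r]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
      ord[i, j] <- ord[j, i] <- as.integer(ligand$bonds$order[r])
    }
  }
  paths <- character(0)
  walk <- function(path) {
    labs <- character(2 * length(path) - 1)
    labs[seq(1, length(labs), 2)] <- elem[path]
    if (length(path) > 1)
      labs[seq(2, length(labs), 2)] <-
        ord[cbind(path[-length(path)], path[-1])]
    fwd <- paste(labs, collapse = "-")
    rev_ <- paste(rev(labs), collapse = "-")
    paths[[length(paths) + 1L]] <<- if (fwd <= rev_) fwd else rev_
    if (length(path) < max_len) {
      for (nb in adj[[path[length(path)]]]) {
        if (!nb %in% path) walk(c(path, nb))
      }
    }
  }
  for (a in seq_len(n)) walk(a)
  bits <- logical(nbits)
  bits[vapply(unique(paths), .hash_string, numeric(1)) %% nbits + 1] <- TRUE
  bits
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|A and B| / |A or B|`; defined as 1 when both fingerprints are empty
#' (identical empty feature sets).
#'
#' @param fp_a,fp_b Logical bit vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) abort("fingerprint length mismatch")
  u <- sum(fp_a | fp_b)
  if (u == 0) return(1)
  sum(fp_a & fp_b) / u
}

# fingerprint with per-ligand memoisation (fingerprints are pure functions
# of the connection table, and the MCS/screening paths reuse them heavily)
ligand_fp <- function(l, nbits = 1024) {
  key <- paste0("fp", nbits)
  if (!is.null(l$.cache[[key]])) return(l$.cache[[key]])
  fingerprint(l, nbits = nbits)
}

cache_fp <- function(l, nbits = 1024) {
  key <- paste0("fp", nbits)
  if (is.null(l$.cache)) l$.cache <- list()
  l$.cache[[key]] <- fingerprint(l, nbits = nbits)
  l
}
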