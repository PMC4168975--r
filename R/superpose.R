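#' Least-squares rigid-body superposition (Kabsch fit)
#'
#' Finds the proper rotation and translation mapping the moving point set
#' onto the reference set with minimum RMSD, via the SVD of the covariance
#' matrix with the usual determinant correction (reflections excluded).
#'
#' @param reference,moving Numeric `n x 3` matrices of paired points
#'   (`n >= 3`, not collinear).
#' @return A `rigid_transform`: list with `rotation` (3x3, det +1) and
#'   `translation` (3-vector); `rotation %*% x + translation` maps a moving
#'   point onto the reference frame.
#' @export
kabsch_fit <- function(reference, moving) {
  P <- as.matrix(reference); Q <- as.matrix(moving)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    abort("point sets must be paired n x 3 matrices")
  if (nrow(P) < 3) abort("at least 3 point pairs required")
  .check_noncollinear(P); .check_noncollinear(Q)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(Q, 2, cq)) %*% sweep(P, 2, cp)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  structure(list(rotation = R, translation = as.numeric(cp - R %*% cq)),
            class = "rigid_transform")
}

.check_noncollinear <- function(X) {
  sv <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = 0)$d
  if (sv[2] < 1e-8) abort("degenerate (collinear) point set")
  invisible(TRUE)
}

identity_transform <- function() {
  structure(list(rotation = diag(3), translation = numeric(3)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(round(x$rotation, 4))
  cat("t =", paste(round(x$translation, 4), collapse = " "), "\n")
  invisible(x)
}

rmsd_points <- function(P, Q) sqrt(mean(rowSums((P - Q)^2)))

#' Superpose one ligand onto another through an atom map
#'
#' Least-squares rigid fit of the mapped atoms of `lig_b` onto the mapped
#' atoms of `lig_a`.
#'
#' @param lig_a Reference `ligand`.
#' @param lig_b Moving `ligand`.
#' @param map An `atom_map` with at least 3 non-collinear pairs.
#' @return List with `transform` (a `rigid_transform` taking B-frame
#'   coordinates into the A frame) and `rmsd` (the minimised RMSD over the
#'   mapped atoms, Angstrom).
#' @export
superpose_ligands <- function(lig_a, lig_b, map = mcs_atom_map(lig_a, lig_b)) {
  if (nrow(map$pairs) < 3) abort("atom map needs at least 3 pairs")
  P <- ligand_coords(lig_a)[map$pairs$a, , drop = FALSE]
  Q <- ligand_coords(lig_b)[map$pairs$b, , drop = FALSE]
  tr <- kabsch_fit(P, Q)
  moved <- t(tr$rotation %*% t(Q) + tr$translation)
  list(transform = tr, rmsd = rmsd_points(P, moved))
}
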