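#' Construct a binding pocket
#'
#' A pocket is a set of predicted binding residues with coordinates and
#' per-residue annotation tracks. Residues live in a tibble with one row per
#' residue; the evolutionary profile is a list-column of 20-vectors ordered
#' as `A R N D C Q E G H I L K M F P S T W Y V`.
#'
#' @param residues Tibble with columns `chain`, `resseq`, `icode`, `aa`,
#'   `ca_x`, `ca_y`, `ca_z`, optionally `cb_x/y/z` and `sc_x/y/z`
#'   (side-chain heavy-atom centroid), `binding_prob`, `ss_h`, `ss_e`,
#'   `ss_c`, `entropy`, and a list-column `profile` of numeric 20-vectors.
#'   Missing optional columns are filled with defaults.
#' @param center Numeric 3-vector, the pocket center (Angstrom). Defaults to
#'   the Calpha centroid.
#' @param props Numeric 5-vector of consensus physicochemical properties of
#'   putative ligands: molecular weight, logP, polar surface area, hydrogen
#'   bond donors and acceptors (`mw`, `logp`, `psa`, `hbd`, `hba`).
#' @param profile_kind `"frequency"` or `"logodds"`; how the profile values
#'   are to be read when normalising for entropy.
#' @return An object of class `pocket`.
#' @export
new_pocket <- function(residues, center = NULL, props = NULL,
                       profile_kind = "frequency") {
  residues <- as_tibble(residues)
  stopifnot(all(c("aa", "ca_x", "ca_y", "ca_z") %in% names(residues)))
  if (!"chain" %in% names(residues)) residues$chain <- "A"
  if (!"resseq" %in% names(residues)) residues$resseq <- seq_len(nrow(residues))
  if (!"icode" %in% names(residues)) residues$icode <- ""
  residues$resid <- paste0(residues$chain, ":", residues$resseq,
                           ifelse(residues$icode == "", "", residues$icode))
  for (col in c("cb_x", "cb_y", "cb_z", "sc_x", "sc_y", "sc_z")) {
    if (!col %in% names(residues)) residues[[col]] <- NA_real_
  }
  if (!"binding_prob" %in% names(residues)) residues$binding_prob <- 0.5
  if (!all(c("ss_h", "ss_e", "ss_c") %in% names(residues))) {
    residues$ss_h <- residues$ss_e <- 0; residues$ss_c <- 1
  }
  if (!"profile" %in% names(residues)) {
    residues$profile <- lapply(residues$aa, function(a) {
      v <- setNames(rep(1 / 20, 20), AA20); v
    })
  }
  if (!"entropy" %in% names(residues)) {
    residues$entropy <- vapply(residues$profile, sequence_entropy,
                               numeric(1), kind = profile_kind)
  }
  center <- center %||% colMeans(as.matrix(residues[, c("ca_x", "ca_y", "ca_z")]))
  props <- props %||% c(mw = 300, logp = 1, psa = 80, hbd = 2, hba = 4)
  names(props) <- c("mw", "logp", "psa", "hbd", "hba")
  p <- structure(list(residues = residues, center = as.numeric(center),
                      props = props, profile_kind = profile_kind),
                 class = "pocket")
  validate_pocket(p)
}

#' Validate pocket invariants
#'
#' Checks residue count, amino-acid alphabet, coordinate finiteness,
#' annotation ranges and profile length; errors on violation.
#'
#' @param p A `pocket`.
#' @return `p`, invisibly unchanged, if valid.
#' @export
validate_pocket <- function(p) {
  r <- p$residues
  if (nrow(r) < 3) abort("a pocket needs at least 3 residues")
  if (anyDuplicated(r$resid)) abort("duplicate residue ids in pocket")
  bad <- setdiff(unique(r$aa), AA20)
  if (length(bad)) abort(paste("non-standard amino acid(s):",
                               paste(bad, collapse = ", ")))
  if (!all(is.finite(as.matrix(r[, c("ca_x", "ca_y", "ca_z")]))))
    abort("non-finite Calpha coordinates")
  if (any(r$binding_prob < 0 | r$binding_prob > 1))
    abort("binding_prob outside [0,1]")
  ss <- as.matrix(r[, c("ss_h", "ss_e", "ss_c")])
  if (any(ss < 0 | ss > 1)) abort("secondary-structure probabilities outside [0,1]")
  if (any(vapply(r$profile, length, integer(1)) != 20))
    abort("profiles must have exactly 20 entries")
  if (any(r$entropy < -1e-9 | r$entropy > log2(20) + 1e-9))
    abort("entropy outside [0, log2 20]")
  p
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket> %d residues, center (%.1f, %.1f, %.1f) A\n",
              nrow(x$residues), x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

pocket_size <- function(p) nrow(p$residues)

# n x 3 coordinate matrices
pocket_ca <- function(p) unname(as.matrix(p$residues[, c("ca_x", "ca_y", "ca_z")]))
pocket_cb <- function(p) unname(as.matrix(p$residues[, c("cb_x", "cb_y", "cb_z")]))
pocket_sc <- function(p) unname(as.matrix(p$residues[, c("sc_x", "sc_y", "sc_z")]))

# profile rows as an n x 20 matrix
pocket_profile_matrix <- function(p) {
  do.call(rbind, lapply(p$residues$profile, as.numeric))
}

#' Pocket amino-acid sequence
#'
#' One-letter sequence of the binding residues in file order (the pocket is
#' order-free; this is only for the global sequence-identity baseline).
#'
#' @param p A `pocket`.
#' @return A single string.
#' @export
pocket_sequence <- function(p) paste(p$residues$aa, collapse = "")

#' Construct a pocket bundle
#'
#' Bundles a pocket with the template ligands placed in the same protein
#' frame, and optionally the experimentally bound ligand (evaluation only).
#'
#' @param pocket A `pocket`.
#' @param template_ligands List of `ligand` objects in the target frame.
#' @param bound_ligand Optional `ligand`, used only to build reference
#'   alignments and evaluation metrics.
#' @return An object of class `pocket_bundle`.
#' @export
new_pocket_bundle <- function(pocket, template_ligands = list(),
                              bound_ligand = NULL) {
  stopifnot(inherits(pocket, "pocket"))
  for (l in template_ligands) stopifnot(inherits(l, "ligand"))
  structure(list(pocket = pocket, template_ligands = template_ligands,
                 bound_ligand = bound_ligand),
            class = "pocket_bundle")
}

#' @export
print.pocket_bundle <- function(x, ...) {
  cat(sprintf("<pocket_bundle> %d residues, %d template ligand(s), bound: %s\n",
              pocket_size(x$pocket), length(x$template_ligands),
              if (is.null(x$bound_ligand)) "no" else "yes"))
  invisible(x)
}

#' @describeIn new_pocket residue table of a pocket as a tibble.
#' @param x A `pocket`.
#' @param ... Unused.
#' @method tidy pocket
#' @export
tidy.pocket <- function(x, ...) x$residues

apply_transform_points <- function(xyz, transform) {
  ok <- stats::complete.cases(xyz)
  out <- xyz
  if (any(ok)) {
    out[ok, ] <- t(transform$rotation %*% t(xyz[ok, , drop = FALSE]) +
                     transform$translation)
  }
  out
}

# rigidly move a pocket (all three point tracks and the center)
transform_pocket <- function(p, transform) {
  r <- p$residues
  ca <- apply_transform_points(pocket_ca(p), transform)
  cb <- apply_transform_points(pocket_cb(p), transform)
  sc <- apply_transform_points(pocket_sc(p), transform)
  r[, c("ca_x", "ca_y", "ca_z")] <- ca
  r[, c("cb_x", "cb_y", "cb_z")] <- cb
  r[, c("sc_x", "sc_y", "sc_z")] <- sc
  p$residues <- r
  p$center <- as.numeric(transform$rotation %*% p$center + transform$translation)
  p
}

# rigidly move a bundle: protein frame and every ligand move together
transform_bundle <- function(b, transform) {
  b$pocket <- transform_pocket(b$pocket, transform)
  b$template_ligands <- lapply(b$template_ligands, transform_ligand, transform)
  if (!is.null(b$bound_ligand))
    b$bound_ligand <- transform_ligand(b$bound_ligand, transform)
  b
}
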