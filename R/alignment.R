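#' Construct a pocket alignment object
#'
#' An injective residue correspondence between two pockets, with the rigid
#' transform (B to A frame) fitted over the aligned Calpha atoms, the
#' minimised pocket RMSD, and the summed cost of the assignment.
#'
#' @param pairs Tibble with columns `i` (residue index in pocket A), `j`
#'   (pocket B), and optionally `dist` (the cost-matrix entry).
#' @param transform A `rigid_transform` or `NULL`.
#' @param pocket_rmsd Calpha RMSD over aligned pairs (Angstrom).
#' @param total_cost Sum of cost-matrix entries over the pairs.
#' @param n,m Pocket sizes.
#' @return An object of class `pocket_alignment` (a tibble subclass).
#' @export
new_pocket_alignment <- function(pairs, transform = NULL,
                                 pocket_rmsd = NA_real_,
                                 total_cost = NA_real_, n = NA_integer_,
                                 m = NA_integer_) {
  pairs <- as_tibble(pairs)
  if (!"dist" %in% names(pairs)) pairs$dist <- NA_real_
  if (nrow(pairs) < 1) abort("an alignment needs at least one pair")
  if (anyDuplicated(pairs$i) || anyDuplicated(pairs$j))
    abort("alignment must be injective in both pockets")
  structure(pairs, transform = transform, pocket_rmsd = pocket_rmsd,
            total_cost = total_cost, n = as.integer(n), m = as.integer(m),
            class = c("pocket_alignment", class(pairs)))
}

#' @export
print.pocket_alignment <- function(x, ...) {
  cat(sprintf("<pocket_alignment> %d pairs (pockets %d x %d), RMSD %.2f A, cost %.2f\n",
              nrow(x), attr(x, "n"), attr(x, "m"),
              attr(x, "pocket_rmsd"), attr(x, "total_cost")))
  NextMethod()
}

#' @describeIn new_pocket_alignment aligned residue pairs as a plain tibble.
#' @param x A `pocket_alignment`.
#' @param ... Unused.
#' @method tidy pocket_alignment
#' @export
tidy.pocket_alignment <- function(x, ...) {
  tibble(i = x$i, j = x$j, dist = x$dist)
}

#' @describeIn new_pocket_alignment one-row summary (length, RMSD, cost).
#' @method glance pocket_alignment
#' @export
glance.pocket_alignment <- function(x, ...) {
  tibble(n_pairs = nrow(x), n_a = attr(x, "n"), m_b = attr(x, "m"),
         pocket_rmsd = attr(x, "pocket_rmsd"),
         total_cost = attr(x, "total_cost"))
}

#' Superpose two pockets over an alignment
#'
#' Least-squares rigid fit of pocket B's aligned Calpha atoms onto pocket
#' A's.
#'
#' @param pocket_a,pocket_b `pocket` objects.
#' @param pairs Tibble with columns `i`, `j` (at least 3 non-collinear
#'   pairs).
#' @return List with `transform` (B to A) and `pocket_rmsd` (Angstrom).
#' @export
superpose_by_alignment <- function(pocket_a, pocket_b, pairs) {
  P <- pocket_ca(pocket_a)[pairs$i, , drop = FALSE]
  Q <- pocket_ca(pocket_b)[pairs$j, , drop = FALSE]
  tr <- kabsch_fit(P, Q)
  moved <- t(tr$rotation %*% t(Q) + tr$translation)
  list(transform = tr, pocket_rmsd = rmsd_points(P, moved))
}

#' Align two pockets with a trained distance model
#'
#' The full sequence order-independent alignment: residue-pair features are
#' computed, the regression model predicts the Calpha-Calpha distance
#' matrix, the Kuhn-Munkres algorithm picks the minimum-cost injective
#' correspondence (its length equals the smaller pocket), and the aligned
#' Calpha atoms define the superposition and pocket RMSD.
#'
#' @param bundle_a,bundle_b `pocket_bundle`s.
#' @param model A regression `distance_model`.
#' @param svc_model Optional classification model; when supplied and
#'   `cost = "svc"`, the cost matrix is `1 - P(match)` instead of the
#'   predicted distance.
#' @param cost `"svr"` (default) or `"svc"`.
#' @param features Precomputed `pair_features` to reuse.
#' @return A `pocket_alignment`.
#' @export
align_pockets <- function(bundle_a, bundle_b, model, svc_model = NULL,
                          cost = c("svr", "svc"), features = NULL) {
  cost <- match.arg(cost)
  pf <- features %||% compute_pair_features(bundle_a, bundle_b)
  dmat <- predict_distance_matrix(model, pf)
  cmat <- if (cost == "svc") {
    if (is.null(svc_model)) abort("cost = 'svc' needs svc_model")
    1 - predict_match_matrix(svc_model, pf)
  } else {
    dmat
  }
  asg <- optimal_assignment(cmat)
  sup <- superpose_by_alignment(bundle_a$pocket, bundle_b$pocket, asg)
  new_pocket_alignment(
    tibble(i = asg$i, j = asg$j, dist = dmat[cbind(asg$i, asg$j)]),
    transform = sup$transform, pocket_rmsd = sup$pocket_rmsd,
    total_cost = attr(asg, "total_cost"),
    n = attr(pf, "n"), m = attr(pf, "m"))
}

#' Reference alignment from bound ligands
#'
#' Gold-standard correspondence used for training and evaluation: the two
#' bound ligands are superposed through their maximum-common-substructure
#' atom map, which places the two proteins in a common frame; the actual
#' all-against-all Calpha distance matrix in that frame is then solved by
#' the Kuhn-Munkres algorithm.
#'
#' @param bundle_a,bundle_b `pocket_bundle`s carrying bound ligands.
#' @return A `pocket_alignment` whose `dist` column holds actual Calpha
#'   distances in the ligand-superposed frame.
#' @export
reference_alignment <- function(bundle_a, bundle_b) {
  if (is.null(bundle_a$bound_ligand) || is.null(bundle_b$bound_ligand))
    abort("reference alignments need bound ligands in both bundles")
  amap <- mcs_atom_map(bundle_a$bound_ligand, bundle_b$bound_ligand)
  if (nrow(amap$pairs) < 3)
    abort("no usable maximum common substructure between bound ligands")
  sup <- superpose_ligands(bundle_a$bound_ligand, bundle_b$bound_ligand, amap)
  ca_a <- pocket_ca(bundle_a$pocket)
  ca_b <- t(sup$transform$rotation %*% t(pocket_ca(bundle_b$pocket)) +
              sup$transform$translation)
  dmat <- .cross_dist(ca_a, ca_b)
  asg <- optimal_assignment(dmat)
  fit <- superpose_by_alignment(bundle_a$pocket, bundle_b$pocket, asg)
  new_pocket_alignment(
    tibble(i = asg$i, j = asg$j, dist = dmat[cbind(asg$i, asg$j)]),
    transform = fit$transform, pocket_rmsd = fit$pocket_rmsd,
    total_cost = attr(asg, "total_cost"),
    n = nrow(ca_a), m = nrow(ca_b))
}

#' Ligand RMSD under a pocket alignment
#'
#' Heavy-atom RMSD over mapped ligand atoms after moving ligand B with the
#' pocket-alignment transform; a correct residue alignment should bring the
#' two bound ligands into a similar pose. `delta_rmsd` subtracts the
#' minimum achievable RMSD (ligand-only superposition over the same atom
#' map), so it is non-negative and free of internal-geometry differences.
#'
#' @param alignment A `pocket_alignment` with a valid transform.
#' @param lig_a,lig_b Bound `ligand`s of the two targets.
#' @param map An `atom_map` between them (default: computed).
#' @return List with `rmsd` and `delta_rmsd` (Angstrom).
#' @export
ligand_rmsd <- function(alignment, lig_a, lig_b,
                        map = mcs_atom_map(lig_a, lig_b)) {
  tr <- attr(alignment, "transform")
  if (is.null(tr)) abort("alignment carries no transform")
  if (nrow(map$pairs) < 3) abort("atom map needs at least 3 pairs")
  A <- ligand_coords(lig_a)[map$pairs$a, , drop = FALSE]
  B <- ligand_coords(lig_b)[map$pairs$b, , drop = FALSE]
  moved <- t(tr$rotation %*% t(B) + tr$translation)
  r <- rmsd_points(A, moved)
  best <- superpose_ligands(lig_a, lig_b, map)$rmsd
  list(rmsd = r, delta_rmsd = max(r - best, 0))
}
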