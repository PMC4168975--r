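#' Sequence profile score
#'
#' Dot product of the two residues' 20-entry position-specific profile
#' vectors.
#'
#' @param pi,pj Numeric 20-vectors.
#' @return Scalar.
#' @export
sequence_profile_score <- function(pi, pj) {
  if (length(pi) != 20 || length(pj) != 20) abort("profiles must be length 20")
  sum(pi * pj)
}

#' Secondary structure score
#'
#' Euclidean distance between the two residues' (helix, extended, coil)
#' probability vectors.
#'
#' @param si,sj Numeric 3-vectors with entries in `[0, 1]`.
#' @return Scalar `>= 0`.
#' @export
secondary_structure_score <- function(si, sj) {
  sqrt(sum((si - sj)^2))
}

.hydro_env <- new.env(parent = emptyenv())

#' The bundled hydrophobicity scale table
#'
#' Twenty published amino-acid hydrophobicity/hydrophilicity scales
#' (one row per scale, one column per amino acid), transcribed from the
#' standard compilations. Each residue type is thus described by a
#' 20-entry vector of scale values.
#'
#' @return A 20 x 20 numeric matrix, rows = scales, columns = amino acids
#'   in the order `A R N D C Q E G H I L K M F P S T W Y V`.
#' @export
hydrophobicity_scales <- function() {
  if (is.null(.hydro_env$scales)) {
    path <- system.file("extdata", "hydrophobicity_scales.csv",
                        package = "pocketalign")
    tab <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(tab[, AA20])
    rownames(m) <- tab$scale
    .hydro_env$scales <- m
  }
  .hydro_env$scales
}

#' Hydrophobicity score
#'
#' Pearson correlation between the two residues' hydrophobicity vectors
#' across the 20 bundled scales.
#'
#' @param aa_i,aa_j One-letter amino-acid codes.
#' @param scales Scale table as returned by [hydrophobicity_scales()].
#' @return Scalar in `[-1, 1]`.
#' @export
hydrophobicity_score <- function(aa_i, aa_j, scales = hydrophobicity_scales()) {
  hi <- scales[, aa_i]; hj <- scales[, aa_j]
  if (sd(hi) == 0 || sd(hj) == 0) abort("zero-variance hydrophobicity vector")
  cor(hi, hj)
}

# 20 x 20 amino-acid pair correlation table, cached
hydrophobicity_table <- function(scales = hydrophobicity_scales()) {
  if (is.null(.hydro_env$table)) .hydro_env$table <- cor(scales)
  .hydro_env$table
}

#' Binding probability score
#'
#' Squared difference between the ligand-binding probabilities assigned to
#' the two residues.
#'
#' @param bi,bj Scalars in `[0, 1]`.
#' @return Scalar `>= 0`.
#' @export
binding_probability_score <- function(bi, bj) (bi - bj)^2

#' Shannon entropy of a profile column
#'
#' Entropy (bits) of the 20-entry profile after normalisation to a
#' probability vector. Frequency profiles are renormalised directly;
#' log-odds profiles go through a base-2 softmax first.
#'
#' @param profile Numeric 20-vector.
#' @param kind `"frequency"`, `"logodds"`, or `"auto"` (detect: negative
#'   entries or a sum far from one means log-odds).
#' @return Entropy in `[0, log2(20)]` bits.
#' @export
sequence_entropy <- function(profile, kind = "auto") {
  v <- as.numeric(profile)
  if (length(v) != 20) abort("profile must have length 20")
  if (kind == "auto") {
    kind <- if (any(v < 0) || abs(sum(v) - 1) > 0.1) "logodds" else "frequency"
  }
  p <- if (kind == "logodds") {
    w <- 2^(v - max(v)); w / sum(w)
  } else {
    if (any(v < 0)) abort("negative entries in a frequency profile")
    if (sum(v) == 0) return(log2(20))
    v / sum(v)
  }
  p <- p[p > 0]
  min(max(-sum(p * log2(p)), 0), log2(20))
}

#' Sequence entropy score
#'
#' Squared difference of the two residues' profile entropies.
#'
#' @param ei,ej Entropies in bits.
#' @return Scalar `>= 0`.
#' @export
sequence_entropy_score <- function(ei, ej) (ei - ej)^2

#' Neighbor Calpha distance vector
#'
#' Distances from residue `i`'s Calpha to every other binding residue in the
#' same pocket; an order-free multiset describing where the residue sits in
#' the pocket.
#'
#' @param pocket A `pocket` of size N.
#' @param i Residue index.
#' @return Numeric vector of length N - 1.
#' @export
neighbor_distance_vector <- function(pocket, i) {
  ca <- pocket_ca(pocket)
  d <- sqrt(rowSums((ca - matrix(ca[i, ], nrow(ca), 3, byrow = TRUE))^2))
  d[-i]
}

# permutation-test statistic: standardised deviation of sum(x) from its
# exact mean under random relabelling (sampling n1 of N pooled values
# without replacement); var formula is the finite-population one
.fp_statistic <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  mu <- n1 * mean(z)
  v <- n1 * n2 / N * sum((z - mean(z))^2) / (N - 1)
  if (v <= 0) return(0)
  (sum(x) - mu) / sqrt(v)
}

#' Fisher-Pitman permutation test for two independent samples
#'
#' Nonparametric comparison of two samples of raw values. The statistic `T`
#' is the standardised difference of the first sample's sum from its mean
#' under the permutation (relabelling) null, using the closed-form
#' permutation mean and variance; `|T|` near 0 means similar distributions.
#' The p-value is two-sided: exact enumeration of all group relabellings
#' when their number is at most `exact_limit`, otherwise `n_perm` seeded
#' Monte Carlo permutations.
#'
#' @param x,y Numeric vectors (non-empty).
#' @param n_perm Monte Carlo sample size.
#' @param exact_limit Enumeration threshold on `choose(n1+n2, n1)`.
#' @param seed Seed for the Monte Carlo path.
#' @return List with `statistic`, `p_value`, and `method`
#'   (`"exact"`/`"montecarlo"`).
#' @export
fisher_pitman <- function(x, y, n_perm = 10000, exact_limit = 20000,
                          seed = 1) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  t_obs <- .fp_statistic(x, y)
  z <- c(x, y)
  n1 <- length(x); N <- length(z)
  if (choose(N, n1) <= exact_limit) {
    idx <- combn(N, n1)
    tt <- apply(idx, 2, function(k) .fp_statistic(z[k], z[-k]))
    p <- mean(abs(tt) >= abs(t_obs) - 1e-12)
    method <- "exact"
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    tt <- replicate(n_perm, {
      k <- sample.int(N, n1)
      .fp_statistic(z[k], z[-k])
    })
    p <- (sum(abs(tt) >= abs(t_obs) - 1e-12) + 1) / (n_perm + 1)
    method <- "montecarlo"
  }
  list(statistic = t_obs, p_value = p, method = method)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Neighbor distribution score
#'
#' Fisher-Pitman statistic comparing two residues' neighbor-distance
#' multisets. Antisymmetric in its arguments; the pair-feature assembly
#' consumes `|T|` by default.
#'
#' @param di,dj Neighbor distance vectors (see
#'   [neighbor_distance_vector()]).
#' @return The signed statistic `T`.
#' @export
neighbor_distribution_score <- function(di, dj) .fp_statistic(di, dj)

#' Template ligand score
#'
#' For every combination of one template ligand from each bundle, the
#' moving protein is re-oriented by superposing its template ligand onto
#' the other bundle's ligand through their maximum-common-substructure atom
#' map, and all inter-pocket Calpha-Calpha distances are recorded. The
#' score for a residue pair is the average of those distances over all
#' usable ligand combinations, weighted by the squared fingerprint Tanimoto
#' coefficient of the ligand pair. Ligand pairs whose atom map has fewer
#' than 3 pairs define no superposition and are skipped (excluded from
#' numerator and denominator).
#'
#' @param bundle_a,bundle_b `pocket_bundle`s with at least one template
#'   ligand each.
#' @param min_weight Combinations with squared-Tanimoto weight below this
#'   are still used but flagged in the diagnostics.
#' @return List with `matrix` (`n x m` of Angstrom) and `diagnostics`
#'   (tibble: one row per ligand combination with `k`, `l`, `tanimoto`,
#'   `map_size`, `used`, `lig_rmsd`).
#' @export
template_ligand_score <- function(bundle_a, bundle_b, min_weight = 0.05^2) {
  la <- bundle_a$template_ligands; lb <- bundle_b$template_ligands
  if (!length(la) || !length(lb))
    abort("both bundles need at least one template ligand")
  ca_a <- pocket_ca(bundle_a$pocket)
  ca_b <- pocket_ca(bundle_b$pocket)
  n <- nrow(ca_a); m <- nrow(ca_b)
  num <- matrix(0, n, m)
  wsum <- 0
  diag_rows <- list()
  for (k in seq_along(la)) {
    for (l in seq_along(lb)) {
      amap <- mcs_atom_map(la[[k]], lb[[l]])
      usable <- nrow(amap$pairs) >= 3
      lig_rmsd <- NA_real_
      if (usable) {
        sup <- tryCatch(superpose_ligands(la[[k]], lb[[l]], amap),
                        error = function(e) NULL)
        usable <- !is.null(sup)
      }
      if (usable) {
        lig_rmsd <- sup$rmsd
        w <- amap$tanimoto^2
        bt <- t(sup$transform$rotation %*% t(ca_b) + sup$transform$translation)
        d <- .cross_dist(ca_a, bt)
        num <- num + w * d
        wsum <- wsum + w
      }
      diag_rows[[length(diag_rows) + 1]] <-
        tibble(k = k, l = l, tanimoto = amap$tanimoto,
               map_size = nrow(amap$pairs), used = usable,
               low_weight = usable && amap$tanimoto^2 < min_weight,
               lig_rmsd = lig_rmsd)
    }
  }
  if (wsum == 0) abort("no usable template-ligand superpositions")
  list(matrix = num / wsum, diagnostics = bind_rows(diag_rows))
}

#' Residue-pair feature matrix
#'
#' Computes the seven residue-level scores for every pair of residues drawn
#' one from each pocket: sequence profile dot product, secondary-structure
#' distance, hydrophobicity correlation, binding-probability difference,
#' neighbor-distribution statistic, entropy difference, and the
#' template-ligand distance.
#'
#' @param bundle_a,bundle_b `pocket_bundle`s.
#' @param nbr `"abs"` (default) stores `|T|` of the neighbor-distribution
#'   statistic, `"signed"` keeps the sign.
#' @param lig Precomputed [template_ligand_score()] result to reuse, or
#'   `NULL` to compute it here.
#' @return A `pair_features` tibble with columns `i`, `j`, `s_prof`,
#'   `s_ss`, `s_hp`, `s_prob`, `s_nbr`, `s_entr`, `s_lig` covering all
#'   `n x m` pairs; attributes `n`, `m` carry the pocket sizes.
#' @export
compute_pair_features <- function(bundle_a, bundle_b, nbr = c("abs", "signed"),
                                  lig = NULL) {
  nbr <- match.arg(nbr)
  pa <- bundle_a$pocket; pb <- bundle_b$pocket
  n <- pocket_size(pa); m <- pocket_size(pb)

  prof_a <- pocket_profile_matrix(pa); prof_b <- pocket_profile_matrix(pb)
  s_prof <- prof_a %*% t(prof_b)

  ss_a <- as.matrix(pa$residues[, c("ss_h", "ss_e", "ss_c")])
  ss_b <- as.matrix(pb$residues[, c("ss_h", "ss_e", "ss_c")])
  s_ss <- .cross_dist(ss_a, ss_b)

  hp_tab <- hydrophobicity_table()
  s_hp <- hp_tab[cbind(rep(pa$residues$aa, times = m),
                       rep(pb$residues$aa, each = n))]
  s_hp <- matrix(s_hp, n, m)

  s_prob <- outer(pa$residues$binding_prob, pb$residues$binding_prob,
                  function(a, b) (a - b)^2)
  s_entr <- outer(pa$residues$entropy, pb$residues$entropy,
                  function(a, b) (a - b)^2)

  nd_a <- lapply(seq_len(n), function(i) neighbor_distance_vector(pa, i))
  nd_b <- lapply(seq_len(m), function(j) neighbor_distance_vector(pb, j))
  s_nbr <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) s_nbr[i, j] <- .fp_statistic(nd_a[[i]], nd_b[[j]])
  }
  if (nbr == "abs") s_nbr <- abs(s_nbr)

  lig <- lig %||% template_ligand_score(bundle_a, bundle_b)
  s_lig <- lig$matrix

  out <- tibble(i = rep(seq_len(n), times = m),
                j = rep(seq_len(m), each = n),
                s_prof = as.numeric(s_prof), s_ss = as.numeric(s_ss),
                s_hp = as.numeric(s_hp), s_prob = as.numeric(s_prob),
                s_nbr = as.numeric(s_nbr), s_entr = as.numeric(s_entr),
                s_lig = as.numeric(s_lig))
  structure(out, n = n, m = m, lig_diagnostics = lig$diagnostics,
            class = c("pair_features", class(out)))
}

FEATURE_COLS <- c("s_prof", "s_ss", "s_hp", "s_prob", "s_nbr", "s_entr",
                  "s_lig")

# long pair-feature tibble column -> n x m matrix
pf_matrix <- function(pf, col) {
  matrix(pf[[col]], attr(pf, "n"), attr(pf, "m"))
}

# exact pairwise Euclidean distances between row sets (summed squared
# per-coordinate outer differences; no cancellation near zero)
.cross_dist <- function(A, B) {
  D2 <- 0
  for (k in seq_len(ncol(A))) D2 <- D2 + outer(A[, k], B[, k], "-")^2
  sqrt(D2)
}
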