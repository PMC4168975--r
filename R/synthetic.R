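#' Synthetic generator configuration
#'
#' Collects the knobs of the synthetic pocket-bundle generator. The
#' defaults are the standard study conditions used throughout the package:
#' pockets of 10-16 residues, 0.5 Angstrom coordinate noise between
#' related pockets, a 10% residue mutation rate, and three template
#' ligands per bundle (two in-family scaffold analogues plus one unrelated
#' scaffold, mimicking the imperfect template sets that evolution-based
#' pocket predictors return).
#'
#' @param size_range Integer 2-vector, min/max pocket size.
#' @param sigma Coordinate noise between paired pockets (Angstrom, sd of
#'   the per-residue displacement along each axis).
#' @param mutation_rate Fraction of residues whose amino-acid type is
#'   resampled in the partner pocket.
#' @param family Scaffold family id (1-8) of the bound ligand.
#' @param n_templates Template ligands per bundle.
#' @param seed Integer seed (mandatory; every draw flows from it).
#' @return A `synth_config` list.
#' @export
synth_config <- function(size_range = c(10, 16), sigma = 0.5,
                         mutation_rate = 0.1, family = 1, n_templates = 3,
                         seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(length(size_range) == 2, size_range[1] >= 4,
            size_range[2] >= size_range[1],
            sigma >= 0, mutation_rate >= 0, mutation_rate <= 1,
            family %in% 1:8, n_templates >= 1)
  structure(list(size_range = as.integer(size_range), sigma = sigma,
                 mutation_rate = mutation_rate, family = as.integer(family),
                 n_templates = as.integer(n_templates),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# scaffold families: even-sized rings alternating carbon with a
# family-specific heteroatom, plus a shared bent 3-carbon anchor chain.
# across families the only connected common substructure is the anchor
# (3 atoms), which is exactly enough to define a superposition
SCAFFOLD_RING <- c(6L, 6L, 8L, 8L, 6L, 8L, 6L, 8L)
SCAFFOLD_HET <- c("N", "O", "S", "P", "F", "Cl", "Br", "I")

#' Generate a scaffold ligand
#'
#' Abstract labelled molecular graph (not real chemistry): an alternating
#' hetero/carbon ring plus a bent three-carbon anchor chain shared by all
#' families; `variant > 0` appends that many family-heteroatom tail atoms
#' to the anchor, lowering the fingerprint Tanimoto to the base scaffold
#' in a controlled way.
#'
#' @param family Family id (1-8).
#' @param variant Non-negative integer, number of tail decorations.
#' @return A `ligand` centred near the origin.
#' @export
make_scaffold <- function(family, variant = 0) {
  rs <- SCAFFOLD_RING[family]
  het <- SCAFFOLD_HET[family]
  r <- 1.5 / (2 * sin(pi / rs))
  ang <- 2 * pi * (seq_len(rs) - 1) / rs
  ring <- tibble(elem = rep(c(het, "C"), rs / 2),
                 x = r * cos(ang), y = r * sin(ang), z = 0)
  ring_bonds <- tibble(from = seq_len(rs),
                       to = c(seq_len(rs)[-1], 1L), order = 1L)
  # bent anchor attached to ring atom 1 (heteroatom), out of plane
  a1 <- c(r + 1.5, 0.0, 0.3)
  a2 <- a1 + c(1.2, 0.9, 0.3)
  a3 <- a2 + c(1.2, -0.9, 0.3)
  anchor <- tibble(elem = "C",
                   x = c(a1[1], a2[1], a3[1]), y = c(a1[2], a2[2], a3[2]),
                   z = c(a1[3], a2[3], a3[3]))
  atoms <- bind_rows(ring, anchor)
  bonds <- bind_rows(ring_bonds,
                     tibble(from = c(1L, rs + 1L, rs + 2L),
                            to = c(rs + 1L, rs + 2L, rs + 3L), order = 1L))
  if (variant > 0) {
    base <- nrow(atoms)
    for (v in seq_len(variant)) {
      atoms <- bind_rows(atoms,
                         tibble(elem = het, x = a3[1] + 1.1 * v,
                                y = a3[2] + 0.8 * (v %% 2), z = a3[3] + 0.5))
      bonds <- bind_rows(bonds,
                         tibble(from = if (v == 1) rs + 3L else base + v - 1L,
                                to = base + v, order = 1L))
    }
  }
  new_ligand(atoms, bonds,
             name = sprintf("scaffold_f%d_v%d", family, variant))
}

.runit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

.rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.rdirichlet1 <- function(n) {
  g <- rgamma(n, 1)
  g / sum(g)
}

# profile peaked on the residue's own type (weight 0.6, remainder Dirichlet)
.synth_profile <- function(aa) {
  p <- 0.4 * .rdirichlet1(19)
  out <- numeric(20)
  out[AA20 != aa] <- p
  out[AA20 == aa] <- 0.6
  setNames(out, AA20)
}

# 3-state Markov sketch along the (arbitrary) residue order
.synth_ss <- function(n, stay = 0.8) {
  states <- integer(n)
  states[1] <- sample.int(3, 1)
  for (k in seq_len(n)[-1]) {
    states[k] <- if (runif(1) < stay) states[k - 1] else sample.int(3, 1)
  }
  t(vapply(states, function(s) {
    p <- 0.25 * .rdirichlet1(3)
    p[s] <- p[s] + 0.75
    p / sum(p)
  }, numeric(3)))
}

#' Generate a synthetic pocket bundle
#'
#' Places binding residues on a shell around a generated ligand scaffold,
#' with annotation tracks consistent with residue identity: profiles
#' peaked on the true type, Markov secondary structure, binding
#' probabilities in `[0.4, 1]`, and template ligands that are scaffold
#' analogues posed on the bound ligand. Deterministic for a given seed.
#'
#' @param config A [synth_config()].
#' @return A `pocket_bundle` with a bound ligand.
#' @export
make_bundle <- function(config) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  .make_bundle_unseeded(config)
}

.make_bundle_unseeded <- function(config) {
  sizes <- seq(config$size_range[1], config$size_range[2])
  n <- sizes[sample.int(length(sizes), 1)]
  bound <- make_scaffold(config$family, variant = 0)
  lig_center <- colMeans(ligand_coords(bound))

  # residue shell: rejection-sample directions so Calpha atoms stay apart
  ca <- matrix(NA_real_, n, 3)
  k <- 1; tries <- 0
  while (k <= n && tries < 4000) {
    tries <- tries + 1
    cand <- lig_center + runif(1, 6, 10) * .runit()
    if (k == 1 || min(sqrt(rowSums(sweep(ca[seq_len(k - 1), , drop = FALSE],
                                         2, cand)^2))) >= 3.8) {
      ca[k, ] <- cand
      k <- k + 1
    }
  }
  if (k <= n) abort("could not place pocket residues; relax size range")

  aa <- sample(AA20, n, replace = TRUE)
  # Cbeta 1.5 A and side-chain centroid ~2.4 A outward from the ligand
  out_dir <- t(apply(ca, 1, function(p) {
    d <- p - lig_center; d / sqrt(sum(d^2))
  }))
  cb <- ca + 1.5 * out_dir + matrix(rnorm(3 * n, 0, 0.15), n, 3)
  sc <- ca + 2.4 * out_dir + matrix(rnorm(3 * n, 0, 0.3), n, 3)
  cb[aa == "G", ] <- ca[aa == "G", ]
  sc[aa == "G", ] <- ca[aa == "G", ]
  sc[aa == "A", ] <- cb[aa == "A", ]

  ss <- .synth_ss(n)
  residues <- tibble(
    chain = "A", resseq = sort(sample(1:300, n)), icode = "",
    aa = aa,
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
    sc_x = sc[, 1], sc_y = sc[, 2], sc_z = sc[, 3],
    binding_prob = runif(n, 0.4, 1),
    ss_h = ss[, 2], ss_e = ss[, 3], ss_c = ss[, 1],
    profile = lapply(aa, .synth_profile))

  templates <- .synth_templates(config, bound)
  props <- rowMeans(vapply(templates, function(l) l$props, numeric(5)))
  pocket <- new_pocket(residues, props = props)
  new_pocket_bundle(pocket, templates, bound_ligand = bound)
}

# template ligands: in-family analogues posed on the bound ligand (small
# jitter), plus one unrelated-family scaffold — template sets recovered
# from evolutionary neighbours are rarely pure
.synth_templates <- function(config, bound) {
  nt <- config$n_templates
  fams <- rep(config$family, nt)
  if (nt >= 2) fams[nt] <- sample(setdiff(1:8, config$family), 1)
  lapply(seq_len(nt), function(k) {
    lig <- make_scaffold(fams[k], variant = sample(0:2, 1))
    xyz <- ligand_coords(lig) + matrix(rnorm(3 * nrow(lig$atoms), 0, 0.25),
                                       ncol = 3)
    lig$atoms$x <- xyz[, 1]; lig$atoms$y <- xyz[, 2]; lig$atoms$z <- xyz[, 3]
    lig$name <- sprintf("template_%d_%s", k, lig$name)
    lig
  })
}

#' Generate a pocket pair with a known relationship
#'
#' Positive pairs are two views of the same binding site: the partner is a
#' copy with per-residue coordinate noise `sigma`, a random residue-order
#' permutation, `mutation_rate` residue substitutions, fresh
#' annotation-track jitter, its own template-ligand draw from the same
#' scaffold family, and a random rigid motion of the whole bundle. The
#' planted correspondence is returned. Negative pairs are two independent
#' bundles whose bound ligands come from different scaffold families.
#'
#' @param config A [synth_config()].
#' @param relationship `"positive"` or `"negative"`.
#' @return List with `a`, `b` (`pocket_bundle`s) and `correspondence`
#'   (tibble `i_a`, `i_b` for positives, `NULL` for negatives).
#' @export
make_pair <- function(config, relationship = c("positive", "negative")) {
  relationship <- match.arg(relationship)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  a <- .make_bundle_unseeded(config)

  if (relationship == "negative") {
    cfg_b <- config
    cfg_b$family <- sample(setdiff(1:8, config$family), 1)
    b <- .make_bundle_unseeded(cfg_b)
    return(list(a = a, b = b, correspondence = NULL))
  }

  n <- pocket_size(a$pocket)
  r <- a$pocket$residues
  # per-residue rigid jiggle: one displacement moves all three points
  disp <- matrix(rnorm(3 * n, 0, config$sigma), n, 3)
  for (cols in list(c("ca_x", "ca_y", "ca_z"), c("cb_x", "cb_y", "cb_z"),
                    c("sc_x", "sc_y", "sc_z"))) {
    r[, cols] <- as.matrix(r[, cols]) + disp
  }
  # mutations: new residue type, profile repeaked, geometry kept
  mut <- runif(n) < config$mutation_rate
  if (any(mut)) {
    r$aa[mut] <- vapply(r$aa[mut],
                        function(x) sample(setdiff(AA20, x), 1), character(1))
    r$profile[mut] <- lapply(r$aa[mut], .synth_profile)
  }
  # annotation jitter: the partner's tracks are re-estimated, not copied
  r$binding_prob <- pmin(pmax(r$binding_prob + rnorm(n, 0, 0.05), 0), 1)
  ssj <- abs(as.matrix(r[, c("ss_h", "ss_e", "ss_c")]) +
               matrix(rnorm(3 * n, 0, 0.03), n, 3))
  ssj <- ssj / rowSums(ssj)
  r$ss_h <- ssj[, 1]; r$ss_e <- ssj[, 2]; r$ss_c <- ssj[, 3]
  r$entropy <- vapply(r$profile, sequence_entropy, numeric(1))

  perm <- sample.int(n)
  r <- r[perm, ]
  r$resseq <- sort(sample(1:300, n))  # fresh author numbering

  pocket_b <- new_pocket(r, props = NULL)
  templates_b <- .synth_templates(config, a$bound_ligand)
  pocket_b$props <- rowMeans(vapply(templates_b, function(l) l$props,
                                    numeric(5)))
  b <- new_pocket_bundle(pocket_b, templates_b, bound_ligand = a$bound_ligand)

  tr <- structure(list(rotation = .rand_rotation(),
                       translation = rnorm(3, 0, 15)),
                  class = "rigid_transform")
  b <- transform_bundle(b, tr)
  list(a = a, b = b,
       correspondence = tibble(i_a = seq_len(n), i_b = order(perm)))
}

#' Distort a pocket to a target Calpha RMSD
#'
#' Adds a seeded Gaussian displacement field to every residue (all three
#' point tracks move together), with the amplitude solved analytically so
#' the realised Calpha RMSD to the input equals the target exactly
#' (RMSD scales linearly with the field amplitude). Residue identities and
#' annotations are unchanged.
#'
#' @param pocket A `pocket`.
#' @param target Target Calpha RMSD (Angstrom, `>= 0`).
#' @param seed Integer seed for the displacement field.
#' @return The distorted `pocket`.
#' @export
distort_to_rmsd <- function(pocket, target, seed = 1) {
  stopifnot(target >= 0)
  if (target == 0) return(pocket)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- pocket_size(pocket)
  D <- matrix(rnorm(3 * n), n, 3)
  s <- target / sqrt(mean(rowSums(D^2)))
  r <- pocket$residues
  for (cols in list(c("ca_x", "ca_y", "ca_z"), c("cb_x", "cb_y", "cb_z"),
                    c("sc_x", "sc_y", "sc_z"))) {
    r[, cols] <- as.matrix(r[, cols]) + s * D
  }
  pocket$residues <- r
  pocket
}

#' Calpha RMSD between two conformations of the same pocket
#'
#' Paired (unsuperposed) RMSD over Calpha atoms, residue by residue.
#'
#' @param pocket_a,pocket_b `pocket`s with identical residue order.
#' @return RMSD in Angstrom.
#' @export
pocket_ca_rmsd <- function(pocket_a, pocket_b) {
  rmsd_points(pocket_ca(pocket_a), pocket_ca(pocket_b))
}

#' Generate a labeled synthetic benchmark
#'
#' Builds `n_pos` positive and `n_neg` negative pocket pairs. Positives
#' are distributed over `n_groups` scaffold families (the ligand groups
#' that drive leave-one-group-out cross-validation); negatives inherit the
#' group label of their first bundle's family. The manifest feeds
#' [benchmark()] and [make_training_set()] directly.
#'
#' @param n_pos,n_neg Pair counts.
#' @param n_groups Number of ligand groups (families 1..`n_groups`,
#'   max 6 so negatives can draw unrelated partners).
#' @param config Base [synth_config()]; its seed drives every pair.
#' @return Tibble with `pair_id`, `ligand_group`, `label`, list-columns
#'   `bundle_a`, `bundle_b`, `correspondence`.
#' @export
make_benchmark <- function(n_pos = 30, n_neg = 30, n_groups = 6, config) {
  stopifnot(n_groups >= 2, n_groups <= 6)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 2, n_pos + n_neg)
  rows <- vector("list", n_pos + n_neg)
  for (k in seq_len(n_pos + n_neg)) {
    positive <- k <= n_pos
    fam <- (k - 1) %% n_groups + 1
    cfg <- config
    cfg$family <- fam
    cfg$seed <- seeds[k]
    pr <- make_pair(cfg, if (positive) "positive" else "negative")
    rows[[k]] <- tibble(pair_id = sprintf("%s%03d",
                                          if (positive) "pos" else "neg", k),
                        ligand_group = sprintf("G%d", fam),
                        label = as.integer(positive),
                        bundle_a = list(pr$a), bundle_b = list(pr$b),
                        correspondence = list(pr$correspondence))
  }
  bind_rows(rows)
}
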