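test_that("fingerprints are deterministic and identity-similar", {
  l <- toy_ligand()
  expect_identical(fingerprint(l), fingerprint(toy_ligand()))
  expect_equal(tanimoto(fingerprint(l), fingerprint(l)), 1)
  # translated copy: same connection table, same fingerprint
  l2 <- toy_ligand(shift = 10)
  expect_identical(fingerprint(l), fingerprint(l2))
})

test_that("tanimoto follows the set formula and its conventions", {
  a <- c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 4))
  b <- c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(tanimoto(a, b), 2 / 6)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, !a), 0)
  expect_equal(tanimoto(logical(8), logical(8)), 1)  # both empty
  expect_error(tanimoto(a, b[1:4]), "length")
})

test_that("MCS size matches the modular-product clique oracle", {
  # identity: full map
  l <- toy_ligand()
  m <- mcs_atom_map(l, l)
  expect_equal(nrow(m$pairs), nrow(l$atoms))
  # assorted scaffolds and variants, checked against igraph cliques
  cases <- list(
    list(make_scaffold(1, 0), make_scaffold(1, 2)),
    list(make_scaffold(1, 0), make_scaffold(2, 0)),
    list(make_scaffold(3, 1), make_scaffold(4, 0)),
    list(toy_ligand(), make_scaffold(1, 0)))
  for (cs in cases) {
    got <- nrow(mcs_atom_map(cs[[1]], cs[[2]])$pairs)
    expect_equal(got, brute_mcs_size(cs[[1]], cs[[2]]))
  }
  # symmetry of the map size
  expect_equal(nrow(mcs_atom_map(cases[[1]][[1]], cases[[1]][[2]])$pairs),
               nrow(mcs_atom_map(cases[[1]][[2]], cases[[1]][[1]])$pairs))
})

test_that("ethane-vs-methane style subgraphs reduce to the shared atom", {
  ethane <- new_ligand(tibble::tibble(elem = c("C", "C", "C"),
                                      x = c(0, 1.5, 3), y = 0, z = c(0, 0.5, 0)),
                       tibble::tibble(from = c(1, 2), to = c(2, 3), order = 1))
  nitro <- new_ligand(tibble::tibble(elem = c("N", "N", "C"),
                                     x = c(0, 1.5, 3), y = 0, z = c(0, 0.5, 0)),
                      tibble::tibble(from = c(1, 2), to = c(2, 3), order = 1))
  expect_equal(nrow(mcs_atom_map(ethane, nitro)$pairs), 1)
  # no common element at all -> empty map
  oxo <- new_ligand(tibble::tibble(elem = c("O", "O", "O"),
                                   x = c(0, 1.5, 3), y = 0, z = c(0, 0.5, 0)),
                    tibble::tibble(from = c(1, 2), to = c(2, 3), order = 1))
  expect_equal(nrow(mcs_atom_map(ethane, oxo)$pairs), 0)
})

test_that("ligand superposition recovers rigid motions exactly", {
  l <- make_scaffold(1, 1)
  R <- rot_z(1.1); tvec <- c(3, -2, 5)
  lm <- l
  xyz <- apply_rt(as.matrix(l$atoms[, c("x", "y", "z")]), R, tvec)
  lm$atoms$x <- xyz[, 1]; lm$atoms$y <- xyz[, 2]; lm$atoms$z <- xyz[, 3]
  full <- mcs_atom_map(l, lm)
  sup <- superpose_ligands(l, lm, full)
  expect_lt(sup$rmsd, 1e-6)
  expect_equal(det(sup$transform$rotation), 1, tolerance = 1e-6)
})

test_that("least-squares fit beats random rigid transforms and a fine grid", {
  set.seed(5)
  for (n in c(4, 7, 10)) {
    P <- matrix(rnorm(3 * n, sd = 3), n, 3)
    Q <- apply_rt(P, rot_z(0.8), c(1, 2, 3)) + matrix(rnorm(3 * n, 0, 0.1),
                                                      n, 3)
    fit <- kabsch_fit(P, Q)
    best <- rmsdp(P, apply_rt(Q, fit$rotation, fit$translation))
    # random-transform lower-bound check
    rand <- replicate(400, {
      q <- rnorm(4); q <- q / sqrt(sum(q^2))
      w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
      Rr <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z),
                     2 * (x * z + w * y),
                     2 * (x * y + w * z), 1 - 2 * (x^2 + z^2),
                     2 * (y * z - w * x),
                     2 * (x * z - w * y), 2 * (y * z + w * x),
                     1 - 2 * (x^2 + y^2)), 3, 3, byrow = TRUE)
      Qc <- apply_rt(sweep(Q, 2, colMeans(Q)), Rr, colMeans(P))
      rmsdp(P, Qc)
    })
    expect_true(all(best <= rand + 1e-9))
  }
})

test_that("noisy 4-point fit agrees with a rotation-grid search oracle", {
  set.seed(9)
  P <- matrix(rnorm(12, sd = 2), 4, 3)
  Q <- apply_rt(P, rot_z(0.35), c(0.5, -1, 2)) +
    matrix(rnorm(12, 0, 0.1), 4, 3)
  fit <- kabsch_fit(P, Q)
  best <- rmsdp(P, apply_rt(Q, fit$rotation, fit$translation))
  # coarse-then-refined grid over z-y-z Euler angles, centroids matched
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  ry <- function(b) matrix(c(cos(b), 0, sin(b), 0, 1, 0,
                             -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  eval_grid <- function(as, bs, cs) {
    gmin <- Inf; arg <- c(0, 0, 0)
    for (a in as) for (b in bs) for (c in cs) {
      v <- rmsdp(Pc, Qc %*% t(rot_z(a) %*% ry(b) %*% rot_z(c)))
      if (v < gmin) { gmin <- v; arg <- c(a, b, c) }
    }
    list(min = gmin, arg = arg)
  }
  step <- 2 * pi / 30
  coarse <- eval_grid(seq(0, 2 * pi, length.out = 31),
                      seq(0, pi, length.out = 16),
                      seq(0, 2 * pi, length.out = 31))
  fine <- eval_grid(coarse$arg[1] + seq(-step, step, length.out = 21),
                    coarse$arg[2] + seq(-step, step, length.out = 21),
                    coarse$arg[3] + seq(-step, step, length.out = 21))
  gmin <- min(coarse$min, fine$min)
  expect_lte(best, gmin + 1e-9)
  expect_lt(abs(best - gmin), 0.02)
})
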