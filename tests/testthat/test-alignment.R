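aln_model <- shared_distance_model()

test_that("superposition by alignment recovers rigid copies", {
  p <- toy_pocket(8, seed = 2)
  pairs <- tibble::tibble(i = 1:8, j = 1:8)
  self <- superpose_by_alignment(p, p, pairs)
  expect_lt(self$pocket_rmsd, 1e-9)
  expect_equal(self$transform$rotation, diag(3), tolerance = 1e-6)

  q <- p
  xyz <- apply_rt(pocketalign:::pocket_ca(p), rot_z(0.5), c(1, -4, 2))
  q$residues$ca_x <- xyz[, 1]; q$residues$ca_y <- xyz[, 2]
  q$residues$ca_z <- xyz[, 3]
  fit <- superpose_by_alignment(p, q, pairs)
  expect_lt(fit$pocket_rmsd, 1e-6)
  expect_equal(fit$transform$rotation %*% rot_z(0.5), diag(3),
               tolerance = 1e-6)
})

test_that("alignment length equals the smaller pocket and is deterministic", {
  pr <- make_pair(synth_config(seed = 77, size_range = c(8, 12)), "positive")
  # force unequal sizes by dropping residues from B
  b <- pr$b
  keep <- seq_len(pocket_size(b$pocket) - 2)
  b$pocket$residues <- b$pocket$residues[keep, ]
  a1 <- align_pockets(pr$a, b, aln_model)
  expect_equal(nrow(a1), min(pocket_size(pr$a$pocket),
                             pocket_size(b$pocket)))
  a2 <- align_pockets(pr$a, b, aln_model)
  expect_identical(tidy(a1), tidy(a2))
})

test_that("aligning a bundle with itself recovers the self-correspondence", {
  cfg <- synth_config(seed = 55, size_range = c(10, 10))
  b <- make_bundle(cfg)
  b$template_ligands <- list(b$bound_ligand)
  aln <- align_pockets(b, b, aln_model)
  expect_gte(mean(aln$i == aln$j), 0.9)
  expect_lt(attr(aln, "pocket_rmsd"), 0.5)
})

test_that("reference alignments recover planted correspondences", {
  # noiseless, unmutated: exact recovery by construction
  pr0 <- make_pair(synth_config(seed = 60, sigma = 0, mutation_rate = 0),
                   "positive")
  ref0 <- reference_alignment(pr0$a, pr0$b)
  key0 <- paste(pr0$correspondence$i_a, pr0$correspondence$i_b)
  expect_true(all(paste(ref0$i, ref0$j) %in% key0))
  expect_lt(attr(ref0, "pocket_rmsd"), 1e-6)

  # sigma = 1: planted pairs recovered almost everywhere (20 replicates)
  hits <- vapply(1:20, function(k) {
    pr <- make_pair(synth_config(seed = 6000 + k, sigma = 1,
                                 size_range = c(20, 20)), "positive")
    ref <- reference_alignment(pr$a, pr$b)
    mean(paste(ref$i, ref$j) %in%
           paste(pr$correspondence$i_a, pr$correspondence$i_b))
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("assignment total cost never exceeds the reference pairing cost", {
  for (k in 1:3) {
    pr <- make_pair(synth_config(seed = 300 + k, size_range = c(8, 8)),
                    "positive")
    pf <- compute_pair_features(pr$a, pr$b)
    dmat <- predict_distance_matrix(aln_model, pf)
    aln <- align_pockets(pr$a, pr$b, aln_model, features = pf)
    ref_cost <- sum(dmat[cbind(pr$correspondence$i_a,
                               pr$correspondence$i_b)])
    expect_lte(attr(aln, "total_cost"), ref_cost + 1e-9)
  }
})

test_that("alignments are invariant to rigid motion of one input bundle", {
  pr <- make_pair(synth_config(seed = 88, size_range = c(8, 8)), "positive")
  a1 <- align_pockets(pr$a, pr$b, aln_model)
  tr <- structure(list(rotation = rot_z(1.3), translation = c(10, 0, -6)),
                  class = "rigid_transform")
  b_moved <- pocketalign:::transform_bundle(pr$b, tr)
  a2 <- align_pockets(pr$a, b_moved, aln_model)
  expect_equal(a1$i, a2$i)
  expect_equal(a1$j, a2$j)
})

test_that("ligand RMSD decomposes into pose error plus the ligand-only fit", {
  pr <- make_pair(synth_config(seed = 91, sigma = 0, mutation_rate = 0),
                  "positive")
  ref <- reference_alignment(pr$a, pr$b)
  lr <- ligand_rmsd(ref, pr$a$bound_ligand, pr$b$bound_ligand)
  expect_lt(lr$rmsd, 1e-6)
  expect_lt(lr$delta_rmsd, 1e-6)

  # hand-rotated case: rotate ligand B by pi about the z-axis through its
  # centroid after a perfect fit; the RMSD is the analytic displacement
  lig <- pr$a$bound_ligand
  X <- as.matrix(lig$atoms[, c("x", "y", "z")])
  ctr <- colMeans(X)
  Xr <- apply_rt(sweep(X, 2, ctr), rot_z(pi), ctr)
  ligr <- lig; ligr$atoms$x <- Xr[, 1]; ligr$atoms$y <- Xr[, 2]
  ligr$atoms$z <- Xr[, 3]
  idn <- structure(list(rotation = diag(3), translation = rep(0, 3)),
                   class = "rigid_transform")
  aln <- new_pocket_alignment(tibble::tibble(i = 1:3, j = 1:3),
                              transform = idn, n = 3, m = 3)
  full_map <- mcs_atom_map(lig, ligr)
  got <- ligand_rmsd(aln, lig, ligr, full_map)
  # analytic: each atom moves 2 * its xy-distance from the centroid axis
  Xm <- Xr[full_map$pairs$b, ]; Xa <- X[full_map$pairs$a, ]
  expect_equal(got$rmsd, sqrt(mean(rowSums((Xa - Xm)^2))), tolerance = 1e-9)
  d_xy <- sweep(X[full_map$pairs$a, 1:2, drop = FALSE], 2, ctr[1:2])
  expect_equal(got$rmsd, sqrt(mean(4 * rowSums(d_xy^2))), tolerance = 1e-9)
  expect_gte(got$delta_rmsd, 0)
})
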