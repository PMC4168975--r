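test_that("closed-form scores match direct recomputation on random inputs", {
  set.seed(31)
  for (t in 1:25) {
    pi_ <- runif(20); pj <- runif(20)
    expect_equal(sequence_profile_score(pi_, pj), sum(pi_ * pj),
                 tolerance = 1e-12)
    si <- runif(3); sj <- runif(3)
    expect_equal(secondary_structure_score(si, sj),
                 sqrt(sum((si - sj)^2)), tolerance = 1e-12)
    bi <- runif(1); bj <- runif(1)
    expect_equal(binding_probability_score(bi, bj), (bi - bj)^2,
                 tolerance = 1e-15)
    ei <- runif(1, 0, 4.3); ej <- runif(1, 0, 4.3)
    expect_equal(sequence_entropy_score(ei, ej), (ei - ej)^2,
                 tolerance = 1e-15)
  }
})

test_that("profile score edge cases follow the dot-product definition", {
  u <- rep(0, 20); u[3] <- 1
  v <- rep(0, 20); v[5] <- 1
  expect_equal(sequence_profile_score(u, u), 1)
  expect_equal(sequence_profile_score(u, v), 0)
  w <- rep(0, 20); w[1] <- 0.5; w[20] <- 0.5
  a1 <- rep(0, 20); a1[1] <- 1
  expect_equal(sequence_profile_score(w, a1), 0.5)
  expect_equal(secondary_structure_score(c(1, 0, 0), c(0, 1, 0)), sqrt(2))
})

test_that("hydrophobicity score is a Pearson correlation over the scales", {
  sc <- hydrophobicity_scales()
  expect_equal(dim(sc), c(20, 20))
  expect_equal(hydrophobicity_score("I", "I"), 1)
  expect_equal(hydrophobicity_score("I", "F"), hydrophobicity_score("F", "I"))
  # spreadsheet-style recomputation of the Pearson formula
  for (pair in list(c("I", "D"), c("K", "R"), c("W", "G"))) {
    h1 <- sc[, pair[1]]; h2 <- sc[, pair[2]]
    n <- 20
    num <- n * sum(h1 * h2) - sum(h1) * sum(h2)
    den <- sqrt(n * sum(h1^2) - sum(h1)^2) * sqrt(n * sum(h2^2) - sum(h2)^2)
    expect_equal(hydrophobicity_score(pair[1], pair[2]), num / den,
                 tolerance = 1e-9)
  }
  # like residues correlate more strongly than unlike ones
  expect_gt(hydrophobicity_score("I", "L"), hydrophobicity_score("I", "D"))
})

test_that("entropy handles uniform, delta and two-state profiles", {
  expect_equal(sequence_entropy(rep(1 / 20, 20)), log2(20), tolerance = 1e-9)
  d <- rep(0, 20); d[7] <- 1
  expect_equal(sequence_entropy(d), 0)
  h <- rep(0, 20); h[1] <- 0.5; h[2] <- 0.5
  expect_equal(sequence_entropy(h), 1)
  # log-odds profiles go through softmax: all-equal stays uniform
  expect_equal(sequence_entropy(rep(2.5, 20), kind = "logodds"), log2(20),
               tolerance = 1e-9)
})

test_that("neighbor distance vectors follow pocket geometry", {
  # equilateral triangle, side 5
  p <- new_pocket(tibble::tibble(
    chain = "A", resseq = 1:3, icode = "", aa = c("A", "R", "D"),
    ca_x = c(0, 5, 2.5), ca_y = c(0, 0, 5 * sqrt(3) / 2), ca_z = 0))
  expect_equal(sort(neighbor_distance_vector(p, 1)), c(5, 5),
               tolerance = 1e-9)
  # collinear 0, 3, 7: middle residue sees {3, 4}
  p2 <- new_pocket(tibble::tibble(
    chain = "A", resseq = 1:3, icode = "", aa = c("A", "R", "D"),
    ca_x = c(0, 3, 7), ca_y = 0, ca_z = 0))
  expect_equal(sort(neighbor_distance_vector(p2, 2)), c(3, 4))
})

test_that("Fisher-Pitman statistic and p-values behave as a permutation test", {
  # identical samples: T = 0, exact p = 1
  fp <- fisher_pitman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(fp$statistic, 0)
  expect_equal(fp$method, "exact")
  expect_equal(fp$p_value, 1)
  # extreme separation: p equals the minimum over the C(6,3)=20 splits
  fp2 <- fisher_pitman(c(1, 1, 1), c(10, 10, 10))
  expect_equal(fp2$p_value, 2 / 20)  # both extreme tails
  expect_gt(abs(fp2$statistic), 1.5)
  # antisymmetry
  expect_equal(neighbor_distribution_score(c(1, 2, 4), c(2, 2, 5)),
               -neighbor_distribution_score(c(2, 2, 5), c(1, 2, 4)),
               tolerance = 1e-12)
})

test_that("Monte-Carlo p-value agrees with exact enumeration within 3 SE", {
  set.seed(12)
  x <- rnorm(8); y <- rnorm(8, mean = 0.8)
  exact <- fisher_pitman(x, y, exact_limit = 20000)
  expect_equal(exact$method, "exact")
  mc <- fisher_pitman(x, y, exact_limit = 1, n_perm = 4000, seed = 3)
  expect_equal(mc$method, "montecarlo")
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 4000)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 1 / 4000)
  expect_equal(mc$statistic, exact$statistic)
})

test_that("template ligand score is a weighted average over combinations", {
  cfg <- synth_config(seed = 21)
  pr <- make_pair(cfg, "positive")
  tl <- template_ligand_score(pr$a, pr$b)
  expect_true(all(is.finite(tl$matrix)))
  expect_true(all(tl$matrix >= 0))
  expect_equal(nrow(tl$diagnostics),
               length(pr$a$template_ligands) * length(pr$b$template_ligands))
  # independent recomputation of the weighted average from the per-pair
  # transforms
  ca_a <- pocketalign:::pocket_ca(pr$a$pocket)
  ca_b <- pocketalign:::pocket_ca(pr$b$pocket)
  num <- matrix(0, nrow(ca_a), nrow(ca_b)); wsum <- 0
  for (k in seq_along(pr$a$template_ligands)) {
    for (l in seq_along(pr$b$template_ligands)) {
      amap <- mcs_atom_map(pr$a$template_ligands[[k]],
                           pr$b$template_ligands[[l]])
      if (nrow(amap$pairs) < 3) next
      sup <- superpose_ligands(pr$a$template_ligands[[k]],
                               pr$b$template_ligands[[l]], amap)
      bt <- apply_rt(ca_b, sup$transform$rotation, sup$transform$translation)
      d <- as.matrix(dist(rbind(ca_a, bt)))[seq_len(nrow(ca_a)),
                                            nrow(ca_a) + seq_len(nrow(bt))]
      num <- num + amap$tanimoto^2 * d
      wsum <- wsum + amap$tanimoto^2
    }
  }
  expect_equal(unname(tl$matrix), unname(num / wsum), tolerance = 1e-8)
})

test_that("self-pair feature matrix shows the identity signature", {
  cfg <- synth_config(seed = 33, size_range = c(8, 8))
  b <- make_bundle(cfg)
  b$template_ligands <- list(b$bound_ligand)  # one identical template
  pf <- compute_pair_features(b, b)
  expect_equal(attr(pf, "n"), 8)
  expect_equal(attr(pf, "m"), 8)
  d <- pf[pf$i == pf$j, ]
  expect_equal(d$s_ss, rep(0, 8), tolerance = 1e-6)
  expect_equal(d$s_prob, rep(0, 8), tolerance = 1e-12)
  expect_equal(d$s_entr, rep(0, 8), tolerance = 1e-12)
  expect_equal(d$s_hp, rep(1, 8), tolerance = 1e-12)
  expect_equal(d$s_nbr, rep(0, 8), tolerance = 1e-12)
  expect_equal(d$s_lig, rep(0, 8), tolerance = 1e-6)
})

test_that("feature matrix equals per-score recomputation entry by entry", {
  cfg <- synth_config(seed = 5, size_range = c(4, 5))
  pr <- make_pair(cfg, "positive")
  pf <- compute_pair_features(pr$a, pr$b)
  pa <- pr$a$pocket; pb <- pr$b$pocket
  for (r in sample(nrow(pf), 10)) {
    i <- pf$i[r]; j <- pf$j[r]
    expect_equal(pf$s_prof[r],
                 sequence_profile_score(pa$residues$profile[[i]],
                                        pb$residues$profile[[j]]),
                 tolerance = 1e-12)
    expect_equal(pf$s_ss[r], secondary_structure_score(
      unlist(pa$residues[i, c("ss_h", "ss_e", "ss_c")]),
      unlist(pb$residues[j, c("ss_h", "ss_e", "ss_c")])),
      tolerance = 1e-6)
    expect_equal(pf$s_hp[r],
                 hydrophobicity_score(pa$residues$aa[i], pb$residues$aa[j]),
                 tolerance = 1e-12)
    expect_equal(pf$s_nbr[r],
                 abs(neighbor_distribution_score(
                   neighbor_distance_vector(pa, i),
                   neighbor_distance_vector(pb, j))), tolerance = 1e-12)
  }
})

test_that("template ligand score is invariant to joint rigid motion", {
  cfg <- synth_config(seed = 13, size_range = c(6, 6))
  pr <- make_pair(cfg, "positive")
  tl1 <- template_ligand_score(pr$a, pr$b)$matrix
  tr <- structure(list(rotation = rot_z(0.9), translation = c(4, -7, 1)),
                  class = "rigid_transform")
  b2 <- pocketalign:::transform_bundle(pr$b, tr)
  tl2 <- template_ligand_score(pr$a, b2)$matrix
  expect_equal(tl1, tl2, tolerance = 1e-6)
})
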