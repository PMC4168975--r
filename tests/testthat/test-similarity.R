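test_that("averaged model scores equal direct sums over aligned pairs", {
  aln <- new_pocket_alignment(tibble::tibble(i = 1:4, j = c(2, 1, 4, 3)),
                              n = 4, m = 4)
  svr <- matrix(2, 4, 4)
  svc <- matrix(0, 4, 4); svc[cbind(1:2, c(2, 1))] <- 1
  avg <- average_model_scores(aln, svr, svc)
  expect_equal(avg$f_svr, 2)
  expect_equal(avg$f_svc, 0.5)
  set.seed(2)
  svr2 <- matrix(runif(16), 4, 4)
  avg2 <- average_model_scores(aln, svr2)
  expect_equal(avg2$f_svr, mean(svr2[cbind(aln$i, aln$j)]), tolerance = 1e-12)
})

test_that("chemical correlation reaches its extremes and matches the oracle", {
  cfg <- synth_config(seed = 70)
  b <- make_bundle(cfg)
  lib <- synthetic_screening_library(40, seed = 5)
  expect_equal(chemical_correlation(b, b, lib), 1)

  # tau against O(n^2) concordant/discordant counting on random scores
  sa <- screening_scores(b, lib)
  b2 <- make_bundle(synth_config(seed = 71, family = 3))
  sb <- screening_scores(b2, lib)
  expect_equal(cor(sa, sb, method = "kendall"), kendall_oracle(sa, sb),
               tolerance = 1e-9)

  # invariance under strictly monotone transforms of the scores
  expect_equal(cor(sa, sb, method = "kendall"),
               cor(exp(3 * sa), sb^3 + sb, method = "kendall"),
               tolerance = 1e-12)
  # exactly reversed rankings
  x <- 1:20; y <- 20:1
  expect_equal(cor(x, y, method = "kendall"), -1)
})

test_that("physicochemical feature uses documented normalized differences", {
  p1 <- c(mw = 300, logp = 1, psa = 80, hbd = 2, hba = 4)
  expect_equal(physicochemical_feature(p1, p1), 0)
  p2 <- c(mw = 400, logp = -1, psa = 110, hbd = 4, hba = 7)
  manual <- mean(c(100 / 500, 2 / 5, 30 / 150, 2 / 5, 3 / 10))
  expect_equal(physicochemical_feature(p1, p2), manual, tolerance = 1e-12)
  expect_equal(physicochemical_feature(p2, p1),
               physicochemical_feature(p1, p2))
  manual_sq <- mean(c((100 / 500)^2, (2 / 5)^2, (30 / 150)^2, (2 / 5)^2,
                      (3 / 10)^2))
  expect_equal(physicochemical_feature(p1, p2, "squared"), manual_sq,
               tolerance = 1e-12)
})

test_that("geometric hashing groups, symmetry and self-identity hold", {
  expect_equal(residue_group("K"), 1)
  expect_equal(residue_group(c("A", "D", "Y", "C")), c(0, 2, 3, 4))
  p <- toy_pocket(6, seed = 3)
  expect_equal(pms_score(p, p), 1)
  q <- toy_pocket(7, seed = 4)
  expect_equal(pms_score(p, q), pms_score(q, p), tolerance = 1e-12)
  s <- pms_score(p, q)
  expect_gte(s, 0); expect_lte(s, 1)
})

test_that("pms score on tiny pockets equals exhaustive list matching", {
  p <- toy_pocket(4, seed = 8)
  q <- toy_pocket(4, seed = 9)
  la <- pocketalign:::.pms_lists(p)
  lb <- pocketalign:::.pms_lists(q)
  expect_length(la, 90)
  matched <- total <- 0
  for (key in names(la)) {
    a <- la[[key]]; b <- lb[[key]]
    # exhaustive greedy replay on the tiny sorted lists
    i <- 1; j <- 1
    while (i <= length(a) && j <= length(b)) {
      if (abs(a[i] - b[j]) <= 0.5) { matched <- matched + 1
        i <- i + 1; j <- j + 1 }
      else if (a[i] < b[j]) i <- i + 1 else j <- j + 1
    }
    total <- total + max(length(a), length(b))
  }
  expect_equal(pms_score(p, q), matched / total, tolerance = 1e-12)
})

test_that("self-pairs produce the identity similarity record", {
  b <- make_bundle(synth_config(seed = 90, size_range = c(8, 8)))
  b$template_ligands <- list(b$bound_ligand)
  m <- shared_distance_model()
  lib <- synthetic_screening_library(40, seed = 2)
  rec <- similarity_features(b, b, m, library = lib)
  expect_lt(rec$f_rms, 1e-6)
  expect_equal(rec$f_tau, 1)
  expect_equal(rec$f_pcf, 0)
  expect_equal(rec$f_pms, 1)
  # record equals per-feature recomputation
  aln <- attr(rec, "alignment")
  pf <- compute_pair_features(b, b)
  svr <- predict_distance_matrix(m, pf)
  expect_equal(rec$f_svr, mean(svr[cbind(aln$i, aln$j)]), tolerance = 1e-9)
  expect_equal(rec$f_pms, pms_score(b$pocket, b$pocket))
  rec2 <- similarity_features(b, b, m, library = lib)
  expect_equal(as.data.frame(rec), as.data.frame(rec2))  # deterministic
})

test_that("similarity classifier separates separable records and calibrates", {
  set.seed(20)
  n <- 300
  recs <- tibble::tibble(
    f_rms = c(runif(n / 2, 0, 1.5), runif(n / 2, 3, 8)),
    f_svr = c(runif(n / 2, 0, 2), runif(n / 2, 4, 10)),
    f_svc = NA_real_,
    f_tau = c(runif(n / 2, 0.5, 1), runif(n / 2, -0.2, 0.4)),
    f_pcf = c(runif(n / 2, 0, 0.1), runif(n / 2, 0.1, 0.5)),
    f_pms = c(runif(n / 2, 0.5, 1), runif(n / 2, 0, 0.45)))
  labels <- rep(c(1, 0), each = n / 2)
  idx <- sample(n)
  train <- idx[1:200]; test <- idx[201:n]
  cls <- train_similarity_classifier(recs[train, ], labels[train], seed = 1)
  prob <- classify_similarity(cls, recs[test, ])
  expect_gt(roc_auc(prob, labels[test])$auc, 0.99)
  expect_true(all(prob >= 0 & prob <= 1))
  expect_error(train_similarity_classifier(recs[1:5, ], rep(1, 5)),
               "both classes")
})

test_that("label shuffling drives the classifier to chance", {
  set.seed(21)
  n <- 500
  recs <- tibble::tibble(f_rms = runif(n, 0, 8), f_svr = runif(n, 0, 10),
                         f_svc = NA_real_, f_tau = runif(n, -1, 1),
                         f_pcf = runif(n, 0, 0.5), f_pms = runif(n))
  labels <- sample(c(0, 1), n, replace = TRUE)
  cls <- train_similarity_classifier(recs[1:250, ], labels[1:250], seed = 1)
  prob <- classify_similarity(cls, recs[251:n, ])
  auc <- roc_auc(prob, labels[251:n])$auc
  expect_lt(abs(auc - 0.5), 0.07)
})

test_that("probability tracks f_pms when it drives the label", {
  set.seed(22)
  n <- 400
  recs <- tibble::tibble(f_rms = 2, f_svr = 3, f_svc = NA_real_,
                         f_tau = 0.2, f_pcf = 0.2, f_pms = runif(n))
  labels <- as.integer(recs$f_pms > 0.5)
  cls <- train_similarity_classifier(recs, labels, seed = 1)
  grid <- recs[1:9, ]
  grid$f_pms <- seq(0.1, 0.9, 0.1)
  prob <- classify_similarity(cls, grid)
  expect_true(all(diff(prob) > -1e-6))
  expect_gt(prob[9], prob[1])
})
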