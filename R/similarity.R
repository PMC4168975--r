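#' Average model scores over an alignment
#'
#' Arithmetic means of the predicted-distance and match-probability
#' matrices over the aligned residue pairs.
#'
#' @param alignment A `pocket_alignment`.
#' @param svr_matrix Predicted distance matrix (`n x m`).
#' @param svc_matrix Match-probability matrix (`n x m`), or `NULL`.
#' @return Named list with `f_svr` and `f_svc` (NA when no matrix given).
#' @export
average_model_scores <- function(alignment, svr_matrix, svc_matrix = NULL) {
  idx <- cbind(alignment$i, alignment$j)
  list(f_svr = mean(svr_matrix[idx]),
       f_svc = if (is.null(svc_matrix)) NA_real_ else mean(svc_matrix[idx]))
}

#' Screening scores of a pocket against a compound library
#'
#' Ligand-based virtual screening stand-in: each library compound is scored
#' by its fingerprint Tanimoto similarity to the pocket's template ligands
#' (maximum over templates by default, mean optionally).
#'
#' @param bundle A `pocket_bundle` with template ligands.
#' @param library List of fingerprint bit vectors.
#' @param mode `"max"` (default) or `"mean"`.
#' @return Numeric vector, one score per library compound.
#' @export
screening_scores <- function(bundle, library, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  if (!length(bundle$template_ligands)) abort("bundle has no template ligands")
  fps <- lapply(bundle$template_ligands, ligand_fp)
  vapply(library, function(fp) {
    s <- vapply(fps, tanimoto, numeric(1), fp_b = fp)
    if (mode == "max") max(s) else mean(s)
  }, numeric(1))
}

#' Chemical correlation between two pockets
#'
#' Kendall rank correlation (tau-b, which handles tied screening scores)
#' between the two pockets' rankings of a common compound library.
#'
#' @param bundle_a,bundle_b `pocket_bundle`s with template ligands.
#' @param library List of at least 10 fingerprint bit vectors (see
#'   [synthetic_screening_library()]).
#' @param mode Screening-score mode, see [screening_scores()].
#' @return Kendall tau in `[-1, 1]`.
#' @export
chemical_correlation <- function(bundle_a, bundle_b, library,
                                 mode = c("max", "mean")) {
  if (length(library) < 10) abort("screening library needs >= 10 compounds")
  sa <- screening_scores(bundle_a, library, mode)
  sb <- screening_scores(bundle_b, library, mode)
  if (sd(sa) == 0 && sd(sb) == 0) return(1)
  if (sd(sa) == 0 || sd(sb) == 0) return(0)
  cor(sa, sb, method = "kendall")
}

# normalisation constants making the five ligand properties commensurate
PCF_NORM <- c(mw = 500, logp = 5, psa = 150, hbd = 5, hba = 10)

#' Physicochemical feature
#'
#' Mean normalised difference between the consensus ligand properties of
#' the two pockets (molecular weight, logP, polar surface area, H-bond
#' donors and acceptors). Each absolute (or squared) difference is divided
#' by a fixed constant (MW 500, logP 5, PSA 150, HBD 5, HBA 10) before
#' averaging.
#'
#' @param props_a,props_b Named 5-vectors (`mw`, `logp`, `psa`, `hbd`,
#'   `hba`).
#' @param mode `"absolute"` (default) or `"squared"` differences.
#' @return Scalar `>= 0`.
#' @export
physicochemical_feature <- function(props_a, props_b,
                                    mode = c("absolute", "squared")) {
  mode <- match.arg(mode)
  d <- (as.numeric(props_a) - as.numeric(props_b)) / PCF_NORM
  mean(if (mode == "absolute") abs(d) else d^2)
}

# PocketMatch-style residue groups
PMS_GROUPS <- c(A = 0, V = 0, I = 0, L = 0, M = 0, G = 0, P = 0,
                K = 1, R = 1, H = 1,
                D = 2, E = 2, Q = 2, N = 2,
                Y = 3, F = 3, W = 3,
                C = 4, S = 4, T = 4)

#' PocketMatch residue group of an amino acid
#'
#' Groups: 0 = \{A,V,I,L,M,G,P\}, 1 = \{K,R,H\}, 2 = \{D,E,Q,N\},
#' 3 = \{Y,F,W\}, 4 = \{C,S,T\}.
#'
#' @param aa One-letter code(s).
#' @return Integer group id(s) in 0..4.
#' @export
residue_group <- function(aa) unname(PMS_GROUPS[aa])

# the 90 sorted distance lists of one pocket: 15 unordered residue-group
# pairs x 6 unordered point-type pairs (Calpha, Cbeta, side-chain centroid)
.pms_lists <- function(pocket) {
  pts <- list(ca = pocket_ca(pocket), cb = pocket_cb(pocket),
              sc = pocket_sc(pocket))
  # fall back per the three-point convention: glycine Cb/centroid -> Calpha
  for (t in c("cb", "sc")) {
    bad <- !is.finite(pts[[t]][, 1])
    pts[[t]][bad, ] <- pts$ca[bad, ]
  }
  grp <- residue_group(pocket$residues$aa)
  n <- pocket_size(pocket)
  types <- c("ca", "cb", "sc")
  lists <- list()
  for (g1 in 0:4) for (g2 in g1:4) {
    for (t1 in 1:3) for (t2 in t1:3) {
      key <- sprintf("g%d%d_%s%s", g1, g2, types[t1], types[t2])
      lists[[key]] <- numeric(0)
    }
  }
  if (n >= 2) {
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    for (k in seq_len(nrow(pr))) {
      r <- pr[k, 1]; s <- pr[k, 2]
      g1 <- min(grp[r], grp[s]); g2 <- max(grp[r], grp[s])
      for (t1 in 1:3) for (t2 in 1:3) {
        if (t2 < t1) next
        key <- sprintf("g%d%d_%s%s", g1, g2, types[t1], types[t2])
        d1 <- sqrt(sum((pts[[t1]][r, ] - pts[[t2]][s, ])^2))
        lists[[key]] <- c(lists[[key]], d1)
        if (t1 != t2) {
          d2 <- sqrt(sum((pts[[t2]][r, ] - pts[[t1]][s, ])^2))
          lists[[key]] <- c(lists[[key]], d2)
        }
      }
    }
  }
  lapply(lists, sort)
}

# greedy two-pointer matching of two sorted lists within tolerance
.match_sorted <- function(a, b, tol) {
  i <- 1; j <- 1; hits <- 0
  while (i <= length(a) && j <= length(b)) {
    if (abs(a[i] - b[j]) <= tol) { hits <- hits + 1; i <- i + 1; j <- j + 1 }
    else if (a[i] < b[j]) i <- i + 1
    else j <- j + 1
  }
  hits
}

#' Geometric hashing pocket score
#'
#' Alignment-free shape-and-chemistry similarity: each pocket becomes 90
#' sorted lists of inter-residue distances (Calpha, Cbeta and side-chain
#' centroid points; residues binned into 5 chemical groups), matched
#' greedily list-by-list within a distance tolerance. The score is the
#' total number of matched elements divided by the larger pocket's total
#' element count — a size-weighted average fraction of matching elements
#' across the lists, in `[0, 1]`.
#'
#' @param pocket_a,pocket_b `pocket`s.
#' @param tol Match tolerance (Angstrom).
#' @return Scalar in `[0, 1]`.
#' @export
pms_score <- function(pocket_a, pocket_b, tol = 0.5) {
  la <- .pms_lists(pocket_a); lb <- .pms_lists(pocket_b)
  matched <- total <- 0
  for (key in names(la)) {
    matched <- matched + .match_sorted(la[[key]], lb[[key]], tol)
    total <- total + max(length(la[[key]]), length(lb[[key]]))
  }
  if (total == 0) return(0)
  matched / total
}

#' The six pocket-level similarity features
#'
#' Runs one alignment pass and assembles the feature vector the similarity
#' classifier consumes: `f_rms` (pocket Calpha RMSD over the alignment),
#' `f_svr`/`f_svc` (model scores averaged over aligned pairs), `f_tau`
#' (virtual-screening rank correlation), `f_pcf` (physicochemical property
#' differences) and `f_pms` (geometric hashing score).
#'
#' @param bundle_a,bundle_b `pocket_bundle`s.
#' @param model Regression `distance_model`.
#' @param svc_model Optional classification `distance_model` (its absence
#'   leaves `f_svc` NA).
#' @param library Screening fingerprint library.
#' @param features,alignment Precomputed intermediates to reuse.
#' @return A one-row `similarity_record` tibble; the alignment is attached
#'   as attribute `"alignment"`.
#' @export
similarity_features <- function(bundle_a, bundle_b, model, svc_model = NULL,
                                library = synthetic_screening_library(),
                                features = NULL, alignment = NULL) {
  pf <- features %||% compute_pair_features(bundle_a, bundle_b)
  aln <- alignment %||% align_pockets(bundle_a, bundle_b, model,
                                      features = pf)
  svr_m <- predict_distance_matrix(model, pf)
  svc_m <- if (!is.null(svc_model)) predict_match_matrix(svc_model, pf)
  avg <- average_model_scores(aln, svr_m, svc_m)
  rec <- tibble(
    f_rms = attr(aln, "pocket_rmsd"),
    f_svr = avg$f_svr,
    f_svc = avg$f_svc,
    f_tau = chemical_correlation(bundle_a, bundle_b, library),
    f_pcf = physicochemical_feature(bundle_a$pocket$props,
                                    bundle_b$pocket$props),
    f_pms = pms_score(bundle_a$pocket, bundle_b$pocket),
    probability = NA_real_)
  structure(rec, alignment = aln,
            class = c("similarity_record", class(rec)))
}

SIM_FEATURES <- c("f_rms", "f_svr", "f_svc", "f_tau", "f_pcf", "f_pms")

#' Train the pocket similarity classifier
#'
#' RBF-kernel support vector classifier with Platt probability calibration
#' on the six pocket-level features; `f_svc` is dropped automatically when
#' absent from the records.
#'
#' @param records Tibble of similarity records (rows = pocket pairs).
#' @param labels Binary vector (1 = pockets bind similar ligands).
#' @param seed Integer seed.
#' @param cost,gamma libSVM hyperparameters.
#' @return A `similarity_model`.
#' @export
train_similarity_classifier <- function(records, labels, seed = 1,
                                        cost = 10, gamma = NULL) {
  feats <- SIM_FEATURES
  if (all(is.na(records$f_svc))) feats <- setdiff(feats, "f_svc")
  X <- as.matrix(records[, feats])
  if (length(unique(labels)) < 2) abort("both classes must be present")
  gamma <- gamma %||% 1 / length(feats)
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- e1071::svm(Xs, factor(labels, levels = c(0, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, probability = TRUE,
                    scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl, features = feats,
                 meta = list(seed = seed, cost = cost, gamma = gamma,
                             version = "1")),
            class = "similarity_model")
}

#' Pocket similarity probability
#'
#' @param model A `similarity_model`.
#' @param records Similarity record tibble (one or more rows).
#' @return Numeric vector of probabilities that each pocket pair binds
#'   similar ligands.
#' @export
classify_similarity <- function(model, records) {
  X <- as.matrix(records[, model$features])
  if (anyNA(X))
    abort(paste("records are missing feature(s) the classifier needs:",
                paste(model$features[apply(is.na(X), 2, any)],
                      collapse = ", ")))
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  pr <- predict(model$fit, Xs, probability = TRUE)
  unname(attr(pr, "probabilities")[, "1"])
}

#' @export
print.similarity_model <- function(x, ...) {
  cat(sprintf("<similarity_model> %d features (%s), %d SVs\n",
              length(x$features), paste(x$features, collapse = ", "),
              nrow(x$fit$SV)))
  invisible(x)
}

#' Synthetic screening fingerprint library
#'
#' A deterministic library of diverse sparse fingerprints standing in for a
#' redundancy-reduced small-molecule screening collection. A real library
#' can be supplied anywhere a `library` argument is accepted, as a list of
#' bit vectors.
#'
#' @param n Number of compounds.
#' @param nbits Fingerprint length.
#' @param density Expected fraction of set bits per compound.
#' @param seed Integer seed (fixed default: the library is package data in
#'   code form).
#' @return List of `n` logical vectors.
#' @export
synthetic_screening_library <- function(n = 1000, nbits = 1024,
                                        density = 0.05, seed = 42) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n), function(k) runif(nbits) < density)
}
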