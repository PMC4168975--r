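#' Build a residue-pair training set from reference alignments
#'
#' One row per residue pair (all `n x m` pairs of every bundle pair): the
#' seven features, the target Calpha-Calpha distance measured in the
#' bound-ligand-superposed frame, and a binary match label (1 when the pair
#' belongs to the reference alignment).
#'
#' @param bundle_pairs List of lists with elements `a`, `b`
#'   (`pocket_bundle`s), optionally `reference` (a `pocket_alignment`;
#'   computed from bound ligands when absent), and optional metadata
#'   `pair_id`, `ligand_group`.
#' @return Tibble with columns `pair_id`, `ligand_group`, `i`, `j`, the
#'   seven feature columns, `target_dist` (Angstrom), `match` (0/1).
#' @export
make_training_set <- function(bundle_pairs) {
  rows <- list()
  for (k in seq_along(bundle_pairs)) {
    bp <- bundle_pairs[[k]]
    ref <- bp$reference %||% tryCatch(reference_alignment(bp$a, bp$b),
                                      error = function(e) NULL)
    if (is.null(ref)) {
      warn(sprintf("pair %s skipped: no reference alignment",
                   bp$pair_id %||% k))
      next
    }
    pf <- bp$features %||% compute_pair_features(bp$a, bp$b)
    # actual distances in the ligand-superposed frame
    amap <- mcs_atom_map(bp$a$bound_ligand, bp$b$bound_ligand)
    sup <- superpose_ligands(bp$a$bound_ligand, bp$b$bound_ligand, amap)
    ca_a <- pocket_ca(bp$a$pocket)
    ca_b <- t(sup$transform$rotation %*% t(pocket_ca(bp$b$pocket)) +
                sup$transform$translation)
    dmat <- .cross_dist(ca_a, ca_b)
    d <- pf
    d$target_dist <- dmat[cbind(pf$i, pf$j)]
    d$match <- as.integer(paste(pf$i, pf$j) %in% paste(ref$i, ref$j))
    d$pair_id <- bp$pair_id %||% as.character(k)
    d$ligand_group <- bp$ligand_group %||% NA_character_
    rows[[length(rows) + 1]] <- as_tibble(d)
  }
  if (!length(rows)) abort("no usable bundle pairs")
  out <- bind_rows(rows)
  out[, c("pair_id", "ligand_group", "i", "j", FEATURE_COLS,
          "target_dist", "match")]
}

#' Train the inter-residue distance (or match) model
#'
#' Epsilon support vector regression (or probability-calibrated C
#' classification) with an RBF kernel on the seven z-scored residue-pair
#' features. Regression targets are Calpha-Calpha distances in Angstrom;
#' classification labels mark reference-aligned pairs, with negatives
#' capped at `neg_cap` times the positives per bundle pair (seeded
#' subsampling) to tame the class imbalance.
#'
#' @param data Training tibble from [make_training_set()] (needs the seven
#'   feature columns plus `target_dist` or `match`).
#' @param kind `"regression"` or `"classification"`.
#' @param seed Integer seed; training is reproducible given it.
#' @param cost,gamma,epsilon libSVM hyperparameters (RBF kernel); `gamma`
#'   defaults to 1/7.
#' @param neg_cap Negative:positive cap for classification.
#' @return A `distance_model`: the fitted SVM plus frozen feature scaling
#'   and training metadata.
#' @export
train_distance_model <- function(data, kind = c("regression",
                                                "classification"),
                                 seed = 1, cost = 10, gamma = 1 / 7,
                                 epsilon = 0.1, neg_cap = 5) {
  kind <- match.arg(kind)
  if (nrow(data) < 50) abort("need at least 50 training rows")
  X <- as.matrix(data[, FEATURE_COLS])
  if (!all(is.finite(X))) abort("non-finite feature values")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (kind == "classification") {
    y <- data$match
    if (length(unique(y)) < 2) abort("both classes must be present")
    keep <- unlist(lapply(split(seq_len(nrow(data)), data$pair_id),
                          function(idx) {
      pos <- idx[y[idx] == 1]; neg <- idx[y[idx] == 0]
      if (length(neg) > neg_cap * max(length(pos), 1))
        neg <- sort(sample(neg, neg_cap * max(length(pos), 1)))
      c(pos, neg)
    }), use.names = FALSE)
    keep <- sort(keep)
    X <- X[keep, , drop = FALSE]
    yf <- factor(y[keep], levels = c(0, 1))
  } else {
    y <- data$target_dist
    if (sd(y) == 0) abort("degenerate targets: all equal")
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  fit <- if (kind == "regression") {
    e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
               cost = cost, gamma = gamma, epsilon = epsilon, scale = FALSE)
  } else {
    e1071::svm(Xs, yf, type = "C-classification", kernel = "radial",
               cost = cost, gamma = gamma, probability = TRUE,
               scale = FALSE)
  }
  structure(list(kind = kind, fit = fit, center = ctr, scale = scl,
                 meta = list(seed = seed, cost = cost, gamma = gamma,
                             epsilon = epsilon, n_rows = nrow(Xs),
                             ligand_groups =
                               sort(unique(stats::na.omit(
                                 data$ligand_group %||% character(0)))),
                             version = "1")),
            class = "distance_model")
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf("<distance_model> %s, %d training rows, %d SVs\n",
              x$kind, x$meta$n_rows, nrow(x$fit$SV)))
  invisible(x)
}

#' @describeIn train_distance_model hyperparameters and metadata as a
#'   one-row tibble.
#' @param x A `distance_model`.
#' @param ... Unused.
#' @method glance distance_model
#' @export
glance.distance_model <- function(x, ...) {
  tibble(kind = x$kind, n_rows = x$meta$n_rows,
         n_support = nrow(x$fit$SV), cost = x$meta$cost,
         gamma = x$meta$gamma, epsilon = x$meta$epsilon,
         seed = x$meta$seed)
}

.model_predict <- function(model, features, prob = FALSE) {
  X <- as.matrix(features[, FEATURE_COLS])
  if (ncol(X) != length(model$center)) abort("feature dimension mismatch")
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  if (prob) {
    pr <- predict(model$fit, Xs, probability = TRUE)
    attr(pr, "probabilities")[, "1"]
  } else {
    as.numeric(predict(model$fit, Xs))
  }
}

#' Predicted Calpha-Calpha distance matrix
#'
#' @param model A regression `distance_model`.
#' @param pf A `pair_features` object.
#' @return `n x m` matrix of predicted distances (Angstrom, clipped at 0).
#' @export
predict_distance_matrix <- function(model, pf) {
  if (model$kind != "regression") abort("model is not a regression model")
  matrix(pmax(.model_predict(model, pf), 0), attr(pf, "n"), attr(pf, "m"))
}

#' Predicted match-probability matrix
#'
#' @param model A classification `distance_model`.
#' @param pf A `pair_features` object.
#' @return `n x m` matrix of alignment probabilities.
#' @export
predict_match_matrix <- function(model, pf) {
  if (model$kind != "classification") abort("model is not a classifier")
  matrix(.model_predict(model, pf, prob = TRUE),
         attr(pf, "n"), attr(pf, "m"))
}

#' Leave-one-ligand-group-out cross-validation
#'
#' Partitions the residue-pair rows by binding-ligand group; each fold
#' trains on the remaining groups and scores the held-out one. Regression
#' folds report the Pearson correlation (PCC), mean squared error and root
#' mean squared error between predicted and actual distances;
#' classification folds report ROC AUC.
#'
#' @param data Training tibble from [make_training_set()] with a non-NA
#'   `ligand_group` column (at least 2 groups).
#' @param kind `"regression"` or `"classification"`.
#' @param seed Integer seed.
#' @param ... Passed to [train_distance_model()].
#' @return A `crossval_report`: list with `folds` (per-group tibble) and
#'   `pooled` (over all held-out predictions).
#' @export
crossvalidate_by_ligand <- function(data, kind = c("regression",
                                                   "classification"),
                                    seed = 1, ...) {
  kind <- match.arg(kind)
  groups <- sort(unique(data$ligand_group))
  groups <- groups[!is.na(groups)]
  if (length(groups) < 2) abort("need at least 2 ligand groups")
  fold_rows <- list()
  pooled_pred <- pooled_obs <- numeric(0)
  for (g in groups) {
    test <- data[data$ligand_group == g, , drop = FALSE]
    train <- data[data$ligand_group != g, , drop = FALSE]
    if (nrow(test) == 0) {
      warn(sprintf("ligand group %s has no pairs; skipped", g))
      next
    }
    stopifnot(!any(test$pair_id %in% train$pair_id))  # leakage guard
    model <- train_distance_model(train, kind = kind, seed = seed, ...)
    if (kind == "regression") {
      pred <- pmax(.model_predict(model, test), 0)
      obs <- test$target_dist
      fold_rows[[g]] <- tibble(ligand_group = g, n = nrow(test),
                               pcc = cor(pred, obs),
                               mse = mean((pred - obs)^2),
                               rmse = sqrt(mean((pred - obs)^2)))
    } else {
      pred <- .model_predict(model, test, prob = TRUE)
      obs <- test$match
      auc <- if (length(unique(obs)) == 2)
        roc_auc(pred, obs)$auc else NA_real_
      fold_rows[[g]] <- tibble(ligand_group = g, n = nrow(test), auc = auc)
    }
    pooled_pred <- c(pooled_pred, pred)
    pooled_obs <- c(pooled_obs, if (kind == "regression") obs else obs)
  }
  folds <- bind_rows(fold_rows)
  pooled <- if (kind == "regression") {
    tibble(pcc = cor(pooled_pred, pooled_obs),
           mse = mean((pooled_pred - pooled_obs)^2),
           rmse = sqrt(mean((pooled_pred - pooled_obs)^2)))
  } else {
    tibble(auc = roc_auc(pooled_pred, pooled_obs)$auc)
  }
  structure(list(folds = folds, pooled = pooled, kind = kind),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report> %s, %d folds\n", x$kind, nrow(x$folds)))
  print(x$folds)
  cat("pooled:\n"); print(x$pooled)
  invisible(x)
}

#' @describeIn crossvalidate_by_ligand per-fold metrics.
#' @param x A `crossval_report`.
#' @param ... Unused.
#' @method tidy crossval_report
#' @export
tidy.crossval_report <- function(x, ...) x$folds

#' @describeIn crossvalidate_by_ligand pooled metrics (one row).
#' @method glance crossval_report
#' @export
glance.crossval_report <- function(x, ...) x$pooled

#' Serialize / restore a distance model
#'
#' Models are stored as a single versioned RDS file.
#'
#' @param model A `distance_model` (or similarity classifier).
#' @param path Output file.
#' @return `path` invisibly; `read_distance_model()` returns the model.
#' @export
write_distance_model <- function(model, path) {
  saveRDS(list(format = "pocketalign_model", version = 1, model = model),
          path)
  invisible(path)
}

#' @rdname write_distance_model
#' @export
read_distance_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pocketalign_model"))
    abort("not a pocketalign model file")
  obj$model
}
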