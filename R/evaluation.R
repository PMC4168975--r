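#' Matthews correlation coefficient between two alignments
#'
#' Compares a predicted residue correspondence against the reference over
#' the full `n x m` residue-pair universe: TP = pairs in both alignments,
#' FP = predicted only, FN = reference only, TN = in neither. Returns 0
#' when any factor of the denominator is 0.
#'
#' @param predicted,reference `pocket_alignment`s over the same pocket
#'   pair.
#' @return MCC in `[-1, 1]`.
#' @export
alignment_mcc <- function(predicted, reference) {
  n <- attr(predicted, "n"); m <- attr(predicted, "m")
  if (!is.na(attr(reference, "n")) &&
      (attr(reference, "n") != n || attr(reference, "m") != m))
    abort("alignments refer to different pocket pairs")
  pk <- paste(predicted$i, predicted$j)
  rk <- paste(reference$i, reference$j)
  tp <- length(intersect(pk, rk))
  fp <- length(setdiff(pk, rk))
  fn <- length(setdiff(rk, pk))
  tn <- as.numeric(n) * m - tp - fp - fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den <= 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (ties included simultaneously)
#' with trapezoidal area, as implemented in pROC.
#'
#' @param scores Numeric similarity scores (larger = more likely positive).
#' @param labels Binary labels (1/0, or a 2-level factor/logical).
#' @return List with `curve` (tibble `fpr`, `tpr`, `threshold`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary (0/1)")
  if (length(unique(labels)) < 2) abort("both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  curve <- tibble(fpr = rev(1 - r$specificities),
                  tpr = rev(r$sensitivities),
                  threshold = rev(r$thresholds))
  list(curve = curve, auc = as.numeric(pROC::auc(r)))
}

#' Global sequence identity baseline
#'
#' Needleman-Wunsch global alignment scored by identity (match 1,
#' mismatch 0) with affine gap penalties (open 1, extend 0.5, subtracted);
#' identity is the fraction of identical aligned positions over the full
#' alignment length (gaps included). Non-standard characters become `X`
#' and never count as identities.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return Identity in `[0, 1]`.
#' @export
sequence_identity <- function(seq_a, seq_b, gap_open = 1, gap_extend = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("sequences must be non-empty")
  clean <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    ch[!ch %in% AA20] <- "X"
    paste(ch, collapse = "")
  }
  alph <- c(AA20, "X")
  sub <- matrix(0, 21, 21, dimnames = list(alph, alph))
  diag(sub) <- 1
  sub["X", "X"] <- 0  # unknowns never count as identical
  pa <- Biostrings::pairwiseAlignment(
    clean(seq_a), clean(seq_b), type = "global", substitutionMatrix = sub,
    gapOpening = gap_open, gapExtension = gap_extend)
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  sum(a == b & a != "-" & a != "X") / length(a)
}

#' Benchmark a labeled set of pocket pairs
#'
#' The full evaluation protocol on a labeled pair manifest: residue-pair
#' features and similarity records are computed once per pair; the distance
#' models and similarity classifier are then trained and applied under
#' leave-one-ligand-group-out cross-validation, so every pair is scored by
#' models that never saw its ligand group. The report collects, per pair,
#' the similarity probability, alignment MCC against the reference (where
#' bound ligands exist) and ligand RMSD, plus pooled ROC/AUC and
#' threshold-fraction summaries.
#'
#' @param pairs Tibble with list-columns `bundle_a`, `bundle_b`, integer
#'   `label` (1 positive / 0 negative), and `ligand_group`; see
#'   [make_benchmark()]. An optional `correspondence` list-column (planted
#'   maps) is used for MCC when present, otherwise references are rebuilt
#'   from bound ligands.
#' @param library Screening fingerprint library.
#' @param seed Integer seed for model training.
#' @param rmsd_thresholds Ligand-RMSD cutoffs reported as fractions.
#' @param svc Also train the match classifier and fill `f_svc` (default
#'   TRUE).
#' @param progress Print per-stage progress.
#' @return A `benchmark_report`: list with `pairs` (per-pair tibble),
#'   `auc`, `roc` (curve tibble), `mean_mcc_positives`,
#'   `rmsd_fractions`, and `cv` metadata.
#' @export
benchmark <- function(pairs, library = synthetic_screening_library(),
                      seed = 1, rmsd_thresholds = c(2, 5), svc = TRUE,
                      progress = FALSE) {
  stopifnot(all(c("bundle_a", "bundle_b", "label", "ligand_group")
                %in% names(pairs)))
  keep <- !is.na(pairs$label)
  if (any(!keep)) warn(sprintf("%d unlabeled pair(s) excluded", sum(!keep)))
  pairs <- pairs[keep, ]
  np <- nrow(pairs)
  if (!"pair_id" %in% names(pairs)) pairs$pair_id <- as.character(seq_len(np))

  say <- function(...) if (progress) message(sprintf(...))
  say("computing features for %d pairs", np)
  feats <- vector("list", np)
  refs <- vector("list", np)
  chem <- vector("list", np)  # model-free features, shared across folds
  for (k in seq_len(np)) {
    a <- pairs$bundle_a[[k]]; b <- pairs$bundle_b[[k]]
    feats[[k]] <- compute_pair_features(a, b)
    refs[[k]] <- tryCatch(reference_alignment(a, b), error = function(e) NULL)
    chem[[k]] <- list(
      f_tau = chemical_correlation(a, b, library),
      f_pcf = physicochemical_feature(a$pocket$props, b$pocket$props),
      f_pms = pms_score(a$pocket, b$pocket))
  }

  # residue-pair training rows come from positives with references
  say("building residue-pair training rows")
  train_idx <- which(pairs$label == 1 & !vapply(refs, is.null, logical(1)))
  bp <- lapply(train_idx, function(k) {
    list(a = pairs$bundle_a[[k]], b = pairs$bundle_b[[k]],
         reference = refs[[k]], features = feats[[k]],
         pair_id = pairs$pair_id[k], ligand_group = pairs$ligand_group[k])
  })
  ts <- make_training_set(bp)

  groups <- sort(unique(pairs$ligand_group))
  say("cross-validating over %d ligand groups", length(groups))
  out <- pairs[, c("pair_id", "ligand_group", "label")]
  out$probability <- NA_real_
  for (col in SIM_FEATURES) out[[col]] <- NA_real_
  out$mcc <- NA_real_
  out$lig_rmsd <- NA_real_
  out$delta_rmsd <- NA_real_

  for (g in groups) {
    hold <- which(pairs$ligand_group == g)
    ts_train <- ts[ts$ligand_group != g, , drop = FALSE]
    dm <- train_distance_model(ts_train, "regression", seed = seed)
    cm <- if (svc) train_distance_model(ts_train, "classification",
                                        seed = seed)
    # similarity records for every pair, under this fold's models; the
    # model-free features are reused from the precomputed cache
    alns <- vector("list", np)
    recs <- lapply(seq_len(np), function(k) {
      pf <- feats[[k]]
      aln <- align_pockets(pairs$bundle_a[[k]], pairs$bundle_b[[k]],
                           model = dm, features = pf)
      alns[[k]] <<- aln
      svr_m <- predict_distance_matrix(dm, pf)
      svc_m <- if (!is.null(cm)) predict_match_matrix(cm, pf)
      avg <- average_model_scores(aln, svr_m, svc_m)
      tibble(f_rms = attr(aln, "pocket_rmsd"), f_svr = avg$f_svr,
             f_svc = avg$f_svc, f_tau = chem[[k]]$f_tau,
             f_pcf = chem[[k]]$f_pcf, f_pms = chem[[k]]$f_pms)
    })
    rec_tbl <- bind_rows(recs)
    cls <- train_similarity_classifier(rec_tbl[-hold, , drop = FALSE],
                                       pairs$label[-hold], seed = seed)
    prob <- classify_similarity(cls, rec_tbl[hold, , drop = FALSE])
    out$probability[hold] <- prob
    for (col in SIM_FEATURES) out[[col]][hold] <- rec_tbl[[col]][hold]
    for (k in hold) {
      aln <- alns[[k]]
      if (!is.null(refs[[k]]))
        out$mcc[k] <- alignment_mcc(aln, refs[[k]])
      a <- pairs$bundle_a[[k]]; b <- pairs$bundle_b[[k]]
      if (!is.null(a$bound_ligand) && !is.null(b$bound_ligand)) {
        lr <- tryCatch(ligand_rmsd(aln, a$bound_ligand, b$bound_ligand),
                       error = function(e) NULL)
        if (!is.null(lr)) {
          out$lig_rmsd[k] <- lr$rmsd
          out$delta_rmsd[k] <- lr$delta_rmsd
        }
      }
    }
    say("fold %s done", g)
  }

  roc <- roc_auc(out$probability, out$label)
  pos <- out[out$label == 1, ]
  fr <- vapply(rmsd_thresholds, function(th)
    mean(pos$lig_rmsd < th, na.rm = TRUE), numeric(1))
  structure(list(pairs = out, auc = roc$auc, roc = roc$curve,
                 mean_mcc_positives = mean(pos$mcc, na.rm = TRUE),
                 rmsd_fractions = setNames(fr, paste0("under_",
                                                      rmsd_thresholds, "A")),
                 cv = list(groups = groups, seed = seed)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d pairs, AUC %.3f, mean MCC(+) %.3f\n",
              nrow(x$pairs), x$auc, x$mean_mcc_positives))
  cat("ligand RMSD fractions:",
      paste(sprintf("%s=%.2f", names(x$rmsd_fractions), x$rmsd_fractions),
            collapse = " "), "\n")
  invisible(x)
}

#' @describeIn benchmark per-pair results.
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @method tidy benchmark_report
#' @export
tidy.benchmark_report <- function(x, ...) x$pairs

#' @describeIn benchmark one-row summary.
#' @method glance benchmark_report
#' @export
glance.benchmark_report <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), auc = x$auc,
         mean_mcc_positives = x$mean_mcc_positives,
         !!!as.list(x$rmsd_fractions))
}
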