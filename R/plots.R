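#' Plot a residue-pair feature matrix
#'
#' Tile map of one of the seven residue-pair scores over the `n x m` pair
#' grid.
#'
#' @param object A `pair_features` object.
#' @param feature Which score column to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_features
#' @export
autoplot.pair_features <- function(object, feature = "s_lig", ...) {
  stopifnot(feature %in% FEATURE_COLS)
  ggplot(object, aes(x = .data$j, y = .data$i,
                     fill = .data[[feature]])) +
    geom_tile() +
    scale_fill_viridis_c(name = feature) +
    coord_equal() +
    labs(x = "residue j (pocket B)", y = "residue i (pocket A)",
         title = "Residue-pair score matrix") +
    theme_minimal()
}

#' Plot a pocket alignment over its distance matrix
#'
#' Tile map of the cost (predicted distance) matrix with the selected
#' assignment marked; mirrors the usual way sequence order-independent
#' alignments are inspected.
#'
#' @param object A `pocket_alignment`.
#' @param cost_matrix Optional `n x m` matrix to use as background; when
#'   absent only the selected pairs are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pocket_alignment
#' @export
autoplot.pocket_alignment <- function(object, cost_matrix = NULL, ...) {
  pairs <- tidy(object)
  p <- if (!is.null(cost_matrix)) {
    grid <- tibble(i = rep(seq_len(nrow(cost_matrix)),
                           times = ncol(cost_matrix)),
                   j = rep(seq_len(ncol(cost_matrix)),
                           each = nrow(cost_matrix)),
                   cost = as.numeric(cost_matrix))
    ggplot(grid, aes(x = .data$j, y = .data$i)) +
      geom_tile(aes(fill = .data$cost)) +
      scale_fill_viridis_c(name = "distance (A)")
  } else {
    ggplot(pairs, aes(x = .data$j, y = .data$i))
  }
  p +
    geom_point(data = pairs, aes(x = .data$j, y = .data$i),
               colour = "green3", size = 2) +
    coord_equal() +
    labs(x = "residue j (pocket B)", y = "residue i (pocket A)",
         title = sprintf("Pocket alignment (RMSD %.2f A)",
                         attr(object, "pocket_rmsd"))) +
    theme_minimal()
}

#' Plot a cross-validation report
#'
#' Per-ligand-group fold metric (PCC for regression, AUC for
#' classification).
#'
#' @param object A `crossval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crossval_report
#' @export
autoplot.crossval_report <- function(object, ...) {
  metric <- if (object$kind == "regression") "pcc" else "auc"
  ggplot(object$folds, aes(x = .data$ligand_group, y = .data[[metric]])) +
    geom_col(fill = "steelblue") +
    labs(x = "held-out ligand group", y = toupper(metric),
         title = "Leave-one-ligand-group-out cross-validation") +
    theme_minimal()
}

#' Plot a benchmark ROC curve
#'
#' @param object A `benchmark_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot benchmark_report
#' @export
autoplot.benchmark_report <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    geom_line(colour = "firebrick") +
    coord_equal() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("Similar-pocket detection (AUC %.3f)", object$auc)) +
    theme_minimal()
}
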