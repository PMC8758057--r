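#' Random-forest variable importance for phenotype discrimination
#'
#' Fits a random forest predicting cluster labels from the feature
#' matrix and reports, per feature, the permutation importance (mean
#' decrease in out-of-bag accuracy, MDA) and the mean decrease in Gini
#' impurity.
#'
#' @param fm A [standardize_features()] result or numeric matrix.
#' @param labels Cluster labels (one per row of \code{fm}).
#' @param n_trees Number of trees (default 500).
#' @param features_per_split Features sampled per split; default
#'   \code{floor(sqrt(p))}.
#' @param seed Integer seed.
#' @return Object of class \code{importance_report}: data.frame
#'   \code{importance} (columns \code{feature},
#'   \code{mean_decrease_accuracy}, \code{mean_decrease_gini}, sorted by
#'   MDA), plus the forest settings.
#' @export
rf_importance <- function(fm, labels, n_trees = 500,
                          features_per_split = NULL, seed) {
  if (missing(seed)) stop("an integer seed is required")
  x <- .fm_matrix(fm)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  stopifnot(n_trees >= 1, length(labels) == nrow(x))
  if (is.null(features_per_split)) features_per_split <- max(1, floor(sqrt(ncol(x))))
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = factor(labels),
                                   ntree = n_trees,
                                   mtry = features_per_split,
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  out <- data.frame(feature = rownames(imp),
                    mean_decrease_accuracy = imp[, "MeanDecreaseAccuracy"],
                    mean_decrease_gini = imp[, "MeanDecreaseGini"],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_decrease_accuracy), ]
  rownames(out) <- NULL
  structure(list(importance = out, n_trees = n_trees,
                 features_per_split = features_per_split,
                 seed = as.integer(seed)),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Random-forest importance (", x$n_trees, "trees )\n")
  print(utils::head(x$importance, 10))
  invisible(x)
}

#' Per-item phenotype z-score matrix
#'
#' For each item and phenotype group, the group mean expressed as a
#' z-score relative to the overall cohort: (group mean - overall mean) /
#' overall SD. Entries for zero-variance items are returned as NA and
#' listed in the \code{flagged} attribute.
#'
#' @param fm_raw Data.frame/matrix of raw (untransformed) item values.
#' @param labels Group label per row (factor or character).
#' @return Matrix (items x groups) of z-scores, with attribute
#'   \code{flagged} naming zero-variance items.
#' @export
phenotype_z_matrix <- function(fm_raw, labels) {
  x <- as.matrix(fm_raw)
  groups <- sort(unique(as.character(labels)))
  if (length(groups) < 2) stop("need at least 2 groups")
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  z <- sapply(groups, function(g) {
    gm <- colMeans(x[labels == g, , drop = FALSE])
    (gm - mu) / sd
  })
  z[sd == 0, ] <- NA_real_
  rownames(z) <- colnames(x)
  attr(z, "flagged") <- colnames(x)[sd == 0]
  z
}

#' Assign top discriminatory items to phenotypes
#'
#' Takes the \code{top_n} features by mean decrease in accuracy and
#' assigns each to the phenotype group with the largest z-matrix entry
#' (ties to the earliest column, flagged).
#'
#' @param report An [rf_importance()] result.
#' @param zmatrix A [phenotype_z_matrix()] result.
#' @param top_n Number of top features to assign (default 20).
#' @return Named list (one element per group) of character item vectors,
#'   with attribute \code{ties} naming tied items.
#' @export
select_discriminatory_items <- function(report, zmatrix, top_n = 20) {
  imp <- report$importance
  if (top_n > nrow(imp)) stop("top_n exceeds the number of features")
  top <- imp$feature[seq_len(top_n)]
  groups <- colnames(zmatrix)
  assigned <- stats::setNames(vector("list", length(groups)), groups)
  ties <- character(0)
  for (f in top) {
    zrow <- zmatrix[f, ]
    if (all(is.na(zrow))) next
    best <- which(zrow == max(zrow, na.rm = TRUE))
    if (length(best) > 1) ties <- c(ties, f)
    g <- groups[min(best)]
    assigned[[g]] <- c(assigned[[g]], f)
  }
  attr(assigned, "ties") <- ties
  assigned
}
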