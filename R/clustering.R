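#' Standardize a raw feature table for clustering
#'
#' Applies \code{log1p} to configured columns, then z-scores every
#' continuous column; binary columns pass through unchanged as 0/1. The
#' transform parameters (per-column mean/SD after the log step) are
#' stored so the identical transform can be re-applied to new data.
#'
#' @param raw Data.frame or matrix of numeric features (rows = subjects).
#' @param binary_cols Character vector of columns to treat as binary
#'   (default: the battery's binary items present in \code{raw}).
#' @param log_cols Character vector of columns to log1p-transform before
#'   z-scoring (default none).
#' @param params Optional parameters from a previous call, to re-apply
#'   the same transform to new data.
#' @return Object of class \code{feature_matrix}: list with \code{x}
#'   (standardized numeric matrix), \code{binary_cols}, \code{log_cols}
#'   and \code{params} (data.frame of per-column center/scale).
#' @export
standardize_features <- function(raw, binary_cols = NULL, log_cols = character(0),
                                 params = NULL) {
  x <- as.matrix(raw)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature table contains missing values")
  if (is.null(binary_cols)) {
    b <- battery_items()
    binary_cols <- intersect(b$item_id[b$kind == "binary"], colnames(x))
  }
  cont <- setdiff(colnames(x), binary_cols)
  bad_bin <- binary_cols[!vapply(binary_cols, function(cn)
    all(x[, cn] %in% c(0, 1)), logical(1))]
  if (length(bad_bin)) stop("binary column(s) with values outside {0,1}: ",
                            paste(bad_bin, collapse = ", "))
  if (length(log_cols)) {
    if (any(x[, log_cols, drop = FALSE] < 0)) {
      stop("log-transform columns must be non-negative")
    }
    x[, log_cols] <- log1p(x[, log_cols, drop = FALSE])
  }
  if (is.null(params)) {
    center <- scale_ <- stats::setNames(rep(NA_real_, ncol(x)), colnames(x))
    center[cont] <- colMeans(x[, cont, drop = FALSE])
    scale_[cont] <- apply(x[, cont, drop = FALSE], 2, stats::sd)
    degenerate <- cont[!is.na(scale_[cont]) & scale_[cont] == 0]
    if (length(degenerate)) {
      stop("zero-variance continuous column(s): ",
           paste(degenerate, collapse = ", "))
    }
    params <- data.frame(column = colnames(x), center = center,
                         scale = scale_, stringsAsFactors = FALSE)
  }
  rownames(params) <- params$column
  for (cn in cont) {
    x[, cn] <- (x[, cn] - params[cn, "center"]) / params[cn, "scale"]
  }
  structure(list(x = x, binary_cols = binary_cols, log_cols = log_cols,
                 params = params), class = "feature_matrix")
}

# Internal: accept either a feature_matrix or a plain numeric matrix.
.fm_matrix <- function(fm) {
  if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)
}

#' Ward hierarchical clustering dendrogram
#'
#' Agglomerative clustering by Ward's minimum-variance criterion. Merge
#' heights equal the increase in total within-cluster sum of squares, so
#' two singletons a, b merge at \eqn{\|a-b\|^2/2}. Implemented via
#' \code{stats::hclust(method = "ward.D")} on squared-Euclidean/2
#' dissimilarities, which propagates exactly these merge costs through
#' the Lance-Williams update.
#'
#' @param fm A [standardize_features()] result or numeric matrix.
#' @return An \code{hclust} object (merge heights as above).
#' @export
ward_dendrogram <- function(fm) {
  x <- .fm_matrix(fm)
  if (nrow(x) < 2) stop("need at least 2 subjects")
  d2 <- stats::dist(x)^2 / 2
  stats::hclust(d2, method = "ward.D")
}

#' Cut a dendrogram into k groups
#'
#' @param tree An \code{hclust} object from [ward_dendrogram()].
#' @param k Number of groups, between 1 and the number of leaves.
#' @return Integer labels in \code{1:k}, numbered by order of first
#'   appearance in the subject sequence.
#' @export
cut_dendrogram <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  raw <- stats::cutree(tree, k = k)
  # renumber by first appearance
  first <- unique(raw)
  as.integer(match(raw, first))
}

# Internal: k-means++ initial centers (Arthur & Vassilvitskii seeding).
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (sum(d2) == 0) {
        idx <- sample.int(n, 1)
      } else {
        idx <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      nd <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
  }
  centers
}

# Internal: squared distances of rows of x to rows of centers (n x k).
.dist2 <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * x %*% t(centers)
}

# Internal: one Lloyd run from given centers. Assignment ties go to the
# lowest cluster index (max.col with ties.method = "first" on negated
# distances); an emptied cluster is re-seeded at the point farthest from
# its nearest centroid.
.lloyd <- function(x, centers, max_iter = 300, tol = 1e-6) {
  k <- nrow(centers)
  labels <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(x, centers)
    labels <- max.col(-d2, ties.method = "first")
    for (j in which(tabulate(labels, k) == 0)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), labels)])
      centers[j, ] <- x[far, ]
      labels[far] <- j
    }
    new_centers <- centers
    for (j in seq_len(k)) {
      new_centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
    moved <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (moved < tol) break
  }
  d2 <- .dist2(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  wss <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(centers = centers, labels = labels, wss = wss, iterations = it)
}

#' K-means clustering with k-means++ starts
#'
#' Lloyd's algorithm from k-means++ initializations, keeping the best of
#' \code{n_restarts} runs by within-cluster sum of squares (WSS).
#' Deterministic given \code{(fm, k, seed)}. Nearest-centroid ties go to
#' the lowest cluster index; a cluster emptied during iteration is
#' re-seeded at the point farthest from its assigned centroid.
#'
#' @param fm A [standardize_features()] result or numeric matrix.
#' @param k Number of clusters (\code{k <= n}).
#' @param seed Integer seed (required).
#' @param n_restarts Number of k-means++ restarts (default 50).
#' @param max_iter,tol Lloyd iteration cap (default 300) and convergence
#'   tolerance on centroid movement (default 1e-6).
#' @return Object of class \code{phenotype_km}: \code{k},
#'   \code{centroids}, \code{labels}, \code{wss}, \code{seed},
#'   \code{n_restarts}.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' km <- kmeans_fit(x, 2, seed = 1)
#' table(km$labels)
#' @export
kmeans_fit <- function(fm, k, seed, n_restarts = 50, max_iter = 300,
                       tol = 1e-6) {
  if (missing(seed)) stop("an integer seed is required")
  x <- .fm_matrix(fm)
  n <- nrow(x)
  if (k > n) stop("k (", k, ") exceeds the number of subjects (", n, ")")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .lloyd(x, .kmeanspp_init(x, k), max_iter, tol)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  structure(list(k = k, centroids = best$centers, labels = best$labels,
                 wss = best$wss, seed = as.integer(seed),
                 n_restarts = n_restarts),
            class = "phenotype_km")
}

#' @export
print.phenotype_km <- function(x, ...) {
  cat("K-means phenotype model: k =", x$k, "\n")
  cat("Cluster sizes:", paste(tabulate(x$labels, x$k), collapse = "/"), "\n")
  cat("Total within-cluster SS:", format(x$wss, digits = 6), "\n")
  invisible(x)
}

#' Assign new subjects to fitted K-means clusters
#' @param object A \code{phenotype_km} model.
#' @param newdata Numeric matrix or \code{feature_matrix} in the same
#'   standardized space as the training data.
#' @param ... Unused.
#' @return Integer cluster labels.
#' @export
predict.phenotype_km <- function(object, newdata, ...) {
  d2 <- .dist2(.fm_matrix(newdata), object$centroids)
  max.col(-d2, ties.method = "first")
}

#' Within-cluster sum-of-squares curve and elbow selection
#'
#' \code{wss_curve()} fits K-means for each k and records the best WSS;
#' \code{suggest_k()} picks the elbow as the k with the largest positive
#' curvature (maximum second forward difference of the WSS curve).
#'
#' @inheritParams kmeans_fit
#' @param k_max Largest k to evaluate.
#' @return \code{wss_curve()}: data.frame with columns \code{k},
#'   \code{wss}. \code{suggest_k()}: a single integer k.
#' @export
wss_curve <- function(fm, k_max = 8, seed, n_restarts = 50) {
  if (missing(seed)) stop("an integer seed is required")
  x <- .fm_matrix(fm)
  if (k_max > nrow(x)) stop("k_max exceeds the number of subjects")
  wss <- vapply(seq_len(k_max), function(k) {
    kmeans_fit(x, k, seed = seed + k, n_restarts = n_restarts)$wss
  }, numeric(1))
  data.frame(k = seq_len(k_max), wss = wss)
}

#' @rdname wss_curve
#' @param curve A data.frame from \code{wss_curve()}.
#' @export
suggest_k <- function(curve) {
  stopifnot(nrow(curve) >= 3)
  w <- curve$wss[order(curve$k)]
  kk <- sort(curve$k)
  d2 <- w[seq_len(length(w) - 2) + 2] - 2 * w[seq_len(length(w) - 2) + 1] +
    w[seq_len(length(w) - 2)]
  kk[which.max(d2) + 1L]
}

#' Principal coordinate analysis with Bray-Curtis dissimilarity
#'
#' Computes Bray-Curtis dissimilarities on non-negative (raw or
#' unit-scaled, not z-scored) features and embeds them by classical
#' multidimensional scaling. A pair of all-zero profiles has
#' dissimilarity 0.
#'
#' @param raw_nonneg Data.frame/matrix of non-negative features.
#' @param n_dims Number of coordinate axes to return (default 2).
#' @return List with \code{coordinates} (n x n_dims matrix) and
#'   \code{eigenvalues}.
#' @export
pcoa_bray <- function(raw_nonneg, n_dims = 2) {
  x <- as.matrix(raw_nonneg)
  if (any(x < 0)) stop("Bray-Curtis requires non-negative features")
  # vegdist warns on all-zero profile pairs; that case is defined here
  # as dissimilarity 0 (identical empty symptom profiles)
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  d[is.na(d)] <- 0
  mds <- stats::cmdscale(d, k = n_dims, eig = TRUE)
  list(coordinates = mds$points, eigenvalues = mds$eig)
}
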