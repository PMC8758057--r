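#' Self-organizing map configuration
#'
#' Defaults follow the analysis design: a 6 x 4 rectangular grid
#' (24 nodes), 1,000,000 online training iterations, initial learning
#' rate 0.1, Gaussian neighborhood. Learning rate and neighborhood
#' radius decay linearly over training, from (alpha0, max(rows, cols)/2)
#' to (~0, 0.5).
#'
#' @param rows,cols Grid dimensions (rows x cols nodes).
#' @param iterations Online training iterations.
#' @param alpha0 Initial learning rate in (0, 1].
#' @param seed Integer seed; mandatory.
#' @return List of class \code{som_config}.
#' @export
som_config <- function(rows = 4, cols = 6, iterations = 1e6, alpha0 = 0.1,
                       seed) {
  if (missing(seed)) stop("an integer seed is required")
  stopifnot(rows * cols >= 2, alpha0 > 0, alpha0 <= 1, iterations >= 1)
  structure(list(rows = rows, cols = cols, iterations = as.integer(iterations),
                 alpha0 = alpha0, neighborhood = "gaussian",
                 topology = "rectangular", seed = as.integer(seed)),
            class = "som_config")
}

# Internal: node grid coordinates (row, col) for a rows x cols grid,
# nodes numbered column-major.
.som_grid <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), times = cols),
        col = rep(seq_len(cols), each = rows))
}

#' Train a Kohonen self-organizing map
#'
#' Online SOM training: at each iteration a random subject is drawn, its
#' best-matching unit (BMU; nearest codebook by Euclidean distance) is
#' found, and every node w is updated by
#' \code{w <- w + alpha(t) * exp(-d_grid^2 / (2 sigma(t)^2)) * (x - w)},
#' where \code{d_grid} is the node's grid distance to the BMU. Codebooks
#' are initialised uniformly at random within each feature's observed
#' range. Deterministic given the config seed.
#'
#' @param fm Numeric matrix or [standardize_features()] result; features
#'   should be scaled to comparable ranges.
#' @param config A [som_config()].
#' @return Object of class \code{phenotype_som}: \code{codebook}
#'   (nodes x features), \code{grid} (node coordinates), \code{bins}
#'   (BMU per subject), \code{config}.
#' @export
train_som <- function(fm, config) {
  stopifnot(inherits(config, "som_config"))
  x <- .fm_matrix(fm)
  if (nrow(x) == 0) stop("empty training data")
  n <- nrow(x); p <- ncol(x)
  m <- config$rows * config$cols
  grid <- .som_grid(config$rows, config$cols)
  gd2 <- as.matrix(stats::dist(grid))^2
  set.seed(config$seed)
  # random-uniform init over each feature's observed range
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  cb <- matrix(stats::runif(m * p, rep(lo, each = m), rep(hi, each = m)),
               m, p)
  colnames(cb) <- colnames(x)
  draws <- sample.int(n, config$iterations, replace = TRUE)
  T_ <- config$iterations
  sigma0 <- max(config$rows, config$cols) / 2
  for (t in seq_len(T_)) {
    frac <- (t - 1) / T_
    alpha <- config$alpha0 * (1 - frac)
    sigma <- sigma0 + frac * (0.5 - sigma0)
    xi <- x[draws[t], ]
    diff <- sweep(cb, 2, xi, "-")
    bmu <- which.min(rowSums(diff^2))
    h <- exp(-gd2[bmu, ] / (2 * sigma^2))
    cb <- cb - (alpha * h) * diff
  }
  bins <- max.col(-.dist2(x, cb), ties.method = "first")
  rownames(cb) <- sprintf("node_%02d", seq_len(m))
  structure(list(codebook = cb, grid = grid, bins = bins, config = config),
            class = "phenotype_som")
}

#' @export
print.phenotype_som <- function(x, ...) {
  cat("Self-organizing map:", x$config$rows, "x", x$config$cols,
      "rectangular grid,", x$config$iterations, "iterations\n")
  cat("Occupied bins:", length(unique(x$bins)), "of", nrow(x$codebook), "\n")
  invisible(x)
}

#' Mean quantization error of a SOM
#'
#' Mean Euclidean distance of each subject to its best-matching unit.
#'
#' @param model A \code{phenotype_som}.
#' @param fm Data to evaluate on.
#' @return Numeric scalar.
#' @export
quantization_error <- function(model, fm) {
  x <- .fm_matrix(fm)
  d2 <- .dist2(x, model$codebook)
  mean(sqrt(pmax(0, apply(d2, 1, min))))
}

#' SOM convergence index
#'
#' Composite of embedding accuracy and topographic accuracy, each
#' weighted 1/2. Embedding accuracy is the fraction of features whose
#' codebook-weight distribution is statistically indistinguishable from
#' the data distribution (two-sample t test on means and F test on
#' variances, both at alpha = 0.05). Topographic accuracy is the
#' fraction of subjects whose best and second-best matching units are
#' grid neighbors (rectangular 4-neighborhood).
#'
#' @param model A trained \code{phenotype_som}.
#' @param fm The training data.
#' @param alpha Test level for the embedding component (default 0.05).
#' @return Value in [0, 1].
#' @export
convergence_index <- function(model, fm, alpha = 0.05) {
  if (!inherits(model, "phenotype_som")) stop("untrained or invalid model")
  x <- .fm_matrix(fm)
  cb <- model$codebook
  embedded <- vapply(seq_len(ncol(x)), function(j) {
    if (stats::sd(x[, j]) == 0 && stats::sd(cb[, j]) == 0) return(TRUE)
    if (stats::sd(x[, j]) == 0 || stats::sd(cb[, j]) == 0) return(FALSE)
    pm <- stats::t.test(cb[, j], x[, j])$p.value
    pv <- stats::var.test(cb[, j], x[, j])$p.value
    pm > alpha && pv > alpha
  }, logical(1))
  d2 <- .dist2(x, cb)
  topo <- vapply(seq_len(nrow(x)), function(i) {
    o <- order(d2[i, ])[1:2]
    sum(abs(model$grid[o[1], ] - model$grid[o[2], ])) == 1
  }, logical(1))
  0.5 * mean(embedded) + 0.5 * mean(topo)
}

#' Metacluster SOM nodes by Ward clustering of codebooks
#'
#' @param model A trained \code{phenotype_som}.
#' @param n_meta Number of metaclusters (1..number of nodes).
#' @return Integer metacluster label per node.
#' @export
metacluster_nodes <- function(model, n_meta) {
  m <- nrow(model$codebook)
  if (n_meta < 1 || n_meta > m) stop("n_meta must be in [1, ", m, "]")
  cut_dendrogram(ward_dendrogram(model$codebook), n_meta)
}

#' Mean codebook distance of each node to its grid neighbors
#'
#' For every node, the mean Euclidean distance in feature space to its
#' rectangular-grid neighbors (4 for interior nodes, 3 on edges, 2 at
#' corners). High values mark symptom patterns dissimilar from their
#' surroundings.
#'
#' @param model A trained \code{phenotype_som}.
#' @return Numeric vector, one value per node.
#' @export
neighbor_distance_map <- function(model) {
  g <- model$grid
  cb <- model$codebook
  vapply(seq_len(nrow(cb)), function(i) {
    nb <- which(abs(g[, "row"] - g[i, "row"]) +
                  abs(g[, "col"] - g[i, "col"]) == 1)
    mean(sqrt(rowSums((cb[nb, , drop = FALSE] -
                         matrix(cb[i, ], length(nb), ncol(cb),
                                byrow = TRUE))^2)))
  }, numeric(1))
}

#' Unit-scale the three phenotype measures over a cohort
#'
#' Min-max scales each of \code{bps_measure}, \code{nupp_measure},
#' \code{mfp_measure} to [0, 1] over the cohort, the input space used
#' for the SOM and for bin purity classification.
#'
#' @param scored A [score_cohort()] data.frame.
#' @return Numeric matrix (subjects x 3) with columns \code{bps},
#'   \code{nupp}, \code{mfp}.
#' @export
unit_scale_measures <- function(scored) {
  m <- as.matrix(scored[, c("bps_measure", "nupp_measure", "mfp_measure")])
  colnames(m) <- c("bps", "nupp", "mfp")
  apply(m, 2, function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(0, length(v)) else (v - r[1]) / diff(r)
  })
}

#' Classify SOM bins as control / pure phenotype / mixed / global pain
#'
#' Per bin, computes the subject count and the mean of each unit-scaled
#' phenotype measure (the pie-slice sizes), then labels the bin:
#' \code{control} if every mean is below \code{low_threshold};
#' \code{global} if every mean exceeds \code{high_threshold};
#' \code{pure-X} if measure X is at least \code{dominance_ratio} times
#' each other measure and at least \code{low_threshold}; otherwise
#' \code{mixed}. Empty bins are labeled \code{empty}.
#'
#' @param model A trained \code{phenotype_som}.
#' @param measures Unit-scaled measures from [unit_scale_measures()]
#'   (subjects x 3, values in [0, 1], columns bps/nupp/mfp).
#' @param low_threshold,high_threshold,dominance_ratio Purity rule
#'   parameters; defaults 0.25, 0.6, 2.
#' @return Data.frame, one row per node: \code{node}, \code{count},
#'   \code{bps}, \code{nupp}, \code{mfp}, \code{label}.
#' @export
classify_bins <- function(model, measures, low_threshold = 0.25,
                          high_threshold = 0.6, dominance_ratio = 2) {
  m <- as.matrix(measures)
  if (any(m < 0) || any(m > 1)) {
    stop("measures must be unit-scaled to [0, 1]; see unit_scale_measures()")
  }
  stopifnot(nrow(m) == length(model$bins), ncol(m) == 3)
  colnames(m) <- c("bps", "nupp", "mfp")
  nn <- nrow(model$codebook)
  out <- data.frame(node = seq_len(nn), count = tabulate(model$bins, nn),
                    bps = NA_real_, nupp = NA_real_, mfp = NA_real_,
                    label = "empty", stringsAsFactors = FALSE)
  pure_names <- c(bps = "pure-BPS", nupp = "pure-NUPP", mfp = "pure-MFP")
  for (i in seq_len(nn)) {
    if (out$count[i] == 0) next
    mu <- colMeans(m[model$bins == i, , drop = FALSE])
    out[i, c("bps", "nupp", "mfp")] <- mu
    lab <- if (all(mu < low_threshold)) "control"
      else if (all(mu > high_threshold)) "global"
      else {
        dom <- which(vapply(1:3, function(j)
          mu[j] >= low_threshold &&
            all(mu[j] >= dominance_ratio * mu[-j]), logical(1)))
        if (length(dom) == 1) pure_names[names(mu)[dom]] else "mixed"
      }
    out$label[i] <- unname(lab)
  }
  out
}
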