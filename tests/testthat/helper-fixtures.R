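# Shared fixtures and independent oracles, built in code at test time.

# Well-separated Gaussian blobs in `dim` dimensions.
make_blobs <- function(n_per, centers, sd = 0.2, dim = 2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(stats::rnorm(n_per * dim, sd = sd), n_per, dim) +
      matrix(centers[i, ], n_per, dim, byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# A complete valid response with every item at its scale floor.
floor_response <- function() {
  b <- battery_items()
  stats::setNames(as.numeric(b$scale_min), b$item_id)
}

# A complete valid response with every item at its scale ceiling.
ceiling_response <- function() {
  b <- battery_items()
  stats::setNames(as.numeric(b$scale_max), b$item_id)
}

# A random valid integer response, for property-style scoring tests.
random_response <- function() {
  b <- battery_items()
  stats::setNames(
    vapply(seq_len(nrow(b)), function(i)
      as.numeric(sample(b$scale_min[i]:b$scale_max[i], 1)), numeric(1)),
    b$item_id)
}

# Brute-force oracle: globally optimal 2-partition of rows of x by total
# within-cluster sum of squares (enumeration over all assignments).
best_two_partition <- function(x) {
  n <- nrow(x)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) { # fix point 1 in cluster 1; skip empty
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(lab)) < 2) next
    w <- sum(vapply(unique(lab), function(cl) {
      xs <- x[lab == cl, , drop = FALSE]
      sum(sweep(xs, 2, colMeans(xs))^2)
    }, numeric(1)))
    if (is.null(best) || w < best$wss) best <- list(labels = lab, wss = w)
  }
  best
}

# Direct Cohen's kappa from two label vectors (formula oracle).
kappa_oracle <- function(a, b) {
  k <- max(a, b)
  tab <- table(factor(a, levels = 1:k), factor(b, levels = 1:k))
  po <- sum(diag(tab)) / length(a)
  pe <- sum(rowSums(tab) * colSums(tab)) / length(a)^2
  (po - pe) / (1 - pe)
}

# Minimal SOM-like object for tests that exercise codebook geometry
# without training.
fake_som <- function(codebook, rows, cols, bins = integer(0)) {
  structure(list(codebook = codebook,
                 grid = bladderphen:::.som_grid(rows, cols),
                 bins = bins,
                 config = som_config(rows = rows, cols = cols,
                                     iterations = 1, seed = 1)),
            class = "phenotype_som")
}

# Expand responder-count cells into per-subject treatment records.
records_from_cells <- function(cells) {
  out <- list(); sid <- 0
  for (i in seq_len(nrow(cells))) {
    n <- cells$attempted[i]; r <- cells$responded[i]
    if (n == 0) next
    sid_new <- sid + seq_len(n)
    out[[i]] <- data.frame(subject_id = sprintf("T%04d", sid_new),
                           phenotype = cells$phenotype[i],
                           therapy = cells$therapy[i],
                           attempted = TRUE,
                           responded = seq_len(n) <= r,
                           stringsAsFactors = FALSE)
    sid <- sid + n
  }
  do.call(rbind, out)
}
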