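#' Align two cluster labelings by maximal Cohen's kappa
#'
#' Searches all k! permutations of the candidate labeling's cluster
#' numbers and returns the permutation maximizing unweighted Cohen's
#' kappa against the reference, together with that kappa. Used to undo
#' the arbitrary cluster numbering K-means assigns on a bootstrap
#' resample before agreement indices are computed.
#'
#' @param reference_labels,candidate_labels Integer labels in
#'   \code{1:k} over the same subjects (same length and order).
#' @return List with \code{permutation} (integer vector: candidate
#'   cluster j becomes \code{permutation[j]}), \code{aligned} (the
#'   relabeled candidate vector) and \code{kappa}.
#' @examples
#' align_labels(c(1, 1, 2, 2, 3, 3), c(2, 2, 3, 3, 1, 1))$kappa # 1
#' @export
align_labels <- function(reference_labels, candidate_labels) {
  if (length(reference_labels) != length(candidate_labels)) {
    stop("labelings cover different subject sets")
  }
  k <- max(reference_labels, candidate_labels)
  perms <- .permutations(k)
  best <- list(kappa = -Inf)
  for (p in perms) {
    aligned <- p[candidate_labels]
    kap <- .cohen_kappa(reference_labels, aligned, k)
    if (kap > best$kappa) {
      best <- list(permutation = p, aligned = aligned, kappa = kap)
    }
  }
  best
}

# Internal: all permutations of 1:k as a list.
.permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- .permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- as.integer(append(p, k, after = pos - 1L))
    }
  }
  out
}

# Internal: unweighted Cohen's kappa of two labelings on 1:k.
.cohen_kappa <- function(a, b, k) {
  n <- length(a)
  tab <- table(factor(a, levels = 1:k), factor(b, levels = 1:k))
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Per-cluster Rand agreement between reference and bootstrap membership
#'
#' Fraction of common subjects whose binary in/out status for one
#' cluster agrees between the reference clustering and the (aligned)
#' bootstrap clustering. Joint absence counts as agreement, which is why
#' a rarely-assigned cluster can show high Rand agreement driven purely
#' by absences.
#'
#' @param ref_membership,boot_membership Vectors of subject ids in the
#'   cluster under the reference and bootstrap clustering.
#' @param common_subjects Subject ids present in both samples.
#' @return Agreement fraction in [0, 1].
#' @export
cluster_rand <- function(ref_membership, boot_membership, common_subjects) {
  if (length(common_subjects) == 0) stop("empty common subject set")
  in_ref <- common_subjects %in% ref_membership
  in_boot <- common_subjects %in% boot_membership
  mean(in_ref == in_boot)
}

#' Per-cluster Jaccard overlap between reference and bootstrap membership
#'
#' Intersection over union of the cluster's membership across the two
#' clusterings, restricted to common subjects; defined as 1 when both
#' memberships are empty.
#'
#' @inheritParams cluster_rand
#' @return Overlap fraction in [0, 1].
#' @export
cluster_jaccard <- function(ref_membership, boot_membership, common_subjects) {
  if (length(common_subjects) == 0) stop("empty common subject set")
  a <- intersect(ref_membership, common_subjects)
  b <- intersect(boot_membership, common_subjects)
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}

#' Bootstrap cluster-stability assessment
#'
#' For each of B replicates: resample n subjects with replacement, refit
#' K-means at the reference k from a fresh seeded start, align the
#' replicate labels to the reference by maximal kappa
#' ([align_labels()]), and compute per-cluster Rand and Jaccard indices
#' over the unique resampled subjects. Reports per-cluster means and
#' 2.5/97.5 percentile confidence intervals over replicates. Replicates
#' where the refit collapses below k non-empty clusters are skipped and
#' counted.
#'
#' @param fm A [standardize_features()] result or numeric matrix the
#'   reference model was fitted on.
#' @param reference_model A [kmeans_fit()] model.
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @param n_restarts K-means++ restarts per replicate refit (default 10).
#' @param out_of_sample \code{"exclude"} (default) drops subjects absent
#'   from a resample from that replicate's agreement computation;
#'   \code{"nearest"} instead assigns them to the nearest replicate
#'   centroid (sensitivity mode).
#' @return Object of class \code{stability_report}: data.frame
#'   \code{clusters} (point estimates and CIs per cluster),
#'   \code{kappas} (alignment kappa per replicate), \code{skipped},
#'   \code{B}, \code{seed}.
#' @export
bootstrap_stability <- function(fm, reference_model, B = 10000, seed,
                                n_restarts = 10,
                                out_of_sample = c("exclude", "nearest")) {
  if (missing(seed)) stop("an integer seed is required")
  out_of_sample <- match.arg(out_of_sample)
  stopifnot(B >= 1, inherits(reference_model, "phenotype_km"))
  x <- .fm_matrix(fm)
  n <- nrow(x)
  k <- reference_model$k
  ref_labels <- reference_model$labels
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  rand <- jac <- matrix(NA_real_, B, k)
  kappas <- rep(NA_real_, B)
  skipped <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    fit <- kmeans_fit(x[idx, , drop = FALSE], k, seed = rep_seeds[b],
                      n_restarts = n_restarts)
    if (length(unique(fit$labels)) < k) { skipped <- skipped + 1L; next }
    if (out_of_sample == "exclude") {
      common <- sort(unique(idx))
      boot_lab_common <- fit$labels[match(common, idx)]
    } else {
      common <- seq_len(n)
      boot_lab_common <- predict(fit, x)
    }
    al <- align_labels(ref_labels[common], boot_lab_common)
    kappas[b] <- al$kappa
    for (cl in seq_len(k)) {
      ref_mem <- common[ref_labels[common] == cl]
      boot_mem <- common[al$aligned == cl]
      rand[b, cl] <- cluster_rand(ref_mem, boot_mem, common)
      jac[b, cl] <- cluster_jaccard(ref_mem, boot_mem, common)
    }
  }
  ci <- function(v) stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  clusters <- do.call(rbind, lapply(seq_len(k), function(cl) {
    rc <- ci(rand[, cl]); jc <- ci(jac[, cl])
    data.frame(cluster = cl,
               rand_point = mean(rand[, cl], na.rm = TRUE),
               rand_lo = rc[1], rand_hi = rc[2],
               jaccard_point = mean(jac[, cl], na.rm = TRUE),
               jaccard_lo = jc[1], jaccard_hi = jc[2])
  }))
  structure(list(clusters = clusters, kappas = kappas, skipped = skipped,
                 B = B, seed = as.integer(seed),
                 out_of_sample = out_of_sample),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Bootstrap cluster stability (B =", x$B, ", skipped =", x$skipped, ")\n")
  df <- x$clusters
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  cluster %d: Rand %.3f (%.3f-%.3f), Jaccard %.3f (%.3f-%.3f)\n",
                df$cluster[i], df$rand_point[i], df$rand_lo[i], df$rand_hi[i],
                df$jaccard_point[i], df$jaccard_lo[i], df$jaccard_hi[i]))
  }
  invisible(x)
}
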