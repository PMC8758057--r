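#' Moment-matched discrete distribution for an ordinal item
#'
#' Builds the discretized, range-truncated normal distribution on the
#' integer support \code{scale_min:scale_max} whose mean matches
#' \code{target_mean} (within 0.01) and whose SD matches
#' \code{target_sd} as closely as the discrete support allows. The
#' location parameter is found by bisection (the discretized mean is
#' monotone in location), nested inside a bisection on the scale
#' parameter for the SD. Binary items (\code{scale_max - scale_min == 1}
#' with \code{kind = "binary"}) reduce to a Bernoulli with
#' \code{p = target_mean}.
#'
#' @param target_mean Target item mean (must lie within the scale range).
#' @param target_sd Target item SD; ignored (implied) for binary items.
#' @param scale_min,scale_max Integer scale bounds.
#' @param kind \code{"ordinal"} or \code{"binary"}.
#' @return An object of class \code{item_dist}: list with \code{support},
#'   \code{prob}, and the achieved \code{mean} and \code{sd}.
#' @examples
#' d <- moment_match_item(4.19, 1.04, 0, 5)
#' d$mean # within 0.01 of 4.19
#' @export
moment_match_item <- function(target_mean, target_sd, scale_min, scale_max,
                              kind = "ordinal") {
  if (target_mean < scale_min || target_mean > scale_max) {
    stop("target mean ", target_mean, " outside scale range [",
         scale_min, ", ", scale_max, "]")
  }
  s <- seq(scale_min, scale_max)
  if (kind == "binary") {
    p <- target_mean
    out <- list(support = c(0L, 1L), prob = c(1 - p, p),
                mean = p, sd = sqrt(p * (1 - p)), kind = "binary")
    class(out) <- "item_dist"
    return(out)
  }
  pmf <- function(mu, sigma) {
    w <- stats::dnorm(s, mu, sigma)
    if (sum(w) == 0) { # degenerate tail: all mass at nearest point
      w <- as.numeric(seq_along(s) == which.min(abs(s - mu)))
    }
    w / sum(w)
  }
  mean_of <- function(p) sum(s * p)
  sd_of <- function(p) sqrt(max(0, sum(s^2 * p) - sum(s * p)^2))
  range_w <- scale_max - scale_min
  match_mu <- function(sigma) {
    # expand the location bracket until it straddles the target mean
    # (large sigma needs a location far outside the scale range)
    step <- max(sigma, range_w)
    lo <- scale_min - step; hi <- scale_max + step
    while (mean_of(pmf(lo, sigma)) > target_mean && is.finite(lo)) {
      step <- step * 2; lo <- lo - step
      if (step > 1e9) break
    }
    step <- max(sigma, range_w)
    while (mean_of(pmf(hi, sigma)) < target_mean && is.finite(hi)) {
      step <- step * 2; hi <- hi + step
      if (step > 1e9) break
    }
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (mean_of(pmf(mid, sigma)) < target_mean) lo <- mid else hi <- mid
      if (hi - lo < 1e-10) break
    }
    (lo + hi) / 2
  }
  # achieved sd at a given sigma, with the mean pinned by match_mu;
  # NA where the mean cannot be represented (density underflow at
  # extreme locations makes very large sigmas infeasible)
  ach_sd <- function(sigma) {
    p <- pmf(match_mu(sigma), sigma)
    if (abs(mean_of(p) - target_mean) > 0.005) return(NA_real_)
    sd_of(p)
  }
  if (!is.finite(target_sd) || is.na(target_sd)) target_sd <- 1
  # sd(sigma) is not reliably monotone at the feasibility edges, so scan
  # a log-spaced grid of feasible sigmas and refine around the best
  grid <- exp(seq(log(0.02), log(20), length.out = 60))
  sds <- vapply(grid, ach_sd, numeric(1))
  ok <- which(!is.na(sds))
  if (!length(ok)) stop("no feasible scale parameter for target mean ",
                        target_mean)
  best <- ok[which.min(abs(sds[ok] - target_sd))]
  lo <- grid[max(1, best - 1)]; hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(function(sg) {
    v <- ach_sd(sg); if (is.na(v)) 1e6 else abs(v - target_sd)
  }, interval = c(lo, hi))
  sigma <- if (is.finite(opt$objective) &&
               opt$objective <= abs(sds[best] - target_sd)) {
    opt$minimum
  } else grid[best]
  mu <- match_mu(sigma)
  p <- pmf(mu, sigma)
  out <- list(support = s, prob = p, mu = mu, sigma = sigma,
              mean = mean_of(p), sd = sd_of(p), kind = "ordinal")
  if (abs(out$mean - target_mean) > 0.01) {
    stop("moment matching failed to reach the target mean")
  }
  class(out) <- "item_dist"
  out
}

# Internal: quantile function of an item_dist, vectorised over u in (0,1).
# Used so that correlated and independent draws share one code path.
.item_quantile <- function(dist, u) {
  cdf <- cumsum(dist$prob)
  dist$support[findInterval(u, cdf, left.open = TRUE) + 1L]
}

#' Synthetic cohort configuration
#'
#' @param groups Group sizes/ages, as [phenotype_group_sizes()]; any
#'   subset of rows may be supplied (e.g. a single phenotype).
#' @param profiles Per-item calibration parameters, as
#'   [phenotype_profiles()].
#' @param mixed_fraction Fraction of each case group drawn from a convex
#'   blend of two phenotypes' parameter vectors (default 0: pure
#'   phenotypes only).
#' @param blend_weight Weight on the subject's own phenotype in a blend,
#'   in (0, 1); default 0.5.
#' @param correlation Optional within-subject dependence in [0, 1): a
#'   shared latent severity factor coupling all of a subject's items via
#'   a Gaussian copula. Default 0 (items independent given group).
#' @param seed Integer seed; mandatory.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(groups = phenotype_group_sizes(),
                          profiles = phenotype_profiles(),
                          mixed_fraction = 0, blend_weight = 0.5,
                          correlation = 0, seed) {
  if (missing(seed) || !is.numeric(seed)) stop("an integer seed is required")
  stopifnot(all(groups$n >= 0), mixed_fraction >= 0, mixed_fraction <= 1,
            blend_weight > 0, blend_weight < 1,
            correlation >= 0, correlation < 1)
  structure(list(groups = groups, profiles = profiles,
                 mixed_fraction = mixed_fraction,
                 blend_weight = blend_weight,
                 correlation = correlation, seed = as.integer(seed)),
            class = "cohort_config")
}

# Internal: matched item distributions for one parameter vector
# (means/sds named by item id, battery definition b).
.match_group <- function(means, sds, b) {
  lapply(b$item_id, function(id) {
    moment_match_item(means[[id]], sds[[id]], b[id, "scale_min"],
                      b[id, "scale_max"], b[id, "kind"])
  })
}

#' Generate a synthetic questionnaire cohort
#'
#' Draws item-level responses for every configured group. Each group's
#' items are drawn from moment-matched discrete distributions
#' ([moment_match_item()]); mixed-phenotype subjects are drawn from a
#' convex blend of two phenotypes' parameter vectors. All draws are a
#' pure function of \code{(config, seed)}.
#'
#' @param config A [cohort_config()].
#' @return List with \code{responses} (data.frame: \code{subject_id},
#'   \code{age}, \code{group_label} (\code{case}/\code{control}), one
#'   column per item) and \code{true_labels} (character vector of the
#'   generating group per subject, \code{"A+B"} for blends).
#' @examples
#' cc <- cohort_config(seed = 42)
#' cohort <- generate_cohort(cc)
#' table(cohort$true_labels)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  b <- battery_items()
  pp <- config$profiles
  rownames(pp) <- pp$item_id
  col_mean <- function(g) stats::setNames(pp[[paste0(tolower(g), "_mean")]], pp$item_id)
  col_sd <- function(g) stats::setNames(pp[[paste0(tolower(g), "_sd")]], pp$item_id)
  dist_cache <- new.env(parent = emptyenv())
  dists_for <- function(key, means, sds) {
    if (is.null(dist_cache[[key]])) dist_cache[[key]] <- .match_group(means, sds, b)
    dist_cache[[key]]
  }
  phenos <- setdiff(config$groups$group, "CONTROL")
  rows <- list(); labels <- character(0); ages <- numeric(0)
  glabel <- character(0)
  for (gi in seq_len(nrow(config$groups))) {
    g <- config$groups$group[gi]; n <- config$groups$n[gi]
    if (n == 0) next
    n_mixed <- if (g != "CONTROL" && length(phenos) > 1) {
      round(config$mixed_fraction * n)
    } else 0L
    is_mixed <- c(rep(TRUE, n_mixed), rep(FALSE, n - n_mixed))
    partners <- setdiff(phenos, g)
    for (si in seq_len(n)) {
      if (is_mixed[si]) {
        other <- sample(partners, 1)
        w <- config$blend_weight
        means <- w * col_mean(g) + (1 - w) * col_mean(other)
        sds <- w * col_sd(g) + (1 - w) * col_sd(other)
        key <- paste0(g, "+", other)
        lab <- paste0(g, "+", other)
      } else {
        means <- col_mean(g); sds <- col_sd(g)
        key <- g; lab <- g
      }
      dd <- dists_for(key, means, sds)
      rho <- config$correlation
      zc <- stats::rnorm(1)
      e <- stats::rnorm(nrow(b))
      u <- stats::pnorm(rho * zc + sqrt(1 - rho^2) * e)
      vals <- vapply(seq_len(nrow(b)), function(j) {
        as.numeric(.item_quantile(dd[[j]], u[j]))
      }, numeric(1))
      rows[[length(rows) + 1L]] <- vals
      labels <- c(labels, lab)
      ages <- c(ages, round(stats::rnorm(1, config$groups$age_mean[gi],
                                         config$groups$age_sd[gi]), 1))
      glabel <- c(glabel, if (g == "CONTROL") "control" else "case")
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- b$item_id
  responses <- data.frame(subject_id = sprintf("S%04d", seq_len(nrow(m))),
                          age = ages, group_label = glabel, m,
                          stringsAsFactors = FALSE, check.names = FALSE)
  list(responses = responses, true_labels = labels)
}

#' Generate synthetic treatment-outcome records
#'
#' For each (phenotype, therapy) cell, the configured number of
#' attempters is drawn from the phenotype's subjects (without
#' replacement, capped at group size) and each attempted therapy responds
#' with the cell's Bernoulli probability.
#'
#' @param true_labels Character vector of phenotype labels, named by
#'   subject id (or unnamed, in which case ids \code{S0001...} are
#'   assumed).
#' @param response_rates Data.frame as [treatment_response_rates()]:
#'   columns \code{phenotype}, \code{therapy}, \code{attempted},
#'   \code{rate}.
#' @param seed Integer seed.
#' @return Data.frame with columns \code{subject_id}, \code{phenotype},
#'   \code{therapy}, \code{attempted} (logical), \code{responded}
#'   (logical; responded implies attempted).
#' @export
generate_treatment_records <- function(true_labels,
                                       response_rates = treatment_response_rates(),
                                       seed) {
  if (missing(seed)) stop("an integer seed is required")
  stopifnot(all(response_rates$rate >= 0), all(response_rates$rate <= 1))
  if (is.null(names(true_labels))) {
    names(true_labels) <- sprintf("S%04d", seq_along(true_labels))
  }
  unknown <- setdiff(response_rates$phenotype, true_labels)
  if (length(unknown)) stop("no subjects with phenotype label(s): ",
                            paste(unknown, collapse = ", "))
  set.seed(as.integer(seed))
  out <- list()
  for (i in seq_len(nrow(response_rates))) {
    ph <- response_rates$phenotype[i]; th <- response_rates$therapy[i]
    ids <- names(true_labels)[true_labels == ph]
    n_att <- min(response_rates$attempted[i], length(ids))
    if (n_att == 0) next
    att <- sample(ids, n_att)
    resp <- stats::runif(n_att) < response_rates$rate[i]
    out[[length(out) + 1L]] <- data.frame(
      subject_id = att, phenotype = ph, therapy = th,
      attempted = TRUE, responded = resp, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
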