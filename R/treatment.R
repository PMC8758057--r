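#' Responder contingency table by phenotype and therapy
#'
#' Aggregates treatment records into a (responders, attempted) cell per
#' (phenotype, therapy), with a totals row summing over phenotypes and a
#' per-phenotype count of subjects with any follow-up.
#'
#' @param records Data.frame with columns \code{subject_id},
#'   \code{therapy}, \code{attempted} (logical), \code{responded}
#'   (logical).
#' @param labels Phenotype label per subject, named by subject id (a
#'   \code{phenotype} column on \code{records} is used if \code{labels}
#'   is missing).
#' @return Object of class \code{responder_table}: list with
#'   \code{responders} and \code{attempted} (phenotype x therapy
#'   matrices including a \code{Total} row) and \code{n_with_followup}.
#' @export
responder_table <- function(records, labels = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(labels)) {
    if (!"phenotype" %in% names(records)) {
      stop("supply labels or a phenotype column on records")
    }
    ph <- records$phenotype
  } else {
    ph <- labels[records$subject_id]
    if (anyNA(ph)) {
      stop("unlabeled subject(s): ",
           paste(unique(records$subject_id[is.na(ph)]), collapse = ", "))
    }
  }
  if (any(records$responded & !records$attempted)) {
    stop("responded implies attempted")
  }
  phenos <- sort(unique(as.character(ph)))
  therapies <- sort(unique(records$therapy))
  mk <- function() matrix(0L, length(phenos) + 1, length(therapies),
                          dimnames = list(c(phenos, "Total"), therapies))
  responders <- attempted <- mk()
  for (i in seq_along(phenos)) {
    for (j in seq_along(therapies)) {
      sel <- ph == phenos[i] & records$therapy == therapies[j]
      attempted[i, j] <- sum(records$attempted[sel])
      responders[i, j] <- sum(records$responded[sel])
    }
  }
  attempted["Total", ] <- colSums(attempted[phenos, , drop = FALSE])
  responders["Total", ] <- colSums(responders[phenos, , drop = FALSE])
  nfu <- vapply(phenos, function(p)
    length(unique(records$subject_id[ph == p & records$attempted])), integer(1))
  structure(list(responders = responders, attempted = attempted,
                 n_with_followup = nfu),
            class = "responder_table")
}

#' @export
print.responder_table <- function(x, ...) {
  cat("Responders / attempted by phenotype and therapy:\n")
  m <- matrix(sprintf("%d/%d", x$responders, x$attempted),
              nrow = nrow(x$responders), dimnames = dimnames(x$responders))
  print(m, quote = FALSE)
  invisible(x)
}

#' Within-group and within-cohort responder proportions
#'
#' \code{within_group[p, t]} = responders / attempted for phenotype p and
#' therapy t; \code{within_cohort[p, t]} = phenotype p's responders as a
#' fraction of all responders to therapy t. Cells with zero denominator
#' are \code{NA} (flagged undefined, never reported as 0).
#'
#' @param table A [responder_table()].
#' @return List with matrices \code{within_group} and
#'   \code{within_cohort}.
#' @export
responder_proportions <- function(table) {
  stopifnot(inherits(table, "responder_table"))
  phenos <- setdiff(rownames(table$responders), "Total")
  resp <- table$responders[phenos, , drop = FALSE]
  att <- table$attempted[phenos, , drop = FALSE]
  wg <- resp / att
  wg[att == 0] <- NA_real_
  tot <- table$responders["Total", ]
  wc <- sweep(resp, 2, tot, "/")
  wc[, tot == 0] <- NA_real_
  list(within_group = wg, within_cohort = wc)
}

#' Two-sample z-test for proportions
#'
#' Pooled-proportion z statistic with a two-sided normal p-value; no
#' continuity correction by default.
#'
#' @param x1,n1,x2,n2 Successes and totals for the two arms.
#' @param continuity Apply the Yates continuity correction (default
#'   FALSE).
#' @return List with \code{z} and \code{p_value}.
#' @examples
#' two_proportion_ztest(18, 20, 1, 10) # z approximately 4.29
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2, continuity = FALSE) {
  if (n1 < 1 || n2 < 1) stop("both arms need n >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("need 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  diff <- p1 - p2
  if (continuity) diff <- sign(diff) * max(0, abs(diff) - 0.5 * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else diff / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Group comparison utilities
#'
#' Thin wrappers over the standard two-sided tests used to compare
#' groups: Mann-Whitney U (normal approximation with tie correction),
#' Pearson chi-square, or Fisher's exact test on a 2x2 table.
#'
#' @param a,b For \code{mann_whitney}: the two samples. For
#'   \code{chi_square}/\code{fisher_2x2}: \code{a} is a contingency
#'   matrix and \code{b} is ignored.
#' @param kind One of \code{"mann_whitney"}, \code{"chi_square"},
#'   \code{"fisher_2x2"}.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
compare_groups <- function(a, b = NULL,
                           kind = c("mann_whitney", "chi_square", "fisher_2x2")) {
  kind <- match.arg(kind)
  if (kind == "mann_whitney") {
    t <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    list(statistic = unname(t$statistic), p_value = t$p.value)
  } else if (kind == "chi_square") {
    m <- as.matrix(a)
    if (any(dim(m) < 2)) stop("malformed contingency table")
    t <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    list(statistic = unname(t$statistic), p_value = t$p.value)
  } else {
    m <- as.matrix(a)
    if (!all(dim(m) == c(2, 2))) stop("fisher_2x2 needs a 2x2 table")
    t <- stats::fisher.test(m)
    list(statistic = unname(t$estimate), p_value = t$p.value)
  }
}
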