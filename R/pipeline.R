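#' Derive a stage seed from the global pipeline seed
#'
#' Stage seeds are a documented deterministic function of the global
#' seed and the stage name, so every stochastic stage is reproducible
#' and independently re-runnable.
#'
#' @param global_seed Integer global seed.
#' @param stage Stage name (character).
#' @return Integer seed in [1, 2^31 - 2].
#' @export
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h) %% (2^31 - 2) + 1)
}

#' Pipeline configuration
#'
#' Bundles the stage parameters of the full phenotyping pipeline. All
#' stage seeds derive from the one global seed via [stage_seed()].
#'
#' @param seed Global integer seed.
#' @param simulate Generate a synthetic cohort (TRUE, default) or read
#'   one from \code{cohort_path}.
#' @param cohort_path,treatment_path Input CSV paths when
#'   \code{simulate = FALSE}.
#' @param out_dir Output directory (created if needed); NULL disables
#'   file output.
#' @param k Number of phenotype clusters (default 3, the study design);
#'   NULL selects k by the elbow method instead.
#' @param k_max Largest k scanned by the WSS curve.
#' @param n_restarts K-means restarts.
#' @param B Bootstrap replicates for the stability stage.
#' @param som_iterations,som_rows,som_cols SOM training parameters.
#' @param n_trees Random-forest trees.
#' @param mixed_fraction,correlation Generator options (see
#'   [cohort_config()]).
#' @param composite A [composite_config()].
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed, simulate = TRUE, cohort_path = NULL,
                            treatment_path = NULL, out_dir = NULL,
                            k = 3, k_max = 8, n_restarts = 50,
                            B = 1000, som_iterations = 1e5,
                            som_rows = 4, som_cols = 6, n_trees = 500,
                            mixed_fraction = 0, correlation = 0,
                            composite = composite_config()) {
  if (missing(seed)) stop("an integer global seed is required")
  structure(list(seed = as.integer(seed), simulate = simulate,
                 cohort_path = cohort_path, treatment_path = treatment_path,
                 out_dir = out_dir, k = k, k_max = k_max,
                 n_restarts = n_restarts, B = B,
                 som_iterations = som_iterations, som_rows = som_rows,
                 som_cols = som_cols, n_trees = n_trees,
                 mixed_fraction = mixed_fraction, correlation = correlation,
                 composite = composite),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON) file of [pipeline_config()]
#'   fields.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  comp <- if (!is.null(cfg$composite)) do.call(composite_config, cfg$composite)
          else composite_config()
  cfg$composite <- NULL
  do.call(pipeline_config, c(cfg, list(composite = comp)))
}

#' Read and validate a cohort CSV
#'
#' Expects one row per subject with a \code{subject_id} column and the
#' 49 battery item columns; optional \code{age} and \code{group_label}.
#' Every value is validated against its item's scale range and the
#' subject ids checked for duplicates; violations are reported with row
#' numbers.
#'
#' @param path CSV path.
#' @return Validated data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  known <- c("subject_id", "age", "group_label", battery_item_ids())
  unknown <- setdiff(names(df), known)
  if (length(unknown)) stop("unknown column(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(c("subject_id", battery_item_ids()), names(df))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    warning("cohort file has a header but no rows: ", path)
    return(df)
  }
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) stop("duplicate subject_id(s): ", paste(unique(dup), collapse = ", "))
  b <- battery_items()
  for (id in b$item_id) {
    v <- df[[id]]
    bad <- which(is.na(v) | v < b[id, "scale_min"] | v > b[id, "scale_max"])
    if (length(bad)) {
      stop("out-of-range value for item ", id, " (scale ", b[id, "scale_min"],
           "-", b[id, "scale_max"], ") in row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  df
}

#' Write a cohort CSV with stable column order
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  lead <- intersect(c("subject_id", "age", "group_label"), names(cohort))
  cols <- c(lead, intersect(battery_item_ids(), names(cohort)))
  utils::write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE)
}

#' Run the full phenotyping pipeline
#'
#' Executes, in order: cohort simulation (or load) -> scoring ->
#' standardization -> Ward dendrogram and WSS/elbow scan -> K-means ->
#' bootstrap stability -> random-forest importance and z-matrix ->
#' phenotype measures -> SOM with bin classification -> treatment
#' responder analysis. When \code{out_dir} is set, each stage's tables
#' are written as CSV alongside a machine-readable \code{summary.json}
#' echoing the configuration and derived stage seeds.
#'
#' @param config A [pipeline_config()].
#' @return List of class \code{phenotype_pipeline} with all stage
#'   results and a \code{summary} list.
#' @examples
#' \donttest{
#' res <- run_pipeline(pipeline_config(seed = 1, B = 50,
#'                                     som_iterations = 2000,
#'                                     n_restarts = 10))
#' res$summary$cluster_sizes
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- sapply(c("simulate", "cluster", "stability", "importance", "som",
                    "treatment"), function(s) stage_seed(config$seed, s))
  # --- cohort ---
  if (config$simulate) {
    cc <- cohort_config(mixed_fraction = config$mixed_fraction,
                        correlation = config$correlation,
                        seed = seeds[["simulate"]])
    gen <- generate_cohort(cc)
    cohort <- gen$responses
    true_labels <- gen$true_labels
    records <- generate_treatment_records(
      stats::setNames(true_labels, cohort$subject_id),
      seed = seeds[["simulate"]] + 1L)
  } else {
    cohort <- read_cohort_csv(config$cohort_path)
    true_labels <- NULL
    records <- if (!is.null(config$treatment_path)) {
      utils::read.csv(config$treatment_path, stringsAsFactors = FALSE)
    } else NULL
  }
  # --- scoring ---
  scored <- score_cohort(cohort, config$composite)
  # --- clustering (cases only) ---
  is_case <- if ("group_label" %in% names(cohort)) {
    cohort$group_label == "case"
  } else rep(TRUE, nrow(cohort))
  case_items <- cohort[is_case, battery_item_ids()]
  fm <- standardize_features(case_items)
  tree <- ward_dendrogram(fm)
  curve <- wss_curve(fm, k_max = config$k_max, seed = seeds[["cluster"]],
                     n_restarts = config$n_restarts)
  k <- if (is.null(config$k)) suggest_k(curve) else config$k
  km <- kmeans_fit(fm, k, seed = seeds[["cluster"]],
                   n_restarts = config$n_restarts)
  bi <- battery_items()
  unit_items <- sweep(sweep(as.matrix(case_items), 2, bi$scale_min, "-"),
                      2, bi$scale_max - bi$scale_min, "/")
  ord <- pcoa_bray(unit_items)
  # --- stability ---
  stab <- bootstrap_stability(fm, km, B = config$B,
                              seed = seeds[["stability"]])
  # --- importance ---
  imp <- rf_importance(fm, km$labels, n_trees = config$n_trees,
                       seed = seeds[["importance"]])
  zmat <- phenotype_z_matrix(case_items, km$labels)
  sel <- select_discriminatory_items(imp, zmat,
                                     top_n = min(20, nrow(imp$importance)))
  # --- SOM over the whole cohort (cases + controls) ---
  meas <- unit_scale_measures(scored)
  som <- train_som(meas, som_config(rows = config$som_rows,
                                    cols = config$som_cols,
                                    iterations = config$som_iterations,
                                    seed = seeds[["som"]]))
  bins <- classify_bins(som, meas)
  conv <- convergence_index(som, meas)
  # --- treatment ---
  treat <- if (!is.null(records)) {
    tab <- responder_table(records)
    list(table = tab, proportions = responder_proportions(tab))
  } else NULL
  summary <- list(
    seed = config$seed, stage_seeds = as.list(seeds),
    n_subjects = nrow(cohort), n_cases = sum(is_case),
    n_controls = sum(!is_case), k = k,
    cluster_sizes = as.integer(tabulate(km$labels, k)),
    wss = km$wss, suggested_k = suggest_k(curve),
    stability = stab$clusters,
    som_convergence = conv,
    pure_or_control_fraction =
      sum(bins$count[bins$label %in% c("control", "pure-BPS", "pure-NUPP",
                                       "pure-MFP")]) / nrow(cohort))
  res <- structure(list(cohort = cohort, true_labels = true_labels,
                        scored = scored, feature_matrix = fm, tree = tree,
                        wss_curve = curve, kmeans = km, pcoa = ord,
                        stability = stab, importance = imp, z_matrix = zmat,
                        discriminatory_items = sel, measures = meas,
                        som = som, bins = bins, treatment = treat,
                        summary = summary, config = config),
                   class = "phenotype_pipeline")
  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config$out_dir)
  res
}

#' @export
print.phenotype_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Phenotyping pipeline:", s$n_subjects, "subjects (",
      s$n_cases, "cases,", s$n_controls, "controls )\n")
  cat("k =", s$k, "; cluster sizes:", paste(s$cluster_sizes, collapse = "/"), "\n")
  cat("SOM convergence index:", round(s$som_convergence, 3), "\n")
  invisible(x)
}

# Internal: write all stage outputs under out_dir.
.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  write_cohort_csv(res$cohort, file.path(out_dir, "cohort.csv"))
  w(res$scored, "scored_profiles.csv")
  case_ids <- res$cohort$subject_id[seq_along(res$kmeans$labels)]
  w(data.frame(subject_id = rownames(res$feature_matrix$x) %||% case_ids,
               cluster = res$kmeans$labels), "cluster_labels.csv")
  w(res$wss_curve, "wss_curve.csv")
  w(data.frame(res$pcoa$coordinates), "pcoa_coordinates.csv")
  w(res$stability$clusters, "stability.csv")
  w(res$importance$importance, "importance.csv")
  zl <- as.data.frame(as.table(res$z_matrix))
  names(zl) <- c("item", "cluster", "z")
  w(zl, "z_matrix_long.csv")
  w(data.frame(res$som$codebook), "som_codebook.csv")
  w(res$bins, "som_bins.csv")
  w(data.frame(node = seq_len(nrow(res$som$codebook)),
               neighbor_distance = neighbor_distance_map(res$som)),
    "som_neighbor_distance.csv")
  if (!is.null(res$treatment)) {
    w(as.data.frame(res$treatment$table$responders), "responders.csv")
    w(as.data.frame(res$treatment$table$attempted), "attempted.csv")
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
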