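#' Compute the per-subject, per-band metrics table
#'
#' For every subject and band, characterises the weighted coherence graph
#' (Small-World Propensity with its clustering and path components) and its
#' minimum spanning tree (maximum betweenness, leaf fraction, diameter,
#' average eccentricity), yielding the 7-index table the group comparison
#' consumes.  Nodal betweenness and eccentricity vectors are collected
#' alongside for the gated follow-up analysis.
#'
#' @param cohort A `synthetic_cohort`, or any list with elements `subjects`
#'   (data frame with `subject`, `group`), `matrices`
#'   (`matrices[[subject]][[band]]` connectivity matrices) and `bands`.
#' @param n_null Random nulls per SWP evaluation (default 50).
#' @param seed Integer seed for the null ensembles.
#' @return A list of class `metrics_result`: `global` (data frame, one row
#'   per subject x band with the 7 index columns) and `nodal` (long data
#'   frame with columns `subject`, `group`, `band`, `metric`, `node`,
#'   `value`).
#' @export
compute_metrics_table <- function(cohort, n_null = 50L, seed = NULL) {
  subjects <- cohort$subjects
  rows <- list()
  nodal <- list()
  counter <- 0L
  for (s in seq_len(nrow(subjects))) {
    sid <- subjects$subject[s]
    for (bd in cohort$bands) {
      counter <- counter + 1L
      W <- cohort$matrices[[sid]][[bd]]
      swp <- small_world_propensity(
        W, n_null = n_null,
        seed = if (is.null(seed)) NULL else substream_seed(seed, counter))
      tree <- minimum_spanning_tree(W)
      tm <- tree_metrics(tree)
      rows[[counter]] <- data.frame(
        subject = sid, group = subjects$group[s], band = bd,
        swp = swp$phi, L = swp$L_given, C = swp$C_given,
        max_bc = tm$max_bc, leaf_fraction = tm$leaf_fraction,
        diameter = tm$diameter, avg_eccentricity = tm$avg_eccentricity,
        stringsAsFactors = FALSE)
      labs <- tm$labels %||% as.character(seq_len(length(tm$bc)))
      nodal[[counter]] <- data.frame(
        subject = sid, group = subjects$group[s], band = bd,
        metric = rep(c("bc", "eccentricity"), each = length(labs)),
        node = c(labs, labs),
        value = c(tm$bc, tm$eccentricity),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(global = do.call(rbind, rows),
                 nodal = do.call(rbind, nodal)),
            class = "metrics_result")
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis.  The defaults
#' reproduce the standard design: 4 bands, 50 random nulls for the
#' Small-World Propensity, 5000 permutation shuffles, significance at
#' q < 0.05.
#'
#' @param mode `"synthetic"` (generate a cohort), `"matrices"` (read
#'   per-subject adjacency files) or `"timeseries"` (read epoch files and
#'   estimate connectivity first).
#' @param bands Named list of `band_spec`s.
#' @param n_null Random nulls per SWP evaluation.
#' @param n_perm Permutation shuffles per test.
#' @param alpha Significance level on q-values.
#' @param seed Master seed; fanned out to independent per-stage substreams.
#' @param n_case,n_ctrl Synthetic cohort sizes.
#' @param effects List of [effect_spec()]s for the synthetic cohort.
#' @param generator Synthetic generator parameters.
#' @param manifest For the file-input modes: a data frame with columns
#'   `subject`, `group`, `band`, `path`.
#' @param out_dir Output directory for [write_report()], or `NULL`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "matrices", "timeseries"),
                            bands = default_bands(), n_null = 50L,
                            n_perm = 5000L, alpha = 0.05, seed = 1L,
                            n_case = 19L, n_ctrl = 52L, effects = list(),
                            generator = default_generator_params(),
                            manifest = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode != "synthetic" && is.null(manifest))
    stop("modes 'matrices' and 'timeseries' require a manifest",
         call. = FALSE)
  structure(list(mode = mode, bands = bands, n_null = n_null,
                 n_perm = n_perm, alpha = alpha, seed = as.integer(seed),
                 n_case = n_case, n_ctrl = n_ctrl, effects = effects,
                 generator = generator, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; `bands`
#' is a mapping of name to `[f_lo, f_hi]`; `effects` a list of mappings
#' with `band`, `target`, `magnitude`, `direction`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("mode", "n_null", "n_perm", "alpha", "seed",
                          "n_case", "n_ctrl", "out_dir"))]
  if (!is.null(raw$bands))
    args$bands <- lapply(stats::setNames(names(raw$bands), names(raw$bands)),
                         function(nm) band_spec(nm, raw$bands[[nm]][1],
                                                raw$bands[[nm]][2]))
  if (!is.null(raw$effects))
    args$effects <- lapply(raw$effects, function(e)
      effect_spec(e$band, e$target, e$magnitude, e$direction %||% 1))
  if (!is.null(raw$manifest))
    args$manifest <- utils::read.csv(raw$manifest, stringsAsFactors = FALSE)
  do.call(pipeline_config, args)
}

#' Read an adjacency matrix from delimited text
#'
#' Expects a square matrix with matching row/column headers of atlas
#' labels; validates symmetry (tolerance `1e-8`), the [0, 1] coherence
#' range, and, when `atlas` is supplied, dimension and label agreement.
#'
#' @param path File path (comma- or tab-delimited, autodetected).
#' @param atlas Optional `roi_atlas` to validate labels against.
#' @param band,subject_id Attached to the result.
#' @return A `connectivity_matrix`.
#' @export
read_adjacency <- function(path, atlas = NULL, band = NULL,
                           subject_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M))
    stop(sprintf("%s: expected a square matrix, got %d rows x %d columns",
                 path, nrow(M), ncol(M)), call. = FALSE)
  if (!is.null(atlas)) {
    if (nrow(M) != nrow(atlas))
      stop(sprintf("%s: expected %d ROIs, found %d", path, nrow(atlas),
                   nrow(M)), call. = FALSE)
    unknown <- setdiff(rownames(M), atlas$label)
    if (length(unknown) > 0)
      stop(sprintf("%s: unknown ROI labels: %s", path,
                   paste(utils::head(unknown, 5), collapse = ", ")),
           call. = FALSE)
    M <- M[atlas$label, atlas$label]    # canonical order
  }
  out <- tryCatch(
    connectivity_matrix(M, band = band, subject_id = subject_id),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
  out
}

#' Write an adjacency matrix as delimited text
#'
#' @param W A `connectivity_matrix` (or plain labelled matrix).
#' @param path Output path; written comma-separated with row and column
#'   headers.
#' @export
write_adjacency <- function(W, path) {
  df <- as.data.frame(as_weight_matrix(W))
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort acquisition (synthetic generation, adjacency files,
#' or spectral estimation from epoch files), per-subject graph and tree
#' metrics, the 7 x 4 global permutation comparison with FDR, and the gated
#' nodal follow-up (run automatically for every band whose global `max_bc`
#' or `avg_eccentricity` test is significant).  Deterministic under a fixed
#' seed: the master seed fans out to independent substreams for cohort
#' generation, SWP nulls, and each permutation test.
#'
#' @param config A `pipeline_config`.
#' @return A list of class `pipeline_report`: `metrics` (per-subject
#'   table), `global` (28-row test table with defaults), `nodal` (gated
#'   nodal results or `NULL`), `config`, `provenance` (seed, counts, config
#'   checksum, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- switch(config$mode,
    synthetic = generate_cohort(
      n_case = config$n_case, n_ctrl = config$n_ctrl,
      effects = config$effects, params = config$generator,
      bands = names(config$bands),
      seed = substream_seed(config$seed, 1L)),
    matrices = load_matrix_cohort(config),
    timeseries = load_timeseries_cohort(config))
  if (min(table(cohort$subjects$group)) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  metrics <- compute_metrics_table(cohort, n_null = config$n_null,
                                   seed = substream_seed(config$seed, 2L))
  global <- compare_global(metrics$global, n_perm = config$n_perm,
                           seed = substream_seed(config$seed, 3L),
                           alpha = config$alpha)
  gated_bands <- unique(global$band[global$significant &
                                      global$index %in%
                                        c("max_bc", "avg_eccentricity")])
  nodal_res <- NULL
  if (length(gated_bands) > 0) {
    keep <- mapply(function(met, bd) {
      gate_idx <- if (met == "bc") "max_bc" else "avg_eccentricity"
      any(global$significant & global$index == gate_idx & global$band == bd)
    }, metrics$nodal$metric, metrics$nodal$band)
    sel <- metrics$nodal[keep, ]
    if (nrow(sel) > 0)
      nodal_res <- compare_nodal(sel, global, n_perm = config$n_perm,
                                 seed = substream_seed(config$seed, 4L),
                                 alpha = config$alpha)
  }
  report <- structure(list(
    metrics = metrics$global,
    nodal_metrics = metrics$nodal,
    global = global,
    nodal = nodal_res,
    config = config,
    provenance = list(
      seed = config$seed,
      n_subjects = nrow(cohort$subjects),
      n_bands = length(config$bands),
      n_global_tests = nrow(global),
      config_checksum = config_checksum(config),
      package_version = as.character(utils::packageVersion("coherenet")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# stable checksum of the configuration (numbers and names only)
config_checksum <- function(config) {
  flat <- utils::capture.output(utils::str(
    config[setdiff(names(config), "manifest")], digits.d = 12))
  sum(utils::head(cumsum(as.integer(charToRaw(paste(flat, collapse = "\n")))),
                  10000) %% 2147483647) %% 2147483647
}

load_matrix_cohort <- function(config) {
  man <- config$manifest
  stopifnot(all(c("subject", "group", "band", "path") %in% names(man)))
  atlas <- build_roi_atlas()
  subjects <- unique(man[, c("subject", "group")])
  bands <- names(config$bands)
  matrices <- lapply(subjects$subject, function(sid) {
    rows <- man[man$subject == sid, ]
    missing_bands <- setdiff(bands, rows$band)
    if (length(missing_bands) > 0)
      stop(sprintf("subject %s is missing band(s): %s", sid,
                   paste(missing_bands, collapse = ", ")), call. = FALSE)
    out <- lapply(bands, function(bd)
      read_adjacency(rows$path[rows$band == bd][1],
                     atlas = if (nrow(atlas) == 84) atlas else NULL,
                     band = bd, subject_id = sid))
    names(out) <- bands
    out
  })
  names(matrices) <- subjects$subject
  list(subjects = subjects, matrices = matrices, bands = bands)
}

load_timeseries_cohort <- function(config) {
  man <- config$manifest
  stopifnot(all(c("subject", "group", "path") %in% names(man)))
  subjects <- unique(man[, c("subject", "group")])
  bands <- names(config$bands)
  matrices <- lapply(subjects$subject, function(sid) {
    paths <- man$path[man$subject == sid]
    eps <- lapply(paths, function(p) {
      sep <- if (grepl("\t", readLines(p, n = 1L))) "\t" else ","
      as.matrix(utils::read.table(p, header = TRUE, sep = sep,
                                  check.names = FALSE))
    })
    cs <- estimate_cross_spectra(epoch_set(eps))
    out <- lapply(config$bands, function(bd)
      lagged_coherence(cs, bd, subject_id = sid))
    names(out) <- bands
    out
  })
  names(matrices) <- subjects$subject
  list(subjects = subjects, matrices = matrices, bands = bands)
}

#' Write a pipeline report to disk
#'
#' Emits the subject-level metrics and test tables as CSV and the whole
#' report (with provenance) as JSON.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$global, file.path(dir, "global_tests.csv"),
                   row.names = FALSE)
  if (!is.null(report$nodal))
    utils::write.csv(report$nodal, file.path(dir, "nodal_tests.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(provenance = report$provenance,
         global = report$global,
         nodal = report$nodal),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects, %d global tests (%d significant)\n",
              x$provenance$n_subjects, nrow(x$global), sum(x$global$significant)))
  if (!is.null(x$nodal))
    cat(sprintf("  nodal follow-up: %d tests (%d significant)\n",
                nrow(x$nodal), sum(x$nodal$significant)))
  invisible(x)
}
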