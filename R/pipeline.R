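# End-to-end orchestration: preprocess -> fuzzy rule matrix -> epsilon
# search + cluster collapse -> adaptive-LASSO scores -> (optional) network
# fusion, with every intermediate persisted and a content-hash manifest.

.pipeline_defaults <- list(
  n_top = 100, n_trees = 500,
  num_labels = 7, max_iter = 10, step_size = 0.01,
  minpts = 2, grid = NULL,
  k_folds = 10,
  disease = NULL,
  seed = 1
)

#' Pipeline configuration
#'
#' All stage parameters with their defaults; unknown keys are rejected.
#'
#' @param ... Overrides of the defaults: `n_top`, `n_trees` (pre-filter);
#'   `num_labels`, `max_iter`, `step_size` (fuzzy inference); `minpts`,
#'   `grid` (epsilon search); `k_folds` (adaptive LASSO); `disease`
#'   (network filter); `seed`.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  if (length(over) > 0L && (is.null(names(over)) || any(names(over) == ""))) {
    stop("all configuration entries must be named")
  }
  unknown <- setdiff(names(over), names(.pipeline_defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(.pipeline_defaults, over, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Write / read the integer rule matrix as TSV
#'
#' @param inferred An `mb_inferred` object.
#' @param path Output TSV path.
#' @return `path` (write) or an `mb_inferred` rebuilt from file (read).
#' @export
write_inferred <- function(inferred, path) {
  stopifnot(inherits(inferred, "mb_inferred"))
  df <- as.data.frame(inferred$values, check.names = FALSE)
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(rule = rownames(inferred$values)),
                                    df), path)
  invisible(path)
}

#' @rdname write_inferred
#' @export
read_inferred <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  if (!"effective_label" %in% names(tab) || ncol(tab) < 3L) {
    stop("clustering input is not a rule matrix ",
         "(missing effective_label column): ", path)
  }
  body <- as.matrix(tab[setdiff(names(tab), "rule")])
  if (!is.numeric(body) || anyNA(body) || any(body < 1) ||
      any(body != round(body))) {
    stop("clustering input is corrupt: rule matrix entries must be ",
         "integers >= 1: ", path)
  }
  storage.mode(body) <- "integer"
  rownames(body) <- if ("rule" %in% names(tab)) tab$rule else NULL
  structure(
    list(values = body, scaled = suppressWarnings(autoscale(body)),
         num_labels = max(body), label_map = NULL),
    class = "mb_inferred"
  )
}

#' Run the full downstream-analysis pipeline
#'
#' Stages run in order: random-forest pre-filter, label augmentation,
#' fuzzy-rule inference, epsilon-selected DBSCAN collapse, adaptive-LASSO
#' scoring, and (when an enrichment table is supplied) network fusion. A
#' failing stage aborts with the stage named; artifacts persisted before
#' the failure are retained. With `out_dir` set, every intermediate is
#' written (`filtered.tsv`, `inferred.tsv`, `clusters.json`,
#' `scores.tsv`, `network.graphml`, `run.log`) together with a
#' `manifest.json` of MD5 content hashes; outputs are deterministic for a
#' fixed seed, so re-running reproduces the hashes.
#'
#' @param data Abundance tibble (`sample_id`, `label`, features) or a
#'   file path (then `labels`/`orientation` apply, see
#'   [read_abundance()]).
#' @param enrichment Enrichment tibble, or CSV path, or `NULL` to skip
#'   fusion (skipping raises a warning).
#' @param taxonomy Optional taxonomy tibble ([read_taxonomy()] layout) or
#'   TSV path, needed for OTU-style feature names.
#' @param synonyms Optional named character vector of name synonyms.
#' @param out_dir Output directory for artifacts (`NULL`: keep results in
#'   memory only).
#' @param config A [pipeline_config()].
#' @param labels,orientation Used only when `data` is a path.
#' @return Invisibly, a list with `filtered`, `model`, `inferred`,
#'   `selection`, `scores`, `network` (or `NULL`), `paths` and
#'   `manifest`.
#' @export
run_pipeline <- function(data, enrichment = NULL, taxonomy = NULL,
                         synonyms = NULL, out_dir = NULL,
                         config = pipeline_config(),
                         labels = NULL, orientation = "samples") {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- list()
  log_lines <- c("mbfuse pipeline run",
                 paste0("config: ", jsonlite::toJSON(
                   config[setdiff(names(config), "grid")], auto_unbox = TRUE,
                   null = "null")))
  persist <- !is.null(out_dir)
  if (persist && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  filtered <- run_stage("preprocess", {
    tab <- if (is.character(data)) {
      read_abundance(data, orientation = orientation, labels = labels)
    } else {
      data
    }
    prefilter_features(tab, n_top = config$n_top, n_trees = config$n_trees,
                       seed = config$seed)
  })
  log_lines <- c(log_lines,
                 paste0("preprocess: ", nrow(filtered), " samples x ",
                        ncol(filtered) - 2L, " features kept"))
  if (persist) {
    paths$filtered <- file.path(out_dir, "filtered.tsv")
    readr::write_tsv(filtered, paths$filtered)
  }

  anfis_out <- run_stage("anfis", {
    aug <- augment(filtered)
    model <- fit_anfis(aug, num_labels = config$num_labels,
                       max_iter = config$max_iter,
                       step_size = config$step_size)
    list(model = model, inferred = extract_inferred_matrix(model))
  })
  model <- anfis_out$model
  inferred <- anfis_out$inferred
  log_lines <- c(log_lines,
                 paste0("anfis: ", nrow(inferred$values),
                        " effective samples (rules) from ",
                        nrow(filtered), " samples; final RMSE ",
                        format(utils::tail(model$history$rmse, 1))))
  if (persist) {
    paths$inferred <- file.path(out_dir, "inferred.tsv")
    write_inferred(inferred, paths$inferred)
  }

  selection <- run_stage("clustering", {
    select_epsilon(inferred, grid = config$grid, minpts = config$minpts)
  })
  n_clusters <- length(unique(
    selection$assignment$cluster[selection$assignment$cluster > 0L]))
  log_lines <- c(log_lines,
                 paste0("clustering: eps = ", selection$eps, ", ",
                        n_clusters, " cluster(s), ",
                        sum(selection$assignment$cluster == 0L),
                        " singleton feature(s)",
                        if (!selection$converged) " [grid exhausted]" else ""))
  if (persist) {
    paths$clusters <- file.path(out_dir, "clusters.json")
    jsonlite::write_json(
      list(eps = selection$eps, converged = selection$converged,
           assignment = selection$assignment,
           loadings = selection$clustered$loadings,
           provenance = selection$clustered$provenance),
      paths$clusters, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  scores <- run_stage("scoring", {
    y <- inferred$scaled[, "effective_label"]
    score_features(selection$clustered, y, k_folds = config$k_folds,
                   seed = config$seed)
  })
  log_lines <- c(log_lines,
                 paste0("scoring: lambda = ", format(attr(scores, "lambda")),
                        "; ", sum(scores$feature_score != 0),
                        " non-zero feature score(s)"))
  if (persist) {
    paths$scores <- file.path(out_dir, "scores.tsv")
    readr::write_tsv(tidy(scores), paths$scores)
  }

  network <- NULL
  if (is.null(enrichment)) {
    warning("no enrichment table supplied; skipping the fusion stage")
    log_lines <- c(log_lines, "fusion: skipped (no enrichment input)")
  } else {
    network <- run_stage("fusion", {
      enr <- if (is.character(enrichment)) read_enrichment(enrichment)
             else enrichment
      tax <- if (is.character(taxonomy)) read_taxonomy(taxonomy) else taxonomy
      feats <- setdiff(names(filtered), c("sample_id", "label"))
      nmap <- build_name_map(feats, taxonomy = tax, synonyms = synonyms)
      net <- build_network(enr, disease = config$disease)
      net <- infuse_clusters(net, selection$clustered, nmap)
      node_scores(net, scores, nmap)
    })
    log_lines <- c(log_lines,
                   paste0("fusion: ", nrow(network$nodes), " nodes, ",
                          nrow(network$edges), " edges"))
    if (persist) {
      paths$network <- file.path(out_dir, "network.graphml")
      export_graph(network, paths$network)
    }
  }

  manifest <- NULL
  if (persist) {
    paths$log <- file.path(out_dir, "run.log")
    writeLines(log_lines, paths$log)
    files <- unlist(paths)
    manifest <- tibble::tibble(
      artifact = names(files),
      file = basename(files),
      md5 = unname(tools::md5sum(files))
    )
    paths$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, pretty = TRUE)
  }

  invisible(list(filtered = filtered, model = model, inferred = inferred,
                 selection = selection, scores = scores, network = network,
                 paths = paths, manifest = manifest, log = log_lines))
}
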