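#' Read an abundance table with sample labels
#'
#' Reads a delimited (TSV/CSV) samples-by-features or features-by-samples
#' abundance table and attaches one categorical outcome label per sample.
#' Entries must be non-negative numbers: raw counts or processed (float)
#' abundances are both admissible. Missing values are not allowed anywhere.
#'
#' @param path Path to a delimited text file. With
#'   `orientation = "samples"` the first column holds sample ids and the
#'   header names the features; with `orientation = "features"` the first
#'   column holds feature names and the header names the samples.
#' @param orientation Either `"samples"` (samples in rows, default) or
#'   `"features"` (features in rows; the table is transposed on read).
#' @param labels Either the name of a label column inside the table
#'   (samples-in-rows only), or the path to a two-column delimited file
#'   mapping sample id to label.
#' @param delim Field delimiter; guessed from the file extension
#'   (`.csv` gives `","`, anything else tab) when `NULL`.
#' @return A tibble with columns `sample_id`, `label`, then one numeric
#'   column per feature.
#' @export
read_abundance <- function(path, orientation = c("samples", "features"),
                           labels, delim = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("abundance file not found: ", path)
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  raw <- tibble::as_tibble(raw)
  if (ncol(raw) < 2L) stop("abundance file needs an id column plus data: ", path)

  id_col <- names(raw)[1L]
  label_col <- NULL
  if (orientation == "samples" && length(labels) == 1L &&
      is.character(labels) && labels %in% names(raw)) {
    label_col <- labels
  }

  body_cols <- setdiff(names(raw), c(id_col, label_col))
  body <- raw[body_cols]
  # fail on the first non-numeric cell, naming its position
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(parsed) & !is.na(col))
      if (length(bad) > 0L) {
        stop("non-numeric entry in column '", body_cols[j], "', row ",
             bad[1L], " ('", col[bad[1L]], "')")
      }
      body[[j]] <- parsed
    }
    if (anyNA(body[[j]])) {
      stop("missing value in column '", body_cols[j], "', row ",
           which(is.na(body[[j]]))[1L])
    }
  }
  values <- as.matrix(body)

  if (orientation == "features") {
    rn <- as.character(raw[[id_col]])
    values <- t(values)
    colnames(values) <- rn
    sample_ids <- body_cols
  } else {
    sample_ids <- as.character(raw[[id_col]])
  }

  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop("negative abundance for sample '", sample_ids[bad[1L]],
         "', feature '", colnames(values)[bad[2L]], "'")
  }

  if (!is.null(label_col)) {
    lab <- as.character(raw[[label_col]])
  } else {
    if (!is.character(labels) || length(labels) != 1L || !file.exists(labels)) {
      stop("`labels` must name a column of the table or an existing ",
           "sample-to-label file")
    }
    ldelim <- if (grepl("\\.csv$", labels)) "," else "\t"
    ltab <- readr::read_delim(labels, delim = ldelim, col_types = readr::cols(),
                              progress = FALSE, show_col_types = FALSE)
    if (ncol(ltab) < 2L) stop("label file needs two columns: ", labels)
    lmap <- stats::setNames(as.character(ltab[[2L]]), as.character(ltab[[1L]]))
    lab <- unname(lmap[sample_ids])
    if (anyNA(lab)) {
      stop("no label for sample(s): ",
           paste(sample_ids[is.na(lab)], collapse = ", "))
    }
  }
  if (length(lab) != nrow(values)) stop("one label per sample is required")

  out <- tibble::as_tibble(as.data.frame(values, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids, label = lab), out)
}

#' Extract the numeric feature matrix from an abundance tibble
#'
#' @param data A tibble as returned by [read_abundance()] or
#'   [simulate_abundance()]: `sample_id`, `label`, then numeric features.
#' @return Numeric matrix (samples x features) with sample ids as rownames.
#' @export
abundance_matrix <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("sample_id", "label") %in% names(data))) {
    stop("expected columns `sample_id` and `label`")
  }
  feats <- setdiff(names(data), c("sample_id", "label"))
  if (length(feats) == 0L) stop("no feature columns present")
  m <- as.matrix(data[feats])
  if (!is.numeric(m)) stop("feature columns must be numeric")
  if (anyNA(m)) stop("missing values are not allowed in the abundance matrix")
  if (any(m < 0)) stop("abundance values must be non-negative")
  rownames(m) <- data$sample_id
  m
}

#' Encode categorical labels as numeric factors
#'
#' Distinct label strings are assigned the integers `1..K` in lexicographic
#' order (the order a stock factor coercion would use), so results are
#' reproducible across runs and platforms.
#'
#' @param labels Character vector, one label per sample.
#' @return A list with `codes` (integer vector) and `map` (named integer
#'   vector, label string to level).
#' @export
encode_labels <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels contain missing values")
  lev <- sort(unique(labels))
  if (length(lev) < 2L) {
    stop("need at least 2 distinct labels, got: ",
         paste(lev, collapse = ", "))
  }
  map <- stats::setNames(seq_along(lev), lev)
  list(codes = unname(map[labels]), map = map)
}

#' Decode numeric label factors back to strings
#'
#' @param codes Integer codes as produced by [encode_labels()].
#' @param map The `map` element returned by [encode_labels()].
#' @return Character vector of label strings.
#' @export
decode_labels <- function(codes, map) {
  inv <- stats::setNames(names(map), map)
  out <- unname(inv[as.character(codes)])
  if (anyNA(out)) stop("codes outside the label map")
  out
}

#' Pre-filter features by random-forest importance
#'
#' Ranks features by the mean-decrease-in-impurity importance of a
#' classification forest trained on the labels and keeps the top `n_top`
#' (all features, reordered, when fewer are present). Columns are put in a
#' canonical (name) order before the forest is grown so the ranking does
#' not depend on the column order of the input; importance ties are broken
#' by original column order.
#'
#' @param data Abundance tibble (`sample_id`, `label`, features).
#' @param n_top Number of features to keep (default 100).
#' @param n_trees Trees in the forest (default 500).
#' @param seed Integer seed making the forest reproducible.
#' @return The tibble restricted to the selected features, feature columns
#'   ordered by decreasing importance.
#' @export
prefilter_features <- function(data, n_top = 100, n_trees = 500, seed = 1) {
  if (!is.numeric(n_top) || length(n_top) != 1L || n_top < 1) {
    stop("`n_top` must be a single value >= 1")
  }
  m <- abundance_matrix(data)
  enc <- encode_labels(data$label)
  feats <- colnames(m)
  canon <- order(feats)
  rf <- withr::with_seed(as.integer(seed), {
    randomForest::randomForest(
      x = m[, canon, drop = FALSE],
      y = factor(data$label),
      ntree = n_trees
    )
  })
  imp <- rf$importance[, "MeanDecreaseGini"]
  # back to original column order, stable tie-break on that order
  imp_orig <- unname(imp[feats])
  keep <- order(-imp_orig, seq_along(feats))[seq_len(min(n_top, length(feats)))]
  dplyr::bind_cols(
    data[c("sample_id", "label")],
    tibble::as_tibble(as.data.frame(m[, keep, drop = FALSE],
                                    check.names = FALSE))
  )
}

#' Augment the abundance matrix with the numeric label column
#'
#' Appends the numeric label factor as the final column, producing the
#' matrix the fuzzy-inference stage learns from. Stripping the last column
#' recovers the abundance values bit-identically.
#'
#' @param data Abundance tibble (`sample_id`, `label`, features).
#' @return A numeric matrix of shape samples x (features + 1) whose last
#'   column is named `label`; the label string-to-level map is attached as
#'   attribute `label_map`.
#' @export
augment <- function(data) {
  m <- abundance_matrix(data)
  enc <- encode_labels(data$label)
  out <- cbind(m, label = as.numeric(enc$codes))
  attr(out, "label_map") <- enc$map
  class(out) <- c("mb_augmented", class(out))
  out
}

#' Center and scale matrix columns (auto-scaling)
#'
#' Each non-constant column is shifted to mean zero and divided by its
#' sample standard deviation; constant columns are mapped to all-zero
#' columns (with a warning) so downstream column indexing stays stable.
#'
#' @param m Numeric matrix or data frame of numbers.
#' @return Numeric matrix of the same shape and dimnames.
#' @export
autoscale <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0L) stop("cannot autoscale an empty matrix")
  if (!is.numeric(m)) stop("autoscale needs a numeric matrix")
  mu <- colMeans(m)
  sds <- apply(m, 2L, stats::sd)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    warning("constant column(s) scaled to zero: ",
            paste(colnames(m)[const] %||% which(const), collapse = ", "))
    sds[const] <- 1
  }
  out <- sweep(sweep(m, 2L, mu, "-"), 2L, sds, "/")
  out[, const] <- 0
  attributes(out)$dimnames <- dimnames(m)
  out
}
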