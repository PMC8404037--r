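# Collinearity removal: DBSCAN over feature columns of the (auto-scaled)
# rule matrix, epsilon chosen by an aliased-coefficient stopping rule, and
# per-cluster collapse onto the first principal-component loading.

#' DBSCAN clustering of feature columns
#'
#' Features (columns of `x`) are the points, represented by their column
#' vectors over effective samples, under Euclidean distance. Standard
#' core/border/noise labelling; with `minpts = 2` the clusters coincide
#' with the connected components of the eps-neighbourhood graph restricted
#' to non-isolated points, and isolated points are noise.
#'
#' @param x Numeric matrix; columns are clustered.
#' @param eps Neighbourhood radius (> 0).
#' @param minpts Minimum points (including the point itself) within `eps`
#'   for a core point; default 2, the setting used throughout the
#'   pipeline.
#' @return A tibble of class `mb_assignment` with columns `feature` and
#'   `cluster` (positive integer; `0` marks noise); attributes `eps` and
#'   `minpts`.
#' @export
dbscan_features <- function(x, eps, minpts = 2) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0) {
    stop("`eps` must be a single positive number")
  }
  x <- as.matrix(x)
  nm <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  npts <- ncol(x)
  D <- as.matrix(stats::dist(t(x)))
  nb <- lapply(seq_len(npts), function(i) which(D[i, ] <= eps))
  core <- lengths(nb) >= minpts
  labels <- rep(0L, npts)
  cid <- 0L
  for (i in seq_len(npts)) {
    if (labels[i] != 0L || !core[i]) next
    cid <- cid + 1L
    labels[i] <- cid
    frontier <- setdiff(nb[[i]], i)
    while (length(frontier) > 0L) {
      q <- frontier[1L]
      frontier <- frontier[-1L]
      if (labels[q] == 0L) {
        labels[q] <- cid
        if (core[q]) frontier <- union(frontier, nb[[q]][labels[nb[[q]]] == 0L])
      }
    }
  }
  out <- tibble::tibble(feature = nm, cluster = labels)
  attr(out, "eps") <- eps
  attr(out, "minpts") <- minpts
  class(out) <- c("mb_assignment", class(out))
  out
}

#' Collapse feature clusters onto their first principal-component loading
#'
#' Every cluster of columns is replaced by a single linear-combination
#' column: the first principal-component loading vector of the cluster's
#' (centred, unscaled) columns supplies the coefficients. The loading has
#' unit Euclidean norm and its largest-magnitude entry is flipped
#' positive, fixing the sign deterministically. Noise (singleton) features
#' pass through verbatim with loading 1. A cluster of zero-variance
#' columns gets a uniform `1/sqrt(k)` loading with a warning.
#'
#' @param x Numeric matrix whose columns are covered by `assignment`.
#' @param assignment An `mb_assignment` from [dbscan_features()].
#' @return Object of class `mb_clustered`: list with `values` (reduced
#'   matrix), `loadings` (per collapsed column, named coefficient vector),
#'   `provenance` (collapsed column -> original features) and the
#'   `assignment`.
#' @export
collapse_clusters <- function(x, assignment) {
  x <- as.matrix(x)
  nm <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- nm
  if (!all(assignment$feature %in% nm) || nrow(assignment) != ncol(x)) {
    stop("assignment must cover exactly the columns of `x`")
  }
  asg <- assignment$cluster[match(nm, assignment$feature)]
  cols <- list(); loadings <- list(); provenance <- list()
  # noise features keep their column and name, in original order
  for (j in which(asg == 0L)) {
    cols[[nm[j]]] <- x[, j]
    loadings[[nm[j]]] <- stats::setNames(1, nm[j])
    provenance[[nm[j]]] <- nm[j]
  }
  for (cl in sort(unique(asg[asg > 0L]))) {
    members <- nm[asg == cl]
    block <- x[, members, drop = FALSE]
    ctr <- sweep(block, 2L, colMeans(block), "-")
    if (all(abs(ctr) < 1e-12)) {
      warning("cluster ", cl, " has only zero-variance columns; ",
              "using a uniform loading")
      v <- rep(1 / sqrt(length(members)), length(members))
    } else {
      v <- svd(ctr, nu = 0L, nv = 1L)$v[, 1L]
    }
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) v <- -v
    cname <- paste0("cluster_", cl)
    cols[[cname]] <- as.numeric(block %*% v)
    loadings[[cname]] <- stats::setNames(v, members)
    provenance[[cname]] <- members
  }
  values <- do.call(cbind, cols)
  colnames(values) <- names(cols)
  structure(
    list(values = values, loadings = loadings, provenance = provenance,
         assignment = assignment),
    class = "mb_clustered"
  )
}

#' @export
print.mb_clustered <- function(x, ...) {
  ncl <- sum(grepl("^cluster_", colnames(x$values)))
  cat("Clustered matrix: ", nrow(x$values), " effective samples x ",
      ncol(x$values), " columns (", ncl, " collapsed cluster(s))\n", sep = "")
  invisible(x)
}

#' @export
tidy.mb_clustered <- function(x, ...) {
  purrr::imap_dfr(x$loadings, function(ld, cname) {
    tibble::tibble(collapsed = cname, feature = names(ld),
                   loading = unname(ld))
  })
}

#' Detect columns aliased with (linearly dependent on) earlier columns
#'
#' Sequential rank-revealing orthogonalisation: column `j` is flagged when
#' its residual after projection onto the span of the preceding unflagged
#' columns falls below `tol` times the largest column magnitude seen so
#' far. This is the mechanism by which a GLM fit reports `NA`
#' coefficients, made deterministic and family-independent; the result is
#' the empty set exactly when the design has full column rank.
#'
#' @param design Numeric matrix (include the intercept column if the
#'   downstream model has one).
#' @param tol Relative pivot threshold (default `1e-7`).
#' @return Integer vector of aliased column indices (possibly empty).
#' @export
detect_aliased_columns <- function(design, tol = 1e-7) {
  design <- as.matrix(design)
  if (nrow(design) < 1L) stop("`design` needs at least one row")
  basis <- matrix(0, nrow(design), 0L)
  aliased <- integer(0)
  max_norm <- 0
  for (j in seq_len(ncol(design))) {
    v <- design[, j]
    max_norm <- max(max_norm, sqrt(sum(v^2)))
    if (ncol(basis) > 0L) {
      for (rep in 1:2) v <- v - basis %*% crossprod(basis, v)  # re-orthogonalise
    }
    rn <- sqrt(sum(v^2))
    if (rn <= tol * max_norm) {
      aliased <- c(aliased, j)
    } else {
      basis <- cbind(basis, v / rn)
    }
  }
  aliased
}

#' Select the DBSCAN epsilon by the aliased-coefficient stopping rule
#'
#' Walks an ascending epsilon grid (default: 1 to the maximum entry of the
#' integer rule matrix, step 0.5). At each value the feature columns are
#' clustered and collapsed, and the resulting design (with intercept) is
#' checked for aliased columns; the first epsilon whose design has full
#' column rank is selected. If no grid value qualifies the final one is
#' returned with a warning. A (multinomial when more than two classes)
#' logistic regression of the labels on the selected clustered matrix is
#' fitted once at the accepted epsilon and returned for diagnostics.
#'
#' @param x An `mb_inferred` object (its auto-scaled feature columns are
#'   clustered and its maximum integer entry bounds the default grid), or
#'   a plain numeric matrix of feature columns.
#' @param labels Outcome per effective sample; defaults to the
#'   `effective_label` column when `x` is an `mb_inferred`.
#' @param grid Ascending numeric vector of candidate epsilon values;
#'   default `seq(1, max_entry, by = 0.5)`.
#' @param minpts DBSCAN minimum points (default 2).
#' @param fit_final Fit the diagnostic logistic model at the selected
#'   epsilon (default TRUE).
#' @return Object of class `mb_eps`: list with `eps`, `assignment`,
#'   `clustered`, `trace` (tibble of eps, cluster and aliased counts),
#'   `converged` and `model`.
#' @export
select_epsilon <- function(x, labels = NULL, grid = NULL, minpts = 2,
                           fit_final = TRUE) {
  if (inherits(x, "mb_inferred")) {
    feat_cols <- setdiff(colnames(x$values), "effective_label")
    S <- x$scaled[, feat_cols, drop = FALSE]
    max_entry <- max(x$values)
    if (is.null(labels)) labels <- x$values[, "effective_label"]
  } else {
    S <- as.matrix(x)
    max_entry <- max(S)
  }
  if (is.null(grid)) grid <- seq(1, max(1, max_entry), by = 0.5)
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) == 0L) stop("epsilon grid is empty")

  trace <- vector("list", length(grid))
  converged <- FALSE
  assignment <- NULL; clustered <- NULL; eps_sel <- NA_real_
  for (k in seq_along(grid)) {
    eps <- grid[k]
    assignment <- dbscan_features(S, eps = eps, minpts = minpts)
    clustered <- collapse_clusters(S, assignment)
    design <- cbind(`(Intercept)` = 1, clustered$values)
    aliased <- detect_aliased_columns(design)
    trace[[k]] <- tibble::tibble(
      eps = eps,
      n_clusters = length(unique(assignment$cluster[assignment$cluster > 0L])),
      n_noise = sum(assignment$cluster == 0L),
      n_aliased = length(aliased)
    )
    eps_sel <- eps
    if (length(aliased) == 0L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("no epsilon on the grid removed all aliased coefficients; ",
            "returning the final grid value ", eps_sel)
  }

  model <- NULL
  if (fit_final && !is.null(labels)) {
    yf <- factor(labels)
    df <- as.data.frame(clustered$values, check.names = TRUE)
    if (nlevels(yf) == 2L) {
      model <- suppressWarnings(
        stats::glm(yf ~ ., data = cbind(yf = yf, df), family = stats::binomial())
      )
    } else {
      model <- nnet::multinom(yf ~ ., data = cbind(yf = yf, df), trace = FALSE)
    }
  }
  structure(
    list(eps = eps_sel, assignment = assignment, clustered = clustered,
         trace = dplyr::bind_rows(trace[!vapply(trace, is.null, TRUE)]),
         converged = converged, model = model),
    class = "mb_eps"
  )
}

#' @export
print.mb_eps <- function(x, ...) {
  cat("Selected eps = ", x$eps,
      if (!x$converged) " (grid exhausted, aliasing unresolved)" else "",
      "; ", max(x$trace$n_clusters[x$trace$eps == x$eps]), " cluster(s)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.mb_eps <- function(x, ...) {
  dplyr::mutate(x$assignment, eps = x$eps)
}

#' @export
glance.mb_eps <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(eps = x$eps, n_clusters = last$n_clusters,
                 n_noise = last$n_noise, converged = x$converged)
}
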