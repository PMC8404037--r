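# Adaptive-LASSO prioritisation: pilot GLM weights, weighted L1 solve via
# the rescaling trick on glmnet, and back-distribution of cluster scores
# to features through the first-PC loadings.

#' Pilot GLM weights for the adaptive LASSO
#'
#' Fits an unpenalised linear-link model of `y` on the (auto-scaled)
#' design and returns the absolute coefficients. A singular or too-wide
#' system (`p >= n`, or exact collinearity) falls back to a tiny-ridge
#' solve with a warning. Near-zero coefficients are floored at `floor` so
#' the adaptive rescaling stays finite.
#'
#' @param X Auto-scaled numeric matrix (more than one row).
#' @param y Numeric response.
#' @param floor Lower bound applied to the absolute coefficients
#'   (default `1e-6`).
#' @return Named positive weight vector, one entry per column of `X`.
#' @export
glm_weights <- function(X, y, floor = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= 1L) stop("need more than one row to fit pilot weights")
  if (length(y) != n) stop("`y` must match the rows of `X`")
  beta <- NULL
  if (p < n) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    cf <- fit$coefficients[-1L]
    if (!anyNA(cf)) beta <- cf
  }
  if (is.null(beta)) {
    warning("singular or wide pilot system; using a tiny-ridge fit")
    Xc <- sweep(X, 2L, colMeans(X), "-")
    yc <- y - mean(y)
    eps <- 1e-6 * (mean(diag(crossprod(Xc))) + 1e-12)
    beta <- as.numeric(solve(crossprod(Xc) + diag(eps, p), crossprod(Xc, yc)))
  }
  w <- pmax(abs(beta), floor)
  stats::setNames(as.numeric(w), colnames(X))
}

#' Adaptive LASSO cluster scores
#'
#' Solves `argmin_b ||y - X b||^2 + lambda * sum_j w_j |b_j|` by the
#' rescaling trick: a plain LASSO is fitted to `x_j / w_j` and the
#' coefficients are mapped back as `b_j = b~_j / w_j`. With `lambda =
#' NULL` the penalty is chosen by k-fold cross-validation at the
#' minimum-CV-error value, with a seeded fold assignment. The quadratic
#' term carries no 1/2 factor, matching the objective as displayed; the
#' `lambda` reported and accepted here is on that scale.
#'
#' @param X Numeric design matrix (auto-scaled columns).
#' @param y Numeric response (centred upstream; the model has no
#'   intercept, consistent with the objective).
#' @param w Positive weight vector, one per column.
#' @param k_folds Cross-validation folds (default 10); must be in
#'   `[2, n]`.
#' @param seed Integer seed for the fold assignment.
#' @param lambda Optional fixed penalty (objective scale); skips CV.
#' @return Object of class `mb_adlasso`: list with `beta` (named cluster
#'   scores), `lambda` (objective scale), `weights`, and the `cv` fit
#'   when CV was used.
#' @export
adaptive_lasso <- function(X, y, w, k_folds = 10, seed = 1, lambda = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(w) != p) stop("`w` must have one entry per column of `X`")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  Xs <- sweep(X, 2L, w, "/")
  if (is.null(lambda)) {
    if (k_folds < 2 || k_folds > n) {
      stop("`k_folds` must be between 2 and the number of rows")
    }
    foldid <- withr::with_seed(as.integer(seed),
                               sample(rep_len(seq_len(k_folds), n)))
    cv <- glmnet::cv.glmnet(Xs, y, foldid = foldid, standardize = FALSE,
                            intercept = FALSE, thresh = 1e-12)
    lam_g <- cv$lambda.min
    bt <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  } else {
    if (!is.numeric(lambda) || lambda < 0) stop("`lambda` must be >= 0")
    cv <- NULL
    lam_g <- lambda / (2 * n)  # objective scale -> glmnet scale
    path <- sort(unique(c(lam_g * c(64, 16, 4), lam_g)), decreasing = TRUE)
    if (lam_g == 0) path <- c(1e-3, 1e-5, 0)
    fit <- glmnet::glmnet(Xs, y, lambda = path, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-14, maxit = 1e7)
    # exact = TRUE refits at s; the approx() collapse warning from the
    # path lookup is cosmetic
    bt <- suppressWarnings(as.numeric(
      stats::coef(fit, s = lam_g, exact = TRUE, x = Xs, y = y,
                  standardize = FALSE, intercept = FALSE,
                  thresh = 1e-14, maxit = 1e7)
    ))[-1L]
  }
  beta <- bt / w
  structure(
    list(beta = stats::setNames(beta, colnames(X)),
         lambda = 2 * n * lam_g, lambda_glmnet = lam_g,
         weights = w, cv = cv),
    class = "mb_adlasso"
  )
}

#' @export
print.mb_adlasso <- function(x, ...) {
  cat("Adaptive LASSO: ", sum(x$beta != 0), " of ", length(x$beta),
      " coefficients non-zero; lambda = ", format(x$lambda), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mb_adlasso <- function(x, ...) {
  tibble::tibble(term = names(x$beta) %||% paste0("V", seq_along(x$beta)),
                 estimate = unname(x$beta), weight = unname(x$weights))
}

#' @export
glance.mb_adlasso <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_nonzero = sum(x$beta != 0),
                 n_terms = length(x$beta))
}

#' Distribute cluster scores to per-feature scores
#'
#' Every original feature receives `cluster_score * loading`; singleton
#' (noise) features carry loading 1 and so inherit their cluster score
#' unchanged.
#'
#' @param cluster_scores Named numeric vector of scores, one per collapsed
#'   column of the clustered matrix.
#' @param clustered `mb_clustered` object supplying loadings/provenance.
#' @return Tibble with `feature`, `collapsed`, `loading`, `cluster_score`
#'   and `feature_score`.
#' @export
feature_scores <- function(cluster_scores, clustered) {
  stopifnot(inherits(clustered, "mb_clustered"))
  cn <- names(cluster_scores)
  if (is.null(cn) || !all(names(clustered$provenance) %in% cn)) {
    stop("`cluster_scores` must be named for every collapsed column")
  }
  purrr::imap_dfr(clustered$provenance, function(members, cname) {
    ld <- clustered$loadings[[cname]]
    missing <- setdiff(members, names(ld))
    if (length(missing) > 0L) {
      stop("no loading recorded for feature(s): ",
           paste(missing, collapse = ", "))
    }
    cs <- unname(cluster_scores[[cname]])
    tibble::tibble(
      feature = members, collapsed = cname,
      loading = unname(ld[members]),
      cluster_score = cs,
      feature_score = cs * unname(ld[members])
    )
  })
}

#' Moment summaries of a score distribution
#'
#' Moment-based (non-excess) estimators: skewness `m3 / m2^(3/2)` and
#' kurtosis `m4 / m2^2`, with the usual sample variance. A constant score
#' vector reports skewness and kurtosis 0 with a warning.
#'
#' @param scores Numeric vector of at least 3 scores.
#' @return One-row tibble: `skewness`, `kurtosis`, `variance`, `min`,
#'   `max`.
#' @export
score_summary <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 3L) stop("need at least 3 scores")
  m <- mean(scores)
  m2 <- mean((scores - m)^2)
  if (m2 <= 0) {
    warning("constant scores; skewness and kurtosis reported as 0")
    sk <- 0; ku <- 0
  } else {
    sk <- mean((scores - m)^3) / m2^1.5
    ku <- mean((scores - m)^4) / m2^2
  }
  tibble::tibble(skewness = sk, kurtosis = ku,
                 variance = stats::var(scores),
                 min = min(scores), max = max(scores))
}

#' Score the features of a clustered matrix
#'
#' Convenience wrapper running the whole scoring stage: auto-scales the
#' clustered matrix, derives pilot GLM weights, fits the adaptive LASSO
#' (CV-selected penalty) against the effective-label response, and
#' distributes the cluster scores to features.
#'
#' @param clustered `mb_clustered` object from [collapse_clusters()] /
#'   [select_epsilon()].
#' @param y Numeric response per effective sample (the scaled
#'   effective-label column in the pipeline).
#' @param k_folds,seed Passed to [adaptive_lasso()].
#' @return A tibble of class `mb_scores` (the [feature_scores()] table)
#'   with attributes `summary`, `lambda` and `fit`.
#' @export
score_features <- function(clustered, y, k_folds = 10, seed = 1) {
  stopifnot(inherits(clustered, "mb_clustered"))
  X <- suppressWarnings(autoscale(clustered$values))
  yc <- as.numeric(scale(y))
  if (anyNA(yc)) yc <- y - mean(y)  # constant response guard
  w <- glm_weights(X, yc)
  fit <- adaptive_lasso(X, yc, w, k_folds = k_folds, seed = seed)
  out <- feature_scores(fit$beta, clustered)
  attr(out, "summary") <- score_summary(out$feature_score)
  attr(out, "lambda") <- fit$lambda
  attr(out, "fit") <- fit
  class(out) <- c("mb_scores", class(out))
  out
}
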