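#' @importFrom rlang %||%
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# coerce an augmented object / matrix to a plain numeric matrix whose last
# column is the numeric label
aug_values <- function(m) {
  if (inherits(m, "mb_augmented")) {
    cls <- class(m)
    class(m) <- setdiff(cls, "mb_augmented")
  }
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("expected a numeric (augmented) matrix")
  if (ncol(m) < 2L) stop("augmented matrix needs at least one feature column")
  m
}

#' @export
tidy.mb_scores <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.mb_scores <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(
    skewness = s$skewness, kurtosis = s$kurtosis, variance = s$variance,
    min = s$min, max = s$max, lambda = attr(x, "lambda") %||% NA_real_
  )
}
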