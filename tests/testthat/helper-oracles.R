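# Independent oracles used to cross-check the implementation paths.

# Connected components of the eps-neighbourhood graph on non-isolated
# points (union-find); isolated points labelled 0. With minpts = 2 this is
# what DBSCAN must produce.
uf_dbscan_oracle <- function(x, eps) {
  D <- as.matrix(stats::dist(t(x)))
  npts <- ncol(x)
  parent <- seq_len(npts)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (npts > 1L) {
    for (i in seq_len(npts - 1L)) {
      for (j in (i + 1L):npts) {
        if (D[i, j] <= eps) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(npts), find, 1L)
  isolated <- vapply(seq_len(npts), function(i) {
    sum(D[i, ] <= eps) < 2L  # only itself within eps
  }, TRUE)
  labels <- rep(0L, npts)
  nz <- which(!isolated)
  labels[nz] <- as.integer(factor(roots[nz], levels = unique(roots[nz])))
  labels
}

# TRUE when two cluster labelings describe the same partition (same noise
# set, same co-membership structure)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  keep <- a > 0L
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0L) return(TRUE)
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# Coordinate descent on ||y - X b||^2 + lambda * sum_j w_j |b_j| (no
# intercept, objective exactly as displayed: no 1/2, no 1/n).
cd_adaptive_lasso <- function(X, y, w, lambda, tol = 1e-13,
                              max_iter = 100000L) {
  p <- ncol(X)
  beta <- rep(0, p)
  xx <- colSums(X^2)
  r <- y
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (xx[j] == 0) next
      zj <- sum(X[, j] * r) + xx[j] * beta[j]
      bj <- soft(zj, lambda * w[j] / 2) / xx[j]
      if (bj != beta[j]) {
        r <- r - X[, j] * (bj - beta[j])
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    if (delta < tol) break
  }
  beta
}

# Maximum KKT violation of the displayed objective at beta
kkt_violation <- function(X, y, beta, w, lambda) {
  g <- -2 * as.numeric(crossprod(X, y - X %*% beta))
  viol <- ifelse(
    beta != 0,
    abs(g + lambda * w * sign(beta)),
    pmax(0, abs(g) - lambda * w)
  )
  max(viol)
}

# Random matrix with exactly orthonormal columns
rand_orthonormal <- function(n, p) {
  qr.Q(qr(matrix(stats::rnorm(n * p), n)))[, seq_len(p), drop = FALSE]
}

# Small abundance tibble built in code
toy_abundance <- function(n = 12, p = 4, labels = NULL, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * p, 20), n, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    lab <- labels %||% rep_len(c("HC", "UC"), n)
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("S%02d", seq_len(n)), label = lab),
      tibble::as_tibble(as.data.frame(m))
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
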