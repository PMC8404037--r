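# Takagi-Sugeno fuzzy inference on a label-augmented abundance matrix.
#
# The premise side uses Gaussian membership functions placed on an equal
# grid over each column's observed range; rules are generated one per
# training sample (argmax-membership term per variable) and de-duplicated
# by antecedent, so the rule count never exceeds the sample count. The
# consequent side is first-order linear, solved globally by least squares;
# premise parameters take damped gradient steps between solves.

# adjacent Gaussians with this width cross at membership 0.5
.mf_width_factor <- 1 / (2 * sqrt(2 * log(2)))

#' Build Gaussian fuzzy variables for every column of an augmented matrix
#'
#' For each column, `num_labels` Gaussian terms are placed with means
#' equally spaced across the observed `[min, max]`; the common standard
#' deviation is chosen so adjacent terms cross at membership 0.5. Constant
#' columns get a single degenerate term with membership 1 everywhere.
#'
#' @param m Augmented matrix ([augment()]) or any numeric matrix.
#' @param num_labels Number of linguistic terms per variable (>= 2,
#'   default 7).
#' @param width_factor Multiplier of the term spacing giving the Gaussian
#'   sigma; the default makes adjacent terms cross at 0.5.
#' @return A list of fuzzy variables, each a list with `name`, `means`,
#'   `sigmas`, `domain` and `degenerate`.
#' @export
build_fuzzy_variables <- function(m, num_labels = 7,
                                  width_factor = .mf_width_factor) {
  if (!is.numeric(num_labels) || num_labels < 2) {
    stop("`num_labels` must be at least 2")
  }
  num_labels <- as.integer(num_labels)
  m <- aug_values(m)
  nm <- colnames(m) %||% paste0("V", seq_len(ncol(m)))
  lapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    lo <- min(x); hi <- max(x)
    if (hi > lo) {
      means <- seq(lo, hi, length.out = num_labels)
      spacing <- (hi - lo) / (num_labels - 1)
      list(name = nm[j], means = means,
           sigmas = rep(spacing * width_factor, num_labels),
           domain = c(lo, hi), degenerate = FALSE)
    } else {
      list(name = nm[j], means = lo, sigmas = 1,
           domain = c(lo, hi), degenerate = TRUE)
    }
  })
}

# n x n_terms matrix of log Gaussian memberships of x under variable v
log_membership <- function(v, x) {
  if (isTRUE(v$degenerate)) {
    return(matrix(0, nrow = length(x), ncol = 1L))
  }
  d <- outer(x, v$means, "-")
  -(d * d) / (2 * rep(v$sigmas^2, each = length(x)))
}

#' Membership of values in one term of a fuzzy variable
#'
#' @param v A fuzzy variable from [build_fuzzy_variables()].
#' @param x Numeric vector of values.
#' @param term Term index.
#' @return Membership degrees in `(0, 1]`.
#' @export
membership <- function(v, x, term) {
  exp(log_membership(v, x)[, term])
}

#' Generate fuzzy rules from training samples (Wang-Mendel style)
#'
#' Each training sample proposes one candidate rule: for every variable the
#' maximum-membership term is selected (ties resolved to the lower term
#' index) and the candidate's degree is the product of those memberships.
#' Candidates sharing an antecedent -- including those that would disagree
#' on the output term -- are collapsed, keeping the candidate of highest
#' degree. The surviving rule count therefore never exceeds the sample
#' count, and duplicated samples strictly reduce it.
#'
#' @param m Augmented matrix; the final column is the output variable.
#' @param vars Fuzzy variables covering all columns of `m`.
#' @return A list with `antecedents` (rules x inputs integer matrix),
#'   `out_terms` (integer vector) and `log_degree` (numeric vector).
#' @export
generate_rules <- function(m, vars) {
  m <- aug_values(m)
  n <- nrow(m)
  if (n == 0L) stop("cannot generate rules from an empty matrix")
  if (length(vars) != ncol(m)) stop("`vars` must cover all columns of `m`")
  p_all <- ncol(m)
  terms <- matrix(0L, n, p_all)
  logdeg <- numeric(n)
  for (j in seq_len(p_all)) {
    lm_j <- log_membership(vars[[j]], m[, j])
    t_j <- max.col(lm_j, ties.method = "first")
    terms[, j] <- t_j
    logdeg <- logdeg + lm_j[cbind(seq_len(n), t_j)]
  }
  ant <- terms[, -p_all, drop = FALSE]
  key <- apply(ant, 1L, paste, collapse = ",")
  ord <- order(key, -logdeg, seq_len(n))  # best degree first within key
  keep <- ord[!duplicated(key[ord])]
  keep <- sort(keep)  # stable: first-occurrence order of winners
  colnames(ant) <- vapply(vars[-p_all], `[[`, "", "name")
  list(
    antecedents = ant[keep, , drop = FALSE],
    out_terms = terms[keep, p_all],
    log_degree = logdeg[keep]
  )
}

# log firing strengths: n x R matrix, rule r = sum_j log mu_{j, ant[r, j]}(x_j)
rule_log_firing <- function(vars_in, antecedents, X) {
  n <- nrow(X)
  R <- nrow(antecedents)
  p <- ncol(X)
  logw <- matrix(0, n, R)
  for (j in seq_len(p)) {
    lm_j <- log_membership(vars_in[[j]], X[, j])
    logw <- logw + lm_j[, antecedents[, j], drop = FALSE]
  }
  logw
}

# row-normalised firing strengths, stable under extreme underflow
normalise_firing <- function(logw) {
  shift <- apply(logw, 1L, max)
  w <- exp(logw - shift)
  w / rowSums(w)
}

new_anfis <- function(vars_in, out_var, rules, consequents, num_labels,
                      label_map = NULL) {
  structure(
    list(vars = vars_in, out_var = out_var, rules = rules,
         consequents = consequents, num_labels = num_labels,
         label_map = label_map, history = list(rmse = numeric())),
    class = "anfis"
  )
}

#' Fit a Takagi-Sugeno fuzzy system to an augmented matrix
#'
#' Builds fuzzy variables over all columns, generates and de-duplicates
#' rules, then runs hybrid learning ([hybrid_learn()]).
#'
#' @param m Augmented matrix from [augment()] (last column = numeric
#'   label).
#' @param num_labels Terms per variable (default 7).
#' @param max_iter Hybrid-learning passes (default 10).
#' @param step_size Premise gradient step (default 0.01).
#' @return An object of class `anfis`.
#' @export
fit_anfis <- function(m, num_labels = 7, max_iter = 10, step_size = 0.01) {
  vals <- aug_values(m)
  vars <- build_fuzzy_variables(vals, num_labels = num_labels)
  rules <- generate_rules(vals, vars)
  p <- ncol(vals) - 1L
  model <- new_anfis(
    vars_in = vars[seq_len(p)], out_var = vars[[p + 1L]], rules = rules,
    consequents = matrix(0, nrow(rules$antecedents), p + 1L),
    num_labels = as.integer(num_labels),
    label_map = attr(m, "label_map")
  )
  hybrid_learn(model, vals, max_iter = max_iter, step_size = step_size)
}

#' Hybrid least-squares / gradient learning for a Takagi-Sugeno model
#'
#' Alternates (1) a global linear least-squares solve for all first-order
#' consequent coefficients on the rule-normalised firing strengths and (2)
#' one damped gradient step on the premise means and sigmas. A premise
#' step is only accepted if it does not increase the training SSE (step
#' halving, up to 8 times), and every least-squares pass is optimal for
#' the current premise, so the SSE recorded after successive passes is
#' non-increasing. A singular least-squares system falls back to a
#' ridge-stabilised solve with a tiny regulariser (warning).
#'
#' @param model An `anfis` object with at least one rule.
#' @param m The augmented training matrix.
#' @param max_iter Number of least-squares passes (default 10).
#' @param step_size Gradient step length in normalised parameter space
#'   (default 0.01).
#' @return The trained `anfis` model; `history$rmse` holds the RMSE after
#'   each least-squares pass.
#' @export
hybrid_learn <- function(model, m, max_iter = 10, step_size = 0.01) {
  stopifnot(inherits(model, "anfis"))
  vals <- aug_values(m)
  p <- ncol(vals) - 1L
  X <- vals[, seq_len(p), drop = FALSE]
  y <- vals[, p + 1L]
  n <- nrow(X)
  R <- nrow(model$rules$antecedents)
  if (R < 1L) stop("model has no rules")
  Xa <- cbind(X, 1)
  rmse <- numeric(0)

  solve_consequents <- function(Wbar) {
    # design: n x R(p+1); block r is Wbar[, r] * [X, 1]
    D <- matrix(0, n, R * (p + 1L))
    for (r in seq_len(R)) {
      D[, ((r - 1L) * (p + 1L) + 1L):(r * (p + 1L))] <- Wbar[, r] * Xa
    }
    coefs <- NULL
    if (ncol(D) <= n) {
      qrD <- qr(D)
      if (qrD$rank == ncol(D)) coefs <- qr.coef(qrD, y)
    }
    if (is.null(coefs) || anyNA(coefs)) {
      warning("singular consequent system; using ridge-stabilised solve")
      eps <- 1e-8 * (mean(colSums(D^2)) + 1e-12)
      if (ncol(D) <= n) {
        coefs <- solve(crossprod(D) + diag(eps, ncol(D)), crossprod(D, y))
      } else {
        coefs <- crossprod(D, solve(tcrossprod(D) + diag(eps, n), y))
      }
      coefs <- as.numeric(coefs)
    }
    list(B = matrix(coefs, nrow = R, ncol = p + 1L, byrow = TRUE),
         fitted = as.numeric(D %*% coefs))
  }

  sse_for <- function(vars_in, B) {
    logw <- rule_log_firing(vars_in, model$rules$antecedents, X)
    Wbar <- normalise_firing(logw)
    Fmat <- Xa %*% t(B)
    yhat <- rowSums(Wbar * Fmat)
    sum((yhat - y)^2)
  }

  for (it in seq_len(max_iter)) {
    logw <- rule_log_firing(model$vars, model$rules$antecedents, X)
    Wbar <- normalise_firing(logw)
    sol <- solve_consequents(Wbar)
    model$consequents <- sol$B
    sse <- sum((sol$fitted - y)^2)
    rmse <- c(rmse, sqrt(sse / n))

    if (it == max_iter || step_size <= 0) next

    # gradient of SSE w.r.t. premise means and sigmas
    Fmat <- Xa %*% t(model$consequents)
    yhat <- rowSums(Wbar * Fmat)
    err <- yhat - y
    G <- 2 * err * Wbar * (Fmat - yhat)   # dSSE / d log w_{ir}
    grads <- vector("list", p)
    gnorm2 <- 0
    for (j in seq_len(p)) {
      v <- model$vars[[j]]
      if (isTRUE(v$degenerate)) { grads[[j]] <- NULL; next }
      Tn <- length(v$means)
      gm <- numeric(Tn); gs <- numeric(Tn)
      ant_j <- model$rules$antecedents[, j]
      for (t in unique(ant_j)) {
        rs <- which(ant_j == t)
        gsum <- rowSums(G[, rs, drop = FALSE])
        dx <- X[, j] - v$means[t]
        gm[t] <- sum(gsum * dx / v$sigmas[t]^2)
        gs[t] <- sum(gsum * dx^2 / v$sigmas[t]^3)
      }
      grads[[j]] <- list(gm = gm, gs = gs)
      gnorm2 <- gnorm2 + sum(gm^2) + sum(gs^2)
    }
    gnorm <- sqrt(gnorm2)
    if (gnorm <= 0 || !is.finite(gnorm)) next

    step <- step_size
    sse_ref <- sse
    for (half in 1:8) {
      cand <- model$vars
      for (j in seq_len(p)) {
        if (is.null(grads[[j]])) next
        cand[[j]]$means <- cand[[j]]$means - step * grads[[j]]$gm / gnorm
        cand[[j]]$sigmas <- pmax(cand[[j]]$sigmas -
                                   step * grads[[j]]$gs / gnorm, 1e-8)
      }
      if (sse_for(cand, model$consequents) <= sse_ref + 1e-12) {
        model$vars <- cand
        break
      }
      step <- step / 2
    }
  }
  model$history$rmse <- rmse
  model
}

#' Predict with a fitted Takagi-Sugeno model
#'
#' Weighted-average defuzzification: the output is the firing-strength
#' weighted mean of the rules' first-order linear consequents. Firing
#' strengths are normalised in log space, so the prediction is invariant
#' to rescaling all strengths by a constant; should every rule's absolute
#' strength fall below `1e-300`, the consequent of the nearest rule (by
#' antecedent-mean distance) is used and a warning is raised.
#'
#' @param object Fitted `anfis` model.
#' @param newdata Numeric matrix or data frame of inputs (one column per
#'   input variable), or a single input vector.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.anfis <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  X <- as.matrix(newdata)
  p <- length(object$vars)
  if (ncol(X) != p) stop("`newdata` must have ", p, " columns")
  logw <- rule_log_firing(object$vars, object$rules$antecedents, X)
  Xa <- cbind(X, 1)
  Fmat <- Xa %*% t(object$consequents)
  out <- numeric(nrow(X))
  degenerate <- apply(logw, 1L, max) < log(1e-300)
  if (any(degenerate)) {
    warning("all firing strengths below 1e-300 for ", sum(degenerate),
            " input(s); using nearest rule")
    centres <- rule_centres(object)
    for (i in which(degenerate)) {
      d2 <- rowSums(sweep(centres, 2L, X[i, ], "-")^2)
      out[i] <- Fmat[i, which.min(d2)]
    }
  }
  ok <- !degenerate
  if (any(ok)) {
    Wbar <- normalise_firing(logw[ok, , drop = FALSE])
    out[ok] <- rowSums(Wbar * Fmat[ok, , drop = FALSE])
  }
  out
}

# rules x inputs matrix of antecedent term means
rule_centres <- function(model) {
  ant <- model$rules$antecedents
  out <- matrix(0, nrow(ant), ncol(ant))
  for (j in seq_len(ncol(ant))) {
    out[, j] <- model$vars[[j]]$means[ant[, j]]
  }
  out
}

#' Extract the integer rule matrix ("inferred matrix") from a model
#'
#' One row per rule; entry `(r, j)` is the antecedent term index of input
#' variable `j`, and the final `effective_label` column holds the output
#' variable's term index. Rows are the "effective samples" that replace
#' the original samples downstream. An auto-scaled copy of the matrix is
#' carried alongside for distance computations.
#'
#' @param model Fitted `anfis` model.
#' @return An object of class `mb_inferred`: list with `values` (integer
#'   matrix, entries in `1..num_labels`), `scaled` (auto-scaled copy) and
#'   `num_labels`.
#' @export
extract_inferred_matrix <- function(model) {
  stopifnot(inherits(model, "anfis"))
  vals <- cbind(model$rules$antecedents, model$rules$out_terms)
  colnames(vals) <- c(colnames(model$rules$antecedents), "effective_label")
  rownames(vals) <- paste0("rule_", seq_len(nrow(vals)))
  storage.mode(vals) <- "integer"
  scaled <- suppressWarnings(autoscale(vals))
  structure(
    list(values = vals, scaled = scaled, num_labels = model$num_labels,
         label_map = model$label_map),
    class = "mb_inferred"
  )
}

#' @export
print.mb_inferred <- function(x, ...) {
  cat("Inferred rule matrix: ", nrow(x$values), " effective samples x ",
      ncol(x$values) - 1L, " effective features (+ effective_label)\n",
      sep = "")
  invisible(x)
}

#' @export
print.anfis <- function(x, ...) {
  cat("Takagi-Sugeno fuzzy system: ", length(x$vars), " inputs, ",
      nrow(x$rules$antecedents), " rules, ", x$num_labels,
      " terms per variable\n", sep = "")
  if (length(x$history$rmse)) {
    cat("final training RMSE: ", format(utils::tail(x$history$rmse, 1)), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
tidy.anfis <- function(x, ...) {
  inf <- extract_inferred_matrix(x)
  out <- tibble::as_tibble(as.data.frame(inf$values, check.names = FALSE))
  dplyr::bind_cols(
    tibble::tibble(rule = seq_len(nrow(out)),
                   log_degree = x$rules$log_degree),
    out
  )
}

#' @export
glance.anfis <- function(x, ...) {
  tibble::tibble(
    n_rules = nrow(x$rules$antecedents),
    n_inputs = length(x$vars),
    num_labels = x$num_labels,
    rmse = if (length(x$history$rmse)) utils::tail(x$history$rmse, 1) else NA_real_,
    passes = length(x$history$rmse)
  )
}

#' Correlation preservation between two feature matrices
#'
#' Computes the Pearson correlation matrix of each input (columns matched
#' by name when both are named) and returns the elementwise absolute
#' difference plus its maximum over off-diagonal entries -- the summary
#' used to check that the rule-matrix conversion conserves the correlation
#' structure of the abundance matrix. Correlations involving constant
#' columns are treated as zero, with a warning.
#'
#' @param before,after Numeric matrices sharing feature columns; at least
#'   3 rows each (rows may differ between the two).
#' @return List with `max_abs_diff` and the symmetric `diff_matrix`.
#' @export
correlation_preservation <- function(before, after) {
  before <- as.matrix(before); after <- as.matrix(after)
  if (nrow(before) < 3L || nrow(after) < 3L) {
    stop("need at least 3 rows in each matrix")
  }
  if (!is.null(colnames(before)) && !is.null(colnames(after))) {
    shared <- intersect(colnames(before), colnames(after))
    if (length(shared) < 2L) stop("matrices share fewer than 2 feature columns")
    before <- before[, shared, drop = FALSE]
    after <- after[, shared, drop = FALSE]
  } else if (ncol(before) != ncol(after)) {
    stop("unnamed matrices must have the same number of columns")
  }
  corr0 <- function(m) {
    cc <- suppressWarnings(stats::cor(m))
    if (anyNA(cc)) {
      warning("constant column(s); their correlations treated as 0")
      cc[is.na(cc)] <- 0
      diag(cc) <- 1
    }
    cc
  }
  d <- abs(corr0(before) - corr0(after))
  diag(d) <- 0
  list(max_abs_diff = if (ncol(d) > 1L) max(d[upper.tri(d)]) else 0,
       diff_matrix = d)
}
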