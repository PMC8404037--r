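test_that("fuzzy variables place equally spaced Gaussians that cross at 0.5", {
  m <- cbind(x = c(0, 3, 6), y = c(1, 2, 3))
  vars <- build_fuzzy_variables(m, num_labels = 7)
  expect_equal(vars[[1]]$means, 0:6)
  # peak membership is exactly 1
  expect_equal(membership(vars[[1]], 4, term = 5), 1)
  # adjacent terms have equal membership 0.5 at the midpoint
  mid <- (vars[[1]]$means[3] + vars[[1]]$means[4]) / 2
  expect_equal(membership(vars[[1]], mid, term = 3), 0.5, tolerance = 1e-12)
  expect_equal(membership(vars[[1]], mid, term = 3),
               membership(vars[[1]], mid, term = 4), tolerance = 1e-12)
  expect_error(build_fuzzy_variables(m, num_labels = 1), "at least 2")

  # constant column degenerates to a single always-on term
  mc <- cbind(a = c(1, 2, 3), b = c(4, 4, 4))
  vc <- build_fuzzy_variables(mc, num_labels = 3)
  expect_true(vc[[2]]$degenerate)
  expect_equal(membership(vc[[2]], c(-5, 4, 50), term = 1), c(1, 1, 1))
})

test_that("rule generation dedups antecedents and keeps one rule per
           distinct region", {
  # two identical samples give one rule
  m <- rbind(c(1, 2, 1), c(1, 2, 1))
  colnames(m) <- c("a", "b", "label")
  span <- rbind(c(0, 0, 1), c(2, 4, 2))  # fixes the variable domains
  vars <- build_fuzzy_variables(rbind(span, m), num_labels = 2)
  rules <- generate_rules(rbind(m, m), vars)
  expect_equal(nrow(rules$antecedents), 1L)

  # samples at distinct term peaks give one rule each (checked against
  # brute-force antecedent uniqueness)
  withr::with_seed(11, {
    for (rep in 1:10) {
      K <- sample(3:5, 1)
      p <- sample(2:4, 1)
      grid <- seq(0, 10, length.out = K)
      picks <- matrix(sample(seq_len(K), 6 * p, replace = TRUE), 6, p)
      mm <- cbind(matrix(grid[picks], 6, p), sample(1:2, 6, replace = TRUE))
      colnames(mm) <- c(paste0("f", seq_len(p)), "label")
      # ensure the variable grids span [0, 10]
      mm[1, seq_len(p)] <- 0; mm[2, seq_len(p)] <- 10
      picks[1, ] <- 1; picks[2, ] <- K
      vv <- build_fuzzy_variables(mm, num_labels = K)
      rr <- generate_rules(mm, vv)
      n_distinct <- nrow(unique(picks))
      expect_equal(nrow(rr$antecedents), n_distinct)
      expect_true(all(rr$antecedents >= 1 & rr$antecedents <= K))
    }
  })
  expect_error(generate_rules(matrix(numeric(0), 0, 2),
                              list(list(), list())), "empty")
})

test_that("hybrid learning reproduces a constant target exactly", {
  withr::with_seed(5, {
    x <- runif(30, 0, 1)
    m <- cbind(x = x, label = rep(4, 30) + x * 0)
    m[1, 2] <- 4; m[2, 2] <- 4.000001  # keep the output var non-degenerate
    model <- fit_anfis(m, num_labels = 3, max_iter = 3)
    expect_lt(tail(model$history$rmse, 1), 1e-5)
    expect_equal(predict(model, matrix(runif(10), ncol = 1)),
                 rep(4, 10), tolerance = 1e-4)
  })
})

test_that("an in-class two-rule system is recovered to near-zero error", {
  withr::with_seed(21, {
    x <- c(0, 1, runif(198))
    # generating model: exactly the variables the fit would construct
    vars <- build_fuzzy_variables(cbind(x = x, y = x), num_labels = 2)
    gen <- structure(
      list(vars = vars[1], out_var = vars[[2]],
           rules = list(antecedents = matrix(1:2, 2, 1,
                                             dimnames = list(NULL, "x")),
                        out_terms = c(1L, 2L), log_degree = c(0, 0)),
           consequents = rbind(c(2, 1), c(-1, 0.5)),
           num_labels = 2L, label_map = NULL,
           history = list(rmse = numeric())),
      class = "anfis"
    )
    y <- predict(gen, matrix(x, ncol = 1))
    fit <- fit_anfis(cbind(x = x, y = y), num_labels = 2, max_iter = 10)
    expect_equal(nrow(fit$rules$antecedents), 2L)
    expect_lt(tail(fit$history$rmse, 1), 1e-3)
    # SSE across least-squares passes is non-increasing
    expect_true(all(diff(fit$history$rmse) <= 1e-9))
  })
})

test_that("defuzzification is a firing-strength weighted average", {
  vars <- build_fuzzy_variables(cbind(x = c(0, 10), y = c(0, 1)),
                                num_labels = 2)
  one_rule <- structure(
    list(vars = vars[1], out_var = vars[[2]],
         rules = list(antecedents = matrix(1L, 1, 1,
                                           dimnames = list(NULL, "x")),
                      out_terms = 1L, log_degree = 0),
         consequents = matrix(c(2, 1), 1, 2),
         num_labels = 2L, label_map = NULL, history = list()),
    class = "anfis"
  )
  # single rule: f(x) = 2x + 1 at x = 3 gives 7
  expect_equal(predict(one_rule, 3), 7)

  # a rule whose competitors are far away dominates the prediction
  two_rule <- one_rule
  two_rule$rules <- list(antecedents = matrix(1:2, 2, 1,
                                              dimnames = list(NULL, "x")),
                         out_terms = c(1L, 2L), log_degree = c(0, 0))
  two_rule$vars[[1]]$sigmas <- rep(0.1, 2)  # sharply separated terms
  two_rule$consequents <- rbind(c(2, 1), c(0, -5))
  expect_equal(predict(two_rule, 0), 1, tolerance = 1e-6)
  expect_equal(predict(two_rule, 10), -5, tolerance = 1e-6)
})

test_that("the inferred matrix is integer, bounded, duplicate-free and
           never taller than the sample count", {
  withr::with_seed(31, {
    n <- 40
    m <- cbind(a = rpois(n, 8), b = rpois(n, 3), label = rep(1:2, 20))
    model <- suppressWarnings(fit_anfis(m, num_labels = 5, max_iter = 2))
    inf <- extract_inferred_matrix(model)
    expect_true(is.integer(inf$values))
    expect_equal(colnames(inf$values), c("a", "b", "effective_label"))
    expect_true(all(inf$values >= 1L & inf$values <= 5L))
    expect_lte(nrow(inf$values), n)
    expect_equal(anyDuplicated(as.data.frame(inf$values)), 0L)

    # duplicating input rows strictly reduces the rule count below the
    # (doubled) sample count
    m2 <- rbind(m, m)
    model2 <- suppressWarnings(fit_anfis(m2, num_labels = 5, max_iter = 2))
    inf2 <- extract_inferred_matrix(model2)
    expect_lt(nrow(inf2$values), nrow(m2))
    expect_equal(nrow(inf2$values), nrow(inf$values))
  })
})

test_that("correlation preservation is zero on identity and symmetric", {
  withr::with_seed(9, {
    m <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    cp <- correlation_preservation(m, m)
    expect_equal(cp$max_abs_diff, 0)
    expect_equal(cp$diff_matrix, t(cp$diff_matrix))
    expect_equal(unname(diag(cp$diff_matrix)), rep(0, 3))

    m2 <- m; m2[, 2] <- -m2[, 2]
    cp2 <- correlation_preservation(m, m2)
    expect_gt(cp2$max_abs_diff, 0)
    expect_error(correlation_preservation(m[1:2, ], m), "3 rows")
  })
})
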