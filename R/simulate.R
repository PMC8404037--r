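# Synthetic fixtures with the statistical structure the pipeline assumes:
# zero-inflated log-normal/Poisson counts, collinear feature blocks,
# class-associated signal features, plus matching enrichment and taxonomy
# tables -- so every stage is testable without external downloads.

#' Specify a synthetic abundance fixture
#'
#' Blocks come in two flavours. `copy = TRUE` blocks are exact scaled
#' replicates of one base count profile, emulating mixed-rank taxonomic
#' nesting (the same clade tabulated at several ranks yields proportional
#' columns); these are the blocks that drive exact collinearity.
#' `copy = FALSE` blocks draw each member from a shared latent Gaussian
#' factor with within-block correlation `rho`. Structural zeros follow a
#' detection-limit mechanism: the zero probability is `sparsity` at the
#' median latent abundance and rises as the latent value falls
#' (`plogis(qlogis(sparsity) - z)`), so presence/absence carries part of
#' any abundance signal, as it does in real surveys. Masks are shared
#' within a block (a structurally absent clade is absent at every rank)
#' and independent per feature elsewhere.
#'
#' @param n_samples,n_features,n_classes Fixture dimensions (defaults
#'   200, 60, 3).
#' @param blocks List of blocks, each `list(size =, rho =, copy =)`;
#'   default: three copy blocks of 5 features.
#' @param sparsity Zero-inflation probability at the median latent
#'   abundance, in `[0, 1)` (default 0.3).
#' @param effect_size Latent-scale mean-shift amplitude of the signal
#'   block across classes (default 2, i.e. class means spread over
#'   `[-2, 2]` latent standard deviations so the designated block
#'   genuinely drives the outcome).
#' @param signal_block Index of the block carrying the class signal
#'   (default 1; `0` for no signal).
#' @param mu_log,sigma_log Log-scale location and dispersion of the
#'   latent log-normal intensities (defaults 3.5 and 0.8).
#' @param seed Mandatory integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_samples = 200, n_features = 60, n_classes = 3,
                         blocks = list(
                           list(size = 5, rho = 1, copy = TRUE),
                           list(size = 5, rho = 1, copy = TRUE),
                           list(size = 5, rho = 1, copy = TRUE)
                         ),
                         sparsity = 0.3, effect_size = 2, signal_block = 1,
                         mu_log = 3.5, sigma_log = 0.8, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (sparsity < 0 || sparsity >= 1) stop("`sparsity` must be in [0, 1)")
  blocks <- lapply(blocks, function(b) {
    list(size = as.integer(b$size), rho = b$rho %||% 1,
         copy = isTRUE(b$copy))
  })
  if (sum(vapply(blocks, `[[`, 1L, "size")) > n_features) {
    stop("block sizes must sum to at most `n_features`")
  }
  if (n_classes < 2) stop("need at least 2 classes")
  structure(
    list(n_samples = as.integer(n_samples),
         n_features = as.integer(n_features),
         n_classes = as.integer(n_classes), blocks = blocks,
         sparsity = sparsity, effect_size = effect_size,
         signal_block = as.integer(signal_block),
         mu_log = mu_log, sigma_log = sigma_log,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' The default study fixture
#'
#' 200 samples by 60 features, 3 balanced classes, three collinear copy
#' blocks of 5 features, block 1 carrying the class signal.
#'
#' @param seed Integer seed.
#' @return A `fixture_spec`.
#' @export
default_fixture_spec <- function(seed) fixture_spec(seed = seed)

#' Generate a synthetic abundance table
#'
#' Latent Gaussians are mapped to non-negative counts via
#' `Poisson(exp(mu_log + sigma_log * z))` and zero-inflated at a latent-
#' dependent detection-limit rate equal to `sparsity` at the median
#' abundance; the signal block's latent values receive per-class mean
#' shifts spread over `[-effect_size, effect_size]`. Deterministic per
#' seed.
#'
#' @param spec A [fixture_spec()].
#' @return List with `data` (abundance tibble: `sample_id`, `label`,
#'   features), `truth` (block membership, signal features, latent
#'   matrix) and `spec`.
#' @export
simulate_abundance <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_samples; p <- spec$n_features; K <- spec$n_classes
  withr::with_seed(spec$seed, {
    labels <- sort(rep_len(paste0("class_", letters[seq_len(K)]), n))
    class_idx <- as.integer(factor(labels))
    shifts <- if (K > 1) seq(-1, 1, length.out = K) * spec$effect_size else 0
    delta <- shifts[class_idx]

    values <- matrix(0, n, p)
    latent <- matrix(NA_real_, n, p)
    fnames <- sprintf("feat_%02d", seq_len(p))
    # detection-limit zeros: probability `sparsity` at the median latent
    # abundance, rising as the latent value falls
    zero_mask <- function(z) {
      if (spec$sparsity == 0) return(rep(FALSE, length(z)))
      stats::runif(length(z)) < stats::plogis(stats::qlogis(spec$sparsity) - z)
    }
    blocks_members <- list()
    j <- 0L
    for (b in seq_along(spec$blocks)) {
      bl <- spec$blocks[[b]]
      idx <- j + seq_len(bl$size)
      j <- j + bl$size
      blocks_members[[b]] <- fnames[idx]
      is_signal <- (b == spec$signal_block)
      if (bl$copy) {
        z <- stats::rnorm(n)
        if (is_signal) z <- z + delta
        mask <- zero_mask(z)  # shared structural zeros
        lam <- exp(spec$mu_log + spec$sigma_log * z)
        base <- stats::rpois(n, lam)
        base[mask] <- 0
        scales <- seq(0.6, 1.6, length.out = bl$size)
        for (k in seq_along(idx)) {
          values[, idx[k]] <- scales[k] * base
          latent[, idx[k]] <- z
        }
      } else {
        f <- stats::rnorm(n)
        zs <- matrix(0, n, bl$size)
        for (k in seq_len(bl$size)) {
          zz <- sqrt(bl$rho) * f + sqrt(1 - bl$rho) * stats::rnorm(n)
          if (is_signal) zz <- zz + delta
          zs[, k] <- zz
        }
        mask <- zero_mask(rowMeans(zs))  # shared structural zeros
        for (k in seq_len(bl$size)) {
          lam <- exp(spec$mu_log + spec$sigma_log * zs[, k])
          cnt <- stats::rpois(n, lam)
          cnt[mask] <- 0
          values[, idx[k]] <- cnt
          latent[, idx[k]] <- zs[, k]
        }
      }
    }
    if (j < p) {
      for (k in (j + 1L):p) {
        z <- stats::rnorm(n)
        lam <- exp(spec$mu_log + spec$sigma_log * z)
        cnt <- stats::rpois(n, lam)
        cnt[zero_mask(z)] <- 0
        values[, k] <- cnt
        latent[, k] <- z
      }
    }
    colnames(values) <- fnames
    colnames(latent) <- fnames
    data <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("S%03d", seq_len(n)), label = labels),
      tibble::as_tibble(as.data.frame(values, check.names = FALSE))
    )
    sig <- if (spec$signal_block >= 1 &&
               spec$signal_block <= length(blocks_members)) {
      blocks_members[[spec$signal_block]]
    } else {
      character(0)
    }
    list(data = data,
         truth = list(blocks = blocks_members, signal_features = sig,
                      latent = latent),
         spec = spec)
  })
}

#' Generate a synthetic enrichment table
#'
#' Studies include each microbe independently with `base_prob`; for each
#' bias pair, joint inclusion is forced with the pair's probability,
#' boosting co-occurrence. The adjacency implied by the realised study
#' sets is computed directly by set counting and returned for oracle
#' comparison.
#'
#' @param microbes Character vector of microbe names.
#' @param n_studies Number of studies (>= 1).
#' @param bias_pairs Optional list of `list(pair = c(a, b), prob =)`.
#' @param base_prob Independent inclusion probability (default 0.4).
#' @param disease Disease annotation stamped on every study (default
#'   `"colorectal cancer"`).
#' @param seed Integer seed.
#' @return List with `table` (enrichment tibble), `adjacency` (expected
#'   symmetric count matrix, occurrences on the diagonal) and
#'   `membership` (logical study-by-microbe matrix).
#' @export
simulate_enrichment <- function(microbes, n_studies, bias_pairs = NULL,
                                base_prob = 0.4,
                                disease = "colorectal cancer", seed) {
  if (n_studies < 1) stop("`n_studies` must be >= 1")
  m <- length(microbes)
  withr::with_seed(as.integer(seed), {
    M <- matrix(stats::runif(n_studies * m) < base_prob, n_studies, m,
                dimnames = list(NULL, microbes))
    for (bp in bias_pairs) {
      ab <- match(bp$pair, microbes)
      if (anyNA(ab)) stop("bias pair references unknown microbe")
      joint <- stats::runif(n_studies) < bp$prob
      M[joint, ab] <- TRUE
    }
    for (s in which(rowSums(M) == 0L)) {
      M[s, sample.int(m, 1L)] <- TRUE  # member sets must be non-empty
    }
    A <- crossprod(M * 1L)
    table <- enrichment_table(
      sprintf("ST%03d", seq_len(n_studies)),
      rep(disease, n_studies),
      apply(M, 1L, function(r) microbes[r], simplify = FALSE)
    )
    list(table = table, adjacency = A, membership = M)
  })
}

#' Generate a mothur-style taxonomy table for OTU features
#'
#' Each OTU gets a six-rank lineage (domain to genus); a stated fraction
#' have genus `unclassified(100)`, exercising the immediate-parent
#' conversion rule.
#'
#' @param features Character vector of OTU-style feature ids.
#' @param unclassified_fraction Fraction of OTUs with unclassified genus
#'   (default 0).
#' @param seed Integer seed.
#' @return Tibble with columns `OTU`, `Size`, `Taxonomy`, parseable by
#'   [read_taxonomy()] after writing to TSV.
#' @export
simulate_taxonomy <- function(features, unclassified_fraction = 0, seed) {
  stopifnot(unclassified_fraction >= 0, unclassified_fraction <= 1)
  n <- length(features)
  withr::with_seed(as.integer(seed), {
    n_uncl <- round(unclassified_fraction * n)
    uncl <- seq_len(n) <= n_uncl  # deterministic assignment per fraction
    phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria")
    lineage <- vapply(seq_len(n), function(i) {
      fam <- sprintf("Family%03d", i)
      gen <- if (uncl[i]) "unclassified" else sprintf("Genus%03d", i)
      paste0("Bacteria(100);", sample(phyla, 1L), "(100);",
             sprintf("Class%03d", i), "(100);",
             sprintf("Order%03d", i), "(100);",
             fam, "(100);", gen, "(100);")
    }, "")
    tibble::tibble(
      OTU = features,
      Size = stats::rpois(n, 500) + 1L,
      Taxonomy = lineage
    )
  })
}
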