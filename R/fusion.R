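# Fusion of data-driven clusters with a literature-derived taxon
# co-occurrence network. Feature names (mixed-level `x__Name` strings or
# OTU ids with a mothur-style taxonomy) are converted to database microbe
# names; studies from an enrichment-results table supply node sizes
# (occurrence) and edge weights (co-occurrence); valid clusters are
# infused as extra nodes/edges; node scores average member feature scores.

.tax_ranks <- c("domain", "phylum", "class", "order", "family",
                "genus", "species")

#' Convert one feature name to a database microbe name
#'
#' Mixed-level names (`x__Name`, with `x` a rank letter) are stripped of
#' the rank prefix and of any trailing qualifier after the base clade
#' token (strain suffixes, `.sp` and the like), so
#' `"f__Myxococcales.0319.6G20"` and `"s__Myxococcales.sp"` both convert
#' to `"Myxococcales"`. OTU ids are resolved through their taxonomy
#' record to the deepest classified rank; ranks named `unclassified`
#' are skipped in favour of the nearest classified ancestor (the
#' immediate-parent rule). An optional synonym table is applied last.
#'
#' @param feature Feature name (single string).
#' @param taxonomy Optional long taxonomy tibble from [read_taxonomy()]
#'   (columns `otu`, `rank`, `name`, `support`).
#' @param synonyms Optional named character vector mapping converted names
#'   to database spellings.
#' @return The converted microbe name (single string).
#' @export
convert_taxon_name <- function(feature, taxonomy = NULL, synonyms = NULL) {
  stopifnot(is.character(feature), length(feature) == 1L)
  name <- NULL
  if (grepl("^[A-Za-z]__", feature)) {
    base <- sub("^[A-Za-z]__", "", feature)
    name <- sub("\\..*$", "", base)  # drop trailing qualifier
    if (!nzchar(name)) name <- NULL
  } else if (!is.null(taxonomy) && feature %in% taxonomy$otu) {
    rec <- taxonomy[taxonomy$otu == feature, , drop = FALSE]
    rec <- rec[order(match(rec$rank, .tax_ranks)), , drop = FALSE]
    classified <- rec$name[!grepl("unclassified", rec$name,
                                  ignore.case = TRUE)]
    if (length(classified) > 0L) name <- classified[length(classified)]
  }
  if (is.null(name)) {
    stop("cannot convert feature to a microbe name: ", feature)
  }
  if (!is.null(synonyms) && name %in% names(synonyms)) {
    name <- unname(synonyms[[name]])
  }
  name
}

#' Map a set of features to microbe names
#'
#' Applies [convert_taxon_name()] to every feature and groups features
#' that share a converted name -- the joining step that merges, for
#' example, an order-level and a species-level record of the same clade
#' into one microbe.
#'
#' @param features Character vector of feature names.
#' @param taxonomy,synonyms Passed to [convert_taxon_name()].
#' @return A tibble of class `mb_name_map` with columns `feature` and
#'   `microbe`; the grouping partitions the features exactly.
#' @export
build_name_map <- function(features, taxonomy = NULL, synonyms = NULL) {
  microbe <- vapply(features, convert_taxon_name, "", taxonomy = taxonomy,
                    synonyms = synonyms, USE.NAMES = FALSE)
  out <- tibble::tibble(feature = features, microbe = microbe)
  class(out) <- c("mb_name_map", class(out))
  out
}

#' Read a mothur-style constaxonomy file
#'
#' Expects a TSV with columns `OTU`, (optionally) `Size` and `Taxonomy`,
#' the latter holding `Name(confidence);`-separated lineage strings from
#' domain downwards.
#'
#' @param path Path to the taxonomy file.
#' @return Long tibble with `otu`, `rank`, `name` and `support` (integer
#'   confidence/count, `NA` when absent).
#' @export
read_taxonomy <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("otu", "taxonomy") %in% names(tab))) {
    stop("taxonomy file needs columns OTU and Taxonomy: ", path)
  }
  purrr::map2_dfr(tab$otu, tab$taxonomy, function(otu, lineage) {
    segs <- stringr::str_split(lineage, ";")[[1]]
    segs <- stringr::str_trim(segs)
    segs <- segs[nzchar(segs)]
    m <- stringr::str_match(segs, "^(.*?)\\((\\d+)\\)$")
    nm <- ifelse(is.na(m[, 2L]), segs, m[, 2L])
    nm <- sub("^[a-z]+:", "", nm)  # tolerate "rank:Name" prefixes
    sup <- suppressWarnings(as.integer(m[, 3L]))
    tibble::tibble(
      otu = otu,
      rank = .tax_ranks[seq_along(nm)],
      name = nm,
      support = sup
    )
  })
}

#' Read an enrichment-results table
#'
#' Flat CSV with one row per study: `study_id`, `disease` and a
#' semicolon-joined `microbes` member list -- the file contract standing
#' in for exported taxon-set enrichment results.
#'
#' @param path Path to the CSV file.
#' @return Tibble with `study_id`, `disease` and a `members` list-column
#'   of microbe name vectors.
#' @export
read_enrichment <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                         show_col_types = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("study_id", "disease", "microbes") %in% names(tab))) {
    stop("enrichment file needs columns study_id, disease, microbes: ", path)
  }
  enrichment_table(tab$study_id, tab$disease,
                   stringr::str_split(tab$microbes, ";\\s*"))
}

#' Assemble an enrichment table from vectors
#'
#' @param study_id Character vector of unique study identifiers.
#' @param disease Disease annotation per study.
#' @param members List of microbe-name character vectors, one per study.
#' @return Tibble with `study_id`, `disease`, `members` (list-column).
#' @export
enrichment_table <- function(study_id, disease, members) {
  members <- lapply(members, function(x) unique(x[nzchar(x)]))
  if (anyDuplicated(study_id)) stop("study ids must be unique")
  if (any(lengths(members) == 0L)) {
    stop("every study needs a non-empty member set")
  }
  tibble::tibble(study_id = as.character(study_id),
                 disease = as.character(disease),
                 members = members)
}

canonical_pairs <- function(members) {
  members <- sort(unique(members))
  if (length(members) < 2L) return(NULL)
  cmb <- utils::combn(members, 2L)
  tibble::tibble(from = cmb[1L, ], to = cmb[2L, ])
}

#' Build the literature co-occurrence network from an enrichment table
#'
#' After the optional disease filter (case-insensitive substring match),
#' each microbe appearing in at least one remaining study becomes a node
#' whose size is its study-occurrence count; each pair of microbes
#' sharing at least one study gets an edge weighted by the co-occurrence
#' count. The diagonal of the adjacency matrix carries the occurrence
#' counts.
#'
#' @param enrichment Tibble as from [read_enrichment()] /
#'   [enrichment_table()].
#' @param disease Optional disease-of-interest filter string.
#' @return An object of class `fused_network`.
#' @export
build_network <- function(enrichment, disease = NULL) {
  stopifnot(all(c("study_id", "disease", "members") %in% names(enrichment)))
  tab <- enrichment
  if (!is.null(disease)) {
    keep <- stringr::str_detect(stringr::str_to_lower(tab$disease),
                                stringr::fixed(stringr::str_to_lower(disease)))
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) == 0L) {
      stop("no study matches the disease filter: '", disease, "'")
    }
  }
  occur <- sort(table(unlist(lapply(tab$members, unique))), decreasing = TRUE)
  nodes <- tibble::tibble(
    name = names(occur),
    size = as.integer(occur),
    score = NA_real_,
    n_scored = 0L,
    origin = "enrichment"
  )
  nodes <- dplyr::arrange(nodes, dplyr::desc(.data$size), .data$name)
  pair_tabs <- purrr::map_dfr(tab$members, canonical_pairs)
  if (nrow(pair_tabs) > 0L) {
    edges <- dplyr::summarise(
      dplyr::group_by(pair_tabs, .data$from, .data$to),
      weight = dplyr::n(), .groups = "drop"
    )
  } else {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = integer())
  }
  edges$origin <- rep("enrichment", nrow(edges))
  edges$in_cluster <- rep(FALSE, nrow(edges))
  structure(list(nodes = nodes, edges = edges), class = "fused_network")
}

#' Symmetric adjacency matrix of a fused network
#'
#' Occurrence counts sit on the diagonal, edge weights off it.
#'
#' @param net A `fused_network`.
#' @return Symmetric numeric matrix with microbe names as dimnames.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "fused_network"))
  nm <- net$nodes$name
  A <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  diag(A) <- net$nodes$size
  if (nrow(net$edges) > 0L) {
    for (i in seq_len(nrow(net$edges))) {
      A[net$edges$from[i], net$edges$to[i]] <- net$edges$weight[i]
      A[net$edges$to[i], net$edges$from[i]] <- net$edges$weight[i]
    }
  }
  A
}

#' Infuse data-driven clusters into the literature network
#'
#' A cluster (of at least two features) is valid when at least one member
#' feature's converted microbe name is already a node. For every valid
#' cluster, absent member names are added as new nodes of size 1 (origin
#' `"infused"`), and the cluster relation is recorded between every pair
#' of the cluster's node names: existing enrichment edges keep their
#' weight and gain the `in_cluster` mark, missing pairs get new edges of
#' weight 1 with origin `"cluster"` (the "red" edges of the display
#' semantics). Invalid clusters leave the network unchanged, as do
#' clusters whose members all map to a single node. The operation is
#' idempotent.
#'
#' @param net A `fused_network`.
#' @param clusters An `mb_clustered` object or a named list mapping
#'   cluster ids to member feature vectors.
#' @param name_map `mb_name_map` (or named vector feature -> microbe)
#'   covering the clusters' features.
#' @return The augmented `fused_network`.
#' @export
infuse_clusters <- function(net, clusters, name_map) {
  stopifnot(inherits(net, "fused_network"))
  prov <- if (inherits(clusters, "mb_clustered")) clusters$provenance
          else clusters
  prov <- prov[lengths(prov) >= 2L]
  fmap <- if (is.data.frame(name_map)) {
    stats::setNames(name_map$microbe, name_map$feature)
  } else {
    name_map
  }
  for (members in prov) {
    unknown <- setdiff(members, names(fmap))
    if (length(unknown) > 0L) {
      stop("cluster references unmapped feature(s): ",
           paste(unknown, collapse = ", "))
    }
    mnames <- unique(unname(fmap[members]))
    if (length(mnames) < 2L) next       # collapses to one microbial node
    if (!any(mnames %in% net$nodes$name)) next  # invalid cluster
    new_nodes <- setdiff(mnames, net$nodes$name)
    if (length(new_nodes) > 0L) {
      net$nodes <- dplyr::bind_rows(
        net$nodes,
        tibble::tibble(name = new_nodes, size = 1L, score = NA_real_,
                       n_scored = 0L, origin = "infused")
      )
    }
    pairs <- canonical_pairs(mnames)
    for (i in seq_len(nrow(pairs))) {
      hit <- net$edges$from == pairs$from[i] & net$edges$to == pairs$to[i]
      if (any(hit)) {
        net$edges$in_cluster[hit] <- TRUE
      } else {
        net$edges <- dplyr::bind_rows(
          net$edges,
          tibble::tibble(from = pairs$from[i], to = pairs$to[i],
                         weight = 1L, origin = "cluster", in_cluster = TRUE)
        )
      }
    }
  }
  net
}

#' Attach node scores to a fused network
#'
#' The score of a node is the mean of the feature scores of its member
#' features (those whose converted name equals the node name); `n` is the
#' member count. Nodes with no scored member features keep an `NA` score
#' and are flagged by `n_scored = 0`.
#'
#' @param net A `fused_network`.
#' @param scores `mb_scores` tibble (or any tibble with `feature` and
#'   `feature_score`), or a named numeric vector of feature scores.
#' @param name_map `mb_name_map` or named vector feature -> microbe.
#' @return The network with `score` and `n_scored` filled in.
#' @export
node_scores <- function(net, scores, name_map) {
  stopifnot(inherits(net, "fused_network"))
  if (is.data.frame(scores)) {
    sc <- stats::setNames(scores$feature_score, scores$feature)
  } else {
    sc <- scores
  }
  fmap <- if (is.data.frame(name_map)) {
    stats::setNames(name_map$microbe, name_map$feature)
  } else {
    name_map
  }
  scored_feats <- intersect(names(sc), names(fmap))
  by_node <- split(unname(sc[scored_feats]), unname(fmap[scored_feats]))
  for (i in seq_len(nrow(net$nodes))) {
    nm <- net$nodes$name[i]
    if (!is.null(by_node[[nm]])) {
      net$nodes$score[i] <- mean(by_node[[nm]])
      net$nodes$n_scored[i] <- length(by_node[[nm]])
    }
  }
  net
}

#' @export
print.fused_network <- function(x, ...) {
  cat("Fused network: ", nrow(x$nodes), " nodes (",
      sum(x$nodes$origin == "infused"), " infused), ",
      nrow(x$edges), " edges (",
      sum(x$edges$origin == "cluster"), " cluster-origin)\n", sep = "")
  invisible(x)
}

#' @export
tidy.fused_network <- function(x, ...) {
  x$edges
}

#' @export
glance.fused_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_infused = sum(x$nodes$origin == "infused"),
    n_edges = nrow(x$edges),
    n_cluster_edges = sum(x$edges$origin == "cluster"),
    score_variance = stats::var(x$nodes$score[!is.na(x$nodes$score)])
  )
}

as_igraph <- function(net) {
  nodes <- net$nodes
  nodes$score[is.na(nodes$score)] <- NaN  # GraphML has no NA
  igraph::graph_from_data_frame(
    d = as.data.frame(net$edges),
    directed = FALSE,
    vertices = as.data.frame(nodes)
  )
}

#' Export a fused network to GraphML or GML
#'
#' Node attributes `size` (occurrence count), `score`, `n_scored` and
#' `origin` and edge attributes `weight`, `origin` and `in_cluster` are
#' written; re-importing with [import_graph()] reproduces the network.
#'
#' @param net A `fused_network`.
#' @param path Output file path.
#' @param format `"graphml"` (default) or `"gml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(net, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Import a fused network written by [export_graph()]
#'
#' @param path GraphML or GML file.
#' @param format File format (default `"graphml"`).
#' @return A `fused_network`.
#' @export
import_graph <- function(path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- igraph::read_graph(path, format = format)
  va <- igraph::vertex_attr(g)
  nodes <- tibble::tibble(
    name = as.character(va$name),
    size = as.integer(round(va$size)),
    score = as.numeric(va$score),
    n_scored = as.integer(round(va$n_scored)),
    origin = as.character(va$origin)
  )
  nodes$score[is.nan(nodes$score)] <- NA_real_
  el <- igraph::as_edgelist(g)
  ea <- igraph::edge_attr(g)
  edges <- tibble::tibble(
    from = pmin(el[, 1L], el[, 2L]),
    to = pmax(el[, 1L], el[, 2L]),
    weight = as.integer(round(ea$weight)),
    origin = as.character(ea$origin),
    in_cluster = as.logical(ea$in_cluster)
  )
  structure(list(nodes = nodes, edges = edges), class = "fused_network")
}
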