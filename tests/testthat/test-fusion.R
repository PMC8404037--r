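test_that("mixed-level and OTU feature names convert to microbe names", {
  expect_equal(convert_taxon_name("c__Gammaproteobacteria"),
               "Gammaproteobacteria")
  # strain/species qualifiers collapse to the base clade token
  expect_equal(convert_taxon_name("f__Myxococcales.0319.6G20"), "Myxococcales")
  expect_equal(convert_taxon_name("s__Myxococcales.sp"), "Myxococcales")

  # genus-unclassified OTU resolves to its family (immediate parent rule)
  tax <- tibble::tibble(
    otu = rep("Otu00002", 6),
    rank = c("domain", "phylum", "class", "order", "family", "genus"),
    name = c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
             "Enterobacteriales", "Enterobacteriaceae", "unclassified"),
    support = rep(100L, 6)
  )
  expect_equal(convert_taxon_name("Otu00002", taxonomy = tax),
               "Enterobacteriaceae")
  # fully classified OTU resolves at genus
  tax2 <- dplyr::mutate(tax, name = replace(name, rank == "genus", "Blautia"))
  expect_equal(convert_taxon_name("Otu00002", taxonomy = tax2), "Blautia")
  expect_error(convert_taxon_name("whatever"), "whatever")
  # synonyms apply last
  expect_equal(convert_taxon_name("s__distasonis",
                                  synonyms = c(distasonis = "Parabacteroides distasonis")),
               "Parabacteroides distasonis")
})

test_that("name maps group features sharing a converted name", {
  feats <- c("f__Myxococcales.0319.6G20", "s__Myxococcales.sp", "g__Rothia")
  nm <- build_name_map(feats)
  expect_equal(sum(nm$microbe == "Myxococcales"), 2L)
  expect_equal(nrow(nm), length(feats))           # partition covers exactly
  expect_equal(anyDuplicated(nm$feature), 0L)
  nm2 <- build_name_map(c("p__A", "c__B", "o__C"))
  expect_equal(dplyr::n_distinct(nm2$microbe), 3L)  # disjoint -> singletons
})

test_that("mothur-style taxonomy files parse", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cons.taxonomy")
  writeLines(c("OTU\tSize\tTaxonomy",
               paste0("Otu01\t120\tBacteria(100);Firmicutes(100);",
                      "Clostridia(100);Clostridiales(100);",
                      "Lachnospiraceae(100);Blautia(97);")), f)
  tax <- read_taxonomy(f)
  expect_equal(nrow(tax), 6L)
  expect_equal(tax$rank, c("domain", "phylum", "class", "order", "family",
                           "genus"))
  expect_equal(tax$name[6], "Blautia")
  expect_equal(tax$support[6], 97L)
  expect_equal(convert_taxon_name("Otu01", taxonomy = tax), "Blautia")
})

test_that("the enrichment network counts occurrences and co-occurrences", {
  enr <- enrichment_table(
    c("A", "B"), rep("colorectal cancer", 2),
    list(c("m1", "m2"), c("m1"))
  )
  net <- build_network(enr)
  expect_equal(net$nodes$size[net$nodes$name == "m1"], 2L)
  expect_equal(net$nodes$size[net$nodes$name == "m2"], 1L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 1L)

  A <- adjacency_matrix(net)
  expect_equal(A, t(A))
  expect_equal(unname(diag(A)[order(-diag(A))]), c(2, 1))
  # co-occurrence never exceeds either occurrence
  expect_lte(A["m1", "m2"], min(A["m1", "m1"], A["m2", "m2"]))

  # disease filter is a case-insensitive substring match
  enr2 <- enrichment_table(
    c("A", "B", "C"), c("Colorectal Cancer", "IBD", "colorectal cancer x"),
    list(c("m1"), c("m2"), c("m3"))
  )
  net2 <- build_network(enr2, disease = "colorectal")
  expect_setequal(net2$nodes$name, c("m1", "m3"))
  expect_error(build_network(enr2, disease = "psoriasis"), "psoriasis")

  # study-record order does not matter
  net3 <- build_network(enr[2:1, ])
  expect_equal(net3$nodes, net$nodes)
  expect_equal(net3$edges, net$edges)
})

test_that("edge thickness ordering mirrors co-occurrence counts", {
  enr <- enrichment_table(
    sprintf("S%d", 1:4), rep("crc", 4),
    list(c("n1", "n2"), c("n1", "n2", "n3"), c("n1", "n2"), c("n1", "n3"))
  )
  net <- build_network(enr)
  w12 <- net$edges$weight[net$edges$from == "n1" & net$edges$to == "n2"]
  w13 <- net$edges$weight[net$edges$from == "n1" & net$edges$to == "n3"]
  expect_gt(w12, w13)
})

test_that("valid clusters infuse size-1 nodes and cluster edges;
           invalid clusters leave the network unchanged", {
  enr <- enrichment_table(
    c("A", "B"), rep("crc", 2),
    list(c("Lentisphaeria", "Other"), c("Lentisphaeria"))
  )
  net <- build_network(enr)
  nmap <- build_name_map(c("c__Lentisphaeria", "p__Lentisphaerae",
                           "o__Victivallales", "g__Rothia",
                           "s__mucilaginosa",
                           "f__Myxococcales.0319.6G20", "s__Myxococcales.sp"))
  clusters <- list(
    cluster_1 = c("c__Lentisphaeria", "p__Lentisphaerae", "o__Victivallales"),
    cluster_2 = c("g__Rothia", "s__mucilaginosa"),
    cluster_3 = c("f__Myxococcales.0319.6G20", "s__Myxococcales.sp")
  )
  fused <- infuse_clusters(net, clusters, nmap)
  # valid cluster: two new nodes with size 1 and three cluster-pair edges
  expect_setequal(fused$nodes$name[fused$nodes$origin == "infused"],
                  c("Lentisphaerae", "Victivallales"))
  expect_true(all(fused$nodes$size[fused$nodes$origin == "infused"] == 1L))
  in_cl <- fused$edges[fused$edges$in_cluster, ]
  expect_equal(nrow(in_cl), 3L)
  expect_setequal(
    paste(in_cl$from, in_cl$to),
    c("Lentisphaerae Lentisphaeria", "Lentisphaeria Victivallales",
      "Lentisphaerae Victivallales")
  )
  # invalid cluster (Rothia/mucilaginosa): nothing added
  expect_false(any(grepl("Rothia|mucilaginosa", fused$nodes$name)))
  # a cluster collapsing to one microbe name adds nothing
  expect_false("Myxococcales" %in% fused$nodes$name)

  # idempotence
  fused2 <- infuse_clusters(fused, clusters, nmap)
  expect_equal(fused2$nodes, fused$nodes)
  expect_equal(fused2$edges, fused$edges)
  expect_error(infuse_clusters(net, list(k = c("c__Lentisphaeria", "zzz")),
                               nmap), "zzz")
})

test_that("node scores average member feature scores", {
  enr <- enrichment_table("A", "crc", list(c("Myxococcales", "Solo")))
  net <- build_network(enr)
  nmap <- build_name_map(c("f__Myxococcales.0319.6G20", "s__Myxococcales.sp",
                           "g__Solo"))
  sc <- c(`f__Myxococcales.0319.6G20` = 5, `s__Myxococcales.sp` = -2,
          g__Solo = 1.25)
  out <- node_scores(net, sc, nmap)
  # two members scored (5, -2) average to 1.5
  expect_equal(out$nodes$score[out$nodes$name == "Myxococcales"], 1.5)
  expect_equal(out$nodes$n_scored[out$nodes$name == "Myxococcales"], 2L)
  # singleton inherits its feature score
  expect_equal(out$nodes$score[out$nodes$name == "Solo"], 1.25)
  # member order does not matter
  out2 <- node_scores(net, rev(sc), nmap[3:1, ])
  expect_equal(out2$nodes$score, out$nodes$score)
})

test_that("GraphML export round-trips the network", {
  enr <- enrichment_table(
    c("A", "B"), rep("crc", 2),
    list(c("X", "Y"), c("X"))
  )
  net <- build_network(enr)
  nmap <- build_name_map(c("c__X", "p__Xp"))
  net <- infuse_clusters(net, list(cl = c("c__X", "p__Xp")), nmap)
  net <- node_scores(net, c(c__X = 2), nmap)
  path <- file.path(withr::local_tempdir(), "net.graphml")
  export_graph(net, path)
  back <- import_graph(path)
  ord <- function(n) {
    n$nodes <- dplyr::arrange(n$nodes, .data$name)
    n$edges <- dplyr::arrange(n$edges, .data$from, .data$to)
    n
  }
  expect_equal(ord(back)$nodes, ord(net)$nodes)
  expect_equal(ord(back)$edges, ord(net)$edges)
  # infused edges carry the cluster origin; unscored nodes stay NA
  expect_true(any(back$edges$origin == "cluster"))
  expect_true(is.na(back$nodes$score[back$nodes$name == "Y"]))
})
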