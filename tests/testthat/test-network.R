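test_that("a hand-built association set yields the expected graph", {
  rec <- make_records(
    exposure = c("E1", "E1", "E2"),
    feature = c("F1", "F2", "F2"),
    effect = c(0.5, -0.3, 0.2), p = c(0.01, 0.02, 0.03),
    significant = TRUE
  )
  net <- build_assoc_network(rec, period = "childhood")
  expect_equal(nrow(net$nodes), 4L)
  expect_equal(nrow(net$edges), 3L)
  expect_equal(length(unique(net$nodes$component_id)), 1L)
  expect_equal(sum(net$nodes$degree), 2 * nrow(net$edges))
})

test_that("bipartite violations are rejected", {
  rec <- make_records(
    exposure = c("E1", "F1"), feature = c("F1", "F2"),
    effect = 0.1, p = 0.01, significant = TRUE
  )
  expect_error(build_assoc_network(rec), "bipartite")
})

test_that("multi-contrast associations collapse to one signed edge", {
  rec <- dplyr::bind_rows(
    make_records("E1", "F1",
      effect = 0.5, p = 0.04, contrast = "medium",
      significant = TRUE
    ),
    make_records("E1", "F1",
      effect = -0.8, p = 0.001, contrast = "high",
      significant = TRUE
    )
  )
  net <- build_assoc_network(rec)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$sign, -1) # sign of the smallest-p contrast
})

test_that("star topology statistics match hand computation", {
  rec <- make_records("E", c("F1", "F2", "F3"),
    effect = 0.2, p = 0.01,
    significant = TRUE
  )
  stats <- network_stats(build_assoc_network(rec))
  expect_equal(stats$mean_degree, 1.5) # degrees 3,1,1,1
  expect_equal(stats$avg_shortest_path, 1.5) # 3 pairs at 1, 3 at 2
  expect_equal(stats$largest_component_fraction, 100)
  single <- network_stats(build_assoc_network(
    make_records("E", "F", effect = 1, p = 0.01, significant = TRUE)
  ))
  expect_equal(single$mean_degree, 1)
  expect_equal(single$avg_shortest_path, 1)
  # node-counting convention adds one edge-to-node offset
  expect_equal(
    network_stats(build_assoc_network(rec), count = "nodes")$avg_shortest_path,
    2.5
  )
})

test_that("distances and components match a Floyd-Warshall oracle", {
  set.seed(77)
  for (i in 1:100) {
    n_e <- sample(2:8, 1)
    n_f <- sample(2:17, 1)
    expos <- paste0("E", seq_len(n_e))
    feats <- paste0("F", seq_len(n_f))
    n_edges <- sample(seq_len(n_e * n_f), 1)
    pairs <- expand.grid(exposure = expos, feature = feats,
      stringsAsFactors = FALSE)
    pairs <- pairs[sample(nrow(pairs), n_edges), ]
    rec <- make_records(pairs$exposure, pairs$feature,
      effect = rnorm(n_edges), p = runif(n_edges), significant = TRUE
    )
    net <- build_assoc_network(rec)
    stats <- network_stats(net)
    d <- floyd_warshall(net$nodes$name, net$edges$exposure, net$edges$feature)
    finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
    expect_equal(stats$avg_shortest_path, mean(finite))
    # component count and sizes from the reachability closure
    reach_comp <- rep(NA_integer_, nrow(d))
    cid <- 0L
    for (v in seq_len(nrow(d))) {
      if (is.na(reach_comp[v])) {
        cid <- cid + 1L
        reach_comp[is.finite(d[v, ])] <- cid
      }
    }
    expect_equal(stats$n_components, cid)
    expect_equal(
      sort(stats$component_sizes[[1]]),
      sort(as.integer(table(reach_comp)))
    )
    expect_equal(sum(net$nodes$degree), 2 * stats$n_edges)
  }
})

test_that("two bridged stars split into two communities at the bridge", {
  # E1 with 4 features, E2 with 4 features, one shared feature
  rec <- dplyr::bind_rows(
    make_records("E1", c("F1", "F2", "F3", "F4", "Fshared"),
      effect = 0.2, p = 0.01, significant = TRUE
    ),
    make_records("E2", c("F5", "F6", "F7", "F8", "Fshared"),
      effect = 0.2, p = 0.01, significant = TRUE
    )
  )
  net <- detect_communities(build_assoc_network(rec))
  expect_equal(length(unique(net$nodes$cluster_id)), 2L)
  side1 <- net$nodes$cluster_id[net$nodes$name %in% c("E1", "F1", "F2", "F3", "F4")]
  side2 <- net$nodes$cluster_id[net$nodes$name %in% c("E2", "F5", "F6", "F7", "F8")]
  expect_equal(length(unique(side1)), 1L)
  expect_equal(length(unique(side2)), 1L)
  expect_false(unique(side1) == unique(side2))
  # the found partition achieves the modularity of the intended 2-block
  # partition (bridge node joins one side)
  membership <- setNames(net$nodes$cluster_id, net$nodes$name)
  q_oracle <- modularity_oracle(
    net$edges$exposure, net$edges$feature, membership
  )
  expect_equal(net$modularity, q_oracle, tolerance = 1e-10)
})

test_that("disconnected components keep their own cluster and labelling is deterministic", {
  rec <- dplyr::bind_rows(
    make_records("E1", c("F1", "F2"), effect = 0.2, p = 0.01, significant = TRUE),
    make_records("E2", c("F3", "F4", "F5"),
      effect = 0.2, p = 0.01,
      significant = TRUE
    )
  )
  net <- detect_communities(build_assoc_network(rec))
  expect_equal(length(unique(net$nodes$cluster_id)), 2L)
  # single star: one community
  star <- detect_communities(build_assoc_network(
    make_records("E", c("F1", "F2", "F3"),
      effect = 0.2, p = 0.01,
      significant = TRUE
    )
  ))
  expect_equal(length(unique(star$nodes$cluster_id)), 1L)
  # determinism under row permutation of the input table
  set.seed(5)
  net2 <- detect_communities(build_assoc_network(rec[sample(nrow(rec)), ]))
  expect_identical(
    net$nodes[order(net$nodes$name), c("name", "cluster_id")],
    net2$nodes[order(net2$nodes$name), c("name", "cluster_id")]
  )
})

test_that("cluster summaries count features, genes and order exposures", {
  rec <- dplyr::bind_rows(
    make_records("E1", c("cpg1", "cpg2"),
      effect = 0.2, p = 0.01,
      layer = "methylation", significant = TRUE
    ),
    make_records("E1", "prot1",
      effect = 0.2, p = 0.01, layer = "protein",
      significant = TRUE
    ),
    make_records("E2", "prot1",
      effect = 0.2, p = 0.01, layer = "protein",
      significant = TRUE
    )
  )
  ann <- tibble::tibble(
    feature_id = c("cpg1", "cpg2", "prot1"),
    gene = c("A", "A", "B")
  )
  net <- detect_communities(build_assoc_network(rec))
  summ <- cluster_summary(net, annotations = ann)
  expect_equal(nrow(summ), length(unique(net$nodes$cluster_id)))
  expect_equal(sum(summ$total_annotated_genes), 2) # genes A and B
  expect_equal(sum(summ$methylation), 2)
  expect_equal(sum(summ$protein), 1)
  # exposures ordered by association count: E1 (3 edges) before E2 (1)
  expect_match(summ$exposures[1], "^E1")
  # conservation: per-layer counts sum to the network's feature nodes
  expect_equal(
    sum(summ$total_features),
    sum(net$nodes$type == "feature")
  )
})

test_that("display filter marks components with at least two molecular features", {
  rec <- dplyr::bind_rows(
    make_records("E1", c("F1", "F2"), effect = 0.2, p = 0.01, significant = TRUE),
    make_records("E2", "F3", effect = 0.2, p = 0.01, significant = TRUE)
  )
  net <- build_assoc_network(rec)
  disp <- net$nodes$displayed
  expect_true(all(disp[net$nodes$component_id == net$nodes$component_id[
    net$nodes$name == "E1"
  ]]))
  expect_false(any(disp[net$nodes$name %in% c("E2", "F3")]))
  stats_full <- network_stats(net)
  stats_disp <- network_stats(net, displayed_only = TRUE)
  expect_equal(stats_full$n_nodes, 5)
  expect_equal(stats_disp$n_nodes, 3)
})

test_that("networks round-trip through the export formats", {
  rec <- make_records("E1", c("F1", "F2"),
    effect = c(0.5, -0.5), p = 0.01,
    significant = TRUE
  )
  net <- build_assoc_network(rec)
  dir <- withr::local_tempdir()
  paths <- write_network(net, dir)
  expect_true(all(file.exists(file.path(
    dir, c("nodes.tsv", "edges.tsv", "network.graphml")
  ))))
  g2 <- igraph::read_graph(file.path(dir, "network.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g2), 3)
  expect_equal(igraph::ecount(g2), 2)
})

test_that("an empty significant set warns and an association table loads back", {
  rec <- make_records("E1", "F1", effect = 0.1, p = 0.5, significant = FALSE)
  expect_warning(net <- build_assoc_network(rec), "no significant")
  expect_equal(nrow(net$edges), 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_association_table(
    make_records("E1", "F1", effect = 0.1, p = 0.5), path
  )
  back <- read_association_table(path)
  expect_equal(back$exposure, "E1")
  expect_error(read_association_table("no/such/file.tsv"), "not found")
})
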