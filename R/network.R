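#' Read a significant-association table from a tab-delimited file
#'
#' The interchange schema produced by [run_exwas()] /
#' [apply_correction()] (exposure, period, family, feature, layer,
#' contrast, effect, se, p, n, model_tag, significance flags), of which
#' only `exposure`, `period`, `feature` and `layer` are required here.
#' Externally curated association catalogues with the same columns load
#' the same way and can feed the network module directly.
#'
#' @param path File path.
#' @return A tibble of association records.
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("association table not found: %s", path))
  rec <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot_cols(
    rec, c("exposure", "period", "feature", "layer"), "association table"
  )
  as_tibble(rec)
}

#' Write association records to a tab-delimited file
#'
#' @param records Association tibble.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_association_table <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Build the period-specific bipartite exposure-feature network
#'
#' Nodes are the unique exposures and molecular features of the period's
#' significant associations; edges are the associations themselves,
#' signed by the direction of the effect. Multiple categorical contrasts
#' for the same exposure-feature pair collapse into a single edge carrying
#' the sign of the smallest-p contrast. Connected components are labelled,
#' and components with at least two molecular features are marked as
#' displayed (the display convention for network figures).
#'
#' @param records Association records; if a `significant` column is
#'   present only significant rows are used.
#' @param period `"pregnancy"` or `"childhood"`; `NULL` keeps all rows.
#' @return An object of class `assoc_network`: list with the `igraph`
#'   graph, a `nodes` tibble (name, type, layer, gene, degree,
#'   component_id, displayed), an `edges` tibble and the `period`.
#' @export
build_assoc_network <- function(records, period = NULL) {
  if (!is.null(period)) {
    records <- filter(records, .data$period == .env$period)
  }
  if ("significant" %in% names(records)) {
    records <- filter(records, .data$significant)
  }
  if (nrow(records) == 0) {
    warn("no significant associations; returning an empty network")
  }
  both <- intersect(unique(records$exposure), unique(records$feature))
  if (length(both) > 0) {
    abort(sprintf(
      "bipartite violation: identifier(s) appear as both exposure and feature: %s",
      compact_chr(both)
    ))
  }
  edges <- records |>
    group_by(.data$exposure, .data$feature) |>
    slice_min(.data$p,
      n = 1, with_ties = FALSE,
      na_rm = FALSE
    ) |>
    ungroup() |>
    mutate(
      sign = ifelse(.data$effect >= 0, 1, -1),
      weight = abs(.data$effect)
    ) |>
    arrange(.data$exposure, .data$feature)
  exposures <- sort(unique(edges$exposure))
  feature_info <- edges |>
    distinct(.data$feature, .data$layer) |>
    arrange(.data$feature)
  gene_map <- if ("gene" %in% names(records)) {
    distinct(records, .data$feature, .data$gene)
  } else {
    tibble(feature = character(), gene = character())
  }
  nodes <- bind_rows(
    tibble(name = exposures, type = "exposure", layer = NA_character_),
    tibble(
      name = feature_info$feature, type = "feature",
      layer = feature_info$layer
    )
  ) |>
    left_join(rename(gene_map, name = "feature"), by = "name")
  if (!"gene" %in% names(nodes)) nodes$gene <- NA_character_
  g <- igraph::graph_from_data_frame(
    select(edges, from = "exposure", to = "feature", "sign", "weight", "p"),
    directed = FALSE,
    vertices = nodes
  )
  comp <- igraph::components(g)
  nodes$degree <- as.numeric(igraph::degree(g)[nodes$name])
  nodes$component_id <- as.integer(comp$membership[nodes$name])
  feat_per_comp <- nodes |>
    filter(.data$type == "feature") |>
    count(.data$component_id)
  displayed_comps <- feat_per_comp$component_id[feat_per_comp$n >= 2]
  nodes$displayed <- nodes$component_id %in% displayed_comps
  structure(
    list(graph = g, nodes = nodes, edges = edges, period = period),
    class = "assoc_network"
  )
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf(
    "<assoc_network%s> %d nodes (%d exposures, %d features), %d edges, %d components\n",
    if (is.null(x$period)) "" else paste0(": ", x$period),
    nrow(x$nodes), sum(x$nodes$type == "exposure"),
    sum(x$nodes$type == "feature"), nrow(x$edges),
    length(unique(x$nodes$component_id))
  ))
  invisible(x)
}

#' Topology statistics of an association network
#'
#' Degree is the incident edge count; the average shortest path is the
#' mean breadth-first-search distance (counted in edges) over all
#' unordered pairs of nodes reachable from one another — pairs in
#' different components are excluded. Setting `count = "nodes"` adds one
#' to every path length (path length counted as the number of nodes
#' visited).
#'
#' @param net An [build_assoc_network()] result.
#' @param displayed_only Compute on the displayed (at least two molecular
#'   features per component) subgraph instead of the full network.
#' @param count `"edges"` (default) or `"nodes"`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `mean_degree`,
#'   `avg_shortest_path`, `n_components`, `largest_component_fraction`
#'   (percent of nodes) and a `component_sizes` list column.
#' @export
network_stats <- function(net, displayed_only = FALSE,
                          count = c("edges", "nodes")) {
  count <- match.arg(count)
  g <- net$graph
  if (displayed_only) {
    keep <- net$nodes$name[net$nodes$displayed]
    g <- igraph::induced_subgraph(g, keep)
  }
  n_nodes <- igraph::vcount(g)
  n_edges <- igraph::ecount(g)
  if (n_nodes == 0) abort("empty network")
  comp <- igraph::components(g)
  apl <- igraph::mean_distance(g, weights = NA, unconnected = TRUE)
  if (count == "nodes") apl <- apl + 1
  tibble(
    n_nodes = n_nodes,
    n_edges = n_edges,
    mean_degree = 2 * n_edges / n_nodes,
    avg_shortest_path = apl,
    n_components = comp$no,
    largest_component_fraction = 100 * max(comp$csize) / n_nodes,
    component_sizes = list(sort(comp$csize, decreasing = TRUE))
  )
}

#' Community detection on an association network
#'
#' Greedy modularity maximization (agglomerative hierarchical merging) on
#' the largest connected component; every smaller component keeps its
#' component as its own cluster. Cluster identifiers are relabelled by
#' decreasing edge count (ties broken by the lexicographically smallest
#' member), so the labelling is deterministic for identical inputs.
#'
#' @param net An [build_assoc_network()] result with at least one edge.
#' @return The network with a `cluster_id` column added to `nodes` and a
#'   `modularity` element (modularity of the partition of the largest
#'   component).
#' @export
detect_communities <- function(net) {
  if (nrow(net$edges) == 0) abort("network has no edges")
  comp_ids <- net$nodes$component_id
  largest <- as.integer(names(which.max(table(comp_ids))))
  in_largest <- net$nodes$name[comp_ids == largest]
  sub <- igraph::induced_subgraph(net$graph, in_largest)
  fg <- igraph::cluster_fast_greedy(sub, weights = NULL)
  member <- igraph::membership(fg)
  q <- igraph::modularity(fg)
  if (q <= 1e-12) {
    # no split improves on the trivial one-community partition (Q = 0)
    member[] <- 1
    q <- igraph::modularity(sub, member)
  }
  cluster_raw <- ifelse(
    comp_ids == largest,
    paste0("L", member[net$nodes$name]),
    paste0("C", comp_ids)
  )
  # Deterministic relabelling: by decreasing edge count, ties by smallest
  # member name.
  edge_cluster <- cluster_raw[match(net$edges$exposure, net$nodes$name)]
  stats <- tibble(raw = unique(cluster_raw)) |>
    mutate(
      n_edges = purrr::map_dbl(.data$raw, ~ sum(edge_cluster == .x)),
      first_member = purrr::map_chr(
        .data$raw, ~ min(net$nodes$name[cluster_raw == .x])
      )
    ) |>
    arrange(desc(.data$n_edges), .data$first_member)
  relabel <- setNames(seq_len(nrow(stats)), stats$raw)
  net$nodes$cluster_id <- as.integer(relabel[cluster_raw])
  net$modularity <- q
  net
}

#' Summarise network clusters
#'
#' One row per cluster: its exposures ordered by number of omics
#' associations (descending, ties lexicographic), the feature count per
#' molecular layer, and the number of unique annotated genes across CpGs,
#' transcript clusters, miRNAs and proteins.
#'
#' @param net A clustered network from [detect_communities()].
#' @param annotations Optional feature-to-gene map (tibble with
#'   `feature_id`, `gene`); defaults to the `gene` node attribute carried
#'   by the association records. Unmapped features count as unannotated.
#' @return A tibble with `cluster_id`, `exposures` (comma-separated,
#'   ordered), `n_exposures`, one count column per layer, `total_features`
#'   and `total_annotated_genes`.
#' @export
cluster_summary <- function(net, annotations = NULL) {
  if (!"cluster_id" %in% names(net$nodes)) {
    abort("run detect_communities() first")
  }
  nodes <- net$nodes
  if (!is.null(annotations)) {
    stopifnot_cols(annotations, c("feature_id", "gene"), "annotation map")
    nodes <- nodes |>
      select(-"gene") |>
      left_join(
        rename(annotations, name = "feature_id"),
        by = "name"
      )
  }
  edge_counts <- net$edges |>
    count(.data$exposure, name = "n_assoc")
  gene_layers <- c("methylation", "expression", "mirna", "protein")
  nodes |>
    group_by(.data$cluster_id) |>
    group_modify(function(d, key) {
      expos <- d |>
        filter(.data$type == "exposure") |>
        left_join(edge_counts, by = c(name = "exposure")) |>
        arrange(desc(.data$n_assoc), .data$name)
      feats <- filter(d, .data$type == "feature")
      layer_counts <- setNames(
        lapply(OMICS_LAYERS, function(ly) sum(feats$layer == ly)),
        OMICS_LAYERS
      )
      genes <- feats$gene[feats$layer %in% gene_layers]
      genes <- unique(genes[!is.na(genes)])
      tibble(
        exposures = paste(expos$name, collapse = ", "),
        n_exposures = nrow(expos),
        !!!layer_counts,
        total_features = nrow(feats),
        total_annotated_genes = length(genes)
      )
    }) |>
    ungroup() |>
    arrange(.data$cluster_id)
}

#' Export a network as node/edge tables and GraphML
#'
#' Writes `nodes.tsv`, `edges.tsv` and `network.graphml` (an XML graph
#' interchange dialect readable by common graph viewers) into a
#' directory.
#'
#' @param net An `assoc_network`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  node_path <- file.path(dir, "nodes.tsv")
  edge_path <- file.path(dir, "edges.tsv")
  gml_path <- file.path(dir, "network.graphml")
  readr::write_tsv(net$nodes, node_path, progress = FALSE)
  readr::write_tsv(
    select(net$edges, -any_of("significant")), edge_path,
    progress = FALSE
  )
  g <- net$graph
  for (at in igraph::vertex_attr_names(g)) {
    v <- igraph::vertex_attr(g, at)
    if (is.character(v) && anyNA(v)) {
      g <- igraph::set_vertex_attr(g, at, value = ifelse(is.na(v), "", v))
    }
  }
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(node_path, edge_path, gml_path))
}
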