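#' Signal-transduction network container
#'
#' A directed molecular network: an edge tibble (`source`, `target`,
#' `relation`) plus a node tibble (`id`, `kind`, `genes`, comma-separated
#' gene symbols, possibly empty for small molecules), backed by an igraph
#' graph for traversal.
#'
#' @param edges Edge tibble (`source`, `target`, `relation`).
#' @param nodes Optional node tibble (`id`, `kind`, `genes`); nodes
#'   appearing only in `edges` are added with empty annotation.
#' @return An object of class `signal_network`.
#' @export
signal_network <- function(edges, nodes = NULL) {
  ids <- unique(c(edges$source, edges$target,
                  if (!is.null(nodes)) nodes$id))
  if (is.null(nodes)) {
    nodes <- tibble::tibble(id = ids, kind = "protein",
                            genes = NA_character_)
  } else {
    missing <- setdiff(ids, nodes$id)
    if (length(missing) > 0) {
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        id = missing, kind = "other", genes = NA_character_))
    }
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target")], directed = TRUE,
    vertices = nodes$id)
  structure(list(edges = edges, nodes = nodes, graph = g),
            class = "signal_network")
}

#' @export
print.signal_network <- function(x, ...) {
  cat("Signal network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges;",
      sum(x$nodes$kind == "tf"), "TF node(s),",
      sum(x$edges$source == x$edges$target), "self-loop(s)\n")
  invisible(x)
}

#' Read a signal-transduction network from an edge-list TSV
#'
#' Rows carry `source`, `target`, `relation` and optional comma-separated
#' `source_genes` / `target_genes`; duplicate edges collapse, self-loops
#' are retained, and per-node gene annotations aggregate over all rows.
#'
#' @param path TSV path.
#' @param reverse_edges Set when the file stores edges target-first
#'   (regulated, regulator).
#' @return A `signal_network`.
#' @export
read_network <- function(path, reverse_edges = FALSE) {
  edges <- read_network_edges(path)
  if (reverse_edges) {
    edges <- dplyr::rename(edges, source = "target", target = "source")
  }
  grab <- function(node_col, gene_col) {
    if (gene_col %in% names(edges)) {
      tibble::tibble(id = edges[[node_col]], genes = edges[[gene_col]])
    } else {
      NULL
    }
  }
  ann <- dplyr::bind_rows(grab("source", "source_genes"),
                          grab("target", "target_genes"))
  nodes <- tibble::tibble(id = unique(c(edges$source, edges$target)))
  if (!is.null(ann) && nrow(ann) > 0) {
    agg <- dplyr::summarize(
      dplyr::group_by(ann[!is.na(ann$genes), ], .data$id),
      genes = paste(sort(unique(unlist(strsplit(.data$genes, ",")))),
                    collapse = ","), .groups = "drop")
    nodes <- dplyr::left_join(nodes, agg, by = "id")
  } else {
    nodes$genes <- NA_character_
  }
  nodes$kind <- "protein"
  signal_network(edges[, c("source", "target", "relation")], nodes)
}

#' Nodes reachable downstream of a candidate within a radius
#'
#' A candidate master regulator sits upstream of its targets; traversal
#' follows edge direction from the candidate toward the TFs. Returns
#' shortest directed distances for every node within `radius` steps
#' (excluding the candidate itself).
#'
#' @param network A `signal_network`.
#' @param node Candidate node id.
#' @param radius Maximum number of steps (>= 1).
#' @return Named integer vector of distances (1..radius).
#' @export
upstream_reach <- function(network, node, radius) {
  if (radius < 1) up_abort("radius must be >= 1")
  if (!node %in% network$nodes$id) up_abort("unknown node id")
  d <- igraph::distances(network$graph, v = node, mode = "out")[1, ]
  d <- d[is.finite(d) & d >= 1 & d <= radius]
  stats::setNames(as.integer(d), names(d))
}

# Distance matrix (candidates x TF universe) used by the scorer and the
# permutation null; Inf where unreachable.
#' @noRd
distance_to <- function(network, to_ids) {
  igraph::distances(network$graph, to = to_ids, mode = "out")
}

#' Score candidate master regulators by TF coverage and proximity
#'
#' For every node reaching at least one TF within `radius` directed
#' steps, the score averages `1 / (1 + d)` over the TF set (zero
#' contribution from unreached TFs): a node directly regulating every TF
#' scores 0.5; covering many TFs at short distance is rewarded, and the
#' score is bounded by (0, 1].
#'
#' @param network A `signal_network`.
#' @param tf_nodes Character vector of TF node ids (>= 2, all present).
#' @param radius Maximum upstream distance in steps (default 12).
#' @return Tibble `node_id`, `genes`, `score`, `n_reached`,
#'   `reached_tfs` (list column of named distance vectors), sorted by
#'   descending score.
#' @export
score_candidates <- function(network, tf_nodes, radius = 12) {
  if (length(tf_nodes) < 2) up_abort("need at least 2 TF nodes")
  if (!all(tf_nodes %in% network$nodes$id)) {
    up_abort("TF node(s) absent from the network")
  }
  D <- distance_to(network, tf_nodes)
  contrib <- ifelse(is.finite(D) & D <= radius, 1 / (1 + D), 0)
  score <- unname(rowMeans(contrib))
  reached_n <- unname(rowSums(contrib > 0))
  keep <- which(reached_n > 0)
  out <- tibble::tibble(
    node_id = rownames(D)[keep],
    genes = network$nodes$genes[match(rownames(D)[keep], network$nodes$id)],
    score = score[keep],
    n_reached = as.integer(reached_n[keep]),
    reached_tfs = purrr::map(keep, function(i) {
      d <- D[i, ]
      d <- d[is.finite(d) & d <= radius]
      stats::setNames(as.integer(d), colnames(D)[is.finite(D[i, ]) &
                                                   D[i, ] <= radius])
    })
  )
  dplyr::arrange(out, dplyr::desc(.data$score), .data$node_id)
}

#' Permutation significance of master-regulator scores
#'
#' Draws `n_perm` random TF sets of the observed size from a TF-like node
#' universe and rescoring every candidate gives a per-node null: `z` is
#' the standard score against that null and `fdr` the empirical estimate
#' (fraction of all null scores at least as high, divided by the fraction
#' of observed scores at least as high, clipped to \[0, 1\]).
#'
#' @param network A `signal_network`.
#' @param tf_nodes Observed TF node ids.
#' @param radius Maximum upstream distance (default 12).
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param tf_universe Node ids to sample null TF sets from; default all
#'   gene-annotated nodes (a degree-plausible stand-in for TF-like
#'   nodes).
#' @return [score_candidates()] output augmented with `z_score` and
#'   `fdr`.
#' @export
permutation_significance <- function(network, tf_nodes, radius = 12,
                                     n_perm = 1000, seed = 1,
                                     tf_universe = NULL) {
  if (n_perm < 100) up_abort("n_perm must be >= 100")
  if (is.null(tf_universe)) {
    tf_universe <- network$nodes$id[!is.na(network$nodes$genes)]
    if (length(tf_universe) < length(tf_nodes)) {
      tf_universe <- network$nodes$id
    }
  }
  if (length(tf_universe) < length(tf_nodes)) {
    up_abort("TF universe smaller than the TF set")
  }
  obs <- score_candidates(network, tf_nodes, radius)
  D <- distance_to(network, tf_universe)
  S <- ifelse(is.finite(D) & D <= radius, 1 / (1 + D), 0)
  k <- length(tf_nodes)
  null_scores <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rowMeans(S[, sample.int(ncol(S), k), drop = FALSE])
    }, numeric(nrow(S)))
  })
  mu <- rowMeans(null_scores)
  sdv <- pmax(apply(null_scores, 1, sd), 1e-9)
  idx <- match(obs$node_id, rownames(D))
  obs$z_score <- (obs$score - mu[idx]) / sdv[idx]
  all_null <- as.vector(null_scores)
  obs$fdr <- vapply(obs$score, function(s) {
    num <- mean(all_null >= s)
    den <- mean(obs$score >= s)
    min(1, num / den)
  }, numeric(1))
  obs
}

#' Rank master regulators by combined score and z ranks
#'
#' `ranks_sum` adds the rank by score (descending) and the rank by z
#' score (descending), ties sharing the smaller rank; results are sorted
#' by `ranks_sum`, then `fdr`.
#'
#' @param results Tibble from [permutation_significance()].
#' @return The tibble with a `ranks_sum` column, re-sorted.
#' @export
rank_regulators <- function(results) {
  if (!all(c("z_score", "fdr") %in% names(results))) {
    up_abort("results must carry z_score and fdr")
  }
  r_score <- rank(-results$score, ties.method = "min")
  r_z <- rank(-results$z_score, ties.method = "min")
  results$ranks_sum <- as.integer(r_score + r_z)
  dplyr::arrange(results, .data$ranks_sum, .data$fdr, .data$node_id)
}

#' Positive-feedback filter on master regulators
#'
#' Keeps regulators whose own encoding gene shows evidence of a positive
#' feedback loop: the gene's promoter composite score reaches the
#' module's critical value AND the gene is among the up-regulated DEGs.
#' Complexes and modified forms pass when any member gene passes.
#'
#' @param results Regulator tibble (with `genes` comma-separated).
#' @param composite_scores Named numeric vector, gene -> composite
#'   promoter score.
#' @param critical_value Composite-score threshold (kept when >=).
#' @param deg_up Character vector of up-regulated genes (already
#'   filtered at the fold-change threshold).
#' @return The filtered tibble, with a `feedback_gene` column naming the
#'   qualifying gene.
#' @export
feedback_filter <- function(results, composite_scores, critical_value,
                            deg_up) {
  qualifying <- function(genes) {
    if (is.na(genes)) return(NA_character_)
    gs <- strsplit(genes, ",")[[1]]
    ok <- gs[gs %in% deg_up &
               !is.na(composite_scores[gs]) &
               composite_scores[gs] >= critical_value]
    if (length(ok) == 0) NA_character_ else ok[1]
  }
  results$feedback_gene <- vapply(results$genes, qualifying, character(1),
                                  USE.NAMES = FALSE)
  results[!is.na(results$feedback_gene), ]
}
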