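#' Weighted running-sum enrichment score
#'
#' Walks the ranked gene list accumulating `+w_i / sum(w_hits)` at set
#' members and `-1 / (n - |S|)` at non-members; the enrichment score is
#' the running-sum extremum of largest magnitude. Weights are typically
#' `|logFC|` (weight exponent 1).
#'
#' @param ranked Tibble with columns `gene` and `weight`, ordered from
#'   most to least interesting; genes must be unique.
#' @param gene_set Character vector of member genes (at least one must be
#'   present in the ranking, and not all genes may be members).
#' @return A list with `es` and the `running` profile (numeric, one entry
#'   per ranked gene).
#' @export
enrichment_score <- function(ranked, gene_set) {
  if (anyDuplicated(ranked$gene)) up_abort("ranked genes must be unique")
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) up_abort("no gene-set member present in the ranking")
  if (all(hit)) up_abort("gene set covers the whole ranking")
  w <- abs(ranked$weight)
  wsum <- sum(w[hit])
  if (wsum == 0) w[hit] <- wsum <- 1  # all-zero weights: fall back to hits
  step <- ifelse(hit, w / sum(w[hit]), -1 / (nrow(ranked) - sum(hit)))
  running <- cumsum(step)
  hi <- max(running); lo <- min(running)
  es <- if (hi >= -lo) hi else lo  # extremum by magnitude, ties positive
  list(es = es, running = running)
}

#' GSEA over a gene-set collection with gene-label permutations
#'
#' Computes the running-sum enrichment score per set, then a null from
#' `n_perm` random same-size gene sets; `nes` normalizes the observed
#' score by the mean magnitude of same-sign null scores, and `p` is the
#' (add-one) fraction of same-sign null scores at least as extreme.
#' False-discovery rates are BH-adjusted across sets.
#'
#' @param ranked Tibble (`gene`, `weight`), ordered.
#' @param collection Gene-set tibble from [read_gmt()].
#' @param n_perm Permutations (>= 100; default 1000).
#' @param min_size Minimum set members present in the ranking
#'   (default 5).
#' @param seed Integer seed.
#' @return Tibble: `set_id`, `size`, `es`, `nes`, `p_value`, `fdr`.
#' @export
gsea <- function(ranked, collection, n_perm = 1000, min_size = 5,
                 seed = 1) {
  if (n_perm < 100) up_abort("n_perm must be >= 100")
  sizes <- vapply(collection$genes,
                  function(g) sum(ranked$gene %in% g), integer(1))
  keep <- sizes >= min_size & sizes < nrow(ranked)
  if (!any(keep)) up_abort("no gene set passes the size filter")
  collection <- collection[keep, ]
  sizes <- sizes[keep]
  withr::with_seed(seed, {
    res <- purrr::map_dfr(seq_len(nrow(collection)), function(i) {
      obs <- enrichment_score(ranked, collection$genes[[i]])$es
      k <- sizes[i]
      null_es <- vapply(seq_len(n_perm), function(j) {
        enrichment_score(ranked, safe_sample(ranked$gene, k))$es
      }, numeric(1))
      same <- null_es[sign(null_es) == sign(obs)]
      nes <- if (length(same) > 0) obs / mean(abs(same)) else NA_real_
      p <- (1 + sum(abs(same) >= abs(obs))) / (1 + length(same))
      tibble::tibble(set_id = collection$set_id[i], size = k, es = obs,
                     nes = nes, p_value = p)
    })
    res$fdr <- p.adjust(res$p_value, "BH")
    res
  })
}

#' Hypergeometric overlap test for two gene lists
#'
#' Upper-tail probability of observing at least the given overlap when
#' both sets are drawn independently from a universe of `universe` genes.
#'
#' @param set_a,set_b Character gene vectors.
#' @param universe Universe size (>= the union size).
#' @return A list with `overlap` and `p`.
#' @export
#' @examples
#' overlap_test(c("A", "B"), c("B", "C"), universe = 100)
overlap_test <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (universe < length(union(set_a, set_b))) {
    up_abort("universe smaller than the union of the sets")
  }
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, length(set_a), universe - length(set_a),
              length(set_b), lower.tail = FALSE)
  list(overlap = k, p = p)
}
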