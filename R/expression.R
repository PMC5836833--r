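#' @noRd
expr_matrix <- function(expr) {
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id"), drop = FALSE])
  rownames(m) <- expr$gene_id
  m
}

#' @noRd
expr_tibble <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m))
}

#' Log2-transform and quantile-align an expression matrix
#'
#' When `log2_input = FALSE` the raw values are log2-transformed
#' (rejecting nonpositive values). With `align = TRUE` each sample is then
#' quantile-normalized to the pooled distribution
#' (via [limma::normalizeQuantiles()]). Already-log2 input with the flag
#' set and `align = FALSE` is returned unchanged.
#'
#' @param expr Wide expression tibble (`gene_id` + one column per sample).
#' @param log2_input Set when values are already on the log2 scale.
#' @param align Quantile-align samples (default: only when transforming
#'   raw input).
#' @return Expression tibble of the same shape.
#' @export
normalize_log2 <- function(expr, log2_input = FALSE, align = !log2_input) {
  m <- expr_matrix(expr)
  if (!log2_input) {
    if (any(m <= 0)) up_abort("raw intensities must be positive")
    m <- log2(m)
  }
  if (align) m <- limma::normalizeQuantiles(m)
  if (any(!is.finite(m))) up_abort("non-finite values after normalization")
  expr_tibble(m)
}

#' Average technical replicates into single samples
#'
#' Samples sharing a `replicate_block` label in the design are averaged
#' gene-wise into one column; the design is collapsed accordingly. With no
#' `replicate_block` column (or all `NA`) the input is returned unchanged.
#'
#' @param expr Wide expression tibble.
#' @param design Design tibble (`sample`, `condition`, ...,
#'   optionally `replicate_block`).
#' @return A list with collapsed `expr` and `design`.
#' @export
collapse_technical_replicates <- function(expr, design) {
  validate_expression(expr, design)
  if (!"replicate_block" %in% names(design) ||
      all(is.na(design$replicate_block))) {
    return(list(expr = expr, design = design))
  }
  design <- design[match(setdiff(names(expr), "gene_id"), design$sample), ]
  block <- ifelse(is.na(design$replicate_block),
                  design$sample, design$replicate_block)
  span <- tapply(design$condition, block, function(x) length(unique(x)))
  if (any(span > 1)) {
    up_abort("a replicate block spans two conditions")
  }
  m <- expr_matrix(expr)
  collapsed <- vapply(unique(block), function(b) {
    rowMeans(m[, block == b, drop = FALSE])
  }, numeric(nrow(m)))
  new_design <- design[!duplicated(block), ]
  new_design$sample <- unique(block)
  new_design$replicate_block <- NULL
  list(expr = expr_tibble(collapsed), design = new_design)
}

#' Differential expression between two conditions
#'
#' `logFC` is the mean log2 difference (group A minus group B). The
#' default method fits the linear model with empirical-Bayes moderated t
#' statistics (limma); `method = "welch"` uses an ordinary per-gene Welch
#' t-test instead. P-values are Benjamini-Hochberg adjusted.
#'
#' @param expr Wide expression tibble.
#' @param design Design tibble with a `condition` column.
#' @param group_a,group_b Condition labels to contrast (A minus B).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return A tibble of DEG records: `gene_id`, `logFC`, `p_value`,
#'   `adj_p`, one row per gene.
#' @export
differential_expression <- function(expr, design, group_a, group_b,
                                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  validate_expression(expr, design)
  design <- design[match(setdiff(names(expr), "gene_id"), design$sample), ]
  in_a <- design$condition == group_a
  in_b <- design$condition == group_b
  if (sum(in_a) < 2 || sum(in_b) < 2) {
    up_abort("each group needs at least 2 samples")
  }
  m <- expr_matrix(expr)[, in_a | in_b, drop = FALSE]
  grp <- factor(design$condition[in_a | in_b], levels = c(group_b, group_a))
  if (method == "moderated") {
    X <- stats::model.matrix(~grp)
    fit <- limma::eBayes(limma::lmFit(m, X))
    tab <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
    out <- tibble::tibble(gene_id = rownames(m), logFC = tab$logFC,
                          p_value = tab$P.Value, adj_p = tab$adj.P.Val)
  } else {
    a <- m[, grp == group_a, drop = FALSE]
    b <- m[, grp == group_b, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
    lfc <- rowMeans(a) - rowMeans(b)
    se2 <- va / na + vb / nb
    tstat <- lfc / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[!is.finite(p)] <- 1
    out <- tibble::tibble(gene_id = rownames(m), logFC = unname(lfc),
                          p_value = unname(p),
                          adj_p = unname(p.adjust(p, "BH")))
  }
  out
}

#' Split DEG records into up- and down-regulated gene sets
#'
#' Uses strict inequalities, the conventional thresholds being
#' `p < 0.05` and `|logFC| > 0.58` (fold change 1.5).
#'
#' @param records DEG tibble from [differential_expression()].
#' @param p_threshold,logfc_threshold Positive thresholds (defaults 0.05
#'   and 0.58).
#' @param use_adjusted Filter on `adj_p` instead of raw `p_value`.
#' @return A list with character vectors `up` and `down`.
#' @export
filter_degs <- function(records, p_threshold = 0.05, logfc_threshold = 0.58,
                        use_adjusted = FALSE) {
  if (p_threshold <= 0 || logfc_threshold <= 0) {
    up_abort("thresholds must be > 0")
  }
  p <- if (use_adjusted) records$adj_p else records$p_value
  list(
    up = records$gene_id[p < p_threshold & records$logFC > logfc_threshold],
    down = records$gene_id[p < p_threshold & records$logFC < -logfc_threshold]
  )
}

#' Compare DEG sets across conditions
#'
#' Partitions the per-condition changed-gene sets (up plus down) into
#' Venn regions, and reports the dynamic categories for each pair of
#' conditions: genes changed in opposite directions, and genes changed in
#' one condition only.
#'
#' @param sets_by_condition Named list; each element a list with `up` and
#'   `down` character vectors (as from [filter_degs()]).
#' @return A list with `regions` (tibble: `conditions`, `n`, `genes`) and
#'   `dynamics` (tibble: `condition_a`, `condition_b`,
#'   `opposite_direction`, `a_only`, `b_only` list columns).
#' @export
compare_deg_sets <- function(sets_by_condition) {
  if (length(sets_by_condition) < 2) {
    up_abort("need at least 2 conditions to compare")
  }
  conds <- names(sets_by_condition)
  changed <- purrr::map(sets_by_condition, ~ union(.x$up, .x$down))
  all_genes <- unique(unlist(changed))
  key <- vapply(all_genes, function(g) {
    paste(conds[vapply(changed, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  regions <- tibble::tibble(
    conditions = unique(key),
    genes = purrr::map(unique(key), ~ all_genes[key == .x])
  )
  regions$n <- lengths(regions$genes)
  regions <- regions[, c("conditions", "n", "genes")]
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  dynamics <- dplyr::bind_rows(purrr::map(pairs, function(pr) {
    a <- sets_by_condition[[pr[1]]]; b <- sets_by_condition[[pr[2]]]
    tibble::tibble(
      condition_a = pr[1], condition_b = pr[2],
      opposite_direction = list(union(intersect(a$up, b$down),
                                      intersect(a$down, b$up))),
      a_only = list(setdiff(union(a$up, a$down), union(b$up, b$down))),
      b_only = list(setdiff(union(b$up, b$down), union(a$up, a$down)))
    )
  }))
  list(regions = regions, dynamics = dynamics)
}

#' Correlate log fold changes between two DEG tables
#'
#' Pearson correlation over genes present in both tables, with the
#' two-sided p-value from the t transform.
#'
#' @param records_a,records_b DEG tibbles.
#' @return A list with `r`, `p` and `n_shared`.
#' @export
logfc_correlation <- function(records_a, records_b) {
  shared <- intersect(records_a$gene_id, records_b$gene_id)
  if (length(shared) < 3) up_abort("need at least 3 shared genes")
  a <- records_a$logFC[match(shared, records_a$gene_id)]
  b <- records_b$logFC[match(shared, records_b$gene_id)]
  ct <- cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_shared = length(shared))
}

#' Correlate gene expression with per-sample drug sensitivity
#'
#' Per-gene Pearson correlation of expression against IC50 across
#' samples; genes significant at `p < p_threshold` are split by
#' correlation sign. Constant-expression genes are excluded with a
#' warning.
#'
#' @param expr Wide expression tibble.
#' @param ic50_by_sample Named numeric vector, sample -> IC50 (uM).
#' @param p_threshold Significance threshold (default 0.01).
#' @return A list with `positive` and `negative` gene vectors and the
#'   full per-gene tibble `table` (`gene_id`, `r`, `p`).
#' @export
correlate_with_sensitivity <- function(expr, ic50_by_sample,
                                       p_threshold = 0.01) {
  samples <- intersect(setdiff(names(expr), "gene_id"),
                       names(ic50_by_sample))
  if (length(samples) < 4) up_abort("need IC50 values for >= 4 samples")
  y <- ic50_by_sample[samples]
  if (sd(y) == 0) up_abort("IC50 vector is constant")
  m <- expr_matrix(expr)[, samples, drop = FALSE]
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(paste0(sum(sds == 0),
                " constant-expression gene(s) excluded from correlation"))
  }
  keep <- sds > 0
  mk <- m[keep, , drop = FALSE]
  n <- length(y)
  r <- as.vector(cor(t(mk), y))
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  tab <- tibble::tibble(gene_id = rownames(mk), r = r, p = p)
  list(
    positive = tab$gene_id[tab$p < p_threshold & tab$r > 0],
    negative = tab$gene_id[tab$p < p_threshold & tab$r < 0],
    table = tab
  )
}
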