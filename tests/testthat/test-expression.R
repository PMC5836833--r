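make_expr <- function(m, genes = sprintf("g%d", seq_len(nrow(m)))) {
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(m))
}

make_design <- function(expr, condition, block = NULL) {
  d <- tibble::tibble(sample = setdiff(names(expr), "gene_id"),
                      condition = condition,
                      cell_line = "L1", replicate = "r1")
  if (!is.null(block)) d$replicate_block <- block
  d
}

test_that("normalization handles log2 flags and quantile alignment", {
  m <- matrix(c(8, 2, 4, 16), 2)
  expr <- make_expr(m)
  # already-log2 input with the flag set is returned unchanged
  expect_equal(normalize_log2(expr, log2_input = TRUE), expr)
  # raw values are log2ed before alignment
  out <- normalize_log2(make_expr(matrix(c(8, 8), 1)), align = FALSE)
  expect_equal(out$s1, 3)
  # permuted samples have identical sorted values after alignment
  x <- rnorm(50, 8)
  expr2 <- make_expr(cbind(x, sample(x)))
  out2 <- normalize_log2(expr2, log2_input = TRUE, align = TRUE)
  expect_equal(sort(out2$s1), sort(out2$s2))
  expect_error(normalize_log2(make_expr(matrix(c(-1, 2), 1))), "positive")
})

test_that("technical replicates collapse gene-wise by block", {
  expr <- make_expr(matrix(c(4, 4, 6, 6, 5, 5), 2))
  design <- make_design(expr, c("A", "A", "B"),
                        block = c("blk1", "blk1", "s3"))
  out <- collapse_technical_replicates(expr, design)
  expect_equal(ncol(out$expr), 3)  # gene_id + 2 samples
  expect_equal(out$expr$blk1, c(5, 5))  # mean of 4 and 6
  # identical replicate columns collapse to the same column
  expr2 <- make_expr(matrix(c(1, 2, 1, 2), 2))
  d2 <- make_design(expr2, c("A", "A"), block = c("b", "b"))
  expect_equal(collapse_technical_replicates(expr2, d2)$expr$b, c(1, 2))
  # no blocks: unchanged
  d3 <- make_design(expr2, c("A", "B"))
  expect_identical(collapse_technical_replicates(expr2, d3)$expr, expr2)
  # a block spanning conditions is rejected
  d4 <- make_design(expr2, c("A", "B"), block = c("b", "b"))
  expect_error(collapse_technical_replicates(expr2, d4), "spans")
})

test_that("differential expression returns mean-difference logFC", {
  set.seed(1)
  m <- matrix(rnorm(100 * 8, 8, 0.5), 100)
  m[1, ] <- rep(c(8, 4), each = 4)  # exact means, zero within-group var
  expr <- make_expr(m)
  design <- make_design(expr, rep(c("A", "B"), each = 4))
  deg <- differential_expression(expr, design, "A", "B")
  expect_equal(deg$logFC[deg$gene_id == "g1"], 4)
  expect_true(all(deg$adj_p >= deg$p_value - 1e-12))
  expect_true(all(deg$p_value >= 0 & deg$p_value <= 1))
  # invariant to sample and gene order
  perm_s <- c(1, sample(2:8))
  expr_p <- expr[, c(1, perm_s + 1)]
  deg_p <- differential_expression(expr_p, design, "A", "B")
  expect_equal(deg_p$logFC, deg$logFC)
  perm_g <- sample(nrow(expr))
  deg_g <- differential_expression(expr[perm_g, ], design, "A", "B")
  expect_equal(deg_g$logFC, deg$logFC[perm_g])
  expect_error(differential_expression(expr, design, "A", "C"),
               "at least 2")
})

test_that("null p-values are uniform and spikes are recovered", {
  sim <- gen_expression_design(10000, 0, 0, noise_sd = 0.25, seed = 21)
  deg <- differential_expression(sim$expr, sim$design, "A", "B")
  ks <- suppressWarnings(ks.test(deg$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)

  sim2 <- gen_expression_design(10000, 300, 1, noise_sd = 0.2, seed = 11)
  deg2 <- differential_expression(sim2$expr, sim2$design, "A", "B")
  sp <- dplyr::inner_join(deg2, sim2$truth$spiked_genes, by = "gene_id")
  dev <- abs(sp$logFC - sp$true_logfc)
  expect_lt(mean(sp$logFC - sp$true_logfc), 0.05)  # unbiased
  expect_gt(mean(dev < 0.2), 0.85)                 # tight recovery
  expect_lt(median(dev), 0.12)
})

test_that("DEG filtering uses strict thresholds and disjoint sets", {
  rec <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    logFC = c(0.58, 1.2, -0.9, -0.9),
    p_value = c(0.01, 0.001, 0.2, 0.01),
    adj_p = c(0.02, 0.002, 0.4, 0.02))
  f <- filter_degs(rec)
  expect_false("a" %in% c(f$up, f$down))  # boundary excluded (strict >)
  expect_true("b" %in% f$up)
  expect_false("c" %in% c(f$up, f$down))  # p too large
  expect_true("d" %in% f$down)
  expect_length(intersect(f$up, f$down), 0)
  expect_error(filter_degs(rec, p_threshold = 0), "> 0")
})

test_that("DEG set comparison partitions and finds opposite movers", {
  sets <- list(
    A = list(up = c("g1", "g2"), down = character(0)),
    B = list(up = "g2", down = "g1"))
  cmp <- compare_deg_sets(sets)
  both <- cmp$regions$genes[[which(cmp$regions$conditions == "A&B")]]
  expect_setequal(both, c("g1", "g2"))
  expect_setequal(cmp$dynamics$opposite_direction[[1]], "g1")
  # disjoint sets
  cmp2 <- compare_deg_sets(list(A = list(up = "x", down = character(0)),
                                B = list(up = "y", down = character(0))))
  expect_false("A&B" %in% cmp2$regions$conditions)
  expect_setequal(cmp2$dynamics$a_only[[1]], "x")
  expect_error(compare_deg_sets(sets["A"]), "at least 2")
})

test_that("logFC correlation behaves at the extremes and under the null", {
  rec <- tibble::tibble(gene_id = sprintf("g%d", 1:100),
                        logFC = rnorm(100), p_value = 0.5, adj_p = 0.5)
  expect_equal(logfc_correlation(rec, rec)$r, 1)
  neg <- rec; neg$logFC <- -rec$logFC
  expect_equal(logfc_correlation(rec, neg)$r, -1)
  big <- tibble::tibble(gene_id = sprintf("g%d", 1:1000),
                        logFC = 0, p_value = 0.5, adj_p = 0.5)
  ok <- withr::with_seed(31, {
    vapply(1:100, function(i) {
      a <- big; b <- big
      a$logFC <- rnorm(1000); b$logFC <- rnorm(1000)
      abs(logfc_correlation(a, b)$r)
    }, numeric(1))
  })
  expect_gte(mean(ok < 0.1), 0.95)
  expect_error(logfc_correlation(rec[1:2, ], rec[1:2, ]), "3 shared")
})

test_that("expression-sensitivity correlation recovers planted responders", {
  withr::with_seed(41, {
    n <- 52
    ic50 <- runif(n, 1, 30)
    m <- matrix(rnorm(300 * n, 8, 1), 300)
    responders <- 1:30
    for (g in responders) m[g, ] <- 8 + 0.3 * ic50 + rnorm(n, 0, 0.5)
    m[300, ] <- 5  # constant gene
    expr <- make_expr(m)
    res <- suppressWarnings(
      correlate_with_sensitivity(expr, setNames(ic50, names(expr)[-1])))
    recall <- mean(sprintf("g%d", responders) %in% res$positive)
    expect_gte(recall, 0.9)
    expect_false("g300" %in% res$table$gene_id)
    expect_warning(
      correlate_with_sensitivity(expr, setNames(ic50, names(expr)[-1])),
      "constant")
  })
  expect_error(correlate_with_sensitivity(
    make_expr(matrix(rnorm(40), 4)),
    setNames(rep(1, 10), sprintf("s%d", 1:10))), "constant")
})
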