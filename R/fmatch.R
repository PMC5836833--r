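#' Yes/No site-frequency enrichment ratio
#'
#' `R_YN = (Sites_Yes / Sites_No) / (Seq_Yes / Seq_No)`: the ratio of
#' per-set site frequencies, normalized by set sizes. A value above 1
#' indicates enrichment of sites in the Yes set. When `sites_no` is 0 a
#' pseudocount (default 0.5) replaces both zero site counts' denominator
#' term so the ratio stays finite.
#'
#' @param sites_yes,sites_no Site counts in the Yes and No sets.
#' @param seq_yes,seq_no Sequence counts (>= 1).
#' @param pseudocount Replacement for a zero `sites_no` (default 0.5).
#' @return The enrichment ratio.
#' @export
#' @examples
#' yes_no_ratio(10, 5, 100, 200)  # 4
yes_no_ratio <- function(sites_yes, sites_no, seq_yes, seq_no,
                         pseudocount = 0.5) {
  if (seq_yes < 1 || seq_no < 1) up_abort("sequence counts must be >= 1")
  if (sites_yes < 0 || sites_no < 0) up_abort("site counts must be >= 0")
  sn <- if (sites_no == 0) pseudocount else sites_no
  (sites_yes / sn) / (seq_yes / seq_no)
}

#' Binomial significance of Yes-set site enrichment
#'
#' Upper-tail binomial probability of observing at least `sites_yes`
#' sites in the Yes set out of `N = sites_yes + sites_no` total sites,
#' when each site lands in the Yes set with probability
#' `p = seq_yes / (seq_yes + seq_no)` (sets of equal-length windows, so
#' sequence counts are proportional to total scanned length):
#' `P(X >= x) = sum_{n=x..N} C(N,n) p^n (1-p)^(N-n)`.
#'
#' @inheritParams yes_no_ratio
#' @return The tail probability in \[0, 1\]; `sites_yes = 0` gives 1.
#' @export
#' @examples
#' binomial_enrichment_p(3, 1, 100, 100)  # 5/16
binomial_enrichment_p <- function(sites_yes, sites_no, seq_yes, seq_no) {
  if (sites_yes < 0 || sites_no < 0) up_abort("site counts must be >= 0")
  if (seq_yes + seq_no < 1) up_abort("need at least one sequence")
  if (sites_yes == 0) return(1)
  p <- seq_yes / (seq_yes + seq_no)
  N <- sites_yes + sites_no
  pbinom(sites_yes - 1, N, p, lower.tail = FALSE)
}

#' Optimize a per-PWM score cutoff by the Yes/No ratio
#'
#' Candidate thresholds are the distinct observed site scores
#' (descending). For each threshold the sites at or above it feed the
#' ratio and the binomial tail; the returned threshold maximizes the
#' ratio among those with `p <= alpha` and at least `min_yes_sites` Yes
#' sites, ties broken by smaller p, then by the higher threshold. When no
#' threshold satisfies the constraints, the result is flagged
#' `enriched = FALSE` and reports the best-p threshold.
#'
#' @param yes_scores,no_scores Numeric vectors of site scores collected
#'   from a permissive floor scan of the Yes and No sets.
#' @param seq_yes,seq_no Number of sequences in each set.
#' @param alpha Significance constraint (default 0.01).
#' @param min_yes_sites Minimum Yes sites at the chosen threshold
#'   (default 5); guards against degenerate single-site optima.
#' @param pseudocount Passed to [yes_no_ratio()].
#' @return A one-row tibble: `cutoff`, `sites_yes`, `sites_no`,
#'   `seq_yes`, `seq_no`, `ratio`, `p_value`, `enriched`.
#' @export
optimize_cutoff <- function(yes_scores, no_scores, seq_yes, seq_no,
                            alpha = 0.01, min_yes_sites = 5,
                            pseudocount = 0.5) {
  stopifnot(alpha > 0, alpha < 1)
  if (seq_yes < 1 || seq_no < 1) up_abort("sequence counts must be >= 1")
  thresholds <- sort(unique(c(yes_scores, no_scores)), decreasing = TRUE)
  if (length(thresholds) == 0) {
    return(tibble::tibble(cutoff = NA_real_, sites_yes = 0L, sites_no = 0L,
                          seq_yes = seq_yes, seq_no = seq_no,
                          ratio = NA_real_, p_value = 1, enriched = FALSE))
  }
  # every observed score is one of the thresholds, so counts at each
  # threshold are cumulative tallies down the sorted threshold list
  sy <- cumsum(tabulate(match(yes_scores, thresholds),
                        nbins = length(thresholds)))
  sn <- cumsum(tabulate(match(no_scores, thresholds),
                        nbins = length(thresholds)))
  sn_eff <- ifelse(sn == 0, pseudocount, sn)
  ratio <- (sy / sn_eff) / (seq_yes / seq_no)
  p_hit <- seq_yes / (seq_yes + seq_no)
  pval <- ifelse(sy == 0, 1,
                 pbinom(sy - 1, sy + sn, p_hit, lower.tail = FALSE))
  ok <- pval <= alpha & sy >= min_yes_sites
  pick_row <- function(idx) {
    tibble::tibble(cutoff = thresholds[idx], sites_yes = sy[idx],
                   sites_no = sn[idx], seq_yes = seq_yes, seq_no = seq_no,
                   ratio = ratio[idx], p_value = pval[idx],
                   enriched = any(ok))
  }
  if (any(ok)) {
    cand <- which(ok)
    # max ratio, then smaller p, then higher threshold
    cand <- cand[order(-ratio[cand], pval[cand], -thresholds[cand])]
    pick_row(cand[1])
  } else {
    best <- order(pval, -thresholds)[1]
    pick_row(best)
  }
}

#' F-Match enrichment over a PWM library
#'
#' Scans both promoter sets at a permissive floor cutoff, optimizes the
#' cutoff per matrix with [optimize_cutoff()], and reports every matrix
#' with its optimized counts, ratio and p-value. Matrices achieving a
#' Yes/No ratio > 1 and `p < alpha` are flagged `passed`; rows are sorted
#' passed-first by descending ratio. A BH-adjusted column is attached for
#' information only (the selection filter uses the raw p, as is
#' conventional for this analysis).
#'
#' @param library PWM library tibble.
#' @param yes,no Promoter set tibbles.
#' @param alpha Significance threshold (default 0.01).
#' @param floor_cutoff Permissive scan floor (default 0.7).
#' @param min_yes_sites Passed to [optimize_cutoff()].
#' @param sites Optional precomputed site table for `yes` and `no`
#'   combined (columns as [scan_set()] plus `set`); skips rescanning.
#' @return Enrichment tibble: `pwm_id`, `tf_gene`, `cutoff`, `sites_yes`,
#'   `sites_no`, `seq_yes`, `seq_no`, `ratio`, `p_value`, `adj_p`,
#'   `passed`.
#' @export
run_fmatch <- function(library, yes, no, alpha = 0.01, floor_cutoff = 0.7,
                       min_yes_sites = 5, sites = NULL) {
  if (nrow(yes) == 0) up_abort("Yes promoter set is empty")
  if (nrow(no) == 0) up_abort("No promoter set is empty")
  if (is.null(sites)) {
    sites <- dplyr::bind_rows(
      dplyr::mutate(scan_set(library, yes, floor_cutoff), set = "yes"),
      dplyr::mutate(scan_set(library, no, floor_cutoff), set = "no"))
  }
  res <- dplyr::bind_rows(purrr::map(seq_len(nrow(library)), function(i) {
    s <- sites[sites$pwm_id == library$id[i], ]
    r <- optimize_cutoff(s$score[s$set == "yes"], s$score[s$set == "no"],
                         seq_yes = nrow(yes), seq_no = nrow(no),
                         alpha = alpha, min_yes_sites = min_yes_sites)
    dplyr::bind_cols(tibble::tibble(pwm_id = library$id[i],
                                    tf_gene = library$tf_gene[i]), r)
  }))
  res$passed <- res$enriched & !is.na(res$ratio) & res$ratio > 1 &
    res$p_value < alpha
  res$adj_p <- p.adjust(res$p_value, "BH")
  dplyr::arrange(res, dplyr::desc(.data$passed), dplyr::desc(.data$ratio))
}
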