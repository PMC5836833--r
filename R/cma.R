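#' Wilcoxon rank-sum test
#'
#' Exact p by enumeration of all group assignments when the pooled size
#' is at most `exact_limit` (ties handled naturally); otherwise the
#' normal approximation with tie correction (no continuity correction).
#'
#' @param a,b Numeric score vectors (each of length >= 2).
#' @param alternative `"two.sided"` (default), `"greater"` (a tends
#'   larger) or `"less"`.
#' @param exact_limit Largest pooled size for the exact branch
#'   (default 12).
#' @return The p-value; 1 when all values are tied.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(3, 4, 5), c(1, 2), alternative = "greater")  # 0.1
wilcoxon_rank_sum <- function(a, b, alternative = c("two.sided", "greater",
                                                    "less"),
                              exact_limit = 12) {
  alternative <- match.arg(alternative)
  if (length(a) < 2 || length(b) < 2) up_abort("need >= 2 values per group")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) return(1)
  na <- length(a); nb <- length(b); n <- na + nb
  u_of <- function(idx_a) {
    sum(rank(pooled)[idx_a]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  if (n <= exact_limit) {
    combos <- combn(n, na)
    r <- rank(pooled)
    u_null <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    p_ge <- mean(u_null >= u_obs)
    p_le <- mean(u_null <= u_obs)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(p)
  }
  r <- rank(pooled)
  ties <- table(r)
  mu <- na * nb / 2
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u_obs - mu) / sqrt(sigma2)
  switch(alternative,
         greater = pnorm(z, lower.tail = FALSE),
         less = pnorm(z),
         two.sided = 2 * pnorm(-abs(z)))
}

#' Separation metrics of Yes versus No composite scores
#'
#' AUC by the rank statistic; the critical value is the score threshold
#' minimizing the sum of false-positive and false-negative rates
#' (classify as Yes when score >= threshold), ties resolved toward the
#' higher threshold.
#'
#' @param yes_scores,no_scores Numeric score vectors (non-empty).
#' @return A list with `auc`, `critical_value`, `fp_rate`, `fn_rate`.
#' @export
classification_metrics <- function(yes_scores, no_scores) {
  if (length(yes_scores) == 0 || length(no_scores) == 0) {
    up_abort("both score vectors must be non-empty")
  }
  na <- length(yes_scores); nb <- length(no_scores)
  r <- rank(c(yes_scores, no_scores))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  auc <- u / (na * nb)
  thr <- sort(unique(c(yes_scores, no_scores)), decreasing = TRUE)
  fp <- vapply(thr, function(t) mean(no_scores >= t), numeric(1))
  fn <- vapply(thr, function(t) mean(yes_scores < t), numeric(1))
  tot <- fp + fn
  best <- which(tot == min(tot))
  pick <- best[1]  # thresholds descending: first minimum = highest threshold
  list(auc = auc, critical_value = thr[pick], fp_rate = fp[pick],
       fn_rate = fn[pick])
}

#' Composite promoter score of a module
#'
#' The module is a set of (matrix, cutoff, weight) members with a
#' co-localization window. For every window placement, each member
#' contributes `weight * best member site score` among its sites at or
#' above its cutoff that start inside the window; the promoter's score is
#' the maximum over placements (windows anchored at site starts suffice).
#' A window spanning the whole promoter disables co-localization.
#'
#' @param module A `composite_module` (see [run_cma()]) or a list with
#'   `members` (tibble: `pwm_id`, `cutoff`, `weight`) and `window`.
#' @param promoter_sites Site tibble for one promoter (`pwm_id`,
#'   `position`, `score`).
#' @return The composite score (0 when no member site passes its cutoff).
#' @export
composite_score <- function(module, promoter_sites) {
  members <- module$members
  window <- module$window
  s <- promoter_sites[promoter_sites$pwm_id %in% members$pwm_id, ]
  if (nrow(s) == 0) return(0)
  m_idx <- match(s$pwm_id, members$pwm_id)
  keep <- s$score >= members$cutoff[m_idx]
  s <- s[keep, ]; m_idx <- m_idx[keep]
  if (nrow(s) == 0) return(0)
  best_total <- 0
  for (a in seq_len(nrow(s))) {
    lo <- s$position[a]; hi <- lo + window
    inside <- s$position >= lo & s$position <= hi
    contrib <- vapply(seq_len(nrow(members)), function(m) {
      sc <- s$score[inside & m_idx == m]
      if (length(sc) == 0) 0 else members$weight[m] * max(sc)
    }, numeric(1))
    best_total <- max(best_total, sum(contrib))
  }
  best_total
}

#' Genetic-algorithm parameters for composite-module search
#'
#' @param population Individuals per generation (>= 10).
#' @param generations Number of generations (>= 1).
#' @param mutation_prob Per-field mutation probability.
#' @param min_members,max_members Module size bounds.
#' @param elitism Elite individuals copied unchanged each generation.
#' @param tournament_k Tournament size for selection.
#' @param cutoff_sd,weight_sd Gaussian mutation SDs for member cutoffs
#'   and weights.
#' @param min_window Smallest co-localization window in bases.
#' @return A named list of GA parameters.
#' @export
cma_ga_control <- function(population = 100, generations = 200,
                           mutation_prob = 0.2, min_members = 2,
                           max_members = 15, elitism = 2, tournament_k = 3,
                           cutoff_sd = 0.05, weight_sd = 0.2,
                           min_window = 100) {
  stopifnot(population >= 10, generations >= 1, min_members >= 2,
            max_members >= min_members, elitism >= 1)
  as.list(environment())
}

# Convert a site table to the CSR layout the C++ evaluator expects.
#' @noRd
sites_csr <- function(sites, promoter_ids, pwm_ids) {
  s <- sites[sites$seq_id %in% promoter_ids & sites$pwm_id %in% pwm_ids, ]
  pidx <- match(s$seq_id, promoter_ids)
  ord <- order(pidx, s$position)
  s <- s[ord, ]; pidx <- pidx[ord]
  counts <- tabulate(pidx, nbins = length(promoter_ids))
  list(
    prom_ptr = as.integer(c(0, cumsum(counts))),
    site_pwm = match(s$pwm_id, pwm_ids) - 1L,
    site_pos = as.numeric(s$position),
    site_score = s$score,
    n_prom = length(promoter_ids)
  )
}

#' @noRd
csr_composite <- function(csr, n_pwms, members_idx, cutoffs, weights,
                          window) {
  member_of <- rep(-1L, n_pwms)
  member_of[members_idx] <- seq_along(members_idx) - 1L
  composite_scores_cpp(csr$prom_ptr, csr$site_pwm, csr$site_pos,
                       csr$site_score, member_of, cutoffs, weights, window)
}

#' Composite-module discovery by genetic algorithm
#'
#' Searches for a combination of matrices with member-specific cutoffs
#' and weights whose composite promoter score (see [composite_score()])
#' best separates the Yes promoters from the No promoters. Individuals
#' encode the member subset, cutoffs, weights and co-localization window;
#' fitness is `-log10` of the one-sided Wilcoxon rank-sum p (Yes scores
#' larger), ties broken by AUC. Selection is tournament (k = 3) with
#' uniform crossover on membership, Gaussian mutation on cutoffs and
#' weights, add/drop mutation on membership, and elitism. Fully
#' deterministic under `seed`.
#'
#' @param library PWM library tibble (the scanning source).
#' @param yes,no Promoter set tibbles.
#' @param ga GA parameters from [cma_ga_control()].
#' @param seed Integer seed.
#' @param candidates Candidate matrices: a character vector of matrix
#'   ids, an enrichment tibble from [run_fmatch()] (its `passed` rows are
#'   used), or `NULL` for the whole library.
#' @param floor_cutoff Permissive scan floor feeding the site table
#'   (default 0.7).
#' @param sites Optional precomputed site table covering both sets.
#' @return A `composite_module` object: `members` tibble (`pwm_id`,
#'   `cutoff`, `weight`), `window`, `fitness`, `p_value`, `auc`,
#'   `critical_value`, `fp_rate`, `fn_rate`, per-promoter score tibbles
#'   `yes_scores` / `no_scores`, and a GA `trace` tibble.
#' @export
run_cma <- function(library, yes, no, ga = cma_ga_control(), seed = 1,
                    candidates = NULL, floor_cutoff = 0.7, sites = NULL) {
  cand_ids <- resolve_candidates(candidates, library)
  if (length(cand_ids) < 4) up_abort("need at least 4 candidate matrices")
  lib <- library[match(cand_ids, library$id), ]
  if (is.null(sites)) {
    sites <- dplyr::bind_rows(scan_set(lib, yes, floor_cutoff),
                              scan_set(lib, no, floor_cutoff))
  }
  csr_yes <- sites_csr(sites, yes$gene_id, cand_ids)
  csr_no <- sites_csr(sites, no$gene_id, cand_ids)
  n_cand <- length(cand_ids)
  prom_len <- max(nchar(yes$sequence))
  max_m <- min(ga$max_members, n_cand)

  evaluate <- function(ind) {
    ys <- csr_composite(csr_yes, n_cand, ind$members, ind$cutoffs,
                        ind$weights, ind$window)
    ns <- csr_composite(csr_no, n_cand, ind$members, ind$cutoffs,
                        ind$weights, ind$window)
    p <- wilcoxon_rank_sum(ys, ns, alternative = "greater")
    na <- length(ys); nb <- length(ns)
    u <- sum(rank(c(ys, ns))[seq_len(na)]) - na * (na + 1) / 2
    list(fitness = -log10(max(p, 1e-300)), p_value = p, auc = u / (na * nb),
         yes_scores = ys, no_scores = ns)
  }
  random_individual <- function() {
    k <- sample(ga$min_members:max_m, 1)
    list(members = sample.int(n_cand, k),
         cutoffs = runif(k, floor_cutoff, 1),
         weights = runif(k, 0.5, 2),
         window = runif(1, ga$min_window, prom_len))
  }
  mutate_ind <- function(ind) {
    k <- length(ind$members)
    hit <- runif(k) < ga$mutation_prob
    ind$cutoffs[hit] <- pmin(1, pmax(floor_cutoff,
                                     ind$cutoffs[hit] +
                                       rnorm(sum(hit), 0, ga$cutoff_sd)))
    hit <- runif(k) < ga$mutation_prob
    ind$weights[hit] <- pmax(0, ind$weights[hit] +
                               rnorm(sum(hit), 0, ga$weight_sd))
    if (runif(1) < ga$mutation_prob) {
      ind$window <- min(prom_len, max(ga$min_window,
                                      ind$window * exp(rnorm(1, 0, 0.2))))
    }
    if (runif(1) < ga$mutation_prob && k < max_m) {
      new <- safe_sample(setdiff(seq_len(n_cand), ind$members), 1)
      ind$members <- c(ind$members, new)
      ind$cutoffs <- c(ind$cutoffs, runif(1, floor_cutoff, 1))
      ind$weights <- c(ind$weights, runif(1, 0.5, 2))
    }
    if (runif(1) < ga$mutation_prob && length(ind$members) > ga$min_members) {
      drop <- sample.int(length(ind$members), 1)
      ind$members <- ind$members[-drop]
      ind$cutoffs <- ind$cutoffs[-drop]
      ind$weights <- ind$weights[-drop]
    }
    ind
  }
  crossover <- function(p1, p2) {
    pool <- union(p1$members, p2$members)
    take <- vapply(pool, function(m) {
      in1 <- m %in% p1$members; in2 <- m %in% p2$members
      if (in1 && in2) TRUE else runif(1) < 0.5
    }, logical(1))
    members <- pool[take]
    if (length(members) < ga$min_members) {
      extra <- safe_sample(setdiff(pool, members),
                           min(ga$min_members - length(members),
                               length(setdiff(pool, members))))
      members <- c(members, extra)
      while (length(members) < ga$min_members) {
        members <- c(members, safe_sample(setdiff(seq_len(n_cand), members), 1))
      }
    }
    if (length(members) > max_m) members <- safe_sample(members, max_m)
    param_from <- function(m) {
      use1 <- m %in% p1$members && (!(m %in% p2$members) || runif(1) < 0.5)
      if (use1) {
        i <- match(m, p1$members); c(p1$cutoffs[i], p1$weights[i])
      } else {
        i <- match(m, p2$members); c(p2$cutoffs[i], p2$weights[i])
      }
    }
    pars <- vapply(members, param_from, numeric(2))
    list(members = members, cutoffs = pars[1, ], weights = pars[2, ],
         window = if (runif(1) < 0.5) p1$window else p2$window)
  }
  better <- function(e1, e2) {
    e1$fitness > e2$fitness ||
      (e1$fitness == e2$fitness && e1$auc > e2$auc)
  }
  tournament <- function(pop, evals) {
    idx <- sample.int(length(pop), ga$tournament_k)
    best <- idx[1]
    for (i in idx[-1]) if (better(evals[[i]], evals[[best]])) best <- i
    pop[[best]]
  }

  withr::with_seed(seed, {
    pop <- purrr::map(seq_len(ga$population), ~random_individual())
    evals <- purrr::map(pop, evaluate)
    trace <- vector("list", ga$generations)
    for (gen in seq_len(ga$generations)) {
      ord <- order(-vapply(evals, `[[`, numeric(1), "fitness"),
                   -vapply(evals, `[[`, numeric(1), "auc"))
      elite_idx <- ord[seq_len(ga$elitism)]
      new_pop <- pop[elite_idx]
      new_evals <- evals[elite_idx]
      while (length(new_pop) < ga$population) {
        child <- mutate_ind(crossover(tournament(pop, evals),
                                      tournament(pop, evals)))
        new_pop[[length(new_pop) + 1]] <- child
        new_evals[[length(new_evals) + 1]] <- evaluate(child)
      }
      pop <- new_pop; evals <- new_evals
      fits <- vapply(evals, `[[`, numeric(1), "fitness")
      trace[[gen]] <- tibble::tibble(generation = gen,
                                     best_fitness = max(fits),
                                     mean_fitness = mean(fits))
    }
    ord <- order(-vapply(evals, `[[`, numeric(1), "fitness"),
                 -vapply(evals, `[[`, numeric(1), "auc"))
    best <- pop[[ord[1]]]
    be <- evals[[ord[1]]]
    met <- classification_metrics(be$yes_scores, be$no_scores)
    structure(list(
      members = tibble::tibble(pwm_id = cand_ids[best$members],
                               cutoff = best$cutoffs,
                               weight = best$weights),
      window = best$window,
      fitness = be$fitness, p_value = be$p_value, auc = be$auc,
      critical_value = met$critical_value,
      fp_rate = met$fp_rate, fn_rate = met$fn_rate,
      yes_scores = tibble::tibble(gene_id = yes$gene_id,
                                  composite_score = be$yes_scores),
      no_scores = tibble::tibble(gene_id = no$gene_id,
                                 composite_score = be$no_scores),
      trace = dplyr::bind_rows(trace)
    ), class = "composite_module")
  })
}

#' @noRd
resolve_candidates <- function(candidates, library) {
  if (is.null(candidates)) return(library$id)
  if (is.character(candidates)) {
    if (!all(candidates %in% library$id)) {
      up_abort("unknown candidate matrix id(s)")
    }
    return(candidates)
  }
  if (is.data.frame(candidates) && "pwm_id" %in% names(candidates)) {
    ids <- if ("passed" %in% names(candidates)) {
      candidates$pwm_id[candidates$passed]
    } else {
      candidates$pwm_id
    }
    return(intersect(library$id, ids))
  }
  up_abort("candidates must be NULL, matrix ids or an enrichment table")
}

#' @export
print.composite_module <- function(x, ...) {
  cat("Composite module:", nrow(x$members), "matrices, window",
      round(x$window), "bp\n")
  cat(sprintf("  fitness -log10(p) = %.2f, AUC = %.3f, critical value = %.3f\n",
              x$fitness, x$auc, x$critical_value))
  cat(sprintf("  fp rate = %.3f, fn rate = %.3f\n", x$fp_rate, x$fn_rate))
  print(x$members)
  invisible(x)
}
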