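#' Ground-truth record for synthetic data
#'
#' Collects everything a generator planted, so downstream recovery (site,
#' DEG, regulator, IC50) can be scored without external data.
#'
#' @param planted_pwm_ids Motif identifiers planted into Yes promoters.
#' @param planted_fraction Fraction of Yes promoters carrying a site,
#'   in (0, 1].
#' @param pair_max_gap Maximum gap in bases between planted pair members
#'   (`NA` when no pair is planted).
#' @param spiked_genes Tibble with `gene_id`, `true_logfc`.
#' @param planted_regulator Node identifier of the planted regulator.
#' @param regulator_tf_coverage Fraction of TF nodes reachable from the
#'   planted regulator, in (0, 1].
#' @param true_ic50 True IC50 in uM.
#' @return An object of class `plant_truth`.
#' @export
plant_truth <- function(planted_pwm_ids = character(),
                        planted_fraction = NA_real_,
                        pair_max_gap = NA_real_,
                        spiked_genes = NULL,
                        planted_regulator = NA_character_,
                        regulator_tf_coverage = NA_real_,
                        true_ic50 = NA_real_) {
  if (!is.na(planted_fraction) &&
      (planted_fraction <= 0 || planted_fraction > 1)) {
    up_abort("planted_fraction must be in (0, 1]")
  }
  if (!is.na(regulator_tf_coverage) &&
      (regulator_tf_coverage <= 0 || regulator_tf_coverage > 1)) {
    up_abort("regulator_tf_coverage must be in (0, 1]")
  }
  structure(list(
    planted_pwm_ids = planted_pwm_ids,
    planted_fraction = planted_fraction,
    pair_max_gap = pair_max_gap,
    spiked_genes = spiked_genes,
    planted_regulator = planted_regulator,
    regulator_tf_coverage = regulator_tf_coverage,
    true_ic50 = true_ic50,
    plant_positions = NULL
  ), class = "plant_truth")
}

#' Generate a synthetic PWM library
#'
#' Each matrix gets a random consensus; column count vectors are drawn
#' from a multinomial whose probabilities come from a Dirichlet biased
#' toward the consensus base, so columns are conserved but not degenerate.
#' Matrices are annotated with synthetic TF gene symbols (`TFG001`, ...).
#'
#' @param n_pwms Number of matrices (>= 1).
#' @param length_range Two integers, min and max motif length in
#'   `[4, 30]`.
#' @param seed Integer seed; the output is a pure function of it.
#' @param conservation Dirichlet weight on the consensus base (higher =
#'   sharper motifs); the off-consensus weight is 0.25.
#' @param column_total Total count per column.
#' @return A PWM library tibble.
#' @export
#' @examples
#' gen_pwm_library(3, c(8, 12), seed = 1)
gen_pwm_library <- function(n_pwms, length_range, seed,
                            conservation = 12, column_total = 100) {
  if (n_pwms < 1) up_abort("n_pwms must be >= 1")
  lo <- length_range[1]; hi <- length_range[2]
  if (!(4 <= lo && lo <= hi && hi <= 30)) {
    up_abort("length_range must satisfy 4 <= min <= max <= 30")
  }
  withr::with_seed(seed, {
    dplyr::bind_rows(purrr::map(seq_len(n_pwms), function(i) {
      L <- if (lo == hi) lo else sample(lo:hi, 1)
      cons <- sample(1:4, L, replace = TRUE)
      counts <- vapply(seq_len(L), function(j) {
        alpha <- rep(0.25, 4)
        alpha[cons[j]] <- conservation
        f <- stats::rgamma(4, shape = alpha)
        f <- f / sum(f)
        drop(stats::rmultinom(1, column_total, f))
      }, numeric(4))
      # guarantee the intended consensus survives sampling
      for (j in seq_len(L)) {
        if (which.max(counts[, j]) != cons[j]) {
          top <- max(counts[, j])
          counts[cons[j], j] <- top + 1
        }
      }
      pwm_row(counts, id = sprintf("M%05d", i),
              tf_gene = sprintf("TFG%03d", i))
    }))
  })
}

#' @noRd
sample_site <- function(counts, site_model) {
  bases <- c("A", "C", "G", "T")
  if (site_model == "consensus") {
    return(pwm_consensus(counts))
  }
  f <- sweep(counts, 2, colSums(counts), "/")
  paste(vapply(seq_len(ncol(f)), function(j) sample(bases, 1, prob = f[, j]),
               character(1)), collapse = "")
}

#' @noRd
revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' @noRd
random_background <- function(n, len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = "")
  }, character(1))
}

#' Generate Yes/No promoter sets with planted binding sites
#'
#' Background promoters are i.i.d. sequences at the requested GC content
#' (split evenly between G/C and A/T). A `planted_fraction` of Yes
#' promoters receive one site per planted matrix, sampled from the
#' matrix's column distributions (or the exact consensus with
#' `site_model = "consensus"`), on a random strand. When
#' `truth$pair_max_gap` is set and two or more matrices are planted, the
#' planted sites of each promoter are co-localized with at most that many
#' bases between consecutive sites. No promoters are pure background.
#'
#' @param library PWM library tibble containing the planted matrices.
#' @param truth A [plant_truth()] carrying `planted_pwm_ids`,
#'   `planted_fraction` and optionally `pair_max_gap`.
#' @param n_yes,n_no Set sizes.
#' @param length Promoter length in bases (>= 200; default 1100, the
#'   conventional -1000/+100 window).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @param site_model `"sample"` (default) or `"consensus"`.
#' @param yes_ids,no_ids Optional gene identifiers for the entries.
#' @return A list with `yes` and `no` promoter tibbles (`gene_id`, `set`,
#'   `sequence`, `tss_offset`) and the updated `truth` whose
#'   `plant_positions` tibble records every planted site.
#' @export
gen_promoter_sets <- function(library, truth, n_yes, n_no, length = 1100,
                              gc = 0.5, seed = 1,
                              site_model = c("sample", "consensus"),
                              yes_ids = NULL, no_ids = NULL) {
  site_model <- match.arg(site_model)
  if (length < 200) up_abort("promoter length must be >= 200")
  if (gc <= 0 || gc >= 1) up_abort("gc must be in (0, 1)")
  planted <- truth$planted_pwm_ids
  if (!all(planted %in% library$id)) {
    up_abort("every planted PWM id must exist in the library")
  }
  idx <- match(planted, library$id)
  site_lens <- vapply(library$counts[idx], ncol, integer(1))
  pair_gap <- truth$pair_max_gap
  total_span <- sum(site_lens) +
    (if (!is.na(pair_gap)) (length(planted) - 1) * pair_gap else 0)
  if (length(planted) > 0 && total_span > length) {
    up_abort("planted site(s) do not fit within the promoter length")
  }
  if (is.null(yes_ids)) yes_ids <- sprintf("YG%04d", seq_len(n_yes))
  if (is.null(no_ids)) no_ids <- sprintf("NG%04d", seq_len(n_no))
  withr::with_seed(seed, {
    yes_seq <- random_background(n_yes, length, gc)
    no_seq <- random_background(n_no, length, gc)
    positions <- list()
    if (length(planted) > 0 && !is.na(truth$planted_fraction)) {
      n_plant <- round(truth$planted_fraction * n_yes)
      which_plant <- sort(sample.int(n_yes, n_plant))
      for (i in which_plant) {
        if (!is.na(pair_gap) && length(planted) >= 2) {
          # co-localized cluster: consecutive sites separated by <= pair_gap
          gaps <- sample.int(pair_max_gap_plus1(pair_gap), length(planted) - 1,
                             replace = TRUE) - 1L
          span <- sum(site_lens) + sum(gaps)
          start <- sample.int(length - span + 1, 1) - 1L
          starts <- start + cumsum(c(0L, (site_lens + c(gaps, 0L))
                                     [-length(site_lens)]))
        } else {
          # independent placement, retried until non-overlapping
          starts <- place_nonoverlapping(length, site_lens)
        }
        s <- yes_seq[i]
        for (k in seq_along(planted)) {
          site <- sample_site(library$counts[[idx[k]]], site_model)
          strand <- sample(c("+", "-"), 1)
          ins <- if (strand == "-") revcomp_chr(site) else site
          substr(s, starts[k] + 1, starts[k] + site_lens[k]) <- ins
          positions[[base::length(positions) + 1]] <- tibble::tibble(
            gene_id = yes_ids[i], set = "yes", pwm_id = planted[k],
            position = starts[k], strand = strand)
        }
        yes_seq[i] <- s
      }
    }
    truth$plant_positions <- if (length(positions) > 0) {
      dplyr::bind_rows(positions)
    } else {
      tibble::tibble(gene_id = character(), set = character(),
                     pwm_id = character(), position = integer(),
                     strand = character())
    }
    yes <- tibble::tibble(gene_id = yes_ids, set = "yes", sequence = yes_seq,
                          tss_offset = length - 100L)
    no <- tibble::tibble(gene_id = no_ids, set = "no", sequence = no_seq,
                         tss_offset = length - 100L)
    list(yes = yes, no = no, truth = truth)
  })
}

#' @noRd
pair_max_gap_plus1 <- function(gap) as.integer(gap) + 1L

#' @noRd
place_nonoverlapping <- function(len, site_lens, tries = 200) {
  for (t in seq_len(tries)) {
    starts <- vapply(site_lens, function(L) sample.int(len - L + 1, 1) - 1L,
                     integer(1))
    ends <- starts + site_lens
    ord <- order(starts)
    if (all(ends[ord][-length(ord)] <= starts[ord][-1])) return(starts)
  }
  up_abort("could not place non-overlapping sites; promoter too short")
}

#' Generate a spiked two-condition expression design
#'
#' Gaussian log2 intensities around gene-specific baselines, with
#' `n_spiked` genes shifted by +/- `true_logfc` in condition A versus B.
#' The design emulates a multi-cell-line two-replicate layout.
#'
#' @param n_genes,n_spiked Gene counts (`n_spiked <= n_genes`).
#' @param true_logfc Absolute spiked log2 fold change; signs alternate.
#' @param n_lines Cell lines per condition arm (default 3).
#' @param n_reps Replicates per (condition, line) block (default 2,
#'   must be >= 2).
#' @param noise_sd Gaussian noise SD on the log2 scale (> 0).
#' @param seed Integer seed.
#' @param baseline_mean,baseline_sd Distribution of gene baselines.
#' @param technical_reps When `TRUE`, replicates within a
#'   (condition, line) block are labelled as technical duplicates via a
#'   `replicate_block` design column, for [collapse_technical_replicates()].
#' @return List with `expr` (wide tibble, `gene_id` + one column per
#'   sample), `design` (sample, condition, cell_line, replicate
#'   \[, replicate_block\]) and `truth`.
#' @export
gen_expression_design <- function(n_genes, n_spiked, true_logfc,
                                  n_lines = 3, n_reps = 2, noise_sd = 0.2,
                                  seed = 1, baseline_mean = 8,
                                  baseline_sd = 1.5,
                                  technical_reps = FALSE) {
  if (n_spiked > n_genes) up_abort("n_spiked must be <= n_genes")
  if (n_reps < 2) up_abort("need at least 2 replicates per block")
  if (noise_sd <= 0) up_abort("noise_sd must be > 0")
  withr::with_seed(seed, {
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    design <- tidyr::expand_grid(
      condition = c("A", "B"),
      cell_line = sprintf("L%d", seq_len(n_lines)),
      replicate = sprintf("r%d", seq_len(n_reps))
    )
    design$sample <- with(design, paste(condition, cell_line, replicate,
                                        sep = "_"))
    design <- design[, c("sample", "condition", "cell_line", "replicate")]
    if (technical_reps) {
      design$replicate_block <- paste(design$condition, design$cell_line,
                                      sep = "_")
    }
    baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
    effect <- numeric(n_genes)
    spiked <- integer(0)
    if (n_spiked > 0) {
      spiked <- sort(sample.int(n_genes, n_spiked))
      signs <- rep(c(1, -1), length.out = n_spiked)
      effect[spiked] <- signs * true_logfc
    }
    vals <- vapply(seq_len(nrow(design)), function(s) {
      mu <- baseline + (if (design$condition[s] == "A") effect else 0)
      rnorm(n_genes, mu, noise_sd)
    }, numeric(n_genes))
    colnames(vals) <- design$sample
    expr <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                             tibble::as_tibble(vals))
    truth <- plant_truth(spiked_genes = tibble::tibble(
      gene_id = gene_ids[spiked],
      true_logfc = effect[spiked]))
    list(expr = expr, design = design, truth = truth)
  })
}

#' Generate a directed signal-transduction network with a planted regulator
#'
#' A directed Erdos-Renyi background graph plus a planted regulator wired
#' with directed paths of length at most `max_plant_depth` reaching a
#' chosen fraction of designated TF nodes. Every node carries a synthetic
#' gene symbol; TF nodes can be given specific symbols so that motif
#' annotations resolve to network nodes.
#'
#' @param n_nodes Node count.
#' @param edge_density Expected out-degree of the background graph.
#' @param tf_nodes Number of designated TF nodes (>= 2).
#' @param truth A [plant_truth()] with `regulator_tf_coverage` set.
#' @param max_plant_depth Maximum planted path length (>= 1).
#' @param seed Integer seed.
#' @param tf_gene_symbols Optional character vector of length `tf_nodes`
#'   with gene symbols for the TF nodes (default `TFG001`, ...).
#' @return List with `network` (a `signal_network`), and updated `truth`
#'   whose `planted_regulator` is filled in.
#' @export
gen_network <- function(n_nodes, edge_density, tf_nodes, truth,
                        max_plant_depth = 3, seed = 1,
                        tf_gene_symbols = NULL) {
  if (tf_nodes < 2) up_abort("need at least 2 TF nodes")
  if (max_plant_depth < 1) up_abort("max_plant_depth must be >= 1")
  coverage <- truth$regulator_tf_coverage
  if (is.na(coverage)) up_abort("truth$regulator_tf_coverage must be set")
  n_targets <- ceiling(coverage * tf_nodes)
  # worst case each planted path needs max_plant_depth - 1 intermediates
  if (n_nodes < tf_nodes + 1 + (max_plant_depth - 1)) {
    up_abort("network too small to wire the planted regulator")
  }
  if (is.null(tf_gene_symbols)) {
    tf_gene_symbols <- sprintf("TFG%03d", seq_len(tf_nodes))
  }
  stopifnot(length(tf_gene_symbols) == tf_nodes)
  withr::with_seed(seed, {
    ids <- sprintf("N%04d", seq_len(n_nodes))
    p <- min(1, edge_density / (n_nodes - 1))
    adj <- which(matrix(runif(n_nodes^2) < p, n_nodes, n_nodes) &
                   !diag(TRUE, n_nodes), arr.ind = TRUE)
    edges <- tibble::tibble(source = ids[adj[, 1]], target = ids[adj[, 2]],
                            relation = "activation")
    tf_idx <- sample.int(n_nodes, tf_nodes)
    non_tf <- setdiff(seq_len(n_nodes), tf_idx)
    reg_idx <- safe_sample(non_tf, 1)
    pool <- setdiff(non_tf, reg_idx)
    targets <- safe_sample(tf_idx, n_targets)
    planted_edges <- list()
    for (t in targets) {
      d <- sample.int(max_plant_depth, 1)
      mids <- if (d > 1) safe_sample(pool, d - 1) else integer(0)
      path <- c(reg_idx, mids, t)
      planted_edges[[length(planted_edges) + 1]] <- tibble::tibble(
        source = ids[path[-length(path)]], target = ids[path[-1]],
        relation = "activation")
    }
    edges <- dplyr::distinct(dplyr::bind_rows(c(list(edges), planted_edges)),
                             .data$source, .data$target, .keep_all = TRUE)
    genes <- paste0("GEN_", ids)
    genes[tf_idx] <- tf_gene_symbols
    nodes <- tibble::tibble(
      id = ids,
      kind = ifelse(seq_len(n_nodes) %in% tf_idx, "tf", "protein"),
      genes = genes)
    truth$planted_regulator <- ids[reg_idx]
    truth$planted_tf_ids <- ids[sort(targets)]
    truth$tf_node_ids <- ids[sort(tf_idx)]
    list(network = signal_network(edges, nodes), truth = truth)
  })
}

#' Generate a noisy probit dose-response viability table
#'
#' Fraction alive follows `pnorm(-slope * (log10(c) - log10(ic50)))` with
#' additive Gaussian noise, clipped to \[0, 1\]; zero-concentration
#' control rows sit at 1 plus noise.
#'
#' @param true_ic50 True IC50 in uM (> 0).
#' @param slope Probit slope per log10 uM.
#' @param concentrations Tested concentrations in uM; must include 0
#'   (control). Default: the six-point series 34, 17, 8.5, 4.25, 2.2, 0.
#' @param noise_sd Gaussian noise SD on the fraction scale (>= 0).
#' @param reps Replicates per concentration (>= 1; default triplicates).
#' @param seed Integer seed.
#' @return Viability tibble (`concentration_uM`, `fraction_alive`,
#'   `replicate`).
#' @export
gen_dose_response <- function(true_ic50, slope = 2,
                              concentrations = c(34, 17, 8.5, 4.25, 2.2, 0),
                              noise_sd = 0.05, reps = 3, seed = 1) {
  if (true_ic50 <= 0) up_abort("true_ic50 must be > 0")
  if (!0 %in% concentrations) up_abort("concentrations must include 0")
  if (noise_sd < 0) up_abort("noise_sd must be >= 0")
  if (reps < 1) up_abort("reps must be >= 1")
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(concentration_uM = concentrations,
                               replicate = sprintf("rep%d", seq_len(reps)))
    mu <- ifelse(grid$concentration_uM == 0, 1,
                 pnorm(-slope * (log10(grid$concentration_uM) -
                                 log10(true_ic50))))
    frac <- mu + if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
    grid$fraction_alive <- pmin(1, pmax(0, frac))
    grid[, c("concentration_uM", "fraction_alive", "replicate")]
  })
}
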