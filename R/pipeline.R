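#' Write a coherent synthetic study bundle to disk
#'
#' Generates every input of the end-to-end pipeline with a shared ground
#' truth: a PWM library with two planted matrices among decoys, a spiked
#' two-condition expression design, one promoter per gene with a
#' co-localized planted site pair in most up-spiked promoters, a signal
#' network whose planted regulator reaches the TF nodes of the planted
#' matrices and is itself encoded by an up-spiked, site-carrying gene,
#' a gene-set collection with one top-loaded set, and a noisy
#' dose-response table. Files: `pwms.transfac`, `expression.tsv`,
#' `design.tsv`, `promoters.fasta`, `network.tsv`, `genesets.gmt`,
#' `viability.tsv`, `truth.json`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed controlling the whole bundle.
#' @param n_genes,n_spiked Expression design size (defaults 2000 / 150).
#' @param true_logfc,noise_sd Spike size and noise (defaults 1 / 0.2).
#' @param n_pwms Library size including the two planted matrices
#'   (default 20).
#' @param plant_fraction Fraction of up-spiked promoters carrying the
#'   planted pair (default 0.7).
#' @param pair_max_gap Maximum gap between pair members (default 100).
#' @param n_nodes Network size (default 300).
#' @param tf_coverage Fraction of TF nodes wired from the planted
#'   regulator (default 1).
#' @param true_ic50 Dose-response truth in uM (default 15).
#' @return Invisibly, a list with the file paths and the truth.
#' @export
simulate_study <- function(dir, seed = 42, n_genes = 2000, n_spiked = 150,
                           true_logfc = 1, noise_sd = 0.2, n_pwms = 20,
                           plant_fraction = 0.7, pair_max_gap = 100,
                           n_nodes = 300, tf_coverage = 1, true_ic50 = 15) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- gen_pwm_library(n_pwms, c(8, 12), seed = seed)
  ex <- gen_expression_design(n_genes, n_spiked, true_logfc,
                              noise_sd = noise_sd, seed = seed + 1)
  spiked_up <- ex$truth$spiked_genes$gene_id[
    ex$truth$spiked_genes$true_logfc > 0]
  other_genes <- setdiff(ex$expr$gene_id, spiked_up)
  truth <- plant_truth(planted_pwm_ids = lib$id[1:2],
                       planted_fraction = plant_fraction,
                       pair_max_gap = pair_max_gap,
                       regulator_tf_coverage = tf_coverage,
                       true_ic50 = true_ic50)
  pr <- gen_promoter_sets(lib, truth, n_yes = length(spiked_up),
                          n_no = length(other_genes), seed = seed + 2,
                          yes_ids = spiked_up, no_ids = other_genes)
  # regulator gene: an up-spiked gene that actually carries the pair
  carrier <- unique(pr$truth$plant_positions$gene_id)
  reg_gene <- sort(carrier)[1]
  net <- gen_network(n_nodes, edge_density = 2, tf_nodes = n_pwms,
                     truth = pr$truth, max_plant_depth = 3,
                     seed = seed + 3, tf_gene_symbols = lib$tf_gene)
  nodes <- net$network$nodes
  nodes$genes[nodes$id == net$truth$planted_regulator] <- reg_gene
  network <- signal_network(net$network$edges, nodes)
  truth <- net$truth
  truth$regulator_gene <- reg_gene
  truth$spiked_genes <- ex$truth$spiked_genes
  # gene sets: one loaded with up-spiked genes among random decoys
  gmt <- withr::with_seed(seed + 4, {
    sets <- purrr::map(seq_len(19), function(i) {
      safe_sample(ex$expr$gene_id, 40)
    })
    sets <- c(list(c(safe_sample(spiked_up, min(30, length(spiked_up))),
                     safe_sample(other_genes, 10))), sets)
    tibble::tibble(set_id = c("planted_up_set", sprintf("SET%02d", 2:20)),
                   description = "synthetic", genes = sets)
  })
  via <- gen_dose_response(true_ic50, seed = seed + 5)

  paths <- list(
    pwms = file.path(dir, "pwms.transfac"),
    expression = file.path(dir, "expression.tsv"),
    design = file.path(dir, "design.tsv"),
    promoters = file.path(dir, "promoters.fasta"),
    network = file.path(dir, "network.tsv"),
    gmt = file.path(dir, "genesets.gmt"),
    viability = file.path(dir, "viability.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_transfac_matrices(lib, paths$pwms)
  write_expression(ex$expr, ex$design, paths$expression, paths$design)
  write_promoters_fasta(dplyr::bind_rows(pr$yes, pr$no), paths$promoters)
  edges <- network$edges
  edges$source_genes <- nodes$genes[match(edges$source, nodes$id)]
  edges$target_genes <- nodes$genes[match(edges$target, nodes$id)]
  write_network_edges(edges, paths$network)
  write_gmt(gmt, paths$gmt)
  write_viability(via, paths$viability)
  jsonlite::write_json(list(
    planted_pwm_ids = truth$planted_pwm_ids,
    planted_fraction = truth$planted_fraction,
    pair_max_gap = truth$pair_max_gap,
    planted_regulator = truth$planted_regulator,
    regulator_gene = reg_gene,
    regulator_tf_coverage = truth$regulator_tf_coverage,
    tf_node_ids = truth$tf_node_ids,
    true_ic50 = truth$true_ic50,
    spiked_genes = truth$spiked_genes,
    seed = seed
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth))
}

#' Assemble and validate a pipeline configuration
#'
#' @param expression,design,pwms,promoters,network,gmt,viability Input
#'   paths (`gmt` and `viability` optional).
#' @param outdir Output directory.
#' @param seed Global seed.
#' @param p_threshold,logfc_threshold DEG thresholds (0.05 / 0.58).
#' @param alpha Enrichment significance threshold (0.01).
#' @param radius Master-regulator search radius in steps (12).
#' @param n_perm Network permutations (1000).
#' @param ga GA parameters ([cma_ga_control()]).
#' @param group_a,group_b Condition labels to contrast.
#' @param no_set_max_logfc,no_set_min_p Definition of clearly non-changed
#'   genes for the No set (0.2 / 0.5).
#' @param no_set_cap_factor Cap of the No set at this multiple of the
#'   Yes size (5).
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, design, pwms, promoters, network,
                            gmt = NULL, viability = NULL,
                            outdir = "upstream_out", seed = 42,
                            p_threshold = 0.05, logfc_threshold = 0.58,
                            alpha = 0.01, radius = 12, n_perm = 1000,
                            ga = cma_ga_control(), group_a = "A",
                            group_b = "B", no_set_max_logfc = 0.2,
                            no_set_min_p = 0.5, no_set_cap_factor = 5) {
  cfg <- as.list(environment())
  required <- c("expression", "design", "pwms", "promoters", "network")
  for (nm in required) {
    if (!file.exists(cfg[[nm]])) {
      up_abort(paste0("config path for '", nm, "' does not exist: ",
                      cfg[[nm]]))
    }
  }
  for (nm in c("gmt", "viability")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      up_abort(paste0("config path for '", nm, "' does not exist"))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    up_abort(paste0("pipeline stage '", name, "' failed: ",
                    conditionMessage(e)),
             class = "upstreamr_stage_error")
  })
}

#' Run the end-to-end upstream analysis
#'
#' Stages, in order: differential expression -> Yes/No promoter sets
#' (Yes = up-regulated genes; No = clearly non-changed genes, capped by a
#' seeded subsample) -> per-matrix cutoff enrichment -> composite-module
#' search -> master-regulator search with permutation significance ->
#' positive-feedback filter; with GSEA and IC50 side channels when a GMT
#' or viability table is configured. Every intermediate is written under
#' `outdir` together with a run manifest (seed, config hash, package
#' version, per-stage row counts). Reruns with the same config are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A report list: `degs`, `deg_sets`, `fmatch`, `module`,
#'   `regulators`, `regulators_filtered`, `gsea`, `ic50`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  dat <- stage("read_inputs", {
    e <- read_expression(config$expression, config$design)
    list(expr = e$expr, design = e$design,
         lib = read_transfac_matrices(config$pwms),
         promoters = read_promoters_fasta(config$promoters),
         network = read_network(config$network))
  })

  degs <- stage("deg", {
    coll <- collapse_technical_replicates(dat$expr, dat$design)
    differential_expression(coll$expr, coll$design,
                            config$group_a, config$group_b)
  })
  readr::write_tsv(degs, out("deg_table.tsv"), progress = FALSE)
  sets <- filter_degs(degs, config$p_threshold, config$logfc_threshold)
  writeLines(sets$up, out("genes_up.txt"))
  writeLines(sets$down, out("genes_down.txt"))

  promo <- stage("promoters", {
    yes <- dat$promoters[dat$promoters$gene_id %in% sets$up, ]
    if (nrow(yes) == 0) up_abort("no up-regulated gene has a promoter")
    unchanged <- degs$gene_id[abs(degs$logFC) < config$no_set_max_logfc &
                                degs$p_value > config$no_set_min_p]
    no <- dat$promoters[dat$promoters$gene_id %in% unchanged, ]
    cap <- config$no_set_cap_factor * nrow(yes)
    if (nrow(no) > cap) {
      keep <- withr::with_seed(config$seed + 101,
                               sort(sample.int(nrow(no), cap)))
      no <- no[keep, ]
    }
    yes$set <- "yes"; no$set <- "no"
    list(yes = yes, no = no)
  })
  write_promoters_fasta(promo$yes, out("promoters_yes.fasta"))
  write_promoters_fasta(promo$no, out("promoters_no.fasta"))

  enrich <- stage("fmatch", {
    run_fmatch(dat$lib, promo$yes, promo$no, alpha = config$alpha)
  })
  readr::write_tsv(dplyr::select(enrich, -dplyr::any_of("enriched")),
                   out("fmatch.tsv"), progress = FALSE)

  module <- stage("cma", {
    cand <- if (sum(enrich$passed) >= 4) enrich else dat$lib$id
    run_cma(dat$lib, promo$yes, promo$no, ga = config$ga,
            seed = config$seed + 202, candidates = cand)
  })
  jsonlite::write_json(list(
    members = module$members, window = module$window,
    fitness = module$fitness, p_value = module$p_value, auc = module$auc,
    critical_value = module$critical_value,
    fp_rate = module$fp_rate, fn_rate = module$fn_rate
  ), out("cma_module.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(module$trace, out("cma_trace.tsv"), progress = FALSE)

  composite <- stage("composite_scores", {
    mlib <- dat$lib[dat$lib$id %in% module$members$pwm_id, ]
    sites <- scan_set(mlib, dat$promoters, cutoff = 0.7)
    csr <- sites_csr(sites, dat$promoters$gene_id, mlib$id)
    idx <- match(module$members$pwm_id, mlib$id)
    sc <- csr_composite(csr, nrow(mlib), idx, module$members$cutoff,
                        module$members$weight, module$window)
    tibble::tibble(gene_id = dat$promoters$gene_id, composite_score = sc)
  })
  readr::write_tsv(composite, out("composite_scores.tsv"), progress = FALSE)

  regulators <- stage("regulators", {
    passed_tfs <- unique(enrich$tf_gene[enrich$passed])
    nodes <- dat$network$nodes
    tf_nodes <- nodes$id[!is.na(nodes$genes) &
                           vapply(strsplit(nodes$genes, ","),
                                  function(g) any(g %in% passed_tfs),
                                  logical(1))]
    if (length(tf_nodes) < 2) {
      up_abort("fewer than 2 enriched TFs resolve to network nodes")
    }
    res <- permutation_significance(dat$network, tf_nodes,
                                    radius = config$radius,
                                    n_perm = config$n_perm,
                                    seed = config$seed + 303)
    rank_regulators(res)
  })
  readr::write_tsv(dplyr::select(regulators, -"reached_tfs"),
                   out("regulators.tsv"), progress = FALSE)

  filtered <- stage("feedback_filter", {
    cs <- stats::setNames(composite$composite_score, composite$gene_id)
    feedback_filter(regulators, cs, module$critical_value, sets$up)
  })
  readr::write_tsv(dplyr::select(filtered, -"reached_tfs"),
                   out("regulators_filtered.tsv"), progress = FALSE)

  gsea_res <- NULL
  if (!is.null(config$gmt)) {
    gsea_res <- stage("gsea", {
      ranked <- dplyr::arrange(
        tibble::tibble(gene = degs$gene_id, weight = abs(degs$logFC),
                       logFC = degs$logFC),
        dplyr::desc(.data$logFC))[, c("gene", "weight")]
      gsea(ranked, read_gmt(config$gmt), seed = config$seed + 404)
    })
    readr::write_tsv(gsea_res, out("gsea.tsv"), progress = FALSE)
  }

  ic50 <- NULL
  if (!is.null(config$viability)) {
    ic50 <- stage("ic50", fit_probit_ic50(read_viability(config$viability)))
    jsonlite::write_json(list(ic50 = ic50$ic50, se = ic50$se,
                              slope = ic50$slope, n = ic50$n,
                              converged = ic50$converged),
                         out("ic50.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("upstreamr")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = list(
      deg = nrow(degs), up = length(sets$up), down = length(sets$down),
      yes_promoters = nrow(promo$yes), no_promoters = nrow(promo$no),
      fmatch_passed = sum(enrich$passed),
      module_members = nrow(module$members),
      regulators = nrow(regulators),
      regulators_filtered = nrow(filtered),
      gsea_sets = if (is.null(gsea_res)) 0L else nrow(gsea_res)
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  list(degs = degs, deg_sets = sets, fmatch = enrich, module = module,
       composite = composite, regulators = regulators,
       regulators_filtered = filtered, gsea = gsea_res, ic50 = ic50,
       manifest = manifest)
}
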