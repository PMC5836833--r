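test_that("rank-sum test reproduces exact and approximate references", {
  # complete separation: one-sided p = 1 / C(5,2)
  expect_equal(wilcoxon_rank_sum(c(3, 4, 5), c(1, 2),
                                 alternative = "greater"), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 4)), 1)
  # exact branch vs the independent subset-enumeration oracle
  withr::with_seed(17, {
    for (i in 1:20) {
      na <- sample(2:6, 1); nb <- sample(2:6, 1)
      a <- sample(1:5, na, replace = TRUE)  # ties likely
      b <- sample(1:5, nb, replace = TRUE)
      for (alt in c("two.sided", "greater", "less")) {
        expect_equal(wilcoxon_rank_sum(a, b, alternative = alt),
                     oracle_wilcoxon_exact(a, b, alt), tolerance = 1e-12)
      }
    }
  })
  # tie-free exact branch agrees with stats::wilcox.test
  a <- c(1.2, 3.4, 5.6, 7.1); b <- c(2.2, 4.9, 0.3)
  expect_equal(wilcoxon_rank_sum(a, b),
               stats::wilcox.test(a, b, exact = TRUE)$p.value)
  # large-sample null calibration
  ps <- withr::with_seed(18, {
    vapply(1:400, function(i) {
      wilcoxon_rank_sum(rnorm(50), rnorm(50))
    }, numeric(1))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("classification metrics minimize fp + fn with the high-tie rule", {
  m <- classification_metrics(c(5, 6, 7), c(1, 2, 3))
  expect_equal(m$auc, 1)
  expect_equal(m$fp_rate, 0)
  expect_equal(m$fn_rate, 0)
  m2 <- classification_metrics(c(2, 3), c(0, 1))
  expect_equal(m2$critical_value, 2)  # ties resolved to higher threshold
  # identical distributions give chance-level AUC
  x <- rnorm(200)
  m3 <- classification_metrics(x, x)
  expect_equal(m3$auc, 0.5)
  # exhaustive optimality of the critical value on small inputs
  withr::with_seed(19, {
    for (i in 1:20) {
      ys <- round(runif(6), 2); ns <- round(runif(8), 2)
      m4 <- classification_metrics(ys, ns)
      thr <- unique(c(ys, ns))
      tot <- vapply(thr, function(t) mean(ns >= t) + mean(ys < t),
                    numeric(1))
      expect_equal(m4$fp_rate + m4$fn_rate, min(tot))
    }
  })
})

test_that("composite score enumerates window placements correctly", {
  mod <- list(members = tibble::tibble(pwm_id = "M1", cutoff = 0.8,
                                       weight = 1),
              window = 300)
  sites <- tibble::tibble(pwm_id = "M1", position = 100, score = 0.9)
  expect_equal(composite_score(mod, sites), 0.9)
  expect_equal(composite_score(mod, dplyr::mutate(sites, score = 0.7)), 0)
  # two members, three sites: co-location decides the sum
  mod2 <- list(members = tibble::tibble(pwm_id = c("A", "B"),
                                        cutoff = c(0.8, 0.8),
                                        weight = c(1, 1)),
               window = 200)
  close_sites <- tibble::tibble(pwm_id = c("A", "B", "A"),
                                position = c(100, 250, 900),
                                score = c(0.9, 0.85, 0.88))
  expect_equal(composite_score(mod2, close_sites), 1.75)
  far <- tibble::tibble(pwm_id = c("A", "B"), position = c(100, 600),
                        score = c(0.9, 0.85))
  expect_equal(composite_score(mod2, far), 0.9)
  # monotone in weight, anti-monotone in cutoff
  mod3 <- mod2; mod3$members$weight <- c(2, 1)
  expect_gte(composite_score(mod3, close_sites),
             composite_score(mod2, close_sites))
  mod4 <- mod2; mod4$members$cutoff <- c(0.95, 0.95)
  expect_lte(composite_score(mod4, close_sites),
             composite_score(mod2, close_sites))
})

test_that("C++ batch evaluation agrees with the reference implementation", {
  lib <- gen_pwm_library(5, c(6, 8), seed = 20)
  truth <- plant_truth(planted_pwm_ids = lib$id[1:2],
                       planted_fraction = 0.8, pair_max_gap = 150)
  ps <- gen_promoter_sets(lib, truth, n_yes = 15, n_no = 10, seed = 20)
  both <- dplyr::bind_rows(ps$yes, ps$no)
  sites <- scan_set(lib, both, 0.7)
  mod <- list(members = tibble::tibble(pwm_id = lib$id[1:3],
                                       cutoff = c(0.85, 0.8, 0.9),
                                       weight = c(1, 0.5, 2)),
              window = 250)
  ref <- vapply(both$gene_id, function(g) {
    composite_score(mod, sites[sites$seq_id == g, ])
  }, numeric(1))
  csr <- upstreamr:::sites_csr(sites, both$gene_id, lib$id)
  got <- upstreamr:::csr_composite(csr, nrow(lib),
                                   match(mod$members$pwm_id, lib$id),
                                   mod$members$cutoff, mod$members$weight,
                                   mod$window)
  expect_equal(unname(ref), got, tolerance = 1e-12)
})

test_that("the genetic algorithm recovers a planted pair deterministically", {
  lib <- gen_pwm_library(8, c(8, 10), seed = 21)
  truth <- plant_truth(planted_pwm_ids = lib$id[1:2],
                       planted_fraction = 0.7, pair_max_gap = 150)
  ps <- gen_promoter_sets(lib, truth, n_yes = 60, n_no = 120, seed = 21)
  ga <- cma_ga_control(population = 30, generations = 25)
  mod <- run_cma(lib, ps$yes, ps$no, ga = ga, seed = 21)
  expect_true(all(lib$id[1:2] %in% mod$members$pwm_id))
  expect_lt(mod$p_value, 1e-6)
  # elitism: best fitness never decreases
  expect_true(all(diff(mod$trace$best_fitness) >= 0))
  # determinism: identical object on the same seed
  mod2 <- run_cma(lib, ps$yes, ps$no, ga = ga, seed = 21)
  expect_identical(mod$members, mod2$members)
  expect_identical(mod$yes_scores, mod2$yes_scores)
  expect_identical(mod$trace, mod2$trace)
  # no signal when Yes equals No
  mod3 <- run_cma(lib, ps$no, ps$no, ga = cma_ga_control(
    population = 20, generations = 5), seed = 22)
  expect_lte(mod3$fitness, 2)
  expect_error(run_cma(lib[1:3, ], ps$yes, ps$no, seed = 1),
               "at least 4")
})

test_that("broom and ggplot methods summarize a module", {
  lib <- gen_pwm_library(5, c(6, 6), seed = 23)
  truth <- plant_truth(planted_pwm_ids = lib$id[1], planted_fraction = 0.9)
  ps <- gen_promoter_sets(lib, truth, n_yes = 20, n_no = 30, seed = 23)
  mod <- run_cma(lib, ps$yes, ps$no,
                 ga = cma_ga_control(population = 12, generations = 3),
                 seed = 23)
  td <- generics::tidy(mod)
  expect_true(all(c("pwm_id", "cutoff", "weight") %in% names(td)))
  gl <- generics::glance(mod)
  expect_equal(nrow(gl), 1)
  expect_true(gl$auc >= 0 && gl$auc <= 1)
  p <- ggplot2::autoplot(mod)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_ga_trace(mod), "ggplot")
})
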