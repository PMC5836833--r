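test_that("TRANSFAC-dialect files round-trip through read and write", {
  lib <- gen_pwm_library(2, c(6, 10), seed = 9)
  lines <- write_transfac_matrices(lib)
  back <- read_transfac_matrices(lines)
  expect_equal(nrow(back), 2)
  expect_equal(back$id, lib$id)
  expect_equal(back$tf_gene, lib$tf_gene)
  expect_equal(back$counts, lib$counts)
  # and write(read(x)) is stable
  expect_identical(write_transfac_matrices(back), lines)
})

test_that("the shipped matrix fixture round-trips byte-identically", {
  f <- system.file("extdata", "example_pwms.transfac",
                   package = "upstreamr")
  lib <- read_transfac_matrices(f)
  expect_equal(nrow(lib), 3)
  expect_identical(as.character(write_transfac_matrices(lib)),
                   readLines(f))
})

test_that("TRANSFAC parser handles missing BF, bad rows, empty input", {
  rec <- c("AC  M1", "ID  M1", "P0  A C G T",
           "01  1 2 3 4  T", "02  4 3 2 1  A", "//")
  lib <- read_transfac_matrices(rec)
  expect_equal(nrow(lib), 1)
  expect_true(is.na(lib$tf_gene))
  bad <- c("AC  M1", "01  1 2 3  G", "//")
  expect_error(read_transfac_matrices(bad), "line 2")
  expect_warning(out <- read_transfac_matrices(""), "empty")
  expect_equal(nrow(out), 0)
  expect_error(read_transfac_matrices(c("AC M2", "01 1 1 1 1 A")),
               "terminator")
})

test_that("promoter windows follow the TSS and strand conventions", {
  withr::with_seed(10, {
    chrom <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                   collapse = "")
  })
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  tss <- tibble::tibble(chrom = "chr1", start = c(5000L, 3000L),
                        end = c(5001L, 3001L), name = c("plus", "minus"),
                        score = 0, strand = c("+", "-"))
  ps <- extract_promoters(genome, tss)
  expect_equal(nchar(ps$sequence), c(1100L, 1100L))
  # + strand: reference positions 4000..5099 (0-based)
  expect_equal(ps$sequence[1], substr(chrom, 4001, 5100))
  # - strand: reverse complement of [tss-100, tss+1000)
  expect_equal(ps$sequence[2],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chrom, 2901, 4000)))))
  # truncation at the chromosome start
  tss2 <- tibble::tibble(chrom = "chr1", start = 50L, end = 51L,
                         name = "edge", score = 0, strand = "+")
  expect_warning(ps2 <- extract_promoters(genome, tss2), "truncated")
  expect_equal(nchar(ps2$sequence), 150L)
  # unknown chromosome
  tss3 <- tss; tss3$chrom <- "chrX"
  expect_error(extract_promoters(genome, tss3), "chrX")
  # duplicate gene names: first TSS wins with a warning
  tss4 <- dplyr::bind_rows(tss, tss[1, ])
  expect_warning(ps4 <- extract_promoters(genome, tss4), "first")
  expect_equal(nrow(ps4), 2)
})

test_that("match score attains its bounds and matches the definition", {
  m <- tiny_pwm()
  expect_equal(pwm_match_score(m, "ACGT"), 1)
  # the per-column minimal-frequency word scores 0
  f <- sweep(m + 0.25, 2, colSums(m) + 1, "/")
  worst <- paste(c("A", "C", "G", "T")[apply(f, 2, which.min)],
                 collapse = "")
  expect_equal(pwm_match_score(m, worst), 0)
  # arbitrary words agree with the direct formula
  withr::with_seed(11, {
    for (i in 1:20) {
      w <- paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                 collapse = "")
      expect_equal(pwm_match_score(m, w), oracle_match_score(m, w),
                   tolerance = 1e-12)
    }
  })
  # uniform columns have zero information: degenerate score is 0
  u <- matrix(25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(pwm_match_score(u, "ACGTAC"), 0)
  # N contributes the column minimum
  expect_lt(pwm_match_score(m, "NCGT"), 1)
  expect_gte(pwm_match_score(m, "NCGT"), 0)
  expect_error(pwm_match_score(m, "ACGTA"), "length")
})

test_that("single-sequence scanning recovers plants and respects strands", {
  m <- tiny_pwm()
  pwm <- pwm_row(m, "M1")
  withr::with_seed(12, {
    bg <- paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE),
                collapse = "")
  })
  seq <- bg
  substr(seq, 311, 314) <- "ACGT"
  hits <- scan_sequence(pwm, seq, cutoff = 1 - 1e-9, seq_id = "p1")
  expect_true(any(hits$position == 310 & hits$strand == "+" &
                    abs(hits$score - 1) < 1e-12))
  # reverse complement: same sites, strands flipped, positions mirrored
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  h1 <- scan_sequence(pwm, seq, cutoff = 0.8)
  h2 <- scan_sequence(pwm, rc, cutoff = 0.8)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(nchar(seq) - 4 - h1$position), sort(h2$position))
  expect_equal(sort(as.vector(table(h1$strand))),
               sort(as.vector(table(h2$strand))))
  # raising the cutoff never adds sites
  h_low <- scan_sequence(pwm, seq, cutoff = 0.7)
  h_high <- scan_sequence(pwm, seq, cutoff = 0.9)
  expect_true(nrow(h_high) <= nrow(h_low))
  expect_true(all(h_high$position %in% h_low$position))
  expect_true(all(h_low$score >= 0 & h_low$score <= 1))
  # promoter shorter than the matrix
  expect_warning(none <- scan_sequence(pwm, "ACG", 0.5), "shorter")
  expect_equal(nrow(none), 0)
})

test_that("library scanning is consistent with per-sequence scanning", {
  lib <- gen_pwm_library(3, c(6, 8), seed = 13)
  truth <- plant_truth(planted_pwm_ids = lib$id[1], planted_fraction = 1)
  ps <- gen_promoter_sets(lib, truth, n_yes = 5, n_no = 0, length = 300,
                          seed = 13)
  # empty library
  expect_equal(nrow(scan_set(lib[0, ], ps$yes, 0.5)), 0)
  # 1 pwm x 1 promoter equals scan_sequence
  s1 <- scan_sequence(lib[2, ], ps$yes$sequence[1], 0.75,
                      seq_id = ps$yes$gene_id[1])
  s2 <- scan_set(lib[2, ], ps$yes[1, ], 0.75)
  expect_equal(as.data.frame(dplyr::arrange(s1, position, strand)),
               as.data.frame(dplyr::arrange(s2, position, strand)))
  # cutoff 0 enumerates every candidate offset on both strands
  L <- ncol(lib$counts[[3]])
  s3 <- scan_set(lib[3, ], ps$yes[1, ], 0)
  expect_equal(nrow(s3), (300 - L + 1) * 2)
  # deterministic ordering
  expect_false(is.unsorted(s3$position[s3$strand == "+"]))
})
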