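#' Position weight matrix libraries
#'
#' A PWM library is a tibble with one row per matrix and columns
#' `id` (matrix accession), `tf_gene` (associated transcription-factor gene
#' symbol, `NA` when unannotated), `consensus` (majority-base string) and
#' `counts` (list column of 4 x L nonnegative count matrices with rows
#' A, C, G, T).
#'
#' @param counts A 4 x L numeric matrix of per-position nucleotide counts,
#'   rows in A, C, G, T order.
#' @param id Matrix accession string.
#' @param tf_gene Associated gene symbol (or `NA`).
#' @return A one-row PWM library tibble.
#' @export
#' @examples
#' m <- matrix(c(10, 0, 0, 0, 0, 10, 0, 0), nrow = 4,
#'             dimnames = list(c("A", "C", "G", "T"), NULL))
#' pwm_row(m, "M1", "TP53")
pwm_row <- function(counts, id, tf_gene = NA_character_) {
  counts <- validate_pwm_counts(counts)
  tibble::tibble(
    id = id, tf_gene = tf_gene,
    consensus = pwm_consensus(counts),
    counts = list(counts)
  )
}

#' @noRd
validate_pwm_counts <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != 4) {
    up_abort("PWM counts must be a 4 x L matrix (rows A, C, G, T)")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    up_abort("PWM counts must be finite and nonnegative")
  }
  if (any(colSums(counts) <= 0)) {
    up_abort("every PWM column must have positive total count")
  }
  rownames(counts) <- c("A", "C", "G", "T")
  counts
}

#' @noRd
pwm_consensus <- function(counts) {
  paste(c("A", "C", "G", "T")[apply(counts, 2, which.max)], collapse = "")
}

# Column frequencies with pseudocount (0.25 added to every cell, so each
# column denominator gains 1); guarantees strictly positive frequencies.
#' @noRd
pwm_frequencies <- function(counts, pseudocount = 0.25) {
  counts <- counts + pseudocount
  sweep(counts, 2, colSums(counts), "/")
}

# Information weight per column: I(i) = sum_b f_i(b) * ln(4 f_i(b)).
# Zero for a uniform column, ln(4) for a fully conserved one.
#' @noRd
pwm_information <- function(freq) {
  colSums(freq * log(4 * freq))
}

# Precomputed scanning weights: 5 x L contribution matrix (row 5 = N base,
# which contributes the column minimum) plus the min/max attainable sums.
#' @noRd
pwm_weights <- function(counts, pseudocount = 0.25) {
  f <- pwm_frequencies(counts, pseudocount)
  info <- pwm_information(f)
  w <- sweep(f, 2, info, "*")
  wmin <- info * apply(f, 2, min)
  list(
    w = rbind(w, N = wmin),
    minsum = sum(wmin),
    maxsum = sum(info * apply(f, 2, max))
  )
}

# Reverse-complement a count matrix: complement bases, reverse positions.
#' @noRd
pwm_revcomp_counts <- function(counts) {
  rc <- counts[4:1, ncol(counts):1, drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  rc
}

#' @noRd
encode_dna <- function(sequence) {
  code <- match(strsplit(toupper(sequence), "")[[1]],
                c("A", "C", "G", "T", "N")) - 1L
  if (anyNA(code)) up_abort("sequence contains letters outside {A,C,G,T,N}")
  code
}

#' Match-style normalized PWM score of a single subsequence
#'
#' Scores a subsequence of exactly the matrix length with the
#' information-weighted normalized similarity
#' `(Current - Min) / (Max - Min)`, where
#' `Current = sum_i I(i) f_i(b_i)`, `I(i) = sum_b f_i(b) ln(4 f_i(b))`
#' is the information weight of column i, and Max/Min substitute each
#' column's maximum/minimum frequency. Frequencies carry a pseudocount of
#' 0.25 per cell. An `N` base contributes the column minimum. A fully
#' uniform (zero-information) matrix scores 0 by convention.
#'
#' @param pwm A one-row PWM library tibble (see [pwm_row()]) or a 4 x L
#'   count matrix.
#' @param subsequence A string over A,C,G,T,N of length equal to the matrix
#'   length.
#' @param pseudocount Pseudocount added to each count cell (default 0.25).
#' @return A score in \[0, 1\]; the consensus sequence scores exactly 1.
#' @export
#' @examples
#' lib <- gen_pwm_library(1, c(8, 8), seed = 1)
#' pwm_match_score(lib[1, ], lib$consensus[1])
pwm_match_score <- function(pwm, subsequence, pseudocount = 0.25) {
  counts <- as_pwm_counts(pwm)
  code <- encode_dna(subsequence)
  if (length(code) != ncol(counts)) {
    up_abort("subsequence length must equal the PWM length")
  }
  wt <- pwm_weights(counts, pseudocount)
  cur <- sum(wt$w[cbind(code + 1L, seq_along(code))])
  if (wt$maxsum - wt$minsum <= 0) return(0)
  (cur - wt$minsum) / (wt$maxsum - wt$minsum)
}

#' @noRd
as_pwm_counts <- function(pwm) {
  if (is.matrix(pwm)) return(validate_pwm_counts(pwm))
  if (is.data.frame(pwm) && "counts" %in% names(pwm) && nrow(pwm) == 1) {
    return(validate_pwm_counts(pwm$counts[[1]]))
  }
  up_abort("`pwm` must be a 4 x L count matrix or a one-row PWM library")
}

#' Scan one promoter sequence with one PWM
#'
#' Slides the matrix over both strands and reports every offset whose
#' Match-style score reaches `cutoff`. Minus-strand sites are reported at
#' the forward-strand coordinate of the site start (0-based).
#'
#' @param pwm One-row PWM library tibble or 4 x L count matrix.
#' @param sequence Promoter sequence string.
#' @param cutoff Minimum score in \[0, 1\].
#' @param seq_id Identifier copied into the output.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return A tibble with columns `seq_id`, `pwm_id`, `position`, `strand`,
#'   `score`, sorted by position.
#' @export
#' @examples
#' lib <- gen_pwm_library(1, c(8, 8), seed = 1)
#' scan_sequence(lib[1, ], paste0("ACGTACGTAC", lib$consensus[1], "GGG"), 0.9)
scan_sequence <- function(pwm, sequence, cutoff, seq_id = "seq",
                          both_strands = TRUE) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  counts <- as_pwm_counts(pwm)
  pwm_id <- if (is.data.frame(pwm)) pwm$id[[1]] else "pwm"
  code <- encode_dna(sequence)
  if (length(code) < ncol(counts)) {
    warn("promoter shorter than the PWM; no sites")
    return(empty_site_table())
  }
  out <- scan_encoded(code, counts, cutoff, both_strands)
  if (length(out$position) == 0) return(empty_site_table())
  dplyr::arrange(
    tibble::tibble(seq_id = seq_id, pwm_id = pwm_id,
                   position = out$position, strand = out$strand,
                   score = out$score),
    .data$position, .data$strand
  )
}

#' @noRd
empty_site_table <- function() {
  tibble::tibble(seq_id = character(), pwm_id = character(),
                 position = integer(), strand = character(),
                 score = double())
}

#' @noRd
scan_encoded <- function(code, counts, cutoff, both_strands = TRUE) {
  wt <- pwm_weights(counts)
  fwd <- scan_scores_cpp(code, wt$w, wt$minsum, wt$maxsum)
  hit_f <- which(fwd >= cutoff)
  pos <- hit_f - 1L
  strand <- rep("+", length(hit_f))
  score <- fwd[hit_f]
  if (both_strands) {
    wtr <- pwm_weights(pwm_revcomp_counts(counts))
    rev <- scan_scores_cpp(code, wtr$w, wtr$minsum, wtr$maxsum)
    hit_r <- which(rev >= cutoff)
    pos <- c(pos, hit_r - 1L)
    strand <- c(strand, rep("-", length(hit_r)))
    score <- c(score, rev[hit_r])
  }
  list(position = as.integer(pos), strand = strand, score = score)
}

#' Scan a promoter set with a PWM library
#'
#' Applies [scan_sequence()] to every (matrix, promoter) pair and returns
#' one site table, deterministically ordered by `pwm_id`, `seq_id`,
#' `position`.
#'
#' @param library PWM library tibble.
#' @param promoters Promoter set tibble with columns `gene_id`, `sequence`
#'   (see [gen_promoter_sets()] / [extract_promoters()]).
#' @param cutoff Minimum score in \[0, 1\].
#' @param both_strands Scan both strands (default `TRUE`).
#' @return Site table tibble (`seq_id`, `pwm_id`, `position`, `strand`,
#'   `score`).
#' @export
scan_set <- function(library, promoters, cutoff, both_strands = TRUE) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (nrow(library) == 0 || nrow(promoters) == 0) return(empty_site_table())
  codes <- lapply(promoters$sequence, encode_dna)
  ptr <- as.integer(c(0, cumsum(lengths(codes))))
  seqs <- unlist(codes, use.names = FALSE)
  res <- purrr::map(seq_len(nrow(library)), function(i) {
    counts <- library$counts[[i]]
    wf <- pwm_weights(counts)
    wr <- pwm_weights(pwm_revcomp_counts(counts))
    hit <- scan_set_cpp(seqs, ptr, wf$w, wf$minsum, wf$maxsum,
                        wr$w, wr$minsum, wr$maxsum, cutoff, both_strands)
    tibble::tibble(seq_id = promoters$gene_id[hit$seq],
                   pwm_id = rep.int(library$id[i], length(hit$pos)),
                   position = hit$pos,
                   strand = c("+", "-")[hit$strand + 1L],
                   score = hit$score)
  })
  dplyr::arrange(dplyr::bind_rows(res),
                 .data$pwm_id, .data$seq_id, .data$position)
}

#' Extract promoter windows around transcription start sites
#'
#' Cuts a window of `upstream` bases before and `downstream` bases after
#' each TSS out of genome sequences. For plus-strand genes the window is
#' `[tss - upstream, tss + downstream)` in 0-based half-open coordinates;
#' for minus-strand genes it is `[tss - downstream, tss + upstream)`
#' reverse-complemented, so that the returned sequence always reads from
#' the most upstream base toward the gene. Windows are truncated at
#' chromosome ends with a warning. When a gene has several TSS rows the
#' first wins, with a warning.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param tss A tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand` (BED-style, 0-based half-open single-base TSS
#'   marks), or a path to a 6-column BED file.
#' @param upstream,downstream Window extents in bases (defaults 1000 and
#'   100, the conventional promoter window).
#' @return Promoter set tibble (`gene_id`, `sequence`, `tss_offset`), with
#'   the window convention stored in the `"window"` attribute.
#' @export
extract_promoters <- function(genome, tss, upstream = 1000, downstream = 100) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(tss)) tss <- read_bed(tss)
  stopifnot(all(c("chrom", "start", "strand", "name") %in% names(tss)))
  if (!all(tss$strand %in% c("+", "-"))) {
    up_abort("TSS strand must be '+' or '-'")
  }
  missing <- setdiff(unique(tss$chrom), names(genome))
  if (length(missing) > 0) {
    up_abort(paste0("TSS chromosomes absent from FASTA: ",
                    paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tss$name)) {
    warn("multiple TSS rows for some genes; keeping the first of each")
    tss <- dplyr::distinct(tss, .data$name, .keep_all = TRUE)
  }
  truncated <- FALSE
  rows <- purrr::map(seq_len(nrow(tss)), function(i) {
    chrom <- genome[[tss$chrom[i]]]
    t0 <- tss$start[i]
    if (tss$strand[i] == "+") {
      lo <- t0 - upstream; hi <- t0 + downstream
    } else {
      lo <- t0 - downstream; hi <- t0 + upstream
    }
    clo <- max(lo, 0); chi <- min(hi, length(chrom))
    if (clo > lo || chi < hi) truncated <<- TRUE
    s <- as.character(Biostrings::subseq(chrom, clo + 1, chi))
    if (tss$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    tibble::tibble(gene_id = tss$name[i], sequence = s,
                   tss_offset = if (tss$strand[i] == "+") t0 - clo
                                else chi - t0)
  })
  if (truncated) warn("some promoter windows truncated at chromosome ends")
  out <- dplyr::bind_rows(rows)
  attr(out, "window") <- c(upstream = upstream, downstream = downstream)
  out
}
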