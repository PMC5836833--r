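#' Read a PWM library in TRANSFAC-dialect flat-file format
#'
#' Parses records of the form `AC`/`ID`/`BF` header lines, a `P0` column
#' header, numbered rows with four counts and a consensus letter, and a
#' `//` terminator. `BF` is optional (unannotated matrices get `NA`).
#'
#' @param path Path to a flat file, or a character vector of lines.
#' @return A PWM library tibble (see [pwm_row()]).
#' @export
read_transfac_matrices <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines_trim <- trimws(lines)
  keep <- which(lines_trim != "")
  if (length(keep) == 0) {
    warn("empty PWM file; returning an empty library")
    return(empty_pwm_library())
  }
  recs <- list()
  cur <- list(ac = NA_character_, id = NA_character_, bf = NA_character_,
              rows = list())
  flush <- function(cur, lineno) {
    if (length(cur$rows) == 0) {
      up_abort(paste0("record ending at line ", lineno, " has no count rows"))
    }
    counts <- do.call(cbind, cur$rows)
    acc <- if (!is.na(cur$ac)) cur$ac else cur$id
    pwm_row(counts, id = acc, tf_gene = cur$bf)
  }
  for (i in keep) {
    ln <- lines_trim[i]
    tag <- toupper(substr(ln, 1, 2))
    rest <- trimws(substr(ln, 3, nchar(ln)))
    if (tag == "//") {
      recs[[length(recs) + 1]] <- flush(cur, i)
      cur <- list(ac = NA_character_, id = NA_character_, bf = NA_character_,
                  rows = list())
    } else if (tag == "AC") {
      cur$ac <- rest
    } else if (tag == "ID") {
      cur$id <- rest
    } else if (tag == "BF") {
      cur$bf <- rest
    } else if (tag == "P0" || tag == "PO") {
      # column header, ignored
    } else if (grepl("^[0-9]+$", substr(ln, 1, 2))) {
      fields <- strsplit(ln, "\\s+")[[1]][-1]
      # trailing consensus letter is optional
      if (length(fields) >= 1 && grepl("^[A-Za-z]+$", fields[length(fields)])) {
        fields <- fields[-length(fields)]
      }
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) != 4 || anyNA(vals)) {
        up_abort(paste0("line ", i,
                        ": expected 4 numeric count fields, got ",
                        length(fields)))
      }
      cur$rows[[length(cur$rows) + 1]] <- vals
    } else {
      # unknown tags tolerated (real TRANSFAC carries many annotation lines)
    }
  }
  if (length(cur$rows) > 0) {
    up_abort("file ends inside a record (missing '//' terminator)")
  }
  if (length(recs) == 0) {
    warn("no matrix records found; returning an empty library")
    return(empty_pwm_library())
  }
  dplyr::bind_rows(recs)
}

#' @noRd
empty_pwm_library <- function() {
  tibble::tibble(id = character(), tf_gene = character(),
                 consensus = character(), counts = list())
}

#' Write a PWM library in TRANSFAC-dialect format
#'
#' @param library PWM library tibble.
#' @param path Output path; when `NULL` the lines are returned invisibly.
#' @return The written lines, invisibly.
#' @export
write_transfac_matrices <- function(library, path = NULL) {
  lines <- unlist(purrr::map(seq_len(nrow(library)), function(i) {
    counts <- library$counts[[i]]
    cons <- strsplit(library$consensus[i], "")[[1]]
    rows <- vapply(seq_len(ncol(counts)), function(j) {
      sprintf("%02d  %s  %s", j,
              paste(formatC(counts[, j], format = "g", width = 6),
                    collapse = "  "),
              cons[j])
    }, character(1))
    c(paste0("AC  ", library$id[i]),
      paste0("ID  ", library$id[i]),
      if (!is.na(library$tf_gene[i])) paste0("BF  ", library$tf_gene[i]),
      "P0       A       C       G       T",
      rows, "//")
  }))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write a promoter set as FASTA
#'
#' Headers follow `gene_id|set|offset` where `set` labels Yes/No membership
#' and `offset` is the TSS offset within the window.
#'
#' @param promoters Promoter set tibble; an optional `set` column is used
#'   for the header, else `set` is used for all entries.
#' @param path Output FASTA path.
#' @param set Default set label when the tibble has no `set` column.
#' @export
write_promoters_fasta <- function(promoters, path, set = "yes") {
  labels <- if ("set" %in% names(promoters)) promoters$set else set
  offs <- if ("tss_offset" %in% names(promoters)) promoters$tss_offset else 0L
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- paste(promoters$gene_id, labels, offs, sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

#' Read a promoter set written by [write_promoters_fasta()]
#'
#' @param path FASTA path.
#' @return Promoter set tibble with `gene_id`, `set`, `tss_offset`,
#'   `sequence`.
#' @export
read_promoters_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- stringr::str_split_fixed(names(seqs), stringr::fixed("|"), 3)
  tibble::tibble(
    gene_id = parts[, 1],
    set = ifelse(parts[, 2] == "", NA_character_, parts[, 2]),
    tss_offset = suppressWarnings(as.integer(parts[, 3])),
    sequence = as.character(seqs)
  )
}

#' Read a BED file of TSS marks
#'
#' @param path Path to a 6-column BED file (chrom, start, end, name, score,
#'   strand; 0-based half-open).
#' @return A tibble with those columns.
#' @export
read_bed <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE)
}

#' Read a gene-set collection in GMT format
#'
#' Tab-separated lines: set id, description, then one gene per field.
#' Duplicate genes within a set are collapsed; empty sets are dropped with
#' a warning.
#'
#' @param path GMT path or character vector of lines.
#' @return A tibble with columns `set_id`, `description`, `genes`
#'   (list column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[trimws(lines) != ""]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      up_abort(paste0("GMT line ", i, ": fewer than 3 tab-separated fields"))
    }
    genes <- unique(trimws(f[-(1:2)]))
    genes <- genes[genes != ""]
    tibble::tibble(set_id = f[1], description = f[2], genes = list(genes))
  })
  out <- dplyr::bind_rows(rows)
  empty <- lengths(out$genes) == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " empty gene set(s) dropped"))
    out <- out[!empty, ]
  }
  out
}

#' Write a gene-set collection in GMT format
#'
#' @param collection Tibble as returned by [read_gmt()].
#' @param path Output path; `NULL` returns the lines invisibly.
#' @export
write_gmt <- function(collection, path = NULL) {
  lines <- purrr::map_chr(seq_len(nrow(collection)), function(i) {
    paste(c(collection$set_id[i], collection$description[i],
            collection$genes[[i]]), collapse = "\t")
  })
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read / write an expression matrix with its design sidecar
#'
#' The expression table is genes x samples TSV with a `gene_id` first
#' column; the design sidecar has columns `sample`, `condition`,
#' `cell_line`, `replicate`.
#'
#' @param expr_path,design_path TSV paths.
#' @return A list with `expr` (wide tibble) and `design` (tibble).
#' @export
read_expression <- function(expr_path, design_path) {
  expr <- readr::read_tsv(expr_path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  design <- readr::read_tsv(design_path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  validate_expression(expr, design)
  list(expr = expr, design = design)
}

#' @rdname read_expression
#' @param expr,design The expression and design tibbles to write.
#' @export
write_expression <- function(expr, design, expr_path, design_path) {
  readr::write_tsv(expr, expr_path, progress = FALSE)
  readr::write_tsv(design, design_path, progress = FALSE)
  invisible(c(expr_path, design_path))
}

#' @noRd
validate_expression <- function(expr, design) {
  samples <- setdiff(names(expr), "gene_id")
  if (anyDuplicated(expr$gene_id)) up_abort("duplicate gene identifiers")
  if (anyDuplicated(samples)) up_abort("duplicate sample identifiers")
  if (!all(samples %in% design$sample)) {
    up_abort("every sample column needs a design row")
  }
  invisible(TRUE)
}

#' Read / write a directed signal-transduction edge list
#'
#' Rows are `source`, `target`, `relation` and optional comma-separated
#' `source_genes`, `target_genes`. Duplicate edges are collapsed.
#'
#' @param path TSV path.
#' @return A tibble of de-duplicated edges.
#' @export
read_network_edges <- function(path) {
  edges <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE),
    error = function(e) up_abort(paste0("cannot parse network TSV: ",
                                        conditionMessage(e))))
  need <- c("source", "target", "relation")
  if (!all(need %in% names(edges))) {
    up_abort("network TSV needs columns source, target, relation")
  }
  bad <- which(is.na(edges$source) | is.na(edges$target))
  if (length(bad) > 0) {
    up_abort(paste0("malformed network row at line ", bad[1] + 1))
  }
  dplyr::distinct(edges, .data$source, .data$target, .keep_all = TRUE)
}

#' @rdname read_network_edges
#' @param edges Edge tibble to write.
#' @export
write_network_edges <- function(edges, path) {
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' Read / write a viability table
#'
#' @param path TSV with columns `concentration_uM`, `fraction_alive`,
#'   `replicate`.
#' @return A tibble.
#' @export
read_viability <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    concentration_uM = readr::col_double(),
    fraction_alive = readr::col_double(),
    replicate = readr::col_character()), progress = FALSE)
}

#' @rdname read_viability
#' @param table Viability tibble to write.
#' @export
write_viability <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}
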