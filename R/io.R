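#' Read a gene expression matrix
#'
#' Reads a tab- or comma-separated table whose first column holds gene
#' identifiers and whose remaining columns hold numeric expression values
#' (genes in rows, samples in columns).
#'
#' @param path Path to a delimited text file.
#' @return A tibble with a `gene_id` character column followed by one numeric
#'   column per sample, in file order.
#' @export
read_expression_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE, col_types = readr::cols())
  if (ncol(df) < 2L) {
    abort("expression file must have a gene-id column plus at least one sample column")
  }
  names(df)[1] <- "gene_id"
  df$gene_id <- as.character(df$gene_id)
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate gene id(s) in expression file: ",
                 paste(unique(dup), collapse = ", ")))
  }
  for (j in seq(2L, ncol(df))) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num))
      if (length(bad) > 0L) {
        abort(sprintf("non-numeric expression value '%s' at row %d, column '%s'",
                      as.character(col[bad[1]]), bad[1], names(df)[j]))
      }
      df[[j]] <- num
    } else if (anyNA(col)) {
      bad <- which(is.na(col))
      abort(sprintf("missing expression value at row %d, column '%s'",
                    bad[1], names(df)[j]))
    }
    if (any(!is.finite(df[[j]]))) {
      bad <- which(!is.finite(df[[j]]))
      abort(sprintf("non-finite expression value at row %d, column '%s'",
                    bad[1], names(df)[j]))
    }
  }
  tibble::as_tibble(df)
}

#' Extract the numeric matrix from an expression tibble
#'
#' @param expr A tibble as returned by [read_expression_matrix()].
#' @return A numeric matrix, genes x samples, with gene ids as rownames.
#' @export
expression_values <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read a regulatory edge list (gold-standard dialect)
#'
#' Reads a whitespace-separated file with two or three columns:
#' `TF target [label]`. A third column of 0/1 marks known negatives versus
#' positives; with two columns every edge is a positive.
#'
#' @param path Path to the edge-list file.
#' @param directed Logical; kept for interface symmetry (edges are always
#'   stored as ordered pairs).
#' @param allow_self_loops Keep rows with source equal to target. Default
#'   `FALSE` drops them with an error.
#' @return A tibble with columns `source`, `target`, `label` (integer 0/1).
#' @export
read_edge_list <- function(path, directed = TRUE, allow_self_loops = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(source = character(), target = character(),
                          label = integer()))
  }
  parts <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed edge-list line %d: expected 2 or 3 fields, found %d",
                  bad[1], nf[bad[1]]))
  }
  src <- vapply(parts, `[[`, character(1), 1L)
  tgt <- vapply(parts, `[[`, character(1), 2L)
  lab <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "1",
                character(1))
  lab_num <- suppressWarnings(as.integer(lab))
  if (anyNA(lab_num) || any(!lab_num %in% c(0L, 1L))) {
    bad <- which(is.na(lab_num) | !lab_num %in% c(0L, 1L))
    abort(sprintf("edge label on line %d must be 0 or 1, found '%s'",
                  bad[1], lab[bad[1]]))
  }
  if (!allow_self_loops && any(src == tgt)) {
    bad <- which(src == tgt)
    abort(sprintf("self-loop edge on line %d (%s -> %s)", bad[1],
                  src[bad[1]], tgt[bad[1]]))
  }
  key <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    abort(sprintf("duplicate edge pair (%s, %s) on line %d",
                  src[d], tgt[d], d))
  }
  tibble::tibble(source = src, target = tgt, label = lab_num)
}

#' Read gene sequences from a FASTA file
#'
#' Header tokens up to the first whitespace are used as gene ids; sequences
#' are uppercased. Alphabet is restricted to A, C, G, T, N.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one uppercase sequence per gene id.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    empty <- ids[!nzchar(seqs)][1]
    abort(sprintf("empty sequence for record '%s'", empty))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id '%s'", ids[duplicated(ids)][1]))
  }
  if (any(grepl("[^ACGTN]", seqs))) {
    bad <- ids[grepl("[^ACGTN]", seqs)][1]
    abort(sprintf("sequence '%s' contains characters outside A/C/G/T/N", bad))
  }
  setNames(seqs, ids)
}

#' Write a named sequence set as FASTA
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  names(set) <- names(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Write ranked edge predictions
#'
#' Writes a tab-separated table of scored directed edges, sorted by
#' descending score with ties broken lexicographically by (source, target).
#'
#' @param scored_edges Tibble or data frame with columns `source`, `target`,
#'   `score` (finite, in \[0, 1\]).
#' @param path Output path.
#' @return The sorted tibble, invisibly.
#' @export
write_predictions <- function(scored_edges, path) {
  df <- tibble::as_tibble(scored_edges)
  stopifnot(all(c("source", "target", "score") %in% names(df)))
  if (nrow(df) > 0 && any(!is.finite(df$score))) {
    abort("prediction scores must be finite")
  }
  df <- dplyr::arrange(df, dplyr::desc(.data$score), .data$source, .data$target)
  readr::write_tsv(df[, c("source", "target", "score")], path, progress = FALSE)
  invisible(df)
}

#' Read ranked edge predictions written by [write_predictions()]
#'
#' @param path Path to the predictions TSV.
#' @return Tibble with `source`, `target`, `score`.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    source = readr::col_character(),
                    target = readr::col_character(),
                    score = readr::col_double()))
}
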