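#' Split a nucleotide sequence into overlapping k-mers
#'
#' Sliding window of width `k`; stride 1 by default so adjacent fragments
#' share context, or stride `k` for non-overlapping segmentation.
#'
#' @param seq Nucleotide string.
#' @param k Fragment length (default 5).
#' @param stride Window step (default 1).
#' @return Character vector of k-mers; empty when `nchar(seq) < k`.
#' @export
kmerize <- function(seq, k = 5L, stride = 1L) {
  if (k < 1L) abort("k must be >= 1")
  if (stride < 1L) abort("stride must be >= 1")
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq.int(1L, n - k + 1L, by = stride)
  substring(seq, starts, starts + k - 1L)
}

base_counts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  counts <- tabulate(idx[!is.na(idx)], nbins = 4L)
  names(counts) <- c("A", "C", "G", "T")
  counts
}

#' Z-curve endpoint of a sequence
#'
#' Cumulative Z-curve coordinates at the end of the sequence:
#' `X = (A+G)-(C+T)`, `Y = (A+C)-(T+G)`, `Z = (A+T)-(C+G)`, counting only
#' A/C/G/T bases (N excluded from counts and from the length `n`). With
#' `normalize = TRUE` (default) each coordinate is divided by `n`, mapping
#' it into \[-1, 1\].
#'
#' @param seq Nucleotide string with at least one non-N base.
#' @param normalize Divide the endpoint by the effective length.
#' @return Named numeric vector `c(zx, zy, zz)`.
#' @export
z_curve <- function(seq, normalize = TRUE) {
  ct <- base_counts(seq)
  n <- sum(ct)
  if (n == 0L) abort("sequence has no A/C/G/T bases")
  v <- c(zx = 2 * (ct[["A"]] + ct[["G"]]) - n,
         zy = 2 * (ct[["A"]] + ct[["C"]]) - n,
         zz = 2 * (ct[["A"]] + ct[["T"]]) - n)
  if (normalize) v / n else v
}

#' GC content of a sequence
#'
#' Proportion of G and C among the A/C/G/T bases.
#'
#' @param seq Nucleotide string with at least one non-N base.
#' @return Number in \[0, 1\].
#' @export
gc_content <- function(seq) {
  ct <- base_counts(seq)
  n <- sum(ct)
  if (n == 0L) abort("sequence has no A/C/G/T bases")
  (ct[["G"]] + ct[["C"]]) / n
}

#' AT/GC ratio of a sequence
#'
#' `(A + T) / (G + C)`. A zero GC count would leave the ratio undefined, so
#' a +1 pseudocount enters the denominator in that case only.
#'
#' @param seq Nucleotide string.
#' @return Nonnegative number.
#' @export
atgc_ratio <- function(seq) {
  ct <- base_counts(seq)
  num <- ct[["A"]] + ct[["T"]]
  den <- ct[["G"]] + ct[["C"]]
  if (den == 0) num / (den + 1) else num / den
}

#' Nucleic acid composition
#'
#' Frequencies of A, C, G, T among the non-N bases; sums to 1.
#'
#' @param seq Nucleotide string with at least one non-N base.
#' @return Named numeric vector of length 4.
#' @export
nac <- function(seq) {
  ct <- base_counts(seq)
  n <- sum(ct)
  if (n == 0L) abort("sequence has no A/C/G/T bases")
  ct / n
}

DINUCS <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          function(a, b) paste0(a, b)))

#' Adjacent dinucleotide frequencies (0-spaced nucleic acid pairs)
#'
#' Frequencies of the 16 adjacent base pairs; pairs touching an N are
#' excluded from numerator and denominator. Sums to 1.
#'
#' @param seq Nucleotide string with at least one valid adjacent pair.
#' @return Named numeric vector of length 16 in row-major A/C/G/T order
#'   (AA, CA, GA, TA, AC, ...): the fixed order of `dinucleotide_order()`.
#' @export
cksnap0 <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(chars) < 2L) abort("sequence shorter than 2 bases")
  a <- chars[-length(chars)]
  b <- chars[-1L]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) abort("sequence has no valid adjacent base pair")
  pair <- paste0(a[ok], b[ok])
  counts <- tabulate(match(pair, DINUCS), nbins = 16L)
  names(counts) <- DINUCS
  counts / sum(counts)
}

#' Fixed dinucleotide ordering used by [cksnap0()]
#' @return Character vector of the 16 dinucleotides.
#' @export
dinucleotide_order <- function() DINUCS

#' Physicochemical descriptor vector of a sequence
#'
#' Concatenates, in fixed order, the normalized Z-curve endpoint (3), GC
#' content (1), AT/GC ratio (1), nucleotide composition (4) and adjacent
#' dinucleotide frequencies (16): 25 values in total.
#'
#' @param seq Nucleotide string.
#' @return Named numeric vector of length 25.
#' @export
physchem_vector <- function(seq) {
  c(z_curve(seq),
    gc = gc_content(seq),
    atgc = atgc_ratio(seq),
    setNames(nac(seq), paste0("nac_", c("A", "C", "G", "T"))),
    setNames(cksnap0(seq), paste0("dnt_", DINUCS)))
}

#' Physicochemical descriptors for a sequence set
#'
#' @param sequences Named character vector of sequences.
#' @return Tibble with `gene_id` plus the 25 descriptor columns.
#' @export
physchem_features <- function(sequences) {
  mat <- t(vapply(sequences, physchem_vector, numeric(25)))
  dplyr::bind_cols(tibble::tibble(gene_id = names(sequences)),
                   tibble::as_tibble(mat))
}
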