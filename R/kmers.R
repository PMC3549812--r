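#' Extract the k-mer spectrum of a sequence
#'
#' Samples one k-mer from every position of `sequence`, left to right, giving
#' the multiset of all `L - k + 1` length-`k` substrings. This is the spectrum
#' that defines the edge set of a de Bruijn graph: each k-mer is a directed
#' edge from its (k-1)-prefix to its (k-1)-suffix.
#'
#' @param sequence A single nucleotide string over the alphabet A, C, G, T.
#' @param k K-mer length in bases (positive integer, `k <= nchar(sequence)`).
#' @param source Tag recording where the spectrum came from, `"reference"` or
#'   `"donor"`. Purely descriptive.
#' @return A `kmer_spectrum` object: list with elements `k`, `kmers`
#'   (character vector in source order) and `source`.
#' @examples
#' extract_kmers("ATAGC", 4)
#' @export
extract_kmers <- function(sequence, k, source = c("donor", "reference")) {
  source <- match.arg(source)
  check_dna(sequence)
  k <- check_k(k)
  L <- nchar(sequence)
  if (L < k) {
    stop("sequence of length ", L, " is shorter than k = ", k, call. = FALSE)
  }
  kmers <- substring(sequence, seq_len(L - k + 1L), seq(k, L))
  kmer_spectrum(kmers, k = k, source = source)
}

#' Construct a k-mer spectrum from a character vector of k-mers
#'
#' @param kmers Character vector, each element of length `k`.
#' @param k K-mer length.
#' @param source See [extract_kmers()].
#' @return A `kmer_spectrum` object.
#' @export
kmer_spectrum <- function(kmers, k, source = "donor") {
  k <- check_k(k)
  if (length(kmers) && any(nchar(kmers) != k)) {
    stop("all k-mers must have length exactly k = ", k, call. = FALSE)
  }
  structure(list(k = k, kmers = as.character(kmers), source = source),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("kmer_spectrum: ", length(x$kmers), " k-mers (k = ", x$k,
      ", ", length(unique(x$kmers)), " distinct, source = ", x$source, ")\n",
      sep = "")
  invisible(x)
}

#' @export
length.kmer_spectrum <- function(x) length(x$kmers)

#' Spell the sequence of a de Bruijn edge path
#'
#' Concatenates a walk of k-mers that overlap by k-1 bases: the first k-mer
#' followed by the final base of each subsequent k-mer. The result has length
#' `length(path) + k - 1`.
#'
#' @param path Character vector of k-mers forming a contiguous walk
#'   (consecutive k-mers must share a (k-1)-mer overlap).
#' @param k K-mer length.
#' @return A single nucleotide string.
#' @examples
#' spell(c("ATAG", "TAGC"), 4)
#' @export
spell <- function(path, k) {
  k <- check_k(k)
  if (length(path) == 0L) stop("empty path", call. = FALSE)
  if (any(nchar(path) != k)) stop("path elements must be k-mers", call. = FALSE)
  if (length(path) > 1L) {
    ok <- substr(path[-length(path)], 2L, k) == substr(path[-1L], 1L, k - 1L)
    if (!all(ok)) {
      stop("discontiguous path at step ", which(!ok)[1L], call. = FALSE)
    }
  }
  paste0(path[1L], paste(substr(path[-1L], k, k), collapse = ""))
}

## ---- internal validation helpers ------------------------------------------

check_dna <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  bad <- regexpr("[^ACGT]", sequence)
  if (bad != -1L) {
    stop("non-ACGT character '", substr(sequence, bad, bad),
         "' at offset ", bad - 1L, " (0-based)", call. = FALSE)
  }
  invisible(sequence)
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  as.integer(k)
}

## Tabulate a spectrum into distinct k-mers and multiplicities, preserving
## first-appearance order.  Used by graph construction.
spectrum_counts <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  uk <- unique(spectrum$kmers)
  mult <- tabulate(match(spectrum$kmers, uk), nbins = length(uk))
  list(kmer = uk, mult = mult)
}

## Sorted multiset signature of a set of contigs' k-mers; the conservation
## invariant compares these across pipeline stages.
contig_kmer_multiset <- function(contigs, k, mult = NULL) {
  if (is.null(mult)) mult <- rep(1L, length(contigs))
  out <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    km <- extract_kmers(contigs[[i]], k)$kmers
    out[[i]] <- rep(km, times = mult[i])
  }
  sort(unlist(out, use.names = FALSE))
}
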