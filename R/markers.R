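#' Build an exact inverted index of reference k-mers
#'
#' Maps every k-mer of the reference to the sorted list of its 0-based
#' positions (reference k-mer indices). Lookup of this index is how contigs
#' are aligned to the reference: reads are error-free in the intended
#' setting, so exact k-mer matching replaces inexact local alignment.
#'
#' @param ref Reference nucleotide string.
#' @param k K-mer length.
#' @return A `reference_index` object.
#' @examples
#' idx <- build_reference_index("ATAGCAATCGTGTTC", 4)
#' index_lookup(idx, "GTTC")
#' @export
build_reference_index <- function(ref, k) {
  check_dna(ref)
  k <- check_k(k)
  if (nchar(ref) < k) stop("reference shorter than k", call. = FALSE)
  kmers <- substring(ref, seq_len(nchar(ref) - k + 1L), seq(k, nchar(ref)))
  uk <- unique(kmers)
  gid <- match(kmers, uk)
  pos <- split(seq_along(kmers) - 1L, factor(gid, levels = seq_along(uk)))
  names(pos) <- NULL
  structure(list(k = k, kmer = uk, positions = pos,
                 n_kmers = length(kmers), ref_length = nchar(ref)),
            class = "reference_index")
}

#' @export
print.reference_index <- function(x, ...) {
  cat("reference_index: ", x$n_kmers, " k-mers (k = ", x$k, ", ",
      length(x$kmer), " distinct)\n", sep = "")
  invisible(x)
}

#' Look up the reference positions of a k-mer
#'
#' @param index A `reference_index`.
#' @param kmer A single k-mer string.
#' @return Integer vector of 0-based reference positions (empty if absent).
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "reference_index"))
  i <- match(kmer, index$kmer)
  if (is.na(i)) integer(0) else index$positions[[i]]
}

#' Compute reference markers of a contig
#'
#' A run of contig k-mers whose reference positions are consecutive
#' (incrementing by one per step) is a reference-parallel run; it is
#' summarized by a reference marker `(start, end)` holding the first and last
#' reference k-mer index, together with the run's offset range inside the
#' contig (in k-mer steps). All maximal runs are reported, including
#' overlapping alternatives arising from reference repeats; a single matching
#' k-mer yields a marker with `start == end`.
#'
#' Internally every (contig offset, reference position) match pair is placed
#' on a diagonal `pos - offset`; maximal runs are the maximal stretches of
#' consecutive offsets on one diagonal.
#'
#' @param contig Contig nucleotide string (`nchar(contig) >= k`).
#' @param index A `reference_index` built from the reference at the same `k`.
#' @return A data frame with columns `start`, `end`, `offset_start`,
#'   `offset_end` (all 0-based, inclusive), ordered by `offset_start` then
#'   `start`. Zero rows if the contig shares no k-mer with the reference.
#' @examples
#' idx <- build_reference_index("TTGTTATTCTAC", 4)
#' compute_markers("GTTATTCT", idx)   # one marker, 0-based (2, 6)
#' @export
compute_markers <- function(contig, index) {
  stopifnot(inherits(index, "reference_index"))
  check_dna(contig)
  k <- index$k
  if (nchar(contig) < k) stop("contig shorter than k", call. = FALSE)
  ck <- substring(contig, seq_len(nchar(contig) - k + 1L), seq(k, nchar(contig)))
  gid <- match(ck, index$kmer)
  hit <- which(!is.na(gid))
  if (length(hit) == 0L) return(empty_markers())
  plist <- index$positions[gid[hit]]
  nper <- lengths(plist)
  I <- rep.int(hit - 1L, nper)            # 0-based contig offsets
  P <- unlist(plist, use.names = FALSE)   # 0-based reference positions
  d <- P - I
  o <- order(d, I)
  I <- I[o]; P <- P[o]; d <- d[o]
  newrun <- c(TRUE, d[-1L] != d[-length(d)] | I[-1L] != I[-length(I)] + 1L)
  first <- which(newrun)
  last <- c(first[-1L] - 1L, length(I))
  m <- data.frame(start = P[first], end = P[last],
                  offset_start = I[first], offset_end = I[last])
  m <- m[order(m$offset_start, m$start), , drop = FALSE]
  rownames(m) <- NULL
  m
}

empty_markers <- function() {
  data.frame(start = integer(0), end = integer(0),
             offset_start = integer(0), offset_end = integer(0))
}

#' Display a marker 1-based
#'
#' Markers are stored with 0-based reference k-mer indices; figures and
#' reports quote them 1-based as `R[start:end]`.
#'
#' @param start,end 0-based reference k-mer indices.
#' @return Character scalar like `"R[3:7]"`.
#' @export
format_marker <- function(start, end) {
  sprintf("R[%d:%d]", start + 1L, end + 1L)
}

#' Does marker `m_i` connect forward to marker `m_j` within distance `d`?
#'
#' Two markers connect when the jump between them could be explained by a
#' single variation event smaller than `d`: the reference gap
#' `m_j$start - m_i$end` must be strictly positive (forward progress on the
#' reference) and strictly below `d`, and the path distance between the
#' markers along the candidate donor walk (in k-mer steps) must also be
#' strictly below `d`. The relation is monotone in `d`.
#'
#' @param m_i,m_j Markers: lists or one-row data frames with `start` and
#'   `end` fields (0-based reference k-mer indices).
#' @param d Maximum gap in k-mer steps (`d > 0`).
#' @param path_distance Accumulated graph distance between `m_i`'s end and
#'   `m_j`'s start, in k-mer steps (`>= 0`).
#' @return `TRUE` or `FALSE`.
#' @examples
#' connects(list(start = 0, end = 0), list(start = 3, end = 4), d = 15,
#'          path_distance = 2)
#' @export
connects <- function(m_i, m_j, d, path_distance) {
  if (d <= 0) stop("d must be positive", call. = FALSE)
  if (path_distance < 0) stop("path_distance must be >= 0", call. = FALSE)
  gap <- m_j$start - m_i$end
  (gap > 0) && (gap < d) && (path_distance < d)
}
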