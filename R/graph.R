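#' Build the colored reference/donor de Bruijn graph
#'
#' Superimposes the de Bruijn graph of the reference (red edges, one per
#' reference k-mer, carrying its 0-based position) and of the donor spectrum
#' (blue edges, one per distinct donor k-mer with an integer multiplicity).
#' A red and a blue edge with the same k-mer are parallel: they connect the
#' same pair of (k-1)-mer nodes, and the blue edge is then called
#' reference-parallel.
#'
#' @param ref Reference nucleotide string.
#' @param donor_spectrum A `kmer_spectrum` of the donor (from reads or a
#'   donor sequence).
#' @param k K-mer length; must equal `donor_spectrum$k`.
#' @return A `colored_graph` object with components `k`, `ref` (the
#'   reference string), `ref_kmers` (red edges in position order), `blue`
#'   (data frame: `kmer`, `from`, `to`, `mult`) and `nodes`.
#' @export
build_reference_donor_graph <- function(ref, donor_spectrum, k) {
  k <- check_k(k)
  stopifnot(inherits(donor_spectrum, "kmer_spectrum"))
  if (donor_spectrum$k != k) {
    stop("k mismatch: spectrum has k = ", donor_spectrum$k,
         ", requested k = ", k, call. = FALSE)
  }
  check_dna(ref)
  if (nchar(ref) < k) stop("reference shorter than k", call. = FALSE)
  ref_kmers <- substring(ref, seq_len(nchar(ref) - k + 1L), seq(k, nchar(ref)))
  cnt <- spectrum_counts(donor_spectrum)
  blue <- data.frame(kmer = cnt$kmer,
                     from = substr(cnt$kmer, 1L, k - 1L),
                     to = substr(cnt$kmer, 2L, k),
                     mult = cnt$mult,
                     stringsAsFactors = FALSE)
  nodes <- unique(c(blue$from, blue$to,
                    substr(ref_kmers, 1L, k - 1L), substr(ref_kmers, 2L, k)))
  structure(list(k = k, ref = ref, ref_kmers = ref_kmers, blue = blue,
                 nodes = nodes),
            class = "colored_graph")
}

#' @export
print.colored_graph <- function(x, ...) {
  np <- sum(x$blue$kmer %in% x$ref_kmers)
  cat("colored_graph: k = ", x$k, ", ", length(x$ref_kmers),
      " red edges, ", nrow(x$blue), " distinct blue edges (",
      sum(x$blue$mult), " with multiplicity, ", np,
      " reference-parallel)\n", sep = "")
  invisible(x)
}

#' Enumerate all donor tours of a colored graph
#'
#' A donor tour is an Eulerian path of the blue subgraph: every blue edge is
#' traversed exactly as many times as its multiplicity. Enumeration is by
#' exhaustive backtracking and is intended for small instances (an oracle
#' for toy examples); the number of tours can grow factorially.
#'
#' Tours are returned in lexicographic order of their spelled sequences: at
#' every junction, outgoing k-mers are tried in lexicographic order (k-mers
#' leaving one node share their first k-1 bases, so this orders the next
#' spelled base).
#'
#' @param graph A `colored_graph`.
#' @param max_tours Stop after this many tours; the result then carries
#'   `attr(, "truncated") = TRUE`.
#' @return List of tours, each a character vector of k-mers (edge sequence).
#' @export
enumerate_donor_tours <- function(graph, max_tours = 1000L) {
  stopifnot(inherits(graph, "colored_graph"))
  blue <- graph$blue
  if (nrow(blue) == 0L) stop("graph has no blue edges", call. = FALSE)
  nodes <- unique(c(blue$from, blue$to))
  outd <- vapply(nodes, function(n) sum(blue$mult[blue$from == n]), 0)
  ind <- vapply(nodes, function(n) sum(blue$mult[blue$to == n]), 0)
  plus <- nodes[outd - ind == 1]
  minus <- nodes[ind - outd == 1]
  balanced <- all(abs(outd - ind) <= 1)
  if (!balanced || length(plus) > 1L || length(minus) > 1L ||
      length(plus) != length(minus)) {
    stop("no Eulerian path exists: blue degrees unbalanced", call. = FALSE)
  }
  if (!blue_connected(blue, nodes)) {
    stop("no Eulerian path exists: blue subgraph disconnected", call. = FALSE)
  }
  starts <- if (length(plus) == 1L) plus else sort(nodes)
  n_edges <- sum(blue$mult)
  out_at <- split(seq_len(nrow(blue)), factor(blue$from, levels = nodes))

  tours <- list()
  truncated <- FALSE
  remaining <- blue$mult
  path <- character(n_edges)
  recur <- function(node, depth) {
    if (truncated) return(invisible())
    if (depth > n_edges) {
      if (length(tours) >= max_tours) {
        truncated <<- TRUE
      } else {
        tours[[length(tours) + 1L]] <<- path
      }
      return(invisible())
    }
    cand <- out_at[[match(node, nodes)]]
    cand <- cand[remaining[cand] > 0L]
    if (length(cand) == 0L) return(invisible())
    for (i in cand[order(blue$kmer[cand])]) {
      remaining[i] <<- remaining[i] - 1L
      path[depth] <<- blue$kmer[i]
      recur(blue$to[i], depth + 1L)
      remaining[i] <<- remaining[i] + 1L
    }
    invisible()
  }
  for (s in starts) {
    recur(s, 1L)
    if (truncated) break
  }
  attr(tours, "truncated") <- truncated
  tours
}

## weak connectivity of the blue edge-induced subgraph
blue_connected <- function(blue, nodes) {
  if (length(nodes) <= 1L) return(TRUE)
  comp <- seq_along(nodes)
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  fi <- match(blue$from, nodes); ti <- match(blue$to, nodes)
  for (e in seq_along(fi)) {
    a <- find(fi[e]); b <- find(ti[e])
    if (a != b) comp[a] <- b
  }
  length(unique(vapply(seq_along(nodes), find, 0L))) == 1L
}

#' Condense a colored graph into a contig graph
#'
#' Collapses every maximal non-branching path of blue edges into a single
#' condensed edge whose contig is the spelled path. A node is interior
#' (non-branching) when it has exactly one distinct incoming and one
#' distinct outgoing blue k-mer with equal multiplicities; repeated k-mers
#' therefore condense into repeat contigs carrying a multiplicity. Red edges
#' are dropped after each contig's reference markers have been computed by
#' exact k-mer chaining against the reference.
#'
#' The multiset of all contig k-mers, each counted with its edge's
#' multiplicity, is exactly the donor spectrum used to build the graph.
#'
#' @param graph A `colored_graph`.
#' @return A `condensed_graph` object; see [condensed_edges()].
#' @export
condense <- function(graph) {
  stopifnot(inherits(graph, "colored_graph"))
  blue <- graph$blue
  if (nrow(blue) == 0L) stop("graph has no blue edges", call. = FALSE)
  k <- graph$k
  nodes <- unique(c(blue$from, blue$to))
  fi <- match(blue$from, nodes)
  ti <- match(blue$to, nodes)
  nn <- length(nodes)
  in_cnt <- tabulate(ti, nn)          # distinct incoming kmers
  out_cnt <- tabulate(fi, nn)
  in_edge <- integer(nn); in_edge[ti] <- seq_len(nrow(blue))   # valid when in_cnt==1
  out_edge <- integer(nn); out_edge[fi] <- seq_len(nrow(blue))
  simple <- in_cnt == 1L & out_cnt == 1L &
    blue$mult[pmax(in_edge, 1L)] == blue$mult[pmax(out_edge, 1L)]

  succ <- ifelse(simple[ti], out_edge[ti], NA_integer_)
  is_start <- !simple[fi]
  visited <- logical(nrow(blue))
  chains <- list()

  buf <- integer(nrow(blue))
  walk <- function(e0) {
    n <- 0L
    e <- e0
    repeat {
      n <- n + 1L
      buf[n] <<- e
      visited[e] <<- TRUE
      nxt <- succ[e]
      if (is.na(nxt) || visited[nxt]) break
      e <- nxt
    }
    buf[seq_len(n)]
  }
  for (e0 in which(is_start)) {
    if (!visited[e0]) chains[[length(chains) + 1L]] <- walk(e0)
  }
  ## leftover edges belong to cycles of interior nodes
  left <- which(!visited)
  while (length(left) > 0L) {
    e0 <- left[order(blue$kmer[left])][1L]
    chains[[length(chains) + 1L]] <- walk(e0)
    left <- which(!visited)
  }

  ref_index <- build_reference_index(graph$ref, k)
  edges <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    idx <- chains[[i]]
    contig <- if (length(idx) == 1L) blue$kmer[idx] else
      paste0(blue$kmer[idx[1L]],
             paste(substr(blue$kmer[idx[-1L]], k, k), collapse = ""))
    edges[[i]] <- list(id = i,
                       from = blue$from[idx[1L]],
                       to = blue$to[idx[length(idx)]],
                       contig = contig,
                       length = length(idx),
                       mult = blue$mult[idx[1L]],
                       local = compute_markers(contig, ref_index),
                       ahead = empty_copies(),
                       behind = empty_copies())
  }
  new_condensed_graph(k, edges, ref_index)
}

empty_copies <- function() {
  data.frame(start = integer(0), end = integer(0), dist = integer(0),
             host = integer(0))
}

new_condensed_graph <- function(k, edges, ref_index, log = list()) {
  structure(list(k = k, edges = edges, ref_index = ref_index, log = log),
            class = "condensed_graph")
}

#' @export
print.condensed_graph <- function(x, ...) {
  len <- vapply(x$edges, function(e) e$length, 0L)
  cat("condensed_graph: ", length(x$edges), " contig edges (k = ", x$k,
      "), lengths ", min(len), "..", max(len), " k-mers, ",
      sum(vapply(x$edges, function(e) nrow(e$local), 0L)),
      " local markers\n", sep = "")
  invisible(x)
}

#' Contig edge table of a condensed graph
#'
#' @param graph A `condensed_graph`.
#' @return Data frame with one row per condensed edge: `id`, `from`, `to`,
#'   `length` (k-mers), `mult`, `n_local`, `n_distant`, `contig`.
#' @export
condensed_edges <- function(graph) {
  stopifnot(inherits(graph, "condensed_graph"))
  do.call(rbind, lapply(graph$edges, function(e) {
    data.frame(id = e$id, from = e$from, to = e$to, length = e$length,
               mult = e$mult, n_local = nrow(e$local),
               n_distant = nrow(e$ahead), contig = e$contig,
               stringsAsFactors = FALSE)
  }))
}

## k-mer multiset spelled by all condensed edges (with multiplicity);
## compared against the donor spectrum by the conservation invariant.
graph_kmer_multiset <- function(graph) {
  stopifnot(inherits(graph, "condensed_graph"))
  contig_kmer_multiset(vapply(graph$edges, function(e) e$contig, ""),
                       graph$k,
                       vapply(graph$edges, function(e) e$mult, 0L))
}
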