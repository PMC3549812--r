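#' Engine configuration for tau-gap reassembly
#'
#' `tau` is the assumed upper bound on the size of any single variation
#' event, expressed in k-mer steps (for contig-scale gaps a k-mer step
#' corresponds to one base). It bounds how far markers are propagated, which
#' marker pairs count as connected, and which merges are considered forced.
#'
#' @param tau Positive integer, maximum variation-event size in k-mer steps.
#' @param max_iterations Safety bound on message-passing relaxations.
#' @param seed Unused by default; reserved for tie randomization.
#' @return An `engine_config` object.
#' @export
engine_config <- function(tau, max_iterations = 1e6, seed = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop("tau must be a positive number", call. = FALSE)
  }
  structure(list(tau = as.numeric(tau), max_iterations = max_iterations,
                 seed = seed),
            class = "engine_config")
}

## ---- adjacency -------------------------------------------------------------

## in/out neighbor positions (indices into graph$edges) for every edge
edge_adjacency <- function(graph) {
  from <- vapply(graph$edges, function(e) e$from, "")
  to <- vapply(graph$edges, function(e) e$to, "")
  n <- length(from)
  out_nb <- lapply(seq_len(n), function(i) which(from == to[i]))
  in_nb <- lapply(seq_len(n), function(i) which(to == from[i]))
  list(out = out_nb, `in` = in_nb)
}

## ---- propagation -----------------------------------------------------------

#' Propagate reference markers through the condensed graph
#'
#' Marker propagation gives every contig edge a view of the markers on
#' edges reachable within `tau` along directed paths. Messages flow
#' *upstream*: an edge receiving a marker adds its own length to the
#' accumulated distance, stores the pair if the distance is still below
#' `tau`, and forwards it to its incoming neighbors. The stored distance is
#' therefore the summed length of the edges strictly between the marker's
#' host and the receiver, including the receiver itself; the minimum over
#' paths is kept.
#'
#' A symmetric *downstream* pass records, on each edge, the markers of
#' upstream edges within `tau` ("behind" markers). These serve as
#' incoming-side witnesses during pruning, mirroring the outgoing-side role
#' of the propagated ("ahead") markers.
#'
#' @param graph A `condensed_graph` with local markers computed.
#' @param config An [engine_config()].
#' @return The graph with `ahead` (distant markers, fields `start`, `end`,
#'   `dist`, `host`) and `behind` tables filled on every edge.
#' @export
propagate <- function(graph, config) {
  stopifnot(inherits(graph, "condensed_graph"), inherits(config, "engine_config"))
  tau <- config$tau
  n <- length(graph$edges)
  adj <- edge_adjacency(graph)
  len <- vapply(graph$edges, function(e) e$length, 0L)
  ids <- vapply(graph$edges, function(e) e$id, 0L)
  ahead <- rep(list(list()), n)
  behind <- rep(list(list()), n)
  relax_budget <- config$max_iterations

  bounded_search <- function(src, nb) {
    ## min accumulated distance (receiver lengths summed) from src along nb
    d <- rep(Inf, n)
    queue <- src
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      du <- if (u == src) 0 else d[u]
      for (v in nb[[u]]) {
        nd <- du + len[v]
        if (nd < tau && nd < d[v]) {
          d[v] <- nd
          queue <- c(queue, v)
          relax_budget <<- relax_budget - 1
          if (relax_budget < 0) {
            stop("propagation exceeded max_iterations; ",
                 "check for zero-length cycles", call. = FALSE)
          }
        }
      }
    }
    d
  }

  for (src in seq_len(n)) {
    loc <- graph$edges[[src]]$local
    if (nrow(loc) == 0L) next
    up <- bounded_search(src, adj$`in`)
    for (v in which(is.finite(up))) {
      if (v == src) next
      ahead[[v]][[length(ahead[[v]]) + 1L]] <-
        list(start = loc$start, end = loc$end,
             dist = rep(up[v], nrow(loc)), host = rep(ids[src], nrow(loc)))
    }
    down <- bounded_search(src, adj$out)
    for (v in which(is.finite(down))) {
      if (v == src) next
      behind[[v]][[length(behind[[v]]) + 1L]] <-
        list(start = loc$start, end = loc$end,
             dist = rep(down[v], nrow(loc)), host = rep(ids[src], nrow(loc)))
    }
  }

  for (i in seq_len(n)) {
    graph$edges[[i]]$ahead <- bind_copies(ahead[[i]])
    graph$edges[[i]]$behind <- bind_copies(behind[[i]])
  }
  graph
}

bind_copies <- function(lst) {
  if (length(lst) == 0L) return(empty_copies())
  out <- data.frame(
    start = unlist(lapply(lst, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(lst, `[[`, "end"), use.names = FALSE),
    dist = unlist(lapply(lst, `[[`, "dist"), use.names = FALSE),
    host = unlist(lapply(lst, `[[`, "host"), use.names = FALSE))
  out <- out[order(out$host, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- pruning ---------------------------------------------------------------

#' Prune orphaned markers to a fixed point
#'
#' A marker is *connected* when it has a compatible partner on both sides: a
#' marker `m_in` on the incoming side and `m_out` on the outgoing side with
#' `m_in ->tau m ->tau m_out` (reference gap strictly between 0 and `tau`).
#' Orphaned markers are removed, removals re-trigger examination of
#' neighbors, and the phase ends at a fixed point. Because connectivity is
#' monotone in the marker sets, the fixed point is unique and independent of
#' sweep order.
#'
#' Side conditions (the package's own design, stated in the methods
#' vignette): edges with no incoming (outgoing) neighbor waive the incoming
#' (outgoing) requirement; a local marker with an intra-contig predecessor
#' (successor) in offset order is connected on that side, since
#' contig-internal order is observed sequence rather than an ordering
#' hypothesis; a propagated "ahead" copy needs no outgoing witness (its host
#' lies within `tau` downstream by construction) but is removed when its
#' host loses the marker; incoming-side witnesses are drawn from the
#' neighbors' local and "behind" markers, outgoing-side witnesses from
#' their local and "ahead" markers.
#'
#' Pruning can legitimately empty an edge's marker list (the published
#' branch-graph example does exactly that on its bottom branch); the `tau`
#' assumption itself is checked once, after the initial propagation, by
#' [reassemble()] — an edge with no marker in reach at that point means no
#' downstream marker lies within `tau` and raises an error of class
#' `reguide_tau_violation`.
#'
#' @param graph A `condensed_graph` after [propagate()].
#' @param config An [engine_config()].
#' @return The pruned graph; removals are appended to `graph$log`.
#' @export
prune <- function(graph, config) {
  stopifnot(inherits(graph, "condensed_graph"), inherits(config, "engine_config"))
  tau <- config$tau
  n <- length(graph$edges)
  adj <- edge_adjacency(graph)
  ids <- vapply(graph$edges, function(e) e$id, 0L)

  gap_ok <- function(starts, ends) {
    ## any pair with 0 < start - end < tau, vectorized over `starts`
    if (length(ends) == 0L || length(starts) == 0L) {
      return(logical(length(starts)))
    }
    g <- outer(starts, ends, "-")
    rowSums(g > 0 & g < tau) > 0L
  }
  gap_ok_rev <- function(ends, starts) {
    ## any pair with 0 < start - end < tau, vectorized over `ends`
    if (length(ends) == 0L || length(starts) == 0L) {
      return(logical(length(ends)))
    }
    g <- outer(starts, ends, "-")
    colSums(g > 0 & g < tau) > 0L
  }

  new_log <- list()
  repeat {
    changed <- FALSE
    ## witness pools from the current state
    loc <- lapply(graph$edges, function(e) e$local)
    ahd <- lapply(graph$edges, function(e) e$ahead)
    bhd <- lapply(graph$edges, function(e) e$behind)
    before_ends <- lapply(seq_len(n), function(i) {
      unlist(lapply(adj$`in`[[i]], function(u) c(loc[[u]]$end, bhd[[u]]$end)),
             use.names = FALSE)
    })
    after_starts <- lapply(seq_len(n), function(i) {
      unlist(lapply(adj$out[[i]], function(w) c(loc[[w]]$start, ahd[[w]]$start)),
             use.names = FALSE)
    })
    ## (host, start, end) keys of all surviving local markers: a propagated
    ## copy dies with the marker it mirrors
    live_keys <- unlist(lapply(seq_len(n), function(i) {
      if (nrow(loc[[i]]) == 0L) return(character(0))
      paste(ids[i], loc[[i]]$start, loc[[i]]$end)
    }), use.names = FALSE)

    for (i in seq_len(n)) {
      e <- graph$edges[[i]]
      no_in <- length(adj$`in`[[i]]) == 0L
      no_out <- length(adj$out[[i]]) == 0L

      if (nrow(e$local)) {
        m <- e$local
        intra_pred <- m$offset_start > min(m$offset_start)
        intra_succ <- m$offset_start < max(m$offset_start)
        pred <- no_in | intra_pred | gap_ok(m$start, before_ends[[i]])
        succ <- no_out | intra_succ | gap_ok_rev(m$end, after_starts[[i]])
        keep <- pred & succ
        if (!all(keep)) {
          changed <- TRUE
          drop <- m[!keep, , drop = FALSE]
          for (j in seq_len(nrow(drop))) {
            new_log[[length(new_log) + 1L]] <-
              list(event = "prune", edge = e$id,
                   marker = c(drop$start[j], drop$end[j]))
          }
          graph$edges[[i]]$local <- m[keep, , drop = FALSE]
        }
      }

      if (nrow(e$ahead)) {
        a <- e$ahead
        hosted <- paste(a$host, a$start, a$end) %in% live_keys
        pred <- no_in |
          gap_ok(a$start, c(graph$edges[[i]]$local$end, before_ends[[i]]))
        keep <- hosted & pred
        if (!all(keep)) {
          changed <- TRUE
          graph$edges[[i]]$ahead <- a[keep, , drop = FALSE]
        }
      }

      if (nrow(e$behind)) {
        b <- e$behind
        hosted <- paste(b$host, b$start, b$end) %in% live_keys
        succ <- no_out |
          gap_ok_rev(b$end, c(graph$edges[[i]]$local$start, after_starts[[i]]))
        keep <- hosted & succ
        if (!all(keep)) {
          changed <- TRUE
          graph$edges[[i]]$behind <- b[keep, , drop = FALSE]
        }
      }
    }
    if (!changed) break
  }
  graph$log <- c(graph$log, new_log)
  graph
}

## The stated assumption: after propagation every edge can see at least one
## marker within tau. Checked once, before any pruning.
check_tau_assumption <- function(graph, config) {
  for (e in graph$edges) {
    if (nrow(e$local) + nrow(e$ahead) == 0L) {
      stop(structure(class = c("reguide_tau_violation", "error", "condition"),
                     list(message = paste0(
                            "edge ", e$id, " has no reference marker within ",
                            "tau = ", config$tau, " of its contig: the tau ",
                            "assumption is violated; increase tau"),
                          call = NULL)))
    }
  }
  invisible(graph)
}

## ---- merging ---------------------------------------------------------------

## Marker-supported transition e -> f between adjacent edges. The branch
## taken after e must lead to markers within tau (f's own or ones visible
## beyond it); when e itself carries local markers, one of them must
## connect forward to a marker visible at f. An edge with no local markers
## imposes no ordering constraint of its own.
transition_supported <- function(graph, i, f, tau) {
  e <- graph$edges[[i]]
  w <- graph$edges[[f]]
  starts <- c(w$local$start, w$ahead$start)
  if (length(starts) == 0L) return(FALSE)
  ends <- e$local$end
  if (length(ends) == 0L) return(TRUE)
  g <- outer(starts, ends, "-")
  any(g > 0 & g < tau)
}

#' Find a forced merge
#'
#' Scans for an adjacent pair of contig edges `(e, f)` whose junction every
#' valid traversal must take: `f` is the only outgoing neighbor of `e`
#' supported by the markers (some marker on `e` connects within `tau` to a
#' marker visible on `f`), and the number of incoming edges forced to `f`
#' does not exceed `f`'s multiplicity. In the parallel-multiedge view a
#' repeat edge of multiplicity `r` is `r` identical edges, so a unique
#' predecessor may claim one copy; `e` itself must have multiplicity one.
#'
#' @param graph A `condensed_graph` after pruning.
#' @param config An [engine_config()].
#' @return Integer vector `c(e_id, f_id)` (lowest id pair), or `NULL`.
#' @export
find_forced_merge <- function(graph, config) {
  stopifnot(inherits(graph, "condensed_graph"), inherits(config, "engine_config"))
  tau <- config$tau
  n <- length(graph$edges)
  adj <- edge_adjacency(graph)
  ids <- vapply(graph$edges, function(e) e$id, 0L)
  mult <- vapply(graph$edges, function(e) e$mult, 0L)

  forced_to <- rep(NA_integer_, n)   # position of unique supported successor
  for (i in seq_len(n)) {
    out <- setdiff(adj$out[[i]], i)
    if (length(out) == 0L) next
    sup <- out[vapply(out, function(f) transition_supported(graph, i, f, tau),
                      TRUE)]
    if (length(sup) == 1L && mult[i] == 1L) forced_to[i] <- sup
  }
  cand <- which(!is.na(forced_to))
  if (length(cand) == 0L) return(NULL)
  ## more claimants than the target has copies is ambiguous
  tab <- table(forced_to[cand])
  room <- as.integer(names(tab))[tab <= mult[as.integer(names(tab))]]
  ok <- cand[forced_to[cand] %in% room]
  if (length(ok) == 0L) return(NULL)
  ord <- order(ids[ok], ids[forced_to[ok]])
  e <- ok[ord[1L]]
  c(ids[e], ids[forced_to[e]])
}

## All forced merges that are mutually independent in the current state:
## lowest-id first, skipping any pair that touches an edge already consumed
## as the source or target of an accepted pair in this round. Used by
## reassemble() to batch a round of merges between propagation passes; each
## accepted pair satisfies the same criterion find_forced_merge() applies.
find_forced_merges <- function(graph, config) {
  tau <- config$tau
  n <- length(graph$edges)
  adj <- edge_adjacency(graph)
  ids <- vapply(graph$edges, function(e) e$id, 0L)
  mult <- vapply(graph$edges, function(e) e$mult, 0L)
  forced_to <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    out <- setdiff(adj$out[[i]], i)
    if (length(out) == 0L) next
    sup <- out[vapply(out, function(f) transition_supported(graph, i, f, tau),
                      TRUE)]
    if (length(sup) == 1L && mult[i] == 1L) forced_to[i] <- sup
  }
  cand <- which(!is.na(forced_to))
  tab <- table(forced_to[cand])
  room <- as.integer(names(tab))[tab <= mult[as.integer(names(tab))]]
  cand <- cand[forced_to[cand] %in% room]
  cand <- cand[order(ids[cand])]
  used_src <- integer(0)   # edges consumed as a merge source this round
  used_tgt <- integer(0)
  pairs <- NULL
  for (e in cand) {
    f <- forced_to[e]
    if (e %in% used_tgt || f %in% used_src) next
    pairs <- rbind(pairs, c(ids[e], ids[f]))
    used_src <- c(used_src, e)
    used_tgt <- c(used_tgt, f)
  }
  pairs
}

#' Merge two adjacent contig edges
#'
#' Replaces `e` and one copy of `f` (with `f` following `e`) by a single
#' edge spelling their (k-1)-overlap concatenation. The merged edge keeps
#' `e`'s id; its length is the sum of the two lengths and its local markers
#' are recomputed from the concatenated contig. When `f` is a repeat edge
#' (multiplicity above one) the merge consumes one of its copies and leaves
#' the rest in place, so the k-mer multiset is conserved. Distant markers
#' must be recomputed by a fresh [propagate()] pass afterwards (as
#' [reassemble()] does).
#'
#' @param graph A `condensed_graph`.
#' @param e_id,f_id Edge ids with `f` an outgoing neighbor of `e` and `e`
#'   of multiplicity one.
#' @return The graph with the pair replaced.
#' @export
merge_edges <- function(graph, e_id, f_id) {
  stopifnot(inherits(graph, "condensed_graph"))
  ids <- vapply(graph$edges, function(e) e$id, 0L)
  i <- match(e_id, ids); j <- match(f_id, ids)
  if (is.na(i) || is.na(j) || i == j) stop("unknown edge ids", call. = FALSE)
  e <- graph$edges[[i]]; f <- graph$edges[[j]]
  if (e$to != f$from) {
    stop("edges ", e_id, " and ", f_id, " are not adjacent", call. = FALSE)
  }
  if (e$mult != 1L) {
    stop("cannot extend a repeat edge (multiplicity > 1)", call. = FALSE)
  }
  k <- graph$k
  contig <- paste0(e$contig, substr(f$contig, k, nchar(f$contig)))
  merged <- list(id = e$id, from = e$from, to = f$to, contig = contig,
                 length = e$length + f$length, mult = 1L,
                 local = compute_markers(contig, graph$ref_index),
                 ahead = empty_copies(), behind = empty_copies())
  graph$edges[[i]] <- merged
  if (f$mult > 1L) {
    graph$edges[[j]]$mult <- f$mult - 1L
  } else {
    graph$edges[[j]] <- NULL
  }
  graph$log[[length(graph$log) + 1L]] <-
    list(event = "merge", e = e_id, f = f_id, new = e$id,
         length = merged$length, f_copies_left = max(f$mult - 1L, 0L))
  graph
}

## ---- full engine -----------------------------------------------------------

#' Run the tau-gap reassembly engine to a fixed point
#'
#' Alternates marker propagation, orphan pruning and forced merging until no
#' further merge is found. Each round applies every forced merge that is
#' independent of the others in the current pruned state (a chain of forced
#' junctions is consumed pairwise, so long chains close in logarithmically
#' many rounds), then re-propagates and re-prunes before looking again.
#' Terminates after at most `sum(mult) - 1` merges. The decision log
#' (prunes and merges, in order) is kept in `$log` and is identical across
#' runs on identical input.
#'
#' @param graph A `condensed_graph` (from [condense()]).
#' @param config An [engine_config()].
#' @return The reassembled `condensed_graph`.
#' @export
reassemble <- function(graph, config) {
  stopifnot(inherits(graph, "condensed_graph"), inherits(config, "engine_config"))
  graph <- propagate(graph, config)
  check_tau_assumption(graph, config)
  graph <- prune(graph, config)
  merges <- 0L
  max_merges <- sum(vapply(graph$edges, function(e) e$mult, 0L))
  while (merges < max_merges) {
    fm <- find_forced_merges(graph, config)
    if (is.null(fm)) break
    for (r in seq_len(nrow(fm))) {
      graph <- merge_edges(graph, fm[r, 1L], fm[r, 2L])
      merges <- merges + 1L
    }
    graph <- propagate(graph, config)
    graph <- prune(graph, config)
  }
  graph
}

#' Extract final contigs
#'
#' @param graph A `condensed_graph`.
#' @return Character vector of contig sequences, longest first, ties broken
#'   lexicographically.
#' @export
extract_contigs <- function(graph) {
  stopifnot(inherits(graph, "condensed_graph"))
  contigs <- vapply(graph$edges, function(e) e$contig, "")
  contigs[order(-nchar(contigs), contigs)]
}
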