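# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: tours by permutation filtering, propagation by exhaustive
# path enumeration, marker support by tour + chain enumeration.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

## All Eulerian edge sequences of a k-mer multiset, by filtering the
## distinct permutations of the multiset for walk validity.
oracle_euler_tours <- function(kmers, k) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (x in unique(v)) {
      rest <- v[-match(x, v)]
      for (p in perms(rest)) out[[length(out) + 1L]] <- c(x, p)
    }
    out
  }
  valid <- function(p) {
    if (length(p) <= 1L) return(TRUE)
    all(substr(p[-length(p)], 2L, k) == substr(p[-1L], 1L, k - 1L))
  }
  Filter(valid, perms(kmers))
}

## Brute-force bounded reachability: for every edge, the set of downstream
## marker hosts with the minimum accumulated distance (receiver-side edge
## lengths summed, host excluded), kept when < tau. Path enumeration only;
## safe on DAGs.
oracle_ahead <- function(graph, tau) {
  n <- length(graph$edges)
  adj <- reguide:::edge_adjacency(graph)
  len <- vapply(graph$edges, function(e) e$length, 0L)
  ids <- vapply(graph$edges, function(e) e$id, 0L)
  best <- function(i) {
    res <- new.env()
    walk <- function(v, d, seen) {
      for (w in adj$out[[v]]) {
        if (w %in% seen) next
        key <- as.character(w)
        if (d < tau && nrow(graph$edges[[w]]$local) > 0L) {
          old <- mget(key, res, ifnotfound = Inf)[[1L]]
          if (d < old) assign(key, d, res)
        }
        walk(w, d + len[w], c(seen, w))
      }
    }
    walk(i, len[i], i)
    got <- as.list(res)
    if (length(got) == 0L) return(NULL)
    data.frame(host = ids[as.integer(names(got))],
               dist = unlist(got, use.names = FALSE))
  }
  lapply(seq_len(n), best)
}

## Condensed-level donor tours: all Eulerian edge-id sequences (each edge
## traversed `mult` times), by backtracking over positions.
oracle_condensed_tours <- function(graph) {
  n <- length(graph$edges)
  from <- vapply(graph$edges, function(e) e$from, "")
  to <- vapply(graph$edges, function(e) e$to, "")
  mult <- vapply(graph$edges, function(e) e$mult, 0L)
  total <- sum(mult)
  nodes <- unique(c(from, to))
  outd <- vapply(nodes, function(x) sum(mult[from == x]), 0)
  ind <- vapply(nodes, function(x) sum(mult[to == x]), 0)
  starts <- nodes[outd - ind == 1]
  if (length(starts) == 0L) starts <- nodes
  tours <- list()
  remaining <- mult
  path <- integer(total)
  recur <- function(node, depth) {
    if (depth > total) {
      tours[[length(tours) + 1L]] <<- path
      return(invisible())
    }
    for (i in which(from == node & remaining > 0L)) {
      remaining[i] <<- remaining[i] - 1L
      path[depth] <<- i
      recur(to[i], depth + 1L)
      remaining[i] <<- remaining[i] + 1L
    }
    invisible()
  }
  for (s in starts) recur(s, 1L)
  tours
}

## Marker support oracle: (edge position, marker row) pairs that can take
## part in a tau-gap-consistent local-marker chain along some donor tour.
## Interior chain members need a connecting partner on both sides; members
## on a graph-boundary edge (no in/out neighbors) are exempt on that side.
oracle_supported_markers <- function(graph, tau) {
  adj <- reguide:::edge_adjacency(graph)
  tours <- oracle_condensed_tours(graph)
  gap_ok <- function(a, b) { g <- b$start - a$end; g > 0 & g < tau }
  supported <- character(0)
  for (tr in tours) {
    locs <- lapply(graph$edges[tr], function(e) e$local)
    if (any(vapply(locs, nrow, 0L) == 0L)) next
    m <- length(tr)
    ## ok[i] rows of locs[[i]] reachable by a chain from the tour start
    fwd <- vector("list", m)
    fwd[[1L]] <- rep(TRUE, nrow(locs[[1L]]))
    valid <- TRUE
    for (i in seq_len(m - 1L)) {
      nxt <- rep(FALSE, nrow(locs[[i + 1L]]))
      for (a in which(fwd[[i]])) for (b in seq_len(nrow(locs[[i + 1L]]))) {
        if (gap_ok(locs[[i]][a, ], locs[[i + 1L]][b, ])) nxt[b] <- TRUE
      }
      if (!any(nxt)) { valid <- FALSE; break }
      fwd[[i + 1L]] <- nxt
    }
    if (!valid) next
    bwd <- vector("list", m)
    bwd[[m]] <- rep(TRUE, nrow(locs[[m]]))
    for (i in rev(seq_len(m - 1L))) {
      prv <- rep(FALSE, nrow(locs[[i]]))
      for (a in seq_len(nrow(locs[[i]]))) for (b in which(bwd[[i + 1L]])) {
        if (gap_ok(locs[[i]][a, ], locs[[i + 1L]][b, ])) prv[a] <- TRUE
      }
      bwd[[i]] <- prv
    }
    for (i in seq_len(m)) {
      pred_exempt <- length(adj$`in`[[tr[i]]]) == 0L
      succ_exempt <- length(adj$out[[tr[i]]]) == 0L
      has_pred <- if (i == 1L) rep(pred_exempt, nrow(locs[[i]])) else fwd[[i]]
      has_succ <- if (i == m) rep(succ_exempt, nrow(locs[[i]])) else bwd[[i]]
      for (r in which(has_pred & has_succ)) {
        supported <- union(supported, paste(tr[i], r, sep = ":"))
      }
    }
  }
  supported
}

## Direct construction of a condensed_graph for toy engine tests: edge
## table (id, from, to, length) plus a list of local marker data frames.
## Contigs are synthetic random strings of consistent length; they are not
## aligned unless a real reference index is supplied.
make_toy_graph <- function(edges, markers, k = 4L, ref = NULL, mult = NULL) {
  if (is.null(ref)) ref <- strrep("A", k + 1L)
  idx <- reguide::build_reference_index(ref, k)
  if (is.null(mult)) mult <- rep(1L, nrow(edges))
  elist <- lapply(seq_len(nrow(edges)), function(i) {
    m <- markers[[i]]
    if (is.null(m)) m <- reguide:::empty_markers()
    stopifnot(all(c("start", "end", "offset_start", "offset_end") %in% names(m)) ||
                nrow(m) == 0L)
    list(id = edges$id[i], from = edges$from[i], to = edges$to[i],
         contig = rand_dna(edges$length[i] + k - 1L),
         length = edges$length[i], mult = mult[i],
         local = m, ahead = reguide:::empty_copies(),
         behind = reguide:::empty_copies())
  })
  reguide:::new_condensed_graph(k, elist, idx)
}

mk_markers <- function(...) {
  ## mk_markers(c(start, end, offset_start, offset_end), ...)
  rows <- list(...)
  if (length(rows) == 0L) return(reguide:::empty_markers())
  do.call(rbind, lapply(rows, function(r)
    data.frame(start = r[1], end = r[2], offset_start = r[3],
               offset_end = r[4])))
}

marker_pairs <- function(graph) {
  ## flat (edge id, start, end) view of local markers, for comparisons
  do.call(rbind, lapply(graph$edges, function(e) {
    if (nrow(e$local) == 0L) return(NULL)
    data.frame(id = e$id, start = e$local$start, end = e$local$end)
  }))
}

## Naive all-pairs maximal-run scan for reference markers (quadratic).
oracle_markers <- function(contig, ref, k) {
  ck <- substring(contig, 1:(nchar(contig) - k + 1), k:nchar(contig))
  rk <- substring(ref, 1:(nchar(ref) - k + 1), k:nchar(ref))
  hit <- function(i, p) i >= 1 && p >= 1 && i <= length(ck) &&
    p <= length(rk) && ck[i] == rk[p]
  out <- NULL
  for (i in seq_along(ck)) for (p in seq_along(rk)) {
    if (!hit(i, p) || hit(i - 1L, p - 1L)) next
    j <- i; q <- p
    while (hit(j + 1L, q + 1L)) { j <- j + 1L; q <- q + 1L }
    out <- rbind(out, data.frame(start = p - 1L, end = q - 1L,
                                 offset_start = i - 1L, offset_end = j - 1L))
  }
  if (is.null(out)) return(reguide:::empty_markers())
  out <- out[order(out$offset_start, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Random small DAG condensed graphs for the propagation oracle.
random_dag_graph <- function(seed, max_edges = 20L) {
  set.seed(seed)
  n_nodes <- sample(4:9, 1L)
  pairs <- expand.grid(a = 1:n_nodes, b = 1:n_nodes)
  pairs <- pairs[pairs$a < pairs$b, ]
  n_edges <- min(max_edges, sample(3:12, 1L))
  pick <- pairs[sample(nrow(pairs), min(n_edges, nrow(pairs))), ]
  edges <- data.frame(id = seq_len(nrow(pick)),
                      from = paste0("n", pick$a), to = paste0("n", pick$b),
                      length = sample(1:10, nrow(pick), replace = TRUE))
  markers <- lapply(seq_len(nrow(edges)), function(i) {
    if (stats::runif(1) > 0.7) return(NULL)
    s <- sample(0:80, 1L); w <- sample(0:5, 1L)
    mk_markers(c(s, s + w, 0, w))
  })
  list(graph = make_toy_graph(edges, markers, k = 4L),
       tau = sample(5:45, 1L))
}
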