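cfg15 <- engine_config(tau = 15)

test_that("propagation reaches exactly the tau-bounded upstream edges", {
  g <- propagate(fig4_graph(), cfg15)
  ahead <- lapply(g$edges, function(e) e$ahead)
  ## the marker on (7,8) (id 5, ref run 40-49) lands one edge back on both
  ## branches at accumulated distance 10, and nowhere farther
  expect_identical(ahead[[3]]$host, 5L)   # (6,7)
  expect_identical(ahead[[3]]$dist, 10)
  expect_identical(ahead[[4]]$host, 5L)   # (5,7)
  expect_identical(ahead[[4]]$dist, 10)
  expect_false(5L %in% ahead[[2]]$host)   # (5,6): distance 20 is too far
  expect_false(5L %in% ahead[[1]]$host)
  ## the symmetric downstream pass mirrors it
  behind <- lapply(g$edges, function(e) e$behind)
  expect_identical(behind[[2]]$host, 1L)
  expect_true(nrow(behind[[5]]) == 0L)
})

test_that("tau = 1 with unit-length edges propagates nothing", {
  edges <- data.frame(id = 1:3, from = c("a", "b", "c"),
                      to = c("b", "c", "d"), length = 1L)
  markers <- list(mk_markers(c(0, 0, 0, 0)), mk_markers(c(2, 2, 0, 0)),
                  mk_markers(c(4, 4, 0, 0)))
  g <- propagate(make_toy_graph(edges, markers), engine_config(tau = 1))
  expect_true(all(vapply(g$edges, function(e) nrow(e$ahead), 0L) == 0L))
})

test_that("propagated sets equal the bounded path-enumeration oracle", {
  for (seed in 1:40) {
    case <- random_dag_graph(seed)
    g <- propagate(case$graph, engine_config(tau = case$tau))
    want <- oracle_ahead(g, case$tau)
    for (i in seq_along(g$edges)) {
      got <- unique(g$edges[[i]]$ahead[, c("host", "dist")])
      if (is.null(want[[i]])) {
        expect_identical(nrow(got), 0L)
      } else {
        w <- want[[i]][order(want[[i]]$host), ]
        got <- got[order(got$host), ]
        expect_equal(got$host, w$host, ignore_attr = TRUE)
        expect_equal(got$dist, w$dist, ignore_attr = TRUE)
      }
    }
  }
})

test_that("pruning keeps the connected branch copy and drops the orphan", {
  g <- prune(propagate(fig4_graph(), cfg15), cfg15)
  expect_identical(g$edges[[3]]$ahead$host, 5L)     # top branch survives
  expect_identical(nrow(g$edges[[4]]$ahead), 0L)    # bottom branch pruned
  ## all local markers survive
  expect_identical(vapply(g$edges, function(e) nrow(e$local), 0L),
                   c(1L, 1L, 0L, 0L, 1L))
})

test_that("a chain of consecutive markers is never pruned", {
  edges <- data.frame(id = 1:4, from = c("a", "b", "c", "d"),
                      to = c("b", "c", "d", "e"), length = 5L)
  markers <- list(mk_markers(c(0, 4, 0, 4)), mk_markers(c(5, 9, 0, 4)),
                  mk_markers(c(10, 14, 0, 4)), mk_markers(c(15, 19, 0, 4)))
  g0 <- propagate(make_toy_graph(edges, markers), engine_config(tau = 10))
  g <- prune(g0, engine_config(tau = 10))
  expect_identical(marker_pairs(g), marker_pairs(g0))
})

test_that("pruning never removes a tour-supported marker and is monotone", {
  processed <- 0L
  for (seed in 1:8) {
    case <- random_repeat_case(seed)
    cg <- condense(build_reference_donor_graph(
      case$ref, extract_kmers(case$donor, case$k), case$k))
    if (length(cg$edges) > 10L) next
    processed <- processed + 1L
    tau <- 40
    g0 <- propagate(cg, engine_config(tau))
    g1 <- prune(g0, engine_config(tau))
    count <- function(g) sum(vapply(g$edges, function(e) nrow(e$local), 0L))
    expect_lte(count(g1), count(g0))
    kept <- marker_pairs(g1)
    for (key in oracle_supported_markers(g0, tau)) {
      ij <- as.integer(strsplit(key, ":")[[1L]])
      m <- g0$edges[[ij[1L]]]$local[ij[2L], ]
      expect_true(any(kept$id == g0$edges[[ij[1L]]]$id &
                        kept$start == m$start & kept$end == m$end))
    }
  }
  expect_gt(processed, 0L)
})

test_that("the forced-merge cascade reproduces the worked example", {
  g <- fig5_fixture()
  g <- prune(propagate(g, cfg15), cfg15)
  ## only (2,3)->(3,5) is unambiguous: edge ids 2 and 4
  expect_identical(find_forced_merge(g, cfg15), c(2L, 4L))

  g <- merge_edges(g, 2L, 4L)
  merged <- g$edges[[which(vapply(g$edges, function(e) e$id, 0L) == 2L)]]
  expect_identical(merged$to, "n5")
  expect_setequal(merged$local$start, c(40, 56))

  g <- prune(propagate(g, cfg15), cfg15)
  ## losing the (3,5) branch orphans the second marker on edge 1 ...
  expect_identical(g$edges[[1L]]$local$start, 20L)
  ## ... which forces the remaining merge (1,3)+(3,4)
  expect_identical(find_forced_merge(g, cfg15), c(1L, 3L))
})

test_that("reassembly of the cascade stops at two merged contigs", {
  g <- reassemble(fig5_fixture(), cfg15)
  expect_length(g$edges, 2L)
  events <- vapply(g$log, `[[`, "", "event")
  expect_identical(events[events == "merge"], c("merge", "merge"))
  expect_true("prune" %in% events)
})

test_that("merging is conservative and validates adjacency", {
  g <- fig5_fixture()
  before <- reguide:::graph_kmer_multiset(g)
  expect_error(merge_edges(g, 1L, 2L), "not adjacent")
  g2 <- merge_edges(g, 2L, 4L)
  expect_identical(reguide:::graph_kmer_multiset(g2), before)
})

test_that("a unique predecessor may claim one copy of a repeat edge", {
  ## x -> R(mult 2), y -> R: both claim a copy; R absorbs them one at a time
  edges <- data.frame(id = 1:3, from = c("a", "b", "r"),
                      to = c("r", "r", "s"), length = 6L)
  markers <- list(mk_markers(c(0, 5, 0, 5)), mk_markers(c(20, 25, 0, 5)),
                  mk_markers(c(6, 11, 0, 5)))
  g <- make_toy_graph(edges, markers, mult = c(1L, 1L, 2L))
  cfg <- engine_config(tau = 10)
  g <- prune(propagate(g, cfg), cfg)
  fm <- find_forced_merge(g, cfg)
  expect_identical(fm, c(1L, 3L))
  g <- merge_edges(g, 1L, 3L)
  mult <- vapply(g$edges, function(e) e$mult, 0L)
  expect_identical(sort(mult), c(1L, 1L, 1L))
})

test_that("identity donors reassemble to a single reference contig", {
  set.seed(19)
  ref <- rand_dna(2000)
  for (tau in c(5, 1000)) {
    cg <- condense(build_reference_donor_graph(ref, extract_kmers(ref, 21), 21))
    rg <- reassemble(cg, engine_config(tau))
    expect_identical(extract_contigs(rg), ref)
  }
})

test_that("reassembly conserves k-mers, shrinks the graph, and replays", {
  set.seed(23)
  ref <- random_genome(60000, seed = 77)
  mut <- mutate_genome(ref, mutation_config(mean_event_size = 1500,
                                            sv_fraction = 0.15,
                                            snv_rate = 0.001, seed = 3))
  k <- 31L
  sp <- extract_kmers(mut$donor, k)
  cg <- condense(build_reference_donor_graph(ref, sp, k))
  cfg <- engine_config(tau = 2 * 2250)
  rg <- reassemble(cg, cfg)
  expect_identical(reguide:::graph_kmer_multiset(rg), sort(sp$kmers))
  expect_lte(length(rg$edges), length(cg$edges))
  expect_identical(accuracy(extract_contigs(rg), mut$donor), 1)
  ## determinism: identical input, identical log and contigs
  rg2 <- reassemble(cg, cfg)
  expect_identical(rg2$log, rg$log)
  expect_identical(extract_contigs(rg2), extract_contigs(rg))
})

test_that("the tau assumption violation is reported as such", {
  ## a markerless edge beyond tau of any marker
  edges <- data.frame(id = 1:2, from = c("a", "b"), to = c("b", "c"),
                      length = 50L)
  markers <- list(mk_markers(c(0, 5, 0, 5)), NULL)
  g <- make_toy_graph(edges, markers)
  expect_error(reassemble(g, engine_config(tau = 10)),
               class = "reguide_tau_violation")
})

test_that("contigs are extracted longest-first with lexicographic ties", {
  g <- reassemble(condense(fig1_graph()), engine_config(tau = 10))
  expect_identical(extract_contigs(g),
                   c("GAGGCAATGAG", "GAGCGTGGAG", "ATAGAG", "GAGTTC"))
})
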