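# Worked-example fixtures: the published toy reference/donor pair, the
# propagation/pruning four-edge branch graph, and the forced-merge cascade
# graph (built from real sequences so merging can recompute markers).

fig1_donor <- "ATAGAGGCAATGAGCGTGGAGTTC"
fig1_ref <- "ATAGCAATCGTGTTC"

fig2_ref <- "TTGTTATTCTAC"
fig2_contig <- "GTTATTCT"

fig1_graph <- function() {
  build_reference_donor_graph(fig1_ref, extract_kmers(fig1_donor, 4L), 4L)
}

## Branch graph for propagation/pruning: all edge lengths 10, tau = 15.
## Top path 5 -> 6 -> 7 carries a marker on (5,6); the bottom edge (5,7)
## skips it; (7,8) hosts the marker that gets propagated one edge back.
fig4_graph <- function() {
  edges <- data.frame(id = 1:5,
                      from = c("n4", "n5", "n6", "n5", "n7"),
                      to = c("n5", "n6", "n7", "n7", "n8"),
                      length = 10L)
  rownames(edges) <- c("e45", "e56", "e67", "e57", "e78")
  markers <- list(mk_markers(c(0, 9, 0, 9)),     # (4,5)
                  mk_markers(c(20, 29, 0, 9)),   # (5,6)
                  NULL,                          # (6,7)
                  NULL,                          # (5,7)
                  mk_markers(c(40, 49, 0, 9)))   # (7,8)
  make_toy_graph(edges, markers)
}

## Forced-merge cascade fixture, built from sequences at k = 8 so that
## merging recomputes markers from real contigs. Topology: A=(1,3) and
## B=(2,3) meet C=(3,4) and D=(3,5) at one junction. Reference-marker
## layout (k-mer indices): A holds a1=(20,24) and a2=(50,54), B holds
## (40,44), C holds (30,34), D holds (56,58). With tau = 15, A connects to
## both C (via a1) and D (via a2) while B connects only to D.
fig5_fixture <- function() {
  set.seed(4242)
  k <- 8L
  ref <- rand_dna(120L)
  sub_kmers <- function(s, e) substr(ref, s + 1L, e + k)   # k-mer run [s, e]
  ref_base <- function(i) substr(ref, i + 1L, i + 1L)      # 0-based base
  other <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  ## a run over k-mers [s, e] extends into a flank exactly when the flank
  ## base touching the block equals the adjacent reference base; forbid it
  guard_left <- function(flank, s) {
    n <- nchar(flank)
    if (substr(flank, n, n) == ref_base(s - 1L))
      substr(flank, n, n) <- other(ref_base(s - 1L))
    flank
  }
  guard_right <- function(flank, e) {
    if (substr(flank, 1L, 1L) == ref_base(e + k))
      substr(flank, 1L, 1L) <- other(ref_base(e + k))
    flank
  }
  junction <- rand_dna(k - 1L)
  contig_A <- paste0(guard_left(rand_dna(25L), 20L), sub_kmers(20L, 24L),
                     guard_left(guard_right(rand_dna(18L), 24L), 50L),
                     sub_kmers(50L, 54L),
                     guard_right(rand_dna(12L), 54L), junction)
  contig_B <- paste0(guard_left(rand_dna(30L), 40L), sub_kmers(40L, 44L),
                     guard_right(rand_dna(15L), 44L), junction)
  contig_C <- paste0(junction, guard_left(rand_dna(12L), 30L),
                     sub_kmers(30L, 34L), guard_right(rand_dna(25L), 34L))
  contig_D <- paste0(junction, guard_left(rand_dna(10L), 56L),
                     sub_kmers(56L, 58L), guard_right(rand_dna(28L), 58L))
  idx <- build_reference_index(ref, k)
  mk_edge <- function(id, from, to, contig) {
    list(id = id, from = from, to = to, contig = contig,
         length = nchar(contig) - k + 1L, mult = 1L,
         local = compute_markers(contig, idx),
         ahead = reguide:::empty_copies(), behind = reguide:::empty_copies())
  }
  g <- reguide:::new_condensed_graph(k, list(
    mk_edge(1L, "n1", "n3", contig_A),
    mk_edge(2L, "n2", "n3", contig_B),
    mk_edge(3L, "n3", "n4", contig_C),
    mk_edge(4L, "n3", "n5", contig_D)), idx)
  ## the random flanks must not create stray alignments or the designed
  ## marker layout is off; fail loudly if the seed ever stops ensuring this
  got <- marker_pairs(g)
  got <- got[order(got$id, got$start), ]
  stopifnot(nrow(got) == 5L,
            all(got$id == c(1L, 1L, 2L, 3L, 4L)),
            all(got$start == c(20, 50, 40, 30, 56)),
            all(got$end == c(24, 54, 44, 34, 58)))
  g
}

## Small random colored graphs with repeat structure, for tour-counting and
## pruning-soundness oracles: a donor assembled from reference blocks (one
## duplicated) joined by short novel linkers.
random_repeat_case <- function(seed, k = 8L) {
  set.seed(seed)
  ref <- rand_dna(160L)
  block <- function(a, b) substr(ref, a, b)
  dup <- block(10L, 35L)
  donor <- paste0(block(1L, 45L), rand_dna(8L), dup, rand_dna(8L),
                  block(60L, 110L), rand_dna(8L), block(120L, 160L))
  list(ref = ref, donor = donor, k = k)
}
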