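# reguide

Reference-guided genome reassembly from error-free short-read k-mer
spectra.

De novo assemblers leave a donor genome in hundreds of unordered contigs;
resequencing pipelines assume the donor differs from a reference only by
small variants. `reguide` targets the middle ground — a donor that is
largely similar to an available reference but carries kilobase-scale
structural variation (insertions, deletions, duplications, translocations).
It uses the reference not as a template to map against but as a *guide for
ordering*: assembly decisions are only committed where every tour of the
assembly graph agrees with them.

## The model

Let `S_R` and `S_D` be the k-mer spectra of reference and donor. Their de
Bruijn graphs are superimposed into a **colored reference/donor graph**:
nodes are (k−1)-mers, red edges are reference k-mers annotated with their
position `e.pos`, blue edges are donor k-mers with multiplicities. Any
donor reconstruction is an Eulerian tour of the blue subgraph; among them,
the most parsimonious tours touch reference positions in near-sequential
order.

Non-branching blue paths are condensed into contig edges. Each run of
contig k-mers whose reference positions increase by one per step is
summarized by a **reference marker** `m = (start, end)`; marker `m_i`
*connects to* `m_j` within distance `d` (`m_i →_d m_j`) when
`0 < m_j.start − m_i.end < d` and the graph path distance between them is
below `d`. Given τ, an assumed upper bound on the size of any single
variation event, the **τ-gap reassembly problem** asks for a donor tour in
which every novel stretch is shorter than τ and bounded by markers at most
τ apart.

The engine approximates this with three message-passing phases, iterated
to a fixed point:

1. **Propagation** — every edge receives the markers of edges reachable
   downstream within τ (distances accumulate edge lengths); a symmetric
   pass records markers reachable upstream.
2. **Pruning** — a marker survives only with a `→_τ` partner on both its
   incoming and outgoing side (graph boundaries and contig-internal
   predecessors exempt); orphaned markers are removed until nothing
   changes.
3. **Forced merging** — when the markers leave a contig exactly one
   eligible successor, the pair is spliced into one contig, markers are
   recomputed, and pruning runs again.

A structural-variant simulator (with an invertible event log) and an
idealized paired-end read generator make the whole method testable without
any external data, and an evaluation module reports contig count, N50, max
contig and accuracy against the simulated donor.

## Worked example

The 24 bp donor `ATAGAGGCAATGAGCGTGGAGTTC` against the 15 bp reference
`ATAGCAATCGTGTTC` at k = 4 (the smallest case in which the reference
resolves a genuine assembly ambiguity):

```r
library(reguide)
donor <- "ATAGAGGCAATGAGCGTGGAGTTC"
ref   <- "ATAGCAATCGTGTTC"

g <- build_reference_donor_graph(ref, extract_kmers(donor, 4), 4)
g
#> colored_graph: k = 4, 12 red edges, 21 distinct blue edges
#>   (21 with multiplicity, 5 reference-parallel)

cg <- condense(g)
condensed_edges(cg)[, c("id", "from", "to", "length", "n_local", "contig")]
#>   id from  to length n_local      contig
#> 1  1  ATA GAG      3       1      ATAGAG
#> 2  2  GAG GAG      8       1 GAGGCAATGAG
#> 3  3  GAG GAG      7       1  GAGCGTGGAG
#> 4  4  GAG TTC      3       1      GAGTTC
```

The blue graph has two Eulerian tours — the two loop contigs can be
traversed in either order — and `enumerate_donor_tours(g)` returns both.
Their reference touch orders are `0,3,4,8,11` (three plain insertions) and
`0,8,3,4,11` (insertions plus a translocation). With τ = 5 the marker gap
between loops forces the parsimonious order and the engine recovers the
donor exactly:

```r
extract_contigs(reassemble(cg, engine_config(tau = 5)))
#> [1] "ATAGAGGCAATGAGCGTGGAGTTC"
```

At genome scale, against a simulated donor (50 kb reference, 1 kb mean
event size, 15% SV content, 0.1% SNVs, k = 31, τ = 3 kb):

```r
ref50 <- random_genome(50000, seed = 42)
mut   <- mutate_genome(ref50, mutation_config(mean_event_size = 1000, seed = 7))
res   <- run_pipeline(run_config(reference = ref50, donor = mut$donor,
                                 k = 31, tau = 3000, seed = 7))
res$comparison
#> naive-debruijn-baseline vs reguide
#>      metric baseline method delta
#>   n_contigs       49     31   -18
#>         n50     9337   5341 -3996
#>  max_contig    17164  17277   113
#>    total_bp    49620  53951
#>    accuracy        1      1     0
```

The contig count drops by a third with no misassembly. (N50 can dip even
as contigs merge: resolving a repeat emits its sequence once per copy, so
the total assembly length — the denominator of N50 — grows. Whether N50
gains or loses from this depends on where the duplications fall in a
given simulation.) The baseline row is the package's own pre-reassembly
condensed graph, i.e. what a naive de Bruijn assembly of the same
spectrum would report.

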