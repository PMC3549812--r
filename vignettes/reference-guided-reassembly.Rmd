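---
title: "Reference-guided reassembly: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-guided reassembly: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reguide)
```

`reguide` reassembles a donor genome from error-free short-read k-mer
spectra, using a reference genome of the same species as an ordering
guide. This vignette is the package's account of the underlying model,
the parameters that matter, and the design decisions taken where the
method leaves room — including what the bundled simulator does and does
not emulate.

## The colored graph and the τ-gap problem

Both genomes are reduced to k-mer spectra and superimposed in one de
Bruijn graph over (k−1)-mer nodes: *red* edges are reference k-mers,
each annotated with its 0-based position; *blue* edges are donor k-mers,
with repeated k-mers collapsed into one edge carrying an integer
multiplicity (equivalently, parallel multiedges). Any donor
reconstruction is an Eulerian tour of the blue subgraph. Maximal
non-branching blue paths are condensed into contig edges whose length is
counted in k-mer steps; a node is interior when exactly one distinct
k-mer enters and one leaves it with equal multiplicities, so a clean
repeat condenses into a single contig with multiplicity.

Runs of contig k-mers whose reference positions increase by one per step
become *reference markers* `(start, end)`. Marker `m_i` connects to
`m_j` within distance `d` when

* `0 < m_j.start − m_i.end < d` (forward progress on the reference,
  strictly within the bound), and
* the path distance between them in the graph, in k-mer steps, is also
  strictly below `d`.

Both inequalities are strict, matching the propagation rule's `d < τ`
test; and the reference gap must be positive — a tour that revisits the
same reference interval is treated as a repeat, not a continuation.
Given τ, an upper bound on the size of any single variation event, a
valid reassembly is a donor tour in which every novel stretch is bounded
by τ-connected markers.

Positions are stored 0-based throughout; reports and figures display
markers 1-based as `R[start+1:end+1]`, which matches the published
convention for the worked examples.

## Parameters

* **k** (bases). The toy worked examples use k = 4; genome-scale runs
  default to k = 99, just below the 100 bp read length, so each read
  mate contributes `l − k + 1 = 2` k-mers and chance (k−1)-mer
  collisions are vanishingly rare. k must stay below the read length and
  above log₄ of the genome size.
* **τ** (k-mer steps; ≈ bases at contig scale). The method's central
  assumption: no single variation event is larger than τ. It bounds
  propagation range, marker connectivity, and merge eligibility. Too
  small a τ triggers a diagnosed violation (see below); too large a τ
  leaves ambiguity unresolved but never fabricates order — merges
  require a *unique* compatible successor, so over-estimating τ is the
  conservative direction. The pipeline default in the end-to-end runs is
  twice the maximum simulated event size.
* **Coverage normalization.** With error-free pairs sampled from every
  donor position, each genomic copy of a k-mer is observed
  `2(l − k + 1)` times (both mates). Raw read k-mer counts are divided
  by this per-copy coverage and rounded, never below one. Within about
  an insert size of the donor ends coverage dips, so a multiplicity ≥ 2
  k-mer there could be undercounted; at the simulated scales this
  window is ~0.1% of the genome and the affected k-mers are almost
  surely unique. When the per-copy coverage is unknown the median raw
  count is used instead, which is robust while repeats are a minority
  of the genome.

## The message-passing engine

**Propagation.** Each edge's local markers are flooded *upstream*: a
receiving edge adds its own length to the accumulated distance, keeps
the pair if the distance is still below τ, and forwards it. The stored
distance is therefore the summed length of the edges strictly between
the marker's host and the receiver, including the receiver itself, and
the minimum over paths is kept. The engine runs a second, symmetric
*downstream* pass ("behind" markers). This is a deliberate extension:
the two-sided connectivity check below needs τ-bounded witnesses on the
incoming side too, and a one-directional pass cannot supply them when
the relevant partner is more than one edge away. After propagation,
every edge must see at least one marker (its own or a propagated copy);
an edge that does not is beyond τ of any anchor, the τ assumption is
violated, and the engine stops with an error of class
`reguide_tau_violation` that recommends increasing τ.

**Pruning.** A marker is kept only with a `→_τ` partner on both sides:
some marker on an incoming neighbor (its locals or its behind-copies)
connecting into it, and some marker on an outgoing neighbor (locals or
ahead-copies) that it connects to. Three exemptions define the package's
semantics at the boundaries the general rule does not cover:

* *Graph boundaries.* Edges with no incoming (outgoing) neighbor waive
  the incoming (outgoing) requirement — the donor tour has to start and
  end somewhere.
* *Contig-internal order.* A local marker with another local marker
  before (after) it in offset order is connected on that side
  unconditionally. A contig is observed sequence, not an ordering
  hypothesis: a translocation captured *inside* one contig produces a
  backward reference jump between adjacent markers, and without this
  exemption the markers downstream of the junction would cascade-prune
  and falsely report a τ violation. The cost is that repeat-induced
  spurious markers buried in contig interiors are retained; they do not
  participate in junction decisions, which only consult
  connectivity across edges.
* *Propagated copies.* An ahead-copy needs no outgoing witness — its
  host lies within τ downstream by construction — but it dies with its
  host's marker and still needs an incoming witness. This reproduces
  the published branch example exactly: the copy on the connected branch
  survives, the copy on the orphaned branch is removed, and the removal
  legitimately empties that edge's marker list.

All keep-conditions are monotone in the marker sets, so the fixed point
is unique and independent of sweep order — this, not luck, is why runs
are deterministic.

**Forced merging.** A transition `e → f` between adjacent edges is
*supported* when some local marker of `e` connects within τ to a marker
visible on `f` (its locals or ahead-copies); an edge with no local
markers imposes no constraint of its own, so any marker-bearing
successor is a candidate for it. A merge is *forced* when `f` is the
only supported successor of `e` and no more claimants are forced to `f`
than `f` has copies: in the parallel-multiedge reading, a repeat edge of
multiplicity r is r identical edges, and a unique predecessor may claim
one copy (the merge decrements r and leaves the rest in place, so the
k-mer multiset is conserved — this is what lets the engine walk into
SNV-divergent repeat copies without ever fusing two variants, which
would be chimeric). Each round applies, in lowest edge-id order, every
forced merge that is independent of the others in the current pruned
state — pairs sharing an edge are deferred to the next round, so a chain
of forced junctions closes pairwise in logarithmically many rounds.
Every merge recomputes the merged contig's markers from sequence, and
every round is followed by a full propagation and pruning pass before
merges are searched again; strictly one merge per round would make the
same individually-justified splices at quadratic cost, which matters
once graphs reach a few hundred edges. Recomputing distant markers
globally rather than patching a τ-neighborhood is the same kind of
simplicity choice: at the contig-graph sizes this package targets a
full pass is cheap, and it removes a class of staleness bugs.

The engine stops when no forced merge remains; residual ambiguity
(e.g. symmetric branches after a translocation) is left as separate
contigs rather than resolved arbitrarily, and the prune/merge decision
log is returned for audit. No final global tour is chosen: the output
surface is the contig set.

## The simulator

`mutate_genome()` draws non-overlapping SV events — novel-sequence
insertions, deletions, dispersed duplications, translocations, by
default in even proportions — with sizes uniform on
`[0.5, 1.5] × mean_event_size`, until their total size reaches the
target fraction (default 15%) of the projected donor; SNVs (default
0.1%) are applied afterwards to every donor base outside novel
insertions, so the event log stays invertible (`apply_events()` replays
it exactly). Duplication copies are dispersed to a random distant locus
by default because dispersal is what creates the ordering ambiguity the
method targets; a tandem mode exists behind a flag. Translocations are
never inverted — inversions are not among the modelled event types, and
with single-strand k-mer matching an inverted segment would simply
surface as novel sequence. `simulate_reads()` emits one error-free
100 bp pair per donor position at a fixed 500 bp insert.

What passing tests on this simulator do *not* show: behavior under
sequencing error, non-uniform coverage, reverse-strand reads, ambiguity
codes, or biological repeat families (the uniform-random reference has
no short tandem repeats or transposable elements, so at k = 99 the only
repeats are the simulated duplications). Read errors in particular
would break both exact k-mer matching and the exact multiset arithmetic;
the intended upstream remedy is error correction before assembly, not
robustness inside the engine.

## Numerical and testing choices

Determinism is treated as a contract: identical configuration yields
byte-identical outputs, tie-breaks are lexicographic (tour enumeration
by spelled sequence, contig output longest-first then lexicographic,
merges by lowest id), and all randomness flows from explicit seeds.
Degenerate inputs error early with named offsets (non-ACGT characters,
sequences shorter than k, k above the read length).

The test suite checks the engine against independent brute-force
oracles at small scale — tour counts against permutation filtering,
propagation against exhaustive path enumeration on random DAGs, pruning
against marker chains over exhaustively enumerated tours — and runs the
full pipeline end-to-end on simulated genomes of 50–60 kb (k = 31)
plus one 500 kb run at the default conditions (k = 99, mean event 5 kb,
τ = 15 kb). These sizes were chosen as the smallest at which every
structural phenomenon of the larger simulations (SNV bubbles inside
duplications, dispersed repeats, τ violations) still occurs.

## Known limitations

* Single-strand model: no reverse complements, no canonical k-mers.
* Exact matching only; alignment with mismatches or gaps is out of
  scope (valid in the error-free regime, wrong outside it).
* "Misassembled" is operationalized as "not an exact substring of the
  donor", which is only meaningful for error-free data.
* τ must be supplied; the engine diagnoses too-small values but cannot
  estimate τ from data.
* Marker-blind repeat interiors: spurious local markers inside long
  contigs survive pruning (see the contig-internal exemption above) and
  can leave extra, harmless ambiguity that suppresses merges near
  repeats.
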