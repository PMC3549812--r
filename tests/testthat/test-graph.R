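test_that("the colored graph pairs donor k-mers with reference positions", {
  g <- fig1_graph()
  shared <- intersect(g$blue$kmer, g$ref_kmers)
  expect_length(shared, 5L)
  expect_setequal(match(shared, g$ref_kmers) - 1L, c(0, 3, 4, 8, 11))

  ident <- build_reference_donor_graph("ACGTA", extract_kmers("ACGTA", 3), 3)
  expect_true(all(ident$blue$kmer %in% ident$ref_kmers))

  disjoint <- build_reference_donor_graph("AAAA", extract_kmers("CCCC", 3), 3)
  expect_false(any(disjoint$blue$kmer %in% disjoint$ref_kmers))

  expect_error(build_reference_donor_graph("ACGTA", extract_kmers("ACGTA", 3), 4),
               "k mismatch")
})

test_that("donor tour enumeration finds all Eulerian paths in spelled order", {
  g <- fig1_graph()
  tours <- enumerate_donor_tours(g)
  expect_length(tours, 2L)
  expect_false(attr(tours, "truncated"))
  spelled <- vapply(tours, spell, "", k = 4L)
  expect_true(fig1_donor %in% spelled)
  expect_identical(spelled, sort(spelled))   # lexicographic tie-break

  lin <- build_reference_donor_graph("AAAA", extract_kmers("ACGTCA", 3), 3)
  expect_length(enumerate_donor_tours(lin), 1L)

  trunc <- enumerate_donor_tours(g, max_tours = 1L)
  expect_length(trunc, 1L)
  expect_true(attr(trunc, "truncated"))
})

test_that("tours traverse every blue edge with its multiplicity", {
  for (seed in 1:5) {
    case <- random_repeat_case(seed)
    g <- build_reference_donor_graph(case$ref, extract_kmers(case$donor, case$k),
                                     case$k)
    tours <- enumerate_donor_tours(g, max_tours = 200L)
    expect_gt(length(tours), 0L)
    blue_multiset <- sort(rep(g$blue$kmer, times = g$blue$mult))
    for (t in tours) {
      expect_identical(sort(t), blue_multiset)
      expect_identical(sort(extract_kmers(spell(t, case$k), case$k)$kmers),
                       blue_multiset)
    }
  }
})

test_that("disconnected or unbalanced blue graphs are rejected", {
  two <- kmer_spectrum(c("AAAC", "GGGT"), 4)
  g <- build_reference_donor_graph("AAAC", two, 4)
  expect_error(enumerate_donor_tours(g), "no Eulerian path")

  unbal <- kmer_spectrum(c("ACGT", "ACGT"), 4)   # one edge twice, open walk
  g2 <- build_reference_donor_graph("ACGT", unbal, 4)
  expect_error(enumerate_donor_tours(g2), "no Eulerian path")
})

test_that("tour counts agree with permutation brute force on small graphs", {
  cases <- list(c("ATAGAGATAC", 3),    # repeat-induced hub
                c("ACGTACGT", 3),
                c("AACCAAGGAA", 4))
  for (case in cases) {
    s <- case[[1]]; k <- as.integer(case[[2]])
    sp <- extract_kmers(s, k)
    g <- build_reference_donor_graph(s, sp, k)
    got <- enumerate_donor_tours(g, max_tours = 10000L)
    want <- oracle_euler_tours(sp$kmers, k)
    expect_identical(length(got), length(want))
    expect_setequal(vapply(got, paste, "", collapse = " "),
                    vapply(want, paste, "", collapse = " "))
  }
})

test_that("condensation collapses exactly the non-branching donor paths", {
  cg <- condense(fig1_graph())
  ed <- condensed_edges(cg)
  expect_identical(nrow(ed), 4L)
  ## the only branch point: in- and out-degree 3 at one junction
  expect_identical(sum(ed$from == "GAG"), 3L)
  expect_identical(sum(ed$to == "GAG"), 3L)
  expect_setequal(ed$contig,
                  c("ATAGAG", "GAGGCAATGAG", "GAGCGTGGAG", "GAGTTC"))
  expect_identical(ed$length, nchar(ed$contig) - 4L + 1L)

  lin <- condense(build_reference_donor_graph("AAAA",
                                              extract_kmers("ACGTCA", 3), 3))
  expect_length(lin$edges, 1L)
  expect_identical(lin$edges[[1L]]$contig, "ACGTCA")
})

test_that("condensed contigs conserve the donor k-mer multiset", {
  for (seed in 1:8) {
    case <- random_repeat_case(seed)
    sp <- extract_kmers(case$donor, case$k)
    cg <- condense(build_reference_donor_graph(case$ref, sp, case$k))
    expect_identical(reguide:::graph_kmer_multiset(cg), sort(sp$kmers))
  }
})

test_that("a repeat-free donor condenses to one edge and one tour", {
  set.seed(11)
  s <- rand_dna(300)
  k <- 12L
  expect_false(any(duplicated(extract_kmers(s, k - 1L)$kmers)))
  g <- build_reference_donor_graph(s, extract_kmers(s, k), k)
  expect_length(condense(g)$edges, 1L)
  expect_length(enumerate_donor_tours(g), 1L)
})

test_that("duplicated donor segments become multiplicity-2 edges", {
  case <- random_repeat_case(3)
  sp <- extract_kmers(case$donor, case$k)
  cg <- condense(build_reference_donor_graph(case$ref, sp, case$k))
  mult <- vapply(cg$edges, function(e) e$mult, 0L)
  expect_true(any(mult == 2L))
  len <- vapply(cg$edges, function(e) e$length, 0L)
  expect_identical(sum(len * mult), length(sp$kmers))
})
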