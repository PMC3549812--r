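test_that("single-event arithmetic works through the event log", {
  set.seed(1)
  ref <- rand_dna(3000)
  del <- data.frame(type = "deletion", ref_pos = 1000L, size = 200L,
                    payload = NA_character_, dest = NA_integer_)
  expect_identical(nchar(apply_events(ref, del)), 2800L)
  expect_identical(apply_events(ref, del),
                   paste0(substr(ref, 1, 1000), substr(ref, 1201, 3000)))

  ins <- data.frame(type = "insertion", ref_pos = 500L, size = 5L,
                    payload = "TTTTT", dest = NA_integer_)
  expect_identical(apply_events(ref, ins),
                   paste0(substr(ref, 1, 500), "TTTTT", substr(ref, 501, 3000)))

  dup <- data.frame(type = "duplication", ref_pos = 100L, size = 50L,
                    payload = NA_character_, dest = 2000L)
  donor <- apply_events(ref, dup)
  expect_identical(nchar(donor), 3050L)
  expect_identical(substr(donor, 2001, 2050), substr(ref, 101, 150))

  tra <- data.frame(type = "translocation", ref_pos = 100L, size = 50L,
                    payload = NA_character_, dest = 2000L)
  donor <- apply_events(ref, tra)
  expect_identical(nchar(donor), 3000L)
  ## the excision shifts the destination left by the block size
  expect_identical(substr(donor, 1951, 2000), substr(ref, 101, 150))
  expect_identical(substr(donor, 51, 150),
                   paste0(substr(ref, 51, 100), substr(ref, 151, 200)))
})

test_that("drawn events hit the configured genome fraction", {
  ref <- random_genome(500000, seed = 303)
  mut <- mutate_genome(ref, mutation_config(mean_event_size = 5000,
                                            sv_fraction = 0.15,
                                            snv_rate = 0.001, seed = 7))
  sv <- mut$events[mut$events$type != "snv", ]
  frac <- sum(sv$size) / nchar(mut$donor)
  expect_gte(frac, 0.12)
  expect_lte(frac, 0.18)
  ## sizes are uniform on [0.5, 1.5] x mean
  expect_true(all(sv$size >= 2500 & sv$size <= 7500))
  expect_setequal(unique(sv$type) %in%
                    c("insertion", "deletion", "duplication", "translocation"),
                  TRUE)
})

test_that("SNV counts match binomial expectation and dispersion", {
  ref <- random_genome(500000, seed = 303)
  mut <- mutate_genome(ref, mutation_config(mean_event_size = 5000,
                                            sv_fraction = 0.15,
                                            snv_rate = 0.001, seed = 7))
  snv <- mut$events[mut$events$type == "snv", ]
  ins <- mut$events[mut$events$type == "insertion", ]
  eligible <- nchar(mut$donor) - sum(ins$size)
  expected <- eligible * 0.001
  expect_lt(abs(nrow(snv) - expected), 3 * sqrt(expected) + 1)
  ## SNVs never fall in novel inserted sequence, and substitute a new base
  donor_wo_snv <- apply_events(ref, mut$events[mut$events$type != "snv", ])
  old <- substring(donor_wo_snv, snv$donor_pos + 1, snv$donor_pos + 1)
  expect_true(all(old != snv$payload))
})

test_that("the simulation is reproducible and the log invertible", {
  ref <- random_genome(100000, seed = 8)
  cfg <- mutation_config(mean_event_size = 2000, seed = 99)
  a <- mutate_genome(ref, cfg)
  b <- mutate_genome(ref, cfg)
  expect_identical(a$donor, b$donor)
  expect_identical(a$events, b$events)
  expect_identical(apply_events(ref, a$events), a$donor)

  c <- mutate_genome(ref, mutation_config(mean_event_size = 2000, seed = 100))
  expect_false(identical(a$donor, c$donor))
})

test_that("read pairs tile the donor with the fixed insert geometry", {
  set.seed(2)
  donor <- rand_dna(500)
  pairs <- simulate_reads(donor)
  expect_length(pairs$read1, 1L)
  expect_identical(pairs$read1, substr(donor, 1, 100))
  expect_identical(pairs$read2, substr(donor, 401, 500))

  donor <- rand_dna(1234)
  pairs <- simulate_reads(donor)
  expect_length(pairs$read1, 1234L - 500L + 1L)
  i <- 101L   # 0-based start 100
  expect_identical(pairs$read2[i],
                   substr(donor, 100 + 400 + 1, 100 + 500))
  ## every donor base is covered by some read
  cov <- logical(1234)
  for (s in c(pairs$donor_start, pairs$donor_start + 400L)) {
    cov[(s + 1):(s + 100)] <- TRUE
  }
  expect_true(all(cov))

  expect_error(simulate_reads(rand_dna(499)), "shorter than the insert")
})

test_that("read k-mer counts follow l - k + 1 per mate", {
  set.seed(3)
  pairs <- simulate_reads(rand_dna(500))
  expect_length(reads_to_spectrum(pairs, 100)$kmers, 2L)
  expect_length(reads_to_spectrum(pairs, 99)$kmers, 4L)
  expect_error(reads_to_spectrum(pairs, 101), "exceeds the read length")
})

test_that("coverage normalization recovers the donor spectrum", {
  set.seed(4)
  donor <- rand_dna(2000)
  k <- 21L
  pairs <- simulate_reads(donor)
  raw <- reads_to_spectrum(pairs, k)
  norm <- normalize_coverage(raw, per_copy = 2L * (100L - k + 1L))
  expect_identical(sort(norm$kmers), sort(extract_kmers(donor, k)$kmers))
  ## the median heuristic agrees when repeats are a minority
  norm2 <- normalize_coverage(raw)
  expect_identical(sort(norm2$kmers), sort(norm$kmers))
})
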