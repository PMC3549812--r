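#' Generate a uniform-random reference genome
#'
#' Bases are drawn i.i.d. uniformly from A, C, G, T. Used for fully
#' self-contained end-to-end simulations.
#'
#' @param length Genome length in bp.
#' @param seed Optional integer seed (`set.seed` is called when supplied).
#' @return A nucleotide string.
#' @export
random_genome <- function(length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Configuration of the structural-variant simulator
#'
#' Defaults mirror the simulation conditions the method targets: mean event
#' size 5 kb (study range 5-50 kb), events totalling roughly 15% of the
#' donor, SNVs at 0.1%, an even mix of the four event types. Event sizes
#' are drawn uniformly on `[0.5, 1.5] * mean_event_size`.
#'
#' @param mean_event_size Mean SV event size in bp.
#' @param sv_fraction Target fraction of the donor made up of SV events.
#' @param snv_rate Per-base substitution probability, applied after the SVs
#'   to every donor base that is not novel inserted sequence.
#' @param event_mix Named proportions over insertion, deletion, duplication,
#'   translocation; must sum to 1.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @param tandem_duplications If `TRUE` duplication copies are placed
#'   immediately after their source; by default they are dispersed to a
#'   random distant locus, which is what creates ordering ambiguity.
#' @return A `mutation_config` object.
#' @export
mutation_config <- function(mean_event_size = 5000, sv_fraction = 0.15,
                            snv_rate = 0.001,
                            event_mix = c(insertion = 0.25, deletion = 0.25,
                                          duplication = 0.25,
                                          translocation = 0.25),
                            seed = 1L, tandem_duplications = FALSE) {
  stopifnot(sv_fraction > 0, sv_fraction < 1, snv_rate >= 0, snv_rate < 1,
            mean_event_size >= 2)
  types <- c("insertion", "deletion", "duplication", "translocation")
  if (!setequal(names(event_mix), types)) {
    stop("event_mix must be named with the four event types", call. = FALSE)
  }
  if (abs(sum(event_mix) - 1) > 1e-8) {
    stop("event_mix must sum to 1", call. = FALSE)
  }
  structure(list(mean_event_size = mean_event_size, sv_fraction = sv_fraction,
                 snv_rate = snv_rate, event_mix = event_mix[types],
                 seed = as.integer(seed),
                 tandem_duplications = isTRUE(tandem_duplications)),
            class = "mutation_config")
}

#' Mutate a reference into a simulated donor genome
#'
#' Draws non-overlapping SV events (insertions of novel sequence, deletions,
#' dispersed duplications, translocations) with sizes uniform on
#' `[0.5, 1.5]` times the configured mean, until their total size reaches
#' the target fraction of the (projected) donor length, then applies SNVs.
#' The returned event log is sufficient to reconstruct the donor exactly
#' with [apply_events()], and the whole draw is reproducible from
#' `config$seed`.
#'
#' @param ref Reference nucleotide string.
#' @param config A [mutation_config()].
#' @return List with `donor` (nucleotide string) and `events` (data frame
#'   with columns `type`, `ref_pos`, `size`, `payload`, `dest`,
#'   `donor_pos`; positions 0-based, anchors are "before this reference
#'   index").
#' @export
mutate_genome <- function(ref, config) {
  stopifnot(inherits(config, "mutation_config"))
  check_dna(ref)
  L <- nchar(ref)
  if (L < 4 * config$mean_event_size) {
    stop("reference much too short for the configured event size", call. = FALSE)
  }
  set.seed(config$seed)

  footprints <- matrix(numeric(0), ncol = 2)   # [start, end) source intervals
  anchors <- integer(0)
  ev <- list()
  sv_bases <- 0
  delta <- 0   # donor length - ref length so far

  point_free <- function(q) {
    !any(footprints[, 1] < q & q < footprints[, 2])
  }
  interval_free <- function(a, b) {
    !any(footprints[, 1] < b & a < footprints[, 2]) &&
      !any(a < anchors & anchors < b)
  }
  draw_anchor <- function(exclude = NULL) {
    for (t in 1:200) {
      q <- sample.int(L + 1L, 1L) - 1L
      if (point_free(q) &&
          (is.null(exclude) || q <= exclude[1] || q >= exclude[2])) return(q)
    }
    NA_integer_
  }
  draw_interval <- function(s) {
    if (s >= L) return(NULL)
    for (t in 1:200) {
      p <- sample.int(L - s, 1L) - 1L
      if (interval_free(p, p + s)) return(c(p, p + s))
    }
    NULL
  }

  repeat {
    target <- config$sv_fraction * (L + delta)
    if (sv_bases >= target) break
    s <- round(stats::runif(1, 0.5, 1.5) * config$mean_event_size)
    type <- sample(names(config$event_mix), 1L, prob = config$event_mix)
    if (type == "insertion") {
      q <- draw_anchor()
      if (is.na(q)) stop("unsatisfiable config: no room for events", call. = FALSE)
      payload <- paste(sample(c("A", "C", "G", "T"), s, TRUE), collapse = "")
      ev[[length(ev) + 1L]] <- list(type = type, ref_pos = q, size = s,
                                    payload = payload, dest = NA_integer_)
      anchors <- c(anchors, q)
      delta <- delta + s
    } else {
      iv <- draw_interval(s)
      if (is.null(iv)) stop("unsatisfiable config: no room for events", call. = FALSE)
      dest <- NA_integer_
      if (type == "duplication") {
        dest <- if (config$tandem_duplications) iv[2] else draw_anchor(iv)
        if (is.na(dest)) stop("unsatisfiable config: no room for events", call. = FALSE)
        delta <- delta + s
      } else if (type == "translocation") {
        dest <- draw_anchor(iv)
        if (is.na(dest)) stop("unsatisfiable config: no room for events", call. = FALSE)
      } else {
        delta <- delta - s
      }
      ev[[length(ev) + 1L]] <- list(type = type, ref_pos = iv[1], size = s,
                                    payload = NA_character_, dest = dest)
      footprints <- rbind(footprints, iv)
      if (!is.na(dest)) anchors <- c(anchors, dest)
    }
    sv_bases <- sv_bases + s
  }

  events <- do.call(rbind, lapply(ev, function(e)
    data.frame(type = e$type, ref_pos = e$ref_pos, size = e$size,
               payload = e$payload, dest = e$dest, stringsAsFactors = FALSE)))
  if (is.null(events)) {
    events <- data.frame(type = character(0), ref_pos = integer(0),
                         size = integer(0), payload = character(0),
                         dest = integer(0))
  }

  built <- apply_sv_events(ref, events)
  events <- built$events
  donor0 <- built$donor

  ## SNVs on every donor base outside novel inserted sequence
  if (config$snv_rate > 0) {
    Ld <- nchar(donor0)
    eligible <- rep(TRUE, Ld)
    if (nrow(built$novel_ranges)) {
      for (r in seq_len(nrow(built$novel_ranges))) {
        eligible[(built$novel_ranges$start[r] + 1L):built$novel_ranges$end[r]] <- FALSE
      }
    }
    elig_pos <- which(eligible)
    hit <- elig_pos[stats::runif(length(elig_pos)) < config$snv_rate]
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      old <- substring(donor0, hit, hit)
      new <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "",
                    USE.NAMES = FALSE)
      snv <- data.frame(type = "snv", ref_pos = NA_integer_, size = 1L,
                        payload = new, dest = NA_integer_,
                        donor_pos = hit - 1L, stringsAsFactors = FALSE)
      events <- rbind(events, snv)
    }
  }

  list(donor = apply_events(ref, events), events = events)
}

## Apply SV events only; returns donor, events augmented with donor_pos,
## and the donor ranges of novel inserted sequence (0-based half-open).
apply_sv_events <- function(ref, events) {
  L <- nchar(ref)
  sv <- events[events$type != "snv", , drop = FALSE]
  src <- sv[sv$type %in% c("deletion", "duplication", "translocation"), ,
            drop = FALSE]
  anch <- data.frame(
    pos = ifelse(sv$type == "insertion", sv$ref_pos, sv$dest),
    idx = seq_len(nrow(sv)))
  anch <- anch[!is.na(anch$pos), , drop = FALSE]

  cuts <- sort(unique(c(0L, L, src$ref_pos, src$ref_pos + src$size, anch$pos)))
  donor_parts <- character(0)
  dlen <- 0L
  donor_pos <- rep(NA_integer_, nrow(sv))
  novel <- list()

  seg_class <- function(a, b) {
    i <- which(src$ref_pos <= a & b <= src$ref_pos + src$size)
    if (length(i) == 0L) return(0L)
    i[1L]   # sources are non-overlapping
  }
  emit <- function(s) {
    donor_parts[length(donor_parts) + 1L] <<- s
    dlen <<- dlen + nchar(s)
  }

  for (ci in seq_along(cuts)) {
    c0 <- cuts[ci]
    ## arrivals anchored at c0, in event order
    for (i in anch$idx[anch$pos == c0]) {
      e <- sv[i, ]
      donor_pos[i] <- dlen
      if (e$type == "insertion") {
        novel[[length(novel) + 1L]] <- c(dlen, dlen + e$size)
        emit(e$payload)
      } else {
        emit(substr(ref, e$ref_pos + 1L, e$ref_pos + e$size))
      }
    }
    if (ci == length(cuts)) break
    c1 <- cuts[ci + 1L]
    cls <- seg_class(c0, c1)
    if (cls == 0L) {
      emit(substr(ref, c0 + 1L, c1))
    } else {
      type <- src$type[cls]
      i <- match(rownames(src)[cls], rownames(sv))
      if (type == "duplication") {
        emit(substr(ref, c0 + 1L, c1))
      } else if (type == "deletion") {
        if (is.na(donor_pos[i])) donor_pos[i] <- dlen
      }
      ## translocation source segments are skipped here; the block is
      ## emitted in full at its destination anchor
    }
  }

  sv$donor_pos <- donor_pos
  novel_ranges <- if (length(novel)) {
    data.frame(start = vapply(novel, `[`, 0, 1), end = vapply(novel, `[`, 0, 2))
  } else data.frame(start = integer(0), end = integer(0))
  list(donor = paste(donor_parts, collapse = ""), events = sv,
       novel_ranges = novel_ranges)
}

#' Reconstruct a donor genome from a reference and an event log
#'
#' Deterministically replays the SV events (by reference coordinates and
#' destination anchors) and then the SNV substitutions (by donor
#' coordinates). `mutate_genome()` builds its donor through this same
#' function, so replaying its event log reproduces the donor byte for byte.
#'
#' @param ref Reference nucleotide string.
#' @param events Event data frame as returned by [mutate_genome()].
#' @return The donor nucleotide string.
#' @export
apply_events <- function(ref, events) {
  donor <- apply_sv_events(ref, events)$donor
  snv <- events[events$type == "snv", , drop = FALSE]
  if (nrow(snv)) {
    v <- charToRaw(donor)
    v[snv$donor_pos + 1L] <- charToRaw(paste(snv$payload, collapse = ""))
    donor <- rawToChar(v)
  }
  donor
}

#' Simulate idealized paired-end reads
#'
#' Error-free pairs from every donor position: pair `i` (0-based) is
#' `(donor[i .. i+read_len-1], donor[i+insert-read_len .. i+insert-1])`, so
#' the second mate ends exactly `insert` bases after the first begins.
#' Exactly `nchar(donor) - insert + 1` pairs are produced.
#'
#' @param donor Donor nucleotide string (`nchar(donor) >= insert`).
#' @param read_len Read length in bp.
#' @param insert Insert size in bp (outer distance), `>= read_len`.
#' @return A `read_set`: list with character vectors `read1`, `read2`,
#'   integer `donor_start` (0-based), and `read_len`, `insert`.
#' @export
simulate_reads <- function(donor, read_len = 100L, insert = 500L) {
  check_dna(donor)
  read_len <- check_k(read_len); insert <- as.integer(insert)
  L <- nchar(donor)
  if (L < insert) stop("donor shorter than the insert size", call. = FALSE)
  if (insert < read_len) stop("insert smaller than read length", call. = FALSE)
  starts <- seq_len(L - insert + 1L)
  structure(list(read1 = substring(donor, starts, starts + read_len - 1L),
                 read2 = substring(donor, starts + insert - read_len,
                                   starts + insert - 1L),
                 donor_start = starts - 1L,
                 read_len = read_len, insert = insert),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set: ", length(x$read1), " pairs, read length ", x$read_len,
      " bp, insert ", x$insert, " bp\n", sep = "")
  invisible(x)
}

#' Break a read set into a donor k-mer spectrum
#'
#' Every read of length `l` contributes its `l - k + 1` k-mers (both mates);
#' multiplicities are preserved, so with uniform coverage each donor k-mer
#' appears about `2 * (read_len - k + 1)` times per genomic copy.
#'
#' @param pairs A `read_set`.
#' @param k K-mer length, `k <= read_len`.
#' @return A `kmer_spectrum` (source `"donor"`).
#' @export
reads_to_spectrum <- function(pairs, k) {
  stopifnot(inherits(pairs, "read_set"))
  k <- check_k(k)
  if (k > pairs$read_len) {
    stop("k = ", k, " exceeds the read length ", pairs$read_len, call. = FALSE)
  }
  noff <- pairs$read_len - k + 1L
  grab <- function(reads) {
    out <- vector("list", noff)
    for (off in seq_len(noff)) {
      out[[off]] <- substring(reads, off, off + k - 1L)
    }
    unlist(out, use.names = FALSE)
  }
  kmer_spectrum(c(grab(pairs$read1), grab(pairs$read2)), k = k,
                source = "donor")
}

#' Normalize read-derived k-mer multiplicities by coverage
#'
#' With error-free reads sampled from every position, each genomic copy of a
#' k-mer is seen `2 * (read_len - k + 1)` times (both mates), except within
#' about `insert` bp of the donor ends. Dividing the raw counts by that
#' per-copy coverage and rounding (never below one) recovers the donor
#' spectrum's true multiplicities.
#'
#' @param spectrum A `kmer_spectrum` from [reads_to_spectrum()].
#' @param per_copy Expected count per genomic copy; when `NULL`, the median
#'   raw count is used, which is robust while repeats are a minority.
#' @return A `kmer_spectrum` with one entry per inferred genomic copy.
#' @export
normalize_coverage <- function(spectrum, per_copy = NULL) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  cnt <- spectrum_counts(spectrum)
  if (is.null(per_copy)) per_copy <- stats::median(cnt$mult)
  mult <- pmax(1L, as.integer(round(cnt$mult / per_copy)))
  kmer_spectrum(rep(cnt$kmer, times = mult), k = spectrum$k,
                source = spectrum$source)
}
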