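#' Read a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that returns plain
#' character sequences and enforces the engine's alphabet: sequences must
#' consist of A, C, G, T only. Ambiguity bases are rejected with an error by
#' default because the graph algorithms have no model for them; with
#' `mask_n = TRUE` each sequence is instead split at runs of `N` into
#' separate records (suffixed `/1`, `/2`, ...).
#'
#' @param path FASTA file.
#' @param mask_n Split at `N` runs instead of erroring.
#' @return Named character vector of sequences (names = record ids).
#' @export
read_fasta <- function(path, mask_n = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) {
    stop("empty header in record ", which(ids == "")[1L], " of ", path,
         call. = FALSE)
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence in record ", which(nchar(seqs) == 0L)[1L], " of ",
         path, call. = FALSE)
  }
  if (mask_n) {
    pieces <- strsplit(seqs, "N+")
    ids <- unlist(mapply(function(id, p) {
      if (length(p) == 1L) id else paste0(id, "/", seq_along(p))
    }, ids, pieces, SIMPLIFY = FALSE), use.names = FALSE)
    seqs <- unlist(pieces, use.names = FALSE)
    keep <- nchar(seqs) > 0L
    seqs <- seqs[keep]; ids <- ids[keep]
  }
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGT]", seqs[i])
    if (bad != -1L) {
      stop("record ", ids[i], ": non-ACGT character '",
           substr(seqs[i], bad, bad), "' at offset ", bad - 1L,
           " (0-based); use mask_n = TRUE to split at N runs", call. = FALSE)
    }
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (names become record ids; unnamed
#'   sequences are labelled `seq1`, `seq2`, ...).
#' @param path Output file.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write simulated read pairs
#'
#' Either as two FASTQ files (`<prefix>_1.fastq`, `<prefix>_2.fastq`, all
#' qualities `I` since reads are error-free) or as one interleaved FASTA
#' (`<prefix>.fasta`, records `read<i>/1`, `read<i>/2`).
#'
#' @param pairs A `read_set` from [simulate_reads()].
#' @param prefix Output path prefix.
#' @param format `"fastq"` or `"fasta"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_reads <- function(pairs, prefix, format = c("fastq", "fasta")) {
  stopifnot(inherits(pairs, "read_set"))
  format <- match.arg(format)
  n <- length(pairs$read1)
  if (format == "fastq") {
    qual <- strrep("I", pairs$read_len)
    files <- paste0(prefix, c("_1.fastq", "_2.fastq"))
    for (m in 1:2) {
      reads <- if (m == 1) pairs$read1 else pairs$read2
      con <- file(files[m], "w")
      writeLines(paste0("@read", seq_len(n), "/", m, "\n", reads,
                        "\n+\n", qual), con)
      close(con)
    }
  } else {
    files <- paste0(prefix, ".fasta")
    inter <- character(2L * n)
    inter[c(TRUE, FALSE)] <- pairs$read1
    inter[c(FALSE, TRUE)] <- pairs$read2
    ids <- character(2L * n)
    ids[c(TRUE, FALSE)] <- paste0("read", seq_len(n), "/1")
    ids[c(FALSE, TRUE)] <- paste0("read", seq_len(n), "/2")
    names(inter) <- ids
    write_fasta(inter, files)
  }
  invisible(files)
}

#' Read paired reads back into a read set
#'
#' Accepts the interleaved FASTA or the two-file FASTQ layout produced by
#' [write_reads()]. All reads must have one common length.
#'
#' @param path Interleaved FASTA path, or the `_1.fastq` of a pair.
#' @return A `read_set` (with unknown `donor_start`).
#' @export
read_reads <- function(path) {
  if (grepl("_1\\.(fastq|fq)$", path)) {
    p2 <- sub("_1\\.", "_2.", path)
    r1 <- toupper(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))
    r2 <- toupper(as.character(Biostrings::readDNAStringSet(p2, format = "fastq")))
  } else {
    seqs <- read_fasta(path)
    if (length(seqs) %% 2L != 0L) {
      stop("interleaved read file has an odd number of records", call. = FALSE)
    }
    r1 <- unname(seqs[c(TRUE, FALSE)])
    r2 <- unname(seqs[c(FALSE, TRUE)])
  }
  len <- unique(c(nchar(r1), nchar(r2)))
  if (length(len) != 1L) stop("reads have mixed lengths", call. = FALSE)
  structure(list(read1 = unname(r1), read2 = unname(r2),
                 donor_start = rep(NA_integer_, length(r1)),
                 read_len = len, insert = NA_integer_),
            class = "read_set")
}

#' Export a condensed graph as GFA 1.0
#'
#' Contigs become S-lines; every junction adjacency becomes an L-line with a
#' `(k-1)M` overlap CIGAR.
#'
#' @param graph A `condensed_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "condensed_graph"))
  adj <- edge_adjacency(graph)
  ids <- vapply(graph$edges, function(e) e$id, 0L)
  lines <- c("H\tVN:Z:1.0",
             vapply(graph$edges, function(e)
               paste("S", paste0("c", e$id), e$contig,
                     paste0("RC:i:", e$mult), sep = "\t"), ""))
  ov <- paste0(graph$k - 1L, "M")
  for (i in seq_along(graph$edges)) {
    for (j in adj$out[[i]]) {
      lines <- c(lines, paste("L", paste0("c", ids[i]), "+",
                              paste0("c", ids[j]), "+", ov, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Dump reference markers as a BED-like TSV
#'
#' One row per local marker: contig id, contig offset range (0-based
#' half-open, k-mer steps), reference k-mer range (0-based half-open).
#'
#' @param graph A `condensed_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_markers_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "condensed_graph"))
  rows <- lapply(graph$edges, function(e) {
    if (nrow(e$local) == 0L) return(NULL)
    data.frame(contig = paste0("c", e$id),
               offset_start = e$local$offset_start,
               offset_end = e$local$offset_end + 1L,
               ref_start = e$local$start,
               ref_end = e$local$end + 1L)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(contig = character(0), offset_start = integer(0),
                      offset_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the engine decision log as JSON lines
#'
#' @param graph A `condensed_graph` after [reassemble()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_engine_log <- function(graph, path) {
  stopifnot(inherits(graph, "condensed_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in graph$log) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Pipeline configuration
#'
#' @param reference Reference: a FASTA path or a nucleotide string.
#' @param reads Donor reads: a `read_set`, a FASTA/FASTQ path readable by
#'   [read_reads()], or `NULL` when `donor` is given (reads are then
#'   simulated from it).
#' @param donor Optional donor genome (path or string); used to simulate
#'   reads when `reads` is `NULL` and to score accuracy.
#' @param k K-mer length (`>= 3`).
#' @param tau Maximum variation-event size, in k-mer steps; see
#'   [engine_config()].
#' @param read_len,insert Read simulation parameters (used when reads are
#'   simulated from `donor`).
#' @param out_prefix Optional output prefix; when set, [run_pipeline()]
#'   writes `<prefix>_contigs.fasta`, `<prefix>_graph.gfa`,
#'   `<prefix>_markers.tsv`, `<prefix>_log.jsonl` and
#'   `<prefix>_report.json`.
#' @param seed Integer seed (the assembly itself is deterministic; the seed
#'   is recorded and used for any randomized input generation).
#' @return A `run_config` object.
#' @export
run_config <- function(reference, reads = NULL, donor = NULL, k = 99L, tau,
                       read_len = 100L, insert = 500L, out_prefix = NULL,
                       seed = 1L) {
  k <- check_k(k)
  if (k < 3L) stop("k must be at least 3", call. = FALSE)
  if (missing(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  if (is.null(reads) && is.null(donor)) {
    stop("either reads or a donor genome is required", call. = FALSE)
  }
  structure(list(reference = reference, reads = reads, donor = donor, k = k,
                 tau = tau, read_len = as.integer(read_len),
                 insert = as.integer(insert), out_prefix = out_prefix,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_sequence <- function(x, what) {
  if (length(x) == 1L && is.character(x) && file.exists(x)) {
    seqs <- read_fasta(x)
    if (length(seqs) != 1L) {
      stop(what, " FASTA must contain exactly one record", call. = FALSE)
    }
    return(unname(seqs))
  }
  check_dna(x)
  x
}

#' Run the full reference-guided reassembly pipeline
#'
#' reads -> donor k-mer spectrum -> coverage normalization -> colored
#' reference/donor graph -> condensed contig graph with reference markers ->
#' tau-gap propagate/prune/merge engine -> contigs and evaluation report.
#' The pre-engine condensed-graph contigs serve as the naive de Bruijn
#' baseline in the comparison. Deterministic given the configuration.
#'
#' @param config A [run_config()].
#' @return List with `report` (method `assembly_report`), `baseline_report`,
#'   `comparison`, `contigs`, `baseline_contigs`, `graph` (final
#'   `condensed_graph`) and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ref <- load_sequence(config$reference, "reference")
  donor <- if (!is.null(config$donor)) load_sequence(config$donor, "donor")
  pairs <- config$reads
  if (is.null(pairs) && nchar(donor) < config$insert) {
    ## toy inputs below the insert size: sample the spectrum directly
    spectrum <- extract_kmers(donor, config$k)
  } else {
    if (is.null(pairs)) {
      pairs <- simulate_reads(donor, config$read_len, config$insert)
    } else if (is.character(pairs)) {
      pairs <- read_reads(pairs)
    }
    stopifnot(inherits(pairs, "read_set"))
    spectrum <- reads_to_spectrum(pairs, config$k)
    per_copy <- 2L * (pairs$read_len - config$k + 1L)
    spectrum <- normalize_coverage(spectrum, per_copy = per_copy)
  }

  colored <- build_reference_donor_graph(ref, spectrum, config$k)
  cg <- condense(colored)
  baseline_contigs <- extract_contigs(cg)
  baseline <- assembly_report(baseline_contigs, donor,
                              label = "naive-debruijn-baseline")

  final <- reassemble(cg, engine_config(tau = config$tau))
  contigs <- extract_contigs(final)
  report <- assembly_report(contigs, donor, label = "reguide")
  comparison <- compare_report(baseline, report)

  if (!is.null(config$out_prefix)) {
    p <- config$out_prefix
    names(contigs) <- paste0("contig", seq_along(contigs))
    write_fasta(contigs, paste0(p, "_contigs.fasta"))
    write_gfa(final, paste0(p, "_graph.gfa"))
    write_markers_tsv(final, paste0(p, "_markers.tsv"))
    write_engine_log(final, paste0(p, "_log.jsonl"))
    report_json(comparison, paste0(p, "_report.json"))
  }
  list(report = report, baseline_report = baseline, comparison = comparison,
       contigs = unname(contigs), baseline_contigs = baseline_contigs,
       graph = final, log = final$log)
}
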