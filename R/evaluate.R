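#' N50 of a set of contig lengths
#'
#' The largest length `L` such that contigs of length at least `L` together
#' cover at least half of the total assembly length.
#'
#' @param lengths Positive contig lengths in bp.
#' @return The N50 in bp.
#' @examples
#' n50(c(6, 5, 4, 3, 2))  # 5
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length list", call. = FALSE)
  if (any(lengths <= 0)) stop("lengths must be positive", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Fraction of contigs that assemble correctly
#'
#' In the error-free setting a contig is correct when it occurs as an exact
#' substring of the donor genome; anything else is counted as misassembled.
#'
#' @param contigs Character vector of contig sequences.
#' @param donor Donor nucleotide string.
#' @return Fraction in `[0, 1]` of contigs found in the donor.
#' @export
accuracy <- function(contigs, donor) {
  if (length(contigs) == 0L) stop("empty contig list", call. = FALSE)
  mean(vapply(contigs, function(s) grepl(s, donor, fixed = TRUE), TRUE,
              USE.NAMES = FALSE))
}

#' Summarize an assembly
#'
#' @param contigs Character vector of contig sequences.
#' @param donor Donor genome for the accuracy check, or `NULL` to skip it.
#' @param label Free-text label for reports.
#' @return An `assembly_report`: list with `label`, `n_contigs`, `n50`,
#'   `max_contig`, `total_bp` and `accuracy` (`NA` when no donor given).
#' @export
assembly_report <- function(contigs, donor = NULL, label = "assembly") {
  lens <- nchar(contigs)
  structure(list(label = label,
                 n_contigs = length(contigs),
                 n50 = n50(lens),
                 max_contig = max(lens),
                 total_bp = sum(lens),
                 accuracy = if (is.null(donor)) NA_real_ else
                   accuracy(contigs, donor)),
            class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("%s: %d contigs, N50 %d, max %d, total %d bp, accuracy %s\n",
              x$label, x$n_contigs, x$n50, x$max_contig, x$total_bp,
              if (is.na(x$accuracy)) "NA" else
                sprintf("%.1f%%", 100 * x$accuracy)))
  invisible(x)
}

#' Compare two assembly reports
#'
#' Renders a baseline-vs-method comparison in the layout of the standard
#' assembly benchmark tables: contig count, N50, max contig, accuracy, with
#' deltas (method minus baseline).
#'
#' @param baseline,method `assembly_report` objects.
#' @return An `assembly_comparison`: list with `baseline`, `method` and a
#'   `delta` list; printable as a text table and serializable with
#'   [report_json()].
#' @export
compare_report <- function(baseline, method) {
  stopifnot(inherits(baseline, "assembly_report"),
            inherits(method, "assembly_report"))
  delta <- list(n_contigs = method$n_contigs - baseline$n_contigs,
                n50 = method$n50 - baseline$n50,
                max_contig = method$max_contig - baseline$max_contig,
                accuracy = method$accuracy - baseline$accuracy)
  structure(list(baseline = baseline, method = method, delta = delta),
            class = "assembly_comparison")
}

#' @export
print.assembly_comparison <- function(x, ...) {
  fields <- c("n_contigs", "n50", "max_contig", "total_bp", "accuracy")
  fmt <- function(v) ifelse(is.na(v), "NA", format(v, digits = 4))
  tab <- data.frame(
    metric = fields,
    baseline = vapply(fields, function(f) fmt(x$baseline[[f]]), ""),
    method = vapply(fields, function(f) fmt(x$method[[f]]), ""),
    delta = vapply(fields, function(f)
      if (f %in% names(x$delta)) fmt(x$delta[[f]]) else "", ""))
  cat(x$baseline$label, "vs", x$method$label, "\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Serialize a report or comparison to JSON
#'
#' @param x An `assembly_report` or `assembly_comparison`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(unclass_deep(x), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
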