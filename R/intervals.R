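#' Build a table of genomic intervals
#'
#' Coordinates are 1-based inclusive, matching clinical array ("arr [hg19]
#' chrN(start-end)") nomenclature, so the span of an interval is
#' `end - start + 1` base pairs.
#'
#' @param chrom Chromosome labels.
#' @param start,end 1-based inclusive coordinates, `end >= start >= 1`.
#' @param assembly Genome assembly label (default `"GRCh37/hg19"`).
#' @return A tibble with columns `chrom`, `start`, `end`, `assembly`.
#' @export
genomic_interval <- function(chrom, start, end, assembly = "GRCh37/hg19") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 1) || any(end < start)) {
    stop_imprint("Intervals require end >= start >= 1 (1-based inclusive).",
                 "imprintscan_error_validation")
  }
  tibble(chrom = as.character(chrom), start = start, end = end,
         assembly = assembly)
}

#' Span of genomic intervals in report units
#'
#' Computes `end - start + 1` base pairs and expresses it in the unit used
#' in copy-number report text: integer kilobases or one-decimal megabases,
#' rounded half-up (so a 146,353 bp duplication is reported as 146 Kb and a
#' 5,746,353 bp duplication as 5.7 Mb).
#'
#' @param intervals A data frame with `start` and `end` columns (see
#'   [genomic_interval()]).
#' @param unit `"kb"`, `"mb"`, or `"bp"`.
#' @param round Apply report rounding (default). With `round = FALSE` the
#'   raw converted span is returned.
#' @return `intervals` with an added `span` column.
#' @export
interval_span <- function(intervals, unit = c("kb", "mb", "bp"),
                          round = TRUE) {
  unit <- match.arg(tolower(unit[1]), c("kb", "mb", "bp"))
  bp <- intervals$end - intervals$start + 1
  span <- switch(unit,
    bp = bp,
    kb = if (round) round_half_up(bp / 1e3, 0) else bp / 1e3,
    mb = if (round) round_half_up(bp / 1e6, 1) else bp / 1e6
  )
  mutate(as_tibble(intervals), span = span)
}

# round-half-up (not banker's rounding): report text convention
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}
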