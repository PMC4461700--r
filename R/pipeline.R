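#' Run the end-to-end epimutation screen
#'
#' Loads (or accepts) the peak table, panel and optional trio genotypes,
#' builds the control baseline, measures methylation (M) and dosage (D) at
#' every DMR locus of every patient, classifies epigenotypes, and — only
#' after the methylation calls are fixed (blind-test ordering) — reconciles
#' mechanism hypotheses with the trio UPD verdicts. Controls are designated
#' explicitly and never inferred from data normality; each control is also
#' re-measured against a leave-one-out baseline and reported if it falls
#' outside the normal range.
#'
#' @param peaks Peak tibble (see [read_peak_table()]) or a CSV path.
#' @param panel An [imprint_panel] or a config path.
#' @param controls Character vector of control sample ids.
#' @param trios Optional trio genotype tibble or CSV path; `trio_id` is
#'   matched against patient sample ids.
#' @param mode Denominator mode, see [relative_areas()].
#' @param range A [normal_range()].
#' @param min_controls,allow_low_n See [build_baseline()].
#' @param min_supporting See [call_upd()].
#' @return An object of class `imprint_screen`: a list with
#'   `measurements`, `calls`, `samples`, `upd`, `marker_calls`,
#'   `control_qc`, `summary`, and `provenance`.
#' @export
run_screen <- function(peaks, panel = default_panel(), controls,
                       trios = NULL, mode = c("reference_only", "all_peaks"),
                       range = normal_range(), min_controls = 5,
                       allow_low_n = FALSE, min_supporting = 3) {
  mode <- match.arg(mode)
  digests <- list()
  if (is.character(panel) && length(panel) == 1) {
    digests$panel <- unname(tools::md5sum(panel))
    panel <- read_panel_config(panel)
  }
  if (is.character(peaks) && length(peaks) == 1) {
    digests$peaks <- unname(tools::md5sum(peaks))
    peaks <- read_peak_table(peaks, panel)
  }
  if (!"amplicon" %in% names(peaks)) peaks <- assign_peaks(peaks, panel)
  if (is.character(trios) && length(trios) == 1) {
    digests$trios <- unname(tools::md5sum(trios))
    trios <- read_trio_genotypes(trios)
  }
  pairs <- pair_runs(peaks, panel, controls = controls)
  absent <- setdiff(controls, unique(pairs$sample_id))
  if (length(absent) > 0) {
    stop_imprint(
      paste0("Designated control(s) absent from the paired peak data: ",
             paste(absent, collapse = ", ")),
      "imprintscan_error_controls"
    )
  }
  baseline <- build_baseline(pairs, panel, mode = mode,
                             min_controls = min_controls,
                             allow_low_n = allow_low_n)
  patient_pairs <- pairs %>% filter(.data$role == "patient")
  if (nrow(patient_pairs) == 0) {
    measurements <- tibble(
      sample_id = character(), locus = character(), M = numeric(),
      D = numeric(), M_per_copy = numeric(), percent_loss = numeric(),
      percent_gain = numeric(), missing_peak = logical(),
      degenerate_dosage = logical(), low_control_n = logical()
    )
    screened <- list(
      calls = measurements %>%
        mutate(methylation_class = character(), dosage_class = character(),
               chrom = character(), mechanisms = list(),
               syndrome = character(), recommendation = character(),
               multilocus_candidate = logical()),
      samples = tibble(sample_id = character(), n_meth_abnormal = integer(),
                       n_dosage_abnormal = integer(), positive = logical(),
                       multilocus_candidate = logical())
    )
  } else {
    measurements <- measure_loci(patient_pairs, baseline, panel)
    screened <- screen_samples(measurements, panel, range)
  }
  calls <- screened$calls
  # leave-one-out QC of the controls (reported, never auto-excluded)
  control_qc <- control_loo_qc(pairs, panel, mode, range)
  upd <- NULL
  marker_calls <- NULL
  if (!is.null(trios) && nrow(trios) > 0) {
    marker_calls <- classify_markers(trios)
    upd <- call_upd(marker_calls, min_supporting = min_supporting)
    calls <- reconcile_with_upd(calls, upd)
  }
  summary <- tibble(
    n_screened = nrow(screened$samples),
    n_controls = attr(baseline, "n_controls"),
    n_positive = sum(screened$samples$positive),
    n_multilocus = sum(screened$samples$multilocus_candidate)
  )
  structure(list(
    panel_name = attr(panel, "panel_name"),
    panel_version = attr(panel, "panel_version"),
    mode = mode,
    range = unclass(range),
    measurements = measurements,
    calls = calls,
    samples = screened$samples,
    upd = upd,
    marker_calls = marker_calls,
    control_qc = control_qc,
    summary = summary,
    provenance = list(
      tool = "imprintscan",
      version = as.character(utils::packageVersion("imprintscan")),
      schema_version = "1.0",
      input_digests = digests
    )
  ), class = "imprint_screen")
}

control_loo_qc <- function(pairs, panel, mode, range) {
  ctrl_ids <- unique(pairs$sample_id[pairs$role == "control"])
  if (length(ctrl_ids) < 3) {
    return(tibble(sample_id = character(), n_flagged = integer()))
  }
  purrr::map_dfr(ctrl_ids, function(id) {
    rest <- pairs %>% filter(.data$role == "control", .data$sample_id != id)
    base <- build_baseline(rest, panel, mode = mode,
                           min_controls = 1, allow_low_n = TRUE)
    m <- measure_loci(pairs %>% filter(.data$sample_id == id), base, panel)
    tibble(sample_id = id,
           n_flagged = sum(m$M < range$low | m$M > range$high |
                           m$D < range$low | m$D > range$high))
  })
}

#' @export
print.imprint_screen <- function(x, ...) {
  cat("Imprinting epimutation screen (", x$panel_name, " v",
      x$panel_version, ", mode ", x$mode, ")\n", sep = "")
  cat("  samples screened:", x$summary$n_screened,
      "| controls:", x$summary$n_controls, "\n")
  cat("  positive:", x$summary$n_positive,
      "| multilocus candidates:", x$summary$n_multilocus, "\n")
  pos <- x$calls %>%
    filter(.data$methylation_class != "NORMAL" |
           .data$dosage_class != "NORMAL")
  if (nrow(pos) > 0) {
    cat("  abnormal calls:\n")
    for (i in seq_len(nrow(pos))) {
      cat(sprintf("    %s %s: M=%.2f D=%.2f %s/%s [%s]\n",
                  pos$sample_id[i], pos$locus[i], pos$M[i], pos$D[i],
                  pos$methylation_class[i], pos$dosage_class[i],
                  paste(pos$mechanisms[[i]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Tidy the per-locus calls of a screen
#'
#' @param x An `imprint_screen`.
#' @param ... Unused.
#' @return The per-locus call tibble with mechanisms collapsed to a
#'   `;`-separated string.
#' @export
tidy.imprint_screen <- function(x, ...) {
  x$calls %>%
    mutate(mechanisms = purrr::map_chr(.data$mechanisms,
                                       paste, collapse = ";"))
}

#' One-row summary of a screen
#'
#' @param x An `imprint_screen`.
#' @param ... Unused.
#' @return A one-row tibble: cohort sizes, positives, multilocus
#'   candidates, mode and normal range.
#' @export
glance.imprint_screen <- function(x, ...) {
  x$summary %>%
    mutate(mode = x$mode, range_low = x$range$low, range_high = x$range$high)
}

#' Write screen report files
#'
#' Writes `report.json` (full report incl. provenance), `calls.tsv` (flat
#' per-locus calls) and `measurements.tsv` into `out_dir`. Output is
#' byte-identical across re-runs on identical inputs.
#'
#' @param screen An `imprint_screen`.
#' @param out_dir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
write_report <- function(screen, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meas_path <- file.path(out_dir, "measurements.tsv")
  calls_path <- file.path(out_dir, "calls.tsv")
  json_path <- file.path(out_dir, "report.json")
  readr::write_tsv(screen$measurements, meas_path, progress = FALSE)
  readr::write_tsv(tidy(screen), calls_path, progress = FALSE)
  report <- list(
    schema_version = screen$provenance$schema_version,
    panel_name = screen$panel_name,
    panel_version = screen$panel_version,
    mode = screen$mode,
    range = screen$range,
    summary = screen$summary,
    measurements = screen$measurements,
    calls = screen$calls,
    samples = screen$samples,
    upd = screen$upd,
    marker_calls = marker_calls_for_json(screen$marker_calls),
    control_qc = screen$control_qc,
    provenance = screen$provenance
  )
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(json_path, calls_path, meas_path))
}

marker_calls_for_json <- function(mc) {
  if (is.null(mc)) return(NULL)
  fmt <- function(g) purrr::map_chr(g, paste, collapse = "/")
  mc %>% mutate(mother = fmt(.data$mother), father = fmt(.data$father),
                child = fmt(.data$child))
}

#' Read a screen report back from JSON
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return An `imprint_screen` (marker genotype list-columns are restored
#'   from their `/`-joined form).
#' @export
read_report <- function(path) {
  r <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  retib <- function(d) if (is.null(d)) NULL else as_tibble(d)
  calls <- retib(r$calls)
  if (!is.null(calls) && nrow(calls) > 0) {
    if (!"mechanisms" %in% names(calls)) {
      calls$mechanisms <- rep(list(character(0)), nrow(calls))
    } else {
      calls$mechanisms <- purrr::map(calls$mechanisms, as.character)
    }
  }
  mc <- retib(r$marker_calls)
  if (!is.null(mc) && nrow(mc) > 0) {
    split_gt <- function(x) purrr::map(x, ~ if (.x == "") character(0)
                                       else stringr::str_split_1(.x, "/"))
    mc$mother <- split_gt(mc$mother)
    mc$father <- split_gt(mc$father)
    mc$child <- split_gt(mc$child)
  }
  structure(list(
    panel_name = r$panel_name, panel_version = r$panel_version,
    mode = r$mode, range = r$range,
    measurements = retib(r$measurements),
    calls = calls, samples = retib(r$samples),
    upd = retib(r$upd), marker_calls = mc,
    control_qc = retib(r$control_qc),
    summary = retib(r$summary),
    provenance = r$provenance
  ), class = "imprint_screen")
}
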