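#' Read a fragment-analysis peak table
#'
#' Reads a GeneMapper-style CSV export with columns
#' `sample_id,condition,size,height,area` (condition `digested` or
#' `undigested`, case-insensitive; `height` optional) and assigns each peak
#' to a panel amplicon by fragment size.
#'
#' @param path CSV file path.
#' @param panel An [imprint_panel].
#' @return A tibble of peak records with an `amplicon` column (`NA` for
#'   peaks outside every assignment window; these are reported with a
#'   warning and excluded downstream).
#' @export
read_peak_table <- function(path, panel) {
  if (!file.exists(path)) {
    stop_imprint(paste0("Peak table not found: ", path),
                 "imprintscan_error_parse")
  }
  peaks <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "condition", "size", "area")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    stop_imprint(
      paste0("Peak table '", path, "' is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "imprintscan_error_parse"
    )
  }
  if (!"height" %in% names(peaks)) peaks$height <- NA_real_
  peaks <- peaks %>%
    mutate(
      sample_id = as.character(.data$sample_id),
      condition = tolower(as.character(.data$condition)),
      size = as.numeric(.data$size),
      height = as.numeric(.data$height),
      area = as.numeric(.data$area)
    )
  bad_cond <- setdiff(unique(peaks$condition), .CONDITIONS)
  if (length(bad_cond) > 0) {
    stop_imprint(
      paste0("Unknown condition value(s): ", paste(bad_cond, collapse = ", "),
             " (expected 'digested' or 'undigested')."),
      "imprintscan_error_parse"
    )
  }
  if (any(!is.na(peaks$area) & peaks$area < 0)) {
    stop_imprint("Peak areas must be >= 0.", "imprintscan_error_validation")
  }
  assign_peaks(peaks, panel)
}

#' Assign peaks to panel amplicons by fragment size
#'
#' A peak is assigned to the unique amplicon whose window
#' `expected_size +/- size_tolerance` contains its size. A peak inside two
#' windows is an ambiguity error (never nearest-wins: silent misassignment
#' would corrupt the denominator of the relative-area statistic). Peaks
#' outside every window are kept with `amplicon = NA` and a warning.
#'
#' @param peaks A peak tibble (see [read_peak_table()]).
#' @param panel An [imprint_panel].
#' @return `peaks` with an `amplicon` column.
#' @export
assign_peaks <- function(peaks, panel) {
  if (nrow(peaks) == 0) {
    peaks$amplicon <- character(0)
    return(as_tibble(peaks))
  }
  dist <- abs(outer(peaks$size, panel$expected_size, "-"))
  within <- dist <= matrix(panel$size_tolerance,
                           nrow = nrow(peaks), ncol = nrow(panel),
                           byrow = TRUE)
  n_hits <- rowSums(within)
  if (any(n_hits > 1)) {
    i <- which(n_hits > 1)[1]
    hits <- panel$name[within[i, ]]
    stop_imprint(
      paste0("Peak of size ", peaks$size[i], " (sample ", peaks$sample_id[i],
             ") falls within the windows of multiple amplicons: ",
             paste(hits, collapse = ", ")),
      "imprintscan_error_ambiguous"
    )
  }
  amplicon <- rep(NA_character_, nrow(peaks))
  one <- n_hits == 1
  amplicon[one] <- panel$name[apply(within[one, , drop = FALSE], 1, which)]
  if (any(!one)) {
    warn(paste0(sum(!one), " peak(s) outside every amplicon window were left",
                " unassigned and will be excluded."))
  }
  peaks$amplicon <- amplicon
  as_tibble(peaks)
}

#' Write a peak table
#'
#' Writes the canonical `sample_id,condition,size,height,area` CSV; amplicon
#' assignment is recovered on re-read from the fragment sizes.
#'
#' @param peaks A peak tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_csv(peaks[, c("sample_id", "condition", "size", "height",
                             "area")], path, progress = FALSE)
  invisible(path)
}

#' Pair digested and undigested runs of each sample
#'
#' Builds one row per sample and amplicon with the digested and undigested
#' peak areas side by side. Samples missing one of the two conditions are
#' dropped with a warning; a sample with two runs of the same condition is a
#' hard error (no silent averaging); expected amplicons without a peak are
#' recorded as area 0 with a missing-peak flag (a fully digested
#' unmethylated DMR amplicon legitimately yields no peak in the digested
#' aliquot).
#'
#' @param peaks An assigned peak tibble (see [assign_peaks()]).
#' @param panel An [imprint_panel].
#' @param controls Character vector of control sample ids; all other samples
#'   get role `"patient"`.
#' @return A tibble with columns `sample_id`, `role`, `amplicon`,
#'   `digested`, `undigested`, `missing_digested`, `missing_undigested`.
#' @export
pair_runs <- function(peaks, panel, controls = character()) {
  peaks <- peaks %>% filter(!is.na(.data$amplicon))
  dup <- peaks %>%
    count(.data$sample_id, .data$condition, .data$amplicon) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop_imprint(
      paste0("Duplicate run detected: sample ", dup$sample_id[1],
             " has more than one '", dup$condition[1],
             "' peak for amplicon ", dup$amplicon[1],
             ". Replicate runs are not merged automatically."),
      "imprintscan_error_duplicate_run"
    )
  }
  conds <- peaks %>%
    distinct(.data$sample_id, .data$condition) %>%
    count(.data$sample_id)
  incomplete <- conds$sample_id[conds$n < 2]
  if (length(incomplete) > 0) {
    warn(paste0("Dropping sample(s) missing one condition: ",
                paste(incomplete, collapse = ", ")))
    peaks <- peaks %>% filter(!.data$sample_id %in% incomplete)
  }
  if (nrow(peaks) == 0) {
    return(tibble(sample_id = character(), role = character(),
                  amplicon = character(), digested = numeric(),
                  undigested = numeric(), missing_digested = logical(),
                  missing_undigested = logical()))
  }
  full <- tidyr::expand_grid(
    sample_id = unique(peaks$sample_id),
    condition = .CONDITIONS,
    amplicon = panel$name
  ) %>%
    left_join(peaks %>% select("sample_id", "condition", "amplicon", "area"),
              by = c("sample_id", "condition", "amplicon")) %>%
    mutate(missing = is.na(.data$area),
           area = ifelse(is.na(.data$area), 0, .data$area))
  wide <- full %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("area", "missing")) %>%
    rename(digested = "area_digested", undigested = "area_undigested",
           missing_digested = "missing_digested",
           missing_undigested = "missing_undigested") %>%
    mutate(role = ifelse(.data$sample_id %in% controls,
                         "control", "patient")) %>%
    select("sample_id", "role", "amplicon", "digested", "undigested",
           "missing_digested", "missing_undigested") %>%
    arrange(.data$sample_id,
            match(.data$amplicon, panel$name))
  wide
}
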