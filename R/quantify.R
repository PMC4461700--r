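#' Relative peak areas per sample and condition
#'
#' The quantification statistic of the screen: within one sample and one
#' aliquot (digested or undigested), each peak area is divided by a
#' denominator to give a dimensionless relative area. Two denominator modes
#' are provided:
#'
#' * `"all_peaks"` — the sum of all assigned peak areas of that sample and
#'   condition (the classical relative area; values sum to 1);
#' * `"reference_only"` — the sum of the REFERENCE amplicon areas only
#'   (the default downstream, because it makes the methylation value linear
#'   in methylated-copy number and so recovers mosaic loss percentages
#'   exactly).
#'
#' @param pairs Output of [pair_runs()].
#' @param panel An [imprint_panel].
#' @param mode `"reference_only"` (default) or `"all_peaks"`.
#' @return A tibble `sample_id, condition, amplicon, area, rel, missing`
#'   with attribute `mode`.
#' @export
relative_areas <- function(pairs, panel,
                           mode = c("reference_only", "all_peaks")) {
  mode <- match.arg(mode)
  refs <- panel$name[panel$kind == "REFERENCE"]
  long <- pairs %>%
    select("sample_id", "amplicon", "digested", "undigested",
           "missing_digested", "missing_undigested") %>%
    tidyr::pivot_longer(c("digested", "undigested"),
                        names_to = "condition", values_to = "area") %>%
    mutate(missing = ifelse(.data$condition == "digested",
                            .data$missing_digested,
                            .data$missing_undigested)) %>%
    select(-"missing_digested", -"missing_undigested")
  denom <- long %>%
    group_by(.data$sample_id, .data$condition) %>%
    summarise(denominator = if (mode == "all_peaks") {
      sum(.data$area)
    } else {
      sum(.data$area[.data$amplicon %in% refs])
    }, .groups = "drop")
  degenerate <- denom %>% filter(.data$denominator <= 0)
  if (nrow(degenerate) > 0) {
    stop_imprint(
      paste0("Degenerate sample: zero ",
             if (mode == "all_peaks") "total" else "reference",
             " peak area for sample ", degenerate$sample_id[1],
             " (", degenerate$condition[1], ")."),
      "imprintscan_error_degenerate"
    )
  }
  out <- long %>%
    left_join(denom, by = c("sample_id", "condition")) %>%
    mutate(rel = .data$area / .data$denominator) %>%
    select("sample_id", "condition", "amplicon", "area", "rel", "missing")
  attr(out, "mode") <- mode
  out
}

#' Build the control baseline
#'
#' Per condition and amplicon, the arithmetic mean of the control samples'
#' relative areas, with the coefficient of variation recorded. Patient
#' values are normalized to these means, so a sample drawn from the control
#' population has expectation 1 at every amplicon. No outlier trimming is
#' applied: controls that themselves fall outside the normal range on a
#' leave-one-out pass are reported downstream, never auto-excluded.
#'
#' @param pairs Output of [pair_runs()]. If a `role` column is present only
#'   `role == "control"` rows are used; otherwise all samples are treated as
#'   controls.
#' @param panel An [imprint_panel].
#' @param mode Denominator mode, see [relative_areas()].
#' @param min_controls Minimum number of control samples (default 5).
#' @param allow_low_n If `TRUE`, fewer controls than `min_controls` is
#'   tolerated and a `low_control_n` flag is propagated to every
#'   measurement instead of an error.
#' @return A tibble `condition, amplicon, mean_rel, cv` of class
#'   `imprint_baseline`, with attributes `mode`, `n_controls`,
#'   `low_control_n`.
#' @export
build_baseline <- function(pairs, panel,
                           mode = c("reference_only", "all_peaks"),
                           min_controls = 5, allow_low_n = FALSE) {
  mode <- match.arg(mode)
  ctrl <- if ("role" %in% names(pairs)) {
    pairs %>% filter(.data$role == "control")
  } else {
    pairs
  }
  n_controls <- n_distinct(ctrl$sample_id)
  if (n_controls < min_controls && !allow_low_n) {
    stop_imprint(
      paste0("Only ", n_controls, " control sample(s); at least ",
             min_controls, " are required (set allow_low_n = TRUE to ",
             "proceed with a LOW_CONTROL_N flag)."),
      "imprintscan_error_controls"
    )
  }
  if (n_controls == 0) {
    stop_imprint("No control samples available to build a baseline.",
                 "imprintscan_error_controls")
  }
  rel <- relative_areas(ctrl, panel, mode)
  base <- rel %>%
    group_by(.data$condition, .data$amplicon) %>%
    summarise(mean_rel = mean(.data$rel),
              # population (1/n) dispersion: descriptive, not inferential
              cv = if (n() > 1 && mean(.data$rel) > 0) {
                sqrt(mean((.data$rel - mean(.data$rel))^2)) / mean(.data$rel)
              } else 0,
              .groups = "drop")
  zero <- base %>% filter(.data$mean_rel <= 0)
  if (nrow(zero) > 0) {
    stop_imprint(
      paste0("Control mean relative area is zero for amplicon ",
             zero$amplicon[1], " (", zero$condition[1],
             "); it cannot be used to normalize."),
      "imprintscan_error_baseline"
    )
  }
  structure(base,
            class = c("imprint_baseline", class(base)),
            mode = mode, n_controls = n_controls,
            low_control_n = n_controls < min_controls)
}

#' Normalize a relative-area profile against the control baseline
#'
#' @param rel Output of [relative_areas()].
#' @param baseline Output of [build_baseline()] (same denominator mode).
#' @return `rel` with a `norm` column, `norm = rel / mean_rel`; the
#'   baseline means normalized against themselves are exactly 1.
#' @export
normalize_profile <- function(rel, baseline) {
  if (!identical(attr(rel, "mode"), attr(baseline, "mode"))) {
    stop_imprint("Profile and baseline were computed under different
denominator modes.", "imprintscan_error_validation")
  }
  unmatched <- anti_join(rel, baseline, by = c("condition", "amplicon"))
  if (nrow(unmatched) > 0) {
    stop_imprint(
      paste0("Amplicon absent from baseline: ", unmatched$amplicon[1],
             " (", unmatched$condition[1], ")."),
      "imprintscan_error_baseline"
    )
  }
  rel %>%
    left_join(as_tibble(baseline), by = c("condition", "amplicon")) %>%
    mutate(norm = .data$rel / .data$mean_rel) %>%
    select("sample_id", "condition", "amplicon", "area", "rel", "norm",
           "missing")
}

#' Per-locus methylation and dosage values
#'
#' For every DMR amplicon of every sample, computes the screen's two
#' control-normalized values: the methylation value `M` (normalized digested
#' value; only methylated template survives the methylation-sensitive
#' digest) and the dosage value `D` (normalized undigested value). Both are
#' ~1 in a normal sample. `M_per_copy = M / D` is reported alongside
#' (0 with a flag when `D = 0`, so complete deletions remain reportable).
#' `percent_loss = 100 (1 - M)` when `M < 1`, `percent_gain = 100 (M - 1)`
#' when `M > 1`; a mosaic loss of methylation in a fraction `c` of cells
#' yields `M = 1 - c`, i.e. `percent_loss = 100 c`.
#'
#' @param pairs Output of [pair_runs()] (patients and/or controls).
#' @param baseline Output of [build_baseline()].
#' @param panel An [imprint_panel].
#' @return A tibble with one row per sample and DMR locus: `sample_id`,
#'   `locus`, `M`, `D`, `M_per_copy`, `percent_loss`, `percent_gain`,
#'   `missing_peak`, `degenerate_dosage`, `low_control_n`.
#' @export
measure_loci <- function(pairs, baseline, panel) {
  mode <- attr(baseline, "mode")
  rel <- relative_areas(pairs, panel, mode)
  norm <- normalize_profile(rel, baseline)
  dmr <- panel %>% filter(.data$kind == "DMR") %>%
    select(amplicon = "name", "locus")
  wide <- norm %>%
    inner_join(dmr, by = "amplicon") %>%
    select("sample_id", "locus", "condition", "norm", "missing") %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("norm", "missing"))
  wide %>%
    mutate(
      M = .data$norm_digested,
      D = .data$norm_undigested,
      degenerate_dosage = .data$D == 0,
      M_per_copy = ifelse(.data$D > 0, .data$M / .data$D, 0),
      percent_loss = ifelse(.data$M < 1, 100 * (1 - .data$M), 0),
      percent_gain = ifelse(.data$M > 1, 100 * (.data$M - 1), 0),
      missing_peak = .data$missing_digested | .data$missing_undigested,
      low_control_n = attr(baseline, "low_control_n")
    ) %>%
    select("sample_id", "locus", "M", "D", "M_per_copy", "percent_loss",
           "percent_gain", "missing_peak", "degenerate_dosage",
           "low_control_n") %>%
    arrange(.data$sample_id, match(.data$locus, dmr$locus))
}
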