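#' Construct and validate an amplicon panel
#'
#' A panel describes the multiplex design of the methylation-sensitive digest
#' assay: which amplicons interrogate a differentially methylated region (DMR)
#' and which are digestion-resistant reference amplicons that form the
#' normalization basis. DMR amplicons carry the imprinting metadata of their
#' locus (cytogenetic band, normally methylated parental allele, and the
#' syndromes associated with loss or gain of methylation).
#'
#' @param amplicons A data frame with one row per amplicon and columns
#'   `name`, `locus`, `expected_size` (bp), `size_tolerance` (bp),
#'   `kind` (`"DMR"` or `"REFERENCE"`), `chrom_band`, `methylated_parent`
#'   (`"maternal"`, `"paternal"`, or `NA` for references), `hypo_syndrome`,
#'   `hyper_syndrome`. Missing metadata columns are filled with `NA`.
#' @param name,version Panel identifier strings carried into reports.
#'
#' @return A tibble of class `imprint_panel` with attributes `panel_name` and
#'   `panel_version`.
#'
#' @details Invariants enforced: amplicon names unique; at least one DMR and
#'   one REFERENCE amplicon; `expected_size > 0`; `size_tolerance >= 0`;
#'   every DMR amplicon has a parental methylated allele and no REFERENCE
#'   amplicon does.
#'
#' @examples
#' panel <- default_panel()
#' dplyr::filter(panel, kind == "DMR")
#' @export
imprint_panel <- function(amplicons, name = "custom", version = "1") {
  required <- c("name", "locus", "expected_size", "size_tolerance", "kind")
  missing_cols <- setdiff(required, names(amplicons))
  if (length(missing_cols) > 0) {
    stop_imprint(
      paste0("Panel is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "imprintscan_error_parse"
    )
  }
  amp <- as_tibble(amplicons)
  for (col in c("chrom_band", "methylated_parent", "hypo_syndrome",
                "hyper_syndrome")) {
    if (!col %in% names(amp)) amp[[col]] <- NA_character_
    amp[[col]] <- as.character(amp[[col]])
  }
  amp$expected_size <- as.numeric(amp$expected_size)
  amp$size_tolerance <- as.numeric(amp$size_tolerance)
  amp$kind <- toupper(as.character(amp$kind))
  amp$methylated_parent <- tolower(amp$methylated_parent)
  amp <- amp[, c(required, "chrom_band", "methylated_parent",
                 "hypo_syndrome", "hyper_syndrome")]
  validate_panel(amp)
  structure(amp,
            class = c("imprint_panel", class(amp)),
            panel_name = name, panel_version = version)
}

validate_panel <- function(amp) {
  if (anyDuplicated(amp$name) > 0) {
    dups <- unique(amp$name[duplicated(amp$name)])
    stop_imprint(
      paste0("Duplicate amplicon name(s): ", paste(dups, collapse = ", ")),
      "imprintscan_error_validation"
    )
  }
  if (!all(amp$kind %in% c("DMR", "REFERENCE"))) {
    stop_imprint("Amplicon kind must be 'DMR' or 'REFERENCE'.",
                 "imprintscan_error_validation")
  }
  if (sum(amp$kind == "REFERENCE") < 1) {
    stop_imprint("Panel must contain at least one REFERENCE amplicon.",
                 "imprintscan_error_validation")
  }
  if (sum(amp$kind == "DMR") < 1) {
    stop_imprint("Panel must contain at least one DMR amplicon.",
                 "imprintscan_error_validation")
  }
  if (any(!is.finite(amp$expected_size)) || any(amp$expected_size <= 0)) {
    stop_imprint("expected_size must be a positive number for every amplicon.",
                 "imprintscan_error_validation")
  }
  if (any(!is.finite(amp$size_tolerance)) || any(amp$size_tolerance < 0)) {
    stop_imprint("size_tolerance must be >= 0 for every amplicon.",
                 "imprintscan_error_validation")
  }
  is_dmr <- amp$kind == "DMR"
  bad_dmr <- is_dmr & !(amp$methylated_parent %in% c("maternal", "paternal"))
  if (any(bad_dmr)) {
    stop_imprint(
      paste0("DMR amplicon(s) without a methylated parental allele: ",
             paste(amp$name[bad_dmr], collapse = ", ")),
      "imprintscan_error_validation"
    )
  }
  bad_ref <- !is_dmr & !is.na(amp$methylated_parent)
  if (any(bad_ref)) {
    stop_imprint(
      paste0("REFERENCE amplicon(s) must not declare a methylated parent: ",
             paste(amp$name[bad_ref], collapse = ", ")),
      "imprintscan_error_validation"
    )
  }
  invisible(amp)
}

#' The default four-locus imprinting panel
#'
#' Four DMR amplicons covering the imprinted loci KCNQ1OT1 (11p15, maternally
#' methylated; hypomethylation in Beckwith-Wiedemann syndrome), H19 (11p15,
#' paternally methylated; hypomethylation in Silver-Russell syndrome,
#' hypermethylation in Beckwith-Wiedemann syndrome), SNRPN (15q12, maternally
#' methylated; hypomethylation in Angelman syndrome, hypermethylation in
#' Prader-Willi syndrome) and MEG3 (14q32, paternally methylated; methylation
#' changes in the UPD(14) syndromes), plus four digestion-resistant reference
#' amplicons. Amplicon sizes are synthetic placeholders chosen to give
#' non-overlapping assignment windows; the imprinting metadata is real.
#'
#' @return An [imprint_panel] named `panel_imprint4`.
#' @export
default_panel <- function() {
  read_panel_config(system.file("extdata", "panel_imprint4.yaml",
                                package = "imprintscan", mustWork = TRUE))
}

#' Read a panel configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file with top-level keys
#'   `name`, `version` and `amplicons` (a list of amplicon records whose keys
#'   match the columns of [imprint_panel()]).
#' @return An [imprint_panel].
#' @export
read_panel_config <- function(path) {
  if (!file.exists(path)) {
    stop_imprint(paste0("Panel config not found: ", path),
                 "imprintscan_error_parse")
  }
  cfg <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) {
      stop_imprint(paste0("Malformed panel config '", path, "': ",
                          conditionMessage(e)),
                   "imprintscan_error_parse")
    }
  )
  if (is.null(cfg$amplicons) || length(cfg$amplicons) == 0) {
    stop_imprint(paste0("Panel config '", path, "' has no 'amplicons' key."),
                 "imprintscan_error_parse")
  }
  amp <- purrr::map_dfr(cfg$amplicons, function(a) {
    tibble(
      name = as.character(a$name %||% NA),
      locus = as.character(a$locus %||% NA),
      expected_size = as.numeric(a$expected_size %||% NA),
      size_tolerance = as.numeric(a$size_tolerance %||% NA),
      kind = as.character(a$kind %||% NA),
      chrom_band = as.character(a$chrom_band %||% NA),
      methylated_parent = as.character(a$methylated_parent %||% NA),
      hypo_syndrome = as.character(a$hypo_syndrome %||% NA),
      hyper_syndrome = as.character(a$hyper_syndrome %||% NA)
    )
  })
  imprint_panel(amp,
                name = cfg$name %||% "unnamed",
                version = as.character(cfg$version %||% "1"))
}

#' Write a panel configuration to YAML
#'
#' @param panel An [imprint_panel].
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_panel_config <- function(panel, path) {
  cfg <- list(
    name = attr(panel, "panel_name"),
    version = attr(panel, "panel_version"),
    amplicons = purrr::pmap(panel, function(...) {
      a <- list(...)
      a[!is.na(a)]
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# "11p15" -> "11"; used to match UPD calls to the loci on that chromosome
chrom_from_band <- function(band) {
  sub("[pq].*$", "", band)
}
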