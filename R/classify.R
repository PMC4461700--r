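#' Normal range for control-normalized values
#'
#' A control-normalized methylation or dosage value within 1 +/- 0.2 is
#' considered normal; the range is inclusive at both ends. Below
#' `complete_loss_max` a loss of methylation is called complete rather than
#' partial (mosaic) — the screen distinguishes the two verbally, and 0.1 is
#' the package's numeric line between them.
#'
#' @param low,high Normal-range bounds (defaults 0.8 and 1.2).
#' @param complete_loss_max Values at or below this are complete loss
#'   (default 0.1). Must satisfy `0 <= complete_loss_max < low < 1 < high`.
#' @return A list of class `normal_range`.
#' @export
normal_range <- function(low = 0.8, high = 1.2, complete_loss_max = 0.1) {
  if (!(complete_loss_max >= 0 && complete_loss_max < low &&
        low < 1 && 1 < high)) {
    stop_imprint(
      "Require 0 <= complete_loss_max < low < 1 < high.",
      "imprintscan_error_validation"
    )
  }
  structure(list(low = low, high = high,
                 complete_loss_max = complete_loss_max),
            class = "normal_range")
}

#' Mechanism hypotheses for one epigenotype
#'
#' The rule table linking the (methylation class, dosage class) pair of a
#' DMR to candidate molecular mechanisms, given which parental allele is
#' normally methylated:
#'
#' * loss of methylation with normal dosage: epimutation, or uniparental
#'   disomy of the *unmethylated* parent (two unmethylated homologues); a
#'   complete loss lists UPD first, a partial (mosaic) loss lists
#'   epimutation first, since UPD is constitutional and rarely mosaic;
#' * gain of methylation with normal dosage: UPD of the *methylated*
#'   parent first, then a (rarer) hypermethylation epimutation; exclusion
#'   requires the trio test;
#' * gain of methylation with dosage gain: duplication of the methylated
#'   allele;
#' * normal/low methylation with dosage gain: duplication of the
#'   unmethylated allele;
#' * dosage loss: deletion.
#'
#' Ordering encodes prior plausibility only; hypotheses are never
#' suppressed.
#'
#' @param methylation_class One of `"NORMAL"`, `"PARTIAL_LOM"`,
#'   `"COMPLETE_LOM"`, `"GOM"`.
#' @param dosage_class One of `"NORMAL"`, `"GAIN"`, `"LOSS"`.
#' @param methylated_parent `"maternal"` or `"paternal"`.
#' @return Ordered character vector of mechanism labels (possibly empty).
#' @export
mechanism_hypotheses <- function(methylation_class, dosage_class,
                                 methylated_parent) {
  upd_meth <- if (methylated_parent == "maternal") "UPD_MATERNAL"
              else "UPD_PATERNAL"
  upd_unmeth <- if (methylated_parent == "maternal") "UPD_PATERNAL"
                else "UPD_MATERNAL"
  if (dosage_class == "LOSS") return("CNV_DEL")
  if (dosage_class == "GAIN") {
    if (methylation_class == "GOM") return("CNV_DUP_METHYLATED_ALLELE")
    return("CNV_DUP_UNMETHYLATED_ALLELE")
  }
  switch(methylation_class,
    NORMAL = character(0),
    PARTIAL_LOM = c("EPIMUTATION", upd_unmeth),
    COMPLETE_LOM = c(upd_unmeth, "EPIMUTATION"),
    GOM = c(upd_meth, "EPIMUTATION")
  )
}

#' Classify per-locus measurements into epigenotype calls
#'
#' Applies the normal-range rule to the methylation value `M` (NORMAL within
#' the range inclusive; PARTIAL_LOM between `complete_loss_max` and the
#' lower bound; COMPLETE_LOM at or below `complete_loss_max`; GOM above the
#' upper bound) and to the dosage value `D` (NORMAL / GAIN / LOSS on the
#' same range), attaches ordered mechanism hypotheses, the syndrome
#' associated with the observed methylation change, and a confirmation
#' recommendation (orthogonal methylation assay plus microsatellite
#' segregation) for every non-normal call.
#'
#' @param measurements Output of [measure_loci()].
#' @param panel An [imprint_panel].
#' @param range A [normal_range()].
#' @return `measurements` with added columns `methylation_class`,
#'   `dosage_class`, `chrom`, `mechanisms` (list column), `syndrome`,
#'   `recommendation`.
#' @export
classify_loci <- function(measurements, panel, range = normal_range()) {
  dmr <- panel %>% filter(.data$kind == "DMR") %>%
    select("locus", "chrom_band", "methylated_parent",
           "hypo_syndrome", "hyper_syndrome")
  unknown <- setdiff(unique(measurements$locus), dmr$locus)
  if (length(unknown) > 0) {
    stop_imprint(
      paste0("Measurement locus not in panel: ",
             paste(unknown, collapse = ", ")),
      "imprintscan_error_validation"
    )
  }
  measurements %>%
    left_join(dmr, by = "locus") %>%
    mutate(
      methylation_class = methylation_class_of(.data$M, range),
      dosage_class = dosage_class_of(.data$D, range),
      chrom = chrom_from_band(.data$chrom_band),
      mechanisms = purrr::pmap(
        list(.data$methylation_class, .data$dosage_class,
             .data$methylated_parent),
        mechanism_hypotheses
      ),
      syndrome = case_when(
        .data$methylation_class %in% c("PARTIAL_LOM", "COMPLETE_LOM") ~
          .data$hypo_syndrome,
        .data$methylation_class == "GOM" ~ .data$hyper_syndrome,
        TRUE ~ NA_character_
      ),
      recommendation = ifelse(
        .data$methylation_class != "NORMAL" | .data$dosage_class != "NORMAL",
        "Confirm by MS-MLPA and microsatellite segregation analysis of the trio",
        ""
      )
    ) %>%
    select(-"hypo_syndrome", -"hyper_syndrome", -"chrom_band")
}

methylation_class_of <- function(M, range) {
  case_when(
    M <= range$complete_loss_max ~ "COMPLETE_LOM",
    M < range$low ~ "PARTIAL_LOM",
    M <= range$high ~ "NORMAL",
    TRUE ~ "GOM"
  )
}

dosage_class_of <- function(D, range) {
  case_when(
    D < range$low ~ "LOSS",
    D <= range$high ~ "NORMAL",
    TRUE ~ "GAIN"
  )
}

#' Screen samples: per-locus calls plus sample-level summary
#'
#' Classifies every measured DMR locus and summarises per sample. A sample
#' is POSITIVE when its methylation value is outside the normal range at
#' any locus (screen positivity is keyed to methylation, the quantity the
#' screen is designed around; dosage abnormalities are still classified and
#' reported per locus). A sample with abnormal methylation at two or more
#' loci is flagged as a multilocus-methylation-defect candidate.
#'
#' @param measurements Output of [measure_loci()]; every sample must cover
#'   every DMR locus of the panel.
#' @param panel An [imprint_panel].
#' @param range A [normal_range()].
#' @return A list with elements `calls` (per-locus tibble, including
#'   `multilocus_candidate`) and `samples` (per-sample tibble with
#'   `n_meth_abnormal`, `n_dosage_abnormal`, `positive`,
#'   `multilocus_candidate`).
#' @export
screen_samples <- function(measurements, panel, range = normal_range()) {
  loci <- panel$locus[panel$kind == "DMR"]
  coverage <- measurements %>%
    distinct(.data$sample_id, .data$locus) %>%
    group_by(.data$sample_id) %>%
    summarise(missing = list(setdiff(loci, .data$locus)), .groups = "drop") %>%
    filter(lengths(.data$missing) > 0)
  if (nrow(coverage) > 0) {
    stop_imprint(
      paste0("Incomplete screen for sample ", coverage$sample_id[1],
             ": missing locus/loci ",
             paste(coverage$missing[[1]], collapse = ", ")),
      "imprintscan_error_incomplete"
    )
  }
  calls <- classify_loci(measurements, panel, range)
  samples <- calls %>%
    group_by(.data$sample_id) %>%
    summarise(
      n_meth_abnormal = sum(.data$methylation_class != "NORMAL"),
      n_dosage_abnormal = sum(.data$dosage_class != "NORMAL"),
      .groups = "drop"
    ) %>%
    mutate(positive = .data$n_meth_abnormal > 0,
           multilocus_candidate = .data$n_meth_abnormal >= 2)
  calls <- calls %>%
    left_join(samples %>% select("sample_id", "multilocus_candidate"),
              by = "sample_id")
  list(calls = calls, samples = samples)
}

#' Reconcile epigenotype calls with trio UPD verdicts
#'
#' Methylation calls are made blind to the trio results and then
#' reconciled: a BIPARENTAL verdict on the chromosome of a locus removes
#' the UPD hypotheses from that locus's mechanism list (epimutation is
#' confirmed by exclusion); a UPD verdict matching one of the hypotheses
#' marks it confirmed and moves it to the head of the list. Calls at loci on
#' other chromosomes, and normal calls, are unchanged.
#'
#' @param calls The `calls` tibble from [screen_samples()].
#' @param upd A tibble of UPD verdicts (see [call_upd()]) with columns
#'   `trio_id`, `chrom`, `verdict`; `trio_id` is matched against
#'   `sample_id`.
#' @return `calls` with added columns `upd_verdict` and
#'   `confirmed_mechanism`, and mechanism lists updated.
#' @export
reconcile_with_upd <- function(calls, upd) {
  calls$upd_verdict <- NA_character_
  if (!"confirmed_mechanism" %in% names(calls)) {
    calls$confirmed_mechanism <- NA_character_
  }
  for (i in seq_len(nrow(upd))) {
    sample <- upd$trio_id[i]
    chrom <- as.character(upd$chrom[i])
    verdict <- upd$verdict[i]
    hit <- which(calls$sample_id == sample & calls$chrom == chrom)
    if (length(hit) == 0) {
      if (any(calls$sample_id == sample)) {
        stop_imprint(
          paste0("UPD verdict for trio ", sample, " is on chromosome ",
                 chrom, ", which carries none of the sample's loci."),
          "imprintscan_error_mismatch"
        )
      }
      next
    }
    for (j in hit) {
      calls$upd_verdict[j] <- verdict
      mech <- calls$mechanisms[[j]]
      if (length(mech) == 0) next
      if (verdict == "BIPARENTAL") {
        kept <- mech[!mech %in% c("UPD_MATERNAL", "UPD_PATERNAL")]
        calls$mechanisms[[j]] <- kept
        if (identical(kept, "EPIMUTATION")) {
          calls$confirmed_mechanism[j] <- "EPIMUTATION"
        }
      } else if (verdict %in% mech) {
        calls$mechanisms[[j]] <- c(verdict, setdiff(mech, verdict))
        calls$confirmed_mechanism[j] <- verdict
      }
    }
  }
  calls
}
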