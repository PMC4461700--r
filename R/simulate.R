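#' Default (normal) epigenotype table for a panel
#'
#' One row per DMR locus with biparental copy number 1/1 and full
#' methylation on the normally methylated parental allele, none on the
#' other — the molecular state the control cohort is assumed to share.
#'
#' @param panel An [imprint_panel].
#' @return A tibble `locus, cn_maternal, cn_paternal, meth_maternal,
#'   meth_paternal`.
#' @export
normal_epigenotypes <- function(panel) {
  panel %>%
    filter(.data$kind == "DMR") %>%
    transmute(
      locus = .data$locus,
      cn_maternal = 1L, cn_paternal = 1L,
      meth_maternal = as.numeric(.data$methylated_parent == "maternal"),
      meth_paternal = as.numeric(.data$methylated_parent == "paternal")
    )
}

#' Amplifiable template copies per condition
#'
#' In the undigested aliquot every copy amplifies:
#' `cn_maternal + cn_paternal`. In the digested aliquot only methylated
#' copies survive the methylation-sensitive digest, plus the unmethylated
#' copies spared by incomplete digestion:
#' `cn_m * meth_m + cn_p * meth_p + (1 - dc) * (unmethylated copies)`.
#' A mosaic loss of methylation in a fraction `c` of cells enters as
#' `meth = 1 - c` on the normally methylated allele.
#'
#' @param epigenotypes A tibble as from [normal_epigenotypes()].
#' @param condition `"digested"` or `"undigested"`.
#' @param digestion_completeness Fraction of unmethylated template actually
#'   cut (default 1 = complete digestion).
#' @return Numeric vector of template copy numbers, one per row.
#' @export
expected_template <- function(epigenotypes,
                              condition = c("digested", "undigested"),
                              digestion_completeness = 1) {
  condition <- match.arg(condition)
  cn_m <- epigenotypes$cn_maternal
  cn_p <- epigenotypes$cn_paternal
  if (condition == "undigested") return(cn_m + cn_p)
  methylated <- cn_m * epigenotypes$meth_maternal +
    cn_p * epigenotypes$meth_paternal
  unmethylated <- (cn_m + cn_p) - methylated
  methylated + (1 - digestion_completeness) * unmethylated
}

#' Simulate the peak records of one digested/undigested sample pair
#'
#' Realizes the measurement chain of the assay: each amplicon's peak area
#' is its amplification efficiency times its amplifiable template copies
#' times a sample loading factor, under multiplicative lognormal noise.
#' Reference amplicons carry no methylation-sensitive site and amplify
#' from 2 template copies in both aliquots — the structural assumption
#' that makes the relative-area statistic meaningful. With
#' `noise_sigma = 0` the output is exactly deterministic.
#'
#' @param panel An [imprint_panel].
#' @param sample_id Sample identifier.
#' @param epigenotypes Per-locus epigenotype tibble; defaults to
#'   [normal_epigenotypes()]; loci not listed get normal defaults.
#' @param loading_factor Positive per-sample scale (input DNA amount).
#' @param noise_sigma Lognormal sigma of per-peak noise (>= 0).
#' @param digestion_completeness See [expected_template()].
#' @param efficiencies Named vector of per-amplicon efficiencies
#'   (default 1 for all).
#' @return A peak tibble (`sample_id, condition, size, height, area,
#'   amplicon`), valid input for [pair_runs()].
#' @export
simulate_sample_pair <- function(panel, sample_id = "S1",
                                 epigenotypes = NULL,
                                 loading_factor = 1, noise_sigma = 0,
                                 digestion_completeness = 1,
                                 efficiencies = NULL) {
  spec <- normal_epigenotypes(panel)
  if (!is.null(epigenotypes)) {
    spec <- spec %>%
      rows_update(as_tibble(epigenotypes), by = "locus")
  }
  if (is.null(efficiencies)) {
    efficiencies <- setNames(rep(1, nrow(panel)), panel$name)
  }
  purrr::map_dfr(.CONDITIONS, function(cond) {
    template <- ifelse(
      panel$kind == "REFERENCE", 2,
      expected_template(spec, cond, digestion_completeness)[
        match(panel$locus, spec$locus)]
    )
    noise <- if (noise_sigma > 0) {
      exp(rnorm(nrow(panel), 0, noise_sigma))
    } else rep(1, nrow(panel))
    area <- efficiencies[panel$name] * template * loading_factor * noise
    out <- tibble(
      sample_id = sample_id, condition = cond,
      size = panel$expected_size,
      height = unname(area) / 10, area = unname(area),
      amplicon = panel$name
    )
    # an instrument reports no peak at all for zero template; the pairing
    # step records such amplicons as area 0 with a missing-peak flag
    out[out$area > 0, ]
  })
}

#' The five positive-patient archetypes of the default panel
#'
#' Epigenotype specifications reproducing the five alteration archetypes
#' the screen is built to detect, as overrides of the normal state:
#'
#' * `P1`: 80% mosaic loss of methylation at KCNQ1OT1
#'   (`meth_maternal = 0.2`), normal copy number;
#' * `P2`: paternal 11p15 duplication covering both H19 and KCNQ1OT1
#'   (`cn_paternal = 2` at both loci) — H19 hypermethylation with dosage
#'   gain, KCNQ1OT1 normal methylation with dosage gain;
#' * `P3`: 40% mosaic loss of methylation at SNRPN (`meth_maternal = 0.6`);
#' * `P4`: paternal UPD(14) at MEG3 (`cn_maternal = 0, cn_paternal = 2`)
#'   — hypermethylation with normal dosage;
#' * `P5`: maternal UPD(14) at MEG3 (`cn_maternal = 2, cn_paternal = 0`)
#'   — complete loss of methylation with normal dosage.
#'
#' @param panel An [imprint_panel] containing the four loci.
#' @return A named list of epigenotype override tibbles, usable as
#'   `patient_specs` in [simulate_cohort()].
#' @export
patients_table1 <- function(panel = default_panel()) {
  base <- normal_epigenotypes(panel)
  override <- function(locus, ...) {
    row <- base %>% filter(.data$locus %in% !!locus)
    mutate(row, ...)
  }
  list(
    P1 = override("KCNQ1OT1", meth_maternal = 0.2),
    P2 = override(c("H19", "KCNQ1OT1"), cn_paternal = 2L),
    P3 = override("SNRPN", meth_maternal = 0.6),
    P4 = override("MEG3", cn_maternal = 0L, cn_paternal = 2L),
    P5 = override("MEG3", cn_maternal = 2L, cn_paternal = 0L)
  )
}

#' Simulate a screening cohort
#'
#' Generates the peak table of `n_patients` patients plus `n_controls`
#' control samples, with per-sample lognormal loading factors and
#' multiplicative per-peak noise, and a truth table recording every
#' patient's true epigenotype (copy numbers, per-allele methylation, and
#' the mosaic loss fraction on the normally methylated allele) for
#' recovery scoring. Deterministic given `seed`.
#'
#' @param panel An [imprint_panel].
#' @param n_patients,n_controls Cohort sizes.
#' @param patient_specs Named list (names = patient sample ids) of
#'   epigenotype override tibbles, e.g. [patients_table1()].
#' @param noise_sigma Per-peak lognormal sigma (default 0.05).
#' @param loading_sdlog Lognormal sdlog of per-sample loading factors
#'   (default 0.3; loading cancels out of the statistic).
#' @param digestion_completeness See [expected_template()].
#' @param efficiencies Named per-amplicon efficiencies (default: all 1).
#' @param seed Integer seed (mandatory; no wall-clock seeding).
#' @return A list with `peaks` (assigned peak tibble), `truth` (per
#'   patient x locus: `cn_maternal, cn_paternal, meth_maternal,
#'   meth_paternal, mosaic_loss`), and `controls` (control sample ids).
#' @export
simulate_cohort <- function(panel, n_patients, n_controls = 20,
                            patient_specs = list(), noise_sigma = 0.05,
                            loading_sdlog = 0.3,
                            digestion_completeness = 1,
                            efficiencies = NULL, seed) {
  if (missing(seed)) {
    stop_imprint("simulate_cohort() requires an explicit seed.",
                 "imprintscan_error_validation")
  }
  set.seed(seed)
  control_ids <- sprintf("C%03d", seq_len(n_controls))
  patient_ids <- sprintf("P%03d", seq_len(n_patients))
  unknown <- setdiff(names(patient_specs), patient_ids)
  if (length(unknown) > 0) {
    stop_imprint(paste0("patient_specs name(s) not in the cohort: ",
                        paste(unknown, collapse = ", ")),
                 "imprintscan_error_validation")
  }
  all_ids <- c(control_ids, patient_ids)
  empty_peaks <- tibble(sample_id = character(), condition = character(),
                        size = numeric(), height = numeric(),
                        area = numeric(), amplicon = character())
  empty_truth <- tibble(sample_id = character(), locus = character(),
                        cn_maternal = integer(), cn_paternal = integer(),
                        meth_maternal = numeric(), meth_paternal = numeric(),
                        mosaic_loss = numeric())
  if (length(all_ids) == 0) {
    return(list(peaks = empty_peaks, truth = empty_truth,
                controls = control_ids))
  }
  loadings <- setNames(exp(rnorm(length(all_ids), 0, loading_sdlog)),
                       all_ids)
  base <- normal_epigenotypes(panel)
  spec_of <- function(id) {
    if (id %in% names(patient_specs)) {
      base %>% rows_update(as_tibble(patient_specs[[id]]), by = "locus")
    } else base
  }
  peaks <- purrr::map_dfr(all_ids, function(id) {
    simulate_sample_pair(
      panel, sample_id = id,
      epigenotypes = if (id %in% patient_ids) spec_of(id) else base,
      loading_factor = loadings[[id]], noise_sigma = noise_sigma,
      digestion_completeness = digestion_completeness,
      efficiencies = efficiencies
    )
  })
  meth_parent <- panel %>% filter(.data$kind == "DMR") %>%
    select("locus", "methylated_parent")
  if (length(patient_ids) == 0) {
    return(list(peaks = peaks, truth = empty_truth, controls = control_ids))
  }
  truth <- purrr::map_dfr(patient_ids, function(id) {
    mutate(spec_of(id), sample_id = id, .before = 1)
  }) %>%
    left_join(meth_parent, by = "locus") %>%
    mutate(mosaic_loss = 1 - ifelse(.data$methylated_parent == "maternal",
                                    .data$meth_maternal,
                                    .data$meth_paternal)) %>%
    select(-"methylated_parent")
  list(peaks = peaks, truth = truth, controls = control_ids)
}

#' Simulate trio microsatellite genotypes under an inheritance scenario
#'
#' Parents are drawn from `n_alleles` equifrequent alleles at each of
#' `n_markers` independent markers; the child is constructed per scenario:
#' `biparental` (one allele from each parent), `upd_mat_iso` /
#' `upd_pat_iso` (two copies of one homologue of that parent),
#' `upd_mat_het` / `upd_pat_het` (both homologues of that parent), or
#' `dup_triallelic` (both maternal homologues plus one paternal allele —
#' three distinct alleles whenever the drawn parental genotypes permit).
#'
#' @param scenario Inheritance scenario, see above.
#' @param n_markers Number of markers (default 12).
#' @param n_alleles Number of equifrequent alleles per marker (default 8;
#'   see [upd_marker_power()] for why the defaults are this large).
#' @param seed Optional integer seed.
#' @param trio_id,chrom Identifiers carried into the output.
#' @return A trio genotype tibble (same shape as
#'   [read_trio_genotypes()]).
#' @export
simulate_trio <- function(scenario = c("biparental", "upd_mat_iso",
                                       "upd_mat_het", "upd_pat_iso",
                                       "upd_pat_het", "dup_triallelic"),
                          n_markers = 12, n_alleles = 8, seed = NULL,
                          trio_id = "T1", chrom = "14") {
  scenario <- match.arg(scenario)
  if (n_alleles < 2) {
    stop_imprint("n_alleles must be >= 2.", "imprintscan_error_validation")
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function() as.character(sample.int(n_alleles, 2, replace = TRUE))
  rows <- purrr::map(seq_len(n_markers), function(i) {
    mother <- draw()
    father <- draw()
    child <- switch(scenario,
      biparental = c(sample(mother, 1), sample(father, 1)),
      upd_mat_iso = rep(sample(mother, 1), 2),
      upd_pat_iso = rep(sample(father, 1), 2),
      upd_mat_het = mother,
      upd_pat_het = father,
      dup_triallelic = c(mother, sample(father, 1))
    )
    tibble(trio_id = trio_id, marker = sprintf("M%02d", i), chrom = chrom,
           mother = list(mother), father = list(father),
           child = list(child))
  })
  bind_rows(rows) %>%
    mutate(
      mother_missing = FALSE, father_missing = FALSE, child_missing = FALSE,
      child_triallelic =
        purrr::map_int(.data$child, ~ length(unique(.x))) == 3
    )
}
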