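one_sample_pairs <- function(d = c(dmr = 200, ref1 = 500, ref2 = 300),
                             u = d, id = "S1") {
  args <- list(list(digested = d, undigested = u))
  names(args) <- id
  do.call(make_pairs, args)
}

test_that("relative areas match hand arithmetic in both denominator modes", {
  panel <- mini_panel()
  pairs <- one_sample_pairs()
  all_mode <- relative_areas(pairs, panel, "all_peaks")
  dig <- dplyr::filter(all_mode, condition == "digested")
  expect_equal(dig$rel[match(c("dmr", "ref1", "ref2"), dig$amplicon)],
               c(0.2, 0.5, 0.3))
  ref_mode <- relative_areas(pairs, panel, "reference_only")
  dig <- dplyr::filter(ref_mode, condition == "digested")
  expect_equal(dig$rel[match(c("dmr", "ref1", "ref2"), dig$amplicon)],
               c(0.25, 0.625, 0.375))
})

test_that("relative areas are invariant to global rescaling of a sample", {
  panel <- mini_panel()
  a <- relative_areas(one_sample_pairs(), panel, "all_peaks")
  b <- relative_areas(one_sample_pairs(d = 10 * c(dmr = 200, ref1 = 500,
                                                  ref2 = 300)),
                      panel, "all_peaks")
  expect_equal(a$rel, b$rel)
})

test_that("an all-zero denominator is a degenerate-sample error", {
  panel <- mini_panel()
  pairs <- one_sample_pairs(d = c(dmr = 5, ref1 = 0, ref2 = 0))
  expect_error(relative_areas(pairs, panel, "reference_only"),
               class = "imprintscan_error_degenerate")
})

test_that("the baseline is the arithmetic mean of control profiles with CV", {
  panel <- mini_panel()
  ctrl <- normal_controls(panel, n = 5)
  base <- build_baseline(ctrl, panel)
  one <- relative_areas(dplyr::filter(ctrl, sample_id == "C1"), panel)
  joined <- dplyr::left_join(one, as_tibble(base),
                             by = c("condition", "amplicon"))
  expect_equal(joined$rel, joined$mean_rel)
  expect_true(all(base$cv == 0))
  expect_equal(attr(base, "n_controls"), 5)
})

test_that("CV is population dispersion over mean (two-control example)", {
  panel <- mini_panel()
  # rel(dmr, digested) = 0.2 for C1 and 0.3 for C2 with references at 1000
  pairs <- make_pairs(
    C1 = list(digested = c(dmr = 200, ref1 = 500, ref2 = 500),
              undigested = c(dmr = 400, ref1 = 500, ref2 = 500)),
    C2 = list(digested = c(dmr = 300, ref1 = 600, ref2 = 400),
              undigested = c(dmr = 400, ref1 = 500, ref2 = 500))
  )
  base <- build_baseline(pairs, panel, min_controls = 2)
  row <- dplyr::filter(base, condition == "digested", amplicon == "dmr")
  expect_equal(row$mean_rel, 0.25)
  expect_equal(row$cv, 0.2)
})

test_that("too few controls errors unless overridden, then flags propagate", {
  panel <- mini_panel()
  ctrl <- normal_controls(panel, n = 3)
  expect_error(build_baseline(ctrl, panel),
               class = "imprintscan_error_controls")
  base <- build_baseline(ctrl, panel, allow_low_n = TRUE)
  expect_true(attr(base, "low_control_n"))
  m <- measure_loci(ctrl, base, panel)
  expect_true(all(m$low_control_n))
})

test_that("a control amplicon with zero mean cannot normalize", {
  panel <- mini_panel()
  pairs <- purrr::map_dfr(1:5, function(i) {
    one_sample_pairs(d = c(dmr = 0, ref1 = 500, ref2 = 300),
                     id = paste0("C", i))
  })
  expect_error(build_baseline(pairs, panel),
               class = "imprintscan_error_baseline")
})

test_that("normalization against the baseline is idempotent and linear", {
  panel <- mini_panel()
  ctrl <- normal_controls(panel, n = 5)
  base <- build_baseline(ctrl, panel)
  m <- measure_loci(dplyr::filter(ctrl, sample_id == "C3"), base, panel)
  expect_equal(m$M, 1)
  expect_equal(m$D, 1)
  expect_equal(m$percent_loss, 0)
  expect_equal(m$percent_gain, 0)
  # 0.05 against a baseline mean of 0.25 normalizes to 0.2
  rel <- relative_areas(one_sample_pairs(), panel, "reference_only")
  fake_base <- structure(
    tibble(condition = rep(c("digested", "undigested"), each = 3),
           amplicon = rep(c("dmr", "ref1", "ref2"), 2),
           mean_rel = 0.25, cv = 0),
    class = c("imprint_baseline", class(tibble())),
    mode = "reference_only", n_controls = 5, low_control_n = FALSE)
  norm <- normalize_profile(rel, fake_base)
  expect_equal(norm$norm, norm$rel / 0.25)
  # amplicon absent from the baseline is an error
  rel_extra <- rel
  rel_extra$amplicon[1] <- "ghost"
  expect_error(normalize_profile(rel_extra, fake_base),
               class = "imprintscan_error_baseline")
})

test_that("noise-free mosaic loss and copy number are recovered exactly", {
  panel <- mini_panel()
  ctrl <- normal_controls(panel, n = 5)
  base <- build_baseline(ctrl, panel)
  for (c_frac in seq(0, 1, by = 0.1)) {
    peaks <- simulate_sample_pair(panel, "P",
      epigenotypes = tibble(locus = "KCNQ1OT1", cn_maternal = 1L,
                            cn_paternal = 1L, meth_maternal = 1 - c_frac,
                            meth_paternal = 0))
    m <- measure_loci(pair_runs(peaks, panel), base, panel)
    expect_equal(m$M, 1 - c_frac, tolerance = 1e-12)
    expect_equal(m$D, 1, tolerance = 1e-12)
    expect_equal(m$percent_loss, 100 * c_frac, tolerance = 1e-9)
  }
  for (cn_m in 0:3) for (cn_p in 0:3) {
    if (cn_m + cn_p == 0) next
    peaks <- simulate_sample_pair(panel, "P",
      epigenotypes = tibble(locus = "KCNQ1OT1",
                            cn_maternal = as.integer(cn_m),
                            cn_paternal = as.integer(cn_p),
                            meth_maternal = 1, meth_paternal = 0))
    m <- measure_loci(pair_runs(peaks, panel), base, panel)
    expect_equal(m$D, (cn_m + cn_p) / 2, tolerance = 1e-12)
    if (m$D > 0) expect_equal(m$M_per_copy * m$D, m$M, tolerance = 1e-9)
  }
})

test_that("complete deletion yields D = 0 and a flagged M_per_copy of 0", {
  panel <- mini_panel()
  ctrl <- normal_controls(panel, n = 5)
  base <- build_baseline(ctrl, panel)
  peaks <- simulate_sample_pair(panel, "P",
    epigenotypes = tibble(locus = "KCNQ1OT1", cn_maternal = 0L,
                          cn_paternal = 0L, meth_maternal = 1,
                          meth_paternal = 0))
  m <- measure_loci(pair_runs(peaks, panel), base, panel)
  expect_equal(m$D, 0)
  expect_equal(m$M_per_copy, 0)
  expect_true(m$degenerate_dosage)
  expect_true(m$missing_peak)
})

test_that("the all-peaks denominator inflates M upward of reference-only", {
  panel <- mini_panel()
  ctrl <- normal_controls(panel, n = 5)
  lom <- tibble(locus = "KCNQ1OT1", cn_maternal = 1L, cn_paternal = 1L,
                meth_maternal = 0.2, meth_paternal = 0)
  pairs <- pair_runs(simulate_sample_pair(panel, "P", epigenotypes = lom),
                     panel)
  m_ref <- measure_loci(pairs, build_baseline(ctrl, panel,
                                              "reference_only"), panel)
  m_all <- measure_loci(pairs, build_baseline(ctrl, panel, "all_peaks"),
                        panel)
  expect_gte(m_all$M, m_ref$M)
  expect_equal(m_ref$M, 0.2, tolerance = 1e-12)
})

test_that("loading factors and global efficiency scaling cancel out", {
  panel <- mini_panel()
  ctrl <- normal_controls(panel, n = 5)
  base <- build_baseline(ctrl, panel)
  lom <- tibble(locus = "KCNQ1OT1", cn_maternal = 1L, cn_paternal = 1L,
                meth_maternal = 0.4, meth_paternal = 0)
  m1 <- measure_loci(pair_runs(
    simulate_sample_pair(panel, "P", epigenotypes = lom), panel),
    base, panel)
  m2 <- measure_loci(pair_runs(
    simulate_sample_pair(panel, "P", epigenotypes = lom,
                         loading_factor = 37.5), panel),
    base, panel)
  eff <- setNames(c(0.5, 2, 1.3), c("dmr", "ref1", "ref2"))
  ctrl_eff <- pair_runs(purrr::map_dfr(paste0("E", 1:5), function(id) {
    simulate_sample_pair(panel, id, efficiencies = eff)
  }), panel, controls = paste0("E", 1:5))
  m3 <- measure_loci(pair_runs(
    simulate_sample_pair(panel, "P", epigenotypes = lom,
                         efficiencies = eff), panel),
    build_baseline(ctrl_eff, panel), panel)
  expect_equal(m1$M, m2$M, tolerance = 1e-12)
  expect_equal(m1$D, m2$D, tolerance = 1e-12)
  expect_equal(m1$M, m3$M, tolerance = 1e-12)
  expect_equal(m1$D, m3$D, tolerance = 1e-12)
})

test_that("incomplete digestion inflates M by the closed-form amount", {
  panel <- mini_panel()
  ctrl <- normal_controls(panel, n = 5) # complete digestion controls
  base <- build_baseline(ctrl, panel)
  dc <- 0.9
  lom <- tibble(locus = "KCNQ1OT1", cn_maternal = 1L, cn_paternal = 1L,
                meth_maternal = 0.2, meth_paternal = 0)
  m <- measure_loci(pair_runs(
    simulate_sample_pair(panel, "P", epigenotypes = lom,
                         digestion_completeness = dc), panel),
    base, panel)
  # methylated template 0.2, unmethylated 1.8, control digested template 1
  expect_equal(m$M, 0.2 + (1 - dc) * 1.8 / 1, tolerance = 1e-12)
})

test_that("few normal samples leave the normal range under assay-scale noise", {
  panel <- default_panel()
  n <- 500
  cohort <- simulate_cohort(panel, n_patients = n, n_controls = 20,
                            noise_sigma = 0.05, seed = 424242)
  pairs <- pair_runs(cohort$peaks, panel, controls = cohort$controls)
  base <- build_baseline(pairs, panel)
  m <- measure_loci(dplyr::filter(pairs, role == "patient"), base, panel)
  outside <- m %>%
    dplyr::group_by(sample_id) %>%
    dplyr::summarise(out = any(M < 0.8 | M > 1.2 | D < 0.8 | D > 1.2))
  expect_lt(mean(outside$out), 0.05)
})
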