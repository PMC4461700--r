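test_that("single markers classify by transmission pattern", {
  cases <- dplyr::bind_rows(
    trio_row(c("1", "2"), c("3", "4"), c("1", "2"), "a"),
    trio_row(c("1", "2"), c("3", "4"), c("1", "3"), "b"),
    trio_row(c("1", "2"), c("2", "3"), c("2", "2"), "c"),
    trio_row(c("1", "2"), c("3", "4"), c("5", "6"), "d"),
    trio_row(c("1", "2"), c("3", "4"), c("1", "2", "3"), "e"),
    trio_row(character(0), c("3", "4"), c("3", "4"), "f")
  )
  calls <- classify_markers(cases)
  expect_equal(calls$verdict,
               c("MATERNAL_ONLY", "BIPARENTAL", "UNINFORMATIVE",
                 "MENDELIAN_ERROR", "TRIALLELIC", "UNINFORMATIVE"))
  expect_equal(calls$zygosity[1], "HETERO")
})

test_that("marker classification agrees with the transmission-enumeration oracle", {
  genotypes <- all_genotypes(4)
  trios <- purrr::map_dfr(seq_along(genotypes), function(i) {
    purrr::map_dfr(seq_along(genotypes), function(j) {
      purrr::map_dfr(seq_along(genotypes), function(k) {
        trio_row(genotypes[[i]], genotypes[[j]], genotypes[[k]],
                 marker = paste(i, j, k))
      })
    })
  })
  calls <- classify_markers(trios)
  oracle <- purrr::pmap(list(trios$mother, trios$father, trios$child),
                        oracle_marker)
  expect_equal(calls$verdict, purrr::map_chr(oracle, "verdict"))
  expect_equal(calls$zygosity, purrr::map_chr(oracle, "zygosity"))
})

test_that("swapping parents mirrors the verdicts", {
  set.seed(11)
  swap_map <- c(MATERNAL_ONLY = "PATERNAL_ONLY",
                PATERNAL_ONLY = "MATERNAL_ONLY",
                BIPARENTAL = "BIPARENTAL",
                UNINFORMATIVE = "UNINFORMATIVE",
                MENDELIAN_ERROR = "MENDELIAN_ERROR",
                TRIALLELIC = "TRIALLELIC")
  for (i in 1:50) {
    mother <- as.character(sample.int(5, 2, replace = TRUE))
    father <- as.character(sample.int(5, 2, replace = TRUE))
    child <- as.character(sample.int(5, 2, replace = TRUE))
    v1 <- classify_markers(trio_row(mother, father, child))$verdict
    v2 <- classify_markers(trio_row(father, mother, child))$verdict
    expect_equal(v2, unname(swap_map[v1]))
  }
})

test_that("UPD verdicts aggregate marker support with contradiction rules", {
  upd_mat <- call_upd(dplyr::bind_rows(
    mc_row("MATERNAL_ONLY", "HETERO", 3),
    mc_row("MATERNAL_ONLY", "ISO", 2),
    mc_row("UNINFORMATIVE", n = 2)
  ))
  expect_equal(upd_mat$verdict, "UPD_MATERNAL")
  expect_equal(upd_mat$disomy_type, "MIXED")
  expect_equal(upd_mat$n_supporting, 5L)
  expect_equal(upd_mat$n_informative, 5L)

  bip <- call_upd(dplyr::bind_rows(mc_row("BIPARENTAL", n = 4),
                                   mc_row("UNINFORMATIVE")))
  expect_equal(bip$verdict, "BIPARENTAL")

  incons <- call_upd(dplyr::bind_rows(mc_row("MATERNAL_ONLY", "ISO", 2),
                                      mc_row("PATERNAL_ONLY", "ISO", 1)))
  expect_equal(incons$verdict, "INCONSISTENT")

  weak <- call_upd(mc_row("MATERNAL_ONLY", "ISO", 2))
  expect_equal(weak$verdict, "INCONCLUSIVE")

  with_err <- call_upd(dplyr::bind_rows(mc_row("MATERNAL_ONLY", "ISO", 4),
                                        mc_row("MENDELIAN_ERROR")))
  expect_equal(with_err$verdict, "INCONSISTENT")
  expect_equal(with_err$n_mendelian_error, 1L)

  pure_iso <- call_upd(mc_row("MATERNAL_ONLY", "ISO", 3))
  expect_equal(pure_iso$disomy_type, "ISODISOMY")

  expect_error(call_upd(mc_row("BIPARENTAL", n = 0)),
               class = "imprintscan_error_validation")
})

test_that("a UPD verdict is never emitted against an opposite-parent marker", {
  set.seed(21)
  for (i in 1:25) {
    n_mat <- sample(0:6, 1)
    n_pat <- sample(0:2, 1)
    n_bip <- sample(0:3, 1)
    calls <- dplyr::bind_rows(
      if (n_mat > 0) mc_row("MATERNAL_ONLY", "HETERO", n_mat),
      if (n_pat > 0) mc_row("PATERNAL_ONLY", "ISO", n_pat),
      if (n_bip > 0) mc_row("BIPARENTAL", n = n_bip),
      mc_row("UNINFORMATIVE")
    )
    v <- call_upd(calls)$verdict
    if (n_pat > 0) expect_false(v == "UPD_MATERNAL")
    if (n_mat > 0) expect_false(v == "UPD_PATERNAL")
  }
})

test_that("a triallelic marker reports the duplication's parental origin", {
  calls <- classify_markers(
    trio_row(c("1", "2"), c("3", "4"), c("1", "2", "3")))
  expect_equal(calls$verdict, "TRIALLELIC")
  expect_equal(calls$maternal_copies, 2L)
  expect_equal(calls$paternal_copies, 1L)
  # triallelic markers never count toward UPD support
  agg <- call_upd(dplyr::bind_rows(
    classify_markers(purrr::map_dfr(1:2, function(i) {
      trio_row(c("1", "2"), c("3", "4"), c("1", "2", "3"),
               marker = paste0("T", i))
    })),
    mc_row("MATERNAL_ONLY", "HETERO", 2)
  ))
  expect_equal(agg$verdict, "INCONCLUSIVE")
  expect_equal(agg$n_triallelic, 2L)
})

test_that("trio genotype tables parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "trio_id,marker,chrom,mother,father,child",
    "T1,D14S1,14,1/2,3/4,1/2",
    "T1,D14S2,14,1/2,3/4,1/2/3",
    "T1,D14S3,14,-,3/4,3/3",
    "T1,D14S4,14,5,3/4,3/5"
  ), path)
  trios <- read_trio_genotypes(path)
  expect_equal(trios$mother[[1]], c("1", "2"))
  expect_equal(trios$child[[2]], c("1", "2", "3"))
  expect_true(trios$child_triallelic[2])
  expect_true(trios$mother_missing[3])
  expect_equal(trios$mother[[4]], "5")

  out <- withr::local_tempfile(fileext = ".csv")
  write_trio_genotypes(trios, out)
  back <- read_trio_genotypes(out)
  expect_equal(back$mother, trios$mother)
  expect_equal(back$child, trios$child)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trio_id,marker,chrom,mother,father,child",
               "T1,D14S1,14,1/2/3,3/4,1/2"), bad)
  expect_error(read_trio_genotypes(bad), class = "imprintscan_error_parse")
})

test_that("exact panel power matches simulated heterodisomy support rates", {
  pw_small <- upd_marker_power(8, 4, 3)
  pw_default <- upd_marker_power(12, 8, 3)
  expect_gt(pw_default$power, 0.99)
  # an 8-marker, 4-allele panel confirms only about half of het-UPD trios
  expect_lt(pw_small$power, 0.6)
  # cross-check the per-marker support probability by simulation
  set.seed(314)
  trios <- purrr::map_dfr(1:400, function(i) {
    simulate_trio("upd_mat_het", n_markers = 1, n_alleles = 4,
                  trio_id = paste0("T", i))
  })
  frac <- mean(classify_markers(trios)$verdict == "MATERNAL_ONLY")
  expect_equal(frac, pw_small$p_marker, tolerance = 0.15)
})
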