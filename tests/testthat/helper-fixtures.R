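# Shared fixtures: a minimal panel, builders for pair tables, and the
# brute-force transmission-enumeration oracle for trio marker calls.

suppressMessages({
  library(dplyr)
  library(purrr)
  library(tibble)
})

# one DMR + two references; enough structure for the quantification math
mini_panel <- function() {
  imprint_panel(tibble(
    name = c("dmr", "ref1", "ref2"),
    locus = c("KCNQ1OT1", "R1", "R2"),
    expected_size = c(150, 120, 200),
    size_tolerance = 2,
    kind = c("DMR", "REFERENCE", "REFERENCE"),
    chrom_band = c("11p15", "1q1", "2q2"),
    methylated_parent = c("maternal", NA, NA)
  ), name = "mini", version = "t")
}

# hand-build a pairs row set from named area vectors
make_pairs <- function(..., roles = NULL) {
  samples <- list(...)
  map_dfr(names(samples), function(id) {
    s <- samples[[id]]
    tibble(
      sample_id = id,
      role = if (is.null(roles)) "control" else roles[[id]],
      amplicon = names(s$digested),
      digested = unname(s$digested),
      undigested = unname(s$undigested),
      missing_digested = FALSE,
      missing_undigested = FALSE
    )
  })
}

# n identical control pairs for a given panel (noise-free normal samples)
normal_controls <- function(panel, n = 5, prefix = "C") {
  peaks <- map_dfr(seq_len(n), function(i) {
    simulate_sample_pair(panel, sample_id = paste0(prefix, i))
  })
  pair_runs(peaks, panel, controls = paste0(prefix, seq_len(n)))
}

# measurement rows for classification tests
meas_row <- function(sample_id, locus, M, D) {
  tibble(sample_id = sample_id, locus = locus, M = M, D = D,
         M_per_copy = ifelse(D > 0, M / D, 0),
         percent_loss = ifelse(M < 1, 100 * (1 - M), 0),
         percent_gain = ifelse(M > 1, 100 * (M - 1), 0),
         missing_peak = FALSE, degenerate_dosage = D == 0,
         low_control_n = FALSE)
}

# ---- independent oracle for single-marker trio classification ----------
# Enumerates every (maternal transmission, paternal transmission)
# assignment and every single-parent transmission pair, and derives the
# verdict from which explanation classes are non-empty. Deliberately
# different machinery from the package's set logic.
oracle_marker <- function(mother, father, child) {
  if (length(mother) == 0 || length(father) == 0 || length(child) == 0) {
    return(list(verdict = "UNINFORMATIVE", zygosity = NA_character_))
  }
  m <- if (length(mother) == 1) rep(mother, 2) else mother
  f <- if (length(father) == 1) rep(father, 2) else father
  obs <- sort(unique(child))
  if (length(obs) == 3) {
    return(list(verdict = "TRIALLELIC", zygosity = NA_character_))
  }
  gt <- function(a, b) sort(unique(c(a, b)))
  biparental <- FALSE
  for (a in m) for (b in f) {
    if (identical(gt(a, b), obs)) biparental <- TRUE
  }
  mat_only <- FALSE
  for (a in m) for (b in m) {
    if (identical(gt(a, b), obs)) mat_only <- TRUE
  }
  pat_only <- FALSE
  for (a in f) for (b in f) {
    if (identical(gt(a, b), obs)) pat_only <- TRUE
  }
  zyg <- if (length(obs) == 1) "ISO" else "HETERO"
  if (!biparental && !mat_only && !pat_only) {
    list(verdict = "MENDELIAN_ERROR", zygosity = NA_character_)
  } else if (biparental && !mat_only && !pat_only) {
    list(verdict = "BIPARENTAL", zygosity = NA_character_)
  } else if (!biparental && mat_only && !pat_only) {
    list(verdict = "MATERNAL_ONLY", zygosity = zyg)
  } else if (!biparental && pat_only && !mat_only) {
    list(verdict = "PATERNAL_ONLY", zygosity = zyg)
  } else {
    list(verdict = "UNINFORMATIVE", zygosity = NA_character_)
  }
}

# all unordered genotypes (with repetition) over alleles 1..n
all_genotypes <- function(n) {
  g <- list()
  for (i in seq_len(n)) for (j in i:n) {
    g[[length(g) + 1]] <- as.character(c(i, j))
  }
  g
}

trio_row <- function(mother, father, child, marker = "M1",
                     trio_id = "T1", chrom = "14") {
  tibble(trio_id = trio_id, marker = marker, chrom = chrom,
         mother = list(mother), father = list(father), child = list(child),
         mother_missing = length(mother) == 0,
         father_missing = length(father) == 0,
         child_missing = length(child) == 0,
         child_triallelic = length(unique(child)) == 3)
}

# marker-call rows for call_upd tests
mc_row <- function(verdict, zygosity = NA_character_, n = 1,
                   trio_id = "T1", chrom = "14") {
  tibble(trio_id = trio_id, chrom = chrom,
         marker = sprintf("M%d", seq_len(n)),
         verdict = verdict, zygosity = zygosity)
}
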