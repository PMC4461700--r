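#' Read trio microsatellite genotypes
#'
#' CSV with header `trio_id,marker,chrom,mother,father,child`; genotypes
#' are slash-separated allele labels (`"1/2"`, `"102/104"`). Alleles are
#' unordered; a single allele stands for a homozygote. Missing genotypes
#' (empty, `NA`, `"-"`, `"./."`) are allowed and flagged. Parents with more
#' than two alleles are a parse error; a child with three distinct alleles
#' is routed to triallelic (duplication) handling, not an error.
#'
#' @param path CSV file path.
#' @return A tibble with list-columns `mother`, `father`, `child` (character
#'   allele vectors) and flags `mother_missing`, `father_missing`,
#'   `child_missing`, `child_triallelic`.
#' @export
read_trio_genotypes <- function(path) {
  if (!file.exists(path)) {
    stop_imprint(paste0("Trio genotype file not found: ", path),
                 "imprintscan_error_parse")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("trio_id", "marker", "chrom", "mother", "father", "child")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_imprint(
      paste0("Trio table '", path, "' is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      "imprintscan_error_parse"
    )
  }
  parse_gt <- function(x) {
    if (is.na(x) || x %in% c("", "-", "./.", "NA")) return(character(0))
    stringr::str_split_1(x, "/")
  }
  mother <- purrr::map(raw$mother, parse_gt)
  father <- purrr::map(raw$father, parse_gt)
  child <- purrr::map(raw$child, parse_gt)
  bad_parent <- lengths(mother) > 2 | lengths(father) > 2
  if (any(bad_parent)) {
    i <- which(bad_parent)[1]
    stop_imprint(
      paste0("Parent genotype with more than two alleles at marker ",
             raw$marker[i], " (trio ", raw$trio_id[i], ")."),
      "imprintscan_error_parse"
    )
  }
  if (any(lengths(child) > 3)) {
    i <- which(lengths(child) > 3)[1]
    stop_imprint(
      paste0("Child genotype with more than three alleles at marker ",
             raw$marker[i], " (trio ", raw$trio_id[i], ")."),
      "imprintscan_error_parse"
    )
  }
  tibble(
    trio_id = raw$trio_id, marker = raw$marker, chrom = raw$chrom,
    mother = mother, father = father, child = child,
    mother_missing = lengths(mother) == 0,
    father_missing = lengths(father) == 0,
    child_missing = lengths(child) == 0,
    child_triallelic = purrr::map_int(child, ~ length(unique(.x))) == 3
  )
}

#' Write trio genotypes to CSV
#'
#' Inverse of [read_trio_genotypes()]; alleles are joined with `/`.
#'
#' @param trios A trio genotype tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trio_genotypes <- function(trios, path) {
  fmt <- function(g) purrr::map_chr(g, ~ paste(.x, collapse = "/"))
  readr::write_csv(
    tibble(trio_id = trios$trio_id, marker = trios$marker,
           chrom = trios$chrom, mother = fmt(trios$mother),
           father = fmt(trios$father), child = fmt(trios$child)),
    path, progress = FALSE
  )
  invisible(path)
}

# Single-marker transmission logic. Explanations are decided by
# enumeration of (maternal allele, paternal allele) assignments, never by
# parental-heterozygosity shortcuts; when a biparental explanation and a
# single-parent-only explanation coexist the marker is uninformative.
classify_marker_one <- function(mother, father, child) {
  if (length(mother) == 0 || length(father) == 0 || length(child) == 0) {
    return(list(verdict = "UNINFORMATIVE", zygosity = NA_character_,
                maternal_copies = NA_integer_, paternal_copies = NA_integer_))
  }
  if (length(mother) == 1) mother <- rep(mother, 2)
  if (length(father) == 1) father <- rep(father, 2)
  distinct_child <- unique(child)
  if (length(distinct_child) == 3) {
    in_m <- distinct_child %in% mother
    in_f <- distinct_child %in% father
    phaseable <- all(xor(in_m, in_f))
    return(list(
      verdict = "TRIALLELIC", zygosity = NA_character_,
      maternal_copies = if (phaseable) sum(in_m) else NA_integer_,
      paternal_copies = if (phaseable) sum(in_f) else NA_integer_
    ))
  }
  # a multiset with <3 distinct alleles is observed as its distinct peaks
  # (allele dosage from peak ratios is not modeled)
  child <- distinct_child
  if (length(child) == 1) child <- rep(child, 2)
  biparental <- any(
    (child[1] %in% mother & child[2] %in% father) |
    (child[2] %in% mother & child[1] %in% father)
  )
  maternal_only <- all(child %in% mother)
  paternal_only <- all(child %in% father)
  if (!biparental && !maternal_only && !paternal_only) {
    return(list(verdict = "MENDELIAN_ERROR", zygosity = NA_character_,
                maternal_copies = NA_integer_, paternal_copies = NA_integer_))
  }
  if (biparental && !maternal_only && !paternal_only) {
    return(list(verdict = "BIPARENTAL", zygosity = NA_character_,
                maternal_copies = NA_integer_, paternal_copies = NA_integer_))
  }
  if (!biparental && maternal_only) {
    zyg <- if (length(unique(child)) == 1) "ISO" else "HETERO"
    return(list(verdict = "MATERNAL_ONLY", zygosity = zyg,
                maternal_copies = NA_integer_, paternal_copies = NA_integer_))
  }
  if (!biparental && paternal_only) {
    zyg <- if (length(unique(child)) == 1) "ISO" else "HETERO"
    return(list(verdict = "PATERNAL_ONLY", zygosity = zyg,
                maternal_copies = NA_integer_, paternal_copies = NA_integer_))
  }
  # biparental and single-parent explanations coexist
  list(verdict = "UNINFORMATIVE", zygosity = NA_character_,
       maternal_copies = NA_integer_, paternal_copies = NA_integer_)
}

#' Classify trio markers by transmission pattern
#'
#' For every marker of every trio, decides between BIPARENTAL (one allele
#' demonstrably from each parent), MATERNAL_ONLY / PATERNAL_ONLY (the child
#' carries alleles of one parent only and no biparental transmission can
#' explain the genotype — evidence for uniparental disomy, with ISO or
#' HETERO zygosity evidence), UNINFORMATIVE (biparental and uniparental
#' explanations coexist, or a genotype is missing), MENDELIAN_ERROR (no
#' transmission assignment explains the child), and TRIALLELIC (three
#' distinct child alleles — evidence of a duplication; parental-origin
#' copies are counted when every child allele is attributable to exactly
#' one parent, e.g. two maternal plus one paternal).
#'
#' @param trios A trio genotype tibble (see [read_trio_genotypes()] or
#'   [simulate_trio()]).
#' @return `trios` with added columns `verdict`, `zygosity`,
#'   `maternal_copies`, `paternal_copies`.
#' @export
classify_markers <- function(trios) {
  res <- purrr::pmap(
    list(trios$mother, trios$father, trios$child),
    classify_marker_one
  )
  trios %>%
    mutate(
      verdict = purrr::map_chr(res, "verdict"),
      zygosity = purrr::map_chr(res, "zygosity"),
      maternal_copies = purrr::map_int(res, "maternal_copies"),
      paternal_copies = purrr::map_int(res, "paternal_copies")
    )
}

#' Aggregate marker calls into a UPD verdict
#'
#' Per trio and chromosome: UPD_MATERNAL when at least `min_supporting`
#' markers are MATERNAL_ONLY and none is PATERNAL_ONLY (symmetrically for
#' paternal); BIPARENTAL when at least `min_supporting` markers are
#' BIPARENTAL and no single-parent-only marker exists; INCONSISTENT when
#' both single-parent directions occur or Mendelian errors exceed the
#' tolerance (default 0 — unexplained genotypes must surface loudly);
#' otherwise INCONCLUSIVE. The disomy type is ISODISOMY when every
#' supporting marker shows iso evidence, HETERODISOMY when every one shows
#' hetero evidence, MIXED otherwise. TRIALLELIC markers are duplication
#' evidence and never count toward UPD support; their count is reported.
#'
#' @param marker_calls Output of [classify_markers()].
#' @param min_supporting Minimum concordant informative markers for any
#'   aggregate verdict (default 3). See [upd_marker_power()] for how many
#'   markers this demands in practice.
#' @param max_mendelian_errors Tolerated Mendelian-error markers
#'   (default 0).
#' @return A tibble with one row per `trio_id` x `chrom`: `verdict`,
#'   `disomy_type`, `n_informative`, `n_supporting`, `n_triallelic`,
#'   `n_mendelian_error`.
#' @export
call_upd <- function(marker_calls, min_supporting = 3,
                     max_mendelian_errors = 0) {
  if (nrow(marker_calls) == 0) {
    stop_imprint("No marker calls to aggregate.", "imprintscan_error_validation")
  }
  if (!"trio_id" %in% names(marker_calls)) marker_calls$trio_id <- "trio"
  if (!"chrom" %in% names(marker_calls)) marker_calls$chrom <- NA_character_
  marker_calls %>%
    group_by(.data$trio_id, .data$chrom) %>%
    group_modify(function(g, key) {
      call_upd_one(g, min_supporting, max_mendelian_errors)
    }) %>%
    ungroup()
}

call_upd_one <- function(g, min_supporting, max_mendelian_errors) {
  n_mat <- sum(g$verdict == "MATERNAL_ONLY")
  n_pat <- sum(g$verdict == "PATERNAL_ONLY")
  n_bip <- sum(g$verdict == "BIPARENTAL")
  n_err <- sum(g$verdict == "MENDELIAN_ERROR")
  n_tri <- sum(g$verdict == "TRIALLELIC")
  disomy_of <- function(which_verdict) {
    z <- g$zygosity[g$verdict == which_verdict]
    if (all(z == "ISO")) "ISODISOMY"
    else if (all(z == "HETERO")) "HETERODISOMY"
    else "MIXED"
  }
  if ((n_mat > 0 && n_pat > 0) || n_err > max_mendelian_errors) {
    verdict <- "INCONSISTENT"; disomy <- NA_character_; n_sup <- 0L
  } else if (n_mat >= min_supporting && n_pat == 0) {
    verdict <- "UPD_MATERNAL"; disomy <- disomy_of("MATERNAL_ONLY")
    n_sup <- n_mat
  } else if (n_pat >= min_supporting && n_mat == 0) {
    verdict <- "UPD_PATERNAL"; disomy <- disomy_of("PATERNAL_ONLY")
    n_sup <- n_pat
  } else if (n_bip >= min_supporting && n_mat == 0 && n_pat == 0) {
    verdict <- "BIPARENTAL"; disomy <- NA_character_; n_sup <- n_bip
  } else {
    verdict <- "INCONCLUSIVE"; disomy <- NA_character_; n_sup <- 0L
  }
  tibble(
    verdict = verdict, disomy_type = disomy,
    n_informative = n_mat + n_pat + n_bip,
    n_supporting = as.integer(n_sup),
    n_triallelic = n_tri, n_mendelian_error = n_err
  )
}

#' Power of a microsatellite panel to confirm heterodisomy
#'
#' Exact (binomial) probability that a trio panel of `n_markers`
#' microsatellites with `n_alleles` equifrequent alleles yields at least
#' `min_supporting` single-parent-only markers in a true uniparental disomy
#' trio, i.e. the probability that [call_upd()] can reach a UPD verdict.
#' Under heterodisomy a marker supports UPD only when the father shares no
#' allele with the (transmitted) maternal genotype; with few, common
#' alleles that is rare, so small panels are badly underpowered: 8 markers
#' of 4 equifrequent alleles confirm only ~52% of heterodisomy trios,
#' whereas 12 markers of 8 alleles confirm >99%.
#'
#' @param n_markers Number of independent markers typed.
#' @param n_alleles Number of equifrequent alleles per marker.
#' @param min_supporting Support threshold used by [call_upd()].
#' @param disomy `"heterodisomy"` (child carries both homologues of one
#'   parent) or `"isodisomy"` (child homozygous for one homologue).
#' @return A list with `p_marker` (per-marker support probability) and
#'   `power` (probability of reaching the UPD verdict).
#' @export
upd_marker_power <- function(n_markers, n_alleles, min_supporting = 3,
                             disomy = c("heterodisomy", "isodisomy")) {
  disomy <- match.arg(disomy)
  n <- n_alleles
  p_marker <- if (disomy == "heterodisomy") {
    # mother het (prob (n-1)/n): support iff father avoids both her alleles;
    # mother hom (prob 1/n): child hom, support iff father lacks the allele
    ((n - 1) / n) * ((n - 2) / n)^2 + (1 / n) * ((n - 1) / n)^2
  } else {
    # child homozygous for one maternal allele: support iff father lacks it
    ((n - 1) / n)^2
  }
  list(p_marker = p_marker,
       power = 1 - pbinom(min_supporting - 1, n_markers, p_marker))
}
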