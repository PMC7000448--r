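#' Per-patient panel variant filtering
#'
#' Applies the cohort-stage filter to each patient: keeps carried
#' variants that (1) lie in a panel gene, (2) change the coding
#' sequence, and (3) have population frequency strictly below
#' `max_frequency` (default 0.05%); groups survivors per patient and
#' gene into gene hits.
#'
#' @param variants Variant tibble.
#' @param genotypes Genotype tibble (only carrying calls matter; absent
#'   rows are homozygous reference).
#' @param panel A `panel_registry` from [build_panel()].
#' @param freq_table Optional population frequency table; otherwise the
#'   `population_frequency` column is used.
#' @param max_frequency Strict upper frequency bound (fraction).
#' @param treat_missing_frequency_as_pass Whether database-absent
#'   variants pass (default `TRUE`).
#' @param patients Optional patient tibble (`patient_id`, `sex`); a
#'   patient with no genotype calls triggers a warning and contributes
#'   an empty hit set.
#' @return A `gene_hits` tibble: `patient_id`, `gene`, `categories`,
#'   `known_modes`, `modifier_only`, `n_variants`, `zygosities`,
#'   `variants` (list column of the supporting variant records).
#' @export
patient_filter <- function(variants, genotypes, panel, freq_table = NULL,
                           max_frequency = 0.0005,
                           treat_missing_frequency_as_pass = TRUE,
                           patients = NULL) {
  assert_variants(variants)
  if (!is.null(patients)) {
    silent <- setdiff(patients$patient_id, unique(genotypes$sample_id))
    if (length(silent) > 0) {
      warn(paste0(
        "patient(s) with zero genotype calls: ", paste(silent, collapse = ", ")
      ))
    }
  }
  f <- lookup_frequency(variants, freq_table)
  keep <- variants$gene %in% panel$symbol &
    variants$consequence %in% coding_consequences() &
    ifelse(is.na(f), treat_missing_frequency_as_pass, f < max_frequency)
  v <- variants[keep, ]
  v$population_frequency <- f[keep]

  empty <- tibble(
    patient_id = character(), gene = character(), categories = character(),
    known_modes = character(), modifier_only = logical(),
    n_variants = integer(), zygosities = character(), variants = list()
  )
  if (nrow(v) == 0 || nrow(genotypes) == 0) {
    return(structure(empty, class = c("gene_hits", class(empty))))
  }

  calls <- genotypes[carries_alt(genotypes$zygosity), ]
  joined <- dplyr::inner_join(
    calls, v,
    by = c("chrom", "pos", "ref", "alt"), relationship = "many-to-many"
  )
  if (nrow(joined) == 0) {
    return(structure(empty, class = c("gene_hits", class(empty))))
  }
  hits <- joined |>
    dplyr::group_by(patient_id = .data$sample_id, .data$gene) |>
    dplyr::summarise(
      n_variants = dplyr::n_distinct(paste(.data$chrom, .data$pos, .data$ref, .data$alt)),
      zygosities = paste(sort(.data$zygosity), collapse = ","),
      variants = list(dplyr::pick(
        "chrom", "pos", "ref", "alt", "consequence", "protein_change",
        "population_frequency", "zygosity"
      )),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(
        as_tibble(panel), gene = "symbol", "categories", "known_modes",
        "modifier_only"
      ),
      by = "gene"
    ) |>
    dplyr::select(
      "patient_id", "gene", "categories", "known_modes", "modifier_only",
      "n_variants", "zygosities", "variants"
    )
  structure(hits, class = c("gene_hits", class(empty)))
}

#' Check a gene hit against the gene's known inheritance modes
#'
#' Adds `inheritance_consistent` and `consistency_reason` columns.
#' Dominant genes are satisfied by a single heterozygous variant;
#' recessive genes require a homozygous variant or at least two distinct
#' variants (accepted phase-unaware and noted as such); X-linked
#' recessive genes require a hemizygous call in males or homozygous in
#' females; a gene of unknown mode is consistent by default.
#'
#' @param hits A `gene_hits` tibble.
#' @param patients Optional patient tibble with `sex` (used for X-linked
#'   genes; hemizygous evidence implies male when sex is unknown).
#' @return `hits` with the two consistency columns added.
#' @export
inheritance_consistency <- function(hits, patients = NULL) {
  sex_of <- function(id) {
    if (is.null(patients)) {
      return(NA_character_)
    }
    s <- patients$sex[match(id, patients$patient_id)]
    if (length(s) == 0) NA_character_ else s
  }
  res <- purrr::map2(hits$variants, seq_len(nrow(hits)), function(v, i) {
    modes <- strsplit(hits$known_modes[[i]], ",", fixed = TRUE)[[1]]
    zyg <- v$zygosity
    n_distinct <- nrow(dplyr::distinct(v[, c("chrom", "pos", "ref", "alt")]))
    sex <- sex_of(hits$patient_id[[i]])
    reasons <- character(0)
    for (m in modes) {
      if (m %in% c("AD", "XLD")) {
        return(list(TRUE, "dominant: heterozygous hit sufficient"))
      }
      if (m == "AR") {
        if (any(zyg == "hom_alt")) {
          return(list(TRUE, "recessive: homozygous"))
        }
        if (n_distinct >= 2) {
          return(list(TRUE, "recessive: presumed biallelic (phase unknown)"))
        }
        reasons <- c(reasons, "single heterozygous hit in recessive gene")
      }
      if (m == "XLR") {
        if (any(zyg == "hemi_alt")) {
          return(list(TRUE, "X-linked recessive: hemizygous"))
        }
        if (any(zyg == "hom_alt") && !identical(sex, "male")) {
          return(list(TRUE, "X-linked recessive: homozygous female"))
        }
        reasons <- c(reasons, "heterozygous hit in X-linked recessive gene")
      }
      if (m == "de_novo") {
        return(list(TRUE, "de novo compatible"))
      }
      if (m == "unknown") {
        return(list(TRUE, "mode unknown"))
      }
    }
    if (length(reasons) == 0) reasons <- "mode unknown"
    list(FALSE, paste(unique(reasons), collapse = "; "))
  })
  hits$inheritance_consistent <- vapply(res, function(x) x[[1]], logical(1))
  hits$consistency_reason <- vapply(res, function(x) x[[2]], character(1))
  hits
}

#' Elevate recurrently hit exome candidates
#'
#' A category-III (family exome candidate) gene is elevated to
#' "likely-causative" when it is hit in at least `min_patients` distinct
#' unrelated patients of the cohort.
#'
#' @param hits A `gene_hits` tibble for the whole cohort.
#' @param min_patients Minimum number of distinct patients (default 2,
#'   the weakest reading of "multiple patients").
#' @return A tibble `gene`, `n_patients`, `patients` (comma-joined
#'   supporting patient ids), one row per elevated gene.
#' @export
recurrence_elevation <- function(hits, min_patients = 2L) {
  cat3 <- hits[has_category(hits$categories, "III"), ]
  if (nrow(cat3) == 0) {
    return(tibble(gene = character(), n_patients = integer(), patients = character()))
  }
  tallies <- cat3 |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_patients = dplyr::n_distinct(.data$patient_id),
      patients = paste(sort(unique(.data$patient_id)), collapse = ","),
      .groups = "drop"
    )
  dplyr::filter(tallies, .data$n_patients >= min_patients)
}

has_category <- function(tags, cc) {
  tags[is.na(tags)] <- ""
  vapply(strsplit(tags, ",", fixed = TRUE), function(t) cc %in% t, logical(1))
}

#' Classify every patient of the cohort
#'
#' Assigns each patient exactly one status using the category precedence
#' I > II > III (elevated) > IV: a consistent hit in a known EDMD gene
#' solves the patient (`solved_known_edmd`, tier dark green); failing
#' that, a consistent hit in a related-dystrophy gene
#' (`solved_related_md`, dark green); then a hit in a recurrently
#' mutated exome candidate (`candidate_recurrent`, purple); then a
#' functional-candidate hit (`candidate_functional`, yellow).  Two or
#' more qualifying genes at the same highest precedence yield
#' `ambiguous_multi` with each hit tiered light green.  Hits in
#' modifier-only genes and inconsistent hits in known genes never confer
#' solved status; they are tiered light green and recorded as notes, as
#' are qualifying hits in lower precedence classes ("possible dual
#' contribution").  Patients without hits are `unsolved`.
#'
#' @param hits A `gene_hits` tibble (consistency columns are computed
#'   when absent).
#' @param patients Patient tibble (`patient_id`, `sex`); every listed
#'   patient receives a classification.
#' @param elevated Optional elevation table from
#'   [recurrence_elevation()]; computed at `min_patients` when `NULL`.
#' @param min_patients Recurrence threshold used when computing
#'   `elevated`.
#' @return A `cohort_classification` object: list with
#'   `classifications` (one row per patient: `patient_id`, `status`,
#'   `assigned_genes`, `n_hits`, `notes`), `hits` (with `tier`),
#'   `elevated`, `n_patients`.
#' @export
classify_patients <- function(hits, patients, elevated = NULL,
                              min_patients = 2L) {
  if (!"inheritance_consistent" %in% names(hits)) {
    hits <- inheritance_consistency(hits, patients)
  }
  if (is.null(elevated)) elevated <- recurrence_elevation(hits, min_patients)

  rank_of <- function(i) {
    if (isTRUE(hits$modifier_only[[i]])) {
      return(NA_integer_)
    }
    tags <- hits$categories[[i]]
    cons <- hits$inheritance_consistent[[i]]
    if (has_category(tags, "I") && cons) {
      return(1L)
    }
    if (has_category(tags, "II") && cons) {
      return(2L)
    }
    if (has_category(tags, "III") && hits$gene[[i]] %in% elevated$gene) {
      return(3L)
    }
    if (has_category(tags, "IV")) {
      return(4L)
    }
    NA_integer_
  }
  hits$rank <- vapply(seq_len(nrow(hits)), rank_of, integer(1))

  base_tier <- function(i) {
    tags <- hits$categories[[i]]
    if (has_category(tags, "I") || has_category(tags, "II")) {
      if (isTRUE(hits$modifier_only[[i]]) || !hits$inheritance_consistent[[i]]) {
        "light_green"
      } else {
        "dark_green"
      }
    } else if (has_category(tags, "III")) {
      "purple"
    } else {
      "yellow"
    }
  }
  hits$tier <- vapply(seq_len(nrow(hits)), base_tier, character(1))

  status_by_rank <- c(
    "solved_known_edmd", "solved_related_md",
    "candidate_recurrent", "candidate_functional"
  )

  empty_cls <- tibble(
    patient_id = character(), status = character(),
    assigned_genes = character(), n_hits = integer(), notes = character()
  )
  rows <- lapply(patients$patient_id, function(pid) {
    h <- which(hits$patient_id == pid)
    notes <- character(0)
    for (i in h) {
      if (isTRUE(hits$modifier_only[[i]])) {
        notes <- c(notes, paste0("modifier gene hit: ", hits$gene[[i]]))
      }
      if (grepl("phase unknown", hits$consistency_reason[[i]], fixed = TRUE)) {
        notes <- c(notes, paste0(hits$gene[[i]], ": phase unknown"))
      }
    }
    if (length(h) == 0) {
      return(tibble(
        patient_id = pid, status = "unsolved", assigned_genes = "",
        n_hits = 0L, notes = ""
      ))
    }
    ranks <- hits$rank[h]
    if (all(is.na(ranks))) {
      incons <- hits$gene[h][!hits$inheritance_consistent[h]]
      if (length(incons) > 0) {
        notes <- c(notes, paste0(
          "inconsistent hit(s) retained: ", paste(incons, collapse = ", ")
        ))
      }
      return(tibble(
        patient_id = pid, status = "unsolved", assigned_genes = "",
        n_hits = length(h), notes = paste(unique(notes), collapse = "; ")
      ))
    }
    best <- min(ranks, na.rm = TRUE)
    best_idx <- h[!is.na(ranks) & ranks == best]
    lower_idx <- h[!is.na(ranks) & ranks > best]
    if (length(lower_idx) > 0) {
      notes <- c(notes, paste0(
        "possible dual contribution: ",
        paste(hits$gene[lower_idx], collapse = ", ")
      ))
    }
    if (length(best_idx) >= 2) {
      hits$tier[best_idx] <<- "light_green"
      status <- "ambiguous_multi"
      notes <- c(notes, "two or more genes of similar likelihood")
    } else {
      status <- status_by_rank[[best]]
    }
    tibble(
      patient_id = pid, status = status,
      assigned_genes = paste(sort(hits$gene[best_idx]), collapse = ","),
      n_hits = length(h), notes = paste(unique(notes), collapse = "; ")
    )
  })

  structure(
    list(
      classifications = dplyr::bind_rows(c(list(empty_cls), rows)),
      hits = hits, elevated = elevated, n_patients = nrow(patients)
    ),
    class = "cohort_classification"
  )
}

#' Summarise a classified cohort
#'
#' @param classification A `cohort_classification`.
#' @param panel The `panel_registry` used (for per-category totals).
#' @return A `cohort_summary` list: `status_counts` (every status, zero
#'   counts included; sums to the cohort size), `category_gene_counts`
#'   (genes with at least one hit per category out of the category
#'   size), `patients_with_category_hit` (distinct patients with at
#'   least one hit per category) and `gene_tallies` (patients per gene).
#' @export
cohort_summary <- function(classification, panel) {
  cl <- classification$classifications
  hits <- classification$hits
  status_counts <- tibble(status = patient_statuses()) |>
    dplyr::left_join(dplyr::count(cl, .data$status), by = "status") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  stopifnot(sum(status_counts$n) == classification$n_patients)

  sizes <- attr(panel, "category_sizes")
  per_cat <- lapply(c("I", "II", "III", "IV"), function(cc) {
    in_cat <- hits[has_category(hits$categories, cc), ]
    tibble(
      category = cc,
      n_genes_hit = dplyr::n_distinct(in_cat$gene),
      n_genes_total = if (is.null(sizes)) NA_integer_ else unname(sizes[[cc]]),
      n_patients_hit = dplyr::n_distinct(in_cat$patient_id)
    )
  })
  category_table <- dplyr::bind_rows(per_cat)

  gene_tallies <- hits |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_patients = dplyr::n_distinct(.data$patient_id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_patients), .data$gene)

  structure(
    list(
      status_counts = status_counts,
      category_gene_counts = category_table[, c("category", "n_genes_hit", "n_genes_total")],
      patients_with_category_hit = category_table[, c("category", "n_patients_hit")],
      gene_tallies = gene_tallies,
      n_patients = classification$n_patients,
      n_clearly_assigned = sum(status_counts$n[
        status_counts$status %in% c("solved_known_edmd", "solved_related_md")
      ])
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", x$n_patients, "patients;",
      x$n_clearly_assigned, "clearly assigned\n")
  print(x$status_counts)
  print(x$category_gene_counts)
  invisible(x)
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat("<cohort_classification>", x$n_patients, "patients,",
      nrow(x$hits), "gene hits,", nrow(x$elevated), "elevated gene(s)\n")
  print(dplyr::count(x$classifications, .data$status))
  invisible(x)
}
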