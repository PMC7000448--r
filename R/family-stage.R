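#' Configure the family-stage filtering cascade
#'
#' Holds the parameters of the exome-stage filters: the declared
#' inheritance mode, the two population-frequency thresholds (fractions;
#' defaults 0.01 and 0.0005, i.e. 1% and 0.05%, both applied with strict
#' `<`), the muscle-expression fold change, and the policies for missing
#' data.
#'
#' @param mode Inheritance mode declared for the family (see
#'   [inheritance_modes()]).
#' @param freq_stage1,freq_stage2 Stage-1 and stage-2 frequency
#'   thresholds, as fractions, with `0 < freq_stage2 <= freq_stage1 < 1`.
#' @param expression_fold Required muscle-over-other-tissue fold change
#'   (> 1; survival requires strictly greater than the fold).
#' @param drop_unaffected_below_age Optional age (years): unaffected
#'   members younger than this are ignored by the co-segregation filter,
#'   modelling carriers who may not yet have presented clinically.
#' @param treat_missing_frequency_as_pass Whether a variant absent from
#'   the frequency source passes the cascade (default `TRUE`: absence
#'   from a population database is evidence of rarity); always flagged
#'   in provenance.
#' @param missing_genotype_policy `"strict"` (a missing call in an
#'   affected member fails segregation) or `"lenient"` (missing calls
#'   are ignored).
#' @param expression_aggregate How "other tissues" are aggregated:
#'   `"max"` (most conservative, default) or `"mean"`.
#' @return A `family_filter_config` list.
#' @export
family_filter_config <- function(mode, freq_stage1 = 0.01, freq_stage2 = 0.0005,
                                 expression_fold = 2,
                                 drop_unaffected_below_age = NULL,
                                 treat_missing_frequency_as_pass = TRUE,
                                 missing_genotype_policy = c("strict", "lenient"),
                                 expression_aggregate = c("max", "mean")) {
  mode <- match.arg(mode, inheritance_modes())
  if (!(freq_stage2 > 0 && freq_stage2 <= freq_stage1 && freq_stage1 < 1)) {
    abort("need 0 < freq_stage2 <= freq_stage1 < 1")
  }
  if (expression_fold <= 1) abort("expression_fold must be > 1")
  structure(
    list(
      mode = mode, freq_stage1 = freq_stage1, freq_stage2 = freq_stage2,
      expression_fold = expression_fold,
      drop_unaffected_below_age = drop_unaffected_below_age,
      treat_missing_frequency_as_pass = treat_missing_frequency_as_pass,
      missing_genotype_policy = match.arg(missing_genotype_policy),
      expression_aggregate = match.arg(expression_aggregate)
    ),
    class = "family_filter_config"
  )
}

#' Filter variants by phenotype co-segregation under an inheritance mode
#'
#' A variant survives iff every affected pedigree member carries the
#' dose the declared mode requires (AD: at least one alternate allele;
#' AR: homozygous alternate, or membership in a pair of distinct
#' heterozygous variants in the same gene each carried by all affected
#' members — accepted phase-unaware and flagged `"phase unknown"`;
#' XLR: hemizygous in males / homozygous in females; XLD: at least one
#' alternate allele; de novo: alternate in every affected member and
#' absent from both of their parents) and no qualifying unaffected
#' member carries that dose.  Unaffected members younger than
#' `drop_unaffected_below_age` do not qualify.
#'
#' @param variants Variant tibble.
#' @param genotypes Genotype tibble (absent sample x variant rows are
#'   homozygous reference; explicit `"missing"` rows follow the missing
#'   genotype policy).
#' @param pedigree Pedigree tibble with affection status.
#' @param config A [family_filter_config()].
#' @param keep_all Return all variants with a `coseg_pass` verdict
#'   column instead of only survivors.
#' @return The surviving variants (with a `coseg_note` column), or all
#'   variants with verdicts when `keep_all = TRUE`.
#' @export
cosegregation_filter <- function(variants, genotypes, pedigree, config,
                                 keep_all = FALSE) {
  assert_variants(variants)
  stray <- setdiff(unique(genotypes$sample_id), pedigree$individual_id)
  if (length(stray) > 0) {
    abort(paste0(
      "genotype sample(s) not in pedigree: ", paste(stray, collapse = ", ")
    ), class = "edmd_integrity_error")
  }
  if (nrow(variants) == 0) {
    out <- dplyr::mutate(variants, coseg_pass = logical(0), coseg_note = character(0))
    return(if (keep_all) out else out)
  }

  ids <- pedigree$individual_id
  affected <- ids[pedigree$affected == "affected"]
  unaff <- ids[pedigree$affected == "unaffected"]
  drop_age <- config$drop_unaffected_below_age
  if (!is.null(drop_age)) {
    ages <- setNames(pedigree$age, ids)
    unaff <- unaff[is.na(ages[unaff]) | ages[unaff] >= drop_age]
  }
  sex <- setNames(pedigree$sex, ids)
  father <- setNames(pedigree$father_id, ids)
  mother <- setNames(pedigree$mother_id, ids)
  lenient <- config$missing_genotype_policy == "lenient"

  ## zygosity matrix: members x variants ("hom_ref" when no row)
  vkey <- variant_key(variants)
  zmat <- matrix("hom_ref", nrow = length(ids), ncol = nrow(variants),
    dimnames = list(ids, vkey)
  )
  if (nrow(genotypes) > 0) {
    gk <- variant_key(genotypes)
    keep <- gk %in% vkey & genotypes$sample_id %in% ids
    zmat[cbind(genotypes$sample_id[keep], gk[keep])] <- genotypes$zygosity[keep]
  }

  carries <- function(z) z %in% c("het", "hom_alt", "hemi_alt")

  req_ok <- function(z_aff, dose_fun) {
    ## does every affected member satisfy dose_fun, under the missing policy?
    miss <- z_aff == "missing"
    if (any(miss) && !lenient) {
      return(FALSE)
    }
    z_use <- z_aff[!miss]
    if (length(z_use) == 0) {
      return(FALSE)
    }
    all(dose_fun(z_use))
  }

  single_pass <- function(j) {
    z <- zmat[, j]
    chromx <- is_x_contig(variants$chrom[[j]])
    switch(config$mode,
      AD = req_ok(z[affected], carries) && !any(carries(z[unaff])),
      AR = req_ok(z[affected], function(x) x == "hom_alt") &&
        !any(z[unaff] == "hom_alt"),
      XLR = {
        xlr_dose <- function(id) {
          zz <- z[[id]]
          if (sex[[id]] == "male") zz %in% c("hemi_alt", "hom_alt") else zz == "hom_alt"
        }
        informative <- affected[z[affected] != "missing"]
        chromx &&
          length(informative) > 0 &&
          (lenient || length(informative) == length(affected)) &&
          all(vapply(informative, xlr_dose, logical(1))) &&
          !any(vapply(unaff[z[unaff] != "missing"], xlr_dose, logical(1)))
      },
      XLD = chromx && req_ok(z[affected], carries) && !any(carries(z[unaff])),
      de_novo = req_ok(z[affected], carries) &&
        all(vapply(affected, function(id) {
          ok <- TRUE
          for (p in c(father[[id]], mother[[id]])) {
            if (p == "0") next
            zp <- z[[p]]
            if (zp == "missing") ok <- ok && lenient else ok <- ok && !carries(zp)
          }
          ok
        }, logical(1))) &&
        !any(carries(z[unaff]))
    )
  }

  pass <- vapply(seq_len(nrow(variants)), single_pass, logical(1))
  note <- rep("", nrow(variants))

  if (config$mode == "AR") {
    ## compound-heterozygous route, phase-unaware
    for (g in unique(variants$gene)) {
      idx <- which(variants$gene == g)
      if (length(idx) < 2) next
      het_all <- vapply(idx, function(j) {
        z <- zmat[, j]
        req_ok(z[affected], function(x) x == "het")
      }, logical(1))
      cand <- idx[het_all]
      if (length(cand) < 2) next
      for (a in seq_along(cand)) {
        for (b in seq_along(cand)) {
          if (b <= a) next
          j1 <- cand[[a]]
          j2 <- cand[[b]]
          both_unaff <- any(
            carries(zmat[unaff, j1]) & carries(zmat[unaff, j2])
          )
          if (!both_unaff) {
            pass[c(j1, j2)] <- TRUE
            note[c(j1, j2)] <- "compound heterozygous; phase unknown"
          }
        }
      }
    }
  }

  out <- dplyr::mutate(variants, coseg_pass = pass, coseg_note = note)
  if (keep_all) out else dplyr::filter(out, .data$coseg_pass)
}

#' Two-stage population-frequency cascade
#'
#' Stage 1 keeps variants with population frequency strictly below
#' `freq_stage1` (default 1%); stage 2 keeps those strictly below
#' `freq_stage2` (default 0.05%).  Boundary values fail (strict `<`).
#' Variants absent from the frequency source pass or fail per
#' `treat_missing_frequency_as_pass` and are flagged.
#'
#' @inheritParams cosegregation_filter
#' @param freq_table Optional frequency table; otherwise the
#'   `population_frequency` column is used.
#' @return Surviving variants with `freq_used`, `freq_missing`,
#'   `pass_stage1`, `pass_stage2` columns (all variants when
#'   `keep_all = TRUE`).
#' @export
frequency_cascade <- function(variants, config, freq_table = NULL,
                              keep_all = FALSE) {
  f <- lookup_frequency(variants, freq_table)
  miss_pass <- isTRUE(config$treat_missing_frequency_as_pass)
  p1 <- ifelse(is.na(f), miss_pass, f < config$freq_stage1)
  p2 <- p1 & ifelse(is.na(f), miss_pass, f < config$freq_stage2)
  out <- dplyr::mutate(variants,
    freq_used = f, freq_missing = is.na(f),
    pass_stage1 = p1, pass_stage2 = p2
  )
  if (keep_all) out else dplyr::filter(out, .data$pass_stage2)
}

#' Keep variants that alter the coding sequence
#'
#' Retains `missense`, `nonsense`, `frameshift`, `splice_donor`,
#' `splice_acceptor` and `inframe_indel`; removes `synonymous`,
#' `intronic`, `utr` and `intergenic`.
#'
#' @inheritParams cosegregation_filter
#' @return Surviving variants (all with a `coding` column when
#'   `keep_all = TRUE`).
#' @export
coding_filter <- function(variants, keep_all = FALSE) {
  assert_variants(variants)
  out <- dplyr::mutate(variants, coding = .data$consequence %in% coding_consequences())
  if (keep_all) out else dplyr::filter(out, .data$coding)
}

#' Filter genes by muscle-specific expression
#'
#' A gene survives iff its muscle expression is strictly greater than
#' `expression_fold` times the aggregate (maximum by default) of its
#' non-muscle tissue values.  Genes absent from the expression table
#' survive with a `"no-expression-data"` note.
#'
#' @param genes Character vector of gene symbols.
#' @param expression Long expression tibble (`gene`, `tissue`, `value`).
#' @param config A [family_filter_config()].
#' @param keep_all Return all genes with verdicts.
#' @return A tibble with `gene`, `muscle`, `other_aggregate`,
#'   `expression_pass`, `expression_note` (filtered to survivors unless
#'   `keep_all`).
#' @export
expression_filter <- function(genes, expression, config, keep_all = FALSE) {
  genes <- unique(genes)
  agg_fun <- if (config$expression_aggregate == "max") max else mean
  rows <- lapply(genes, function(g) {
    e <- expression[expression$gene == g, ]
    if (nrow(e) == 0) {
      return(tibble(
        gene = g, muscle = NA_real_, other_aggregate = NA_real_,
        expression_pass = TRUE, expression_note = "no-expression-data"
      ))
    }
    muscle <- e$value[e$tissue == "muscle"]
    others <- e$value[e$tissue != "muscle"]
    muscle <- if (length(muscle)) muscle[[1]] else NA_real_
    agg <- if (length(others)) agg_fun(others) else 0
    pass <- !is.na(muscle) && muscle > config$expression_fold * agg
    tibble(
      gene = g, muscle = muscle, other_aggregate = agg,
      expression_pass = pass, expression_note = ""
    )
  })
  out <- dplyr::bind_rows(rows)
  if (length(rows) == 0) {
    out <- tibble(
      gene = character(), muscle = double(), other_aggregate = double(),
      expression_pass = logical(), expression_note = character()
    )
  }
  if (keep_all) out else dplyr::filter(out, .data$expression_pass)
}

#' Run the full family-stage cascade
#'
#' Applies, in order: co-segregation under the declared mode, the
#' two-stage frequency cascade, the coding-consequence filter, and the
#' muscle-expression filter; collects per-variant provenance for every
#' stage.  If the cascade yields no candidates and `fallback_drop_age`
#' is supplied, the cascade is re-run ignoring unaffected members below
#' that age (the young-carrier fallback used when a family yields
#' nothing under the strict reading).
#'
#' @inheritParams cosegregation_filter
#' @param expression Optional long expression tibble; when `NULL` the
#'   expression filter is skipped (all genes survive, noted).
#' @param freq_table Optional frequency table.
#' @param family_id Family label carried into the result.
#' @param fallback_drop_age Optional age for the fallback re-run.
#' @return A `candidate_gene_set`: list with `family_id`, `genes`
#'   (tibble of surviving genes with supporting variant counts and
#'   flags), `variants` (surviving variant records), `provenance` (one
#'   row per variant x stage with the verdict) and `fallback_used`.
#' @export
run_family_stage <- function(variants, genotypes, pedigree, config,
                             expression = NULL, freq_table = NULL,
                             family_id = NULL, fallback_drop_age = NULL) {
  family_id <- family_id %||%
    (if (nrow(pedigree) > 0) pedigree$family_id[[1]] else "FAM")

  run_once <- function(cfg) {
    s1 <- cosegregation_filter(variants, genotypes, pedigree, cfg, keep_all = TRUE)
    surv1 <- dplyr::filter(s1, .data$coseg_pass)
    s2 <- frequency_cascade(surv1, cfg, freq_table, keep_all = TRUE)
    surv2 <- dplyr::filter(s2, .data$pass_stage2)
    s3 <- coding_filter(surv2, keep_all = TRUE)
    surv3 <- dplyr::filter(s3, .data$coding)
    if (is.null(expression)) {
      s4 <- tibble(
        gene = unique(surv3$gene), muscle = NA_real_,
        other_aggregate = NA_real_, expression_pass = TRUE,
        expression_note = "no-expression-data"
      )
    } else {
      s4 <- expression_filter(unique(surv3$gene), expression, cfg, keep_all = TRUE)
    }
    surviving_genes <- s4$gene[s4$expression_pass]
    final <- dplyr::filter(surv3, .data$gene %in% surviving_genes)

    prov <- dplyr::bind_rows(
      dplyr::transmute(s1,
        stage = "cosegregation", chrom = .data$chrom, pos = .data$pos,
        ref = .data$ref, alt = .data$alt, gene = .data$gene,
        verdict = .data$coseg_pass, note = .data$coseg_note
      ),
      dplyr::transmute(s2,
        stage = "frequency_stage1", chrom = .data$chrom, pos = .data$pos,
        ref = .data$ref, alt = .data$alt, gene = .data$gene,
        verdict = .data$pass_stage1,
        note = dplyr::if_else(.data$freq_missing, "frequency absent from database", "")
      ),
      dplyr::transmute(s2,
        stage = "frequency_stage2", chrom = .data$chrom, pos = .data$pos,
        ref = .data$ref, alt = .data$alt, gene = .data$gene,
        verdict = .data$pass_stage2,
        note = dplyr::if_else(.data$freq_missing, "frequency absent from database", "")
      ),
      dplyr::transmute(s3,
        stage = "coding", chrom = .data$chrom, pos = .data$pos,
        ref = .data$ref, alt = .data$alt, gene = .data$gene,
        verdict = .data$coding, note = ""
      ),
      dplyr::transmute(s4,
        stage = "expression", chrom = NA_character_, pos = NA_integer_,
        ref = NA_character_, alt = NA_character_, gene = .data$gene,
        verdict = .data$expression_pass, note = .data$expression_note
      )
    )

    genes <- dplyr::summarise(
      dplyr::group_by(final, .data$gene),
      n_variants = dplyr::n(),
      notes = paste(unique(.data$coseg_note[.data$coseg_note != ""]), collapse = "; "),
      .groups = "drop"
    )
    genes <- dplyr::left_join(
      genes,
      dplyr::select(s4, "gene", "expression_note"),
      by = "gene"
    )
    list(genes = genes, variants = final, provenance = prov)
  }

  res <- run_once(config)
  fallback_used <- FALSE
  if (nrow(res$genes) == 0 && !is.null(fallback_drop_age) &&
    is.null(config$drop_unaffected_below_age)) {
    cfg2 <- config
    cfg2$drop_unaffected_below_age <- fallback_drop_age
    res <- run_once(cfg2)
    fallback_used <- TRUE
  }

  structure(
    list(
      family_id = family_id, genes = res$genes, variants = res$variants,
      provenance = res$provenance, config = config,
      fallback_used = fallback_used
    ),
    class = "candidate_gene_set"
  )
}

#' Merge candidate gene sets across families
#'
#' @param sets A list of `candidate_gene_set` objects.
#' @return A tibble with one row per (family, gene), plus the union of
#'   gene symbols in `attr(, "genes")`.
#' @export
merge_candidates <- function(sets) {
  rows <- lapply(sets, function(s) {
    if (nrow(s$genes) == 0) {
      return(NULL)
    }
    dplyr::mutate(s$genes, family_id = s$family_id, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      family_id = character(), gene = character(),
      n_variants = integer(), notes = character(),
      expression_note = character()
    )
  }
  attr(out, "genes") <- unique(out$gene)
  out
}

#' @export
print.candidate_gene_set <- function(x, ...) {
  cat("<candidate_gene_set> family", x$family_id, "-",
      nrow(x$genes), "candidate gene(s)\n")
  if (x$fallback_used) cat("  (young-carrier fallback engaged)\n")
  print(x$genes, ...)
  invisible(x)
}

#' @method tidy candidate_gene_set
#' @export
tidy.candidate_gene_set <- function(x, ...) {
  dplyr::mutate(x$genes, family_id = x$family_id, .before = 1)
}
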