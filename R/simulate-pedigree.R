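#' Built-in pedigree templates
#'
#' Structures (ids, parentage, sex) without affection status; affection
#' is assigned by [simulate_pedigree()] from the simulated genotypes.
#'
#' @param name `"trio"` (father, mother, son), `"quartet"` (adds a
#'   daughter) or `"two_gen_8"` (founder couple with six children).
#' @param family_id Family identifier.
#' @return A template tibble (`individual_id`, `father_id`, `mother_id`,
#'   `sex`) with the designated proband in `attr(, "proband")`.
#' @export
pedigree_template <- function(name = c("trio", "quartet", "two_gen_8"),
                              family_id = "FAM1") {
  name <- match.arg(name)
  tmpl <- switch(name,
    trio = tibble(
      individual_id = c("1", "2", "3"),
      father_id = c("0", "0", "1"),
      mother_id = c("0", "0", "2"),
      sex = c("male", "female", "male")
    ),
    quartet = tibble(
      individual_id = c("1", "2", "3", "4"),
      father_id = c("0", "0", "1", "1"),
      mother_id = c("0", "0", "2", "2"),
      sex = c("male", "female", "male", "female")
    ),
    two_gen_8 = tibble(
      individual_id = as.character(1:8),
      father_id = c("0", "0", rep("1", 6)),
      mother_id = c("0", "0", rep("2", 6)),
      sex = c("male", "female", "male", "female", "male", "female", "male", "male")
    )
  )
  tmpl$family_id <- family_id
  attr(tmpl, "proband") <- "3"
  tmpl
}

#' Simulate genotypes and affection over a pedigree
#'
#' Plants a causal allele (or compound-heterozygous pair) so that the
#' designated proband carries the dose the inheritance mode requires,
#' transmits alleles Mendelianly to every other member, and assigns
#' affection from the carried dose: at penetrance 1 exactly the members
#' carrying the mode-required dose are affected.  An optional
#' age-of-onset model reverts carriers younger than the onset age to
#' unaffected, emulating a carrier who has not yet presented clinically.
#'
#' @param template A template tibble from [pedigree_template()] (or a
#'   compatible tibble with an attached `"proband"` attribute), or a
#'   template name.
#' @param mode Inheritance mode: `"AD"`, `"AR"`, `"XLR"`, `"XLD"` or
#'   `"de_novo"`.
#' @param penetrance Probability that a dose carrier is affected.
#' @param seed Integer seed (fixed seed, identical output).
#' @param causal_gene Symbol of the causal gene.
#' @param ar_form For `mode = "AR"`: `"hom"` (homozygous causal allele)
#'   or `"compound_het"` (two distinct variants, one per parent).
#' @param ages Optional named vector of ages (years) per individual.
#' @param age_of_onset Optional onset age for the late-onset model.
#' @param gene_models Optional gene models; synthesised when absent.
#' @return A `pedigree_simulation` list: `pedigree` (with affection),
#'   `variants`, `genotypes`, `truth`.
#' @export
simulate_pedigree <- function(template = "trio", mode, penetrance = 1,
                              seed = 1L, causal_gene = "CAUSAL1",
                              ar_form = c("hom", "compound_het"),
                              ages = NULL, age_of_onset = NULL,
                              gene_models = NULL) {
  if (is.character(template) && length(template) == 1) {
    template <- pedigree_template(template)
  }
  mode <- match.arg(mode, inheritance_modes())
  ar_form <- match.arg(ar_form)
  if (penetrance < 0 || penetrance > 1) abort("penetrance must lie in [0, 1]")
  proband <- attr(template, "proband") %||% template$individual_id[
    template$father_id != "0" & template$mother_id != "0"
  ][1]
  ped <- new_pedigree(dplyr::mutate(template, affected = "unknown"))
  x_linked <- mode %in% c("XLR", "XLD")
  if (mode == "XLR" && ped$sex[ped$individual_id == proband] != "male") {
    abort("XLR causal allele requires a male proband in this template",
      class = "edmd_infeasibility_error"
    )
  }
  pr_parents <- ped[ped$individual_id == proband, c("father_id", "mother_id")]
  if (mode %in% c("AR", "de_novo") &&
    (pr_parents$father_id == "0" || pr_parents$mother_id == "0")) {
    abort("mode requires both proband parents in the pedigree",
      class = "edmd_infeasibility_error"
    )
  }

  if (is.null(gene_models)) {
    gene_models <- synthetic_gene_models(
      causal_gene,
      x_genes = if (x_linked) causal_gene else character(0)
    )
  }

  withr::with_seed(seed, {
    sim <- transmit_causal(ped, mode, ar_form, proband)
    body <- gene_body(gene_models, causal_gene)
    n_var <- ncol(sim$dose)
    csq <- if (mode == "AR" && ar_form == "compound_het") {
      c("missense", "frameshift")
    } else {
      rep("missense", n_var)
    }
    variants <- tibble(
      chrom = body$chrom,
      pos = gene_position(gene_models, causal_gene, seq_len(n_var)),
      ref = vapply(csq, function(x) plant_alleles(x)[[1]], character(1)),
      alt = vapply(csq, function(x) plant_alleles(x)[[2]], character(1)),
      gene = causal_gene, consequence = csq,
      protein_change = NA_character_, population_frequency = 0
    )
    genotypes <- dose_to_genotypes(sim$dose, variants, ped, x_linked)

    carrier <- sim$full_dose
    expressed <- carrier & (runif(nrow(ped)) <= penetrance)
    if (!is.null(age_of_onset) && !is.null(ages)) {
      young <- ages[ped$individual_id] < age_of_onset
      expressed <- expressed & !(carrier & !is.na(young) & young)
      ped$age <- unname(ages[ped$individual_id])
    }
    ped$affected <- ifelse(expressed, "affected", "unaffected")

    truth <- tibble(
      family_id = ped$family_id[[1]], gene = causal_gene, mode = mode,
      chrom = variants$chrom, pos = variants$pos,
      ref = variants$ref, alt = variants$alt
    )
    structure(
      list(pedigree = ped, variants = variants, genotypes = genotypes,
           truth = truth, proband = proband),
      class = "pedigree_simulation"
    )
  })
}

## Returns dose matrix (members x variants, causal allele count per
## variant) and full_dose (logical: carries the mode-required dose).
transmit_causal <- function(ped, mode, ar_form, proband) {
  ids <- ped$individual_id
  n <- length(ids)
  sex <- setNames(ped$sex, ids)
  father <- setNames(ped$father_id, ids)
  mother <- setNames(ped$mother_id, ids)
  ord <- topological_order(ped)
  pr_f <- father[[proband]]
  pr_m <- mother[[proband]]

  n_var <- if (mode == "AR" && ar_form == "compound_het") 2L else 1L
  dose <- matrix(0L, nrow = n, ncol = n_var, dimnames = list(ids, NULL))

  founder_path <- function() {
    ## chain of ancestors from a carrier founder down to the proband
    path <- proband
    cur <- proband
    while (father[[cur]] != "0" || mother[[cur]] != "0") {
      cur <- if (father[[cur]] != "0") father[[cur]] else mother[[cur]]
      path <- c(cur, path)
    }
    path
  }

  transmit_from <- function(dose_col, x_linked = FALSE) {
    for (id in ord) {
      if (father[[id]] == "0" && mother[[id]] == "0") next
      from_f <- dose_col[[father[[id]]]]
      from_m <- dose_col[[mother[[id]]]]
      if (x_linked) {
        m_gift <- rbinom(1, 1, min(from_m, 2) / 2)
        f_gift <- if (sex[[id]] == "female") as.integer(from_f >= 1) else 0L
        dose_col[[id]] <- m_gift + f_gift
      } else {
        dose_col[[id]] <- rbinom(1, 1, min(from_f, 2) / 2) +
          rbinom(1, 1, min(from_m, 2) / 2)
      }
    }
    dose_col
  }

  if (mode == "AD") {
    path <- founder_path()
    col <- setNames(rep(0L, n), ids)
    col[[path[[1]]]] <- 1L
    for (id in ord) {
      if (id %in% path) {
        col[[id]] <- 1L
      } else if (father[[id]] != "0" || mother[[id]] != "0") {
        col[[id]] <- rbinom(1, 1, min(col[[father[[id]]]], 2) / 2) +
          rbinom(1, 1, min(col[[mother[[id]]]], 2) / 2)
      }
    }
    dose[, 1] <- col[ids]
    full <- dose[, 1] >= 1
  } else if (mode == "AR" && ar_form == "hom") {
    col <- setNames(rep(0L, n), ids)
    col[[pr_f]] <- 1L
    col[[pr_m]] <- 1L
    col <- transmit_from(col)
    col[[proband]] <- 2L
    dose[, 1] <- col[ids]
    full <- dose[, 1] == 2
  } else if (mode == "AR" && ar_form == "compound_het") {
    c1 <- setNames(rep(0L, n), ids)
    c2 <- setNames(rep(0L, n), ids)
    c1[[pr_f]] <- 1L
    c2[[pr_m]] <- 1L
    c1 <- transmit_from(c1)
    c2 <- transmit_from(c2)
    c1[[proband]] <- 1L
    c2[[proband]] <- 1L
    dose[, 1] <- c1[ids]
    dose[, 2] <- c2[ids]
    full <- dose[, 1] >= 1 & dose[, 2] >= 1
  } else if (mode %in% c("XLR", "XLD")) {
    col <- setNames(rep(0L, n), ids)
    col[[pr_m]] <- 1L
    col <- transmit_from(col, x_linked = TRUE)
    col[[proband]] <- max(col[[proband]], 1L)
    dose[, 1] <- col[ids]
    full <- if (mode == "XLR") {
      ifelse(sex[ids] == "male", dose[, 1] >= 1, dose[, 1] >= 2)
    } else {
      dose[, 1] >= 1
    }
  } else { # de_novo
    dose[proband, 1] <- 1L
    full <- dose[, 1] >= 1
  }
  list(dose = dose, full_dose = unname(full))
}

dose_to_genotypes <- function(dose, variants, ped, x_linked) {
  rows <- list()
  for (j in seq_len(ncol(dose))) {
    for (i in seq_len(nrow(ped))) {
      d <- dose[i, j]
      male <- ped$sex[[i]] == "male"
      zyg <- if (x_linked && male) {
        if (d >= 1) "hemi_alt" else "hom_ref"
      } else if (d >= 2) {
        "hom_alt"
      } else if (d == 1) "het" else "hom_ref"
      rows[[length(rows) + 1L]] <- tibble(
        sample_id = ped$individual_id[[i]],
        chrom = variants$chrom[[j]], pos = variants$pos[[j]],
        ref = variants$ref[[j]], alt = variants$alt[[j]], zygosity = zyg
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate a full family-stage input set
#'
#' Wraps [simulate_pedigree()] and adds benign background variants
#' (founder-borne, transmitted Mendelianly) plus the expression table, so
#' the result can be piped straight into [run_family_stage()].  The
#' causal gene is flagged muscle-specific; background genes are a
#' mixture.
#'
#' @inheritParams simulate_pedigree
#' @param n_background Number of benign background variants.
#' @param maf_shape1,maf_shape2 Beta spectrum of background frequencies.
#' @return A list with `pedigree`, `variants`, `genotypes`,
#'   `expression`, `truth`.
#' @export
simulate_family <- function(template = "trio", mode = "AD", penetrance = 1,
                            seed = 1L, causal_gene = "CAUSAL1",
                            ar_form = c("hom", "compound_het"),
                            n_background = 200L, maf_shape1 = 0.2,
                            maf_shape2 = 20) {
  ar_form <- match.arg(ar_form)
  base <- simulate_pedigree(template, mode,
    penetrance = penetrance, seed = seed,
    causal_gene = causal_gene, ar_form = ar_form
  )
  ped <- base$pedigree
  bg_genes <- sprintf("BG%03d", seq_len(max(40L, ceiling(n_background / 4))))
  models <- synthetic_gene_models(c(causal_gene, bg_genes),
    x_genes = if (mode %in% c("XLR", "XLD")) causal_gene else character(0)
  )

  withr::with_seed(seed + 1000L, {
    vrows <- list()
    grows <- list()
    slot <- setNames(rep(100L, length(bg_genes)), bg_genes)
    for (k in seq_len(n_background)) {
      g <- sample(bg_genes, 1)
      slot[[g]] <- slot[[g]] + 1L
      pos <- gene_position(models, g, slot[[g]])
      csq <- sample(consequence_vocabulary(), 1,
        prob = c(.30, .02, .02, .02, .02, .02, .20, .25, .10, .05)
      )
      freq <- rbeta(1, maf_shape1, maf_shape2)
      alleles <- plant_alleles(csq)
      vrows[[k]] <- tibble(
        chrom = gene_body(models, g)$chrom, pos = pos,
        ref = alleles[[1]], alt = alleles[[2]], gene = g,
        consequence = csq, protein_change = NA_character_,
        population_frequency = freq
      )
      carrier <- sample(founders(ped), 1)
      col <- setNames(rep(0L, nrow(ped)), ped$individual_id)
      col[[carrier]] <- 1L
      ord <- topological_order(ped)
      father <- setNames(ped$father_id, ped$individual_id)
      mother <- setNames(ped$mother_id, ped$individual_id)
      for (id in ord) {
        if (father[[id]] == "0" && mother[[id]] == "0") next
        col[[id]] <- rbinom(1, 1, min(col[[father[[id]]]], 2) / 2) +
          rbinom(1, 1, min(col[[mother[[id]]]], 2) / 2)
      }
      zyg <- ifelse(col >= 2, "hom_alt", ifelse(col == 1, "het", "hom_ref"))
      grows[[k]] <- tibble(
        sample_id = ped$individual_id, chrom = vrows[[k]]$chrom,
        pos = pos, ref = alleles[[1]], alt = alleles[[2]],
        zygosity = unname(zyg[ped$individual_id])
      )
    }
    muscle_specific <- c(causal_gene, sample(bg_genes, length(bg_genes) %/% 3))
    tables <- generate_tables(
      genes = c(causal_gene, bg_genes),
      muscle_specific = muscle_specific, seed = seed + 2000L
    )
    list(
      pedigree = ped,
      variants = dplyr::bind_rows(c(list(base$variants), vrows)),
      genotypes = dplyr::bind_rows(c(list(base$genotypes), grows)),
      expression = tables$expression,
      truth = base$truth
    )
  })
}
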