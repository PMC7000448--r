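#' Specify a planted causal allele
#'
#' A plant spec describes one causal signal to inject into a simulated
#' cohort: the gene, the consequence(s), the zygosity pattern and how
#' many (or exactly which) patients carry it.
#'
#' @param gene Gene symbol.
#' @param consequence Consequence token (see [consequence_vocabulary()]).
#'   For `compound_het` plants, `consequences` gives the two tokens (it
#'   defaults to `c(consequence, "frameshift")`, the classic
#'   missense-plus-truncating combination seen in recessive disease).
#' @param zygosity One of `"het"`, `"hom"`, `"compound_het"`, `"hemi"`.
#'   `compound_het` plants two distinct variant positions in the gene;
#'   `hemi` forces the carriers to be male and the gene onto the X contig.
#' @param carrier_count Number of patients to plant.
#' @param population_frequency Population frequency of the planted
#'   allele(s), default 0 (absent from the reference database).
#' @param carriers Optional explicit patient ids; overrides random
#'   carrier assignment (and permits deliberate overlap between plants).
#' @param consequences Length-2 consequence vector for `compound_het`.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(gene, consequence = "missense",
                       zygosity = c("het", "hom", "compound_het", "hemi"),
                       carrier_count = 1L, population_frequency = 0,
                       carriers = NULL, consequences = NULL) {
  zygosity <- match.arg(zygosity)
  assert_consequences(consequence, "plant_spec")
  if (zygosity == "compound_het") {
    consequences <- consequences %||% c(consequence, "frameshift")
    if (length(consequences) != 2) abort("compound_het plants need two consequences")
    assert_consequences(consequences, "plant_spec")
  } else {
    consequences <- rep(consequence, 1)
  }
  if (carrier_count < 1) abort("carrier_count must be >= 1")
  if (population_frequency < 0 || population_frequency >= 1) {
    abort("population_frequency must lie in [0, 1)")
  }
  if (!is.null(carriers) && length(carriers) != carrier_count) {
    abort("length(carriers) must equal carrier_count")
  }
  structure(
    list(
      gene = gene, zygosity = zygosity, consequences = consequences,
      carrier_count = as.integer(carrier_count),
      population_frequency = population_frequency, carriers = carriers
    ),
    class = "plant_spec"
  )
}

#' Configure a synthetic unrelated-patient cohort
#'
#' Bundles everything [simulate_cohort()] needs: the seed, the cohort
#' size, the planted causal alleles, the benign background burden, and
#' the population-frequency spectrum of background variants.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical outputs.
#' @param n_patients Number of unrelated patients (>= 1).
#' @param plants List of [plant_spec()] objects.
#' @param background_rate Expected benign rare variants per patient
#'   (Poisson mean).
#' @param maf_shape1,maf_shape2 Beta parameters of the benign-variant
#'   population-frequency spectrum.  The default Beta(0.2, 20) has the
#'   heavy rare tail typical of population databases.
#' @param min_background_frequency Lower truncation for background
#'   frequencies (0 keeps the pure Beta spectrum).  Setting this above a
#'   filtering threshold models a cohort whose residual benign variation
#'   is common polymorphism only.
#' @param tissues Tissue names for the expression table; must include
#'   `"muscle"`.
#' @param gene_universe Optional gene universe; defaults to the planted
#'   genes plus synthetic background genes.
#' @param annotation Optional list of designation vectors consumed by
#'   [generate_tables()]: `muscle_specific`, `ne_genes`,
#'   `go_genome_organisation_genes`, `go_cytoskeleton_genes`,
#'   `plasma_membrane_genes`, `edges`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_patients = 56L, plants = list(),
                              background_rate = 8, maf_shape1 = 0.2,
                              maf_shape2 = 20, min_background_frequency = 0,
                              tissues = c("muscle", "heart", "brain", "liver",
                                          "lung", "kidney"),
                              gene_universe = NULL, annotation = list()) {
  if (n_patients < 1) abort("n_patients must be >= 1")
  if (!"muscle" %in% tissues) abort("tissues must include 'muscle'")
  if (background_rate < 0) abort("background_rate must be >= 0")
  plants <- lapply(plants, function(p) {
    if (!inherits(p, "plant_spec")) abort("plants must be plant_spec objects")
    if (p$carrier_count > n_patients) {
      abort(paste0("carrier_count for ", p$gene, " exceeds n_patients"))
    }
    p
  })
  structure(
    list(
      seed = as.integer(seed), n_patients = as.integer(n_patients),
      plants = plants, background_rate = background_rate,
      maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
      min_background_frequency = min_background_frequency,
      tissues = tissues, gene_universe = gene_universe,
      annotation = annotation
    ),
    class = "simulation_config"
  )
}

default_universe <- function(config) {
  unique(c(
    vapply(config$plants, `[[`, character(1), "gene"),
    sprintf("BG%03d", seq_len(120))
  ))
}

#' Simulate an unrelated-patient cohort with planted causal alleles
#'
#' Generates `n_patients` unrelated patients, realises every plant spec
#' in exactly `carrier_count` distinct patients (explicit `carriers`
#' allow a patient to receive two plants), and adds benign background
#' variants per patient at the configured Poisson rate with population
#' frequencies drawn from the configured Beta spectrum.  Everything is
#' recorded in a ground-truth ledger.
#'
#' @param config A [simulation_config()].
#' @return A `cohort_simulation` list: `patients` (id, sex), `variants`,
#'   `genotypes`, `truth` (per planted/background event), `gene_models`
#'   and the echoed `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  patients <- tibble(
    patient_id = sprintf("P%02d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE)
  )
  universe <- config$gene_universe %||% default_universe(config)
  hemi_genes <- vapply(
    Filter(function(p) p$zygosity == "hemi", config$plants),
    `[[`, character(1), "gene"
  )
  models <- synthetic_gene_models(universe, x_genes = hemi_genes)

  variants <- list()
  genotypes <- list()
  truth <- list()
  slot_by_gene <- new.env(parent = emptyenv())
  next_slot <- function(gene) {
    k <- (get0(gene, envir = slot_by_gene) %||% 0L) + 1L
    assign(gene, k, envir = slot_by_gene)
    k
  }
  taken <- character(0)

  for (p in config$plants) {
    if (is.null(p$carriers)) {
      pool <- setdiff(patients$patient_id, taken)
      if (length(pool) < p$carrier_count) {
        abort(paste0(
          "cannot place ", p$carrier_count, " non-overlapping carriers for ",
          p$gene, ": only ", length(pool), " unassigned patients remain"
        ), class = "edmd_infeasibility_error")
      }
      carriers <- sort(sample(pool, p$carrier_count))
      taken <- c(taken, carriers)
    } else {
      missing <- setdiff(p$carriers, patients$patient_id)
      if (length(missing) > 0) {
        abort(paste0("unknown carrier id(s): ", paste(missing, collapse = ", ")))
      }
      carriers <- p$carriers
    }
    if (p$zygosity == "hemi") {
      patients$sex[patients$patient_id %in% carriers] <- "male"
    }

    n_var <- length(p$consequences)
    vrows <- lapply(seq_len(n_var), function(j) {
      slot <- next_slot(p$gene)
      pos <- gene_position(models, p$gene, slot)
      alleles <- plant_alleles(p$consequences[[j]])
      tibble(
        chrom = gene_body(models, p$gene)$chrom, pos = pos,
        ref = alleles[[1]], alt = alleles[[2]], gene = p$gene,
        consequence = p$consequences[[j]],
        protein_change = sprintf("p.%s%d%s", "A", slot, "V"),
        population_frequency = p$population_frequency
      )
    })
    vtab <- dplyr::bind_rows(vrows)
    variants[[length(variants) + 1L]] <- vtab

    zyg <- switch(p$zygosity,
      het = "het", hom = "hom_alt", hemi = "hemi_alt", compound_het = "het"
    )
    for (carrier in carriers) {
      genotypes[[length(genotypes) + 1L]] <- tibble(
        sample_id = carrier, chrom = vtab$chrom, pos = vtab$pos,
        ref = vtab$ref, alt = vtab$alt, zygosity = zyg
      )
      truth[[length(truth) + 1L]] <- tibble(
        patient_id = carrier, gene = p$gene, chrom = vtab$chrom,
        pos = vtab$pos, ref = vtab$ref, alt = vtab$alt,
        zygosity = zyg, origin = "planted"
      )
    }
  }

  ## benign background: private variants, vectorised over all draws
  if (config$background_rate > 0) {
    counts <- rpois(n, config$background_rate)
    total <- sum(counts)
    if (total > 0) {
      carrier <- rep(patients$patient_id, counts)
      carrier_sex <- rep(patients$sex, counts)
      genes <- sample(universe, total, replace = TRUE)
      occ <- stats::ave(seq_len(total), genes, FUN = seq_along)
      body_idx <- match(genes, models$gene[models$feature == "gene"])
      bodies <- models[models$feature == "gene", ][body_idx, ]
      pos <- as.integer(bodies$start + 2100L + (200L + occ - 1L) * 37L)
      csq <- sample(consequence_vocabulary(), total,
        replace = TRUE,
        prob = c(.30, .02, .02, .02, .02, .02, .20, .25, .10, .05)
      )
      freq <- rbeta(total, config$maf_shape1, config$maf_shape2)
      for (it in 1:50) {
        low <- freq < config$min_background_frequency
        if (!any(low)) break
        freq[low] <- rbeta(sum(low), config$maf_shape1, config$maf_shape2)
      }
      freq <- pmax(freq, config$min_background_frequency)
      zyg <- sample(c("het", "hom_alt"), total, replace = TRUE, prob = c(.97, .03))
      zyg[is_x_contig(bodies$chrom) & carrier_sex == "male" & zyg == "het"] <- "hemi_alt"
      ref <- ifelse(csq == "frameshift", "CA", ifelse(csq == "inframe_indel", "CTTT", "C"))
      alt <- ifelse(csq %in% c("frameshift", "inframe_indel"), "C", "T")

      variants[[length(variants) + 1L]] <- tibble(
        chrom = bodies$chrom, pos = pos, ref = ref, alt = alt, gene = genes,
        consequence = csq, protein_change = NA_character_,
        population_frequency = freq
      )
      genotypes[[length(genotypes) + 1L]] <- tibble(
        sample_id = carrier, chrom = bodies$chrom, pos = pos,
        ref = ref, alt = alt, zygosity = zyg
      )
      truth[[length(truth) + 1L]] <- tibble(
        patient_id = carrier, gene = genes, chrom = bodies$chrom, pos = pos,
        ref = ref, alt = alt, zygosity = zyg, origin = "background"
      )
    }
  }

  empty_variants <- tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    gene = character(), consequence = character(),
    protein_change = character(), population_frequency = double()
  )
  empty_geno <- tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), zygosity = character()
  )
  variants <- if (length(variants)) {
    dplyr::arrange(
      dplyr::distinct(dplyr::bind_rows(variants)),
      .data$chrom, .data$pos, .data$ref, .data$alt
    )
  } else {
    empty_variants
  }
  genotypes <- if (length(genotypes)) dplyr::bind_rows(genotypes) else empty_geno
  truth <- if (length(truth)) {
    dplyr::bind_rows(truth)
  } else {
    dplyr::mutate(empty_geno[, -1], patient_id = character(),
                  gene = character(), zygosity = character(),
                  origin = character())[, c("patient_id", "gene", "chrom",
                                            "pos", "ref", "alt", "zygosity",
                                            "origin")]
  }

  structure(
    list(
      patients = patients, variants = variants, genotypes = genotypes,
      truth = truth, gene_models = models, config = config
    ),
    class = "cohort_simulation"
  )
}

plant_alleles <- function(consequence) {
  switch(consequence,
    frameshift = c("CA", "C"),
    inframe_indel = c("CTTT", "C"),
    c("C", "T")
  )
}

#' Write a simulated cohort to disk
#'
#' Emits the multi-sample VCF, the patient metadata TSV and the JSON
#' ground-truth ledger.  Reruns with the same seed produce byte-identical
#' files.
#'
#' @param sim A `cohort_simulation` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "cohort.vcf"),
    patients = file.path(dir, "patients.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(sim$variants, sim$genotypes, paths[["vcf"]],
    samples = sim$patients$patient_id
  )
  write_table_tsv(sim$patients, paths[["patients"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA)
  invisible(paths)
}
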