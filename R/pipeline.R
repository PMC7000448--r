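#' Run the full multistage discovery pipeline
#'
#' Orchestrates simulate -> (optional family stage) -> panel
#' construction -> cohort classification -> enrichment/connectivity
#' from a single configuration, writing every intermediate artifact and
#' a JSON + Markdown report into the output directory.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   * `seed`: integer seed used for every random draw;
#'   * `out_dir`: output directory;
#'   * `simulation`: either `"edmd_screen"` (the built-in scenario) or a
#'     [simulation_config()];
#'   * `family`: optional list of [simulate_family()] arguments; when
#'     present the family stage runs on that simulated family, when
#'     absent the pipeline starts at panel construction;
#'   * `min_recurrence`, `max_frequency`, `score_min`: stage parameters
#'     (defaults 2, 0.0005, 0.7);
#'   * `stages`: optional logical toggles `cohort`, `enrichment`.
#' @return A `run_report` list: per-stage record counts (telescoping:
#'   each stage's input equals the previous stage's output), the
#'   classification and summary, enrichment results, the package
#'   version, the echoed config and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% abort("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% list()
  do_cohort <- !isFALSE(stages$cohort)
  do_enrich <- !isFALSE(stages$enrichment)
  counts <- list()
  outputs <- character(0)

  ## --- simulation -----------------------------------------------------
  sim_cfg <- config$simulation %||% "edmd_screen"
  if (identical(sim_cfg, "edmd_screen")) sim_cfg <- edmd_screen_scenario(seed = seed)
  if (!inherits(sim_cfg, "simulation_config")) {
    abort("config$simulation must be 'edmd_screen' or a simulation_config")
  }
  sim <- simulate_cohort(sim_cfg)
  paths <- write_cohort(sim, out_dir)
  outputs <- c(outputs, paths)
  counts$simulated_variants <- nrow(sim$variants)
  counts$simulated_patients <- nrow(sim$patients)

  ann <- sim_cfg$annotation
  tables <- generate_tables(
    genes = unique(c(sim$variants$gene, sim_cfg$gene_universe %||% character(0))),
    muscle_specific = ann$muscle_specific %||% character(0),
    ne_genes = ann$ne_genes %||% character(0),
    go_genome_organisation_genes = ann$go_genome_organisation_genes %||% character(0),
    go_cytoskeleton_genes = ann$go_cytoskeleton_genes %||% character(0),
    plasma_membrane_genes = ann$plasma_membrane_genes %||% character(0),
    edges = ann$edges, variants = sim$variants, seed = seed
  )
  for (nm in c("frequency", "expression", "annotations", "edges")) {
    if (!is.null(tables[[nm]])) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      write_table_tsv(tables[[nm]], f)
      outputs <- c(outputs, f)
    }
  }

  ## --- family stage (optional) ----------------------------------------
  family_result <- NULL
  if (!is.null(config$family)) {
    fam_args <- config$family
    fam_args$seed <- fam_args$seed %||% seed
    fam <- do.call(simulate_family, fam_args)
    fcfg <- family_filter_config(mode = fam_args$mode %||% "AD")
    family_result <- run_family_stage(
      fam$variants, fam$genotypes, fam$pedigree, fcfg,
      expression = fam$expression
    )
    counts$family_variants_in <- nrow(fam$variants)
    counts$family_candidate_genes <- nrow(family_result$genes)
    f <- file.path(out_dir, "family_candidates.tsv")
    write_table_tsv(tidy(family_result), f)
    outputs <- c(outputs, f)
  }

  ## --- panel ----------------------------------------------------------
  panel <- if (is.null(config$panel_lists)) {
    edmd_panel()
  } else {
    build_panel(lapply(config$panel_lists, read_gene_list))
  }
  counts$panel_genes <- nrow(panel)
  f <- file.path(out_dir, "panel_registry.tsv")
  write_table_tsv(as_tibble(panel), f)
  outputs <- c(outputs, f)

  ## --- cohort classification ------------------------------------------
  classification <- NULL
  summary <- NULL
  if (do_cohort) {
    hits <- patient_filter(
      sim$variants, sim$genotypes, panel,
      freq_table = tables$frequency,
      max_frequency = config$max_frequency %||% 0.0005,
      patients = sim$patients
    )
    counts$cohort_variants_in <- counts$simulated_variants
    counts$cohort_gene_hits <- nrow(hits)
    classification <- classify_patients(
      hits, sim$patients,
      min_patients = config$min_recurrence %||% 2L
    )
    summary <- cohort_summary(classification, panel)
    counts$patients_classified <- nrow(classification$classifications)

    jsonlite::write_json(
      classification$classifications,
      file.path(out_dir, "classifications.json"),
      digits = NA
    )
    write_table_tsv(render_patient_table(classification),
      file.path(out_dir, "patient_table.tsv")
    )
    write_table_tsv(summary$status_counts, file.path(out_dir, "status_counts.tsv"))
    outputs <- c(outputs, file.path(out_dir, c(
      "classifications.json", "patient_table.tsv", "status_counts.tsv"
    )))
  }

  ## --- enrichment / connectivity --------------------------------------
  enrichment <- NULL
  connectivity_report <- NULL
  if (do_enrich && do_cohort && nrow(classification$hits) > 0) {
    fg <- sort(unique(
      classification$hits$gene[!(classification$hits$modifier_only %in% TRUE)]
    ))
    enrichment <- candidate_enrichment(fg, tables$annotations)
    if (!is.null(tables$edges)) {
      connectivity_report <- connectivity(
        fg, tables$edges,
        threshold = config$score_min %||% 0.7,
        annotations = tables$annotations
      )
    }
    jsonlite::write_json(enrichment, file.path(out_dir, "enrichment.json"),
      digits = NA
    )
    outputs <- c(outputs, file.path(out_dir, "enrichment.json"))
    counts$candidate_genes_tested <- length(fg)
  }

  ## telescoping self-check
  if (do_cohort && counts$cohort_variants_in != counts$simulated_variants) {
    abort("internal consistency error: stage counts do not telescope")
  }

  report <- structure(
    list(
      version = as.character(packageVersion("edmdpanel")),
      seed = seed, counts = counts,
      classification = classification, summary = summary,
      family = family_result,
      enrichment = enrichment, connectivity = connectivity_report,
      config = config, outputs = unname(outputs)
    ),
    class = "run_report"
  )
  jsonlite::write_json(
    list(version = report$version, seed = seed, counts = counts,
         outputs = report$outputs),
    file.path(out_dir, "report.json"),
    digits = NA, auto_unbox = TRUE
  )
  writeLines(render_report_md(report), file.path(out_dir, "report.md"))
  report
}

render_report_md <- function(report) {
  lines <- c(
    "# Multistage candidate-gene discovery run",
    "",
    paste0("- package version: ", report$version),
    paste0("- seed: ", report$seed),
    "",
    "## Stage record counts",
    vapply(names(report$counts), function(n) {
      paste0("- ", n, ": ", report$counts[[n]])
    }, character(1))
  )
  if (!is.null(report$summary)) {
    sc <- report$summary$status_counts
    lines <- c(
      lines, "", "## Patient classification",
      sprintf("- %s: %d", sc$status, sc$n),
      sprintf("- clearly assigned: %d", report$summary$n_clearly_assigned)
    )
  }
  if (!is.null(report$connectivity)) {
    lines <- c(
      lines, "", "## Connectivity",
      sprintf(
        "- NE to plasma-membrane path: %s",
        if (report$connectivity$ne_to_pm_path_exists) {
          paste(report$connectivity$example_path, collapse = " - ")
        } else {
          report$connectivity$reason
        }
      )
    )
  }
  lines
}

#' Render the per-patient hit table
#'
#' One row per patient x gene hit, mirroring the columns of a clinical
#' result table: patient, gene, protein changes, zygosity, highest
#' population frequency, evidence tier, patient status, notes.  An
#' empty cohort yields a header-only (zero-row) table.
#'
#' @param classification A `cohort_classification`.
#' @return A tibble.
#' @export
render_patient_table <- function(classification) {
  hits <- classification$hits
  cl <- classification$classifications
  if (nrow(hits) == 0) {
    return(tibble(
      patient_id = character(), gene = character(),
      protein_changes = character(), zygosity = character(),
      max_frequency = double(), tier = character(), status = character(),
      notes = character()
    ))
  }
  hits |>
    dplyr::mutate(
      protein_changes = vapply(.data$variants, function(v) {
        paste(ifelse(is.na(v$protein_change), ".", v$protein_change),
          collapse = ","
        )
      }, character(1)),
      max_frequency = vapply(.data$variants, function(v) {
        if (all(is.na(v$population_frequency))) NA_real_ else
          max(v$population_frequency, na.rm = TRUE)
      }, double(1))
    ) |>
    dplyr::left_join(
      dplyr::select(cl, "patient_id", "status", cl_notes = "notes"),
      by = "patient_id"
    ) |>
    dplyr::transmute(
      patient_id = .data$patient_id, gene = .data$gene,
      protein_changes = .data$protein_changes,
      zygosity = .data$zygosities, max_frequency = .data$max_frequency,
      tier = .data$tier, status = .data$status, notes = .data$cl_notes
    ) |>
    dplyr::arrange(.data$patient_id, .data$gene)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> edmdpanel", x$version, "seed", x$seed, "\n")
  for (n in names(x$counts)) cat("  ", n, ": ", x$counts[[n]], "\n", sep = "")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
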