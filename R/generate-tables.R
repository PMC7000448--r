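#' Generate the annotation side tables for a simulated gene universe
#'
#' Produces the four tables the analysis stages consume: per-tissue
#' expression (designated muscle-specific genes receive a muscle value
#' strictly greater than twice their highest other-tissue value),
#' gene-annotation flags (nuclear-envelope localisation, the two GO
#' flags, plasma membrane) and an interaction edge table.  A frequency
#' table can be derived from a variant table.
#'
#' @param genes Gene universe (non-empty character vector).
#' @param tissues Tissue names; must include `"muscle"`.
#' @param muscle_specific Genes to flag muscle-specific.
#' @param ne_genes,go_genome_organisation_genes,go_cytoskeleton_genes,plasma_membrane_genes
#'   Genes to flag in the annotation table.
#' @param edges Optional edge tibble (`gene_a`, `gene_b`, `confidence`);
#'   canonicalised on the way in.
#' @param variants Optional variant tibble from which the frequency
#'   table (`chrom, pos, ref, alt, frequency`) is derived.
#' @param seed Integer seed; fixed seed, identical tables.
#' @return A list: `frequency` (or `NULL`), `expression`, `annotations`,
#'   `edges` (or `NULL`).
#' @export
generate_tables <- function(genes,
                            tissues = c("muscle", "heart", "brain", "liver",
                                        "lung", "kidney"),
                            muscle_specific = character(0),
                            ne_genes = character(0),
                            go_genome_organisation_genes = character(0),
                            go_cytoskeleton_genes = character(0),
                            plasma_membrane_genes = character(0),
                            edges = NULL, variants = NULL, seed = 1L) {
  if (length(genes) == 0) abort("gene universe must be non-empty")
  if (!"muscle" %in% tissues) abort("tissues must include 'muscle'")
  genes <- unique(genes)
  other <- setdiff(tissues, "muscle")

  expression <- withr::with_seed(seed, {
    rows <- lapply(genes, function(g) {
      vals <- rlnorm(length(other), meanlog = log(10), sdlog = 0.4)
      muscle <- if (g %in% muscle_specific) {
        max(vals) * runif(1, 2.2, 5)
      } else {
        rlnorm(1, meanlog = log(10), sdlog = 0.4)
      }
      tibble(gene = g, tissue = c("muscle", other), value = c(muscle, vals))
    })
    dplyr::bind_rows(rows)
  })

  annotations <- tibble(
    gene = genes,
    ne_localised = genes %in% ne_genes,
    go_genome_organisation = genes %in% go_genome_organisation_genes,
    go_cytoskeleton = genes %in% go_cytoskeleton_genes,
    plasma_membrane = genes %in% plasma_membrane_genes
  )

  frequency <- NULL
  if (!is.null(variants) && nrow(variants) > 0) {
    frequency <- tibble(
      chrom = variants$chrom, pos = variants$pos,
      ref = variants$ref, alt = variants$alt,
      frequency = variants$population_frequency
    )
    frequency <- dplyr::distinct(frequency)
  }
  if (!is.null(edges)) edges <- canonicalise_edges(edges)

  list(
    frequency = frequency, expression = expression,
    annotations = annotations, edges = edges
  )
}
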