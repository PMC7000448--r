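#' Readers and writers for the tab-delimited annotation tables
#'
#' All side tables consumed by the pipeline are plain TSV with a header
#' row: the population allele-frequency table (gnomAD-style, frequencies
#' stored as fractions), the per-tissue expression table (long format),
#' the gene-annotation flag table, the interaction edge table and the
#' panel category gene lists.
#'
#' Duplicate rows with conflicting values raise a conflict error;
#' identical duplicates are collapsed silently.  A gene or variant absent
#' from a table is treated as "absent" (`NA`) by downstream lookups,
#' never silently as zero.
#'
#' @param path Path to the TSV file.
#' @return A tibble with validated columns (see Details).
#' @details Expected columns: frequency table `chrom, pos, ref, alt,
#'   frequency`; expression table `gene, tissue, value`; annotation table
#'   `gene, ne_localised, go_genome_organisation, go_cytoskeleton,
#'   plasma_membrane` (logical); edge table `gene_a, gene_b, confidence`;
#'   gene lists `symbol` plus optional `modes` and `modifier_only`.
#' @name annotation_tables
NULL

read_tsv_quiet <- function(path, col_types) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE)
}

check_conflicts <- function(df, keys, what) {
  dup <- dplyr::distinct(df)
  if (anyDuplicated(dup[keys])) {
    bad <- dup[duplicated(dup[keys]), keys, drop = FALSE]
    abort(paste0(
      "conflicting duplicate rows in ", what, " for: ",
      paste(do.call(paste, c(bad, sep = ":"))[1], collapse = ", ")
    ), class = "edmd_conflict_error")
  }
  dup
}

#' @rdname annotation_tables
#' @export
read_frequency_table <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), alt = readr::col_character(),
    frequency = readr::col_double()
  ))
  check_conflicts(df, c("chrom", "pos", "ref", "alt"), "frequency table")
}

#' @rdname annotation_tables
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    gene = readr::col_character(), tissue = readr::col_character(),
    value = readr::col_double()
  ))
  if (any(!is.finite(df$value)) || any(df$value < 0)) {
    abort("expression values must be finite and non-negative")
  }
  check_conflicts(df, c("gene", "tissue"), "expression table")
}

#' @rdname annotation_tables
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    gene = readr::col_character(),
    ne_localised = readr::col_logical(),
    go_genome_organisation = readr::col_logical(),
    go_cytoskeleton = readr::col_logical(),
    plasma_membrane = readr::col_logical()
  ))
  check_conflicts(df, "gene", "annotation table")
}

#' @rdname annotation_tables
#' @export
read_edge_table <- function(path) {
  df <- read_tsv_quiet(path, readr::cols(
    gene_a = readr::col_character(), gene_b = readr::col_character(),
    confidence = readr::col_double()
  ))
  canonicalise_edges(df)
}

#' Canonicalise an undirected interaction edge table
#'
#' Orders each pair alphabetically, removes self-edges with an error, and
#' collapses duplicates (conflicting confidences raise a conflict error).
#'
#' @param edges Tibble with `gene_a`, `gene_b`, `confidence`.
#' @return The canonical edge tibble.
#' @export
canonicalise_edges <- function(edges) {
  if (any(edges$gene_a == edges$gene_b)) {
    abort("self-interaction edges are not allowed")
  }
  if (any(edges$confidence < 0 | edges$confidence > 1)) {
    abort("edge confidences must lie in [0, 1]")
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  out <- tibble(gene_a = a, gene_b = b, confidence = edges$confidence)
  check_conflicts(out, c("gene_a", "gene_b"), "edge table")
}

#' @rdname annotation_tables
#' @export
read_gene_list <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"symbol" %in% names(df)) abort("gene list must have a 'symbol' column")
  if ("modifier_only" %in% names(df)) {
    df$modifier_only <- as.logical(df$modifier_only)
  }
  df
}

#' Look up population frequencies for variant records
#'
#' Left-joins a frequency table onto a variant table by the
#' (chrom, pos, ref, alt) identity key.  Variants absent from the table
#' get `NA` ("absent"), which downstream filters handle explicitly.
#'
#' @param variants Variant tibble.
#' @param freq_table Frequency tibble from [read_frequency_table()], or
#'   `NULL` to use the `population_frequency` column already present.
#' @return Numeric vector of frequencies (fractions), `NA` when absent.
#' @export
lookup_frequency <- function(variants, freq_table = NULL) {
  if (is.null(freq_table)) {
    if (!"population_frequency" %in% names(variants)) {
      return(rep(NA_real_, nrow(variants)))
    }
    return(variants$population_frequency)
  }
  key <- variant_key(variants)
  tab <- setNames(freq_table$frequency, variant_key(freq_table))
  unname(tab[key])
}

#' @rdname annotation_tables
#' @param df Tibble to write.
#' @export
write_table_tsv <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
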