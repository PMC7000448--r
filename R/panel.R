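#' Build the four-category gene panel registry
#'
#' Combines four category gene lists into a single registry with one
#' entry per unique symbol.  Categories: I — known EDMD-linked genes
#' (the `LMNA` and `EMD` entries cover the whole gene, all other genes
#' their ORF only); II — genes of similar muscular dystrophies; III —
#' family exome-sequencing candidates; IV — functional candidates
#' (mostly muscle-specific nuclear-envelope proteins).  A gene present
#' in several lists receives the union of category tags.
#'
#' @param category_lists Named list with elements `I`, `II`, `III`,
#'   `IV`; each a character vector of symbols or a tibble with `symbol`
#'   and optional `modes` (comma-separated inheritance modes) and
#'   `modifier_only` columns.
#' @param metadata Optional tibble (`symbol`, `modes`, `modifier_only`)
#'   overriding per-list metadata.
#' @return A `panel_registry` tibble: `symbol`, `categories`
#'   (comma-joined tags), `region_scope` (`whole_gene` for `LMNA`/`EMD`
#'   in category I, else `orf_only`), `known_modes`, `association`,
#'   `modifier_only`.  Category sizes are attached as
#'   `attr(, "category_sizes")`.
#' @details Duplicate symbols within one list are deduplicated with a
#'   warning; an empty category list is a configuration error.  The
#'   single "primary" association label follows the precedence
#'   I > II > IV > III.
#' @export
build_panel <- function(category_lists, metadata = NULL) {
  cats <- c("I", "II", "III", "IV")
  if (!all(cats %in% names(category_lists))) {
    abort("category_lists must have elements I, II, III and IV")
  }
  norm <- lapply(cats, function(cc) {
    x <- category_lists[[cc]]
    if (is.character(x)) x <- tibble(symbol = x)
    if (!"symbol" %in% names(x)) abort("each category list needs a 'symbol' column")
    if (nrow(x) == 0) {
      abort(paste0("category ", cc, " list is empty"), class = "edmd_config_error")
    }
    if (anyDuplicated(x$symbol)) {
      warn(paste0(
        "duplicate symbol(s) within category ", cc, " list: ",
        paste(unique(x$symbol[duplicated(x$symbol)]), collapse = ", ")
      ))
      x <- x[!duplicated(x$symbol), ]
    }
    x$category <- cc
    x
  })
  all_rows <- dplyr::bind_rows(norm)
  if (!"modes" %in% names(all_rows)) all_rows$modes <- NA_character_
  if (!"modifier_only" %in% names(all_rows)) all_rows$modifier_only <- NA

  registry <- dplyr::summarise(
    dplyr::group_by(all_rows, .data$symbol),
    categories = paste(sort(unique(.data$category)), collapse = ","),
    known_modes = {
      m <- unique(stats::na.omit(.data$modes))
      if (length(m) == 0) "unknown" else paste(m, collapse = ",")
    },
    modifier_only = isTRUE(any(.data$modifier_only)),
    .groups = "drop"
  )
  if (!is.null(metadata)) {
    md <- dplyr::select(metadata, "symbol",
      md_modes = dplyr::any_of("modes"),
      md_modifier = dplyr::any_of("modifier_only")
    )
    registry <- dplyr::left_join(registry, md, by = "symbol")
    if ("md_modes" %in% names(registry)) {
      registry$known_modes <- dplyr::coalesce(registry$md_modes, registry$known_modes)
      registry$md_modes <- NULL
    }
    if ("md_modifier" %in% names(registry)) {
      registry$modifier_only <- dplyr::coalesce(registry$md_modifier, registry$modifier_only)
      registry$md_modifier <- NULL
    }
  }

  has_cat <- function(tags, cc) {
    vapply(strsplit(tags, ",", fixed = TRUE), function(t) cc %in% t, logical(1))
  }
  registry$region_scope <- ifelse(
    registry$symbol %in% c("LMNA", "EMD") & has_cat(registry$categories, "I"),
    "whole_gene", "orf_only"
  )
  precedence <- c("I", "II", "IV", "III")
  assoc_map <- c(
    I = "edmd_linked", II = "related_md",
    IV = "functional_candidate", III = "exome_candidate"
  )
  registry$association <- vapply(
    strsplit(registry$categories, ",", fixed = TRUE),
    function(t) unname(assoc_map[[precedence[precedence %in% t][1]]]),
    character(1)
  )
  registry <- dplyr::arrange(
    dplyr::select(
      registry, "symbol", "categories", "region_scope", "known_modes",
      "association", "modifier_only"
    ),
    .data$association, .data$symbol
  )
  attr(registry, "category_sizes") <- vapply(
    cats, function(cc) sum(has_cat(registry$categories, cc)), integer(1)
  )
  class(registry) <- c("panel_registry", class(registry))
  registry
}

#' Gene categories of a panel registry as a logical helper
#'
#' @param registry A `panel_registry` tibble.
#' @param category One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return Character vector of symbols tagged with that category.
#' @export
panel_genes <- function(registry, category = NULL) {
  if (is.null(category)) {
    return(registry$symbol)
  }
  sel <- vapply(
    strsplit(registry$categories, ",", fixed = TRUE),
    function(t) category %in% t, logical(1)
  )
  registry$symbol[sel]
}

#' The packaged four-category EDMD panel
#'
#' Builds the registry from the packaged category lists: 8 known
#' EDMD-linked genes (I), 25 related-muscular-dystrophy genes (II), 252
#' exome-stage candidates (III) and 16 functional candidates (IV) — 301
#' genes in total.  The category III and IV lists are synthetic
#' stand-ins (the genuine supplementary lists are not distributed):
#' they keep the named top candidates and pad with placeholder symbols
#' to the printed category sizes.
#'
#' @return A `panel_registry` tibble of 301 genes.
#' @export
edmd_panel <- function() {
  path <- function(f) system.file("extdata", f, package = "edmdpanel", mustWork = TRUE)
  build_panel(list(
    I = read_gene_list(path("panel_category_I_known_edmd.tsv")),
    II = read_gene_list(path("panel_category_II_related_md.tsv")),
    III = read_gene_list(path("panel_category_III_exome_candidates_synthetic.tsv")),
    IV = read_gene_list(path("panel_category_IV_functional_candidates_synthetic.tsv"))
  ))
}

#' Emit target regions for a panel registry
#'
#' `orf_only` genes contribute their merged ORF exon intervals;
#' `whole_gene` entries contribute the full gene body extended upstream
#' by a promoter flank (default 2 kb), so promoter and other non-coding
#' variation in those genes is captured.  Output is 0-based half-open
#' (BED convention); input gene models are 1-based inclusive.
#'
#' @param registry A `panel_registry`.
#' @param gene_models Gene-model tibble (see [synthetic_gene_models()]).
#' @param promoter_flank Upstream flank in bp for `whole_gene` entries.
#' @return A tibble `chrom`, `start`, `end`, `gene`, sorted, with
#'   per-gene intervals merged (non-overlapping within a gene).
#' @export
target_regions <- function(registry, gene_models, promoter_flank = 2000L) {
  missing <- setdiff(registry$symbol, unique(gene_models$gene))
  if (length(missing) > 0) {
    abort(paste0(
      "no gene model for panel gene(s): ", paste(missing, collapse = ", ")
    ), class = "edmd_coverage_error")
  }
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    g <- registry$symbol[[i]]
    if (registry$region_scope[[i]] == "whole_gene") {
      body <- gene_body(gene_models, g)
      tibble(
        chrom = body$chrom,
        start = max(0L, body$start - 1L - as.integer(promoter_flank)),
        end = body$end, gene = g
      )
    } else {
      ex <- gene_models[gene_models$gene == g & gene_models$feature == "orf_exon", ]
      if (nrow(ex) == 0) {
        abort(paste0("no ORF exons modelled for ", g), class = "edmd_coverage_error")
      }
      merged <- IRanges::reduce(IRanges::IRanges(start = ex$start, end = ex$end))
      tibble(
        chrom = ex$chrom[[1]],
        start = IRanges::start(merged) - 1L,
        end = IRanges::end(merged), gene = g
      )
    }
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$chrom, .data$start, .data$end)
}

#' Read/write target regions as BED
#'
#' BED is 0-based half-open with columns chrom, start, end, name.
#'
#' @param regions Region tibble from [target_regions()].
#' @param path File path.
#' @return `read_bed()` returns the region tibble; `write_bed()` the
#'   path, invisibly.
#' @export
write_bed <- function(regions, path) {
  write.table(
    regions[, c("chrom", "start", "end", "gene")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- read.table(path,
    header = FALSE, sep = "\t",
    col.names = c("chrom", "start", "end", "gene"),
    colClasses = c("character", "integer", "integer", "character")
  )
  as_tibble(df)
}

#' @export
print.panel_registry <- function(x, ...) {
  sizes <- attr(x, "category_sizes")
  cat("<panel_registry>", nrow(x), "genes",
      sprintf("(I: %d, II: %d, III: %d, IV: %d)\n",
              sizes[["I"]], sizes[["II"]], sizes[["III"]], sizes[["IV"]]))
  NextMethod()
}
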