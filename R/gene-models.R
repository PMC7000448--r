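#' Deterministic synthetic gene models
#'
#' Assigns every gene in a universe a contig, a gene interval and a fixed
#' number of coding (ORF) exons.  The layout is a deterministic function
#' of the sorted gene symbols, so the same universe always yields the
#' same models regardless of the random seed.  Genes known to be X-linked
#' in this disease area (`DMD`, `EMD`, `FHL1`) are placed on the X
#' contig; additional X genes can be requested (needed when a hemizygous
#' allele is planted in an arbitrary gene).
#'
#' @param genes Character vector of gene symbols.
#' @param x_genes Genes to place on the X contig.
#' @param gene_length Length of each synthetic gene body in bp.
#' @param n_exons Number of ORF exons per gene.
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`
#'   (1-based, inclusive) and `feature` (`"gene"` or `"orf_exon"`).
#' @export
synthetic_gene_models <- function(genes, x_genes = character(0),
                                  gene_length = 20000L, n_exons = 3L) {
  genes <- unique(genes)
  x_genes <- union(c("DMD", "EMD", "FHL1"), x_genes)
  ord <- sort(genes)
  rows <- lapply(seq_along(ord), function(i) {
    g <- ord[[i]]
    chrom <- if (g %in% x_genes) "X" else as.character((i %% 22L) + 1L)
    start <- 1000000L + i * 100000L
    end <- start + gene_length - 1L
    exon_starts <- start + 2000L + (seq_len(n_exons) - 1L) * 6000L
    tibble(
      gene = g,
      chrom = chrom,
      start = c(start, exon_starts),
      end = c(end, exon_starts + 1499L),
      feature = c("gene", rep("orf_exon", n_exons))
    )
  })
  dplyr::bind_rows(rows)
}

gene_body <- function(gene_models, gene) {
  row <- gene_models[gene_models$gene == gene & gene_models$feature == "gene", ]
  if (nrow(row) == 0) {
    abort(paste0("no gene model for: ", gene), class = "edmd_coverage_error")
  }
  row[1, ]
}

## Deterministic within-gene position allocator: slot k of a gene body.
gene_position <- function(gene_models, gene, slot) {
  body <- gene_body(gene_models, gene)
  pos <- body$start + 2100L + (slot - 1L) * 37L
  if (any(pos > body$end)) abort(paste0("position allocator overflow in ", gene))
  as.integer(pos)
}
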