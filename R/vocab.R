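#' Controlled vocabularies
#'
#' The closed vocabularies shared by every stage of the pipeline: variant
#' consequences, the subset of consequences that alter the coding sequence,
#' inheritance modes, and per-sample zygosity levels.
#'
#' Consequences are consumed as pre-computed annotations (one token per
#' variant allele); the package never derives them from transcripts.
#'
#' @return A character vector of tokens.
#' @examples
#' consequence_vocabulary()
#' coding_consequences()
#' @export
consequence_vocabulary <- function() {
  c(
    "missense", "nonsense", "frameshift", "splice_donor", "splice_acceptor",
    "inframe_indel", "synonymous", "intronic", "utr", "intergenic"
  )
}

#' @rdname consequence_vocabulary
#' @export
coding_consequences <- function() {
  c(
    "missense", "nonsense", "frameshift", "splice_donor", "splice_acceptor",
    "inframe_indel"
  )
}

#' @rdname consequence_vocabulary
#' @export
inheritance_modes <- function() c("AD", "AR", "XLR", "XLD", "de_novo")

#' @rdname consequence_vocabulary
#' @export
zygosity_levels <- function() c("hom_ref", "het", "hom_alt", "hemi_alt", "missing")

#' @rdname consequence_vocabulary
#' @export
patient_statuses <- function() {
  c(
    "solved_known_edmd", "solved_related_md", "candidate_recurrent",
    "candidate_functional", "ambiguous_multi", "unsolved"
  )
}

#' @rdname consequence_vocabulary
#' @export
evidence_tiers <- function() c("dark_green", "light_green", "yellow", "purple")

assert_consequences <- function(x, where = "variant table") {
  bad <- setdiff(unique(x[!is.na(x)]), consequence_vocabulary())
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown consequence token(s) in %s: %s",
      where, paste(bad, collapse = ", ")
    ), class = "edmd_vocabulary_error")
  }
  invisible(x)
}

is_x_contig <- function(chrom) chrom %in% c("X", "chrX", "Y", "chrY")

carries_alt <- function(zygosity) zygosity %in% c("het", "hom_alt", "hemi_alt")

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

assert_variants <- function(variants) {
  needed <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  missing <- setdiff(needed, names(variants))
  if (length(missing) > 0) {
    abort(paste0("variant table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(variants) > 0) {
    if (any(variants$pos < 1)) abort("variant positions must be >= 1")
    if (any(variants$ref == variants$alt)) abort("ref and alt alleles must differ")
    assert_consequences(variants$consequence)
  }
  invisible(variants)
}
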