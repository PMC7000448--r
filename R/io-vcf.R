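#' Read a multi-sample VCF into tidy variant and genotype tables
#'
#' Parses a VCF v4.2 file whose `INFO` field carries `GENE`, `CSQ` and
#' (optionally) `AF` and `HGVSP` keys, and whose `FORMAT` includes `GT`.
#' Multi-allelic sites are decomposed into one record per ALT allele;
#' per-allele INFO values (comma separated) are split alongside.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A list with two tibbles:
#'   * `variants`: one row per (chrom, pos, ref, alt) with `gene`,
#'     `consequence`, `protein_change` and `population_frequency`
#'     (`NA` when the allele is absent from the frequency source).
#'   * `genotypes`: one row per sample x variant with `zygosity`
#'     (`hom_ref`, `het`, `hom_alt`, `hemi_alt` or `missing`).
#' @details Unknown consequence tokens are rejected with a vocabulary
#'   error; malformed body lines are reported with their line number.
#' @seealso [write_vcf()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such VCF file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[[1]], "##fileformat=VCF")) {
    abort(paste0("malformed VCF header (line 1): missing ##fileformat in ", path),
      class = "edmd_parse_error"
    )
  }
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    nf <- length(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (nf < 8) {
      abort(sprintf("malformed VCF line %d: %d field(s), expected >= 8", i, nf),
        class = "edmd_parse_error"
      )
    }
  }

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  samples <- if (is.null(gt)) character(0) else colnames(gt)[-1]

  variants <- vector("list", nrow(fix))
  genos <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    info <- parse_info(fix[i, "INFO"])
    per_allele <- function(key, default = NA_character_) {
      v <- info[[key]] %||% default
      v <- strsplit(v, ",", fixed = TRUE)[[1]]
      if (length(v) == 1) v <- rep(v, length(alts))
      v
    }
    gene <- per_allele("GENE")
    csq <- per_allele("CSQ")
    af <- suppressWarnings(as.numeric(per_allele("AF")))
    hgvsp <- per_allele("HGVSP")
    hgvsp[hgvsp == "."] <- NA_character_

    variants[[i]] <- tibble(
      chrom = fix[i, "CHROM"],
      pos = as.integer(fix[i, "POS"]),
      ref = fix[i, "REF"],
      alt = alts,
      gene = gene,
      consequence = csq,
      protein_change = hgvsp,
      population_frequency = af
    )

    if (length(samples) > 0) {
      gts <- sub(":.*$", "", gt[i, -1])
      alleles <- strsplit(gsub("|", "/", gts, fixed = TRUE), "/", fixed = TRUE)
      rows <- lapply(seq_along(alts), function(k) {
        zyg <- unname(vapply(alleles, classify_gt, character(1), k = k))
        tibble(
          sample_id = samples,
          chrom = fix[i, "CHROM"],
          pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"],
          alt = alts[[k]],
          zygosity = zyg
        )
      })
      genos[[i]] <- dplyr::bind_rows(rows)
    }
  }
  variants <- dplyr::bind_rows(variants)
  genotypes <- dplyr::bind_rows(genos)
  if (nrow(genotypes) == 0) {
    genotypes <- tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), zygosity = character()
    )
  }
  assert_variants(variants)
  list(variants = variants, genotypes = genotypes)
}

parse_info <- function(x) {
  if (is.na(x) || x == "." || x == "") {
    return(list())
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) >= 2) p[[2]] else TRUE)
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

classify_gt <- function(alleles, k) {
  if (any(alleles == ".")) {
    return("missing")
  }
  n_alt <- sum(alleles == as.character(k))
  if (length(alleles) == 1) {
    if (n_alt >= 1) "hemi_alt" else "hom_ref"
  } else if (n_alt >= 2) {
    "hom_alt"
  } else if (n_alt == 1) {
    "het"
  } else {
    "hom_ref"
  }
}

#' Write tidy variant and genotype tables as VCF v4.2
#'
#' The inverse of [read_vcf()].  One line is emitted per variant record;
#' genotype rows absent for a sample x variant pair are written as
#' homozygous reference (the sparse-storage convention used throughout
#' the package).
#'
#' @param variants Tibble of variant records (see [read_vcf()]).
#' @param genotypes Tibble of genotype calls, or `NULL` for a site-only VCF.
#' @param path Output path.
#' @param samples Sample column order; defaults to the sorted unique
#'   `sample_id` values.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes = NULL, path, samples = NULL) {
  assert_variants(variants)
  if (is.null(samples)) {
    samples <- if (is.null(genotypes)) character(0) else sort(unique(genotypes$sample_id))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Variant consequence\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency (fraction)\">",
    "##INFO=<ID=HGVSP,Number=A,Type=String,Description=\"Protein change\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      if (length(samples) > 0) c("FORMAT", samples)
    ), collapse = "\t")
  )

  v <- dplyr::arrange(variants, .data$chrom, .data$pos, .data$ref, .data$alt)
  gt_map <- c(
    hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
    hemi_alt = "1", missing = "./."
  )
  geno_lookup <- NULL
  if (length(samples) > 0 && !is.null(genotypes) && nrow(genotypes) > 0) {
    geno_lookup <- setNames(
      genotypes$zygosity,
      paste(genotypes$sample_id, variant_key(genotypes), sep = "|")
    )
  }

  body <- vapply(seq_len(nrow(v)), function(i) {
    info <- c(
      paste0("GENE=", v$gene[[i]]),
      paste0("CSQ=", v$consequence[[i]])
    )
    af <- v$population_frequency[[i]]
    if (!is.null(af) && !is.na(af)) {
      info <- c(info, paste0(
        "AF=", format(af, scientific = FALSE, trim = TRUE, digits = 15)
      ))
    }
    pc <- if ("protein_change" %in% names(v)) v$protein_change[[i]] else NA_character_
    if (!is.na(pc)) info <- c(info, paste0("HGVSP=", pc))
    fields <- c(
      v$chrom[[i]], v$pos[[i]], ".", v$ref[[i]], v$alt[[i]], ".", "PASS",
      paste(info, collapse = ";")
    )
    if (length(samples) > 0) {
      key <- paste(samples, variant_key(v[i, ]), sep = "|")
      zyg <- geno_lookup[key]
      zyg[is.na(zyg)] <- "hom_ref"
      fields <- c(fields, "GT", unname(gt_map[zyg]))
    }
    paste(fields, collapse = "\t")
  }, character(1))

  writeLines(c(header, body), path)
  invisible(path)
}
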