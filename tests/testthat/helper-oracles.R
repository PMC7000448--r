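## Independent oracles used across the suite.  Deliberately written as
## plain loops / closed forms so they share no code with the package.

## Brute-force Mendelian transmission check: every non-founder's allele
## count must be reachable as one allele from each parent (X-linked:
## sons draw from the mother only, fathers transmit their X to all
## daughters).
oracle_mendelian_ok <- function(pedigree, genotypes) {
  count_of <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, hemi_alt = 1L)
  keys <- unique(paste(genotypes$chrom, genotypes$pos, genotypes$ref,
                       genotypes$alt, sep = ":"))
  for (key in keys) {
    sub <- genotypes[paste(genotypes$chrom, genotypes$pos, genotypes$ref,
                           genotypes$alt, sep = ":") == key, ]
    on_x <- sub$chrom[[1]] %in% c("X", "chrX")
    cnt <- setNames(count_of[sub$zygosity], sub$sample_id)
    ploidy <- function(id) {
      if (on_x && pedigree$sex[pedigree$individual_id == id] == "male") 1L else 2L
    }
    gametes <- function(id) {
      d <- cnt[[id]]
      p <- ploidy(id)
      if (p == 1L) d else unique(c(if (d >= 1) 1L else 0L, if (d <= 1) 0L else 1L))
    }
    for (i in seq_len(nrow(pedigree))) {
      f <- pedigree$father_id[[i]]
      m <- pedigree$mother_id[[i]]
      if (f == "0" || m == "0") next
      id <- pedigree$individual_id[[i]]
      male <- pedigree$sex[[i]] == "male"
      possible <- if (on_x && male) {
        gametes(m)
      } else {
        as.vector(outer(gametes(f), gametes(m), `+`))
      }
      if (!(cnt[[id]] %in% possible)) return(FALSE)
    }
  }
  TRUE
}

## Union-find connected components over an edge list.
oracle_components <- function(nodes, edges_a, edges_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(edges_a)) {
    ra <- find(edges_a[[i]])
    rb <- find(edges_b[[i]])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  match(roots, unique(roots))
}

## Exact over-representation tail by exhaustive subset enumeration:
## P(overlap >= k) when drawing n genes from a universe of N with K
## flagged, counting subsets directly.
oracle_enrichment_p <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  flagged <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% flagged))
  mean(hits >= k)
}

## Closed-form hypergeometric upper tail via explicit binomials.
oracle_hyper_tail <- function(N, K, n, k) {
  js <- k:min(n, K)
  if (length(js) == 0 || k > min(n, K)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## Plain-rule co-segregation verdict for a single autosomal variant.
## zyg: named zygosity vector over all members.
oracle_coseg_single <- function(zyg, mode, affected, unaffected,
                                sex = NULL, on_x = FALSE,
                                father = NULL, mother = NULL) {
  carry <- function(z) z %in% c("het", "hom_alt", "hemi_alt")
  if (mode == "AD") {
    all(carry(zyg[affected])) && !any(carry(zyg[unaffected]))
  } else if (mode == "AR") {
    all(zyg[affected] == "hom_alt") && !any(zyg[unaffected] == "hom_alt")
  } else if (mode == "XLR") {
    dose <- function(id) {
      if (sex[[id]] == "male") {
        zyg[[id]] %in% c("hemi_alt", "hom_alt")
      } else {
        zyg[[id]] == "hom_alt"
      }
    }
    on_x && all(vapply(affected, dose, logical(1))) &&
      !any(vapply(unaffected, dose, logical(1)))
  } else if (mode == "XLD") {
    on_x && all(carry(zyg[affected])) && !any(carry(zyg[unaffected]))
  } else if (mode == "de_novo") {
    parents_clear <- all(vapply(affected, function(id) {
      ok <- TRUE
      for (p in c(father[[id]], mother[[id]])) {
        if (p != "0") ok <- ok && !carry(zyg[[p]])
      }
      ok
    }, logical(1)))
    all(carry(zyg[affected])) && parents_clear && !any(carry(zyg[unaffected]))
  } else {
    stop("unknown mode")
  }
}

## Six-member two-generation pedigree used by the exhaustive tests:
## affected father (1), unaffected mother (2), affected children 3, 4,
## unaffected children 5, 6.
six_member_pedigree <- function() {
  new_pedigree(tibble::tibble(
    family_id = "F6",
    individual_id = as.character(1:6),
    father_id = c("0", "0", "1", "1", "1", "1"),
    mother_id = c("0", "0", "2", "2", "2", "2"),
    sex = c("male", "female", "male", "female", "male", "female"),
    affected = c("affected", "unaffected", "affected", "affected",
                 "unaffected", "unaffected")
  ))
}

## Small variant/genotype builders.
mk_variant <- function(chrom = "1", pos = 100L, ref = "C", alt = "T",
                       gene = "G1", consequence = "missense",
                       frequency = 0) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, gene = gene,
    consequence = consequence, protein_change = NA_character_,
    population_frequency = frequency
  )
}

mk_genotypes <- function(variant, zygosities) {
  tibble::tibble(
    sample_id = names(zygosities),
    chrom = variant$chrom, pos = variant$pos,
    ref = variant$ref, alt = variant$alt,
    zygosity = unname(zygosities)
  )
}
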