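trio_ped <- function(aff = c("affected", "unaffected", "affected")) {
  new_pedigree(tibble::tibble(
    family_id = "F1", individual_id = c("1", "2", "3"),
    father_id = c("0", "0", "1"), mother_id = c("0", "0", "2"),
    sex = c("male", "female", "male"), affected = aff
  ))
}

test_that("AD co-segregation keeps variants tracking affection and drops the rest", {
  ped <- trio_ped() # affected father and child, unaffected mother
  cfg <- family_filter_config("AD")
  v <- mk_variant()
  ## het in both affecteds, absent in the unaffected -> survives
  g <- mk_genotypes(v, c("1" = "het", "2" = "hom_ref", "3" = "het"))
  expect_equal(nrow(cosegregation_filter(v, g, ped, cfg)), 1)
  ## also het in the unaffected mother -> removed
  g2 <- mk_genotypes(v, c("1" = "het", "2" = "het", "3" = "het"))
  expect_equal(nrow(cosegregation_filter(v, g2, ped, cfg)), 0)
  ## missing call in an affected member fails under the strict policy...
  g3 <- mk_genotypes(v, c("1" = "missing", "2" = "hom_ref", "3" = "het"))
  expect_equal(nrow(cosegregation_filter(v, g3, ped, cfg)), 0)
  ## ...and is ignored under the lenient policy
  cfg_len <- family_filter_config("AD", missing_genotype_policy = "lenient")
  expect_equal(nrow(cosegregation_filter(v, g3, ped, cfg_len)), 1)
})

test_that("genotype samples not in the pedigree raise an integrity error", {
  ped <- trio_ped()
  v <- mk_variant()
  g <- mk_genotypes(v, c("1" = "het", "99" = "het"))
  expect_error(
    cosegregation_filter(v, g, ped, family_filter_config("AD")),
    class = "edmd_integrity_error"
  )
})

test_that("single-variant co-segregation matches exhaustive rule enumeration", {
  ped <- six_member_pedigree()
  ids <- ped$individual_id
  affected <- ids[ped$affected == "affected"]
  unaffected <- ids[ped$affected == "unaffected"]
  father <- setNames(ped$father_id, ids)
  mother <- setNames(ped$mother_id, ids)
  sex <- setNames(ped$sex, ids)

  auto_levels <- c("hom_ref", "het", "hom_alt")
  grid <- expand.grid(rep(list(auto_levels), 6), stringsAsFactors = FALSE)
  v_auto <- mk_variant(chrom = "5")
  v_x <- mk_variant(chrom = "X")

  for (mode in c("AD", "AR", "de_novo")) {
    cfg <- family_filter_config(mode)
    got <- logical(nrow(grid))
    want <- logical(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      zyg <- setNames(as.character(grid[r, ]), ids)
      g <- mk_genotypes(v_auto, zyg)
      got[r] <- nrow(cosegregation_filter(v_auto, g, ped, cfg)) == 1
      want[r] <- oracle_coseg_single(zyg, mode, affected, unaffected,
        sex = sex, on_x = FALSE, father = father, mother = mother
      )
    }
    expect_identical(got, want, label = paste("mode", mode))
  }

  ## X-linked: males are hom_ref / hemi_alt, females the autosomal levels
  x_levels <- lapply(ids, function(id) {
    if (sex[[id]] == "male") c("hom_ref", "hemi_alt") else auto_levels
  })
  x_grid <- expand.grid(x_levels, stringsAsFactors = FALSE)
  names(x_grid) <- ids
  for (mode in c("XLR", "XLD")) {
    cfg <- family_filter_config(mode)
    got <- logical(nrow(x_grid))
    want <- logical(nrow(x_grid))
    for (r in seq_len(nrow(x_grid))) {
      zyg <- setNames(as.character(x_grid[r, ]), ids)
      g <- mk_genotypes(v_x, zyg)
      got[r] <- nrow(cosegregation_filter(v_x, g, ped, cfg)) == 1
      want[r] <- oracle_coseg_single(zyg, mode, affected, unaffected,
        sex = sex, on_x = TRUE, father = father, mother = mother
      )
    }
    expect_identical(got, want, label = paste("mode", mode))
  }
})

test_that("AR compound-heterozygous pairs match exhaustive enumeration on a trio", {
  ped <- trio_ped(c("unaffected", "unaffected", "affected"))
  ids <- ped$individual_id
  affected <- "3"
  unaffected <- c("1", "2")
  cfg <- family_filter_config("AR")
  v1 <- mk_variant(pos = 100)
  v2 <- mk_variant(pos = 200, consequence = "frameshift", ref = "CA", alt = "C")
  variants <- dplyr::bind_rows(v1, v2)
  levels3 <- c("hom_ref", "het", "hom_alt")
  grid <- expand.grid(rep(list(levels3), 6), stringsAsFactors = FALSE)

  oracle_pair <- function(z1, z2) {
    hom_route <- function(z) {
      all(z[affected] == "hom_alt") && !any(z[unaffected] == "hom_alt")
    }
    carry <- function(z) z %in% c("het", "hom_alt")
    pair_route <- all(z1[affected] == "het") && all(z2[affected] == "het") &&
      !any(carry(z1[unaffected]) & carry(z2[unaffected]))
    c(hom_route(z1) || pair_route, hom_route(z2) || pair_route)
  }

  for (r in seq_len(nrow(grid))) {
    z1 <- setNames(as.character(grid[r, 1:3]), ids)
    z2 <- setNames(as.character(grid[r, 4:6]), ids)
    g <- dplyr::bind_rows(mk_genotypes(v1, z1), mk_genotypes(v2, z2))
    out <- cosegregation_filter(variants, g, ped, cfg, keep_all = TRUE)
    expect_identical(out$coseg_pass, unname(oracle_pair(z1, z2)),
      label = paste("config row", r)
    )
  }
})

test_that("the frequency cascade applies its strict two-stage thresholds", {
  cfg <- family_filter_config("AD")
  v <- dplyr::bind_rows(
    mk_variant(pos = 1, frequency = 0.002), # 0.2%: stage 1 only
    mk_variant(pos = 2, frequency = 0), # passes both
    mk_variant(pos = 3, frequency = 0.0005), # boundary: fails stage 2
    mk_variant(pos = 4, frequency = 0.01), # boundary: fails stage 1
    mk_variant(pos = 5, frequency = NA_real_) # absent from the database
  )
  out <- frequency_cascade(v, cfg, keep_all = TRUE)
  expect_equal(out$pass_stage1, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$pass_stage2, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$freq_missing, c(FALSE, FALSE, FALSE, FALSE, TRUE))

  strict <- family_filter_config("AD", treat_missing_frequency_as_pass = FALSE)
  out2 <- frequency_cascade(v, strict, keep_all = TRUE)
  expect_false(out2$pass_stage2[5])
})

test_that("frequency filtering is monotone in the threshold", {
  withr::with_seed(21, {
    freqs <- c(0, runif(40, 0, 0.02), NA_real_)
    v <- mk_variant(pos = seq_along(freqs), frequency = freqs)
    thresholds <- sort(runif(6, 1e-4, 0.02))
    survivors <- lapply(thresholds, function(t2) {
      cfg <- family_filter_config("AD", freq_stage1 = 0.05, freq_stage2 = t2)
      frequency_cascade(v, cfg)$pos
    })
    for (i in seq_len(length(thresholds) - 1)) {
      expect_true(all(survivors[[i]] %in% survivors[[i + 1]]))
    }
  })
})

test_that("the coding filter keeps exactly the coding-altering vocabulary", {
  v <- mk_variant(pos = seq_along(consequence_vocabulary()),
                  consequence = consequence_vocabulary())
  kept <- coding_filter(v)
  expect_setequal(kept$consequence, coding_consequences())
  expect_false(any(c("synonymous", "intronic", "utr", "intergenic") %in%
    kept$consequence))
})

test_that("the expression filter demands strictly more than the fold change", {
  cfg <- family_filter_config("AD")
  expr <- tibble::tibble(
    gene = rep(c("A", "B", "C"), each = 2),
    tissue = rep(c("muscle", "heart"), 3),
    value = c(50, 20, 30, 20, 40, 20)
  )
  out <- expression_filter(c("A", "B", "C", "D"), expr, cfg, keep_all = TRUE)
  expect_equal(out$expression_pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$expression_note[4], "no-expression-data")

  ## mean aggregation is less conservative than max
  expr2 <- tibble::tibble(
    gene = "E", tissue = c("muscle", "heart", "brain"), value = c(50, 30, 10)
  )
  expect_equal(nrow(expression_filter("E", expr2, cfg)), 0)
  cfg_mean <- family_filter_config("AD", expression_aggregate = "mean")
  expect_equal(nrow(expression_filter("E", expr2, cfg_mean)), 1)
})

test_that("coding and expression filters commute with the frequency cascade", {
  withr::with_seed(33, {
    n <- 60
    v <- tibble::tibble(
      chrom = "1", pos = 1:n, ref = "C", alt = "T",
      gene = sample(c("A", "B", "C", "D"), n, TRUE),
      consequence = sample(consequence_vocabulary(), n, TRUE),
      protein_change = NA_character_,
      population_frequency = runif(n, 0, 0.002)
    )
    cfg <- family_filter_config("AD")
    a <- frequency_cascade(coding_filter(v), cfg)
    b <- coding_filter(frequency_cascade(v, cfg))
    expect_equal(a$pos, b$pos)
  })
})

test_that("the full cascade recovers a planted causal gene and is empty-safe", {
  fam <- simulate_family("quartet", "AD", n_background = 150, seed = 17)
  cfg <- family_filter_config("AD")
  res <- run_family_stage(fam$variants, fam$genotypes, fam$pedigree, cfg,
    expression = fam$expression
  )
  expect_true(fam$truth$gene[1] %in% res$genes$gene)
  ## every stage output is a subset of its input (monotone cascade)
  prov <- res$provenance
  expect_true(all(table(prov$stage[prov$verdict]) <= nrow(fam$variants)))

  ## causal allele at 1% population frequency is removed at stage 1
  fam2 <- fam
  causal_key <- paste(fam$truth$chrom, fam$truth$pos)
  is_causal <- paste(fam2$variants$chrom, fam2$variants$pos) %in% causal_key
  fam2$variants$population_frequency[is_causal] <- 0.01
  res2 <- run_family_stage(fam2$variants, fam2$genotypes, fam2$pedigree, cfg,
    expression = fam2$expression
  )
  expect_false(fam$truth$gene[1] %in% res2$genes$gene)

  ## zero variants in -> empty candidate set, no error
  empty <- fam$variants[0, ]
  res3 <- run_family_stage(empty, fam$genotypes[0, ], fam$pedigree, cfg)
  expect_s3_class(res3, "candidate_gene_set")
  expect_equal(nrow(res3$genes), 0)
})

test_that("the young-carrier fallback rescues a family with a presymptomatic carrier", {
  ## affected father+child, plus a young unaffected carrier child
  ped <- new_pedigree(tibble::tibble(
    family_id = "F1", individual_id = c("1", "2", "3", "4"),
    father_id = c("0", "0", "1", "1"), mother_id = c("0", "0", "2", "2"),
    sex = c("male", "female", "male", "female"),
    affected = c("affected", "unaffected", "affected", "unaffected"),
    age = c(45, 44, 20, 8)
  ))
  v <- mk_variant()
  g <- mk_genotypes(v, c("1" = "het", "2" = "hom_ref", "3" = "het", "4" = "het"))
  cfg <- family_filter_config("AD")
  strict <- run_family_stage(v, g, ped, cfg)
  expect_equal(nrow(strict$genes), 0)
  rescued <- run_family_stage(v, g, ped, cfg, fallback_drop_age = 16)
  expect_true(rescued$fallback_used)
  expect_equal(rescued$genes$gene, "G1")
})

test_that("candidate sets merge across families into a union", {
  fams <- lapply(1:3, function(s) {
    fam <- simulate_family("trio", "AD",
      n_background = 60, seed = s,
      causal_gene = paste0("CAUSAL", s)
    )
    run_family_stage(fam$variants, fam$genotypes, fam$pedigree,
      family_filter_config("AD"),
      expression = fam$expression, family_id = paste0("F", s)
    )
  })
  merged <- merge_candidates(fams)
  expect_true(all(paste0("CAUSAL", 1:3) %in% attr(merged, "genes")))
  expect_true(all(c("family_id", "gene") %in% names(merged)))
})
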