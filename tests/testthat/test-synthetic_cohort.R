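test_that("AD trio: causal allele is transmitted to the proband and affection follows dose", {
  for (seed in 1:5) {
    ps <- simulate_pedigree("trio", "AD", penetrance = 1, seed = seed)
    zyg <- setNames(ps$genotypes$zygosity, ps$genotypes$sample_id)
    expect_equal(unname(zyg[["3"]]), "het")
    parent_zyg <- zyg[c("1", "2")]
    expect_true(sum(parent_zyg == "het") == 1 && sum(parent_zyg == "hom_ref") == 1)
    aff <- setNames(ps$pedigree$affected, ps$pedigree$individual_id)
    carriers <- names(zyg)[zyg != "hom_ref"]
    expect_setequal(names(aff)[aff == "affected"], carriers)
  }
})

test_that("AR trio: affected child is biallelic with unaffected carrier parents", {
  ps <- simulate_pedigree("trio", "AR", ar_form = "hom", seed = 4)
  zyg <- setNames(ps$genotypes$zygosity, ps$genotypes$sample_id)
  expect_equal(unname(zyg[["3"]]), "hom_alt")
  expect_equal(unname(zyg[c("1", "2")]), c("het", "het"))
  aff <- setNames(ps$pedigree$affected, ps$pedigree$individual_id)
  expect_equal(unname(aff[c("1", "2", "3")]), c("unaffected", "unaffected", "affected"))

  ps2 <- simulate_pedigree("trio", "AR", ar_form = "compound_het", seed = 4)
  expect_equal(nrow(ps2$variants), 2)
  child <- ps2$genotypes[ps2$genotypes$sample_id == "3", ]
  expect_equal(child$zygosity, c("het", "het"))
  expect_equal(nrow(dplyr::distinct(child[, c("pos")])), 2)
  ## each parent carries exactly one of the pair
  for (parent in c("1", "2")) {
    pz <- ps2$genotypes$zygosity[ps2$genotypes$sample_id == parent]
    expect_equal(sum(pz == "het"), 1)
  }
})

test_that("X-linked and de novo modes place the required doses", {
  ps <- simulate_pedigree("trio", "XLR", seed = 9)
  expect_equal(ps$variants$chrom, "X")
  zyg <- setNames(ps$genotypes$zygosity, ps$genotypes$sample_id)
  expect_equal(unname(zyg[["3"]]), "hemi_alt")
  expect_equal(unname(zyg[["2"]]), "het") # carrier mother
  aff <- setNames(ps$pedigree$affected, ps$pedigree$individual_id)
  expect_equal(unname(aff[["2"]]), "unaffected") # het female not affected under XLR

  dn <- simulate_pedigree("trio", "de_novo", seed = 9)
  zyg <- setNames(dn$genotypes$zygosity, dn$genotypes$sample_id)
  expect_equal(unname(zyg[c("1", "2", "3")]), c("hom_ref", "hom_ref", "het"))

  expect_error(
    simulate_pedigree(
      {
        t <- pedigree_template("trio")
        t$sex[3] <- "female"
        t
      },
      "XLR",
      seed = 1
    ),
    class = "edmd_infeasibility_error"
  )
})

test_that("simulated pedigrees are Mendelian-consistent (brute-force transmission check)", {
  for (seed in c(7, 1:6)) {
    for (mode in c("AD", "AR", "XLR", "XLD")) {
      ps <- simulate_pedigree("two_gen_8", mode, seed = seed)
      expect_true(oracle_mendelian_ok(ps$pedigree, ps$genotypes),
        label = paste("mode", mode, "seed", seed)
      )
      ## penetrance 1: affected set == full-dose carriers (checked via truth)
      expect_true(all(ps$pedigree$affected %in% c("affected", "unaffected")))
    }
  }
})

test_that("family simulation keeps background variants Mendelian too", {
  fam <- simulate_family("two_gen_8", "AD", n_background = 120, seed = 13)
  expect_true(oracle_mendelian_ok(fam$pedigree, fam$genotypes))
})

test_that("cyclic pedigrees are rejected as structural errors", {
  bad <- tibble::tibble(
    family_id = "F", individual_id = c("A", "B"),
    father_id = c("B", "A"), mother_id = c("0", "0"),
    sex = c("male", "male"), affected = c("affected", "unaffected")
  )
  expect_error(new_pedigree(bad), class = "edmd_structural_error")
})

test_that("every plant spec is realised in exactly carrier_count patients", {
  cfg <- simulation_config(
    seed = 1, n_patients = 10, background_rate = 0,
    plants = list(plant_spec("G1", carrier_count = 3))
  )
  sim <- simulate_cohort(cfg)
  carriers <- unique(sim$genotypes$sample_id[carries_alt(sim$genotypes$zygosity)])
  expect_equal(length(carriers), 3)
  expect_equal(sum(!sim$patients$patient_id %in% carriers), 7)

  ## explicit overlapping carriers: 17 hits across 16 distinct patients
  sim2 <- simulate_cohort(edmd_screen_scenario(seed = 1))
  cat4 <- c(
    "WFS1", "TMEM201", "TMEM38A", "PLPP7", "TMEM214", "LPCAT3",
    "KLHL31", "BVES"
  )
  planted <- sim2$truth[sim2$truth$origin == "planted" & sim2$truth$gene %in% cat4, ]
  gene_hits <- dplyr::distinct(planted[, c("patient_id", "gene")])
  expect_equal(nrow(gene_hits), 17)
  expect_equal(length(unique(gene_hits$patient_id)), 16)
})

test_that("carrier demand beyond the cohort size is an infeasibility error", {
  cfg <- simulation_config(
    seed = 1, n_patients = 4, background_rate = 0,
    plants = list(
      plant_spec("G1", carrier_count = 3),
      plant_spec("G2", carrier_count = 3)
    )
  )
  expect_error(simulate_cohort(cfg), class = "edmd_infeasibility_error")
  expect_error(
    simulation_config(n_patients = 2, plants = list(plant_spec("G1", carrier_count = 3)))
  )
})

test_that("no plants and zero background give an empty variant set", {
  sim <- simulate_cohort(simulation_config(seed = 5, n_patients = 3, background_rate = 0))
  expect_equal(nrow(sim$variants), 0)
  expect_equal(nrow(sim$genotypes), 0)
  expect_equal(nrow(sim$patients), 3)
})

test_that("fixed seeds give byte-identical cohort outputs", {
  cfg <- function() {
    simulation_config(
      seed = 42, n_patients = 8, background_rate = 5,
      plants = list(plant_spec("LMNA", carrier_count = 2))
    )
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg()), d1)
  write_cohort(simulate_cohort(cfg()), d2)
  for (f in c("cohort.vcf", "patients.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      label = f
    )
  }
  t1 <- generate_tables(c("A", "B"), muscle_specific = "A", seed = 3)
  t2 <- generate_tables(c("A", "B"), muscle_specific = "A", seed = 3)
  expect_identical(t1, t2)
})

test_that("designated muscle-specific genes exceed twice every other tissue", {
  tabs <- generate_tables(sprintf("G%d", 1:30),
    muscle_specific = sprintf("G%d", 1:10), seed = 8
  )
  wide <- tidyr::pivot_wider(tabs$expression,
    names_from = "tissue", values_from = "value"
  )
  other_max <- apply(wide[, setdiff(names(wide), c("gene", "muscle"))], 1, max)
  spec <- wide$gene %in% sprintf("G%d", 1:10)
  expect_true(all(wide$muscle[spec] > 2 * other_max[spec]))
})

test_that("planted allele frequencies propagate to the frequency table", {
  sim <- simulate_cohort(simulation_config(
    seed = 2, n_patients = 4, background_rate = 0,
    plants = list(plant_spec("G1", population_frequency = 0))
  ))
  tabs <- generate_tables(unique(sim$variants$gene), variants = sim$variants, seed = 2)
  expect_equal(tabs$frequency$frequency, 0)
})

test_that("background frequencies follow the configured Beta spectrum", {
  sim <- simulate_cohort(simulation_config(
    seed = 99, n_patients = 50, background_rate = 210,
    maf_shape1 = 0.2, maf_shape2 = 20
  ))
  freqs <- sim$variants$population_frequency
  expect_gt(length(freqs), 10000)
  ## empirical CDF matches Beta(0.2, 20) within sampling error
  for (q in c(1e-4, 1e-3, 1e-2, 0.1)) {
    theo <- pbeta(q, 0.2, 20)
    se <- sqrt(theo * (1 - theo) / length(freqs))
    expect_lt(abs(mean(freqs < q) - theo), 5 * se)
  }
  expect_lt(abs(mean(freqs) - 0.2 / 20.2), 5 * sd(freqs) / sqrt(length(freqs)))
})
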