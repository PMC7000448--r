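mini_panel <- function() {
  build_panel(list(
    I = c("LMNA", "EMD", "SYNE1", "SUN2"),
    II = c("CAPN3", "DMD", "TTN", "VCP"),
    III = c("ANK2", "INTS1"),
    IV = c("WFS1", "TMEM38A", "PLPP7")
  ), metadata = tibble::tibble(
    symbol = c("LMNA", "EMD", "SYNE1", "SUN2", "CAPN3", "DMD", "TTN", "VCP"),
    modes = c("AD", "XLR", "AD", "AD", "AR", "XLR", "AR", "AD"),
    modifier_only = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  ))
}

two_patients <- tibble::tibble(
  patient_id = c("MD-01", "MD-02"), sex = c("male", "female")
)

test_that("patient filtering keeps rare coding panel variants only", {
  panel <- mini_panel()
  v <- dplyr::bind_rows(
    mk_variant(pos = 1, gene = "LMNA", consequence = "missense", frequency = 0),
    mk_variant(pos = 2, gene = "LMNA", consequence = "synonymous", frequency = 0),
    mk_variant(pos = 3, gene = "NOTPANEL", consequence = "nonsense", frequency = 0),
    mk_variant(pos = 4, gene = "CAPN3", consequence = "missense", frequency = 0.0005),
    mk_variant(pos = 5, gene = "VCP", consequence = "missense", frequency = 0.0004)
  )
  g <- tibble::tibble(
    sample_id = "MD-01", chrom = "1", pos = 1:5, ref = "C", alt = "T",
    zygosity = "het"
  )
  hits <- patient_filter(v, g, panel, patients = two_patients[1, ])
  expect_equal(sort(hits$gene), c("LMNA", "VCP"))
  ## boundary frequency 0.0005 fails the strict < 0.05% rule
  expect_false("CAPN3" %in% hits$gene)
})

test_that("a patient with zero genotype calls warns and yields no hits", {
  panel <- mini_panel()
  v <- mk_variant(gene = "LMNA")
  g <- mk_genotypes(v, c("MD-01" = "het"))
  expect_warning(
    hits <- patient_filter(v, g, panel, patients = two_patients),
    "MD-02"
  )
  expect_equal(unique(hits$patient_id), "MD-01")
})

test_that("inheritance consistency follows the gene's known modes", {
  panel <- mini_panel()
  v <- dplyr::bind_rows(
    mk_variant(pos = 1, gene = "CAPN3", consequence = "missense"),
    mk_variant(pos = 2, gene = "CAPN3", consequence = "frameshift",
               ref = "CA", alt = "C"),
    mk_variant(pos = 3, gene = "TTN", consequence = "missense"),
    mk_variant(chrom = "X", pos = 4, gene = "DMD", consequence = "nonsense"),
    mk_variant(pos = 5, gene = "ANK2", consequence = "missense")
  )
  g <- dplyr::bind_rows(
    ## MD-01: CAPN3 missense + frameshift, DMD hemizygous nonsense
    tibble::tibble(
      sample_id = "MD-01", chrom = c("1", "1", "X"), pos = c(1L, 2L, 4L),
      ref = c("C", "CA", "C"), alt = c("T", "C", "T"),
      zygosity = c("het", "het", "hemi_alt")
    ),
    ## MD-02: single het in recessive TTN, het in mode-unknown ANK2
    tibble::tibble(
      sample_id = "MD-02", chrom = "1", pos = c(3L, 5L), ref = "C", alt = "T",
      zygosity = "het"
    )
  )
  hits <- inheritance_consistency(
    patient_filter(v, g, panel), patients = two_patients
  )
  get <- function(p, gene) hits[hits$patient_id == p & hits$gene == gene, ]
  capn3 <- get("MD-01", "CAPN3")
  expect_true(capn3$inheritance_consistent)
  expect_match(capn3$consistency_reason, "phase unknown")
  dmd <- get("MD-01", "DMD")
  expect_true(dmd$inheritance_consistent)
  expect_match(dmd$consistency_reason, "hemizygous")
  ttn <- get("MD-02", "TTN")
  expect_false(ttn$inheritance_consistent)
  expect_match(ttn$consistency_reason, "single heterozygous hit in recessive gene")
  ank2 <- get("MD-02", "ANK2")
  expect_true(ank2$inheritance_consistent)
  expect_match(ank2$consistency_reason, "mode unknown")
})

test_that("recurrence elevation counts distinct patients and matches a brute-force tally", {
  panel <- mini_panel()
  withr::with_seed(7, {
    n_pat <- 20
    pats <- sprintf("MD-%02d", 1:n_pat)
    rows <- list()
    for (g in c("ANK2", "INTS1")) {
      carriers <- sample(pats, sample(1:8, 1))
      for (p in carriers) rows[[length(rows) + 1]] <- list(p = p, g = g)
    }
    v <- dplyr::bind_rows(lapply(seq_along(rows), function(i) {
      mk_variant(pos = i, gene = rows[[i]]$g)
    }))
    g <- dplyr::bind_rows(lapply(seq_along(rows), function(i) {
      tibble::tibble(
        sample_id = rows[[i]]$p, chrom = "1", pos = i, ref = "C", alt = "T",
        zygosity = "het"
      )
    }))
    hits <- patient_filter(v, g, panel)
    for (minp in 1:4) {
      elev <- recurrence_elevation(hits, min_patients = minp)
      tally <- table(vapply(rows, function(r) r$g, character(1)))
      brute <- names(tally)[vapply(names(tally), function(gene) {
        length(unique(vapply(
          Filter(function(r) r$g == gene, rows),
          function(r) r$p, character(1)
        ))) >= minp
      }, logical(1))]
      expect_setequal(elev$gene, brute)
    }
  })
})

test_that("elevation is monotone: adding patients never de-elevates a gene", {
  panel <- mini_panel()
  mk_hits <- function(patients) {
    v <- mk_variant(gene = "ANK2")
    g <- dplyr::bind_rows(lapply(patients, function(p) {
      tibble::tibble(sample_id = p, chrom = "1", pos = 100L, ref = "C",
                     alt = "T", zygosity = "het")
    }))
    patient_filter(v, g, panel)
  }
  small <- recurrence_elevation(mk_hits(c("A", "B")))
  large <- recurrence_elevation(mk_hits(c("A", "B", "C", "D")))
  expect_true(all(small$gene %in% large$gene))
})

test_that("classification follows the category precedence with dual hits noted", {
  panel <- mini_panel()
  v <- dplyr::bind_rows(
    mk_variant(pos = 1, gene = "LMNA", consequence = "missense"),
    mk_variant(pos = 2, gene = "TTN", consequence = "missense"),
    mk_variant(pos = 3, gene = "TTN", consequence = "missense"),
    mk_variant(pos = 4, gene = "SYNE1", consequence = "missense"),
    mk_variant(pos = 5, gene = "SUN2", consequence = "missense"),
    mk_variant(pos = 6, gene = "WFS1", consequence = "missense")
  )
  pats <- tibble::tibble(
    patient_id = c("MD-01", "MD-02", "MD-03", "MD-04", "MD-05"),
    sex = "female"
  )
  g <- dplyr::bind_rows(
    tibble::tibble(sample_id = "MD-01", chrom = "1", pos = 1L, ref = "C",
                   alt = "T", zygosity = "het"),
    tibble::tibble(sample_id = "MD-02", chrom = "1", pos = 2:4, ref = "C",
                   alt = "T", zygosity = "het"),
    tibble::tibble(sample_id = "MD-03", chrom = "1", pos = 5L, ref = "C",
                   alt = "T", zygosity = "het"),
    tibble::tibble(sample_id = "MD-04", chrom = "1", pos = 6L, ref = "C",
                   alt = "T", zygosity = "het")
  )
  cls <- classify_patients(patient_filter(v, g, panel), pats)
  cl <- cls$classifications
  status <- setNames(cl$status, cl$patient_id)

  ## consistent LMNA hit alone -> solved, dark green
  expect_equal(unname(status[["MD-01"]]), "solved_known_edmd")
  expect_equal(cls$hits$tier[cls$hits$patient_id == "MD-01"], "dark_green")

  ## biallelic TTN plus a SYNE1 hit: higher class wins, dual candidacy noted
  expect_equal(unname(status[["MD-02"]]), "solved_known_edmd")
  md2 <- cl[cl$patient_id == "MD-02", ]
  expect_match(md2$notes, "possible dual contribution")
  expect_match(md2$notes, "TTN")
  expect_equal(sum(cls$hits$patient_id == "MD-02"), 2)

  ## modifier-only SUN2 never solves a patient
  expect_equal(unname(status[["MD-03"]]), "unsolved")
  expect_match(cl$notes[cl$patient_id == "MD-03"], "modifier")

  ## category IV hit -> functional candidate, yellow tier
  expect_equal(unname(status[["MD-04"]]), "candidate_functional")
  expect_equal(cls$hits$tier[cls$hits$patient_id == "MD-04"], "yellow")

  ## no hits -> unsolved
  expect_equal(unname(status[["MD-05"]]), "unsolved")
})

test_that("two consistent genes at the same precedence yield ambiguous_multi", {
  panel <- mini_panel()
  v <- dplyr::bind_rows(
    mk_variant(pos = 1, gene = "TMEM38A"),
    mk_variant(pos = 2, gene = "PLPP7")
  )
  pats <- tibble::tibble(patient_id = "MD-32", sex = "male")
  g <- tibble::tibble(
    sample_id = "MD-32", chrom = "1", pos = 1:2, ref = "C", alt = "T",
    zygosity = "het"
  )
  cls <- classify_patients(patient_filter(v, g, panel, patients = pats), pats)
  expect_equal(cls$classifications$status, "ambiguous_multi")
  expect_equal(cls$hits$tier, c("light_green", "light_green"))
})

test_that("classification is deterministic and order-invariant, statuses partition the cohort", {
  sim <- simulate_cohort(edmd_screen_scenario(seed = 6))
  panel <- edmd_panel()
  hits <- patient_filter(sim$variants, sim$genotypes, panel, patients = sim$patients)
  cls <- classify_patients(hits, sim$patients)

  perm <- withr::with_seed(1, sample(nrow(sim$patients)))
  hits_perm <- patient_filter(
    sim$variants, sim$genotypes[sample(nrow(sim$genotypes)), ],
    panel,
    patients = sim$patients[perm, ]
  )
  cls_perm <- classify_patients(hits_perm, sim$patients[perm, ])
  a <- dplyr::arrange(cls$classifications, patient_id)
  b <- dplyr::arrange(cls_perm$classifications, patient_id)
  expect_equal(as.data.frame(a), as.data.frame(b))

  ## exactly one status per patient; counts telescope to the cohort size
  expect_equal(nrow(cls$classifications), 56)
  expect_equal(anyDuplicated(cls$classifications$patient_id), 0)
  summ <- cohort_summary(cls, panel)
  expect_equal(sum(summ$status_counts$n), 56)
})

test_that("an empty cohort summarises to all-zero counts", {
  panel <- mini_panel()
  pats <- tibble::tibble(patient_id = character(0), sex = character(0))
  hits <- suppressWarnings(patient_filter(
    mk_variant(gene = "LMNA")[0, ],
    tibble::tibble(
      sample_id = character(0), chrom = character(0), pos = integer(0),
      ref = character(0), alt = character(0), zygosity = character(0)
    ),
    panel,
    patients = pats
  ))
  cls <- classify_patients(hits, pats)
  summ <- cohort_summary(cls, panel)
  expect_equal(sum(summ$status_counts$n), 0)
  expect_equal(summ$n_clearly_assigned, 0)
})
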