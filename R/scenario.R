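#' Built-in 56-patient EDMD-like screen scenario
#'
#' A ready-made [simulation_config()] describing a cohort of 56
#' unrelated clinically diagnosed patients whose planted hit pattern
#' mirrors a characteristic outcome of a four-category panel screen in
#' this disease:
#'
#' * category I: three patients with heterozygous `LMNA` alleles (two
#'   missense, one frameshift);
#' * category II: eighteen patients with causative-grade hits —
#'   four `CAPN3` missense+frameshift compound heterozygotes, four
#'   biallelic `GBE1` patients (three missense, one splice-site), two
#'   heterozygous `VCP`, two biallelic `TTN`, and one patient each for
#'   `COL6A1`, `CAV3` (heterozygous), `DMD` (hemizygous nonsense near
#'   the start codon) and biallelic `ANO5`, `DYSF`, `POMT1`;
#' * category III: recurrent heterozygous hits in the exome candidates
#'   `ANK2` (6 patients), `INTS1` (5, one of them the `POMT1` patient),
#'   `XIRP1` (5) and `USP34` (5, overlapping solved patients);
#' * category IV: seventeen functional-candidate hits across sixteen
#'   distinct patients — `WFS1` x4, `TMEM201` x3, `TMEM38A` x3,
#'   `PLPP7` x2, `TMEM214` x2, `LPCAT3`, `KLHL31`, `BVES` x1 — with one
#'   patient carrying both a `TMEM38A` and a `PLPP7` variant.
#'
#' Carrier assignments are explicit, so the planted pattern (and hence
#' the downstream classification counts) is identical for every seed;
#' the seed only affects background variation and table noise.
#' Background benign variants are modelled as common polymorphisms
#' (population frequency at least 0.1%, above the 0.05% cohort filter):
#' the scenario represents a cohort in which upstream quality control
#' already removed sequencing artefacts, so the planted pattern is the
#' only rare coding signal.
#'
#' @param seed Integer seed for the background draw.
#' @param background_rate Expected benign (common) variants per patient.
#' @return A `simulation_config`.
#' @seealso [simulate_cohort()], [edmd_panel()], [run_pipeline()]
#' @export
edmd_screen_scenario <- function(seed = 1L, background_rate = 8) {
  p <- function(i) sprintf("P%02d", i)
  plants <- list(
    ## category I -- previously missed LMNA alleles
    plant_spec("LMNA", "missense", "het", 2, carriers = p(1:2)),
    plant_spec("LMNA", "frameshift", "het", 1, carriers = p(3)),
    ## category II -- related muscular dystrophies (18 patients)
    plant_spec("CAPN3", "missense", "compound_het", 4,
      carriers = p(4:7), consequences = c("missense", "frameshift")
    ),
    plant_spec("GBE1", "missense", "hom", 3, carriers = p(8:10)),
    plant_spec("GBE1", "splice_donor", "hom", 1, carriers = p(11)),
    plant_spec("VCP", "missense", "het", 2, carriers = p(12:13)),
    plant_spec("TTN", "missense", "compound_het", 2,
      carriers = p(14:15), consequences = c("missense", "missense")
    ),
    plant_spec("COL6A1", "missense", "het", 1, carriers = p(16)),
    plant_spec("CAV3", "missense", "het", 1, carriers = p(17)),
    plant_spec("DMD", "nonsense", "hemi", 1, carriers = p(18)),
    plant_spec("ANO5", "missense", "compound_het", 1, carriers = p(19)),
    plant_spec("DYSF", "missense", "compound_het", 1, carriers = p(20)),
    plant_spec("POMT1", "missense", "compound_het", 1, carriers = p(21)),
    ## category IV -- functional candidates (17 hits, 16 patients)
    plant_spec("WFS1", "missense", "het", 4, carriers = p(22:25)),
    plant_spec("TMEM201", "missense", "het", 3, carriers = p(26:28)),
    plant_spec("TMEM38A", "missense", "het", 3, carriers = p(29:31)),
    plant_spec("PLPP7", "missense", "het", 2, carriers = p(c(31, 32))),
    plant_spec("TMEM214", "missense", "het", 2, carriers = p(33:34)),
    plant_spec("LPCAT3", "missense", "het", 1, carriers = p(35)),
    plant_spec("KLHL31", "missense", "het", 1, carriers = p(36)),
    plant_spec("BVES", "missense", "het", 1, carriers = p(37)),
    ## category III -- recurrent exome candidates
    plant_spec("ANK2", "missense", "het", 6, carriers = p(38:43)),
    plant_spec("INTS1", "missense", "het", 5, carriers = p(c(21, 44:47))),
    plant_spec("XIRP1", "missense", "het", 5, carriers = p(c(48:51, 4))),
    plant_spec("USP34", "missense", "het", 5, carriers = p(c(52:54, 8, 12)))
  )
  genes <- unique(vapply(plants, `[[`, character(1), "gene"))
  simulation_config(
    seed = seed, n_patients = 56L, plants = plants,
    background_rate = background_rate,
    maf_shape1 = 2, maf_shape2 = 40, min_background_frequency = 0.001,
    gene_universe = c(genes, sprintf("BG%03d", seq_len(120))),
    annotation = edmd_screen_annotation(genes)
  )
}

## Designation vectors for the scenario's side tables: which simulated
## genes carry nuclear-envelope, GO and plasma-membrane labels, and a
## high-confidence interaction chain from the nuclear envelope through
## the cytoskeleton to the plasma membrane.
edmd_screen_annotation <- function(genes) {
  ne <- c(
    "LMNA", "WFS1", "TMEM201", "TMEM38A", "PLPP7", "TMEM214", "LPCAT3",
    "KLHL31", "BVES", "INTS1", "ANK2", "TTN", "VCP", "COL6A1", "CAV3",
    "DYSF", "DMD"
  )
  go_org <- c(
    "LMNA", "INTS1", "ANK2", "WFS1", "TMEM38A", "PLPP7", "TMEM201",
    "TMEM214", "USP34", "VCP", "GBE1"
  )
  go_cyto <- c(
    "LMNA", "DMD", "ANK2", "XIRP1", "KLHL31", "TTN", "CAPN3", "DYSF",
    "CAV3", "COL6A1", "TMEM214"
  )
  pm <- c("CAV3", "DMD", "DYSF", "ANO5", "BVES", "COL6A1")
  chain <- tibble(
    gene_a = c("LMNA", "TMEM201", "ANK2", "TTN", "XIRP1", "DMD", "TTN",
               "CAPN3", "WFS1", "TMEM38A", "PLPP7", "VCP"),
    gene_b = c("TMEM201", "ANK2", "TTN", "XIRP1", "DMD", "CAV3", "CAPN3",
               "DYSF", "LMNA", "LMNA", "LMNA", "LMNA"),
    confidence = c(0.9, 0.85, 0.8, 0.9, 0.82, 0.95, 0.88, 0.75, 0.8,
                   0.78, 0.76, 0.81)
  )
  low_conf <- tibble(
    gene_a = c("GBE1", "USP34", "LPCAT3"),
    gene_b = c("POMT1", "KLHL31", "BVES"),
    confidence = c(0.4, 0.35, 0.5)
  )
  list(
    muscle_specific = c("TMEM38A", "PLPP7", "TMEM201", "TMEM214", "KLHL31",
                        "BVES", "XIRP1", "CAPN3", "CAV3", "DMD", "TTN"),
    ne_genes = intersect(ne, genes),
    go_genome_organisation_genes = intersect(go_org, genes),
    go_cytoskeleton_genes = intersect(go_cyto, genes),
    plasma_membrane_genes = intersect(pm, genes),
    edges = dplyr::bind_rows(chain, low_conf)
  )
}
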