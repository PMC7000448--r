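#' One-sided gene-set enrichment against a background
#'
#' Tests whether a foreground gene set is enriched for a boolean
#' annotation flag relative to a background universe.  With a full
#' background table the test is the exact hypergeometric upper tail
#' (over-representation only); when only a background fraction is known
#' (e.g. the genome-wide nuclear-envelope fraction of 5.9%) the test
#' degrades to an exact one-sided binomial against that fraction, and
#' the mode is reported.
#'
#' @param foreground Character vector of genes (non-empty; must be a
#'   subset of the background when one is supplied).
#' @param flag Name of a logical column of `annotations` (genes absent
#'   from `annotations` count as unflagged).
#' @param annotations Annotation tibble with `gene` and flag columns.
#' @param background Character vector of background genes; defaults to
#'   `annotations$gene` when annotations are supplied.
#' @param background_fraction Background flag fraction for binomial
#'   mode (default 0.059, the genome-wide nuclear-envelope portion).
#' @param method `"auto"` (hypergeometric whenever a background gene
#'   table is available, binomial otherwise), or force one of
#'   `"hypergeometric"` / `"binomial"`.
#' @return An `enrichment_result`: `flag`, `method`, `foreground_size`,
#'   `background_size`, `foreground_hits`, `background_hits`,
#'   `fraction_fg`, `fraction_bg`, `odds_ratio`, `p_value`,
#'   `adjusted_p` (`NA` until [adjust_enrichment()] is applied).
#' @export
set_enrichment <- function(foreground, flag, annotations = NULL,
                           background = NULL, background_fraction = 0.059,
                           method = c("auto", "hypergeometric", "binomial")) {
  method <- match.arg(method)
  foreground <- unique(foreground)
  if (length(foreground) == 0) {
    abort("empty foreground: enrichment fractions are undefined")
  }
  flag_of <- function(genes) {
    if (is.null(annotations)) abort("annotations are required to flag genes")
    v <- annotations[[flag]][match(genes, annotations$gene)]
    v[is.na(v)] <- FALSE
    v
  }
  n <- length(foreground)
  k <- sum(flag_of(foreground))

  if (method != "binomial" && !is.null(annotations) && is.null(background)) {
    background <- unique(annotations$gene)
  }
  if (method == "binomial") background <- NULL

  if (!is.null(background)) {
    background <- unique(background)
    outside <- setdiff(foreground, background)
    if (length(outside) > 0) {
      abort(paste0(
        "foreground gene(s) missing from background: ",
        paste(head(outside, 5), collapse = ", ")
      ))
    }
    N <- length(background)
    K <- sum(flag_of(background))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k
    b <- n - k
    cc <- K - k
    d <- (N - n) - (K - k)
    or <- if (a == 0) 0 else if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    res <- list(
      flag = flag, method = "hypergeometric",
      foreground_size = n, background_size = N,
      foreground_hits = k, background_hits = K,
      fraction_fg = k / n, fraction_bg = K / N,
      odds_ratio = or, p_value = p, adjusted_p = NA_real_
    )
  } else {
    q <- background_fraction
    if (q <= 0 || q >= 1) abort("background_fraction must lie in (0, 1)")
    p <- stats::binom.test(k, n, q, alternative = "greater")$p.value
    or <- if (k == 0) 0 else if (k == n) Inf else (k / (n - k)) / (q / (1 - q))
    res <- list(
      flag = flag, method = "binomial",
      foreground_size = n, background_size = NA_integer_,
      foreground_hits = k, background_hits = NA_integer_,
      fraction_fg = k / n, fraction_bg = q,
      odds_ratio = or, p_value = p, adjusted_p = NA_real_
    )
  }
  structure(res, class = "enrichment_result")
}

#' Dual GO-term enrichment (genome organisation AND cytoskeleton)
#'
#' Tests over-representation of genes simultaneously carrying both the
#' genome-organisation and the cytoskeleton GO flag — the signature of
#' candidates positioned to transduce mechanical signals to the genome.
#'
#' @inheritParams set_enrichment
#' @return An `enrichment_result` for the combined flag
#'   `"go_genome_organisation+go_cytoskeleton"`.
#' @export
dual_go_enrichment <- function(foreground, annotations, background = NULL,
                               background_fraction = 0.059) {
  ann <- dplyr::mutate(
    annotations,
    dual_go = .data$go_genome_organisation & .data$go_cytoskeleton
  )
  res <- set_enrichment(foreground, "dual_go", ann, background, background_fraction)
  res$flag <- "go_genome_organisation+go_cytoskeleton"
  res
}

#' Benjamini-Hochberg adjustment across a set of enrichment results
#'
#' @param results A list of `enrichment_result` objects tested in one
#'   run.
#' @return The list with `adjusted_p` filled in (BH, capped at 1,
#'   order-preserving).
#' @export
adjust_enrichment <- function(results) {
  p <- vapply(results, `[[`, numeric(1), "p_value")
  adj <- p.adjust(p, method = "BH")
  purrr::map2(results, adj, function(r, a) {
    r$adjusted_p <- a
    r
  })
}

#' Run the standard enrichment battery for a candidate set
#'
#' Nuclear-envelope localisation, each GO flag, the dual GO flag and
#' plasma-membrane localisation, BH-adjusted together.
#'
#' @inheritParams set_enrichment
#' @return A tibble with one row per flag (see [tidy.enrichment_result()]).
#' @export
candidate_enrichment <- function(foreground, annotations, background = NULL,
                                 background_fraction = 0.059) {
  flags <- c(
    "ne_localised", "go_genome_organisation", "go_cytoskeleton",
    "plasma_membrane"
  )
  results <- lapply(flags, function(fl) {
    set_enrichment(foreground, fl, annotations, background, background_fraction)
  })
  results <- c(results, list(
    dual_go_enrichment(foreground, annotations, background, background_fraction)
  ))
  dplyr::bind_rows(lapply(adjust_enrichment(results), tidy))
}

#' Candidate connectivity over a high-confidence interaction graph
#'
#' Induces the subgraph of the candidate genes using interaction edges
#' at or above the confidence threshold (0.7, the conventional
#' "high confidence" cutoff of interaction databases), reports its
#' connected components, the fraction of candidates with at least one
#' candidate neighbour, and whether a path exists from any
#' nuclear-envelope-localised candidate to any plasma-membrane
#' candidate — the physical chain consistent with mechanotransduction
#' from the cell surface to the genome.
#'
#' @param candidates Character vector of candidate genes.
#' @param edges Edge tibble (`gene_a`, `gene_b`, `confidence`).
#' @param threshold Minimum edge confidence (inclusive).
#' @param annotations Annotation tibble supplying `ne_localised` and
#'   `plasma_membrane` labels.
#' @return A `connectivity_report`: `nodes` (gene, component, degree,
#'   ne, pm), `edges_used`, `n_components`,
#'   `fraction_with_candidate_neighbour`, `ne_to_pm_path_exists`,
#'   `example_path`, `reason`.
#' @export
connectivity <- function(candidates, edges, threshold = 0.7,
                         annotations = NULL) {
  candidates <- unique(candidates)
  if (length(candidates) == 0) abort("no candidate genes supplied")
  edges <- canonicalise_edges(edges)
  used <- edges[
    edges$confidence >= threshold &
      edges$gene_a %in% candidates & edges$gene_b %in% candidates,
  ]
  g <- igraph::graph_from_data_frame(
    used[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = data.frame(name = candidates)
  )
  comp <- igraph::components(g)
  deg <- igraph::degree(g)

  flag_of <- function(col) {
    if (is.null(annotations) || !col %in% names(annotations)) {
      return(rep(FALSE, length(candidates)))
    }
    v <- annotations[[col]][match(candidates, annotations$gene)]
    v[is.na(v)] <- FALSE
    v
  }
  ne <- flag_of("ne_localised")
  pm <- flag_of("plasma_membrane")
  nodes <- tibble(
    gene = candidates,
    component = unname(comp$membership[candidates]),
    degree = unname(deg[candidates]),
    ne = ne, pm = pm
  )

  path_exists <- FALSE
  example_path <- character(0)
  reason <- ""
  if (!any(ne) || !any(pm)) {
    reason <- "no labelled NE and/or plasma-membrane candidate"
  } else {
    shared <- intersect(nodes$component[ne], nodes$component[pm])
    if (length(shared) > 0) {
      path_exists <- TRUE
      from <- nodes$gene[ne & nodes$component == shared[[1]]][[1]]
      to <- nodes$gene[pm & nodes$component == shared[[1]]][[1]]
      sp <- igraph::shortest_paths(g, from = from, to = to, output = "vpath")
      example_path <- names(sp$vpath[[1]])
    } else {
      reason <- "NE and plasma-membrane candidates lie in different components"
    }
  }

  structure(
    list(
      nodes = nodes, edges_used = used, n_components = comp$no,
      fraction_with_candidate_neighbour = mean(nodes$degree > 0),
      ne_to_pm_path_exists = path_exists,
      example_path = example_path, reason = reason,
      threshold = threshold
    ),
    class = "connectivity_report"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s (%s): %d/%d foreground (%.1f%%) vs %.1f%% background, p = %.3g\n",
    x$flag, x$method, x$foreground_hits, x$foreground_size,
    100 * x$fraction_fg, 100 * x$fraction_bg, x$p_value
  ))
  invisible(x)
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat(
    "<connectivity_report>", nrow(x$nodes), "candidates,",
    nrow(x$edges_used), "edges >=", x$threshold, "->",
    x$n_components, "component(s)\n"
  )
  if (x$ne_to_pm_path_exists) {
    cat("  NE -> PM path:", paste(x$example_path, collapse = " - "), "\n")
  } else {
    cat("  no NE -> PM path:", x$reason, "\n")
  }
  invisible(x)
}
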