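#' Read a 6-column pedigree (PED) file
#'
#' Standard whitespace-delimited PED: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female), affection (1 = unaffected,
#' 2 = affected, 0/-9 = unknown).  An optional 7th column is read as age
#' in years.
#'
#' @param path Path to the PED file.
#' @return A pedigree tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id` (`"0"` for founders), `sex`, `affected`,
#'   `age`.
#' @details Referential integrity is enforced: a parent id that does not
#'   appear as an individual raises an integrity error; a parentage cycle
#'   (including self-ancestry) raises a structural error; fathers must be
#'   male and mothers female.
#' @seealso [write_ped()], [new_pedigree()]
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) abort(paste0("no such PED file: ", path))
  raw <- read.table(path, header = FALSE, colClasses = "character",
                    fill = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 6 || ncol(raw) > 7) {
    abort(sprintf("PED file must have 6 (or 7) columns, found %d", ncol(raw)),
      class = "edmd_parse_error"
    )
  }
  sex <- dplyr::case_match(raw[[5]], "1" ~ "male", "2" ~ "female")
  if (any(is.na(sex))) abort("PED sex codes must be 1 (male) or 2 (female)")
  affected <- dplyr::case_match(
    raw[[6]],
    "1" ~ "unaffected", "2" ~ "affected", c("0", "-9") ~ "unknown"
  )
  if (any(is.na(affected))) abort("PED affection codes must be 1, 2, 0 or -9")
  age <- if (ncol(raw) == 7) suppressWarnings(as.numeric(raw[[7]])) else NA_real_
  new_pedigree(tibble(
    family_id = raw[[1]], individual_id = raw[[2]],
    father_id = raw[[3]], mother_id = raw[[4]],
    sex = sex, affected = affected, age = age
  ))
}

#' Construct and validate a pedigree tibble
#'
#' @param df Tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `affected` and optionally `age`.
#' @return The validated pedigree tibble (class `edmd_pedigree`).
#' @export
new_pedigree <- function(df) {
  df <- as_tibble(df)
  if (!"age" %in% names(df)) df$age <- NA_real_
  df$father_id <- as.character(df$father_id)
  df$mother_id <- as.character(df$mother_id)
  df$individual_id <- as.character(df$individual_id)

  if (anyDuplicated(df$individual_id)) abort("duplicate individual ids in pedigree")
  parents <- c(df$father_id, df$mother_id)
  dangling <- setdiff(setdiff(parents, "0"), df$individual_id)
  if (length(dangling) > 0) {
    abort(paste0("dangling parent id(s): ", paste(dangling, collapse = ", ")),
      class = "edmd_integrity_error"
    )
  }
  fathers <- df$father_id[df$father_id != "0"]
  mothers <- df$mother_id[df$mother_id != "0"]
  if (any(df$sex[match(fathers, df$individual_id)] != "male")) {
    abort("father ids must refer to male individuals", class = "edmd_integrity_error")
  }
  if (any(df$sex[match(mothers, df$individual_id)] != "female")) {
    abort("mother ids must refer to female individuals", class = "edmd_integrity_error")
  }

  ## cycle detection by iterated founder stripping
  placed <- character(0)
  remaining <- df$individual_id
  repeat {
    ready <- remaining[
      (df$father_id[match(remaining, df$individual_id)] %in% c("0", placed)) &
        (df$mother_id[match(remaining, df$individual_id)] %in% c("0", placed))
    ]
    if (length(ready) == 0) break
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining) > 0) {
    abort(paste0("pedigree contains a parentage cycle involving: ",
                 paste(remaining, collapse = ", ")),
      class = "edmd_structural_error"
    )
  }
  class(df) <- c("edmd_pedigree", class(df))
  df
}

#' @rdname read_ped
#' @param pedigree A pedigree tibble.
#' @export
write_ped <- function(pedigree, path) {
  sex <- ifelse(pedigree$sex == "male", 1L, 2L)
  aff <- dplyr::case_match(pedigree$affected,
    "unaffected" ~ 1L, "affected" ~ 2L, "unknown" ~ 0L
  )
  out <- data.frame(
    pedigree$family_id, pedigree$individual_id,
    pedigree$father_id, pedigree$mother_id, sex, aff
  )
  if (any(!is.na(pedigree$age))) out$age <- pedigree$age
  write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Pedigree helpers
#'
#' `founders()` returns the ids of members with no recorded parents;
#' `topological_order()` returns member ids with parents always before
#' children.
#'
#' @param pedigree A pedigree tibble.
#' @return A character vector of individual ids.
#' @export
founders <- function(pedigree) {
  pedigree$individual_id[pedigree$father_id == "0" & pedigree$mother_id == "0"]
}

#' @rdname founders
#' @export
topological_order <- function(pedigree) {
  placed <- character(0)
  remaining <- pedigree$individual_id
  idx <- function(id) match(id, pedigree$individual_id)
  while (length(remaining) > 0) {
    ready <- remaining[
      pedigree$father_id[idx(remaining)] %in% c("0", placed) &
        pedigree$mother_id[idx(remaining)] %in% c("0", placed)
    ]
    if (length(ready) == 0) abort("pedigree contains a cycle", class = "edmd_structural_error")
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}
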