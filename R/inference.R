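# Presence matrix, vetting overrides, peroxisome-loss calling, enzyme
# localization matrix, and unique-orthogroup complexity counts.

PRESENCE_STATES <- c("present_high", "present_low", "absent")

#' Build the species-by-family presence matrix
#'
#' A cell is `present_high` if any assignment to that family in that
#' species has high confidence, `present_low` if only low-confidence
#' assignments exist, and `absent` otherwise. Provenance (supporting
#' protein ids and the best score) is kept per non-absent cell.
#'
#' @param assignments Tibble from [assign_orthogroups()] (already filtered
#'   to positive scores).
#' @param panel Marker panel tibble (peroxins and enzymes).
#' @param species_ids All species in the screen, including species with no
#'   assignments at all.
#' @param background_ids Family ids outside the panel (background
#'   orthogroups) that assignments may legitimately reference; any other
#'   foreign family id is a configuration error.
#' @return Tibble (long form): `species_id`, `family_id`, `marker_class`,
#'   `state`, `protein_ids`, `score`.
#' @export
build_presence_matrix <- function(assignments, panel, species_ids,
                                  background_ids = character()) {
  check_panel(panel)
  foreign <- setdiff(unique(assignments$family_id),
                     c(panel$family_id, background_ids))
  if (length(foreign)) {
    perox_abort_config(paste0(
      "assignments reference families outside the panel and background set: ",
      paste(foreign, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(
    species_id = species_ids,
    family_id = panel$family_id
  ) |>
    dplyr::left_join(dplyr::select(panel, "family_id", "marker_class"),
                     by = "family_id")
  cells <- assignments |>
    dplyr::filter(.data$family_id %in% panel$family_id) |>
    dplyr::group_by(.data$species_id, .data$family_id) |>
    dplyr::summarise(
      state = ifelse(any(.data$confidence == "high"), "present_high", "present_low"),
      protein_ids = paste(sort(.data$protein_id), collapse = ","),
      score = if (dplyr::n() > 0) max(.data$score) else NA_real_,
      .groups = "drop"
    )
  grid |>
    dplyr::left_join(cells, by = c("species_id", "family_id")) |>
    dplyr::mutate(
      state = dplyr::coalesce(.data$state, "absent"),
      protein_ids = dplyr::coalesce(.data$protein_ids, ""),
      score = dplyr::coalesce(.data$score, NA_real_)
    )
}

#' Apply external vetting verdicts to a presence matrix
#'
#' Ingests the outcome of an external (e.g. phylogenetic) vetting of
#' flagged cells: `reject` sets the cell to `absent` with a provenance
#' note; `confirm` promotes `present_low` to `present_high`.
#'
#' @param matrix Presence matrix from [build_presence_matrix()].
#' @param verdicts Tibble with `species_id`, `family_id`, `verdict`
#'   (`"confirm"` or `"reject"`).
#' @return The updated matrix, with a `vetting` note column.
#' @export
apply_vetting_overrides <- function(matrix, verdicts) {
  if (!"vetting" %in% names(matrix)) matrix$vetting <- ""
  if (is.null(verdicts) || nrow(verdicts) == 0) return(matrix)
  bad <- !(verdicts$verdict %in% c("confirm", "reject"))
  if (any(bad)) {
    perox_abort_input(paste0("unknown verdict value(s): ",
                             paste(unique(verdicts$verdict[bad]), collapse = ", ")))
  }
  keys <- paste(matrix$species_id, matrix$family_id, sep = "\r")
  vkeys <- paste(verdicts$species_id, verdicts$family_id, sep = "\r")
  missing <- !(vkeys %in% keys)
  if (any(missing)) {
    perox_abort_input(paste0(
      "vetting verdict for unknown cell(s): ",
      paste(sprintf("(%s, %s)", verdicts$species_id[missing],
                    verdicts$family_id[missing]), collapse = ", ")))
  }
  for (i in seq_len(nrow(verdicts))) {
    j <- which(keys == vkeys[i])
    if (verdicts$verdict[i] == "reject") {
      matrix$state[j] <- "absent"
      matrix$vetting[j] <- "rejected_by_vetting"
    } else {
      if (matrix$state[j] == "present_low") matrix$state[j] <- "present_high"
      matrix$vetting[j] <- "confirmed_by_vetting"
    }
  }
  matrix
}

#' Call peroxisome loss per species
#'
#' The organelle verdict rests on the essential peroxins (Pex3, Pex19),
#' whose experimental loss abolishes peroxisome biogenesis:
#' `peroxisomes_lost` iff every peroxin cell is absent;
#' `peroxisomes_retained` iff at least one peroxin is `present_high` *and*
#' both essential markers are present (any confidence); `indeterminate`
#' otherwise (e.g. only low-confidence evidence, essential markers absent
#' while others are present, or a proteome with zero proteins).
#'
#' @param matrix Presence matrix (after any vetting overrides).
#' @param panel Marker panel with `essential` flags.
#' @param proteome_sizes Optional tibble `species_id`, `n_proteins`;
#'   species with zero proteins are reported `indeterminate` (absence of
#'   data is not absence of genes).
#' @return Tibble of loss calls: `species_id`, `verdict`, `n_present`,
#'   `n_present_high`, `n_absent`, `essential_present`, `absent_peroxins`,
#'   `low_confidence_cells`.
#' @export
call_peroxisome_loss <- function(matrix, panel, proteome_sizes = NULL) {
  peroxins <- panel$family_id[panel$marker_class == "peroxin"]
  essentials <- panel$family_id[panel$marker_class == "peroxin" & panel$essential]
  missing <- setdiff(peroxins, unique(matrix$family_id))
  if (length(missing)) {
    perox_abort_config(paste0("presence matrix does not cover panel peroxins: ",
                              paste(missing, collapse = ", ")))
  }
  px <- dplyr::filter(matrix, .data$family_id %in% peroxins)
  out <- px |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_present = sum(.data$state != "absent"),
      n_present_high = sum(.data$state == "present_high"),
      n_absent = sum(.data$state == "absent"),
      essential_present = all(.data$state[.data$family_id %in% essentials] != "absent"),
      absent_peroxins = paste(.data$family_id[.data$state == "absent"], collapse = ","),
      low_confidence_cells = paste(.data$family_id[.data$state == "present_low"],
                                   collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      verdict = dplyr::case_when(
        .data$n_present == 0 ~ "peroxisomes_lost",
        .data$n_present_high >= 1 & .data$essential_present ~ "peroxisomes_retained",
        .default = "indeterminate"
      )
    )
  if (!is.null(proteome_sizes)) {
    out <- out |>
      dplyr::left_join(proteome_sizes, by = "species_id") |>
      dplyr::mutate(
        verdict = ifelse(!is.na(.data$n_proteins) & .data$n_proteins == 0,
                         "indeterminate", .data$verdict)
      ) |>
      dplyr::select(-"n_proteins")
    }
  dplyr::select(out, "species_id", "verdict", dplyr::everything())
}

#' Build the enzyme presence/localization matrix
#'
#' Per (species, enzyme family): presence as in [build_presence_matrix()],
#' and a localization category from the union of signal flags across all
#' proteins assigned to that family in that species (paralogs pooled),
#' collapsed with [combine_localization()].
#'
#' @param assignments Tibble from [assign_orthogroups()].
#' @param targeting_calls Tibble from [call_targeting()] covering every
#'   assigned protein.
#' @param panel Marker panel.
#' @param species_ids All species in the screen.
#' @param background_ids As in [build_presence_matrix()].
#' @return Long tibble: `species_id`, `family_id`, `state`, `category`,
#'   `protein_ids`.
#' @export
build_enzyme_matrix <- function(assignments, targeting_calls, panel, species_ids,
                                background_ids = character()) {
  enzymes <- panel[panel$marker_class == "enzyme", ]
  pm <- build_presence_matrix(assignments, panel, species_ids, background_ids) |>
    dplyr::filter(.data$marker_class == "enzyme")
  enz_assign <- dplyr::filter(assignments, .data$family_id %in% enzymes$family_id)
  uncovered <- setdiff(enz_assign$protein_id, targeting_calls$protein_id)
  if (length(uncovered)) {
    perox_abort_input(paste0("missing targeting call for assigned protein(s): ",
                             paste(uncovered, collapse = ", ")))
  }
  flags <- enz_assign |>
    dplyr::left_join(
      dplyr::select(targeting_calls, "protein_id", "pts1", "pts2", "nterm"),
      by = "protein_id"
    ) |>
    dplyr::group_by(.data$species_id, .data$family_id) |>
    dplyr::summarise(
      any_pts = any(!is.na(.data$pts1)) || any(!is.na(.data$pts2)),
      any_mito = any(.data$nterm == "mito"),
      any_sec = any(.data$nterm == "sec"),
      .groups = "drop"
    )
  # union of flags across paralogs, then the eight-way collapse (spelled
  # out so mito+sec unions are kept; combine_localization() takes a single
  # nterm class per protein, not a union)
  flags$category <- dplyr::case_when(
    flags$any_pts & flags$any_mito & flags$any_sec ~ "pts_mito_sec",
    flags$any_pts & flags$any_mito ~ "pts_mito",
    flags$any_pts & flags$any_sec ~ "pts_sec",
    flags$any_mito & flags$any_sec ~ "sec_mito",
    flags$any_pts ~ "pts",
    flags$any_mito ~ "mito",
    flags$any_sec ~ "sec",
    .default = "none"
  )
  pm |>
    dplyr::left_join(dplyr::select(flags, "species_id", "family_id", "category"),
                     by = c("species_id", "family_id")) |>
    dplyr::mutate(category = ifelse(.data$state == "absent", "none",
                                    dplyr::coalesce(.data$category, "none"))) |>
    dplyr::select("species_id", "family_id", "state", "category", "protein_ids")
}

#' Count unique orthologous groups per species
#'
#' The genome-complexity measure: the number of distinct families (over the
#' full profile set, panel plus background groups) with at least one
#' positive-score assignment in the species.
#'
#' @param assignments Tibble from [assign_orthogroups()].
#' @param species_ids All species (species without assignments count 0).
#' @return Tibble: `species_id`, `n_unique_orthogroups`.
#' @export
count_orthogroups <- function(assignments, species_ids) {
  counts <- assignments |>
    dplyr::distinct(.data$species_id, .data$family_id) |>
    dplyr::count(.data$species_id, name = "n_unique_orthogroups")
  tibble::tibble(species_id = species_ids) |>
    dplyr::left_join(counts, by = "species_id") |>
    dplyr::mutate(n_unique_orthogroups = dplyr::coalesce(.data$n_unique_orthogroups, 0L))
}
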