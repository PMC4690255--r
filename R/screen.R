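# End-to-end orchestration: configuration, the full screen, deterministic
# TSV output, and the textual report.

#' Screen configuration
#'
#' Collects every tunable of the pipeline with its documented default.
#' A config round-trips through JSON serialization unchanged.
#'
#' @param evalue_max Acceptance threshold on hit E-values (default `1e-3`);
#'   hits above it are regarded as false positives.
#' @param score_high Score margin separating high from low confidence
#'   (default 2, i.e. 100-fold E-value separation).
#' @param pseudocount Profile pseudocount weight (default 1).
#' @param n_null Null sample size for E-value calibration (default 1000).
#' @param null_length Null sequence length (default 300).
#' @param evalue_ceiling Hit reporting ceiling (default 10).
#' @param seed Run seed; all stage substreams derive from it.
#' @param pts2_rule PTS2 window rule, `"contain"` (default) or `"start"`.
#' @param enext_default_rule `"evalue_max"` (default): `enext` falls back
#'   to `evalue_max` when only one family survives.
#' @param log_base Base of the assignment-score logarithm (default 10).
#' @return List of class `perox_config`.
#' @export
screen_config <- function(evalue_max = 1e-3, score_high = 2, pseudocount = 1,
                          n_null = 1000L, null_length = 300L,
                          evalue_ceiling = 10, seed = 1L,
                          pts2_rule = c("contain", "start"),
                          enext_default_rule = "evalue_max",
                          log_base = 10) {
  pts2_rule <- match.arg(pts2_rule)
  if (evalue_max <= 0) perox_abort_config("`evalue_max` must be positive.")
  structure(
    list(evalue_max = as.numeric(evalue_max), score_high = as.numeric(score_high),
         pseudocount = as.numeric(pseudocount), n_null = as.integer(n_null),
         null_length = as.integer(null_length),
         evalue_ceiling = as.numeric(evalue_ceiling), seed = as.integer(seed),
         pts2_rule = pts2_rule, enext_default_rule = enext_default_rule,
         log_base = as.numeric(log_base)),
    class = "perox_config"
  )
}

#' Serialize / deserialize a screen configuration
#'
#' @param config A `perox_config`.
#' @param path File path.
#' @return `read_screen_config()` returns a `perox_config`.
#' @export
write_screen_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_screen_config
#' @export
read_screen_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(screen_config, vals)
}

config_fingerprint <- function(config) {
  rlang::hash(unclass(config))
}

#' Run the full presence/absence screen
#'
#' Builds and calibrates a scoring profile per family alignment (or ingests
#' external HMMER3 domain tables for designated species), assigns proteins
#' to marker groups, scans targeting signals, builds the presence and
#' enzyme matrices, applies vetting overrides, calls peroxisome loss, and
#' counts unique orthogroups.
#'
#' @param cohort A `perox_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config A [screen_config()].
#' @param nterm_predictions Optional tibble from
#'   [parse_nterm_predictions()]; if `NULL` the built-in rule-based
#'   classifier is used.
#' @param vetting Optional verdict tibble for
#'   [apply_vetting_overrides()].
#' @param domtbl Optional named list (species_id -> file path or character
#'   lines) of HMMER3 domain tables; those species use the `domtbl`
#'   backend instead of the built-in scorer. Mixing backends across
#'   species is allowed and recorded in the manifest.
#' @return A `perox_screen`: list with `config`, `hits`, `assignments`,
#'   `targeting`, `presence`, `loss_calls`, `enzyme_matrix`, `complexity`,
#'   `species`, `panel`, `manifest`.
#' @export
run_screen <- function(cohort, config = screen_config(),
                       nterm_predictions = NULL, vetting = NULL,
                       domtbl = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  panel <- cohort$panel
  check_panel(panel)
  marker_panel <- panel[panel$marker_class %in% c("peroxin", "enzyme"), ]
  background_ids <- panel$family_id[panel$marker_class == "background_og"]
  seed <- config$seed

  profiles <- purrr::map(cohort$families, function(fam) {
    prof <- build_profile(fam$members, family_id = fam$family_id,
                          pseudocount = config$pseudocount)
    calibrate_evalue(prof, n_null = config$n_null,
                     null_length = config$null_length,
                     seed = substream_seed(seed, paste0("calibrate:", fam$family_id)))
  })

  species_ids <- cohort$species$species_id
  domtbl_species <- intersect(names(domtbl %||% list()), species_ids)
  builtin_species <- setdiff(species_ids, domtbl_species)

  hits_builtin <- search_proteome(
    profiles,
    dplyr::filter(cohort$proteomes, .data$species_id %in% builtin_species),
    evalue_ceiling = config$evalue_ceiling
  )
  hits_domtbl <- purrr::map_dfr(domtbl_species, function(sp) {
    parse_domtbl(domtbl[[sp]], species_id = sp)
  })
  hits <- dplyr::bind_rows(hits_builtin, hits_domtbl)

  assignments <- assign_orthogroups(
    hits, evalue_max = config$evalue_max,
    enext_default = config$evalue_max,
    score_high = config$score_high, log_base = config$log_base
  )

  targeting <- call_targeting(cohort$proteomes, nterm_predictions,
                              pts2_rule = config$pts2_rule)

  presence <- build_presence_matrix(assignments, marker_panel, species_ids,
                                    background_ids = background_ids)
  presence <- apply_vetting_overrides(presence, vetting)
  sizes <- dplyr::count(cohort$proteomes, .data$species_id, name = "n_proteins") |>
    dplyr::right_join(tibble::tibble(species_id = species_ids), by = "species_id") |>
    dplyr::mutate(n_proteins = dplyr::coalesce(.data$n_proteins, 0L))
  loss_calls <- call_peroxisome_loss(presence, marker_panel, proteome_sizes = sizes)
  enzyme_matrix <- build_enzyme_matrix(assignments, targeting, marker_panel,
                                       species_ids, background_ids = background_ids)
  complexity <- count_orthogroups(assignments, species_ids)

  manifest <- list(
    package_version = as.character(utils::packageVersion("peroxscreen")),
    config = unclass(config),
    config_hash = config_fingerprint(config),
    seed = seed,
    n_species = length(species_ids),
    n_families = nrow(panel),
    backends = list(builtin = builtin_species, domtbl = domtbl_species),
    nterm_source = if (is.null(nterm_predictions)) "builtin" else "ingested",
    stage_counts = list(
      hits = nrow(hits), assignments = nrow(assignments),
      targeting_calls = nrow(targeting)
    )
  )
  structure(
    list(config = config, hits = hits, assignments = assignments,
         targeting = targeting, presence = presence, loss_calls = loss_calls,
         enzyme_matrix = enzyme_matrix, complexity = complexity,
         species = cohort$species, panel = panel, manifest = manifest),
    class = "perox_screen"
  )
}

#' @export
print.perox_screen <- function(x, ...) {
  cat(sprintf("<perox_screen> %d species x %d families; %d assignments\n",
              x$manifest$n_species, x$manifest$n_families, nrow(x$assignments)))
  tab <- table(x$loss_calls$verdict)
  for (v in names(tab)) cat(sprintf("  %s: %d\n", v, tab[[v]]))
  invisible(x)
}

#' Write screen outputs as deterministic TSVs
#'
#' Writes `assignments.tsv`, `targeting.tsv`, `presence_matrix.tsv` (wide:
#' species rows, family columns), `enzyme_matrix.tsv`, `loss_calls.tsv`,
#' `complexity.tsv`, `manifest.json` and a full-provenance
#' `provenance.json`. All TSVs use UNIX newlines, UTF-8, `.` decimal and a
#' fixed column order, so reruns are byte-identical.
#'
#' @param screen A `perox_screen`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_screen <- function(screen, out_dir) {
  if (!dir.exists(dirname(out_dir))) {
    perox_abort_input(sprintf("parent directory does not exist: %s", dirname(out_dir)))
  }
  dir.create(out_dir, showWarnings = FALSE)
  w <- function(df, name) readr::write_tsv(df, file.path(out_dir, name), progress = FALSE)
  w(screen$assignments, "assignments.tsv")
  w(screen$targeting, "targeting.tsv")
  wide <- screen$presence |>
    dplyr::select("species_id", "family_id", "state") |>
    tidyr::pivot_wider(names_from = "family_id", values_from = "state")
  w(wide, "presence_matrix.tsv")
  w(screen$enzyme_matrix, "enzyme_matrix.tsv")
  w(screen$loss_calls, "loss_calls.tsv")
  w(screen$complexity, "complexity.tsv")
  jsonlite::write_json(screen$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(presence = screen$presence, hits_n = nrow(screen$hits),
         manifest = screen$manifest),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' Human-readable screen summary
#'
#' One verdict line per species (with the absent-peroxin count) followed by
#' a complexity ranking table.
#'
#' @param screen A `perox_screen`, or a directory written by
#'   [write_screen()].
#' @return Character vector of report lines, invisibly; printed when
#'   `quiet = FALSE`.
#' @param quiet Suppress printing.
#' @export
screen_report <- function(screen, quiet = FALSE) {
  if (is.character(screen)) {
    dir <- screen
    lc_path <- file.path(dir, "loss_calls.tsv")
    cx_path <- file.path(dir, "complexity.tsv")
    if (!file.exists(lc_path) || !file.exists(cx_path)) {
      perox_abort_input(sprintf("screen outputs not found under %s", dir))
    }
    loss_calls <- readr::read_tsv(lc_path, show_col_types = FALSE) |>
      dplyr::mutate(dplyr::across(
        c("absent_peroxins", "low_confidence_cells"),
        ~ dplyr::coalesce(as.character(.x), "")
      ))
    complexity <- readr::read_tsv(cx_path, show_col_types = FALSE)
    n_peroxins <- NULL
  } else {
    loss_calls <- screen$loss_calls
    complexity <- screen$complexity
    n_peroxins <- sum(screen$panel$marker_class == "peroxin")
  }
  if (is.null(n_peroxins)) {
    n_peroxins <- max(loss_calls$n_present + loss_calls$n_absent)
  }
  lines <- c("== peroxisome screen: per-species verdicts ==")
  lc <- dplyr::arrange(loss_calls, .data$verdict, .data$species_id)
  for (i in seq_len(nrow(lc))) {
    r <- lc[i, ]
    lines <- c(lines, sprintf(
      "%-20s %-22s absent peroxins %d/%d%s", r$species_id, r$verdict,
      r$n_absent, n_peroxins,
      if (nzchar(r$absent_peroxins) && r$n_absent < n_peroxins)
        paste0(" (", r$absent_peroxins, ")") else ""))
  }
  lines <- c(lines, "", "== unique orthologous groups (complexity ranking) ==")
  cx <- dplyr::arrange(complexity, dplyr::desc(.data$n_unique_orthogroups),
                       .data$species_id)
  lines <- c(lines, sprintf("%-20s %4d", cx$species_id, cx$n_unique_orthogroups))
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}
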