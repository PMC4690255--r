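# Best-vs-next-hit orthologous-group assignment.

EVALUE_FLOOR <- 1e-300

#' Assign proteins to orthologous marker groups
#'
#' Implements the acceptance filter and log E-value separation score. Per
#' protein: hits with E-value above `evalue_max` are regarded as false
#' positives and discarded; surviving hits are collapsed to one per family
#' (minimum E-value) and sorted; `ehit` is the best family's E-value and
#' `enext` the next family's (or `enext_default` when no second family
#' survives); `score = log10(enext) - log10(ehit)` (base configurable).
#' Only strict winners (score > 0) are emitted; ties score zero and yield
#' no assignment. Confidence is `"high"` when the score reaches
#' `score_high` (default 2, i.e. a 100-fold E-value separation), else
#' `"low"`.
#'
#' @param hits Tibble of hits (`species_id`, `protein_id`, `family_id`,
#'   `evalue`, optionally `raw_score`, `backend`); proteins may be mixed.
#' @param evalue_max Acceptance threshold (default `1e-3`).
#' @param enext_default E-value used for `enext` when only one family
#'   survives; defaults to `evalue_max`, the least favorable accepted value.
#' @param score_high Confidence margin on the score (default 2).
#' @param log_base Base of the logarithm (default 10; any base preserves
#'   the sign law).
#' @return Tibble of assignments: `species_id`, `protein_id`, `family_id`,
#'   `ehit`, `enext`, `score`, `confidence`, `backend`.
#' @export
#' @examples
#' hits <- tibble::tibble(
#'   species_id = "sp1", protein_id = "p1",
#'   family_id = c("Pex5", "Pex7"), evalue = c(1e-10, 1e-5),
#'   backend = "builtin"
#' )
#' assign_orthogroups(hits)
assign_orthogroups <- function(hits, evalue_max = 1e-3,
                               enext_default = evalue_max,
                               score_high = 2, log_base = 10) {
  empty <- tibble::tibble(
    species_id = character(), protein_id = character(), family_id = character(),
    ehit = double(), enext = double(), score = double(),
    confidence = character(), backend = character()
  )
  if (evalue_max <= 0) perox_abort_config("`evalue_max` must be positive.")
  if (nrow(hits) == 0) return(empty)
  if (!"backend" %in% names(hits)) hits$backend <- NA_character_
  if (any(hits$evalue <= 0)) {
    warn(sprintf("%d hit(s) with E-value <= 0 floored at %g before taking logs.",
                 sum(hits$evalue <= 0), EVALUE_FLOOR))
    hits$evalue <- pmax(hits$evalue, EVALUE_FLOOR)
  }
  lg <- function(x) log(x, base = log_base)
  out <- hits |>
    dplyr::filter(.data$evalue <= evalue_max) |>
    dplyr::group_by(.data$species_id, .data$protein_id, .data$family_id) |>
    dplyr::slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    dplyr::group_by(.data$species_id, .data$protein_id) |>
    dplyr::arrange(.data$evalue, .data$family_id, .by_group = TRUE) |>
    dplyr::summarise(
      family_id = .data$family_id[1],
      ehit = .data$evalue[1],
      enext = if (dplyr::n() >= 2) .data$evalue[2] else enext_default,
      backend = .data$backend[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      score = lg(.data$enext) - lg(.data$ehit),
      confidence = ifelse(.data$score >= score_high, "high", "low")
    ) |>
    dplyr::filter(.data$score > 0) |>
    dplyr::select("species_id", "protein_id", "family_id", "ehit", "enext",
                  "score", "confidence", "backend")
  if (nrow(out) == 0) empty else out
}
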