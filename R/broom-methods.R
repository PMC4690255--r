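# broom-style accessors for screen results.

#' Tidy a screen result
#'
#' Returns the per-species loss calls joined with the complexity counts —
#' the screen's headline table, one row per species.
#'
#' @param x A `perox_screen`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.perox_screen <- function(x, ...) {
  dplyr::left_join(x$loss_calls, x$complexity, by = "species_id")
}

#' One-row summary of a screen result
#'
#' @param x A `perox_screen`.
#' @param ... Unused.
#' @return A one-row tibble with cohort size and verdict counts.
#' @export
glance.perox_screen <- function(x, ...) {
  v <- x$loss_calls$verdict
  tibble::tibble(
    n_species = x$manifest$n_species,
    n_families = x$manifest$n_families,
    n_assignments = nrow(x$assignments),
    n_lost = sum(v == "peroxisomes_lost"),
    n_retained = sum(v == "peroxisomes_retained"),
    n_indeterminate = sum(v == "indeterminate"),
    seed = x$config$seed
  )
}
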