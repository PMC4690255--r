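# ggplot2 views of screen results.

#' Plot the peroxin presence/absence matrix
#'
#' Tile plot of the species-by-peroxin grid; high-confidence cells dark,
#' low-confidence cells pale (conventionally asterisked for vetting),
#' absent cells empty.
#'
#' @param screen A `perox_screen`.
#' @return A ggplot object.
#' @export
plot_presence_matrix <- function(screen) {
  df <- dplyr::filter(screen$presence, .data$marker_class == "peroxin")
  df$family_id <- factor(df$family_id,
                         levels = unique(screen$panel$family_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family_id, y = .data$species_id,
                                   fill = .data$state)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_manual(values = c(
      present_high = "#1b7837", present_low = "#a6dba0", absent = "white")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "state",
                  title = "Peroxin presence/absence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

LOCALIZATION_COLORS <- c(
  none = "grey80", pts = "#d7191c", mito = "#2c7bb6", sec = "#ffd700",
  pts_mito = "#7b3294", pts_sec = "#fdae61", sec_mito = "#1a9641",
  pts_mito_sec = "black"
)

#' Plot the enzyme localization matrix
#'
#' Tile plot of enzyme presence colored by the eight-way localization
#' category (union of signals across paralogs).
#'
#' @param screen A `perox_screen`.
#' @return A ggplot object.
#' @export
plot_enzyme_matrix <- function(screen) {
  df <- screen$enzyme_matrix
  df$category <- factor(df$category, levels = names(LOCALIZATION_COLORS))
  df$shown <- ifelse(df$state == "absent", NA, as.character(df$category))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family_id, y = .data$species_id,
                                   fill = .data$shown)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_manual(values = LOCALIZATION_COLORS, na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "localization",
                  title = "Peroxisomal enzymes and predicted localization") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot unique-orthogroup counts per species
#'
#' Dot plot of the genome-complexity measure, colored by the peroxisome
#' verdict; species lacking peroxisomes sit visibly below their relatives.
#'
#' @param screen A `perox_screen`.
#' @return A ggplot object.
#' @export
plot_complexity <- function(screen) {
  df <- dplyr::left_join(screen$complexity,
                         dplyr::select(screen$loss_calls, "species_id", "verdict"),
                         by = "species_id")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$species_id, .data$n_unique_orthogroups),
    y = .data$n_unique_orthogroups, color = .data$verdict)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_color_manual(values = c(
      peroxisomes_lost = "#d7191c", peroxisomes_retained = "grey30",
      indeterminate = "#fdae61")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "unique orthologous groups",
                  title = "Genome complexity and peroxisome loss") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_complexity Default view of a screen result.
#' @param object A `perox_screen`.
#' @param type One of `"complexity"`, `"presence"`, `"enzymes"`.
#' @param ... Unused.
#' @export
autoplot.perox_screen <- function(object, type = c("complexity", "presence", "enzymes"),
                                  ...) {
  switch(match.arg(type),
         complexity = plot_complexity(object),
         presence = plot_presence_matrix(object),
         enzymes = plot_enzyme_matrix(object))
}
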