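# A deliberately small cohort (9 families, 3 species) so end-to-end screen
# tests stay fast; the default 24-species cohort is exercised by the
# planted-loss recovery tests.

small_panel <- function() {
  dplyr::bind_rows(
    marker_family_spec("Pex3", "peroxin", essential = TRUE),
    marker_family_spec("Pex19", "peroxin", essential = TRUE),
    marker_family_spec("Pex5", "peroxin"),
    marker_family_spec("Pex14", "peroxin"),
    marker_family_spec("Cat", "enzyme"),
    marker_family_spec("Acaa1", "enzyme"),
    marker_family_spec("Crat", "enzyme"),
    marker_family_spec("OG0001", "background_og"),
    marker_family_spec("OG0002", "background_og")
  )
}

small_specs <- function(panel = small_panel()) {
  fams <- panel$family_id
  peroxins <- panel$family_id[panel$marker_class == "peroxin"]
  loss_plan <- stats::setNames(rep("present", length(fams)), fams)
  loss_plan[peroxins] <- "absent"
  loss_plan[c("Acaa1", "Crat")] <- "absent"
  full_plan <- stats::setNames(rep("present", length(fams)), fams)
  sig <- function(sp) {
    out <- list("pts1", "pts2", c("pts1", "mito"))
    names(out) <- paste0(sp, "|", c("Cat", "Acaa1", "Crat"))
    out
  }
  list(
    species_spec("loss_A", loss_plan,
                 stats::setNames(list("sec"), "loss_A|Cat"), n_decoys = 10L),
    species_spec("ok_A", full_plan, sig("ok_A"), n_decoys = 10L),
    species_spec("ok_B", full_plan, sig("ok_B"), n_decoys = 10L)
  )
}

small_cohort <- function(seed = 7L) {
  generate_cohort(small_specs(), panel = small_panel(), seed = seed)
}

small_config <- function(seed = 7L) {
  screen_config(n_null = 250L, seed = seed)
}
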