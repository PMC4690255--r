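mini_panel <- function() {
  dplyr::bind_rows(
    marker_family_spec("Pex3", "peroxin", essential = TRUE),
    marker_family_spec("Pex19", "peroxin", essential = TRUE),
    marker_family_spec("Pex5", "peroxin"),
    marker_family_spec("Cat", "enzyme"),
    marker_family_spec("Acaa1", "enzyme")
  )
}

assignment_row <- function(species, protein, family, score,
                           confidence = if (score >= 2) "high" else "low") {
  tibble::tibble(
    species_id = species, protein_id = protein, family_id = family,
    ehit = 10^(-score - 3), enext = 1e-3, score = score,
    confidence = confidence, backend = "builtin"
  )
}

test_that("assignment scores equal the log E-value separation exactly", {
  hits <- tibble::tibble(
    species_id = "sp", protein_id = "winner",
    family_id = c("Pex5", "Pex7"), evalue = c(1e-10, 1e-5), backend = "builtin"
  )
  out <- assign_orthogroups(hits)
  expect_identical(out$family_id, "Pex5")
  expect_identical(out$score, 5)
  expect_identical(out$confidence, "high")
  expect_identical(out$ehit, 1e-10)
  expect_identical(out$enext, 1e-5)
})

test_that("tied best E-values yield no assignment", {
  hits <- tibble::tibble(
    species_id = "sp", protein_id = "tied",
    family_id = c("Pex5", "Pex7"), evalue = c(1e-6, 1e-6), backend = "builtin"
  )
  expect_equal(nrow(assign_orthogroups(hits)), 0L)
})

test_that("a lone surviving family scores against the acceptance threshold", {
  hits <- tibble::tibble(
    species_id = "sp", protein_id = "lone",
    family_id = "Pex5", evalue = 1e-6, backend = "builtin"
  )
  out <- assign_orthogroups(hits)
  expect_identical(out$enext, 1e-3)
  expect_identical(out$score, 3)
  expect_identical(out$confidence, "high")
})

test_that("hits above the acceptance threshold are treated as false positives", {
  hits <- tibble::tibble(
    species_id = "sp", protein_id = c("p1", "p2"),
    family_id = "Pex5", evalue = c(5e-3, 1e-2), backend = "builtin"
  )
  expect_equal(nrow(assign_orthogroups(hits)), 0L)
  # the discarded second family also no longer competes as enext
  hits2 <- tibble::tibble(
    species_id = "sp", protein_id = "p1",
    family_id = c("Pex5", "Pex7"), evalue = c(1e-6, 5e-3), backend = "builtin"
  )
  out <- assign_orthogroups(hits2)
  expect_identical(out$enext, 1e-3)
})

test_that("zero E-values are floored before taking logarithms", {
  hits <- tibble::tibble(
    species_id = "sp", protein_id = "p0",
    family_id = c("Pex5", "Pex7"), evalue = c(0, 1e-5), backend = "builtin"
  )
  expect_warning(out <- assign_orthogroups(hits), "floored")
  expect_identical(out$ehit, 1e-300)
  expect_identical(out$score, log10(1e-5) - log10(1e-300))
})

test_that("duplicate domains collapse to the per-family minimum E-value", {
  hits <- tibble::tibble(
    species_id = "sp", protein_id = "p1",
    family_id = c("Pex5", "Pex5", "Pex7"), evalue = c(1e-8, 1e-6, 1e-4),
    backend = "domtbl"
  )
  out <- assign_orthogroups(hits)
  expect_identical(out$ehit, 1e-8)
  expect_identical(out$enext, 1e-4)
  expect_identical(out$score, 4)
})

test_that("the confidence margin and log base behave as documented", {
  hits <- tibble::tibble(
    species_id = "sp", protein_id = "edge",
    family_id = c("A", "B"), evalue = c(1e-5, 1e-3), backend = "builtin"
  )
  out <- assign_orthogroups(hits)
  expect_identical(out$score, 2) # exactly at the margin counts as high
  expect_identical(out$confidence, "high")
  out2 <- assign_orthogroups(hits, log_base = 2)
  expect_equal(out2$score, 2 * log2(10))
  expect_error(assign_orthogroups(hits, evalue_max = 0),
               class = "perox_config_error")
  expect_equal(nrow(assign_orthogroups(hits[0, ])), 0L)
})

test_that("the presence matrix covers every species-family cell with provenance", {
  panel <- mini_panel()
  assignments <- dplyr::bind_rows(
    assignment_row("spA", "spA|Pex3", "Pex3", 5),
    assignment_row("spA", "spA|Pex3b", "Pex3", 1.5),
    assignment_row("spA", "spA|Cat", "Cat", 1.2),
    assignment_row("spA", "spA|og", "OG0001", 3)
  )
  pm <- build_presence_matrix(assignments, panel, c("spA", "spB"),
                              background_ids = "OG0001")
  expect_equal(nrow(pm), 2L * nrow(panel))
  cell <- function(sp, fam) pm[pm$species_id == sp & pm$family_id == fam, ]
  expect_identical(cell("spA", "Pex3")$state, "present_high")
  # paralog provenance is pooled and sorted
  expect_identical(cell("spA", "Pex3")$protein_ids, "spA|Pex3,spA|Pex3b")
  expect_identical(cell("spA", "Cat")$state, "present_low")
  expect_identical(cell("spA", "Pex19")$state, "absent")
  expect_true(all(cell("spB", "Pex3")$state == "absent"))
  # background orthogroups are counted elsewhere, never matrix rows
  expect_false("OG0001" %in% pm$family_id)
  stray <- assignment_row("spA", "spA|x", "NotAFamily", 3)
  expect_error(build_presence_matrix(stray, panel, "spA"),
               class = "perox_config_error", regexp = "NotAFamily")
})

test_that("vetting verdicts override cells and are validated", {
  panel <- mini_panel()
  assignments <- dplyr::bind_rows(
    assignment_row("spA", "spA|Pex3", "Pex3", 5),
    assignment_row("spA", "spA|Cat", "Cat", 1.2)
  )
  pm <- build_presence_matrix(assignments, panel, "spA")
  vet <- tibble::tibble(
    species_id = "spA", family_id = c("Pex3", "Cat"),
    verdict = c("reject", "confirm")
  )
  out <- apply_vetting_overrides(pm, vet)
  expect_identical(out$state[out$family_id == "Pex3"], "absent")
  expect_identical(out$vetting[out$family_id == "Pex3"], "rejected_by_vetting")
  expect_identical(out$state[out$family_id == "Cat"], "present_high")
  expect_error(
    apply_vetting_overrides(pm, tibble::tibble(
      species_id = "spA", family_id = "Pex3", verdict = "maybe")),
    class = "perox_input_error")
  expect_error(
    apply_vetting_overrides(pm, tibble::tibble(
      species_id = "spZ", family_id = "Pex3", verdict = "reject")),
    class = "perox_input_error", regexp = "spZ")
  expect_identical(apply_vetting_overrides(pm, NULL)$state, pm$state)
})

test_that("loss verdicts follow the essential-peroxin rule", {
  panel <- mini_panel()
  species <- c("lost", "retained", "no_essential", "low_only")
  assignments <- dplyr::bind_rows(
    # retained: all three peroxins, Pex3 high
    assignment_row("retained", "retained|Pex3", "Pex3", 5),
    assignment_row("retained", "retained|Pex19", "Pex19", 1),
    assignment_row("retained", "retained|Pex5", "Pex5", 1),
    # no_essential: strong Pex5 but both essential markers absent
    assignment_row("no_essential", "ne|Pex5", "Pex5", 5),
    # low_only: everything present but only at low confidence
    assignment_row("low_only", "lo|Pex3", "Pex3", 1),
    assignment_row("low_only", "lo|Pex19", "Pex19", 1),
    assignment_row("low_only", "lo|Pex5", "Pex5", 1)
  )
  pm <- build_presence_matrix(assignments, panel, species)
  calls <- call_peroxisome_loss(pm, panel)
  verdict <- function(sp) calls$verdict[calls$species_id == sp]
  expect_identical(verdict("lost"), "peroxisomes_lost")
  expect_identical(verdict("retained"), "peroxisomes_retained")
  expect_identical(verdict("no_essential"), "indeterminate")
  expect_identical(verdict("low_only"), "indeterminate")
  lost_row <- calls[calls$species_id == "lost", ]
  expect_equal(lost_row$n_absent, 3L)
  # panel order (Pex3 before Pex19), as laid out by the presence grid
  expect_identical(lost_row$absent_peroxins, "Pex3,Pex19,Pex5")
  expect_identical(calls$low_confidence_cells[calls$species_id == "low_only"],
                   "Pex3,Pex19,Pex5")
})

test_that("an empty proteome is indeterminate, not a loss call", {
  panel <- mini_panel()
  pm <- build_presence_matrix(
    assignment_row("spA", "spA|Pex3", "Pex3", 5)[0, ], panel, c("empty", "lost"))
  sizes <- tibble::tibble(species_id = c("empty", "lost"), n_proteins = c(0L, 40L))
  calls <- call_peroxisome_loss(pm, panel, proteome_sizes = sizes)
  expect_identical(calls$verdict[calls$species_id == "empty"], "indeterminate")
  expect_identical(calls$verdict[calls$species_id == "lost"], "peroxisomes_lost")
  # a matrix that does not cover the panel peroxins is a configuration error
  expect_error(call_peroxisome_loss(pm[pm$family_id != "Pex5", ], panel),
               class = "perox_config_error", regexp = "Pex5")
})

test_that("enzyme localization pools signal flags across paralogs", {
  panel <- mini_panel()
  assignments <- dplyr::bind_rows(
    assignment_row("spA", "spA|Cat1", "Cat", 5),
    assignment_row("spA", "spA|Cat2", "Cat", 5),
    assignment_row("spA", "spA|Acaa1", "Acaa1", 5),
    assignment_row("spB", "spB|Cat1", "Cat", 5),
    assignment_row("spB", "spB|Cat2", "Cat", 5)
  )
  targeting <- tibble::tibble(
    protein_id = c("spA|Cat1", "spA|Cat2", "spA|Acaa1", "spB|Cat1", "spB|Cat2"),
    pts1 = c("SKL", NA, NA, NA, NA),
    pts2 = c(NA, NA, "RLAAVSAAHL", NA, NA),
    nterm = c("none", "mito", "none", "sec", "mito")
  )
  em <- build_enzyme_matrix(assignments, targeting, panel, c("spA", "spB"))
  cell <- function(sp, fam) em[em$species_id == sp & em$family_id == fam, ]
  # one paralog peroxisomal + one mitochondrial -> dual category
  expect_identical(cell("spA", "Cat")$category, "pts_mito")
  expect_identical(cell("spA", "Acaa1")$category, "pts")
  # sec + mito union is reachable only through paralog pooling
  expect_identical(cell("spB", "Cat")$category, "sec_mito")
  expect_identical(cell("spB", "Acaa1")$state, "absent")
  expect_identical(cell("spB", "Acaa1")$category, "none")
  expect_false(any(em$family_id %in% c("Pex3", "Pex19", "Pex5")))
  expect_error(
    build_enzyme_matrix(assignments, targeting[-1, ], panel, c("spA", "spB")),
    class = "perox_input_error", regexp = "spA\\|Cat1")
})

test_that("orthogroup complexity counts distinct families and ignores duplication", {
  assignments <- dplyr::bind_rows(
    assignment_row("spA", "spA|a", "Cat", 5),
    assignment_row("spA", "spA|b", "Cat", 5),   # second paralog, same family
    assignment_row("spA", "spA|c", "OG0001", 5),
    assignment_row("spB", "spB|a", "Cat", 5)
  )
  cx <- count_orthogroups(assignments, c("spA", "spB", "spC"))
  expect_identical(cx$n_unique_orthogroups, c(2L, 1L, 0L))
  # duplicating every assigned protein changes nothing
  dup <- dplyr::mutate(assignments, protein_id = paste0(protein_id, "_dup"))
  cx2 <- count_orthogroups(dplyr::bind_rows(assignments, dup),
                           c("spA", "spB", "spC"))
  expect_identical(cx2, cx)
})
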