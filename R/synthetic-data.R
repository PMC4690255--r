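# Synthetic cohort generator: marker families planted at controlled
# divergence, targeting signals planted per protein, designated loss species
# with zero peroxin homologs, and a machine-checkable ground truth.

PEROXIN_FAMILIES <- c(
  "Pex1", "Pex2", "Pex3", "Pex5", "Pex6", "Pex7", "Pex10", "Pex11",
  "Pex12", "Pex13", "Pex14", "Pex16", "Pex19", "Pex26"
)
ESSENTIAL_PEROXINS <- c("Pex3", "Pex19")

ENZYME_FAMILIES <- c(
  "Acox1", "Acox3", "Lbp", "Dbp", "Acaa1", "Scp2", "Amacr", "Crat", "Crot",
  "Ech1", "Decr", "Pec1", "Vlcs", "Pte1", "Pte2", "Phyh", "Hpcl2", "Gnpat",
  "Agps", "Far1", "Far2", "Agxt", "Pipox", "Cat", "Prdx5", "Dao", "Hao1",
  "Ephx2", "Gstk1", "Paox", "Xdh", "Uox", "Allc"
)

#' Specify a marker family
#'
#' @param family_id Short family label, e.g. `"Pex3"`.
#' @param marker_class One of `"peroxin"`, `"enzyme"`, `"background_og"`.
#' @param essential Logical; in the default panel true only for Pex3 and
#'   Pex19, the peroxins whose experimental loss abolishes the organelle.
#' @param n_seed_seqs Number of member sequences in the family alignment
#'   (at least 2).
#' @param seq_length Consensus length in residues.
#' @param divergence Per-site substitution probability in `[0, 0.5]` used
#'   when sampling members from the family consensus.
#' @return One-row tibble.
#' @export
marker_family_spec <- function(family_id,
                               marker_class = c("peroxin", "enzyme", "background_og"),
                               essential = FALSE,
                               n_seed_seqs = 8L,
                               seq_length = 150L,
                               divergence = 0.15) {
  marker_class <- match.arg(marker_class)
  if (!is.numeric(divergence) || divergence < 0 || divergence > 0.5) {
    perox_abort_config("`divergence` must lie in [0, 0.5].")
  }
  if (n_seed_seqs < 2) {
    perox_abort_config("`n_seed_seqs` must be at least 2.")
  }
  tibble::tibble(
    family_id = family_id, marker_class = marker_class,
    essential = essential, n_seed_seqs = as.integer(n_seed_seqs),
    seq_length = as.integer(seq_length), divergence = divergence
  )
}

#' Default marker panel: 14 peroxins and 33 enzyme families
#'
#' The peroxin panel is the 13-member core conserved across eukaryotes
#' (Pex1, 2, 3, 5, 6, 7, 10, 11, 12, 13, 14, 16, 19) plus Pex26; Pex3 and
#' Pex19 are flagged essential. The enzyme panel covers peroxisomal
#' beta-oxidation, ether-lipid synthesis, amino-acid and purine catabolism
#' and oxygen metabolism.
#'
#' @param n_seed_seqs,seq_length,divergence Per-family generator settings
#'   applied uniformly.
#' @return Tibble with one row per family (47 rows).
#' @export
default_marker_panel <- function(n_seed_seqs = 8L, seq_length = 150L,
                                 divergence = 0.15) {
  dplyr::bind_rows(
    purrr::map_dfr(PEROXIN_FAMILIES, function(f) {
      marker_family_spec(f, "peroxin", essential = f %in% ESSENTIAL_PEROXINS,
                         n_seed_seqs = n_seed_seqs, seq_length = seq_length,
                         divergence = divergence)
    }),
    purrr::map_dfr(ENZYME_FAMILIES, function(f) {
      marker_family_spec(f, "enzyme", essential = FALSE,
                         n_seed_seqs = n_seed_seqs, seq_length = seq_length,
                         divergence = divergence)
    })
  )
}

#' Background orthologous groups for complexity counting
#'
#' Families outside the peroxisomal panel, planted in every species, so the
#' unique-orthogroup complexity count has a shared baseline. They take part
#' in orthogroup counting but never in loss calling.
#'
#' @param n Number of background groups.
#' @inheritParams default_marker_panel
#' @return Tibble with one row per group.
#' @export
default_background_families <- function(n = 10L, n_seed_seqs = 8L,
                                        seq_length = 150L, divergence = 0.15) {
  purrr::map_dfr(sprintf("OG%04d", seq_len(n)), function(f) {
    marker_family_spec(f, "background_og", essential = FALSE,
                       n_seed_seqs = n_seed_seqs, seq_length = seq_length,
                       divergence = divergence)
  })
}

check_panel <- function(panel) {
  need <- c("family_id", "marker_class", "essential", "n_seed_seqs",
            "seq_length", "divergence")
  if (!all(need %in% names(panel))) {
    perox_abort_config("panel must contain the marker_family_spec() columns.")
  }
  if (anyDuplicated(panel$family_id)) {
    perox_abort_config("panel family_ids must be unique.")
  }
  invisible(panel)
}

# substitute each site independently with probability `divergence`, always
# to a *different* residue, so expected identity is exactly 1 - divergence
mutate_sequence <- function(sequence, divergence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < divergence
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA_ALPHABET20, a), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate one marker family (consensus plus aligned members)
#'
#' Draws an ungapped consensus and `n_seed_seqs` members, each derived from
#' the consensus by independent per-site substitution with probability
#' `divergence`. Members all have the consensus length, so they form a
#' gap-free alignment.
#'
#' @param spec One-row tibble from [marker_family_spec()].
#' @param seed Integer seed; identical spec and seed give byte-identical
#'   output.
#' @return List with `family_id`, `spec`, `consensus`, and `members`
#'   (named character vector, the aligned FASTA block).
#' @export
generate_marker_family <- function(spec, seed) {
  if (spec$divergence < 0 || spec$divergence > 0.5 || spec$n_seed_seqs < 2) {
    perox_abort_config("invalid marker family spec.")
  }
  withr::with_seed(seed, {
    consensus <- random_aa_sequence(spec$seq_length)
    members <- vapply(seq_len(spec$n_seed_seqs), function(i) {
      mutate_sequence(consensus, spec$divergence)
    }, character(1))
  })
  names(members) <- sprintf("%s_seed%02d", spec$family_id, seq_along(members))
  list(family_id = spec$family_id, spec = spec,
       consensus = consensus, members = members)
}

# deterministic mitochondrial-presequence-like 25-mer: rich in R/K and S/T,
# free of D/E, with run-breaking polar residues every 5th position so no
# 8-residue hydrophobic stretch can form even across the planting boundary
random_mito_nterm <- function() {
  res <- character(25)
  allowed <- c("R", "K", "S", "T", "Q", "N", "G", "A", "L", "P")
  breakers <- c("S", "T", "N", "Q")
  res[1] <- "M"
  res[2] <- sample(c("R", "K"), 1)
  res[3] <- sample(c("S", "T"), 1)
  res[7] <- sample(c("R", "K"), 1)
  res[8] <- sample(c("S", "T"), 1)
  res[12] <- sample(c("R", "K"), 1)
  for (p in c(5, 10, 15, 20, 25)) res[p] <- sample(breakers, 1)
  open <- which(res == "")
  res[open] <- sample(allowed, length(open), replace = TRUE)
  paste(res, collapse = "")
}

# deterministic signal-peptide-like 25-mer: a 12-residue hydrophobic core
# after a short polar n-region; position 25 breaks runs into what follows
random_sec_nterm <- function() {
  res <- character(25)
  res[1] <- "M"
  res[2:4] <- sample(c("S", "T", "Q", "N", "K", "R"), 3, replace = TRUE)
  res[5:16] <- sample(NTERM_HYDROPHOBIC, 12, replace = TRUE)
  res[17:24] <- sample(c("A", "G", "S", "T", "P", "Q"), 8, replace = TRUE)
  res[25] <- sample(c("S", "T", "N", "Q"), 1)
  paste(res, collapse = "")
}

random_pts2_motif <- function() {
  paste(vapply(PTS2_CLASSES, function(cls) {
    if (is.null(cls)) sample(AA_ALPHABET20, 1) else sample(cls, 1)
  }, character(1)), collapse = "")
}

#' Plant a targeting signal into a sequence
#'
#' `pts1` replaces the final three residues with an accepted PTS1
#' tripeptide; `pts2` writes a 10-mer matching the PTS2 pattern at a
#' position whose match lies entirely within residues 1--100; `mito` and
#' `sec` replace the first 25 residues with an N-terminus that the built-in
#' classifier deterministically calls `mito` or `sec`.
#'
#' @param sequence Protein sequence (at least 120 residues for `pts2`).
#' @param signal One of `"pts1"`, `"pts2"`, `"mito"`, `"sec"`.
#' @param start Optional 1-based PTS2 start; the match must end at or
#'   before residue 100, otherwise planting is refused.
#' @return The modified sequence.
#' @export
plant_targeting_signal <- function(sequence, signal = c("pts1", "pts2", "mito", "sec"),
                                   start = NULL) {
  signal <- match.arg(signal)
  n <- nchar(sequence)
  if (signal == "pts1") {
    if (n < 3) perox_abort_input("sequence too short to plant a PTS1 tripeptide.")
    motif <- sample(pts1_motif_set(), 1)
    return(paste0(substr(sequence, 1, n - 3), motif))
  }
  if (signal == "pts2") {
    if (n < 120) perox_abort_input("sequence must have >= 120 residues for PTS2 planting.")
    if (is.null(start)) start <- sample(2:91, 1)
    if (start < 1 || start + 9L > 100L) {
      perox_abort_input(sprintf(
        "PTS2 planting at start %d refused: the match must lie within residues 1-100.", start))
    }
    motif <- random_pts2_motif()
    return(paste0(substr(sequence, 1, start - 1), motif,
                  substr(sequence, start + 10L, n)))
  }
  # mito / sec
  if (n < 26) perox_abort_input("sequence too short to plant an N-terminal signal.")
  nterm <- if (signal == "mito") random_mito_nterm() else random_sec_nterm()
  paste0(nterm, substr(sequence, 26L, n))
}

#' Specify one synthetic species
#'
#' @param species_id Species label.
#' @param presence_plan Named character vector over family ids with values
#'   `"present"` or `"absent"`.
#' @param signal_plan Named list: planted protein id -> character vector of
#'   signals from `{"pts1", "pts2", "mito", "sec"}`.
#' @param n_decoys Number of random background proteins.
#' @param decoy_length_range Length-2 integer vector (min, max residues).
#' @return List of class `perox_species_spec`.
#' @export
species_spec <- function(species_id, presence_plan, signal_plan = list(),
                         n_decoys = 25L, decoy_length_range = c(80L, 240L)) {
  structure(
    list(species_id = species_id, presence_plan = presence_plan,
         signal_plan = signal_plan, n_decoys = as.integer(n_decoys),
         decoy_length_range = as.integer(decoy_length_range)),
    class = "perox_species_spec"
  )
}

planted_protein_id <- function(species_id, family_id) {
  paste0(species_id, "|", family_id)
}

scrub_decoy_cterm <- function(sequence) {
  accepted <- pts1_motif_set()
  n <- nchar(sequence)
  if (n < 3) return(sequence)
  while (substr(sequence, n - 2, n) %in% accepted) {
    sequence <- paste0(substr(sequence, 1, n - 3),
                       random_aa_sequence(3))
  }
  sequence
}

#' Generate a species proteome with ground truth
#'
#' Emits one protein per "present" family (sampled from the family consensus
#' at the family divergence, with signals planted per the signal plan) plus
#' `n_decoys` i.i.d. random background proteins. By default decoy C-termini
#' that happen to match the PTS1 motif set are resampled so planted truth is
#' unambiguous; disable with `scrub_decoy_motifs = FALSE` for
#' false-positive-rate studies.
#'
#' @param species A [species_spec()].
#' @param families Named list of generated families (from
#'   [generate_marker_family()]) covering every family in the presence plan.
#' @param seed Integer seed.
#' @param scrub_decoy_motifs Logical, default `TRUE`.
#' @return List with `proteome` (tibble: `species_id`, `protein_id`,
#'   `sequence`) and `truth` (tibble: `species_id`, `protein_id`,
#'   `family_id`, `signals`, `loss_species`).
#' @export
generate_proteome <- function(species, families, seed, scrub_decoy_motifs = TRUE) {
  present <- names(species$presence_plan)[species$presence_plan == "present"]
  missing <- setdiff(present, names(families))
  if (length(missing)) {
    perox_abort_config(paste0("families not generated: ", paste(missing, collapse = ", ")))
  }
  bad_keys <- setdiff(names(species$signal_plan),
                      planted_protein_id(species$species_id, present))
  if (length(bad_keys)) {
    perox_abort_config(paste0("signal_plan keys do not refer to planted proteins: ",
                              paste(bad_keys, collapse = ", ")))
  }
  peroxin_ids <- vapply(families, function(f) f$spec$marker_class, character(1))
  planned_peroxins <- names(species$presence_plan)[
    names(species$presence_plan) %in% names(peroxin_ids)[peroxin_ids == "peroxin"]]
  loss_species <- length(planned_peroxins) > 0 &&
    all(species$presence_plan[planned_peroxins] == "absent")

  withr::with_seed(seed, {
    rows <- purrr::map(present, function(fid) {
      fam <- families[[fid]]
      seqn <- mutate_sequence(fam$consensus, fam$spec$divergence)
      pid <- planted_protein_id(species$species_id, fid)
      signals <- species$signal_plan[[pid]] %||% character()
      # N-terminal plants first, then PTS2 clear of the N-terminal block,
      # then the C-terminal tripeptide
      for (s in intersect(c("mito", "sec"), signals)) {
        seqn <- plant_targeting_signal(seqn, s)
      }
      if ("pts2" %in% signals) {
        start <- if (any(c("mito", "sec") %in% signals)) sample(26:91, 1) else sample(2:91, 1)
        seqn <- plant_targeting_signal(seqn, "pts2", start = start)
      }
      if ("pts1" %in% signals) seqn <- plant_targeting_signal(seqn, "pts1")
      list(protein_id = pid, family_id = fid, sequence = seqn,
           signals = paste(sort(signals), collapse = ","))
    })
    decoys <- purrr::map(seq_len(species$n_decoys), function(i) {
      len <- sample(seq(species$decoy_length_range[1], species$decoy_length_range[2]), 1)
      seqn <- random_aa_sequence(len)
      if (scrub_decoy_motifs) seqn <- scrub_decoy_cterm(seqn)
      list(protein_id = sprintf("%s|decoy%03d", species$species_id, i),
           family_id = "decoy", sequence = seqn, signals = "")
    })
  })
  all_rows <- c(rows, decoys)
  proteome <- tibble::tibble(
    species_id = species$species_id,
    protein_id = purrr::map_chr(all_rows, "protein_id"),
    sequence = purrr::map_chr(all_rows, "sequence")
  )
  truth <- tibble::tibble(
    species_id = species$species_id,
    protein_id = purrr::map_chr(all_rows, "protein_id"),
    family_id = purrr::map_chr(all_rows, "family_id"),
    signals = purrr::map_chr(all_rows, "signals"),
    loss_species = loss_species
  )
  list(proteome = proteome, truth = truth)
}

# default per-enzyme signal plan for species retaining peroxisomes:
# most matrix enzymes carry a PTS1; thiolase-type and phytanoyl enzymes a
# PTS2; carnitine transferases and the racemase are dually targeted
default_enzyme_signals <- function() {
  sig <- stats::setNames(rep(list("pts1"), length(ENZYME_FAMILIES)), ENZYME_FAMILIES)
  sig[["Acaa1"]] <- "pts2"
  sig[["Phyh"]] <- "pts2"
  sig[["Crat"]] <- c("pts1", "mito")
  sig[["Crot"]] <- c("pts1", "mito")
  sig[["Amacr"]] <- c("pts1", "mito")
  sig
}

LOSS_RETAINED_ENZYMES <- c("Cat", "Gstk1", "Xdh", "Ephx2")

# enzymes retained by loss species carry no peroxisomal signal; catalase
# carries a secretory signal peptide instead
loss_species_signals <- function() {
  list(Cat = "sec", Gstk1 = character(), Xdh = character(), Ephx2 = character())
}

make_default_species <- function(species_id, panel, kind,
                                 n_decoys = 25L, decoy_length_range = c(80L, 240L)) {
  fams <- panel$family_id
  classes <- stats::setNames(panel$marker_class, panel$family_id)
  plan <- stats::setNames(rep("present", length(fams)), fams)
  sig_by_family <- list()
  if (kind == "full_loss") {
    plan[classes[fams] == "peroxin"] <- "absent"
    plan[classes[fams] == "enzyme" & !(fams %in% LOSS_RETAINED_ENZYMES)] <- "absent"
    sig_by_family <- loss_species_signals()
  } else {
    if (kind == "pex7_loss") plan[["Pex7"]] <- "absent"
    if (kind == "pex26_loss") plan[["Pex26"]] <- "absent"
    sig_by_family <- default_enzyme_signals()
  }
  present <- names(plan)[plan == "present"]
  signal_plan <- list()
  for (fid in intersect(names(sig_by_family), present)) {
    s <- sig_by_family[[fid]]
    if (length(s)) signal_plan[[planted_protein_id(species_id, fid)]] <- s
  }
  species_spec(species_id, plan, signal_plan,
               n_decoys = n_decoys, decoy_length_range = decoy_length_range)
}

#' Default cohort plan: 24 species, 6 full-loss
#'
#' Emulates the taxonomic structure of a metazoan screen: six species with
#' zero peroxins (flukes, tapeworms, a whipworm-like trichocephalid and an
#' appendicularian-like free-living tunicate), one species lacking only
#' Pex7, one lacking only Pex26, and sixteen species with the complete
#' panel.
#'
#' @param panel Marker panel including background groups (default:
#'   [default_marker_panel()] plus [default_background_families()]).
#' @param n_decoys,decoy_length_range Decoy settings per species.
#' @return List of [species_spec()] objects.
#' @export
default_cohort_specs <- function(panel = dplyr::bind_rows(default_marker_panel(),
                                                          default_background_families()),
                                 n_decoys = 25L,
                                 decoy_length_range = c(80L, 240L)) {
  check_panel(panel)
  full_loss <- c("fluke_A", "fluke_B", "tapeworm_A", "tapeworm_B",
                 "whipworm_A", "appendicularian_A")
  complete <- c("vertebrate_A", "vertebrate_B", "vertebrate_C", "ascidian_A",
                "ascidian_B", "annelid_A", "mollusc_A", "arthropod_B",
                "arthropod_C", "nematode_B", "cnidarian_A", "placozoan_A",
                "echinoderm_A", "hemichordate_A", "flatworm_A", "lancelet_A")
  c(
    purrr::map(full_loss, make_default_species, panel = panel, kind = "full_loss",
               n_decoys = n_decoys, decoy_length_range = decoy_length_range),
    list(make_default_species("nematode_A", panel, "pex7_loss",
                              n_decoys = n_decoys, decoy_length_range = decoy_length_range)),
    list(make_default_species("arthropod_A", panel, "pex26_loss",
                              n_decoys = n_decoys, decoy_length_range = decoy_length_range)),
    purrr::map(complete, make_default_species, panel = panel, kind = "complete",
               n_decoys = n_decoys, decoy_length_range = decoy_length_range)
  )
}

#' Generate a full synthetic cohort
#'
#' Generates every marker family and species proteome from per-stage
#' substreams of one seed; optionally writes the fixture set to disk
#' (one protein FASTA per species, one aligned FASTA per family, a
#' ground-truth TSV and a JSON panel config).
#'
#' @param specs List of [species_spec()] (default: [default_cohort_specs()]).
#' @param panel Marker panel tibble including background groups.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @param scrub_decoy_motifs Passed to [generate_proteome()].
#' @return A `perox_cohort`: list with `panel`, `families`, `proteomes`
#'   (one tibble), `truth`, `species` (tibble with per-species loss flag and
#'   planted orthogroup count), and `seed`.
#' @export
generate_cohort <- function(specs = default_cohort_specs(),
                            panel = dplyr::bind_rows(default_marker_panel(),
                                                     default_background_families()),
                            seed = 1L, out_dir = NULL,
                            scrub_decoy_motifs = TRUE) {
  check_panel(panel)
  families <- purrr::map(seq_len(nrow(panel)), function(i) {
    spec <- panel[i, ]
    generate_marker_family(spec, substream_seed(seed, paste0("family:", spec$family_id)))
  })
  names(families) <- panel$family_id

  gen <- purrr::map(specs, function(sp) {
    generate_proteome(sp, families, substream_seed(seed, paste0("proteome:", sp$species_id)),
                      scrub_decoy_motifs = scrub_decoy_motifs)
  })
  proteomes <- purrr::map_dfr(gen, "proteome")
  truth <- purrr::map_dfr(gen, "truth")
  species <- purrr::map_dfr(specs, function(sp) {
    tibble::tibble(
      species_id = sp$species_id,
      loss_species = any(truth$loss_species[truth$species_id == sp$species_id]) ||
        (length(sp$presence_plan) > 0 &&
           all(sp$presence_plan[names(sp$presence_plan) %in%
                                  panel$family_id[panel$marker_class == "peroxin"]] == "absent")),
      n_planted_orthogroups = sum(sp$presence_plan == "present"),
      n_proteins = sum(proteomes$species_id == sp$species_id)
    )
  })
  cohort <- structure(
    list(panel = panel, families = families, proteomes = proteomes,
         truth = truth, species = species, seed = seed),
    class = "perox_cohort"
  )
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.perox_cohort <- function(x, ...) {
  cat(sprintf("<perox_cohort> %d species, %d families (%d peroxins, %d enzymes, %d background), %d proteins\n",
              nrow(x$species), nrow(x$panel),
              sum(x$panel$marker_class == "peroxin"),
              sum(x$panel$marker_class == "enzyme"),
              sum(x$panel$marker_class == "background_og"),
              nrow(x$proteomes)))
  cat(sprintf("  planted loss species: %d\n", sum(x$species$loss_species)))
  invisible(x)
}

write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
}

#' Write a cohort fixture set to disk
#'
#' Layout: `proteomes/<species>.fasta` (60-column wrapped),
#' `families/<family>.aln.fasta`, `truth.tsv`, `panel.json`.
#'
#' @param cohort A `perox_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(dirname(out_dir))) {
    perox_abort_input(sprintf("parent directory does not exist: %s", dirname(out_dir)))
  }
  dir.create(out_dir, showWarnings = FALSE)
  dir.create(file.path(out_dir, "proteomes"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "families"), showWarnings = FALSE)
  for (sp in cohort$species$species_id) {
    rows <- cohort$proteomes[cohort$proteomes$species_id == sp, ]
    write_fasta(stats::setNames(rows$sequence, rows$protein_id),
                file.path(out_dir, "proteomes", paste0(sp, ".fasta")))
  }
  for (fam in cohort$families) {
    write_fasta(fam$members,
                file.path(out_dir, "families", paste0(fam$family_id, ".aln.fasta")))
  }
  readr::write_tsv(cohort$truth, file.path(out_dir, "truth.tsv"))
  jsonlite::write_json(cohort$panel, file.path(out_dir, "panel.json"),
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a cohort fixture set from disk
#'
#' Reads the layout written by [write_cohort()]. Family consensus sequences
#' are not stored on disk; the returned families carry only the alignment
#' members, which is all the screen needs.
#'
#' @param dir Cohort directory.
#' @return A `perox_cohort` (without per-family consensus or seed).
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) perox_abort_input(sprintf("cohort directory not found: %s", dir))
  panel_path <- file.path(dir, "panel.json")
  panel <- if (file.exists(panel_path)) {
    tibble::as_tibble(jsonlite::read_json(panel_path, simplifyVector = TRUE))
  } else {
    NULL
  }
  fam_files <- sort(list.files(file.path(dir, "families"), pattern = "\\.aln\\.fasta$",
                               full.names = TRUE))
  families <- purrr::map(fam_files, function(f) {
    id <- sub("\\.aln\\.fasta$", "", basename(f))
    aln <- Biostrings::readAAStringSet(f)
    spec_row <- if (!is.null(panel)) panel[panel$family_id == id, ] else NULL
    list(family_id = id, spec = spec_row, consensus = NULL,
         members = stats::setNames(as.character(aln), names(aln)))
  })
  names(families) <- vapply(families, `[[`, character(1), "family_id")
  prot_files <- sort(list.files(file.path(dir, "proteomes"), pattern = "\\.fasta$",
                                full.names = TRUE))
  proteomes <- purrr::map_dfr(prot_files, function(f) {
    sp <- sub("\\.fasta$", "", basename(f))
    seqs <- Biostrings::readAAStringSet(f)
    tibble::tibble(species_id = sp, protein_id = names(seqs),
                   sequence = unname(as.character(seqs)))
  })
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, show_col_types = FALSE,
                    col_types = readr::cols(signals = readr::col_character())) |>
      dplyr::mutate(signals = dplyr::coalesce(.data$signals, ""))
  } else {
    NULL
  }
  species <- tibble::tibble(
    species_id = sub("\\.fasta$", "", basename(prot_files)),
    n_proteins = vapply(sub("\\.fasta$", "", basename(prot_files)), function(sp) {
      sum(proteomes$species_id == sp)
    }, integer(1))
  )
  structure(
    list(panel = panel, families = families, proteomes = proteomes,
         truth = truth, species = species, seed = NULL),
    class = "perox_cohort"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
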