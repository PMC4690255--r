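# Peroxisomal targeting-signal scanners, N-terminal signal classification,
# and the eight-way localization category.

# PTS1 character classes and the enumerated non-conforming mammalian
# tripeptides accepted in addition to the class pattern.
PTS1_CLASS1 <- c("S", "A", "C")
PTS1_CLASS2 <- c("K", "R", "H", "N")
PTS1_CLASS3 <- c("L", "I", "M")
PTS1_EXCEPTIONS <- c("ASL", "THL", "LKL", "SKV", "KKL", "SQL", "PRL")

# PTS2 pattern: [RK][LVIQ]..[LVIHQ][LSGAK]..[HQ][LAF]; '.' matches any
# canonical residue or X, character classes never match X.
PTS2_CLASSES <- list(
  c("R", "K"),
  c("L", "V", "I", "Q"),
  NULL,
  NULL,
  c("L", "V", "I", "H", "Q"),
  c("L", "S", "G", "A", "K"),
  NULL,
  NULL,
  c("H", "Q"),
  c("L", "A", "F")
)
PTS2_DOT <- c(AA_ALPHABET20, "X")

#' The full set of accepted PTS1 tripeptides
#'
#' Expands the class pattern `[SAC][KRHN][LIM]` (36 tripeptides) and adds the
#' seven enumerated exceptions; the two sets do not overlap, giving 43
#' accepted C-terminal tripeptides.
#'
#' @return Character vector of accepted tripeptides.
#' @export
pts1_motif_set <- function() {
  grid <- expand.grid(a = PTS1_CLASS1, b = PTS1_CLASS2, c = PTS1_CLASS3,
                      stringsAsFactors = FALSE)
  class_set <- paste0(grid$a, grid$b, grid$c)
  unique(c(class_set, PTS1_EXCEPTIONS))
}

#' Scan C-termini for a PTS1 signal
#'
#' Examines only the final three residues of each sequence; a match is either
#' the class pattern `[SAC][KRHN][LIM]` or one of the seven enumerated
#' tripeptides (`ASL`, `THL`, `LKL`, `SKV`, `KKL`, `SQL`, `PRL`).
#' Matching is case-insensitive.
#'
#' @param sequences Character vector of protein sequences.
#' @return Character vector: the matched tripeptide, or `NA` where none.
#' @export
#' @examples
#' scan_pts1(c("MSTESKL", "MAAPRL", "MSKLG"))
scan_pts1 <- function(sequences) {
  up <- toupper(sequences)
  last3 <- ifelse(nchar(up) >= 3, substr(up, nchar(up) - 2, nchar(up)), NA_character_)
  hit <- !is.na(last3) &
    (grepl("^[SAC][KRHN][LIM]$", last3) | last3 %in% PTS1_EXCEPTIONS)
  ifelse(hit, last3, NA_character_)
}

pts2_regex <- function() {
  dot <- paste0("[", paste(PTS2_DOT, collapse = ""), "]")
  cls <- function(x) paste0("[", paste(x, collapse = ""), "]")
  paste0(
    cls(PTS2_CLASSES[[1]]), cls(PTS2_CLASSES[[2]]), dot, dot,
    cls(PTS2_CLASSES[[5]]), cls(PTS2_CLASSES[[6]]), dot, dot,
    cls(PTS2_CLASSES[[9]]), cls(PTS2_CLASSES[[10]])
  )
}

#' Scan N-proximal regions for a PTS2 signal
#'
#' Matches the 10-position pattern `[RK][LVIQ]..[LVIHQ][LSGAK]..[HQ][LAF]`
#' near the N-terminus. Under the default `rule = "contain"` the entire
#' match must lie within residues 1--100 (1-based, inclusive); under
#' `rule = "start"` only the match start must be at or before residue 100.
#' `.` matches any canonical residue or `X`; character classes never match
#' `X`. The leftmost qualifying window is reported.
#'
#' @param sequences Character vector of protein sequences.
#' @param rule Window rule, `"contain"` (default) or `"start"`.
#' @return A tibble with one row per input: `pts2` (matched 10-mer or `NA`)
#'   and `pts2_start` (1-based start or `NA`).
#' @export
#' @examples
#' scan_pts2(paste0("M", "RLAALSAAHL", strrep("G", 120)))
scan_pts2 <- function(sequences, rule = c("contain", "start")) {
  rule <- match.arg(rule)
  pat <- pts2_regex()
  res <- vapply(toupper(sequences), function(s) {
    n <- nchar(s)
    window_end <- if (rule == "contain") min(n, 100L) else min(n, 109L)
    region <- substr(s, 1L, window_end)
    m <- regexpr(pat, region)
    if (m > 0 && (rule == "contain" || m <= 100L)) {
      c(substr(region, m, m + 9L), as.character(m))
    } else {
      c(NA_character_, NA_character_)
    }
  }, character(2), USE.NAMES = FALSE)
  tibble::tibble(
    pts2 = res[1, ],
    pts2_start = as.integer(res[2, ])
  )
}

# residue sets used by the rule-based N-terminal classifier
NTERM_HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W", "C")

#' Rule-based N-terminal signal classifier
#'
#' A deterministic stand-in for machine-learned N-terminal predictors so
#' that synthetic cohorts are self-contained; real analyses should ingest
#' external predictions via [parse_nterm_predictions()]. Rules, checked in
#' order: `sec` iff residues 1--30 contain at least 8 consecutive residues
#' from `{A,I,L,M,F,V,W,C}`; otherwise `mito` iff residues 1--20 contain at
#' least 3 of `{R,K}`, at least 2 of `{S,T}` and none of `{D,E}`;
#' otherwise `none`.
#'
#' @param sequences Character vector of protein sequences.
#' @return Character vector in `{"mito", "sec", "none"}`.
#' @export
naive_nterm_classifier <- function(sequences) {
  up <- toupper(sequences)
  first30 <- substr(up, 1L, 30L)
  first20 <- substr(up, 1L, 20L)
  sec <- grepl(paste0("[", paste(NTERM_HYDROPHOBIC, collapse = ""), "]{8}"), first30)
  n_rk <- stringr::str_count(first20, "[RK]")
  n_st <- stringr::str_count(first20, "[ST]")
  n_de <- stringr::str_count(first20, "[DE]")
  mito <- !sec & n_rk >= 3 & n_st >= 2 & n_de == 0
  dplyr::case_when(sec ~ "sec", mito ~ "mito", .default = "none")
}

#' Parse external N-terminal targeting predictions
#'
#' Reads a two-column tab-separated table of `(protein_id, predicted_class)`
#' with classes `M`/`S`/`O` or `mito`/`sec`/`other` (as produced by
#' TargetP-style predictors) and normalizes to `{"mito", "sec", "none"}`.
#' Proteins absent from the table default to `none` downstream.
#'
#' @param input Path to a file, or a character vector of lines.
#' @return Tibble with columns `protein_id`, `nterm`.
#' @export
parse_nterm_predictions <- function(input) {
  lines <- if (length(input) == 1 && file.exists(input)) readLines(input) else input
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(protein_id = character(), nterm = character()))
  }
  map <- c(M = "mito", S = "sec", O = "none",
           mito = "mito", sec = "sec", other = "none")
  parts <- strsplit(lines, "[\t ]+")
  purrr::imap_dfr(parts, function(p, i) {
    if (length(p) < 2) {
      perox_abort_parse(sprintf("line %d: expected (protein_id, class), got %d field(s)", i, length(p)))
    }
    cls <- map[p[2]]
    if (is.na(cls)) {
      perox_abort_parse(sprintf("line %d: unknown class token '%s'", i, p[2]))
    }
    tibble::tibble(protein_id = p[1], nterm = unname(cls))
  })
}

LOCALIZATION_CATEGORIES <- c(
  "none", "pts", "mito", "sec", "pts_mito", "pts_sec", "sec_mito", "pts_mito_sec"
)

#' Collapse per-protein signal flags to a localization category
#'
#' The eight-way category used to color the enzyme matrix: `none`, `pts`
#' (PTS1 or PTS2), `mito`, `sec`, and the combinations `pts_mito`,
#' `pts_sec`, `sec_mito`, `pts_mito_sec`.
#'
#' @param pts1,pts2 Logical vectors (or character/match vectors where `NA`
#'   means absent) for the two peroxisomal signals.
#' @param nterm Character vector in `{"mito", "sec", "none"}`.
#' @return Character vector of categories.
#' @export
#' @examples
#' combine_localization(TRUE, FALSE, "mito")
combine_localization <- function(pts1, pts2, nterm) {
  as_flag <- function(x) if (is.logical(x)) x %in% TRUE else !is.na(x)
  pts <- as_flag(pts1) | as_flag(pts2)
  mito <- nterm == "mito"
  sec <- nterm == "sec"
  dplyr::case_when(
    pts & mito & sec ~ "pts_mito_sec",
    pts & mito ~ "pts_mito",
    pts & sec ~ "pts_sec",
    mito & sec ~ "sec_mito",
    pts ~ "pts",
    mito ~ "mito",
    sec ~ "sec",
    .default = "none"
  )
}

#' Targeting calls for a whole proteome
#'
#' Runs the PTS1 and PTS2 scanners on every protein and attaches an
#' N-terminal class, either ingested (preferred for real data) or from the
#' built-in rule-based classifier, then collapses the flags to one of the
#' eight localization categories.
#'
#' @param proteome Tibble with columns `protein_id`, `sequence` (a
#'   `species_id` column is carried through if present).
#' @param nterm_predictions Optional tibble from [parse_nterm_predictions()];
#'   proteins not listed default to `none`.
#' @param pts2_rule Passed to [scan_pts2()].
#' @return Tibble with columns `protein_id`, `pts1`, `pts2`, `pts2_start`,
#'   `nterm`, `nterm_source`, `category` (plus `species_id` if supplied).
#' @export
call_targeting <- function(proteome, nterm_predictions = NULL,
                           pts2_rule = c("contain", "start")) {
  pts2_rule <- match.arg(pts2_rule)
  out <- proteome |>
    dplyr::select(dplyr::any_of("species_id"), "protein_id", "sequence") |>
    dplyr::mutate(pts1 = scan_pts1(.data$sequence)) |>
    dplyr::bind_cols(scan_pts2(proteome$sequence, rule = pts2_rule))
  if (is.null(nterm_predictions)) {
    out$nterm <- naive_nterm_classifier(out$sequence)
    out$nterm_source <- "builtin"
  } else {
    idx <- match(out$protein_id, nterm_predictions$protein_id)
    out$nterm <- ifelse(is.na(idx), "none", nterm_predictions$nterm[idx])
    out$nterm_source <- "ingested"
  }
  out$category <- combine_localization(out$pts1, out$pts2, out$nterm)
  dplyr::select(out, -"sequence")
}
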