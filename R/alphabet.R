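# Amino-acid alphabet, sequence encoding, seeding and error helpers shared
# across the package.

#' The 20 canonical amino-acid one-letter codes
#'
#' Alphabet used throughout the package. Ambiguity codes are tolerated on
#' input: `X` (and any other non-canonical letter) is mapped to a neutral
#' index that scores zero in every profile column.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# index 21 = X / any non-canonical residue (neutral)
AA_X_INDEX <- 21L

#' Uniform background residue frequencies
#'
#' The default null model: each of the 20 canonical residues at 1/20.
#'
#' @return Named numeric vector over [AA_ALPHABET20] summing to 1.
#' @export
uniform_background <- function() {
  stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
}

check_background <- function(background) {
  if (!is.numeric(background) || is.null(names(background)) ||
      !setequal(names(background), AA_ALPHABET20)) {
    abort("`background` must be a named numeric vector over the 20 canonical residues.",
          class = "perox_config_error")
  }
  background <- background[AA_ALPHABET20]
  if (any(background <= 0)) {
    abort("`background` frequencies must be strictly positive.",
          class = "perox_config_error")
  }
  background / sum(background)
}

# Encode one sequence as integer indices 1..21 (21 = X / non-canonical).
aa_encode <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET20)
  idx[is.na(idx)] <- AA_X_INDEX
  idx
}

# Sample a random protein sequence from a background distribution.
random_aa_sequence <- function(length, background = uniform_background()) {
  paste(
    sample(AA_ALPHABET20, length, replace = TRUE, prob = background),
    collapse = ""
  )
}

#' Derive a stage-specific seed from a single run seed
#'
#' All randomness in the package flows from one run seed; each stage
#' (per-family generation, per-species proteome, per-profile calibration, ...)
#' draws from its own substream so stages are independently reproducible.
#' The derivation is a small deterministic integer hash of the stage label
#' mixed with the run seed, kept below 2^31.
#'
#' @param seed Integer run seed.
#' @param stage Character stage label, e.g. `"calibrate:Pex5"`.
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 17) %% 2147483629)
}

perox_abort_input <- function(msg) abort(msg, class = "perox_input_error")
perox_abort_config <- function(msg) abort(msg, class = "perox_config_error")
perox_abort_format <- function(msg) abort(msg, class = "perox_format_error")
perox_abort_parse <- function(msg) abort(msg, class = "perox_parse_error")
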