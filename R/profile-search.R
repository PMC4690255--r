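# Scoring profiles from marker alignments, Gumbel E-value calibration,
# proteome search, and HMMER3 domain-table ingestion.

GAP_CHARS <- c("-", ".")
EULER_GAMMA <- 0.57721566490153286

#' Build a scoring profile from a marker-family alignment
#'
#' Columns whose gap fraction exceeds 0.5 are dropped; each remaining column
#' holds per-residue log-odds in bits,
#' `log2((count_a + pseudocount * background_a) / (n + pseudocount) / background_a)`
#' where `n` is the number of non-gap residues in the column. The ambiguity
#' residue `X` (and any non-canonical letter) scores 0 in every column.
#'
#' @param alignment Named character vector of aligned sequences (equal
#'   lengths; gaps `-` or `.`), or an `AAStringSet`.
#' @param family_id Family label; defaults to the name attribute prefix.
#' @param pseudocount Positive pseudocount weight (default 1).
#' @param background Named residue frequency vector (default uniform).
#' @return A `perox_profile`: list with `family_id`, `mat` (21 x K log-odds
#'   matrix, row 21 the neutral X row), `kept_column_count`,
#'   `alignment_length`, and `calibration` (`NULL` until
#'   [calibrate_evalue()]).
#' @export
build_profile <- function(alignment, family_id = NULL, pseudocount = 1,
                          background = uniform_background()) {
  if (inherits(alignment, "XStringSet")) alignment <- as.character(alignment)
  if (length(alignment) < 2) {
    perox_abort_config("profile construction needs an alignment with >= 2 rows.")
  }
  if (length(unique(nchar(alignment))) != 1) {
    perox_abort_format("ragged alignment: rows have unequal lengths.")
  }
  if (pseudocount <= 0) perox_abort_config("`pseudocount` must be positive.")
  background <- check_background(background)
  if (is.null(family_id)) {
    family_id <- sub("_seed[0-9]+$", "", names(alignment)[1] %||% "profile")
  }
  chars <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  L <- ncol(chars)
  gap_frac <- colMeans(matrix(chars %in% GAP_CHARS, nrow = nrow(chars)))
  keep <- which(gap_frac <= 0.5)
  mat <- matrix(0, nrow = 21L, ncol = length(keep),
                dimnames = list(c(AA_ALPHABET20, "X"), NULL))
  for (j in seq_along(keep)) {
    col <- chars[, keep[j]]
    col <- col[col %in% AA_ALPHABET20]
    counts <- table(factor(col, levels = AA_ALPHABET20))
    n <- sum(counts)
    mat[1:20, j] <- log2(((as.numeric(counts) + pseudocount * background) /
                            (n + pseudocount)) / background)
  }
  structure(
    list(family_id = family_id, mat = mat,
         kept_column_count = length(keep), alignment_length = L,
         calibration = NULL),
    class = "perox_profile"
  )
}

#' @export
print.perox_profile <- function(x, ...) {
  cat(sprintf("<perox_profile> %s: %d columns kept of %d%s\n",
              x$family_id, x$kept_column_count, x$alignment_length,
              if (is.null(x$calibration)) " (uncalibrated)"
              else sprintf(" (Gumbel mu=%.2f, beta=%.2f)",
                           x$calibration$mu, x$calibration$beta)))
  invisible(x)
}

#' Score a sequence against a profile
#'
#' Returns the maximum, over all complete placements of the profile along
#' the sequence, of the summed column log-odds (bits). If the sequence is
#' shorter than the profile, the best partial-overlap placement covering at
#' least 50% of the profile columns is returned; `-Inf` if no placement
#' qualifies.
#'
#' @param profile A `perox_profile`.
#' @param sequence Protein sequence (non-empty).
#' @return Raw score in bits.
#' @export
score_sequence <- function(profile, sequence) {
  if (!nzchar(sequence)) perox_abort_input("cannot score an empty sequence.")
  sweep_score_cpp(profile$mat, aa_encode(sequence))
}

score_sequences <- function(profile, encoded_list) {
  sweep_scores_batch_cpp(profile$mat, encoded_list)
}

gumbel_moments_fit <- function(scores) {
  s <- stats::sd(scores)
  if (!is.finite(s) || s < 1e-9) {
    perox_abort_config("degenerate null-score variance; cannot calibrate.")
  }
  beta <- s * sqrt(6) / pi
  mu <- mean(scores) - EULER_GAMMA * beta
  list(mu = mu, beta = beta)
}

# Default null-length grid for a profile of L kept columns. The scoring
# rule changes regime at n = L (partial-overlap placements below, complete
# placements at and above), so the grid covers both regimes; interpolation
# never crosses the boundary.
default_length_grid <- function(L, null_length) {
  short <- if (L >= 4) c(ceiling(L / 2), round(0.75 * L), L - 1) else integer()
  long <- c(L, round(1.3 * L), round(1.7 * L), null_length)
  grid <- unique(sort(c(short[short >= 1], long)))
  grid[grid <= max(null_length, L)]
}

#' Calibrate a profile's empirical E-value model
#'
#' Scores `n_null` i.i.d. background sequences and fits a Gumbel law to the
#' raw scores by the method of moments (`beta = sd * sqrt(6) / pi`,
#' `mu = mean - gamma * beta`). Thereafter
#' `E(s) = database_size * (1 - exp(-exp(-(s - mu) / beta)))`.
#'
#' The null-score distribution depends on the query length: longer queries
#' offer more placements, and queries shorter than the profile align fewer
#' columns, which shifts the score location. The calibration therefore
#' repeats the fit on a grid of null lengths spanning the shortest
#' scoreable query (half the profile width) up to `null_length`; E-value
#' conversion interpolates the Gumbel location and scale at the query
#' length (clamped to the grid range). The fit at `null_length` itself is
#' stored as the profile's headline `mu`/`beta`.
#'
#' @param profile A `perox_profile`.
#' @param n_null Number of null sequences per grid length (>= 200).
#' @param null_length Reference null sequence length in residues.
#' @param seed Integer seed for the null sample.
#' @param background Residue frequencies for the null model.
#' @param length_grid Integer vector of null lengths; default spans
#'   0.5--1.7 profile widths plus `null_length`.
#' @return The profile with `calibration` set (`mu`, `beta`,
#'   `null_sample_size`, `null_length`, and the per-length `grid`).
#' @export
calibrate_evalue <- function(profile, n_null = 1000L, null_length = 300L,
                             seed = 1L, background = uniform_background(),
                             length_grid = NULL) {
  if (n_null < 200) perox_abort_config("`n_null` must be at least 200.")
  background <- check_background(background)
  L <- ncol(profile$mat)
  grid_lengths <- sort(unique(as.integer(
    c(length_grid %||% default_length_grid(L, null_length), null_length)
  )))
  fits <- purrr::map(seq_along(grid_lengths), function(gi) {
    len <- grid_lengths[gi]
    scores <- withr::with_seed(substream_seed(seed, paste0("null_len:", len)), {
      nulls <- lapply(seq_len(n_null), function(i) {
        as.integer(sample.int(20L, len, replace = TRUE, prob = background))
      })
      sweep_scores_batch_cpp(profile$mat, nulls)
    })
    gumbel_moments_fit(scores)
  })
  grid <- tibble::tibble(
    length = grid_lengths,
    mu = vapply(fits, `[[`, double(1), "mu"),
    beta = vapply(fits, `[[`, double(1), "beta")
  )
  ref <- grid[grid$length == null_length, ]
  profile$calibration <- list(
    mu = ref$mu[1], beta = ref$beta[1],
    null_sample_size = as.integer(n_null),
    null_length = as.integer(null_length),
    grid = grid
  )
  profile
}

# Interpolate Gumbel parameters at the query length, within the query's
# placement regime only (short: n < L, long: n >= L); lengths outside a
# regime's grid range are clamped to its nearest point.
interp_gumbel <- function(grid, query_length, profile_width) {
  interp_sub <- function(sub, n) {
    if (length(n) == 0) return(list(mu = double(), beta = double()))
    if (nrow(sub) == 1) {
      return(list(mu = rep(sub$mu, length(n)), beta = rep(sub$beta, length(n))))
    }
    n <- pmin(pmax(n, min(sub$length)), max(sub$length))
    list(mu = stats::approx(sub$length, sub$mu, xout = n, rule = 2)$y,
         beta = stats::approx(sub$length, sub$beta, xout = n, rule = 2)$y)
  }
  short_grid <- grid[grid$length < profile_width, ]
  long_grid <- grid[grid$length >= profile_width, ]
  is_short <- query_length < profile_width & nrow(short_grid) > 0
  mu <- beta <- numeric(length(query_length))
  sh <- interp_sub(short_grid, query_length[is_short])
  lo <- interp_sub(long_grid, query_length[!is_short])
  mu[is_short] <- sh$mu; beta[is_short] <- sh$beta
  mu[!is_short] <- lo$mu; beta[!is_short] <- lo$beta
  list(mu = mu, beta = beta)
}

#' E-value of a raw score under a calibrated profile
#'
#' @param profile A calibrated `perox_profile`.
#' @param score Raw score(s) in bits.
#' @param database_size Number of sequences searched (here: proteins in the
#'   species proteome).
#' @param query_length Optional query length(s); when given, the Gumbel
#'   parameters are interpolated from the calibration's length grid,
#'   otherwise the reference fit at `null_length` is used.
#' @return Expected number of chance hits at or above `score`.
#' @export
profile_evalue <- function(profile, score, database_size, query_length = NULL) {
  if (is.null(profile$calibration)) {
    perox_abort_config(sprintf("profile %s is not calibrated.", profile$family_id))
  }
  if (is.null(query_length) || is.null(profile$calibration$grid)) {
    mu <- profile$calibration$mu
    beta <- profile$calibration$beta
  } else {
    par <- interp_gumbel(profile$calibration$grid, query_length,
                         ncol(profile$mat))
    mu <- par$mu
    beta <- par$beta
  }
  z <- (score - mu) / beta
  database_size * (-expm1(-exp(-z)))
}

#' Search a proteome against a set of calibrated profiles
#'
#' Scores every protein against every profile and converts raw scores to
#' E-values with `database_size` equal to the number of proteins in the
#' species' proteome. One hit is reported per (protein, family) pair whose
#' E-value is at or below the reporting ceiling.
#'
#' @param profiles List of calibrated `perox_profile` objects.
#' @param proteome Tibble with `species_id`, `protein_id`, `sequence`.
#' @param evalue_ceiling Reporting ceiling (default 10).
#' @return Tibble of hits: `species_id`, `protein_id`, `family_id`,
#'   `raw_score`, `evalue`, `backend` (`"builtin"`).
#' @export
search_proteome <- function(profiles, proteome, evalue_ceiling = 10) {
  empty <- tibble::tibble(
    species_id = character(), protein_id = character(), family_id = character(),
    raw_score = double(), evalue = double(), backend = character()
  )
  if (nrow(proteome) == 0) return(empty)
  encoded <- lapply(proteome$sequence, aa_encode)
  qlen <- nchar(proteome$sequence)
  by_species <- split(seq_len(nrow(proteome)), proteome$species_id)
  out <- purrr::map_dfr(profiles, function(prof) {
    scores <- score_sequences(prof, encoded)
    purrr::map_dfr(by_species, function(rows) {
      db <- length(rows)
      ev <- profile_evalue(prof, scores[rows], db, query_length = qlen[rows])
      keep <- is.finite(scores[rows]) & ev <= evalue_ceiling
      tibble::tibble(
        species_id = proteome$species_id[rows][keep],
        protein_id = proteome$protein_id[rows][keep],
        family_id = prof$family_id,
        raw_score = scores[rows][keep],
        evalue = ev[keep],
        backend = "builtin"
      )
    })
  })
  if (nrow(out) == 0) empty else dplyr::arrange(out, .data$species_id, .data$protein_id, .data$evalue)
}

# documented column layout of HMMER3 --domtblout (22 fixed columns before
# the free-text description)
DOMTBL_MIN_FIELDS <- 22L

#' Parse HMMER3 per-domain tabular output
#'
#' Alternate search backend: ingests `--domtblout` text from a real HMMER3
#' run. Maps target name to `protein_id`, query name to `family_id`, the
#' independent (per-domain) E-value column to `evalue` and the domain bit
#' score to `raw_score`. Multiple domains for one (protein, family) pair
#' are all retained; downstream assignment uses the minimum E-value.
#'
#' @param input Path to a file, or a character vector of lines.
#' @param species_id Species label attached to every hit.
#' @return Tibble of hits with `backend = "domtbl"`.
#' @export
parse_domtbl <- function(input, species_id = NA_character_) {
  lines <- if (length(input) == 1 && file.exists(input)) readLines(input) else input
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- purrr::imap(lines, function(line, i) {
    if (!keep[i]) return(NULL)
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < DOMTBL_MIN_FIELDS) {
      perox_abort_parse(sprintf(
        "line %d: expected >= %d whitespace-delimited fields, got %d",
        i, DOMTBL_MIN_FIELDS, length(f)))
    }
    tibble::tibble(
      species_id = species_id,
      protein_id = f[1],
      family_id = f[4],
      raw_score = as.numeric(f[14]),
      evalue = as.numeric(f[13]),
      backend = "domtbl"
    )
  })
  out <- purrr::compact(rows)
  if (length(out) == 0) {
    return(tibble::tibble(
      species_id = character(), protein_id = character(), family_id = character(),
      raw_score = double(), evalue = double(), backend = character()
    ))
  }
  dplyr::bind_rows(out)
}

#' Format hits as HMMER3-style per-domain table text
#'
#' Writes the 22-column layout consumed by [parse_domtbl()] with full
#' numeric precision, so hits survive a write/parse round trip exactly.
#' Intended for tests and for exchanging built-in search results.
#'
#' @param hits Tibble of hits.
#' @return Character vector of lines (with a comment header).
#' @export
format_domtbl <- function(hits) {
  header <- c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  )
  body <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paste(
      h$protein_id, "-", "0", h$family_id, "-", "0",
      format(h$evalue, digits = 17), format(h$raw_score, digits = 17), "0.0",
      "1", "1",
      format(h$evalue, digits = 17), format(h$evalue, digits = 17),
      format(h$raw_score, digits = 17), "0.0",
      "1", "1", "1", "1", "1", "1", "0.99", "-"
    )
  }, character(1))
  c(header, body)
}
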