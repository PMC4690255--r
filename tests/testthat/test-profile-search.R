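test_that("profile log-odds match the hand-computed pseudocount formula", {
  aln <- c(s1 = "AC", s2 = "AC")
  prof <- build_profile(aln, family_id = "toy")
  bg <- 1 / 20
  observed <- log2(((2 + 1 * bg) / (2 + 1)) / bg)
  unobserved <- log2(((0 + 1 * bg) / (2 + 1)) / bg)
  expect_equal(unname(prof$mat["A", 1]), observed)
  expect_equal(unname(prof$mat["C", 2]), observed)
  expect_equal(unname(prof$mat["C", 1]), unobserved)
  expect_equal(unname(prof$mat["W", 2]), unobserved)
  # the ambiguity row is neutral everywhere
  expect_true(all(prof$mat["X", ] == 0))
  expect_equal(dim(prof$mat), c(21L, 2L))
})

test_that("majority-gap columns are dropped from the profile", {
  aln <- c(a = "A-CA", b = "A-CA", c = "A.-A", d = "AACG")
  # col 2 gap fraction 0.75 (dropped); cols 3 (0.25) and 4 (0) kept
  prof <- build_profile(aln, family_id = "gappy")
  expect_equal(prof$kept_column_count, 3L)
  expect_equal(prof$alignment_length, 4L)
  aln2 <- c(a = "A-", b = "A-", c = "AC", d = "AC")
  # gap fraction exactly 0.5 is kept
  expect_equal(build_profile(aln2)$kept_column_count, 2L)
})

test_that("profile construction validates its inputs", {
  expect_error(build_profile(c(only = "ACDE")), class = "perox_config_error")
  expect_error(build_profile(c(a = "ACDE", b = "ACD")), class = "perox_format_error")
  expect_error(build_profile(c(a = "ACDE", b = "ACDE"), pseudocount = 0),
               class = "perox_config_error")
  expect_error(score_sequence(build_profile(c(a = "ACDE", b = "ACDE")), ""),
               class = "perox_input_error")
})

test_that("the sweep scorer equals exhaustive placement enumeration at all lengths", {
  withr::with_seed(31L, {
    fam <- generate_marker_family(
      marker_family_spec("Osc", "background_og", seq_length = 12L), seed = 311L)
    prof <- build_profile(fam$members)
    L <- ncol(prof$mat)
    expect_equal(L, 12L)
    for (len in c(5L, 6L, 7L, 11L, 12L, 13L, 20L, 30L)) {
      for (r in 1:25) {
        s <- random_test_seq(len, alphabet = c(AA_ALPHABET20, "X"))
        expect_equal(score_sequence(prof, s), oracle_sweep_score(prof$mat, s),
                     info = sprintf("len=%d rep=%d", len, r))
      }
    }
    # below the 50%-overlap floor no placement qualifies
    short <- random_test_seq(5L)
    expect_identical(score_sequence(prof, short), oracle_sweep_score(prof$mat, short))
    expect_identical(score_sequence(prof, random_test_seq(4L)), -Inf)
  })
})

test_that("family members outscore their shuffles against the family profile", {
  withr::with_seed(32L, {
    for (s in 1:10) {
      fam <- generate_marker_family(
        marker_family_spec("Shuf", "enzyme", seq_length = 80L), seed = 5000L + s)
      prof <- build_profile(fam$members)
      member <- fam$members[[1]]
      shuffled <- paste(sample(strsplit(member, "")[[1]]), collapse = "")
      expect_gt(score_sequence(prof, member), score_sequence(prof, shuffled))
    }
  })
})

test_that("Gumbel calibration is deterministic and spans both placement regimes", {
  fam <- generate_marker_family(
    marker_family_spec("Cal", "enzyme", seq_length = 40L), seed = 41L)
  prof <- build_profile(fam$members)
  a <- calibrate_evalue(prof, n_null = 250L, null_length = 120L, seed = 9L)
  b <- calibrate_evalue(prof, n_null = 250L, null_length = 120L, seed = 9L)
  expect_identical(a$calibration, b$calibration)
  L <- ncol(prof$mat)
  expect_true(all(c(ceiling(L / 2), L, 120L) %in% a$calibration$grid$length))
  expect_true(all(a$calibration$grid$beta > 0))
  # the headline fit is the reference-length row of the grid
  ref <- a$calibration$grid[a$calibration$grid$length == 120L, ]
  expect_identical(a$calibration$mu, ref$mu)
  expect_identical(a$calibration$beta, ref$beta)
  expect_error(calibrate_evalue(prof, n_null = 100L), class = "perox_config_error")
})

test_that("a degenerate null-score distribution refuses to calibrate", {
  flat <- structure(
    list(family_id = "flat", mat = matrix(0, 21L, 10L),
         kept_column_count = 10L, alignment_length = 10L, calibration = NULL),
    class = "perox_profile"
  )
  expect_error(calibrate_evalue(flat, n_null = 250L, null_length = 50L),
               class = "perox_config_error")
})

test_that("the E-value at the Gumbel location equals (1 - 1/e) of the database size", {
  fam <- generate_marker_family(
    marker_family_spec("Ev", "enzyme", seq_length = 40L), seed = 42L)
  prof <- calibrate_evalue(build_profile(fam$members),
                           n_null = 250L, null_length = 120L, seed = 10L)
  N <- 5000
  expect_equal(profile_evalue(prof, prof$calibration$mu, N), (1 - exp(-1)) * N)
  # E is strictly decreasing in the score and bounded by the database size
  scores <- seq(prof$calibration$mu - 10, prof$calibration$mu + 30, length.out = 50)
  ev <- profile_evalue(prof, scores, N)
  expect_true(all(diff(ev) < 0))
  expect_true(all(ev > 0 & ev <= N))
  expect_lt(profile_evalue(prof, prof$calibration$mu + 40 * prof$calibration$beta, N),
            N * exp(-39))
  expect_error(profile_evalue(build_profile(fam$members), 1, N),
               class = "perox_config_error")
})

test_that("length-resolved E-values never interpolate across the placement boundary", {
  fam <- generate_marker_family(
    marker_family_spec("Len", "enzyme", seq_length = 40L), seed = 43L)
  prof <- calibrate_evalue(build_profile(fam$members),
                           n_null = 300L, null_length = 120L, seed = 11L)
  L <- ncol(prof$mat)
  grid <- prof$calibration$grid
  par <- peroxscreen:::interp_gumbel(grid, c(L - 1L, L), L)
  # at grid points the interpolated parameters equal the fitted ones
  expect_equal(par$mu[1], grid$mu[grid$length == L - 1L])
  expect_equal(par$mu[2], grid$mu[grid$length == L])
  # a query one residue short of the profile maximizes over many partial
  # placements while a full-width query has a single complete placement, so
  # the null location is strictly higher on the short side of the boundary
  expect_gt(par$mu[1], par$mu[2])
  s <- grid$mu[grid$length == L] + 5
  ev <- profile_evalue(prof, rep(s, 2), 100, query_length = c(L - 1L, L))
  expect_true(all(is.finite(ev)))
  # lengths outside the grid clamp to its edge instead of extrapolating
  par_lo <- peroxscreen:::interp_gumbel(grid, min(grid$length) - 5L, L)
  expect_equal(par_lo$mu, grid$mu[which.min(grid$length)])
})

test_that("proteome search reports calibrated hits per species database", {
  withr::with_seed(33L, {
    fams <- lapply(c("FamA", "FamB"), function(f) {
      generate_marker_family(marker_family_spec(f, "enzyme", seq_length = 40L),
                             seed = 600L + nchar(f) + utf8ToInt(substr(f, 4, 4)))
    })
    profs <- lapply(fams, function(f) {
      calibrate_evalue(build_profile(f$members), n_null = 250L,
                       null_length = 120L, seed = 12L)
    })
    proteome <- tibble::tibble(
      species_id = c("sp1", "sp1", "sp2"),
      protein_id = c("sp1|m", "sp1|d", "sp2|d"),
      sequence = c(fams[[1]]$members[[1]], random_test_seq(100), random_test_seq(100))
    )
    hits <- search_proteome(profs, proteome)
    expect_identical(names(hits),
                     c("species_id", "protein_id", "family_id", "raw_score",
                       "evalue", "backend"))
    expect_identical(unique(hits$backend), "builtin")
    top <- hits[hits$protein_id == "sp1|m", ]
    expect_identical(top$family_id[which.min(top$evalue)], "FamA")
    expect_lt(min(top$evalue), 1e-6)
    expect_true(all(hits$evalue <= 10))
    empty <- search_proteome(profs, proteome[0, ])
    expect_equal(nrow(empty), 0L)
  })
})

test_that("domain tables round-trip hits at full numeric precision", {
  hits <- tibble::tibble(
    species_id = "spX",
    protein_id = c("p1", "p1", "p2"),
    family_id = c("Pex5", "Pex7", "Pex5"),
    raw_score = c(123.45678901234567, 17.1, 0.125),
    evalue = c(1.2345678901234567e-8, 1e-300, 3.5e-2),
    backend = "builtin"
  )
  lines <- format_domtbl(hits)
  back <- parse_domtbl(lines, species_id = "spX")
  expect_identical(back$protein_id, hits$protein_id)
  expect_identical(back$family_id, hits$family_id)
  expect_identical(back$evalue, hits$evalue)
  expect_identical(back$raw_score, hits$raw_score)
  expect_identical(unique(back$backend), "domtbl")
})

test_that("domain-table parsing skips comments and flags malformed lines", {
  expect_equal(nrow(parse_domtbl(c("# a comment", "   ", "# another"))), 0L)
  good <- format_domtbl(tibble::tibble(
    species_id = "s", protein_id = "p1", family_id = "F",
    raw_score = 10, evalue = 1e-5, backend = "builtin"
  ))
  bad <- c(good, "p2 - 0 F - 0 too short")
  expect_error(parse_domtbl(bad), class = "perox_parse_error",
               regexp = sprintf("line %d", length(bad)))
  # several domains for one (protein, family) pair are all retained
  dup <- format_domtbl(tibble::tibble(
    species_id = "s", protein_id = "p1", family_id = c("F", "F"),
    raw_score = c(10, 8), evalue = c(1e-5, 1e-4), backend = "builtin"
  ))
  expect_equal(nrow(parse_domtbl(dup)), 2L)
})
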