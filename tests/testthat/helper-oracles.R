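# Independent brute-force oracles. These deliberately re-derive the
# scanning and scoring semantics from first principles (explicit set
# expansion, exhaustive placement enumeration) so they share no code with
# the implementations they check.

random_test_seq <- function(len, alphabet = peroxscreen::AA_ALPHABET20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exhaustive placement enumeration for the profile sweep
oracle_sweep_score <- function(mat, sequence) {
  alphabet <- c(peroxscreen::AA_ALPHABET20, "X")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet)
  idx[is.na(idx)] <- 21L
  L <- ncol(mat)
  n <- length(idx)
  if (n == 0 || L == 0) return(-Inf)
  best <- -Inf
  if (n >= L) {
    for (shift in 0:(n - L)) {
      s <- 0
      for (k in seq_len(L)) s <- s + mat[idx[k + shift], k]
      if (s > best) best <- s
    }
    return(unname(best))
  }
  min_overlap <- ceiling(L / 2)
  for (shift in (-(L - 1)):(n - 1)) {
    ks <- seq_len(L)
    pos <- ks + shift # 1-based sequence positions aligned to columns ks
    ok <- pos >= 1 & pos <= n
    if (sum(ok) < min_overlap) next
    s <- sum(mat[cbind(idx[pos[ok]], ks[ok])])
    if (s > best) best <- s
  }
  unname(best)
}

# PTS1 oracle: independent expansion of the accepted tripeptide set
oracle_pts1_set <- function() {
  out <- character()
  for (a in c("S", "A", "C")) {
    for (b in c("K", "R", "H", "N")) {
      for (c3 in c("L", "I", "M")) out <- c(out, paste0(a, b, c3))
    }
  }
  c(out, "ASL", "THL", "LKL", "SKV", "KKL", "SQL", "PRL")
}

oracle_scan_pts1 <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 3) return(NA_character_)
  tail3 <- substr(s, n - 2, n)
  if (tail3 %in% oracle_pts1_set()) tail3 else NA_character_
}

# PTS2 oracle: window-by-window membership test with explicit residue sets
oracle_scan_pts2 <- function(sequence, rule = "contain") {
  sets <- list(
    c("R", "K"), c("L", "V", "I", "Q"), NULL, NULL,
    c("L", "V", "I", "H", "Q"), c("L", "S", "G", "A", "K"), NULL, NULL,
    c("H", "Q"), c("L", "A", "F")
  )
  dot <- c(peroxscreen::AA_ALPHABET20, "X")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 10) return(list(match = NA_character_, start = NA_integer_))
  for (start in seq_len(n - 9)) {
    if (rule == "contain" && start + 9 > 100) break
    if (rule == "start" && start > 100) break
    ok <- TRUE
    for (k in 1:10) {
      r <- chars[start + k - 1]
      allowed <- if (is.null(sets[[k]])) dot else sets[[k]]
      if (!(r %in% allowed)) { ok <- FALSE; break }
    }
    if (ok) {
      return(list(match = paste(chars[start:(start + 9)], collapse = ""),
                  start = start))
    }
  }
  list(match = NA_character_, start = NA_integer_)
}
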