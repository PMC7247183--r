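# Shared fixtures and independent oracles used across the test files.

AA20 <- asrfam:::AA20

random_protein <- function(n, residues = AA20) {
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive affine-gap alignment oracle, DP-free: enumerates every monotone
# matching of residue pairs; unmatched stretches between/around matches are
# charged as contiguous affine gap runs (the arrangement the optimum uses).
bf_align_score <- function(a, b, S, gap_open, gap_ext, local = FALSE) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  m <- length(ca); n <- length(cb)
  gc <- function(L) if (L <= 0) 0 else gap_open + (L - 1) * gap_ext
  best <- if (local) 0 else gc(m) + gc(n)   # empty matching
  for (k in seq_len(min(m, n))) {
    As <- utils::combn(m, k, simplify = FALSE)
    Bs <- utils::combn(n, k, simplify = FALSE)
    for (A in As) for (B in Bs) {
      sc <- sum(S[cbind(ca[A], cb[B])])
      if (k >= 2) {
        sc <- sc + sum(vapply(diff(A) - 1, gc, 0)) +
          sum(vapply(diff(B) - 1, gc, 0))
      }
      if (!local)
        sc <- sc + gc(A[1] - 1) + gc(B[1] - 1) +
          gc(m - A[k]) + gc(n - B[k])
      if (sc > best) best <- sc
    }
  }
  best
}

# sharp consensus PWM over ACGT for planting/scanning tests
consensus_pwm <- function(consensus, name = "TF", match_p = 0.94) {
  letters <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - match_p) / 3, 4, length(cons),
              dimnames = list(letters, NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- match_p
  pwm_create(m, name = name,
             background = c(A = .25, C = .25, G = .25, T = .25))
}

# plant a word into a background sequence at a given offset (1-based)
plant_word <- function(seq, word, offset) {
  paste0(substr(seq, 1, offset - 1), word,
         substr(seq, offset + nchar(word), nchar(seq)))
}
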