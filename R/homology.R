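#' BLOSUM62 substitution matrix with affine gap penalties
#'
#' Wraps the published BLOSUM62 matrix (as shipped with Biostrings) together
#' with affine gap penalties and the gapped Karlin-Altschul parameters used
#' for E-values.
#'
#' @param gap_open Score added when a gap is opened (negative).
#' @param gap_ext Score added per additional gapped position (negative).
#' @return A substitution-matrix object: list with `scores` (integer matrix),
#'   `gap_open`, `gap_ext`, `lambda`, `K`.
#' @export
blosum62 <- function(gap_open = -11, gap_ext = -1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  S <- env$BLOSUM62
  stopifnot(gap_open < 0, gap_ext < 0)
  structure(list(scores = S, gap_open = gap_open, gap_ext = gap_ext,
                 lambda = BLOSUM62_GAPPED_LAMBDA, K = BLOSUM62_GAPPED_K),
            class = "subst_matrix")
}

#' Pairwise protein alignment with affine gaps (Gotoh)
#'
#' Local (Smith-Waterman) or global (Needleman-Wunsch) alignment by exact
#' dynamic programming with affine gap costs: a gap of length L costs
#' `gap_open + (L - 1) * gap_ext`. Traceback ties are resolved
#' diagonal > up > left, so results are reproducible. Identity is counted
#' over aligned columns with gap columns included in the denominator (local
#' alignments have no end gaps by construction). The E-value is
#' `K * m * n * exp(-lambda * score)` with the matrix's gapped
#' Karlin-Altschul parameters.
#'
#' @param a,b Protein sequences (single character strings; names used as
#'   ids when present).
#' @param matrix Substitution-matrix object from [blosum62()].
#' @param mode `"local"` or `"global"`.
#' @return A list with `query_id`, `subject_id`, `mode`, `score`,
#'   `aligned_a`, `aligned_b` (gapped strings), `aligned_cols`,
#'   `identities`, `identity_pct`, `evalue`.
#' @export
align_pair <- function(a, b, matrix = blosum62(),
                       mode = c("local", "global")) {
  mode <- match.arg(mode)
  qid <- if (!is.null(names(a))) names(a)[1] else NA_character_
  sid <- if (!is.null(names(b))) names(b)[1] else NA_character_
  a <- toupper(unname(a[[1]])); b <- toupper(unname(b[[1]]))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  S <- matrix$scores
  if (!all(ca %in% rownames(S)) || !all(cb %in% colnames(S)))
    stop("sequence contains residues absent from the substitution matrix ",
         "alphabet")
  C <- S[ca, cb, drop = FALSE]
  storage.mode(C) <- "double"
  dp <- affine_dp_cpp(C, matrix$gap_open, matrix$gap_ext, mode == "local")
  ai <- dp$a_idx; bi <- dp$b_idx
  aligned_a <- ifelse(ai > 0, ca[pmax(ai, 1)], "-")
  aligned_b <- ifelse(bi > 0, cb[pmax(bi, 1)], "-")
  idn <- sum(ai > 0 & bi > 0 & aligned_a == aligned_b)
  ncol_aln <- length(ai)
  ev <- matrix$K * length(ca) * length(cb) * exp(-matrix$lambda * dp$score)
  list(query_id = qid, subject_id = sid, mode = mode, score = dp$score,
       aligned_a = paste(aligned_a, collapse = ""),
       aligned_b = paste(aligned_b, collapse = ""),
       aligned_cols = ncol_aln, identities = idn,
       identity_pct = if (ncol_aln > 0) 100 * idn / ncol_aln else 0,
       evalue = ev)
}

#' Build a log-odds family profile from a seed alignment
#'
#' Columns with a gap fraction above `max_gap_frac` are dropped; per-column
#' residue frequencies get a flat pseudocount, and scores are log2 odds
#' against the background.
#'
#' @param seed_alignment Named character vector of aligned sequences (equal
#'   lengths, `-` gaps), at least two.
#' @param background Background residue frequencies over the 20 standard
#'   residues; defaults to uniform.
#' @param pseudocount Pseudocount added per residue per column.
#' @param max_gap_frac Columns with a larger gap fraction are dropped.
#' @return A family-profile object: list with `width`, `probs` and
#'   `log_odds` (20 x width matrices, rows named by residue), `background`,
#'   `consensus`, `pseudocount`.
#' @export
build_profile <- function(seed_alignment, background = NULL,
                          pseudocount = 0.1, max_gap_frac = 0.5) {
  if (length(seed_alignment) < 2L)
    stop("a family profile needs at least 2 seed sequences")
  lens <- nchar(seed_alignment)
  if (length(unique(lens)) != 1L)
    stop("ragged seed alignment: sequence lengths differ")
  if (is.null(background)) {
    background <- rep(1 / 20, 20)
    names(background) <- AA20
  }
  background <- background[AA20]
  rows <- do.call(rbind, strsplit(toupper(seed_alignment), "", fixed = TRUE))
  gap_frac <- colMeans(rows == "-" | rows == ".")
  keep <- which(gap_frac <= max_gap_frac)
  if (length(keep) == 0L) stop("all columns are gap-dominated")
  rows <- rows[, keep, drop = FALSE]
  probs <- vapply(seq_len(ncol(rows)), function(j) {
    cnt <- table(factor(rows[, j], levels = AA20)) + pseudocount
    as.numeric(cnt / sum(cnt))
  }, numeric(20))
  rownames(probs) <- AA20
  log_odds <- log2(probs / background)
  consensus <- paste(AA20[apply(probs, 2, which.max)], collapse = "")
  structure(list(width = ncol(probs), probs = probs, log_odds = log_odds,
                 background = background, consensus = consensus,
                 pseudocount = pseudocount),
            class = "family_profile")
}

#' Score a proteome against a family profile and call members
#'
#' Each protein is aligned to the profile by affine-gap local alignment of
#' its residues against the per-column log2-odds scores. Hits are kept when
#' the E-value (`width * n * 2^-score`) is at or below `evalue_max` and the
#' matched span covers at least `min_span_frac` of the profile width (the
#' domain-completeness rule). Proteins with byte-identical sequences are
#' collapsed to a single row whose representative is the lexicographically
#' smallest id; all member ids are retained.
#'
#' @param proteome Named character vector of protein sequences.
#' @param profile Family profile from [build_profile()].
#' @param evalue_max Maximum E-value for membership.
#' @param min_span_frac Minimum fraction of profile columns covered.
#' @param gap_open,gap_ext Affine gap penalties in bits.
#' @return A hit-table data frame: `protein_id`, `members`, `n_members`,
#'   `profile_score`, `evalue`, `span_start`, `span_end`, `span_frac`,
#'   `kept`, `reason`.
#' @export
identify_family <- function(proteome, profile, evalue_max = 1e-10,
                            min_span_frac = 0.8,
                            gap_open = -10, gap_ext = -1) {
  if (length(proteome) == 0L) stop("empty proteome")
  if (is.null(names(proteome))) stop("proteome sequences must be named")
  seqs <- toupper(proteome)
  groups <- split(names(seqs), unname(seqs))
  reps <- vapply(groups, function(ids) sort(ids)[1], "")
  ord <- order(match(reps, names(seqs)))
  groups <- groups[ord]; reps <- reps[ord]
  uniq <- names(groups)  # the unique sequences themselves

  LO <- profile$log_odds
  rows <- lapply(seq_along(uniq), function(i) {
    chars <- strsplit(uniq[i], "", fixed = TRUE)[[1]]
    chars[!chars %in% AA20] <- NA
    C <- matrix(0, nrow = profile$width, ncol = length(chars))
    ok <- !is.na(chars)
    C[, ok] <- t(LO)[, chars[ok], drop = FALSE]
    # non-standard residues score the column minimum (mildly penalized)
    if (any(!ok)) C[, !ok] <- matrix(apply(LO, 2, min),
                                     nrow = profile$width,
                                     ncol = sum(!ok))
    dp <- affine_dp_cpp(C, gap_open, gap_ext, TRUE)
    prof_cols <- dp$a_idx[dp$a_idx > 0]
    span <- if (length(prof_cols) > 0)
      c(min(prof_cols), max(prof_cols)) else c(NA_real_, NA_real_)
    span_frac <- if (length(prof_cols) > 0)
      (span[2] - span[1] + 1) / profile$width else 0
    ev <- profile$width * length(chars) * 2^(-dp$score)
    data.frame(protein_id = reps[i],
               members = paste(sort(groups[[i]]), collapse = ","),
               n_members = length(groups[[i]]),
               profile_score = dp$score, evalue = ev,
               span_start = span[1], span_end = span[2],
               span_frac = span_frac, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  pass_e <- hits$evalue <= evalue_max
  pass_span <- hits$span_frac >= min_span_frac
  hits$kept <- pass_e & pass_span
  hits$reason <- ifelse(hits$kept, "ok",
                        ifelse(!pass_e, "evalue above threshold",
                               "incomplete domain"))
  hits[order(hits$evalue), , drop = FALSE]
}
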