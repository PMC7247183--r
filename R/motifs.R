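#' Construct a position weight matrix object
#'
#' @param probs Probability matrix, rows = alphabet letters (named), columns
#'   = positions; columns must sum to 1.
#' @param name Motif name.
#' @param background Background letter frequencies (defaults to uniform).
#' @param pseudocount Pseudocount that was applied (recorded).
#' @return A `pwm` object: list with `name`, `alphabet` (`"dna"` or
#'   `"protein"`), `width`, `probs`, `background`, `log_odds` (log2),
#'   `pseudocount`.
#' @export
pwm_create <- function(probs, name = "motif", background = NULL,
                       pseudocount = 0) {
  stopifnot(is.matrix(probs), !is.null(rownames(probs)))
  alphabet <- if (all(rownames(probs) %in% c("A", "C", "G", "T")) &&
                  nrow(probs) == 4L) "dna" else "protein"
  if (any(abs(colSums(probs) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  if (is.null(background)) {
    background <- rep(1 / nrow(probs), nrow(probs))
    names(background) <- rownames(probs)
  }
  background <- background[rownames(probs)]
  p <- pmax(probs, 1e-9)
  structure(list(name = name, alphabet = alphabet, width = ncol(probs),
                 probs = probs, background = background,
                 log_odds = log2(p / background),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Consensus string of a PWM
#' @param pwm A `pwm` object.
#' @return Character string of per-column most probable letters.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$probs)[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Reverse complement of a DNA PWM
#' @param pwm A DNA `pwm` object.
#' @return A `pwm` object for the opposite strand.
#' @export
pwm_revcomp <- function(pwm) {
  stopifnot(pwm$alphabet == "dna")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  p <- pwm$probs[comp[rownames(pwm$probs)], rev(seq_len(pwm$width)),
                 drop = FALSE]
  rownames(p) <- names(comp)[match(rownames(p), comp)]
  p <- p[c("A", "C", "G", "T"), , drop = FALSE]
  pwm_create(p, name = pwm$name, background = pwm$background,
             pseudocount = pwm$pseudocount)
}

#' Read motifs from a JASPAR-style PFM file
#'
#' Accepts the 4-line `A|C|G|T [counts]` blocks preceded by a `>` header.
#' Counts are converted to probabilities with the given pseudocount.
#'
#' @param path File path.
#' @param pseudocount Added per cell before normalization.
#' @return List of `pwm` objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no JASPAR records in ", path)
  out <- lapply(seq_along(heads), function(i) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    rows <- lapply(block, function(l) {
      m <- regmatches(l, regexec("^([ACGT])\\s*\\[?([0-9. \t]+)\\]?", l))[[1]]
      if (length(m) != 3L) stop("malformed JASPAR matrix line: ", l)
      list(base = m[2], counts = as.numeric(strsplit(trimws(m[3]),
                                                     "\\s+")[[1]]))
    })
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(counts) <- vapply(rows, `[[`, "", "base")
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE] + pseudocount
    probs <- sweep(counts, 2, colSums(counts), "/")
    nm <- sub("^>\\s*", "", lines[heads[i]])
    nm <- strsplit(nm, "\\s+")[[1]]
    pwm_create(probs, name = nm[length(nm)], pseudocount = pseudocount)
  })
  out
}

#' Write motifs as a JASPAR-style PFM file
#'
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @param scale Counts written as `probs * scale`.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path, scale = 100) {
  con <- file(path, "wb"); on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    for (b in rownames(p$probs))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(round(p$probs[b, ] * scale, 2)),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' Read motifs in MEME minimal text format
#' @param path File path.
#' @return List of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  heads <- grep("^MOTIF", lines)
  if (length(heads) == 0L) stop("no MOTIF records in ", path)
  bg <- NULL
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) > 0L) {
    toks <- strsplit(trimws(lines[bgl[1] + 1L]), "\\s+")[[1]]
    bg <- as.numeric(toks[seq(2, length(toks), 2)])
    names(bg) <- toks[seq(1, length(toks), 2)]
  }
  lapply(heads, function(h) {
    nm <- strsplit(trimws(lines[h]), "\\s+")[[1]][2]
    li <- grep("^letter-probability matrix", lines[h:length(lines)])[1] +
      h - 1L
    w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[li]))
    alen <- as.integer(sub(".*alength=\\s*([0-9]+).*", "\\1", lines[li]))
    rows <- lines[(li + 1L):(li + w)]
    m <- t(vapply(rows, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]), numeric(alen)))
    letters <- if (alen == 4L) c("A", "C", "G", "T") else AA20
    probs <- t(m)
    dimnames(probs) <- list(letters, NULL)
    probs <- sweep(probs, 2, colSums(probs), "/")
    pwm_create(probs, name = nm,
               background = if (!is.null(bg)) bg[letters] else NULL)
  })
}

#' Write motifs in MEME minimal text format
#' @param pwms List of `pwm` objects (common alphabet).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "wb"); on.exit(close(con))
  letters <- rownames(pwms[[1]]$probs)
  writeLines(c("MEME version 4", "",
               sprintf("ALPHABET= %s", paste(letters, collapse = "")), "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", letters,
                             pwms[[1]]$background[letters]),
                     collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= %d w= %d nsites= 0 E= 0",
      nrow(p$probs), p$width), con)
    for (j in seq_len(p$width))
      writeLines(paste(sprintf("%.6f", p$probs[, j]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Extract promoter sequences upstream of gene starts
#'
#' For plus-strand genes the promoter is the `length` bases immediately
#' upstream of the gene start; for minus-strand genes, the reverse
#' complement of the `length` bases downstream of the gene end, so planted
#' sites read forward in the extracted sequence. Promoters are truncated at
#' contig edges with the realized length recorded. Genes with unknown
#' strand are treated as plus strand.
#'
#' @param genome Named character vector of contig sequences.
#' @param loci Locus data frame.
#' @param length Promoter length in bp.
#' @return Data frame `gene_id`, `seq`, `length`, `truncated`, `strand`.
#' @export
extract_promoters <- function(genome, loci, length = 2000L) {
  missing_chr <- setdiff(unique(loci$chromosome), names(genome))
  if (length(missing_chr) > 0L)
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  out <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    contig <- genome[[l$chromosome]]
    clen <- nchar(contig)
    if (identical(l$strand, "-")) {
      from <- l$end_bp + 1; to <- min(clen, l$end_bp + length)
      s <- if (from > to) "" else revcomp(substr(contig, from, to))
    } else {
      from <- max(1, l$start_bp - length); to <- l$start_bp - 1
      s <- if (from > to) "" else substr(contig, from, to)
    }
    data.frame(gene_id = l$gene_id, seq = s, length = nchar(s),
               truncated = nchar(s) < length,
               strand = l$strand, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' De novo motif discovery by ZOOPS expectation-maximization
#'
#' MEME-style discovery under the zero-or-one-occurrence-per-sequence
#' model. For each candidate width (coarse grid over `width_range`, then
#' refinement around the best), EM is started from the most enriched exact
#' word and iterated until the log-likelihood converges; the log-likelihood
#' is non-decreasing by construction and asserted each run. Width selection
#' and the stopping rule use a BIC-penalized log-likelihood-ratio against
#' the background-only model. After a motif is accepted its sites are
#' masked and discovery repeats, so no two motifs claim overlapping sites.
#'
#' @param seqs Named character vector of protein sequences (>= 2).
#' @param max_motifs Maximum number of motifs to report.
#' @param width_range Motif width bounds (inclusive).
#' @param seed Integer seed (EM initialization is deterministic but the
#'   seed also fixes any downstream use).
#' @param grid_step Coarse width-grid step.
#' @return List of motif models, each with `pwm`, `consensus`, `width`,
#'   `sites` (data frame `sequence_id`, `offset` 1-based), `log_lik`,
#'   `llr`, `bic_score`.
#' @export
discover_motifs <- function(seqs, max_motifs = 20L, width_range = c(6L, 50L),
                            seed = 1L, grid_step = 4L) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  max_len <- max(nchar(seqs))
  if (width_range[1] < 2L || width_range[1] > max_len)
    stop("width_range outside [2, sequence length]")
  width_range[2] <- min(width_range[2], max_len)
  enc <- lapply(toupper(seqs), function(s)
    match(strsplit(s, "", fixed = TRUE)[[1]], AA20))
  bg <- table(factor(AA20[unlist(enc)], levels = AA20))
  bg <- as.numeric(bg + 1) / sum(bg + 1)
  names(bg) <- AA20

  motifs <- list()
  local_seed(seed, {
    for (m in seq_len(max_motifs)) {
      widths <- unique(pmin(seq(width_range[1], width_range[2],
                                by = grid_step), width_range[2]))
      fits <- lapply(widths, function(w) zoops_em(enc, w, bg))
      scores <- vapply(fits, function(f)
        if (is.null(f)) -Inf else f$bic_score, 0)
      if (all(!is.finite(scores))) break
      bw <- widths[which.max(scores)]
      refine <- setdiff(intersect(c(bw - 2L, bw - 1L, bw + 1L, bw + 2L),
                                  width_range[1]:width_range[2]), widths)
      fits2 <- lapply(refine, function(w) zoops_em(enc, w, bg))
      all_fits <- c(fits, fits2)
      all_w <- c(widths, refine)
      sc <- vapply(all_fits, function(f)
        if (is.null(f)) -Inf else f$bic_score, 0)
      best <- all_fits[[which.max(sc)]]
      if (is.null(best) || best$bic_score <= 0) break
      motifs[[length(motifs) + 1L]] <- best
      # mask accepted sites
      for (r in seq_len(nrow(best$sites))) {
        sid <- best$sites$sequence_id[r]; off <- best$sites$offset[r]
        enc[[sid]][off:(off + best$width - 1L)] <- NA
      }
    }
  })
  lapply(motifs, function(f) {
    f$sites$sequence_id <- names(seqs)[f$sites$sequence_id]
    f
  })
}

# ZOOPS EM for one width; enc = list of integer vectors (NA = masked).
# Returns NULL when no valid start exists.
zoops_em <- function(enc, w, bg, max_iter = 100L, tol = 1e-6,
                     pseudocount = 0.1) {
  lbg <- log(bg)
  # valid windows: no NA inside
  valid <- lapply(enc, function(x) {
    m <- length(x) - w + 1L
    if (m < 1L) return(integer(0))
    bad <- is.na(x)
    if (!any(bad)) return(seq_len(m))
    cs <- cumsum(bad)
    starts <- seq_len(m)
    starts[(cs[starts + w - 1L] - c(0, cs)[starts]) == 0]
  })
  n_windows <- sum(lengths(valid))
  if (n_windows < 2L) return(NULL)

  # init from the most frequent exact word (ties: lexicographic)
  words <- unlist(lapply(seq_along(enc), function(i) {
    if (length(valid[[i]]) == 0L) return(character(0))
    vapply(valid[[i]], function(j)
      paste(AA20[enc[[i]][j:(j + w - 1L)]], collapse = ""), "")
  }))
  tab <- sort(table(words), decreasing = TRUE)
  top <- names(tab)[tab == tab[1]]
  seed_word <- match(strsplit(sort(top)[1], "", fixed = TRUE)[[1]], AA20)
  probs <- matrix(rep(bg, w) * 0.4, nrow = 20, ncol = w)
  for (t in seq_len(w)) probs[seed_word[t], t] <-
      probs[seed_word[t], t] + 0.6
  probs <- sweep(probs, 2, colSums(probs), "/")
  gamma <- 0.5

  bg_ll <- sum(vapply(enc, function(x) sum(lbg[x[!is.na(x)]]), 0))
  prev_obj <- -Inf
  prev_ll <- -Inf
  ll <- NA_real_
  z <- NULL
  for (iter in seq_len(max_iter)) {
    lodds <- log(probs) - lbg     # 20 x w
    # E-step
    z <- vector("list", length(enc))
    ll <- bg_ll
    for (i in seq_along(enc)) {
      vj <- valid[[i]]
      if (length(vj) == 0L) { z[[i]] <- numeric(0); next }
      s <- numeric(length(vj))
      x <- enc[[i]]
      for (t in seq_len(w)) s <- s + lodds[cbind(x[vj + t - 1L], t)]
      u <- exp(s) * (gamma / length(vj))
      denom <- (1 - gamma) + sum(u)
      z[[i]] <- u / denom
      ll <- ll + log(denom)
    }
    # with pseudocounts the M-step maximizes the Dirichlet-penalized
    # objective, which is the quantity guaranteed non-decreasing
    obj <- ll + pseudocount * sum(log(probs))
    if (obj < prev_obj - 1e-6 * max(1, abs(prev_obj)))
      stop("EM penalized objective decreased (", prev_obj, " -> ", obj, ")")
    if (is.finite(prev_ll) && abs(ll - prev_ll) < tol) break
    prev_obj <- obj
    prev_ll <- ll
    # M-step
    cnt <- matrix(pseudocount, 20, w)
    tot_z <- 0
    for (i in seq_along(enc)) {
      vj <- valid[[i]]
      if (length(vj) == 0L) next
      zi <- z[[i]]; x <- enc[[i]]
      tot_z <- tot_z + sum(zi)
      for (t in seq_len(w)) {
        res <- x[vj + t - 1L]
        cnt[, t] <- cnt[, t] + vapply(1:20, function(a)
          sum(zi[res == a]), 0)
      }
    }
    probs <- sweep(cnt, 2, colSums(cnt), "/")
    gamma <- min(0.99, max(1e-4, tot_z / length(enc)))
  }
  # MAP sites: at most one per sequence, total site posterior > 0.5
  sites <- do.call(rbind, lapply(seq_along(enc), function(i) {
    if (length(z[[i]]) == 0L || sum(z[[i]]) <= 0.5) return(NULL)
    j <- which.max(z[[i]])
    data.frame(sequence_id = i, offset = valid[[i]][j],
               posterior = z[[i]][j])
  }))
  if (is.null(sites)) sites <- data.frame(sequence_id = integer(0),
                                          offset = integer(0),
                                          posterior = numeric(0))
  llr <- ll - bg_ll
  # ZOOPS: each sequence contributes at most one site observation, so the
  # BIC sample size is the number of sequences, not the window count
  bic <- llr - 0.5 * (19 * w + 1) * log(length(enc))
  rownames(probs) <- AA20
  list(pwm = pwm_create(probs, name = sprintf("motif_w%d", w),
                        background = bg),
       consensus = paste(AA20[apply(probs, 2, which.max)], collapse = ""),
       width = w, sites = sites, log_lik = ll, llr = llr, bic_score = bic,
       gamma = gamma)
}

#' Scan promoters with PWMs on both strands, with exact p-values
#'
#' Every window on the forward and reverse strand is scored by log2 odds.
#' Score p-values under the background are exact: per-column score
#' distributions (scores discretized to `1/granularity` units) are combined
#' by dynamic-programming convolution, and a window is a hit when
#' `P(score >= observed) <= p_max`.
#'
#' @param promoters Promoter data frame from [extract_promoters()].
#' @param pwms List of DNA `pwm` objects.
#' @param p_max Per-window p-value threshold.
#' @param granularity Score discretization unit (log2-odds units).
#' @return List with `hits` (data frame `gene_id`, `tf_name`, `position`
#'   (1-based window start on the promoter), `strand`, `score`, `p_value`)
#'   and `counts` (gene x TF hit-count matrix).
#' @export
scan_pwm <- function(promoters, pwms, p_max = 1e-4, granularity = 1e-3) {
  stopifnot(is.data.frame(promoters), all(c("gene_id", "seq") %in%
                                            names(promoters)))
  for (p in pwms) if (p$alphabet != "dna")
    stop("scan_pwm requires DNA PWMs (motif '", p$name, "')")
  hits <- list()
  counts <- matrix(0L, nrow(promoters), length(pwms),
                   dimnames = list(promoters$gene_id,
                                   vapply(pwms, `[[`, "", "name")))
  for (p in pwms) {
    sd <- pwm_score_distribution(p, granularity)
    thr <- score_threshold(sd, p_max)
    prc <- pwm_revcomp(p)
    int_fwd <- round(p$log_odds / granularity)
    int_rev <- round(prc$log_odds / granularity)
    for (gi in seq_len(nrow(promoters))) {
      s <- toupper(promoters$seq[gi])
      if (nchar(s) < p$width) next
      x <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
      for (strand in c("+", "-")) {
        M <- if (strand == "+") int_fwd else int_rev
        sc <- window_scores_int(x, M)
        hit_at <- which(!is.na(sc) & sc >= thr)
        for (j in hit_at) {
          hits[[length(hits) + 1L]] <- data.frame(
            gene_id = promoters$gene_id[gi], tf_name = p$name,
            position = j, strand = strand,
            score = sc[j] * granularity,
            p_value = pvalue_of(sd, sc[j]), stringsAsFactors = FALSE)
          counts[gi, p$name] <- counts[gi, p$name] + 1L
        }
      }
    }
  }
  hits <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(gene_id = character(0), tf_name = character(0),
               position = integer(0), strand = character(0),
               score = numeric(0), p_value = numeric(0))
  list(hits = hits, counts = counts)
}

# integer window scores; NA where the window contains a non-ACGT base
window_scores_int <- function(x, M) {
  w <- ncol(M)
  m <- length(x) - w + 1L
  if (m < 1L) return(numeric(0))
  sc <- numeric(m); bad <- logical(m)
  for (t in seq_len(w)) {
    xi <- x[t:(t + m - 1L)]
    bad <- bad | is.na(xi)
    v <- M[cbind(xi, t)]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc[bad] <- NA
  sc
}

# Exact distribution of the discretized log-odds score of one window under
# the background: DP convolution over columns. Returns list(min, probs)
# where probs[v - min + 1] = P(score == v).
pwm_score_distribution <- function(pwm, granularity = 1e-3) {
  M <- round(pwm$log_odds / granularity)
  bg <- pwm$background[rownames(pwm$probs)]
  lo <- sum(apply(M, 2, min)); hi <- sum(apply(M, 2, max))
  probs <- numeric(hi - lo + 1)
  cur_min <- 0
  probs[1] <- 1  # before any column: score 0 at offset cur_min
  cur <- c(1)
  for (t in seq_len(ncol(M))) {
    col <- M[, t]
    new_min <- cur_min + min(col)
    new_max <- cur_min + length(cur) - 1 + max(col)
    new <- numeric(new_max - new_min + 1)
    for (a in seq_along(col)) {
      sh <- cur_min + col[a] - new_min
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + bg[a] * cur
    }
    cur <- new; cur_min <- new_min
  }
  list(min = cur_min, probs = cur,
       tail = rev(cumsum(rev(cur))))  # tail[i] = P(score >= min + i - 1)
}

# smallest integer score with P(score >= s) <= p_max
score_threshold <- function(sd, p_max) {
  ok <- which(sd$tail <= p_max)
  if (length(ok) == 0L) return(Inf)
  sd$min + ok[1] - 1
}

pvalue_of <- function(sd, s) {
  i <- s - sd$min + 1
  if (i <= 0) return(1)
  if (i > length(sd$tail)) return(0)
  sd$tail[i]
}
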