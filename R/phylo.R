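#' Fractional common k-mer distance between sequences
#'
#' `d = 1 - shared_kmers / (min(L1, L2) - k + 1)` where `shared_kmers` sums
#' the per-word minimum of the two k-mer count vectors. Used for the guide
#' tree of the progressive aligner.
#'
#' @param seqs Named character vector of sequences.
#' @param k Word length.
#' @return Symmetric distance matrix.
#' @export
kmer_distance <- function(seqs, k = 3L) {
  n <- length(seqs)
  counts <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(table(character(0)))
    table(substring(s, 1:(L - k + 1), k:L))
  })
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- sum(pmin(ci[names(ci) %in% names(cj)],
                       cj[names(ci)[names(ci) %in% names(cj)]]))
    denom <- min(nchar(seqs[i]), nchar(seqs[j])) - k + 1
    d[i, j] <- d[j, i] <- 1 - if (denom > 0) shared / denom else 0
  }
  d
}

#' Progressive multiple sequence alignment
#'
#' ClustalW-style progressive alignment: a guide tree is built by
#' neighbor-joining on fractional common 3-mer distances, then profiles are
#' merged by global profile-profile alignment (sum-of-pairs BLOSUM62 column
#' scores, affine gaps) in guide-tree postorder. Deterministic for a given
#' input; guide-tree ties are broken on lexicographically sorted ids.
#'
#' @param seqs Named character vector of at least two protein sequences.
#' @param matrix Substitution-matrix object; default BLOSUM62 with gap
#'   open -10, extend -1.
#' @param k Guide-tree word length.
#' @return An MSA: named character vector of equal-length gapped sequences
#'   in the original input order.
#' @export
progressive_align <- function(seqs, matrix = blosum62(-10, -1), k = 3L) {
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  seqs <- toupper(seqs)
  if (length(seqs) == 2L) {
    al <- align_pair(seqs[1], seqs[2], matrix, mode = "global")
    out <- c(al$aligned_a, al$aligned_b)
    names(out) <- names(seqs)
    return(out)
  }
  S <- matrix$scores[AA20, AA20]
  storage.mode(S) <- "double"

  ord_ids <- sort(names(seqs))          # tie-break order
  d <- kmer_distance(seqs[ord_ids], k)
  guide <- nj_tree(d)
  guide <- ape::reorder.phylo(guide, "postorder")

  ntip <- length(guide$tip.label)
  profs <- vector("list", ntip + guide$Nnode)
  for (i in seq_len(ntip))
    profs[[i]] <- seqs[guide$tip.label[i]]
  children <- split(guide$edge[, 2], guide$edge[, 1])
  # postorder edge ordering guarantees children are built before parents
  for (node in unique(guide$edge[, 1])) {
    kids <- children[[as.character(node)]]
    prof <- profs[[kids[1]]]
    for (kk in kids[-1])
      prof <- merge_profiles(prof, profs[[kk]], S,
                             matrix$gap_open, matrix$gap_ext)
    profs[[node]] <- prof
  }
  msa <- profs[[ntip + 1L]]
  msa[names(seqs)]
}

# Merge two profiles (named character vectors of aligned rows) by global
# profile-profile alignment over sum-of-pairs column scores.
merge_profiles <- function(pa, pb, S, gap_open, gap_ext) {
  fa <- profile_freqs(pa); fb <- profile_freqs(pb)
  C <- t(fa) %*% S %*% fb
  dp <- affine_dp_cpp(C, gap_open, gap_ext, FALSE)
  expand <- function(rows, idx) {
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out <- matrix("-", nrow(mat), length(idx))
    out[, idx > 0] <- mat[, idx[idx > 0], drop = FALSE]
    stats::setNames(apply(out, 1, paste, collapse = ""), names(rows))
  }
  c(expand(pa, dp$a_idx), expand(pb, dp$b_idx))
}

# residue frequency matrix (20 x L) of an aligned profile; gaps carry no mass
profile_freqs <- function(rows) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  vapply(seq_len(ncol(mat)), function(j)
    as.numeric(table(factor(mat[, j], levels = AA20))) / nrow(mat),
    numeric(20))
}

#' Pairwise distances from a multiple alignment
#'
#' Gap handling is pairwise deletion: for each pair, columns where either
#' row has a gap or a non-standard residue are excluded. Models: `"p"`
#' (proportion of differing compared sites), `"poisson"` (`-ln(1 - p)`), and
#' `"jtt_ml"` (maximum-likelihood time under the JTT rate matrix, 1-D
#' optimization of the pairwise likelihood).
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param model One of `"p"`, `"poisson"`, `"jtt_ml"`.
#' @return Symmetric distance matrix with attributes `model` and
#'   `saturated` (logical matrix flagging pairs at/near saturation).
#' @export
compute_distances <- function(msa, model = c("p", "poisson", "jtt_ml")) {
  model <- match.arg(model)
  if (length(msa) < 2L) stop("need at least 2 aligned sequences")
  if (length(unique(nchar(msa))) != 1L) stop("ragged alignment")
  rows <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  n <- nrow(rows)
  idx <- matrix(match(rows, AA20), n)      # NA for gaps/non-standard
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  jtt_map <- match(AA20, JTT_ORDER)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
    if (!any(ok))
      stop("no comparable columns for pair ", names(msa)[i], " / ",
           names(msa)[j])
    xi <- idx[i, ok]; yi <- idx[j, ok]
    p <- mean(xi != yi)
    val <- switch(model,
      p = p,
      poisson = {
        if (p >= 1) { sat[i, j] <- sat[j, i] <- TRUE; Inf }
        else { if (p >= 0.95) sat[i, j] <- sat[j, i] <- TRUE; -log(1 - p) }
      },
      jtt_ml = {
        r <- jtt_ml_distance(jtt_map[xi], jtt_map[yi])
        if (r$saturated) sat[i, j] <- sat[j, i] <- TRUE
        r$distance
      })
    d[i, j] <- d[j, i] <- val
  }
  structure(d, model = model, saturated = sat)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion; ties are
#' broken by the smallest (i, j) pair in the current cluster order. Branch
#' lengths follow the standard NJ formulas; negative estimates are clamped
#' to zero and flagged in the `"clamped"` attribute. Additive input matrices
#' are reproduced exactly.
#'
#' @param d Symmetric distance matrix with row/col names (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree (trifurcating root).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", 1:n)
  labels <- vapply(rownames(d), function(x)
    sprintf("%s", x), "")
  # each active cluster holds a newick fragment
  frag <- as.list(labels)
  act <- d
  clamped <- FALSE
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (nrow(act) > 3L) {
    r <- nrow(act)
    R <- rowSums(act)
    Q <- (r - 2) * act - outer(R, R, `+`)
    diag(Q) <- Inf
    # smallest Q; ties -> smallest row index, then column index
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    i <- ij[1]; j <- ij[2]
    li <- act[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- act[i, j] - li
    if (li < 0 || lj < 0) clamped <- TRUE
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[[i]], fmt(li),
                        frag[[j]], fmt(lj))
    du <- (act[i, ] + act[j, ] - act[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    act2 <- act[keep, keep, drop = FALSE]
    act2 <- rbind(cbind(act2, du[keep]), c(du[keep], 0))
    frag <- c(frag[keep], list(new_frag))
    act <- act2
  }
  # final three-cluster star: three-point formulas
  l1 <- (act[1, 2] + act[1, 3] - act[2, 3]) / 2
  l2 <- (act[1, 2] + act[2, 3] - act[1, 3]) / 2
  l3 <- (act[1, 3] + act[2, 3] - act[1, 2]) / 2
  if (min(l1, l2, l3) < 0) clamped <- TRUE
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[[1]], fmt(l1),
                 frag[[2]], fmt(l2), frag[[3]], fmt(l3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicate trees containing the same bipartition.
#'
#' @param msa Named character vector of aligned sequences.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param model Distance model passed to [compute_distances()].
#' @return The original NJ tree with `node.label` set to supports (0-100);
#'   the root label is `NA`.
#' @export
bootstrap_supports <- function(msa, n_reps = 1000L, seed, model = "p") {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (missing(seed)) stop("a seed is required")
  rows <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  L <- ncol(rows)
  base_tree <- nj_tree(compute_distances(msa, model))
  boot <- local_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      sub <- apply(rows[, cols, drop = FALSE], 1, paste, collapse = "")
      names(sub) <- names(msa)
      nj_tree(suppressWarnings(p_distance_fast(sub)))
    })
  })
  cnt <- ape::prop.clades(base_tree, boot, rooted = FALSE)
  cnt[is.na(cnt)] <- 0
  support <- 100 * cnt / n_reps
  support[1] <- NA  # root bipartition is trivial
  base_tree$node.label <- support
  base_tree
}

# p-distance with pairwise deletion; empty pairs get distance 0 (bootstrap
# resamples can drop all comparable columns for heavily gapped pairs).
p_distance_fast <- function(msa) {
  rows <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  n <- nrow(rows)
  idx <- matrix(match(rows, AA20), n)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
    d[i, j] <- d[j, i] <- if (any(ok)) mean(idx[i, ok] != idx[j, ok]) else 0
  }
  d
}

#' Cut a phylogeny into k groups, or assign groups by reference leaves
#'
#' `cut_k` mode removes the `k - 1` longest internal edges (ties broken by
#' edge index) and reports the resulting leaf partition; every group is a
#' clade of the tree. Reference mode assigns each unlabeled leaf the group
#' of its nearest labeled reference leaf by patristic distance.
#'
#' @param tree An `ape::phylo` tree.
#' @param k Number of groups for cut mode.
#' @param reference Named character vector mapping reference leaf labels to
#'   group labels (reference mode).
#' @return Data frame `gene_id`, `group`; groups are labeled `G1..Gk` in
#'   order of first appearance along the tip ordering (cut mode).
#' @export
extract_groups <- function(tree, k = NULL, reference = NULL) {
  ntip <- length(tree$tip.label)
  if (!is.null(reference)) {
    dm <- ape::cophenetic.phylo(tree)
    refs <- intersect(names(reference), tree$tip.label)
    if (length(refs) == 0L) stop("no reference leaves present in the tree")
    grp <- vapply(tree$tip.label, function(tip) {
      reference[[refs[which.min(dm[tip, refs])]]]
    }, "")
    return(data.frame(gene_id = tree$tip.label, group = unname(grp),
                      stringsAsFactors = FALSE))
  }
  if (is.null(k)) stop("supply k or a reference map")
  if (k > ntip) stop("k exceeds the number of leaves")
  edges <- tree$edge
  internal <- which(edges[, 2] > ntip)
  drop <- integer(0)
  if (k > 1L) {
    if (length(internal) < k - 1L)
      stop("tree has fewer internal edges than k - 1")
    len <- tree$edge.length[internal]
    drop <- internal[order(-len, seq_along(len))][seq_len(k - 1L)]
  }
  keep <- setdiff(seq_len(nrow(edges)), drop)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(edges[keep, , drop = FALSE]), ncol = 2),
    directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(as.character(unique(as.vector(edges))),
                      igraph::V(g)$name)),
    name = setdiff(as.character(unique(as.vector(edges))),
                   igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  tip_comp <- comp[as.character(seq_len(ntip))]
  grp_id <- match(tip_comp, unique(tip_comp))
  data.frame(gene_id = tree$tip.label,
             group = paste0("G", grp_id), stringsAsFactors = FALSE)
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
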