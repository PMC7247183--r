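#' All-vs-all homolog pairs within a gene family
#'
#' Scores every unordered pair of family proteins by local affine-gap
#' alignment and declares homologs under the strict thresholds
#' `evalue < evalue_max` and `identity_pct > identity_min`. For
#' same-chromosome pairs the separation between the nearer gene ends (end
#' of the upstream gene to start of the downstream gene) is recorded.
#'
#' @param proteins Named character vector of family protein sequences.
#' @param loci Locus data frame (as from [parse_locus()] /
#'   [read_family_table()]) covering every protein id.
#' @param evalue_max E-value upper bound (strict `<`).
#' @param identity_min Identity lower bound in percent (strict `>`).
#' @param matrix Substitution-matrix object.
#' @param strict Error on proteins without a locus (otherwise they are
#'   flagged `unanchored_locus = NA` and still scored).
#' @return Data frame of all scored pairs: `gene_a`, `gene_b` (a < b
#'   lexicographically), `identity_pct`, `evalue`, `score`, `is_homolog`,
#'   `same_chromosome`, `separation_bp`.
#' @export
find_homolog_pairs <- function(proteins, loci, evalue_max = 1e-20,
                               identity_min = 75, matrix = blosum62(),
                               strict = TRUE) {
  ids <- names(proteins)
  missing_loci <- setdiff(ids, loci$gene_id)
  if (length(missing_loci) > 0L && strict)
    stop("protein(s) without locus: ", paste(missing_loci, collapse = ", "))
  loc <- loci[match(ids, loci$gene_id), , drop = FALSE]
  n <- length(ids)
  if (n < 2L) stop("need at least 2 proteins")
  out <- list(); kk <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- ids[i]; b <- ids[j]
    if (a > b) { tmp <- a; a <- b; b <- tmp
                 ii <- j; jj <- i } else { ii <- i; jj <- j }
    al <- align_pair(proteins[ii], proteins[jj], matrix, mode = "local")
    la <- loc[ii, ]; lb <- loc[jj, ]
    same_chr <- !is.na(la$chromosome) && !is.na(lb$chromosome) &&
      la$chromosome == lb$chromosome
    sep <- NA_real_
    if (isTRUE(same_chr)) {
      up <- if (la$start_bp <= lb$start_bp) la else lb
      dn <- if (la$start_bp <= lb$start_bp) lb else la
      sep <- max(0, dn$start_bp - up$end_bp)
    }
    kk <- kk + 1L
    out[[kk]] <- data.frame(
      gene_a = a, gene_b = b, identity_pct = al$identity_pct,
      evalue = al$evalue, score = al$score,
      is_homolog = al$evalue < evalue_max & al$identity_pct > identity_min,
      same_chromosome = isTRUE(same_chr), separation_bp = sep,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Classify family duplications into tandem arrays and segmental pairs
#'
#' Same-chromosome homologs are chained into maximal tandem arrays: family
#' genes are sorted by start coordinate per chromosome and consecutive genes
#' are linked when they form a homolog pair separated by at most
#' `tandem_window_bp` and, when a full gene annotation is supplied, no
#' annotated gene intervenes. Cross-chromosome homolog pairs are reported as
#' segmental duplicates. Genes on unanchored scaffolds (subgenome `"U"`) are
#' excluded from both calls and listed separately.
#'
#' @param pairs Output of [find_homolog_pairs()].
#' @param loci Locus data frame for the family genes.
#' @param annotation Optional locus data frame of *all* genes in the genome;
#'   when absent the intervening-gene rule cannot be checked and the result
#'   is flagged `family_only = TRUE`.
#' @param tandem_window_bp Maximum separation between consecutive tandem
#'   genes.
#' @return List with `tandem_arrays` (list of data frames: `chromosome`,
#'   `members` in start order, `separations_bp`), `tandem_pairs`
#'   (consecutive pairs within arrays, the pair-counting convention),
#'   `segmental_pairs` (data frame), `unanchored` (gene ids),
#'   `family_only` flag.
#' @export
classify_duplications <- function(pairs, loci, annotation = NULL,
                                  tandem_window_bp = 150000) {
  fam <- loci[!is.na(loci$chromosome), , drop = FALSE]
  unanchored <- fam$gene_id[fam$subgenome == "U"]
  fam <- fam[fam$subgenome != "U", , drop = FALSE]
  hom <- pairs[pairs$is_homolog, , drop = FALSE]
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  hom_keys <- key(hom$gene_a, hom$gene_b)

  arrays <- list(); tandem_pairs <- list()
  for (chr in sort(unique(fam$chromosome))) {
    sub <- fam[fam$chromosome == chr, , drop = FALSE]
    sub <- sub[order(sub$start_bp, sub$gene_id), , drop = FALSE]
    if (nrow(sub) < 2L) next
    linked <- logical(nrow(sub) - 1L)
    seps <- numeric(nrow(sub) - 1L)
    for (i in seq_len(nrow(sub) - 1L)) {
      a <- sub$gene_id[i]; b <- sub$gene_id[i + 1L]
      seps[i] <- max(0, sub$start_bp[i + 1L] - sub$end_bp[i])
      ok <- key(a, b) %in% hom_keys && seps[i] <= tandem_window_bp
      if (ok && !is.null(annotation)) {
        inter <- annotation[
          annotation$chromosome == chr &
            annotation$start_bp > sub$end_bp[i] &
            annotation$end_bp < sub$start_bp[i + 1L] &
            !(annotation$gene_id %in% fam$gene_id), , drop = FALSE]
        if (nrow(inter) > 0L) ok <- FALSE
      }
      linked[i] <- ok
    }
    # maximal runs of linked consecutive genes
    r <- rle(linked)
    pos <- cumsum(c(1L, r$lengths))
    for (g in seq_along(r$values)) {
      if (!r$values[g]) next
      i0 <- pos[g]; i1 <- pos[g + 1L]  # genes i0 .. i1 form the array
      arrays[[length(arrays) + 1L]] <- list(
        chromosome = chr,
        members = sub$gene_id[i0:i1],
        separations_bp = seps[i0:(i1 - 1L)])
      for (i in i0:(i1 - 1L))
        tandem_pairs[[length(tandem_pairs) + 1L]] <- data.frame(
          chromosome = chr, gene_a = sub$gene_id[i],
          gene_b = sub$gene_id[i + 1L], separation_bp = seps[i],
          stringsAsFactors = FALSE)
    }
  }
  seg <- hom[!hom$same_chromosome, , drop = FALSE]
  seg <- seg[!(seg$gene_a %in% unanchored | seg$gene_b %in% unanchored), ,
             drop = FALSE]
  anchored <- loci$gene_id[!is.na(loci$chromosome) & loci$subgenome != "U"]
  seg <- seg[seg$gene_a %in% anchored & seg$gene_b %in% anchored, ,
             drop = FALSE]
  list(tandem_arrays = arrays,
       tandem_pairs = if (length(tandem_pairs) > 0)
         do.call(rbind, tandem_pairs) else NULL,
       segmental_pairs = seg[, c("gene_a", "gene_b", "identity_pct",
                                 "evalue")],
       unanchored = unanchored,
       family_only = is.null(annotation))
}

#' Chromosome, subgenome and homoeologous-group summary of a gene family
#'
#' @param loci Locus data frame.
#' @return List with `per_chromosome` (count, cluster `span_kb` from the
#'   smallest start to the largest end, percentage of total), `per_subgenome`
#'   and `per_group` (homoeologous chromosome group, i.e. the numeric prefix
#'   of the chromosome name) count/percentage tables, and `n_total`.
#'   Percentages are rounded to 1 decimal.
#' @export
summarize_chromosomes <- function(loci) {
  if (nrow(loci) == 0L) stop("no loci")
  n <- nrow(loci)
  per_chr <- do.call(rbind, lapply(sort(unique(loci$chromosome)),
                                   function(chr) {
    sub <- loci[loci$chromosome == chr, ]
    data.frame(chromosome = chr, count = nrow(sub),
               span_kb = (max(sub$end_bp) - min(sub$start_bp)) / 1000,
               pct = round(100 * nrow(sub) / n, 1),
               stringsAsFactors = FALSE)
  }))
  sg <- table(factor(loci$subgenome, levels = c("A", "B", "D", "U")))
  per_sg <- data.frame(subgenome = names(sg), count = as.integer(sg),
                       pct = round(100 * as.integer(sg) / n, 1),
                       stringsAsFactors = FALSE)
  grp_of <- sub("^([0-9]+).*$", "\\1", loci$chromosome)
  grp_of[!grepl("^[0-9]", loci$chromosome)] <- "unanchored"
  gg <- table(grp_of)
  per_grp <- data.frame(group = names(gg), count = as.integer(gg),
                        pct = round(100 * as.integer(gg) / n, 1),
                        stringsAsFactors = FALSE)
  list(per_chromosome = per_chr, per_subgenome = per_sg,
       per_group = per_grp, n_total = n)
}

#' Assign homoeologous groups across the A/B/D subgenomes
#'
#' Builds the homolog graph restricted to cross-subgenome edges and reports
#' its connected components as homoeolog groups. Within a component the
#' canonical member per subgenome is the gene with the highest mean identity
#' to members of the other subgenomes (ties by gene id); surplus
#' same-subgenome members are flagged as expansion copies.
#'
#' @param pairs Output of [find_homolog_pairs()].
#' @param loci Locus data frame.
#' @return List of groups, each a list with `label`, `members` (data frame
#'   `gene_id`, `subgenome`, `canonical`, `expansion_copy`), `complete`
#'   (one canonical member on each of A, B, D).
#' @export
assign_homoeologs <- function(pairs, loci) {
  sg <- stats::setNames(loci$subgenome, loci$gene_id)
  hom <- pairs[pairs$is_homolog, , drop = FALSE]
  cross <- hom[sg[hom$gene_a] != sg[hom$gene_b] &
                 sg[hom$gene_a] != "U" & sg[hom$gene_b] != "U", ,
               drop = FALSE]
  if (nrow(cross) == 0L) return(list())
  g <- igraph::graph_from_edgelist(as.matrix(cross[, c("gene_a", "gene_b")]),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- groups[order(vapply(groups, function(x) sort(x)[1], ""))]
  lapply(seq_along(groups), function(gi) {
    members <- sort(groups[[gi]])
    msg <- sg[members]
    # mean identity to members of other subgenomes
    mean_id <- vapply(members, function(m) {
      others <- members[sg[members] != sg[m]]
      if (length(others) == 0L) return(0)
      sel <- (hom$gene_a == m & hom$gene_b %in% others) |
        (hom$gene_b == m & hom$gene_a %in% others)
      if (!any(sel)) 0 else mean(hom$identity_pct[sel])
    }, 0)
    canonical <- logical(length(members))
    for (s in unique(msg)) {
      in_s <- which(msg == s)
      best <- in_s[order(-mean_id[in_s], members[in_s])][1]
      canonical[best] <- TRUE
    }
    df <- data.frame(gene_id = members, subgenome = unname(msg),
                     canonical = canonical,
                     expansion_copy = !canonical,
                     stringsAsFactors = FALSE)
    list(label = paste0("H", gi), members = df,
         complete = all(c("A", "B", "D") %in% msg[canonical]))
  })
}
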