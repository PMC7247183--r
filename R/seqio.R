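#' Read a FASTA file into a validated sequence set
#'
#' Parses a (possibly line-wrapped) FASTA file into a named character vector
#' of residues. The record id is the first whitespace-delimited token of each
#' header. Residues are upper-cased and checked against the IUPAC alphabet of
#' the declared sequence type (ambiguity codes allowed).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return A named character vector with attribute `alphabet`; one element
#'   per record, in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  names(seqs) <- ids
  validate_residues(seqs, alphabet)
  structure(seqs, alphabet = alphabet)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of residues.
#' @param path Output path.
#' @param width Line-wrap width for sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", seqs[[i]])
    writeLines(c(paste0(">", names(seqs)[i]), sub("\n$", "", body)),
               con, sep = "\n")
  }
  invisible(path)
}

validate_residues <- function(seqs, alphabet) {
  allowed <- if (alphabet == "protein") AA_IUPAC else DNA_IUPAC
  for (i in seq_along(seqs)) {
    if (nchar(seqs[[i]]) == 0L)
      stop("empty sequence for record '", names(seqs)[i], "'")
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad) > 0L)
      stop("non-IUPAC character '", chars[bad[1]], "' at position ", bad[1],
           " in record '", names(seqs)[i], "' (", alphabet, " alphabet)")
  }
  invisible(TRUE)
}

#' Derive the wheat subgenome label from a chromosome name
#'
#' The trailing letter of the chromosome name gives the subgenome
#' (A, B or D); anything else, including the unanchored `"Un"`, maps to
#' `"U"`.
#'
#' @param chromosome Character vector of chromosome names (without the
#'   `"chr"` prefix).
#' @return Character vector over `{"A","B","D","U"}`.
#' @export
subgenome_of <- function(chromosome) {
  last <- substring(chromosome, nchar(chromosome), nchar(chromosome))
  ifelse(last %in% c("A", "B", "D"), last, "U")
}

#' Parse a locus string of the form "chr3D: 600607844-600608597"
#'
#' @param text Character vector of locus strings.
#' @param gene_id Optional gene ids to attach (recycled against `text`).
#' @param strand Strand labels; defaults to `"unknown"` (the tabulated loci
#'   carry no strand).
#' @return A locus data frame with columns `gene_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `strand`, `subgenome`, `span_bp` (1-based
#'   inclusive coordinates).
#' @export
parse_locus <- function(text, gene_id = NA_character_, strand = "unknown") {
  m <- regmatches(text, regexec("^chr([A-Za-z0-9]+):\\s*([0-9]+)-([0-9]+)$",
                                text))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("malformed locus string: '", text[which(bad)[1]], "'")
  chromosome <- vapply(m, `[[`, "", 2L)
  start_bp <- as.numeric(vapply(m, `[[`, "", 3L))
  end_bp <- as.numeric(vapply(m, `[[`, "", 4L))
  if (any(start_bp > end_bp))
    stop("locus start exceeds end: '", text[which(start_bp > end_bp)[1]], "'")
  data.frame(gene_id = rep_len(gene_id, length(text)),
             chromosome = chromosome,
             start_bp = start_bp, end_bp = end_bp,
             strand = rep_len(strand, length(text)),
             subgenome = subgenome_of(chromosome),
             span_bp = end_bp - start_bp + 1,
             stringsAsFactors = FALSE)
}

#' Format a locus data frame back to "chr<chrom>: <start>-<end>" strings
#'
#' Inverse of [parse_locus()] on its locus columns.
#'
#' @param locus Locus data frame (columns `chromosome`, `start_bp`, `end_bp`).
#' @return Character vector.
#' @export
format_locus <- function(locus) {
  sprintf("chr%s: %.0f-%.0f", locus$chromosome, locus$start_bp, locus$end_bp)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon/CDS features and returns per-transcript gene
#' structures (exon/intron intervals in gene-relative, 5'-to-3' coordinates)
#' together with the gene loci. Minus-strand transcripts are reported 5'->3',
#' i.e. exon order is reversed relative to chromosome order.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @return A list with `structures` (list of gene-structure lists: `gene_id`,
#'   `transcript_id`, `strand`, `exons`, `introns` as two-column matrices,
#'   `utr5_bp`, `utr3_bp`) and `loci` (locus data frame).
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gff3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p) == 0L) NA_character_ else as.character(p[[1]]), "")
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(mrnas) > 0L && anyNA(mrnas$Parent))
    stop("mRNA feature without Parent attribute")
  if (nrow(exons) > 0L && anyNA(exons$Parent))
    stop("exon feature without Parent attribute")

  chrom <- sub("^chr", "", genes$seqnames)
  loci <- data.frame(gene_id = genes$ID, chromosome = chrom,
                     start_bp = genes$start, end_bp = genes$end,
                     strand = ifelse(genes$strand %in% c("+", "-"),
                                     genes$strand, "unknown"),
                     subgenome = subgenome_of(chrom),
                     span_bp = genes$end - genes$start + 1,
                     stringsAsFactors = FALSE)

  structures <- lapply(seq_len(nrow(mrnas)), function(i) {
    tx <- mrnas[i, ]
    g <- genes[genes$ID == tx$Parent, , drop = FALSE]
    if (nrow(g) != 1L)
      stop("mRNA '", tx$ID, "' has unresolvable Parent '", tx$Parent, "'")
    ex <- exons[exons$Parent == tx$ID, , drop = FALSE]
    if (nrow(ex) == 0L) stop("mRNA '", tx$ID, "' has no exons")
    if (any(ex$start < g$start | ex$end > g$end))
      stop("exon outside parent gene bounds for mRNA '", tx$ID, "'")
    cd <- cdss[cdss$Parent == tx$ID, , drop = FALSE]
    build_structure(g$ID, tx$ID, g$strand, g$start, g$end,
                    ex[, c("start", "end")], cd[, c("start", "end")])
  })
  list(structures = structures, loci = loci)
}

# Convert absolute exon/CDS intervals into a gene-relative 5'->3' structure.
build_structure <- function(gene_id, transcript_id, strand,
                            gene_start, gene_end, exons_abs, cds_abs = NULL) {
  exons_abs <- exons_abs[order(exons_abs$start), , drop = FALSE]
  if (nrow(exons_abs) > 1L &&
      any(exons_abs$start[-1] <= exons_abs$end[-nrow(exons_abs)]))
    stop("overlapping exons in transcript '", transcript_id, "'")
  if (identical(strand, "-")) {
    rel <- cbind(start = gene_end - exons_abs$end + 1,
                 end = gene_end - exons_abs$start + 1)
    rel <- rel[order(rel[, "start"]), , drop = FALSE]
  } else {
    rel <- cbind(start = exons_abs$start - gene_start + 1,
                 end = exons_abs$end - gene_start + 1)
  }
  introns <- if (nrow(rel) > 1L)
    cbind(start = rel[-nrow(rel), "end"] + 1, end = rel[-1, "start"] - 1)
  else
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))

  utr5 <- utr3 <- 0
  if (!is.null(cds_abs) && nrow(cds_abs) > 0L) {
    # UTR lengths measured on the spliced transcript.
    cds_lo <- min(cds_abs$start); cds_hi <- max(cds_abs$end)
    spliced_before <- function(pos) {
      # spliced bases strictly 5' of absolute position pos
      sum(pmax(0, pmin(exons_abs$end, pos - 1) - exons_abs$start + 1))
    }
    spliced_len <- sum(exons_abs$end - exons_abs$start + 1)
    if (identical(strand, "-")) {
      utr5 <- spliced_len - spliced_before(cds_hi + 1)
      utr3 <- spliced_before(cds_lo)
    } else {
      utr5 <- spliced_before(cds_lo)
      utr3 <- spliced_len - spliced_before(cds_hi + 1)
    }
  }
  list(gene_id = gene_id, transcript_id = transcript_id, strand = strand,
       exons = rel, introns = introns, utr5_bp = utr5, utr3_bp = utr3)
}

#' Infer exon/intron structure by splicing a CDS against its genomic sequence
#'
#' Reconstructs exons as maximal exact-match blocks: at each step the longest
#' prefix of the remaining CDS that occurs downstream in the genomic sequence
#' is taken as the next exon, at its leftmost (intron-minimal) occurrence.
#' If the greedy maximal block leaves the remainder unspliceable the block is
#' shortened until a full reconstruction exists.
#'
#' @param cds Coding (spliced) sequence, a single character string.
#' @param genomic Genomic (unspliced) sequence, a single character string.
#' @return A gene-structure list as in [read_gff3()], with exon coordinates
#'   relative to `genomic` (1-based inclusive), or an error `"unspliceable"`
#'   if the CDS cannot be reconstructed.
#' @export
infer_gene_structure <- function(cds, genomic) {
  stopifnot(is.character(cds), is.character(genomic))
  cds <- toupper(unname(cds[[1]])); genomic <- toupper(unname(genomic[[1]]))
  exons <- splice_search(cds, genomic, 1L, 1L)
  if (is.null(exons)) stop("unspliceable: CDS cannot be reconstructed ",
                           "from the genomic sequence")
  rel <- do.call(rbind, exons)
  colnames(rel) <- c("start", "end")
  introns <- if (nrow(rel) > 1L)
    cbind(start = rel[-nrow(rel), "end"] + 1, end = rel[-1, "start"] - 1)
  else
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  list(gene_id = NA_character_, transcript_id = NA_character_,
       strand = "+", exons = rel, introns = introns,
       utr5_bp = 0, utr3_bp = 0)
}

# Recursive greedy splice: longest matching CDS prefix at the leftmost
# occurrence >= gpos, backing off on failure. Returns list of c(start, end)
# in genomic coordinates, or NULL.
splice_search <- function(cds, genomic, cpos, gpos, depth = 0L) {
  nc <- nchar(cds); ng <- nchar(genomic)
  if (cpos > nc) return(list())
  if (gpos > ng || depth > 64L) return(NULL)
  tail_g <- substr(genomic, gpos, ng)
  # binary search for the longest matchable prefix (monotone in length)
  lo <- 0L; hi <- min(nc - cpos + 1L, nchar(tail_g))
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    hit <- regexpr(substr(cds, cpos, cpos + mid - 1L), tail_g,
                   fixed = TRUE) > 0L
    if (hit) lo <- mid else hi <- mid - 1L
  }
  for (len in seq(lo, 1L)) {
    if (lo == 0L) break
    off <- regexpr(substr(cds, cpos, cpos + len - 1L), tail_g, fixed = TRUE)
    while (off > 0L) {
      exon_start <- gpos + as.integer(off) - 1L
      rest <- splice_search(cds, genomic, cpos + len,
                            exon_start + len, depth + 1L)
      if (!is.null(rest))
        return(c(list(c(exon_start, exon_start + len - 1L)), rest))
      # try the next occurrence at this length before shortening
      nxt <- regexpr(substr(cds, cpos, cpos + len - 1L),
                     substr(tail_g, as.integer(off) + 1L, nchar(tail_g)),
                     fixed = TRUE)
      off <- if (nxt > 0L) as.integer(off) + nxt else -1L
      if (depth + len > 4096L) break
    }
  }
  NULL
}

#' Read a gene-family characterization table (wheat ASR survey layout)
#'
#' Reads a TSV with the columns of the published wheat ASR family table:
#' `gene_id`, `transcript_id`, `locus` (a `"chr..: start-end"` string),
#' `exon_count`, `orf_bp`, `aa_len`, `mw_kda`, `pi`, `gravy`. The ORF length
#' convention includes the stop codon, so `orf_bp = 3 * (aa_len + 1)`.
#'
#' @param path Path to the TSV; defaults to the packaged wheat ASR fixture
#'   transcribed from the published survey.
#' @return Data frame with parsed locus columns appended.
#' @export
read_family_table <- function(path = system.file("extdata",
                                                 "table1_wheat_asr.tsv",
                                                 package = "asrfam")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  need <- c("gene_id", "transcript_id", "locus", "exon_count", "orf_bp",
            "aa_len", "mw_kda", "pi", "gravy")
  if (!all(need %in% names(tab)))
    stop("family table missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  loc <- parse_locus(tab$locus, gene_id = tab$gene_id)
  cbind(tab[setdiff(names(tab), "locus")],
        loc[c("chromosome", "start_bp", "end_bp", "strand",
              "subgenome", "span_bp")])
}

# reverse complement of a DNA string (IUPAC-aware via Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
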