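test_that("FASTA reading parses records, preserves order, ignores wrapping", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "ACDEF", ">s2", "GH", "IKL", "MN",
               "PQ", "RS"), f)
  recs <- read_fasta(f, "protein")
  expect_named(recs, c("s1", "s2"))
  expect_equal(unname(recs["s2"]), "GHIKLMNPQRS")
  expect_equal(nchar(recs), c(s1 = 5L, s2 = 11L))
})

test_that("FASTA reading rejects empty files, duplicate ids, bad residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  file.create(f)
  expect_error(read_fasta(f, "protein"), "no records")
  writeLines(c(">a", "ACD", ">a", "EFG"), f)
  expect_error(read_fasta(f, "protein"), "duplicate.*a")
  writeLines(c(">a", "AC1D"), f)
  expect_error(read_fasta(f, "protein"), "position 3")
})

test_that("FASTA round trip is the identity on ids and residues", {
  set.seed(1)
  seqs <- vapply(1:5, function(i) random_protein(sample(10:200, 1)), "")
  names(seqs) <- paste0("gene", 1:5)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f, "protein")
  expect_equal(unname(back), unname(seqs), ignore_attr = TRUE)
  expect_equal(names(back), names(seqs))
})

test_that("locus strings parse with subgenome assignment and span", {
  l <- parse_locus("chr2B: 453077970-453078937")
  expect_equal(l$chromosome, "2B")
  expect_equal(l$span_bp, 968)
  expect_equal(l$subgenome, "B")
  expect_equal(parse_locus("chrUn: 358203209-358203643")$subgenome, "U")
  expect_equal(parse_locus("chr3A: 5-5")$span_bp, 1)
  expect_error(parse_locus("3A:5-6"), "malformed")
  expect_error(parse_locus("chr3A: 10-5"), "start exceeds end")
})

test_that("parse_locus(format_locus(.)) is the identity", {
  l <- parse_locus(c("chr3D: 600607844-600608597", "chrUn: 1-20"))
  expect_equal(parse_locus(format_locus(l))[names(l)], l)
})

test_that("GFF3 gene models convert to gene-relative 5'->3' structures", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t1100\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1001\t1100\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tID=gA.1.e1;Parent=gA.1",
    "chr1\tsrc\tgene\t2001\t2300\t.\t+\t.\tID=gB",
    "chr1\tsrc\tmRNA\t2001\t2300\t.\t+\t.\tID=gB.1;Parent=gB",
    "chr1\tsrc\texon\t2001\t2050\t.\t+\t.\tID=gB.1.e1;Parent=gB.1",
    "chr1\tsrc\texon\t2101\t2170\t.\t+\t.\tID=gB.1.e2;Parent=gB.1",
    "chr1\tsrc\texon\t2211\t2300\t.\t+\t.\tID=gB.1.e3;Parent=gB.1",
    "chr1\tsrc\tgene\t3001\t3200\t.\t-\t.\tID=gC",
    "chr1\tsrc\tmRNA\t3001\t3200\t.\t-\t.\tID=gC.1;Parent=gC",
    "chr1\tsrc\texon\t3001\t3060\t.\t-\t.\tID=gC.1.e1;Parent=gC.1",
    "chr1\tsrc\texon\t3151\t3200\t.\t-\t.\tID=gC.1.e2;Parent=gC.1"), f)
  g <- read_gff3(f)
  sA <- g$structures[[1]]
  expect_equal(nrow(sA$exons), 1L)
  expect_equal(nrow(sA$introns), 0L)
  # three-exon gene: intron lengths are the planted gaps (50 and 40 bp)
  sB <- g$structures[[2]]
  expect_equal(unname(sB$introns[, "end"] - sB$introns[, "start"] + 1),
               c(50, 40))
  # minus strand: chromosome-last exon comes first in 5'->3' order
  sC <- g$structures[[3]]
  expect_equal(unname(sC$exons[1, ]), c(start = 1, end = 50),
               ignore_attr = TRUE)
  expect_equal(unname(sC$exons[2, ]), c(start = 141, end = 200),
               ignore_attr = TRUE)
  # exon + intron lengths tile the gene span for every structure
  for (s in g$structures) {
    total <- sum(s$exons[, 2] - s$exons[, 1] + 1)
    if (nrow(s$introns) > 0)
      total <- total + sum(s$introns[, 2] - s$introns[, 1] + 1)
    expect_equal(total, max(s$exons[, 2]))
  }
})

test_that("splice inference recovers planted exon boundaries", {
  set.seed(42)
  # single exon
  cds <- random_dna_str(120)
  st <- infer_gene_structure(cds, cds)
  expect_equal(nrow(st$exons), 1L)
  expect_equal(unname(st$exons[1, ]), c(1, 120), ignore_attr = TRUE)
  # two exons around a planted 100-bp intron
  e1 <- random_dna_str(90); e2 <- random_dna_str(60)
  intron <- random_dna_str(100)
  st2 <- infer_gene_structure(paste0(e1, e2), paste0(e1, intron, e2))
  expect_equal(nrow(st2$exons), 2L)
  spliced <- paste0(
    substr(paste0(e1, intron, e2), st2$exons[1, 1], st2$exons[1, 2]),
    substr(paste0(e1, intron, e2), st2$exons[2, 1], st2$exons[2, 2]))
  expect_equal(spliced, paste0(e1, e2))
  # a base absent from the genomic sequence is unspliceable
  expect_error(infer_gene_structure("ACGTACGT", "AAAACCCCGGGG"),
               "unspliceable")
})

test_that("splice inference recovers planted exon counts from the generator", {
  gen <- generate_family_genome(synthetic_config(
    seed = 77, n_triads = 2, tandem_array_sizes = integer(0), n_decoys = 0))
  for (i in seq_along(gen$structures)) {
    l <- gen$loci[i, ]
    gseq <- substr(gen$genome[[l$chromosome]], l$start_bp, l$end_bp)
    st <- infer_gene_structure(gen$cds[[l$gene_id]], gseq)
    expect_equal(nrow(st$exons), nrow(gen$structures[[i]]$exons))
  }
})

test_that("the packaged wheat family table matches its published shape", {
  tab <- read_family_table()
  expect_equal(nrow(tab), 33L)
  expect_true(all(tab$orf_bp == 3 * (tab$aa_len + 1)))
  r <- tab[tab$gene_id == "TaASR5B", ]
  expect_equal(r$orf_bp, 840)
  expect_equal(r$aa_len, 279)
  expect_equal(r$mw_kda, 30.34)
  expect_equal(r$chromosome, "2B")
  expect_equal(r$span_bp, 968)
})
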