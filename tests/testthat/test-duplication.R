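mk_loci <- function(gene_id, chromosome, start, end, strand = "+") {
  data.frame(gene_id = gene_id, chromosome = chromosome, start_bp = start,
             end_bp = end, strand = strand,
             subgenome = subgenome_of(chromosome),
             span_bp = end - start + 1, stringsAsFactors = FALSE)
}

test_that("homolog pairs apply both thresholds and compute separations", {
  set.seed(30)
  s <- random_protein(120)
  loci <- mk_loci(c("g1", "g2"), c("3A", "3B"), c(1000, 5000),
                  c(1500, 5500))
  pairs <- find_homolog_pairs(c(g1 = s, g2 = s), loci)
  expect_true(pairs$is_homolog)
  expect_false(pairs$same_chromosome)
  expect_true(is.na(pairs$separation_bp))
  # same chromosome: separation between nearer ends
  loci2 <- mk_loci(c("g1", "g2"), c("3A", "3A"), c(1000, 20000),
                   c(1500, 20500))
  p2 <- find_homolog_pairs(c(g1 = s, g2 = s), loci2)
  expect_equal(p2$separation_bp, 18500)
  # ~70% identity stays below the 75% homolog threshold
  ch <- strsplit(s, "")[[1]]
  pos <- seq(1, 120, length.out = 36)
  for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  p3 <- find_homolog_pairs(c(g1 = s, g2 = paste(ch, collapse = "")), loci2)
  expect_false(p3$is_homolog)
  expect_error(find_homolog_pairs(c(g1 = s, gX = s), loci, strict = TRUE),
               "without locus")
})

test_that("tandem chaining follows the 150-kb consecutive-separation rule", {
  set.seed(31)
  s <- random_protein(150)
  # genes at 0, 100 kb, 190 kb: gaps 100 kb and ~89 kb -> one array of 3
  loci <- mk_loci(paste0("g", 1:3), "3A",
                  c(1, 100001, 190001), c(600, 100600, 190600))
  prot <- stats::setNames(rep(s, 3), paste0("g", 1:3))
  pairs <- find_homolog_pairs(prot, loci)
  dup <- classify_duplications(pairs, loci)
  expect_length(dup$tandem_arrays, 1L)
  expect_equal(dup$tandem_arrays[[1]]$members, paste0("g", 1:3))
  expect_equal(dup$tandem_arrays[[1]]$separations_bp, c(99401, 89401))
  expect_equal(nrow(dup$tandem_pairs), 2L)
  expect_true(dup$family_only)
  # two homologous genes 200 kb apart: no array
  loci2 <- mk_loci(c("g1", "g2"), "3A", c(1, 200601), c(600, 201200))
  dup2 <- classify_duplications(find_homolog_pairs(prot[1:2], loci2), loci2)
  expect_length(dup2$tandem_arrays, 0L)
  # homologs on different chromosomes: a segmental pair
  loci3 <- mk_loci(c("g1", "g2"), c("2A", "2D"), c(1, 1), c(600, 600))
  dup3 <- classify_duplications(find_homolog_pairs(prot[1:2], loci3), loci3)
  expect_equal(nrow(dup3$segmental_pairs), 1L)
})

test_that("a supplied annotation breaks arrays at intervening genes", {
  set.seed(32)
  s <- random_protein(150)
  loci <- mk_loci(c("g1", "g2"), "3A", c(1, 50001), c(600, 50600))
  prot <- stats::setNames(rep(s, 2), c("g1", "g2"))
  pairs <- find_homolog_pairs(prot, loci)
  ann <- rbind(loci, mk_loci("other1", "3A", 20000, 21000))
  dup <- classify_duplications(pairs, loci, annotation = ann)
  expect_length(dup$tandem_arrays, 0L)
  expect_false(dup$family_only)
  # without the intervening gene the array is called
  dup2 <- classify_duplications(pairs, loci, annotation = loci)
  expect_length(dup2$tandem_arrays, 1L)
})

test_that("unanchored genes are excluded from duplication calls", {
  set.seed(33)
  s <- random_protein(150)
  loci <- mk_loci(c("g1", "gU"), c("3A", "Un"), c(1, 1), c(600, 600))
  dup <- classify_duplications(
    find_homolog_pairs(stats::setNames(rep(s, 2), c("g1", "gU")), loci),
    loci)
  expect_equal(dup$unanchored, "gU")
  expect_equal(nrow(dup$segmental_pairs), 0L)
})

test_that("classification is invariant under input-order permutation and
           arrays partition their members", {
  gen <- generate_family_genome(synthetic_config(
    seed = 34, n_triads = 2, tandem_array_sizes = c(3L, 2L), n_decoys = 0))
  fam <- gen$proteome[gen$truth$members$gene_id]
  loci <- gen$loci[gen$loci$gene_id %in% names(fam), ]
  pairs <- find_homolog_pairs(fam, loci)
  dup <- classify_duplications(pairs, loci)
  perm <- sample(seq_along(fam))
  dup_p <- classify_duplications(
    find_homolog_pairs(fam[perm], loci[sample(nrow(loci)), ]),
    loci[rev(seq_len(nrow(loci))), ])
  canon <- function(d) lapply(d$tandem_arrays, `[[`, "members")
  expect_equal(canon(dup), canon(dup_p))
  members <- unlist(canon(dup))
  expect_equal(anyDuplicated(members), 0L)
  for (a in dup$tandem_arrays) {
    expect_equal(length(unique(gen$truth$members$array_id[
      match(a$members, gen$truth$members$gene_id)])), 1L)
    expect_true(all(a$separations_bp <= 150000))
  }
})

test_that("planted arrays are recovered exactly, split at gaps > 150 kb", {
  for (seed in c(41, 42, 43)) {
    gen <- generate_family_genome(synthetic_config(
      seed = seed, n_triads = 1, tandem_array_sizes = c(4L, 3L),
      n_decoys = 0))
    fam <- gen$proteome[gen$truth$members$gene_id]
    loci <- gen$loci[gen$loci$gene_id %in% names(fam), ]
    pairs <- find_homolog_pairs(fam, loci)
    dup <- classify_duplications(pairs, loci)
    # expected arrays: planted arrays split wherever a planted spacing
    # exceeds the 150-kb window
    sp <- gen$truth$array_spacings
    expected <- list()
    for (aid in unique(sp$array_id)) {
      block <- sp[sp$array_id == aid, ]
      run <- block$gene_upstream[1]
      for (i in seq_len(nrow(block))) {
        if (block$spacing_bp[i] <= 150000) {
          run <- c(run, block$gene_downstream[i])
        } else {
          if (length(run) >= 2) expected[[length(expected) + 1L]] <- run
          run <- block$gene_downstream[i]
        }
      }
      if (length(run) >= 2) expected[[length(expected) + 1L]] <- run
    }
    got <- lapply(dup$tandem_arrays, `[[`, "members")
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(expected, paste, collapse = ","))
  }
})

test_that("chromosome summaries count, span and percentage correctly", {
  loci <- mk_loci(c("g1", "g2", "g3"), c("3A", "3A", "3B"),
                  c(1000, 5000, 100), c(1500, 6000, 700))
  s <- summarize_chromosomes(loci)
  expect_equal(s$n_total, 3L)
  a3 <- s$per_chromosome[s$per_chromosome$chromosome == "3A", ]
  expect_equal(a3$count, 2L)
  expect_equal(a3$span_kb, 5)
  expect_equal(a3$pct, 66.7)
  expect_equal(sum(s$per_chromosome$pct), 100, tolerance = 0.2)
  expect_equal(s$per_group$count[s$per_group$group == "3"], 3L)
  single <- summarize_chromosomes(loci[3, ])
  expect_equal(single$per_chromosome$span_kb, 0.6)
})

test_that("homoeolog groups form across subgenomes with expansion copies
           flagged", {
  set.seed(35)
  s <- random_protein(140)
  # identical triplet on 4A/4B/4D: one complete group
  loci <- mk_loci(paste0("g", 1:3), c("4A", "4B", "4D"),
                  rep(1, 3), rep(500, 3))
  prot <- stats::setNames(rep(s, 3), paste0("g", 1:3))
  hg <- assign_homoeologs(find_homolog_pairs(prot, loci), loci)
  expect_length(hg, 1L)
  expect_true(hg[[1]]$complete)
  # B/D pair only: incomplete group
  loci2 <- mk_loci(c("g1", "g2"), c("3B", "3D"), c(1, 1), c(500, 500))
  hg2 <- assign_homoeologs(find_homolog_pairs(prot[1:2], loci2), loci2)
  expect_length(hg2, 1L)
  expect_false(hg2[[1]]$complete)
  # triad plus a tandem expansion copy on A
  gen <- generate_family_genome(synthetic_config(
    seed = 36, n_triads = 2, tandem_array_sizes = integer(0), n_decoys = 0))
  fam <- gen$proteome
  loci3 <- gen$loci
  extra <- fam[["triad1A"]]
  fam <- c(fam, triad1A2 = extra)
  loci3 <- rbind(loci3, mk_loci("triad1A2", "3A",
                                max(loci3$end_bp) + 50000,
                                max(loci3$end_bp) + 50600))
  hg3 <- assign_homoeologs(find_homolog_pairs(fam, loci3), loci3)
  expect_length(hg3, 2L)
  g1 <- hg3[[which(vapply(hg3, function(g)
    "triad1A2" %in% g$members$gene_id, TRUE))]]
  expect_true(g1$complete)
  expect_equal(sum(g1$members$expansion_copy), 1L)
})
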