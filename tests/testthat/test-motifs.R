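test_that("promoter extraction respects strand, length and contig edges", {
  set.seed(50)
  contig <- random_dna_str(10000)
  loci <- data.frame(gene_id = c("plus", "edge", "minus"),
                     chromosome = "c1",
                     start_bp = c(3000, 500, 6000),
                     end_bp = c(3500, 900, 6400),
                     strand = c("+", "+", "-"),
                     subgenome = "U", span_bp = 0,
                     stringsAsFactors = FALSE)
  pr <- extract_promoters(c(c1 = contig), loci, length = 2000)
  expect_equal(pr$seq[1], substr(contig, 1000, 2999))
  expect_equal(pr$length[1], 2000L)
  expect_false(pr$truncated[1])
  expect_equal(pr$length[2], 499L)
  expect_true(pr$truncated[2])
  # minus strand: upstream means downstream on the plus strand, reverse
  # complemented, so a planted minus-strand site reads forward
  site <- "TTGACCGGA"
  contig2 <- plant_word(contig, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(site))), 6500)
  pr2 <- extract_promoters(c(c1 = contig2), loci[3, ], length = 2000)
  # plus-strand site at 6500-6508 maps to promoter position 8400-6508+1
  expect_equal(substr(pr2$seq, 1893, 1901), site, ignore_attr = TRUE)
  expect_true(grepl(site, pr2$seq, fixed = TRUE))
  expect_error(extract_promoters(c(cX = contig), loci), "absent")
})

test_that("ZOOPS EM recovers a planted 8-mer with high site recall and
           stays quiet on random input", {
  set.seed(51)
  bg_seq <- function(n) random_protein(n)
  motif <- "WHKYRDQW"
  truth_off <- integer(30)
  seqs <- vapply(1:30, function(i) {
    s <- bg_seq(80)
    m <- strsplit(motif, "")[[1]]
    if (stats::runif(1) < 0.5) m[sample(8, 1)] <- sample(AA20, 1)
    off <- sample(1:(80 - 8), 1)
    truth_off[i] <<- off
    plant_word(s, paste(m, collapse = ""), off)
  }, "")
  names(seqs) <- paste0("s", 1:30)
  mot <- discover_motifs(seqs, max_motifs = 3, width_range = c(6, 20),
                         seed = 7)
  expect_gte(length(mot), 1L)
  m1 <- mot[[1]]
  expect_equal(m1$consensus, motif)
  hits <- m1$sites$offset == truth_off[match(m1$sites$sequence_id,
                                             names(seqs))]
  expect_gte(sum(hits) / 30, 0.9)
  # determinism under a fixed seed
  mot2 <- discover_motifs(seqs, max_motifs = 3, width_range = c(6, 20),
                          seed = 7)
  expect_identical(m1$pwm$probs, mot2[[1]]$pwm$probs)
  # negative control: purely random sequences yield no significant motif
  rnd <- vapply(1:20, function(i) bg_seq(80), "")
  names(rnd) <- paste0("r", 1:20)
  expect_length(discover_motifs(rnd, max_motifs = 5,
                                width_range = c(6, 20), seed = 7), 0L)
})

test_that("a repeated bare motif yields near one-hot columns and motifs
           never claim overlapping sites", {
  seqs <- stats::setNames(rep("MKWHRDYWQA", 12), paste0("s", 1:12))
  mot <- discover_motifs(seqs, max_motifs = 2, width_range = c(6, 10),
                         seed = 1)
  expect_gte(length(mot), 1L)
  top <- apply(mot[[1]]$pwm$probs, 2, max)
  expect_true(all(top > 0.8))
  # planted two distinct motifs: reported site sets must not overlap
  set.seed(52)
  seqs2 <- vapply(1:20, function(i) {
    s <- random_protein(90)
    s <- plant_word(s, "WHKYRDQW", 10)
    plant_word(s, "MMCPFCNN", 60)
  }, "")
  names(seqs2) <- paste0("t", 1:20)
  mot2 <- discover_motifs(seqs2, max_motifs = 2, width_range = c(6, 12),
                          seed = 2)
  expect_equal(length(mot2), 2L)
  occupied <- list()
  for (m in mot2) for (r in seq_len(nrow(m$sites))) {
    key <- m$sites$sequence_id[r]
    span <- m$sites$offset[r]:(m$sites$offset[r] + m$width - 1)
    expect_length(intersect(occupied[[key]], span), 0L)
    occupied[[key]] <- c(occupied[[key]], span)
  }
})

test_that("PWM scanning finds planted sites, equals a brute-force rescan,
           and respects reverse-complement symmetry", {
  set.seed(53)
  pw <- consensus_pwm("TGCCAGTA", "TF1")
  prom <- random_dna_str(1500)
  prom <- plant_word(prom, "TGCCAGTA", 700)
  promoters <- data.frame(gene_id = "g1", seq = prom, length = 1500,
                          truncated = FALSE, strand = "+")
  sc <- scan_pwm(promoters, list(pw), p_max = 1e-4)
  expect_true(any(sc$hits$position == 700 & sc$hits$strand == "+"))
  # brute-force rescan with an independent scorer
  sd <- asrfam:::pwm_score_distribution(pw, 1e-3)
  brute <- list()
  for (strand in c("+", "-")) {
    M <- if (strand == "+") pw$log_odds else pwm_revcomp(pw)$log_odds
    Mi <- round(M / 1e-3)
    for (j in 1:(nchar(prom) - pw$width + 1)) {
      win <- strsplit(substr(prom, j, j + pw$width - 1), "")[[1]]
      s <- 0
      for (t in seq_along(win)) s <- s + Mi[win[t], t]
      if (asrfam:::pvalue_of(sd, s) <= 1e-4)
        brute[[length(brute) + 1L]] <- c(j, strand)
    }
  }
  got <- sc$hits[order(sc$hits$position, sc$hits$strand),
                 c("position", "strand")]
  exp <- do.call(rbind, brute)
  exp <- exp[order(as.integer(exp[, 1]), exp[, 2]), , drop = FALSE]
  expect_equal(nrow(got), nrow(exp))
  expect_equal(got$position, as.integer(exp[, 1]))
  expect_equal(got$strand, exp[, 2])
  # palindromic PWM: every hit occurs on both strands at the same position
  pal <- consensus_pwm("TGACGTCA", "PAL")
  prom2 <- plant_word(random_dna_str(800), "TGACGTCA", 300)
  sc2 <- scan_pwm(data.frame(gene_id = "g1", seq = prom2, length = 800,
                             truncated = FALSE, strand = "+"),
                  list(pal), p_max = 1e-4)
  pos <- split(sc2$hits$strand, sc2$hits$position)
  expect_true(all(vapply(pos, function(s)
    setequal(s, c("+", "-")), TRUE)))
  # per-gene counts equal the grouped hit-list lengths
  expect_equal(unname(sc$counts["g1", "TF1"]),
               sum(sc$hits$gene_id == "g1" & sc$hits$tf_name == "TF1"))
})

test_that("exact DP score p-values match Monte-Carlo estimates", {
  set.seed(54)
  for (i in 1:3) {
    w <- sample(6:10, 1)
    probs <- matrix(stats::rgamma(4 * w, 1), 4,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
    probs <- sweep(probs, 2, colSums(probs), "/")
    pw <- pwm_create(probs, background = c(A = .3, C = .2, G = .2, T = .3))
    sd <- asrfam:::pwm_score_distribution(pw, 1e-3)
    thr <- asrfam:::score_threshold(sd, 0.01)
    p_exact <- asrfam:::pvalue_of(sd, thr)
    Mi <- round(pw$log_odds / 1e-3)
    draws <- matrix(sample(1:4, 1e5 * w, replace = TRUE,
                           prob = c(.3, .2, .2, .3)), ncol = w)
    sc <- numeric(1e5)
    for (t in seq_len(w)) sc <- sc + Mi[cbind(draws[, t], t)]
    p_mc <- mean(sc >= thr)
    se <- sqrt(p_exact * (1 - p_exact) / 1e5)
    expect_lt(abs(p_mc - p_exact), 3 * se + 1e-12)
  }
})

test_that("MEME minimal and JASPAR round trips preserve matrices", {
  pw <- consensus_pwm("TGCCAGTA", "TFX")
  f1 <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(pw), f1)
  back <- read_meme(f1)
  expect_equal(back[[1]]$name, "TFX")
  expect_equal(back[[1]]$probs, pw$probs, tolerance = 1e-5)
  f2 <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(list(pw), f2, scale = 1e4)
  back2 <- read_jaspar(f2, pseudocount = 0)
  expect_equal(back2[[1]]$probs, pw$probs, tolerance = 1e-3)
})
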