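# Seeded synthetic genomes with planted gene-family structure: homoeolog
# triads across the A/B/D subgenomes, tandem arrays with controlled
# spacing, shuffled decoys, promoters with planted PWM sites, and matched
# expression / qPCR tables with known effects.

GENETIC_CODE_BY_AA <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"), F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), M = "ATG",
  N = c("AAT", "AAC"), P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))

#' Configuration for the synthetic family-genome generator
#'
#' Defaults mirror the structure of the wheat ASR survey setting: three
#' subgenomes (A/B/D), homoeolog triads at high within-triad protein
#' identity, tandem arrays whose spacings straddle the 150-kb tandem
#' window, and shuffled decoys.
#'
#' @param seed Integer seed (mandatory; every generator output is a pure
#'   function of the configuration including this seed).
#' @param n_triads Number of homoeolog triads (one member on each of
#'   A, B, D).
#' @param tandem_array_sizes Integer vector; one tandem array per entry,
#'   with that many members.
#' @param tandem_spacing_range Inter-gene spacing (bp) within tandem
#'   arrays, drawn uniformly; the default straddles the 150-kb rule.
#' @param triad_identity Target pairwise protein identity within triads
#'   and arrays.
#' @param between_group_identity Target identity between different groups.
#' @param n_decoys Number of residue-shuffled decoy proteins.
#' @param protein_length Family protein length (residues).
#' @param intron_length_range Range of planted intron lengths (bp).
#' @param solo_spacing_range Spacing (bp) between non-tandem neighbours on
#'   a chromosome; the default keeps them well beyond the tandem window.
#' @param chromosome_group Numeric chromosome-group label used for the
#'   family chromosomes.
#' @param promoter_pwms Optional list of DNA [pwm_create()] objects whose
#'   consensus sites are planted in every family promoter.
#' @param sites_per_promoter Planted sites per promoter per PWM.
#' @param members Optional explicit member table (data frame `gene_id`,
#'   `group`, `chromosome`, `array_id` (NA for non-tandem), `identical`
#'   flag per group); overrides the counts above.
#' @param expr_sd Log-scale standard deviation of synthetic FPKM values.
#' @param qpcr_ddct Optional data frame `gene_id`, `condition`,
#'   `timepoint_h`, `tissue`, `ddct` of planted qPCR effects (unlisted
#'   cells default to 0).
#' @param qpcr_rep_sd Replicate noise s.d. on dCt.
#' @param qpcr_n_rep Biological replicates per cell.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             n_triads = 5L,
                             tandem_array_sizes = c(3L, 2L),
                             tandem_spacing_range = c(5e3, 2e5),
                             triad_identity = 0.96,
                             between_group_identity = 0.45,
                             n_decoys = 50L,
                             protein_length = 150L,
                             intron_length_range = c(60L, 400L),
                             solo_spacing_range = c(2.5e5, 4e5),
                             chromosome_group = "3",
                             promoter_pwms = NULL,
                             sites_per_promoter = 1L,
                             members = NULL,
                             expr_sd = 0.3,
                             qpcr_ddct = NULL,
                             qpcr_rep_sd = 0.2,
                             qpcr_n_rep = 3L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_triads >= 0, all(tandem_array_sizes >= 2),
            triad_identity > 0, triad_identity <= 1,
            between_group_identity > 0, between_group_identity < 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic multi-subgenome genome carrying a planted family
#'
#' Family proteins are evolved from group ancestors by independent per-site
#' JTT substitution calibrated to the configured identity targets; genes
#' are back-translated, split into two exons by a planted intron, and
#' placed on the A/B/D chromosomes with homoeolog triads at matched
#' positions and tandem arrays at the configured spacings. Decoys are
#' residue-shuffled family proteins. Truth tables record every planted
#' triad, array (with spacings), group and motif site.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `genome` (named contig sequences), `proteome`
#'   (family + decoys), `cds`, `loci` (family + decoy loci), `structures`
#'   (planted exon structures), `promoter_truth` (planted PWM sites),
#'   `truth` (list: `members`, `triads`, `arrays`, `groups`).
#' @export
generate_family_genome <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  local_seed(cfg$seed, generate_family_genome_impl(cfg))
}

generate_family_genome_impl <- function(cfg) {
  sgs <- c("A", "B", "D")
  members <- cfg$members
  if (is.null(members)) {
    rows <- list()
    for (i in seq_len(cfg$n_triads)) {
      for (s in sgs)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("triad%d%s", i, s),
          group = sprintf("T%d", i),
          chromosome = paste0(cfg$chromosome_group, s),
          array_id = NA_character_, identical = FALSE,
          stringsAsFactors = FALSE)
    }
    for (a in seq_along(cfg$tandem_array_sizes)) {
      chr <- paste0(cfg$chromosome_group, sgs[(a - 1L) %% 3L + 1L])
      for (k in seq_len(cfg$tandem_array_sizes[a]))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("array%d_%d", a, k),
          group = sprintf("A%d", a),
          chromosome = chr,
          array_id = sprintf("array%d", a), identical = FALSE,
          stringsAsFactors = FALSE)
    }
    members <- do.call(rbind, rows)
  }
  groups <- unique(members$group)

  # between-group divergence: each ancestor evolved from a common root so
  # that inter-group identity hits the configured target
  t_between <- jtt_time_for_identity(cfg$between_group_identity)
  t_within <- if (cfg$triad_identity >= 1) 0 else
    jtt_time_for_identity(cfg$triad_identity)
  root <- jtt_evolve(n_sites = cfg$protein_length, t = 0)
  ancestors <- lapply(groups, function(g)
    jtt_evolve(t = t_between / 2, ancestor = root))
  names(ancestors) <- groups

  proteins <- character(nrow(members))
  for (i in seq_len(nrow(members))) {
    g <- members$group[i]
    ident <- isTRUE(members$identical[i])
    proteins[i] <- if (ident || t_within == 0) ancestors[[g]]
      else jtt_evolve(t = t_within / 2, ancestor = ancestors[[g]])
  }
  names(proteins) <- members$gene_id

  # back-translate and plant one intron
  cds <- vapply(proteins, function(p) {
    aa <- strsplit(p, "", fixed = TRUE)[[1]]
    paste0(paste(vapply(aa, function(a) {
      cod <- GENETIC_CODE_BY_AA[[a]]
      cod[sample.int(length(cod), 1L)]
    }, ""), collapse = ""), "TAA")
  }, "")
  structures <- vector("list", nrow(members))
  gene_seqs <- character(nrow(members))
  for (i in seq_len(nrow(members))) {
    cd <- cds[i]
    n_cod <- nchar(cd) / 3
    cut <- 3 * sample(seq(2L, n_cod - 2L), 1L)   # codon-boundary split
    ilen <- sample(seq(cfg$intron_length_range[1],
                       cfg$intron_length_range[2]), 1L)
    intron <- random_dna(ilen)
    exon1 <- substr(cd, 1, cut); exon2 <- substr(cd, cut + 1, nchar(cd))
    gene_seqs[i] <- paste0(exon1, intron, exon2)
    structures[[i]] <- list(
      gene_id = members$gene_id[i], transcript_id = members$gene_id[i],
      strand = "+",
      exons = cbind(start = c(1, cut + ilen + 1),
                    end = c(cut, cut + ilen + nchar(exon2))),
      introns = cbind(start = cut + 1, end = cut + ilen),
      utr5_bp = 0, utr3_bp = 0)
  }

  # decoys: residue-shuffled family proteins (non-homologous by design)
  decoys <- character(cfg$n_decoys)
  if (cfg$n_decoys > 0) {
    for (k in seq_len(cfg$n_decoys)) {
      src <- strsplit(proteins[[(k - 1L) %% length(proteins) + 1L]], "",
                      fixed = TRUE)[[1]]
      decoys[k] <- paste(sample(src), collapse = "")
    }
    names(decoys) <- sprintf("decoy%03d", seq_len(cfg$n_decoys))
  }

  # placement: per chromosome in member order; tandem arrays contiguous
  # with planted spacings, everything else far apart
  promoter_len <- 2000L
  margin <- promoter_len + 1000L
  chroms <- unique(members$chromosome)
  loci <- list(); spacings_truth <- list()
  chrom_seq <- stats::setNames(vector("list", length(chroms)), chroms)
  for (chr in chroms) {
    idx <- which(members$chromosome == chr)
    parts <- list(random_dna(margin))
    cursor <- margin
    prev_array <- NA_character_
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      if (ii > 1L) {
        same_array <- !is.na(members$array_id[i]) &&
          identical(members$array_id[i], prev_array)
        gap <- if (same_array)
          round(stats::runif(1, cfg$tandem_spacing_range[1],
                             cfg$tandem_spacing_range[2]))
        else
          round(stats::runif(1, cfg$solo_spacing_range[1],
                             cfg$solo_spacing_range[2]))
        if (same_array)
          spacings_truth[[length(spacings_truth) + 1L]] <- data.frame(
            array_id = members$array_id[i],
            gene_upstream = members$gene_id[idx[ii - 1L]],
            gene_downstream = members$gene_id[i],
            spacing_bp = gap, stringsAsFactors = FALSE)
        parts[[length(parts) + 1L]] <- random_dna(gap)
        cursor <- cursor + gap
      }
      start <- cursor + 1L
      parts[[length(parts) + 1L]] <- gene_seqs[i]
      cursor <- cursor + nchar(gene_seqs[i])
      loci[[length(loci) + 1L]] <- data.frame(
        gene_id = members$gene_id[i], chromosome = chr,
        start_bp = start, end_bp = cursor, strand = "+",
        subgenome = subgenome_of(chr),
        span_bp = cursor - start + 1, stringsAsFactors = FALSE)
      prev_array <- members$array_id[i]
    }
    parts[[length(parts) + 1L]] <- random_dna(1000L)
    chrom_seq[[chr]] <- paste(parts, collapse = "")
  }
  loci <- do.call(rbind, loci)

  # decoy loci on a separate chromosome, widely spaced
  if (cfg$n_decoys > 0) {
    dchr <- paste0("9", sgs[1])
    parts <- list(random_dna(margin)); cursor <- margin
    dl <- list()
    for (k in seq_len(cfg$n_decoys)) {
      dlen <- 3L * nchar(decoys[k])
      start <- cursor + 1L
      parts[[length(parts) + 1L]] <- random_dna(dlen)
      cursor <- cursor + dlen
      dl[[k]] <- data.frame(gene_id = names(decoys)[k], chromosome = dchr,
                            start_bp = start, end_bp = cursor,
                            strand = "+", subgenome = subgenome_of(dchr),
                            span_bp = dlen, stringsAsFactors = FALSE)
      gap <- round(stats::runif(1, 5e3, 2e4))
      parts[[length(parts) + 1L]] <- random_dna(gap)
      cursor <- cursor + gap
    }
    chrom_seq[[dchr]] <- paste(parts, collapse = "")
    loci <- rbind(loci, do.call(rbind, dl))
  }

  # plant PWM consensus sites in family promoters (overwrite background)
  promoter_truth <- list()
  if (!is.null(cfg$promoter_pwms)) {
    for (i in seq_len(nrow(members))) {
      li <- loci[loci$gene_id == members$gene_id[i], ]
      chr <- li$chromosome
      for (p in cfg$promoter_pwms) {
        cons <- pwm_consensus(p)
        for (s in seq_len(cfg$sites_per_promoter)) {
          off <- sample.int(promoter_len - nchar(cons) + 1L, 1L)
          abs_start <- li$start_bp - promoter_len + off - 1L
          chrom_seq[[chr]] <- paste0(
            substr(chrom_seq[[chr]], 1, abs_start - 1), cons,
            substr(chrom_seq[[chr]], abs_start + nchar(cons),
                   nchar(chrom_seq[[chr]])))
          promoter_truth[[length(promoter_truth) + 1L]] <- data.frame(
            gene_id = li$gene_id, tf_name = p$name, position = off,
            strand = "+", site = cons, stringsAsFactors = FALSE)
        }
      }
    }
  }

  triads <- members[!is.na(members$chromosome) & is.na(members$array_id), ,
                    drop = FALSE]
  triad_tab <- do.call(rbind, lapply(split(triads$gene_id, triads$group),
                                     function(ids)
    data.frame(group = NA, members = paste(sort(ids), collapse = ","),
               n = length(ids))))
  arrays <- split(members$gene_id[!is.na(members$array_id)],
                  members$array_id[!is.na(members$array_id)])

  list(genome = unlist(chrom_seq),
       proteome = c(proteins, decoys),
       cds = cds,
       loci = loci,
       structures = structures,
       promoter_truth = if (length(promoter_truth) > 0)
         do.call(rbind, promoter_truth) else NULL,
       truth = list(members = members,
                    groups = stats::setNames(members$group,
                                             members$gene_id),
                    triads = triad_tab,
                    arrays = arrays,
                    array_spacings = if (length(spacings_truth) > 0)
                      do.call(rbind, spacings_truth) else NULL))
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write a synthetic genome bundle to standard files
#'
#' Emits `genome.fasta`, `proteome.fasta`, `cds.fasta`, `annotation.gff3`
#' and the truth tables as TSV under `dir`.
#'
#' @param gen Output of [generate_family_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_genome <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(gen$genome, file.path(dir, "genome.fasta"))
  write_fasta(gen$proteome, file.path(dir, "proteome.fasta"))
  write_fasta(gen$cds, file.path(dir, "cds.fasta"))
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(gen$loci))) {
    l <- gen$loci[i, ]
    lines <- c(lines, sprintf(
      "%s\tasrfam\tgene\t%.0f\t%.0f\t.\t%s\t.\tID=%s",
      l$chromosome, l$start_bp, l$end_bp, l$strand, l$gene_id))
    st <- Filter(function(s) identical(s$gene_id, l$gene_id),
                 gen$structures)
    if (length(st) == 1L) {
      s <- st[[1]]
      lines <- c(lines, sprintf(
        "%s\tasrfam\tmRNA\t%.0f\t%.0f\t.\t%s\t.\tID=%s.1;Parent=%s",
        l$chromosome, l$start_bp, l$end_bp, l$strand, l$gene_id,
        l$gene_id))
      for (e in seq_len(nrow(s$exons)))
        lines <- c(lines, sprintf(
          "%s\tasrfam\texon\t%.0f\t%.0f\t.\t%s\t.\tID=%s.1.exon%d;Parent=%s.1",
          l$chromosome, l$start_bp + s$exons[e, "start"] - 1,
          l$start_bp + s$exons[e, "end"] - 1, l$strand, l$gene_id, e,
          l$gene_id))
    }
  }
  writeLines(lines, file.path(dir, "annotation.gff3"))
  utils::write.table(gen$truth$members,
                     file.path(dir, "truth_members.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(gen$promoter_truth))
    utils::write.table(gen$promoter_truth,
                       file.path(dir, "truth_promoter_sites.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Generate a synthetic tissue-expression matrix with planted group design
#'
#' FPKM values are log-normal around per-group per-condition means, with
#' optional planted tissue-specific zeros, emulating the group-structured
#' tissue profiles seen in gene-family RNA-seq compendia.
#'
#' @param cfg A [synthetic_config()].
#' @param gene_groups Named character vector gene_id -> group; defaults to
#'   two groups of 20 genes.
#' @param group_means Named list group -> named numeric vector of log-scale
#'   means per condition; conditions default to the 15 tissue_stage labels
#'   of the wheat compendium layout.
#' @param zero_pattern Named list group -> condition labels forced to zero.
#' @return List with `fpkm` (matrix genes x conditions) and `truth`
#'   (the design used).
#' @export
generate_expression <- function(cfg, gene_groups = NULL,
                                group_means = NULL, zero_pattern = NULL) {
  conditions <- c("grain_Z71", "grain_Z75", "grain_Z85",
                  "leaf_Z10", "leaf_Z23", "leaf_Z71",
                  "root_Z10", "root_Z13", "root_Z39",
                  "spike_Z32", "spike_Z39", "spike_Z65",
                  "stem_Z30", "stem_Z32", "stem_Z65")
  if (is.null(gene_groups)) {
    gene_groups <- stats::setNames(rep(c("G1", "G2"), each = 20L),
                                   sprintf("g%03d", 1:40))
  }
  groups <- unique(gene_groups)
  if (is.null(group_means)) {
    group_means <- lapply(seq_along(groups), function(gi) {
      mu <- rep(1, length(conditions))
      names(mu) <- conditions
      pref <- c("leaf", "root", "stem", "grain", "spike")[
        (gi - 1L) %% 5L + 1L]
      mu[grepl(paste0("^", pref), conditions)] <- 4
      mu
    })
    names(group_means) <- groups
  }
  local_seed(cfg$seed + 1L, {
    fpkm <- t(vapply(names(gene_groups), function(g) {
      mu <- group_means[[gene_groups[[g]]]][conditions]
      x <- exp(stats::rnorm(length(conditions), mean = mu,
                            sd = cfg$expr_sd))
      if (!is.null(zero_pattern)) {
        zp <- zero_pattern[[gene_groups[[g]]]]
        if (!is.null(zp)) x[conditions %in% zp] <- 0
      }
      x
    }, numeric(length(conditions))))
    colnames(fpkm) <- conditions
    list(fpkm = fpkm,
         truth = list(gene_groups = gene_groups,
                      group_means = group_means,
                      zero_pattern = zero_pattern))
  })
}

#' Generate a synthetic qPCR Ct table with planted ddCt effects
#'
#' Emulates the stress-treatment design of the wheat survey: NaCl at 6 and
#' 24 h, PEG at 6 and 48 h, leaf and root tissue, `qpcr_n_rep` biological
#' replicates, plus a per-tissue untreated control. Control dCt per gene is
#' drawn around a gene-level mean; treated dCt adds the planted ddCt and
#' replicate noise.
#'
#' @param cfg A [synthetic_config()].
#' @param gene_ids Gene ids; default `g01..g10`.
#' @return List with `records` (qPCR data frame: `gene_id`, `condition`,
#'   `timepoint_h`, `tissue`, `replicate`, `ct_target`, `ct_reference`)
#'   and `truth` (planted ddCt per cell).
#' @export
generate_qpcr <- function(cfg, gene_ids = sprintf("g%02d", 1:10)) {
  design <- rbind(
    data.frame(condition = "NaCl", timepoint_h = c(6, 24)),
    data.frame(condition = "PEG", timepoint_h = c(6, 48)))
  tissues <- c("leaf", "root")
  planted <- cfg$qpcr_ddct
  ddct_of <- function(g, cond, tp, tis) {
    if (is.null(planted)) return(0)
    sel <- planted$gene_id == g & planted$condition == cond &
      planted$timepoint_h == tp & planted$tissue == tis
    if (any(sel)) planted$ddct[which(sel)[1]] else 0
  }
  local_seed(cfg$seed + 2L, {
    mu_g <- stats::setNames(stats::rnorm(length(gene_ids), 2, 1), gene_ids)
    rows <- list(); truth <- list()
    for (g in gene_ids) for (tis in tissues) {
      for (r in seq_len(cfg$qpcr_n_rep)) {
        ref <- stats::rnorm(1, 20, 0.05)
        dct <- mu_g[[g]] + stats::rnorm(1, 0, cfg$qpcr_rep_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, condition = "control", timepoint_h = 0,
          tissue = tis, replicate = r, ct_target = ref + dct,
          ct_reference = ref, stringsAsFactors = FALSE)
      }
      for (d in seq_len(nrow(design))) {
        dd <- ddct_of(g, design$condition[d], design$timepoint_h[d], tis)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_id = g, condition = design$condition[d],
          timepoint_h = design$timepoint_h[d], tissue = tis, ddct = dd,
          stringsAsFactors = FALSE)
        for (r in seq_len(cfg$qpcr_n_rep)) {
          ref <- stats::rnorm(1, 20, 0.05)
          dct <- mu_g[[g]] + dd + stats::rnorm(1, 0, cfg$qpcr_rep_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, condition = design$condition[d],
            timepoint_h = design$timepoint_h[d], tissue = tis,
            replicate = r, ct_target = ref + dct, ct_reference = ref,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(records = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' A synthetic configuration shaped like the wheat ASR family
#'
#' Thirty-three genes in six groups with the published family's structure:
#' a seven-member group of byte-identical proteins clustered in a tandem
#' array on 3A (plus one unanchored copy), homoeolog triads on chromosome
#' groups 2, 3 and 4, a B/D-only pair, and a ten-member main group. The
#' member names follow the published naming so structural expectations can
#' be phrased directly; all sequences are synthetic stand-ins, not the real
#' wheat proteins.
#'
#' @param seed Integer seed.
#' @return A [synthetic_config()] whose `members` table encodes the family
#'   shape.
#' @export
paper_shaped_config <- function(seed) {
  mk <- function(gene_id, group, chromosome, array_id = NA_character_,
                 identical = FALSE)
    data.frame(gene_id = gene_id, group = group, chromosome = chromosome,
               array_id = array_id, identical = identical,
               stringsAsFactors = FALSE)
  members <- rbind(
    # group I: triads 1 and 2 plus the 3-series, on chromosome group 3
    mk("TaASR1A", "I", "3A", "arr3A_I"), mk("TaASR2A", "I", "3A",
                                            "arr3A_I"),
    mk("TaASR3A1", "I", "3A", "arr3A_I"), mk("TaASR3A2", "I", "3A",
                                             "arr3A_I"),
    mk("TaASR1B", "I", "3B", "arr3B_I"), mk("TaASR2B", "I", "3B",
                                            "arr3B_I"),
    mk("TaASR3B", "I", "3B"),
    mk("TaASR1D", "I", "3D", "arr3D_I"), mk("TaASR2D", "I", "3D",
                                            "arr3D_I"),
    mk("TaASR3D", "I", "3D"),
    # group II: 4A/4B/4D triad
    mk("TaASR4A", "II", "4A"), mk("TaASR4B", "II", "4B"),
    mk("TaASR4D", "II", "4D"),
    # group III: 2A/2B/2D triad
    mk("TaASR5A", "III", "2A"), mk("TaASR5B", "III", "2B"),
    mk("TaASR5D", "III", "2D"),
    # group IV: 6A/6B and the 6D-7D tandem
    mk("TaASR6A", "IV", "3A"), mk("TaASR6B", "IV", "3B"),
    mk("TaASR6D", "IV", "3D", "arr3D_IV"),
    mk("TaASR7D1", "IV", "3D", "arr3D_IV"),
    mk("TaASR7D2", "IV", "3D", "arr3D_IV"),
    # group V: 8B/8D pair (no A member) plus the 9-series
    mk("TaASR8B", "V", "3B", "arr3B_V"), mk("TaASR9B", "V", "3B",
                                            "arr3B_V"),
    mk("TaASR8D", "V", "3D", "arr3D_V"), mk("TaASR9D", "V", "3D",
                                            "arr3D_V"),
    mk("TaASR9A", "V", "3A"),
    # group VI: seven identical copies, six tandem on 3A + one unanchored
    mk("TaASR10A1", "VI", "3A", "arr3A_VI", TRUE),
    mk("TaASR10A2", "VI", "3A", "arr3A_VI", TRUE),
    mk("TaASR10A3", "VI", "3A", "arr3A_VI", TRUE),
    mk("TaASR10A4", "VI", "3A", "arr3A_VI", TRUE),
    mk("TaASR10A5", "VI", "3A", "arr3A_VI", TRUE),
    mk("TaASR10A6", "VI", "3A", "arr3A_VI", TRUE),
    mk("TaASR10U", "VI", "Un", NA_character_, TRUE))
  synthetic_config(seed = seed, members = members,
                   tandem_spacing_range = c(5e3, 1.4e5),
                   n_decoys = 20L)
}
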