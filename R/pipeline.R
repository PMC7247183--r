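#' Default pipeline configuration
#'
#' Thresholds default to the survey's stated values: family-search E-value
#' 1e-10 with a complete ABA/WDS-style domain, homolog calls at E < 1e-20
#' and identity > 75%, a 150-kb tandem window, 2000-bp promoters, motif
#' widths 6-50 with at most 20 motifs, and 1000 bootstrap replicates.
#'
#' @param ... Overrides for any field (input paths: `proteome`,
#'   `seed_alignment`, `genome`, `gff3`, `locus_table`, `pwms`,
#'   `expression`, `qpcr`; plus `outdir`, `seed` and the thresholds).
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    proteome = NULL, seed_alignment = NULL, genome = NULL, gff3 = NULL,
    locus_table = NULL, pwms = NULL, expression = NULL, qpcr = NULL,
    outdir = tempfile("asrfam_run_"), seed = 1L,
    family_evalue = 1e-10, min_domain_span = 0.8,
    homolog_evalue = 1e-20, identity_min = 75,
    tandem_window_bp = 150000, promoter_bp = 2000,
    motif_width = c(6L, 50L), max_motifs = 20L,
    scan_p_max = 1e-4, bootstrap_reps = 1000L, groups_k = 6L)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0L)
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Run the full family-characterization pipeline
#'
#' Executes, in order: family identification (profile search), protein
#' physicochemistry, phylogeny and grouping, duplication classification and
#' chromosome summaries, gene structure, motif discovery, promoter TFBS
#' scanning, tissue expression, and qPCR quantification. A stage is skipped
#' (and marked so) when its inputs are absent; the proteome plus either a
#' seed alignment or a locus table is mandatory. Per-stage tables are
#' written as TSV under `cfg$outdir` along with a JSON run manifest
#' recording the seed and every threshold used.
#'
#' @param cfg Configuration from [pipeline_config()], or a path to a YAML
#'   file with the same fields.
#' @return Invisibly, a list of per-stage results (`NULL` for skipped
#'   stages) plus `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- pipeline_config(yaml::read_yaml(cfg))
  if (is.null(cfg$proteome)) stop("mandatory input missing: proteome")
  if (is.null(cfg$seed_alignment) && is.null(cfg$locus_table))
    stop("need a seed alignment (identification) or a locus table")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  tsv <- function(df, name) {
    utils::write.table(df, file.path(cfg$outdir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  proteome <- read_fasta(cfg$proteome, "protein")

  # --- identify ---------------------------------------------------------
  family <- proteome
  if (!is.null(cfg$seed_alignment)) {
    seed_aln <- read_fasta(cfg$seed_alignment, "protein")
    profile <- build_profile(seed_aln)
    hits <- identify_family(proteome, profile,
                            evalue_max = cfg$family_evalue,
                            min_span_frac = cfg$min_domain_span)
    tsv(hits, "family_hits")
    kept_members <- unlist(strsplit(hits$members[hits$kept], ","))
    family <- proteome[names(proteome) %in% kept_members]
    res$identify <- hits
  }

  # --- protparam --------------------------------------------------------
  pp <- lapply(names(family), function(id)
    compute_protparam(family[[id]], gene_id = id))
  pp_df <- do.call(rbind, lapply(pp, function(r)
    data.frame(gene_id = r$gene_id, aa_len = r$aa_len,
               mw_kda = r$mw_kda, pi = r$pi_2dp, gravy = r$gravy_3dp)))
  tsv(pp_df, "protparam")
  res$protparam <- list(table = pp_df, summary = summarize_family(pp))

  # --- phylo ------------------------------------------------------------
  if (length(family) >= 3L) {
    msa <- progressive_align(family)
    tree <- bootstrap_supports(msa, n_reps = cfg$bootstrap_reps,
                               seed = cfg$seed)
    ape::write.tree(tree, file.path(cfg$outdir, "family_nj.nwk"))
    # cutting internal edges can yield at most (leaves - 2) clades
    groups <- extract_groups(tree, k = max(1L, min(cfg$groups_k,
                                                   length(family) - 2L)))
    tsv(groups, "groups")
    res$phylo <- list(msa = msa, tree = tree, groups = groups)
  }

  # --- duplication ------------------------------------------------------
  loci <- NULL
  if (!is.null(cfg$locus_table)) {
    loci <- read_family_table(cfg$locus_table)
  } else if (!is.null(cfg$gff3)) {
    loci <- read_gff3(cfg$gff3)$loci
  }
  if (!is.null(loci)) {
    fam_loci <- loci[loci$gene_id %in% names(family), , drop = FALSE]
    pairs <- find_homolog_pairs(family, fam_loci,
                                evalue_max = cfg$homolog_evalue,
                                identity_min = cfg$identity_min,
                                strict = FALSE)
    dup <- classify_duplications(pairs, fam_loci,
                                 tandem_window_bp = cfg$tandem_window_bp)
    tsv(pairs, "homolog_pairs")
    if (!is.null(dup$tandem_pairs)) tsv(dup$tandem_pairs, "tandem_pairs")
    tsv(dup$segmental_pairs, "segmental_pairs")
    chrsum <- summarize_chromosomes(fam_loci)
    tsv(chrsum$per_chromosome, "chromosome_summary")
    res$duplication <- list(pairs = pairs, duplications = dup,
                            chromosomes = chrsum,
                            homoeologs = assign_homoeologs(pairs, fam_loci))
  }

  # --- structure --------------------------------------------------------
  if (!is.null(cfg$gff3)) {
    g3 <- read_gff3(cfg$gff3)
    st <- do.call(rbind, lapply(g3$structures, function(s)
      data.frame(gene_id = s$gene_id, transcript_id = s$transcript_id,
                 exon_count = nrow(s$exons),
                 intron_count = nrow(s$introns))))
    tsv(st, "gene_structure")
    res$structure <- st
  }

  # --- motifs -----------------------------------------------------------
  if (length(family) >= 2L) {
    mot <- discover_motifs(family, max_motifs = cfg$max_motifs,
                           width_range = cfg$motif_width, seed = cfg$seed)
    if (length(mot) > 0L) {
      write_meme(lapply(mot, `[[`, "pwm"),
                 file.path(cfg$outdir, "motifs.meme"))
      tsv(do.call(rbind, lapply(seq_along(mot), function(i)
        cbind(motif = i, width = mot[[i]]$width,
              consensus = mot[[i]]$consensus, mot[[i]]$sites))),
        "motif_sites")
    }
    res$motifs <- mot
  }

  # --- tfbs -------------------------------------------------------------
  if (!is.null(cfg$genome) && !is.null(cfg$pwms) && !is.null(loci)) {
    genome <- read_fasta(cfg$genome, "dna")
    pwms <- read_jaspar(cfg$pwms)
    fam_loci <- loci[loci$gene_id %in% names(family), , drop = FALSE]
    fam_loci <- fam_loci[fam_loci$chromosome %in% names(genome), ,
                         drop = FALSE]
    prom <- extract_promoters(genome, fam_loci, length = cfg$promoter_bp)
    scan <- scan_pwm(prom, pwms, p_max = cfg$scan_p_max)
    tsv(scan$hits, "tfbs_hits")
    res$tfbs <- scan
  }

  # --- expression -------------------------------------------------------
  if (!is.null(cfg$expression)) {
    em <- as.matrix(utils::read.delim(cfg$expression, row.names = 1L,
                                      check.names = FALSE))
    hs <- transform_fpkm(em)
    tsv(data.frame(gene_id = rownames(em)[hs$row_order],
                   hs$transformed[hs$row_order, , drop = FALSE],
                   check.names = FALSE), "expression_log2")
    res$expression <- hs
  }

  # --- qpcr -------------------------------------------------------------
  if (!is.null(cfg$qpcr)) {
    qr <- utils::read.csv(cfg$qpcr, stringsAsFactors = FALSE)
    rel <- ddct_fold_change(qr)
    calls <- call_stress_response(rel)
    tsv(calls$calls, "qpcr_relative_expression")
    tsv(calls$induced_counts, "qpcr_induced_counts")
    res$qpcr <- calls
  }

  manifest <- list(
    package = "asrfam",
    version = as.character(utils::packageVersion("asrfam")),
    seed = cfg$seed,
    thresholds = cfg[c("family_evalue", "min_domain_span", "homolog_evalue",
                       "identity_min", "tandem_window_bp", "promoter_bp",
                       "motif_width", "max_motifs", "scan_p_max",
                       "bootstrap_reps", "groups_k")],
    inputs = Filter(Negate(is.null),
                    cfg[c("proteome", "seed_alignment", "genome", "gff3",
                          "locus_table", "pwms", "expression", "qpcr")]),
    stages_run = names(res))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
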