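#' Prepare an FPKM matrix for heatmap display
#'
#' Applies the elementwise `log2(FPKM + 1)` transform and orders rows by
#' average-linkage hierarchical clustering on Euclidean distances of the
#' transformed rows (the standard `hclust` leaf order, which breaks ties
#' toward the lower original index). Columns keep their input order.
#'
#' @param m Numeric matrix, genes x conditions, FPKM values (>= 0).
#' @param linkage Agglomeration method for the row dendrogram.
#' @return List with `transformed` (matrix), `row_order` (permutation of
#'   row indices), `col_order`, `dendrogram` (`hclust` object or `NULL`
#'   for single-row input).
#' @export
transform_fpkm <- function(m, linkage = "average") {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("non-finite FPKM value")
  if (any(m < 0)) stop("negative FPKM value")
  tr <- log2(m + 1)
  if (nrow(tr) > 1L) {
    hc <- stats::hclust(stats::dist(tr), method = linkage)
    row_order <- hc$order
  } else {
    hc <- NULL
    row_order <- 1L
  }
  list(transformed = tr, row_order = row_order,
       col_order = seq_len(ncol(tr)), dendrogram = hc)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = ct_target - ct_reference`; per cell
#' (gene x condition x timepoint x tissue), `ddCt` is the difference of
#' replicate-mean dCt between the treated cell and the control cell of the
#' same gene and tissue, and `fold_change = 2^-ddCt`. P-values come from a
#' two-sided Welch t-test on the replicate dCt values (treated vs control);
#' a pooled-variance Student test is available via `var_equal = TRUE`.
#'
#' @param records Data frame with columns `gene_id`, `condition`,
#'   `timepoint_h`, `tissue`, `replicate`, `ct_target`, `ct_reference`.
#' @param control_label Condition label of the untreated control.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Data frame `gene_id`, `condition`, `timepoint_h`, `tissue`,
#'   `n_treated`, `n_control`, `ddct`, `fold_change`, `p_value`; control
#'   cells appear with `fold_change = 1` and `p_value = NA`.
#' @export
ddct_fold_change <- function(records, control_label = "control",
                             var_equal = FALSE) {
  need <- c("gene_id", "condition", "timepoint_h", "tissue", "replicate",
            "ct_target", "ct_reference")
  if (!all(need %in% names(records)))
    stop("qPCR records missing column(s): ",
         paste(setdiff(need, names(records)), collapse = ", "))
  if (any(records$ct_target <= 0 | records$ct_target >= 45 |
            records$ct_reference <= 0 | records$ct_reference >= 45))
    stop("Ct values must lie in (0, 45)")
  records$dct <- records$ct_target - records$ct_reference
  cells <- unique(records[c("gene_id", "condition", "timepoint_h",
                            "tissue")])
  ctrl_of <- function(gene, tissue) {
    x <- records[records$gene_id == gene & records$tissue == tissue &
                   records$condition == control_label, , drop = FALSE]
    if (nrow(x) == 0L)
      stop("missing control cell for gene ", gene, ", tissue ", tissue)
    x$dct
  }
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    tr <- records[records$gene_id == cl$gene_id &
                    records$condition == cl$condition &
                    records$timepoint_h == cl$timepoint_h &
                    records$tissue == cl$tissue, , drop = FALSE]
    if (nrow(tr) < 2L)
      stop("fewer than 2 replicates for cell ", cl$gene_id, "/",
           cl$condition, "/", cl$timepoint_h, "h/", cl$tissue)
    if (cl$condition == control_label) {
      return(cbind(cl, data.frame(n_treated = nrow(tr),
                                  n_control = nrow(tr), ddct = 0,
                                  fold_change = 1, p_value = NA_real_)))
    }
    ctrl <- ctrl_of(cl$gene_id, cl$tissue)
    ddct <- mean(tr$dct) - mean(ctrl)
    p <- tryCatch(stats::t.test(tr$dct, ctrl, var.equal = var_equal)$p.value,
                  error = function(e) NA_real_)
    cbind(cl, data.frame(n_treated = nrow(tr), n_control = length(ctrl),
                         ddct = ddct, fold_change = 2^(-ddct), p_value = p))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call per-cell stress responses from relative-expression results
#'
#' A cell is `up` when `fold_change > 1` and `p <= alpha`, `down` when
#' `fold_change < 1` and `p <= alpha`, otherwise `ns`. Also reports the
#' count of induced (up) genes per condition x timepoint x tissue cell.
#'
#' @param results Output of [ddct_fold_change()].
#' @param alpha Significance level.
#' @return List with `calls` (the input plus a `direction` column) and
#'   `induced_counts` (data frame `condition`, `timepoint_h`, `tissue`,
#'   `n_up`, `n_down`).
#' @export
call_stress_response <- function(results, alpha = 0.05) {
  dir <- rep("ns", nrow(results))
  sig <- !is.na(results$p_value) & results$p_value <= alpha
  dir[sig & results$fold_change > 1] <- "up"
  dir[sig & results$fold_change < 1] <- "down"
  results$direction <- dir
  cells <- unique(results[c("condition", "timepoint_h", "tissue")])
  counts <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    sel <- results$condition == cl$condition &
      results$timepoint_h == cl$timepoint_h & results$tissue == cl$tissue
    cbind(cl, data.frame(n_up = sum(dir[sel] == "up"),
                         n_down = sum(dir[sel] == "down")))
  }))
  rownames(counts) <- NULL
  list(calls = results, induced_counts = counts)
}
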