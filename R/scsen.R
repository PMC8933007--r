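#' Library-size normalize and log-transform single-cell counts
#'
#' Scales each cell to the median library size and applies `log1p`.  This
#' is the monotone normalized scale the scoring functions operate on; it
#' deliberately is not a variance-stabilizing transform.
#'
#' @param counts Gene-by-cell count matrix (dense or sparse).
#' @return Dense normalized matrix of the same shape.
#' @export
normalize_cells <- function(counts) {
  m <- as.matrix(counts)
  lib <- colSums(m)
  if (any(lib == 0)) stop("cell(s) with zero total counts")
  log1p(sweep(m, 2L, median(lib) / lib, `*`))
}

#' Control-matched module score per cell
#'
#' Scores each cell for a gene program as the mean normalized expression of
#' the program genes minus the mean over a matched control set.  Controls
#' are drawn per program gene from the same average-expression bin
#' (`n_bins` equal-count bins over all genes), `n_ctrl` genes per program
#' gene, without replacement within a bin (a bin smaller than `n_ctrl`
#' contributes all its genes); the drawn controls are pooled uniquely.
#' Uses the current R RNG state.
#'
#' @param expr Normalized gene-by-cell matrix (see [normalize_cells()]).
#' @param gene_set Character vector of program genes.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Controls drawn per program gene (default 100).
#' @return Numeric per-cell score, named by column.
#' @export
module_score <- function(expr, gene_set, n_bins = 24L, n_ctrl = 100L) {
  stopifnot(is.matrix(expr))
  genes <- intersect(gene_set, rownames(expr))
  if (!length(genes)) stop("gene set shares no genes with the matrix")
  avg <- rowMeans(expr)
  r <- rank(avg, ties.method = "first")
  bin <- ceiling(r * n_bins / length(avg))
  names(bin) <- rownames(expr)
  ctrl <- character(0)
  for (g in genes) {
    pool <- rownames(expr)[bin == bin[[g]]]
    take <- min(n_ctrl, length(pool))
    ctrl <- c(ctrl, sample(pool, take, replace = FALSE))
  }
  ctrl <- unique(ctrl)
  colMeans(expr[genes, , drop = FALSE]) -
    colMeans(expr[ctrl, , drop = FALSE])
}

#' Assign cell-cycle phase from S and G2M scores
#'
#' Cells with both scores non-positive are called `G1`; otherwise the phase
#' of the larger score wins, with an exact tie of positive scores resolved
#' to `S` (and logged).
#'
#' @param s_score,g2m_score Numeric per-cell module scores.
#' @return Character vector in `G1`, `S`, `G2M`.
#' @export
assign_phase <- function(s_score, g2m_score) {
  stopifnot(length(s_score) == length(g2m_score))
  if (anyNA(s_score) || anyNA(g2m_score)) stop("missing phase score(s)")
  phase <- rep("G1", length(s_score))
  active <- s_score > 0 | g2m_score > 0
  phase[active & s_score >= g2m_score] <- "S"
  phase[active & g2m_score > s_score] <- "G2M"
  n_tie <- sum(active & s_score == g2m_score)
  if (n_tie) ss_log("assign_phase: ", n_tie, " positive-score tie(s) resolved to S")
  phase
}

#' Genes uniquely induced in one of two perturbations
#'
#' A gene is induced in a condition when its differential result passes
#' both the p-value and fold-change cutoffs; genes induced in one condition
#' but not the other form that condition's specific signature.
#'
#' @param de_A,de_B Data frames with `feature_id`, `p`, `log2fc`.
#' @param fc_cutoff Log2 fold-change cutoff (induced means `log2fc >`
#'   this).
#' @param p_cutoff P-value cutoff.
#' @return List with character vectors `unique_A`, `unique_B`.
#' @export
specific_signature <- function(de_A, de_B, fc_cutoff = 0.5, p_cutoff = 0.01) {
  if (!length(intersect(de_A$feature_id, de_B$feature_id))) {
    stop("the two differential tables share no genes")
  }
  induced <- function(de) de$feature_id[de$p < p_cutoff & de$log2fc > fc_cutoff]
  a <- induced(de_A)
  b <- induced(de_B)
  list(unique_A = setdiff(a, b), unique_B = setdiff(b, a))
}

#' Pseudobulk aggregation by (PDL, phase) with the standard filters
#'
#' Sums counts over cells within each (PDL, phase) group, drops groups
#' represented by 15 or fewer cells (strictly more than `min_cells` cells
#' are required), and keeps the `top_n_genes` highest-expressed genes by
#' total summed counts across the surviving groups (lexical tie-break).
#'
#' @param counts Gene-by-cell count matrix.
#' @param cell_meta Data frame with per-cell `PDL` and `phase` in column
#'   order of `counts`.
#' @param min_cells Groups kept only when cell count is strictly greater
#'   (default 15).
#' @param top_n_genes Genes retained (default 8000).
#' @return List of class `pseudobulk`: `counts` (gene by group), `groups`
#'   (data frame `group`, `PDL`, `phase`, `n_cells`).
#' @export
pseudobulk_by_group <- function(counts, cell_meta, min_cells = 15L,
                                top_n_genes = 8000L) {
  m <- as.matrix(counts)
  stopifnot(nrow(cell_meta) == ncol(m),
            all(c("PDL", "phase") %in% names(cell_meta)))
  key <- paste(cell_meta$PDL, cell_meta$phase, sep = "_")
  sizes <- table(key)
  keep_groups <- names(sizes)[sizes > min_cells]
  if (!length(keep_groups)) stop("no (PDL, phase) group exceeds ", min_cells, " cells")
  ss_log("pseudobulk_by_group: ", length(sizes), " groups, ",
         length(keep_groups), " kept (> ", min_cells, " cells)")
  pb <- vapply(keep_groups,
               function(g) rowSums(m[, key == g, drop = FALSE]),
               numeric(nrow(m)))
  tot <- rowSums(pb)
  o <- order(-tot, rownames(pb), method = "radix")
  keep_genes <- sort(rownames(pb)[head(o, top_n_genes)])
  pb <- pb[keep_genes, , drop = FALSE]
  first_cell <- match(keep_groups, key)
  groups <- data.frame(group = keep_groups,
                       PDL = cell_meta$PDL[first_cell],
                       phase = cell_meta$phase[first_cell],
                       n_cells = as.integer(sizes[keep_groups]),
                       stringsAsFactors = FALSE)
  structure(list(counts = pb, groups = groups), class = "pseudobulk")
}

#' CPM log2 fold changes against each phase's earliest PDL
#'
#' Converts pseudobulk counts to counts per million, adds a +1 pseudocount
#' and expresses each group as a log2 fold change over the reference group
#' of the same cell-cycle phase (the phase's earliest PDL).
#'
#' @param pb A [pseudobulk_by_group()] result.
#' @return Gene-by-group log2FC matrix (reference columns identically 0).
#' @export
cpm_log2fc <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk"))
  m <- pb$counts
  lib <- colSums(m)
  if (any(lib == 0)) stop("zero library size in pseudobulk group")
  cpm <- sweep(m, 2L, 1e6 / lib, `*`)
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (ph in unique(pb$groups$phase)) {
    cols <- which(pb$groups$phase == ph)
    ref <- cols[which.min(pb$groups$PDL[cols])]
    out[, cols] <- log2(cpm[, cols, drop = FALSE] + 1) - log2(cpm[, ref] + 1)
  }
  out
}
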