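#' Assign peaks to their nearest gene within a window
#'
#' Each peak is assigned to the nearest gene when the distance between the
#' peak and the gene body is at most `window` bp (distance 0 for overlap),
#' and labeled `intergenic` otherwise.  Equidistant ties break to the gene
#' with the smaller start, then to the lexically smaller gene ID.
#'
#' @param peaks Interval set of peaks.
#' @param genes Interval set of genes with `name` IDs.
#' @param window Maximum peak-to-gene distance in bp (default 50 kb).
#' @return Data frame with `peak_id`, `gene` (`"intergenic"` when none in
#'   range) and `distance` (`NA` for intergenic peaks).
#' @export
peaks_near_genes <- function(peaks, genes, window = 50000L) {
  validate_intervals(peaks)
  validate_intervals(genes)
  ids <- peaks$name
  if (is.null(ids) || any(is.na(ids))) ids <- paste0("peak_", seq_len(nrow(peaks)))
  gene <- rep("intergenic", nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  if (nrow(genes)) {
    pg <- as_granges(peaks)
    gg <- as_granges(genes)
    # every gene within the window, then the minimum pairwise distance;
    # this keeps all equidistant candidates so ties break deterministically
    hits <- GenomicRanges::findOverlaps(pg, gg, maxgap = window,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    d <- GenomicRanges::distance(pg[qh], gg[sh], ignore.strand = TRUE)
    keep <- d <= window    # maxgap counts adjacency differently; re-filter
    for (i in unique(qh[keep])) {
      sel <- which(qh == i & keep)
      dmin <- min(d[sel])
      js <- sh[sel][d[sel] == dmin]
      o <- order(genes$start[js], genes$name[js])
      gene[i] <- genes$name[js[o[1L]]]
      dist[i] <- dmin
    }
  }
  data.frame(peak_id = ids, gene = gene, distance = dist,
             stringsAsFactors = FALSE)
}

#' Per-motif binomial enrichment in a target peak set
#'
#' For each motif, the background peaks define a null presence frequency
#' `p0`; the observed motif hit count among the target peaks is tested
#' against `Binomial(|target|, p0)` with an inclusive upper tail.
#' Degenerate motifs are handled exactly: `p0 = 0` with zero target hits
#' (or `p0 = 1`) yields `p = 1`; target hits of an impossible event
#' (`p0 = 0`, hits > 0) yield `p = 0` with a flag.
#'
#' @param target_peaks,background_peaks Disjoint character vectors of peak
#'   IDs, both present among the matrix rows.
#' @param matrix Binary peak-by-motif matrix (rows = peak IDs).
#' @return Data frame with `motif`, `fraction_in_target`, `p0`, `p`, `q`
#'   (BH across motifs) and `impossible` flag.
#' @export
motif_enrichment_binomial <- function(target_peaks, background_peaks, matrix) {
  if (!length(target_peaks) || !length(background_peaks)) {
    stop("target and background peak sets must both be non-empty")
  }
  if (length(intersect(target_peaks, background_peaks))) {
    stop("target and background peak sets overlap")
  }
  stopifnot(all(target_peaks %in% rownames(matrix)),
            all(background_peaks %in% rownames(matrix)))
  tm <- matrix[target_peaks, , drop = FALSE]
  bm <- matrix[background_peaks, , drop = FALSE]
  n <- nrow(tm)
  k <- colSums(tm)
  p0 <- colMeans(bm)
  p <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  impossible <- p0 == 0 & k > 0
  p[p0 == 0 & k == 0] <- 1
  p[p0 == 1] <- 1
  p[impossible] <- 0
  data.frame(motif = colnames(matrix), fraction_in_target = k / n, p0 = p0,
             p = p, q = bh_adjust(p), impossible = impossible,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Label peaks by direction of significant accessibility change
#'
#' Splits peaks into those of significantly increased (`up`) and
#' significantly decreased (`down`) accessibility over the time course;
#' everything else is excluded.
#'
#' @param trend Per-peak results with `feature_id`, `p` and `beta1` (signed
#'   log2 fold change / slope).
#' @param p_cutoff Significance cutoff (default 0.001).
#' @return List with character vectors `up` and `down`.
#' @export
prepare_labels <- function(trend, p_cutoff = 0.001) {
  sig <- trend$p < p_cutoff
  list(up = trend$feature_id[sig & trend$beta1 > 0],
       down = trend$feature_id[sig & trend$beta1 < 0])
}

# Rank-statistic AUC: probability a random positive outscores a random
# negative, with half credit for ties.
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1L
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

fit_ridge_logistic <- function(x, y, penalty) {
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = penalty, standardize = FALSE,
                        intercept = TRUE)
  as.numeric(fit$beta[, 1L])
}

#' Ridge-logistic model of accessibility direction from motif content
#'
#' Trains an L2-penalized logistic regression on the binary peak-by-motif
#' matrix to distinguish peaks gaining accessibility from peaks losing it,
#' using a stratified train/test split, and reports the held-out AUC.
#' Features enter as raw binaries (no standardization), so coefficients
#' read as per-motif log-odds; the intercept is unpenalized.  When
#' `penalty` is `NULL` it is chosen by 5-fold cross-validated deviance over
#' a small grid on the training set.
#'
#' @param matrix Binary peak-by-motif matrix.
#' @param labels List with `up` and `down` peak-ID vectors (see
#'   [prepare_labels()]); `up` is the positive class.
#' @param split_fraction Training fraction (default 2/3).
#' @param penalty Ridge penalty `lambda`; `NULL` for cross-validated
#'   selection.
#' @param seed Integer seed controlling the split (and CV folds).
#' @return List of class `motif_model_result`: `auc`, `coefficients`
#'   (per-motif, from the training fit), `intercept`, `penalty`, `seed`,
#'   `n_train`, `n_test`.
#' @export
ridge_motif_model <- function(matrix, labels, split_fraction = 2 / 3,
                              penalty = NULL, seed = 1L) {
  dat <- motif_design(matrix, labels)
  set.seed(seed)
  tr <- stratified_split(dat$y, split_fraction)
  if (length(unique(dat$y[tr])) < 2L || length(unique(dat$y[!tr])) < 2L) {
    stop("train/test split left a single class; re-seed or rebalance labels")
  }
  xtr <- dat$x[tr, , drop = FALSE]
  ytr <- dat$y[tr]
  if (is.null(penalty)) penalty <- choose_ridge_penalty(xtr, ytr)
  fit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                        lambda = penalty, standardize = FALSE)
  scores <- as.numeric(predict(fit, dat$x[!tr, , drop = FALSE]))
  auc <- rank_auc(scores, dat$y[!tr])
  ss_log("ridge_motif_model: ", sum(tr), " train / ", sum(!tr),
         " test peaks, lambda = ", signif(penalty, 3), ", AUC = ",
         round(auc, 3), " (seed ", seed, ")")
  structure(list(auc = auc,
                 coefficients = setNames(as.numeric(fit$beta[, 1L]),
                                         colnames(dat$x)),
                 intercept = as.numeric(fit$a0), penalty = penalty,
                 seed = seed, n_train = sum(tr), n_test = sum(!tr)),
            class = "motif_model_result")
}

#' Bootstrap-aggregated motif coefficients
#'
#' Fits `n_models` ridge-logistic models, each on a bootstrap resample of
#' all labeled peaks, and averages the per-motif coefficients; motifs are
#' ranked by mean coefficient (rank 1 = largest).  A resample that loses a
#' class is redrawn (and counted in the log).
#'
#' @inheritParams ridge_motif_model
#' @param n_models Number of bootstrap fits (default 10).
#' @param seed Integer seed; per-model seeds are derived from it.
#' @return List of class `motif_model_result`: `coefficients` (motif by
#'   model matrix), `mean_coefficient`, `rank`, `penalty`, `seed`.
#' @export
aggregate_coefficients <- function(matrix, labels, n_models = 10L,
                                   penalty = NULL, seed = 1L) {
  stopifnot(n_models >= 1L)
  dat <- motif_design(matrix, labels)
  set.seed(seed)
  if (is.null(penalty)) penalty <- choose_ridge_penalty(dat$x, dat$y)
  n <- length(dat$y)
  coefs <- matrix(NA_real_, ncol(dat$x), n_models,
                  dimnames = list(colnames(dat$x),
                                  paste0("model_", seq_len(n_models))))
  redraws <- 0L
  for (m in seq_len(n_models)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(dat$y[idx])) == 2L) break
      redraws <- redraws + 1L
    }
    coefs[, m] <- fit_ridge_logistic(dat$x[idx, , drop = FALSE], dat$y[idx],
                                     penalty)
  }
  if (redraws) ss_log("aggregate_coefficients: ", redraws, " single-class bootstrap redraw(s)")
  mean_coef <- rowMeans(coefs)
  rk <- rank(-mean_coef, ties.method = "first")
  structure(list(coefficients = coefs, mean_coefficient = mean_coef,
                 rank = rk, penalty = penalty, seed = seed),
            class = "motif_model_result")
}

motif_design <- function(matrix, labels) {
  stopifnot(is.matrix(matrix))
  if (!all(matrix %in% c(0, 1))) stop("motif matrix must be binary")
  up <- labels$up
  down <- labels$down
  if (!length(up) || !length(down)) {
    stop("both label classes must be non-empty; refusing to fit")
  }
  ids <- c(up, down)
  stopifnot(all(ids %in% rownames(matrix)))
  list(x = matrix[ids, , drop = FALSE],
       y = c(rep(1L, length(up)), rep(0L, length(down))))
}

stratified_split <- function(y, split_fraction) {
  tr <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_tr <- floor(length(idx) * split_fraction)
    tr[sample(idx, n_tr)] <- TRUE
  }
  tr
}

choose_ridge_penalty <- function(x, y, grid = 10^seq(-3, 1, length.out = 9)) {
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = sort(grid, decreasing = TRUE),
                          standardize = FALSE, nfolds = 5)
  cv$lambda.min
}
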