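#' Population-doubling increment for one passage
#'
#' The number of population doublings accrued between seeding and harvest,
#' `log2(harvested / seeded)`.  The quantity is additive over serial
#' passages, which is what makes the cumulative PDL axis of a senescence
#' time course well defined.
#'
#' @param seeded,harvested Positive cell counts.
#' @return Number of doublings (float).
#' @export
pdl_increment <- function(seeded, harvested) {
  if (any(!is.finite(seeded)) || any(!is.finite(harvested)) ||
      any(seeded <= 0) || any(harvested <= 0)) {
    stop("cell counts must be positive")
  }
  log2(harvested / seeded)
}

#' Per-feature linear trend test over a time-course covariate
#'
#' For each feature (metabolite, protein, peak, FRiP value...) fits
#' `y_it = beta0 + beta1 * T_t + e_it` by ordinary least squares, where
#' `T_t` is the timepoint covariate (typically the cell-passage / PDL
#' vector), and tests `H0: beta1 = 0` with a two-sided t-test on `n - 2`
#' degrees of freedom.  No information is shared across features.
#'
#' @param values Numeric feature-by-sample matrix of log-scale abundances
#'   (a vector is treated as a single feature).
#' @param covariate Numeric covariate `T_t`, one value per sample, with at
#'   least 3 distinct values.
#' @return Data frame with columns `feature_id`, `beta0`, `beta1`, `se1`,
#'   `t_stat`, `p`, `q` (Benjamini-Hochberg across features).
#' @export
linear_trend_test <- function(values, covariate) {
  if (is.null(dim(values))) {
    values <- matrix(values, nrow = 1L, dimnames = list("feature_1", NULL))
  }
  x <- as.numeric(covariate)
  n <- ncol(values)
  if (length(x) != n) stop("covariate length must equal number of samples")
  if (anyNA(values) || anyNA(x)) stop("missing values are not allowed")
  if (length(unique(x)) < 3L) {
    stop("covariate must take at least 3 distinct values",
         if (length(unique(x)) == 1L) " (constant covariate: slope unidentifiable)")
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  beta1 <- as.numeric(values %*% xc) / sxx
  beta0 <- rowMeans(values) - beta1 * mean(x)
  fitted <- outer(beta1, x) + beta0
  rss <- rowSums((values - fitted)^2)
  df <- n - 2L
  s2 <- rss / df
  se1 <- sqrt(s2 / sxx)
  t_stat <- beta1 / se1
  p <- 2 * pt(-abs(t_stat), df)
  # zero-residual exact fits: se 0, infinite t, p 0
  p[se1 == 0 & beta1 != 0] <- 0
  ids <- rownames(values)
  if (is.null(ids)) ids <- paste0("feature_", seq_len(nrow(values)))
  ss_log("linear_trend_test: ", nrow(values), " features x ", n, " samples")
  data.frame(feature_id = ids, beta0 = beta0, beta1 = beta1, se1 = se1,
             t_stat = t_stat, p = p, q = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1; delegates to
#' [stats::p.adjust()] after validating the input range.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, `q >= p` componentwise.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Protein-concentration normalization of raw metabolite values
#'
#' Samples harvested at each timepoint are normalized by total protein: the
#' factor for a (line, timepoint) group is the group's median protein
#' concentration divided by the median concentration across all samples of
#' that cell line, and every raw value in the group is multiplied by it.
#' Set `invert = TRUE` to divide instead (scaling high-protein samples
#' down rather than up).
#'
#' @param raw Metabolite-by-sample numeric matrix.
#' @param meta [sample_meta()] with `protein_conc` for every sample in
#'   `raw`.
#' @param invert Divide by the factor instead of multiplying.
#' @return Normalized matrix of the same shape.
#' @export
protein_normalize <- function(raw, meta, invert = FALSE) {
  stopifnot(is.matrix(raw))
  m <- meta[match(colnames(raw), meta$sample_id), , drop = FALSE]
  if (anyNA(m$sample_id)) {
    stop("samples missing from metadata: ",
         paste(head(setdiff(colnames(raw), meta$sample_id), 5L), collapse = ", "))
  }
  if (anyNA(m$protein_conc)) {
    stop("missing protein concentration for sample(s): ",
         paste(head(m$sample_id[is.na(m$protein_conc)], 5L), collapse = ", "))
  }
  line_med <- tapply(m$protein_conc, m$line, median)
  grp <- paste(m$line, m$timepoint)
  grp_med <- tapply(m$protein_conc, grp, median)
  factor_s <- as.numeric(grp_med[grp]) / as.numeric(line_med[m$line])
  if (invert) factor_s <- 1 / factor_s
  sweep(raw, 2L, factor_s, `*`)
}

#' Paired-control batch correction for metabolite time courses
#'
#' Removes sample-day batch effects by dividing each WT metabolite value by
#' the value in its temporally paired immortalized-control sample (equal
#' `timepoint`, matched `replicate` index), then expressing the ratio as a
#' log2 fold change against the reference timepoint's mean ratio.  Because
#' a batch factor shared by both members of a pair cancels exactly in the
#' division, the output is invariant to any per-timepoint multiplicative
#' batch effect.
#'
#' When WT and control replicate counts differ at a timepoint, the WT
#' values at that timepoint are divided by the per-timepoint mean of the
#' control replicates.
#'
#' @param wt Metabolite-by-sample matrix for the WT line.
#' @param ctrl Metabolite-by-sample matrix for the paired control line.
#' @param meta [sample_meta()] covering the columns of both matrices.
#' @param reference_timepoint Timepoint used as the log2-ratio reference;
#'   its (identically zero) columns are dropped from the output.
#' @return Metabolite-by-sample log2-ratio matrix over the non-reference WT
#'   samples.
#' @export
paired_batch_correct <- function(wt, ctrl, meta, reference_timepoint) {
  stopifnot(is.matrix(wt), is.matrix(ctrl))
  mw <- meta[match(colnames(wt), meta$sample_id), , drop = FALSE]
  mc <- meta[match(colnames(ctrl), meta$sample_id), , drop = FALSE]
  if (anyNA(mw$sample_id) || anyNA(mc$sample_id)) {
    stop("all matrix columns must appear in the metadata")
  }
  if (!reference_timepoint %in% mw$timepoint) {
    stop("reference timepoint ", reference_timepoint, " not present in WT samples")
  }
  if (anyNA(ctrl) || any(ctrl == 0)) {
    bad <- which(is.na(ctrl) | ctrl == 0, arr.ind = TRUE)[1L, ]
    stop("zero or missing control value for metabolite '",
         rownames(ctrl)[bad[1L]], "' in sample '", colnames(ctrl)[bad[2L]], "'")
  }
  ratios <- matrix(NA_real_, nrow(wt), ncol(wt), dimnames = dimnames(wt))
  for (j in seq_len(ncol(wt))) {
    tp <- mw$timepoint[j]
    csel <- which(mc$timepoint == tp)
    if (!length(csel)) {
      stop("no control sample at timepoint ", tp, " for WT sample '",
           colnames(wt)[j], "'")
    }
    cmatch <- csel[mc$replicate[csel] == mw$replicate[j]]
    denom <- if (length(cmatch) == 1L && length(csel) == sum(mw$timepoint == tp)) {
      ctrl[, cmatch]
    } else {
      rowMeans(ctrl[, csel, drop = FALSE])
    }
    ratios[, j] <- wt[, j] / denom
  }
  ref_cols <- which(mw$timepoint == reference_timepoint)
  ref_ratio <- rowMeans(ratios[, ref_cols, drop = FALSE])
  if (any(ref_ratio == 0)) {
    stop("zero reference ratio for metabolite '",
         rownames(wt)[which(ref_ratio == 0)[1L]], "'")
  }
  out <- log2(ratios / ref_ratio)
  ss_log("paired_batch_correct: ", ncol(wt), " WT samples, reference dropped: ",
         length(ref_cols))
  out[, -ref_cols, drop = FALSE]
}
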