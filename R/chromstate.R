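#' Assign ATAC-seq peaks to chromatin states
#'
#' Each peak is compared against the state segmentation and classified as
#' `inside` (the peak lies entirely within a single state interval),
#' `inside_feature` (the peak fully contains one or more intervals of a
#' single state and touches no base pair of any other state), or
#' `discarded` (the peak overlaps intervals of more than one state, or
#' partially overlaps a single state interval without containing it).
#' Coordinates are half-open, so contact at a shared boundary is not
#' overlap.
#'
#' @param peaks Interval set of peaks; `name` is used as the peak ID
#'   (falling back to `peak_<row>` when absent).
#' @param states A [chromatin_state_map()].
#' @return Data frame with columns `peak_id`, `state` (state identifier or
#'   `"discarded"`), `relation` (`inside`/`inside_feature`/`discarded`) and
#'   `category`; every input peak appears exactly once.
#' @export
assign_peaks_to_states <- function(peaks, states) {
  validate_intervals(peaks)
  stopifnot(inherits(states, "chromatin_state_map"))
  si <- states$intervals
  missing_chrom <- setdiff(unique(peaks$chrom), unique(si$chrom))
  if (length(missing_chrom)) {
    stop("peak chromosome(s) absent from the state map: ",
         paste(missing_chrom, collapse = ", "))
  }
  ids <- peaks$name
  if (is.null(ids) || any(is.na(ids))) ids <- paste0("peak_", seq_len(nrow(peaks)))
  pg <- as_granges(peaks)
  sg <- as_granges(si)
  hits <- GenomicRanges::findOverlaps(pg, sg, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  state <- rep("discarded", nrow(peaks))
  relation <- rep("discarded", nrow(peaks))
  if (length(qh)) {
    for (i in unique(qh)) {
      js <- sh[qh == i]
      st <- unique(si$name[js])
      if (length(st) != 1L) next   # spans more than one state
      contained_in <- any(si$start[js] <= peaks$start[i] &
                            si$end[js] >= peaks$end[i])
      contains <- any(peaks$start[i] <= si$start[js] &
                        peaks$end[i] >= si$end[js])
      if (contained_in) {
        state[i] <- st; relation[i] <- "inside"
      } else if (contains) {
        state[i] <- st; relation[i] <- "inside_feature"
      }
    }
  }
  category <- ifelse(state == "discarded", NA_character_,
                     unname(states$categories[state]))
  ss_log("assign_peaks_to_states: ", nrow(peaks), " peaks in, ",
         sum(relation != "discarded"), " assigned")
  data.frame(peak_id = ids, state = state, relation = relation,
             category = category, stringsAsFactors = FALSE)
}

#' Per-sample signal fractions across chromatin states
#'
#' Given read counts per state instance, sums counts over all instances of
#' the same state and normalizes per sample, so each sample's fractions over
#' the 25 states (or the four broad categories) sum to one.
#'
#' @param signal Numeric instance-by-sample count matrix whose rows follow
#'   the row order of `states$intervals`.
#' @param states A [chromatin_state_map()].
#' @param grouping `"state"` (25 rows) or `"category"` (4 rows).
#' @return Fraction matrix (group by sample); columns sum to 1.
#' @export
state_signal_fractions <- function(signal, states,
                                   grouping = c("state", "category")) {
  grouping <- match.arg(grouping)
  stopifnot(is.matrix(signal), inherits(states, "chromatin_state_map"))
  if (nrow(signal) != nrow(states$intervals)) {
    stop("signal rows must match the state-instance rows of the state map")
  }
  if (any(signal < 0)) stop("counts must be non-negative")
  key <- states$intervals$name
  if (grouping == "category") key <- unname(states$categories[key])
  sums <- rowsum(signal, group = key)
  tot <- colSums(sums)
  if (any(tot == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(signal)[tot == 0], collapse = ", "))
  }
  sweep(sums, 2L, tot, `/`)
}

#' Quantile-normalize a count matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' per-rank means of the column-sorted input.  Within-column rank order is
#' preserved, and ties within a column receive the mean of the reference
#' values their ranks span.  Delegates to [limma::normalizeQuantiles()].
#'
#' @param m Numeric matrix, no missing values.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("missing values are not allowed")
  if (ncol(m) == 1L) {
    warning("single-column matrix: quantile normalization is a no-op")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over features, of the
#' ratio of each sample's count to the feature's geometric mean across
#' samples.  When accessibility changes are asymmetric (concentrated gains
#' in heterochromatic domains), restricting the median to `control_features`
#' known to sit outside the responsive domains avoids the compression bias
#' that whole-matrix normalization introduces.
#'
#' @param counts Feature-by-sample count matrix.
#' @param control_features Optional character vector of feature IDs (or
#'   logical/integer row index) used to compute the medians.
#' @return Numeric per-sample size factor.
#' @export
size_factors <- function(counts, control_features = NULL) {
  stopifnot(is.matrix(counts))
  m <- if (is.null(control_features)) counts else counts[control_features, , drop = FALSE]
  logm <- log(m)
  ref <- rowMeans(logm)          # log geometric mean; -Inf when any zero
  ok <- is.finite(ref)
  if (!any(ok)) stop("no feature with all-positive counts to anchor size factors")
  sf <- apply(logm[ok, , drop = FALSE], 2L, function(col) {
    median(col - ref[ok])
  })
  exp(sf)
}

#' Median accessibility fold change per chromatin state
#'
#' For each non-reference sample, computes each significantly changing
#' peak's log2 fold change over the mean of the reference-timepoint
#' replicates (on quantile-normalized counts with a +1 pseudocount) and
#' reports the per-state median.  States with no qualifying peak are
#' reported as `NA`, never 0.
#'
#' @param norm_counts Quantile-normalized peak-by-sample matrix.
#' @param assignment Output of [assign_peaks_to_states()] for the same
#'   peaks (rows matched by `peak_id` / row name).
#' @param trend Per-peak trend results (`feature_id`, `p`) used as the
#'   significance filter.
#' @param meta [sample_meta()] for the matrix columns.
#' @param cutoff Significance cutoff on the trend p-value (in `(0, 1]`).
#' @param reference_timepoint Reference timepoint; defaults to the earliest
#'   in `meta`.
#' @return State-by-sample matrix of median log2 fold changes over the
#'   non-reference samples.
#' @export
state_fc_summary <- function(norm_counts, assignment, trend, meta,
                             cutoff = 0.001,
                             reference_timepoint = NULL) {
  stopifnot(is.matrix(norm_counts))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("cutoff must lie in (0, 1]")
  }
  m <- meta[match(colnames(norm_counts), meta$sample_id), , drop = FALSE]
  if (anyNA(m$sample_id)) stop("all matrix columns must appear in the metadata")
  if (is.null(reference_timepoint)) reference_timepoint <- min(m$timepoint)
  ref_cols <- which(m$timepoint == reference_timepoint)
  if (!length(ref_cols)) stop("reference timepoint absent from metadata")
  ids <- rownames(norm_counts)
  if (is.null(ids)) stop("norm_counts must have peak row names")
  st <- assignment$state[match(ids, assignment$peak_id)]
  pv <- trend$p[match(ids, trend$feature_id)]
  keep <- !is.na(st) & st != "discarded" & !is.na(pv) & pv < cutoff
  ss_log("state_fc_summary: ", length(ids), " peaks, ", sum(keep),
         " significant & assigned")
  ref_mean <- rowMeans(norm_counts[, ref_cols, drop = FALSE])
  lfc <- log2(norm_counts + 1) - log2(ref_mean + 1)
  lfc <- lfc[keep, -ref_cols, drop = FALSE]
  st <- st[keep]
  states_all <- sort(unique(assignment$state[assignment$state != "discarded"]))
  out <- matrix(NA_real_, length(states_all), ncol(lfc),
                dimnames = list(states_all, colnames(lfc)))
  for (s in states_all) {
    rows <- which(st == s)
    if (length(rows)) {
      out[s, ] <- apply(lfc[rows, , drop = FALSE], 2L, median)
    }
  }
  out
}

#' Fraction of reads in peaks and its trend over PDL
#'
#' FRiP (reads in peaks / total reads) is a signal-to-noise metric; a
#' decline with PDL indicates signal spreading out of called peaks.  The
#' trend is tested with the package's per-feature linear model against the
#' timepoint covariate.
#'
#' @param reads_in_peaks,total_reads Per-sample read counts; names matching
#'   `meta$sample_id` order is assumed positional.
#' @param meta [sample_meta()] for the samples.
#' @return List with `frip` (per-sample vector), `slope`, `p`.
#' @export
frip_trend <- function(reads_in_peaks, total_reads, meta) {
  if (any(total_reads <= 0)) stop("total read counts must be positive")
  if (any(reads_in_peaks > total_reads)) {
    stop("reads_in_peaks cannot exceed total_reads")
  }
  if (any(reads_in_peaks < 0)) stop("read counts must be non-negative")
  frip <- reads_in_peaks / total_reads
  res <- linear_trend_test(matrix(frip, nrow = 1L,
                                  dimnames = list("FRiP", NULL)),
                           meta$timepoint)
  list(frip = setNames(frip, meta$sample_id), slope = res$beta1, p = res$p)
}
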