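#' Bin, spline-smooth and scale one gene's pseudotime trajectory
#'
#' Cells are partitioned into `n_bins` equal-width bins over the observed
#' pseudotime range and the per-bin mean expression is computed; a cubic
#' smoothing spline (stiffness by generalized cross-validation unless
#' `spar` is given) is fit to the non-empty bin centers and evaluated at
#' all bin centers; the result is min-max scaled to \[0, 1\].  A constant
#' trajectory cannot be scaled and is returned as all zeros with the
#' `constant` attribute set.
#'
#' @param expr Numeric expression per cell (one gene).
#' @param pseudotime Numeric pseudotime per cell.
#' @param n_bins Number of bins (default 60).
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` for GCV.
#' @return Numeric length-`n_bins` scaled trajectory with attributes
#'   `constant` (logical) and `bin_centers`.
#' @export
bin_smooth_trajectory <- function(expr, pseudotime, n_bins = 60L,
                                  spar = NULL) {
  stopifnot(length(expr) == length(pseudotime))
  if (length(unique(pseudotime)) < 4L) {
    stop("need at least 4 distinct pseudotime values")
  }
  rng <- range(pseudotime)
  width <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((pseudotime - rng[1]) / width) + 1L, n_bins)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * width
  means <- tapply(expr, factor(idx, levels = seq_len(n_bins)), mean)
  filled <- which(!is.na(means))
  if (length(filled) < 4L) stop("fewer than 4 non-empty pseudotime bins")
  if (diff(range(means[filled])) == 0) {
    out <- rep(0, n_bins)
    attr(out, "constant") <- TRUE
    attr(out, "bin_centers") <- centers
    return(out)
  }
  sp <- if (is.null(spar)) {
    smooth.spline(centers[filled], means[filled], cv = FALSE)
  } else {
    smooth.spline(centers[filled], means[filled], spar = spar)
  }
  y <- predict(sp, centers)$y
  lo <- min(y); hi <- max(y)
  if (hi == lo) {
    out <- rep(0, n_bins)
    attr(out, "constant") <- TRUE
  } else {
    out <- (y - lo) / (hi - lo)
    attr(out, "constant") <- FALSE
  }
  attr(out, "bin_centers") <- centers
  out
}

#' Smooth many gene trajectories at once
#'
#' Applies [bin_smooth_trajectory()] to each row of a gene-by-cell matrix.
#'
#' @param expr Gene-by-cell numeric matrix.
#' @param pseudotime Numeric pseudotime per cell.
#' @inheritParams bin_smooth_trajectory
#' @return List with `trajectories` (gene by bin, scaled) and `constant`
#'   (logical per gene).
#' @export
smooth_trajectories <- function(expr, pseudotime, n_bins = 60L, spar = NULL) {
  stopifnot(is.matrix(expr))
  out <- matrix(NA_real_, nrow(expr), n_bins,
                dimnames = list(rownames(expr), NULL))
  const <- logical(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    tr <- bin_smooth_trajectory(expr[i, ], pseudotime, n_bins, spar)
    out[i, ] <- tr
    const[i] <- attr(tr, "constant")
  }
  list(trajectories = out, constant = const)
}

#' K-median clustering under cosine similarity
#'
#' Alternates assignment (maximal cosine similarity to a cluster median)
#' and update (coordinate-wise median of assigned rows), initialized
#' k-means++-style by cosine distance from the seeded RNG.  An empty
#' cluster is re-seeded from the worst-fit row.  Because a coordinate-wise
#' median is not guaranteed to reduce a cosine objective, the objective
#' (sum of cosine distances to assigned medians) is tracked and an update
#' that would increase it is rolled back, making the objective
#' non-increasing by construction and terminating the loop.
#'
#' @param trajectories Numeric row-per-gene matrix (e.g. scaled
#'   trajectories); rows must be non-zero.
#' @param k Number of clusters; at most the number of distinct rows.
#' @param seed Integer RNG seed for initialization.
#' @param max_iter Iteration cap (default 100).
#' @return List: `assignment` (1..k per row), `medians` (k by bin),
#'   `objective`, `iterations`.
#' @export
kmedians_cosine <- function(trajectories, k = 25L, seed = 1L,
                            max_iter = 100L) {
  x <- as.matrix(trajectories)
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) stop("all-zero row(s) cannot be clustered by cosine similarity")
  if (k > nrow(unique(x))) {
    stop("k = ", k, " exceeds the number of distinct rows (", nrow(unique(x)), ")")
  }
  xn <- x / norms
  n <- nrow(x)
  set.seed(seed)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d <- 1 - as.numeric(xn %*% xn[centers[1L], ])
  for (j in seq_len(k)[-1L]) {
    w <- pmax(d, 0)
    centers[j] <- if (sum(w) == 0) sample.int(n, 1L) else sample.int(n, 1L, prob = w)
    d <- pmin(d, 1 - as.numeric(xn %*% xn[centers[j], ]))
  }
  medians <- xn[centers, , drop = FALSE]
  cluster_objective <- function(assign, medians) {
    mn <- sqrt(rowSums(medians^2))
    mn[mn == 0] <- 1
    sims <- (xn %*% t(medians / mn))
    sum(1 - sims[cbind(seq_len(n), assign)])
  }
  assign_rows <- function(medians) {
    mn <- sqrt(rowSums(medians^2))
    mn[mn == 0] <- 1
    sims <- xn %*% t(medians / mn)
    max.col(sims, ties.method = "first")
  }
  assign <- assign_rows(medians)
  obj <- cluster_objective(assign, medians)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    new_medians <- medians
    for (j in seq_len(k)) {
      rows <- which(assign == j)
      if (length(rows)) {
        # medians of the unit-normalized rows keep the procedure invariant
        # to positive rescaling of any input row
        new_medians[j, ] <- apply(xn[rows, , drop = FALSE], 2L, median)
      }
    }
    # re-seed empty clusters from the worst-fit row
    empty <- setdiff(seq_len(k), unique(assign))
    if (length(empty)) {
      mn <- sqrt(rowSums(new_medians^2)); mn[mn == 0] <- 1
      best_sim <- apply(xn %*% t(new_medians / mn), 1L, max)
      for (j in empty) {
        worst <- which.min(best_sim)
        new_medians[j, ] <- xn[worst, ]
        best_sim[worst] <- 1
        ss_log("kmedians_cosine: re-seeded empty cluster ", j)
      }
    }
    new_assign <- assign_rows(new_medians)
    new_obj <- cluster_objective(new_assign, new_medians)
    if (new_obj > obj + 1e-12) break        # roll back a worsening update
    converged <- identical(new_assign, assign) && new_obj >= obj - 1e-12
    assign <- new_assign
    medians <- new_medians
    obj <- new_obj
    if (converged) break
  }
  list(assignment = assign, medians = medians, objective = obj,
       iterations = iter)
}

#' Label clusters early / transition / late
#'
#' Each cluster's (median) profile is located by its argmax bin: bins up to
#' `boundaries[1]` are `early`, up to `boundaries[2]` `transition`, later
#' bins `late`.  Argmax ties (including flat profiles) resolve to the
#' earliest bin, with flat profiles flagged.
#'
#' @param medians Cluster-by-bin numeric matrix of median profiles.
#' @param boundaries Two increasing bin indices splitting the grid
#'   (default `c(20, 40)` on a 60-bin grid).
#' @return Data frame with `cluster`, `peak_bin`, `category`, `flat`.
#' @export
categorize_clusters <- function(medians, boundaries = c(20L, 40L)) {
  m <- as.matrix(medians)
  stopifnot(all(is.finite(m)), length(boundaries) == 2L,
            boundaries[1] < boundaries[2], boundaries[2] < ncol(m))
  peak <- apply(m, 1L, which.max)   # earliest bin on ties
  flat <- apply(m, 1L, function(r) diff(range(r)) == 0)
  category <- ifelse(peak <= boundaries[1], "early",
                     ifelse(peak <= boundaries[2], "transition", "late"))
  data.frame(cluster = seq_len(nrow(m)), peak_bin = peak,
             category = category, flat = flat, stringsAsFactors = FALSE)
}

#' Select genes for trajectory analysis by significance
#'
#' Filters a per-gene p-value table at `p_cutoff`, orders ascending by p
#' with a lexical tie-break on gene ID, and keeps at most `top_n`.
#'
#' @param de Data frame with `feature_id` and `p`.
#' @param p_cutoff Significance cutoff (default 0.001).
#' @param top_n Maximum genes returned (default 5000).
#' @return Character vector of gene IDs.
#' @export
select_trajectory_genes <- function(de, p_cutoff = 0.001, top_n = 5000L) {
  keep <- de[de$p < p_cutoff, , drop = FALSE]
  keep <- keep[order(keep$p, keep$feature_id, method = "radix"), , drop = FALSE]
  head(keep$feature_id, top_n)
}
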