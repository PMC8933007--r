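#' Expression-matched gene sampling
#'
#' Draws a null gene sample the same size as the target set, matching the
#' target's expression distribution: universe genes are split into
#' equal-count expression bins (deciles by default) and the sample draws,
#' without replacement and within bin, exactly as many genes as the target
#' holds in that bin.  Nothing but expression bin membership constrains the
#' draw.  Uses the current R RNG state; seed with [set.seed()].
#'
#' @param universe Character vector of all candidate gene IDs.
#' @param expression Numeric expression score per universe gene (parallel
#'   to `universe`).
#' @param target Character vector of target gene IDs, a subset of
#'   `universe`.
#' @param n_bins Number of equal-count expression bins (default 10).
#' @return Character vector of sampled gene IDs, `length(target)` long.
#' @export
expression_matched_sample <- function(universe, expression, target,
                                      n_bins = 10L) {
  stopifnot(length(universe) == length(expression))
  if (!all(target %in% universe)) {
    stop("target genes must be a subset of the universe")
  }
  n <- length(universe)
  r <- rank(expression, ties.method = "first")
  bin <- ceiling(r * n_bins / n)
  names(bin) <- universe
  tgt_counts <- table(factor(bin[target], levels = seq_len(n_bins)))
  out <- character(0)
  for (b in seq_len(n_bins)) {
    need <- tgt_counts[[b]]
    if (need == 0L) next
    pool <- universe[bin == b]
    if (length(pool) < need) {
      stop("expression bin ", b, " holds ", length(pool),
           " universe genes but the target requires ", need)
    }
    out <- c(out, sample(pool, need, replace = FALSE))
  }
  out
}

#' Permutation overlap test with expression-matched nulls
#'
#' Tests whether target genes overlap a set of genomic domains (NADs, LADs)
#' more (or less) than expected, against a null of expression-matched gene
#' samples drawn from the universe.  A gene overlaps when at least one base
#' pair of its body intersects a domain; no promoter extension is added.
#' The empirical p-value uses the add-one rule, so it is never 0; the
#' Z-score is `(observed - mean(null)) / sd(null)`, reported as 0 with a
#' `degenerate` flag when the null is constant.
#'
#' @param targets Character vector of target gene IDs, or an interval set
#'   whose `name`s are gene IDs.
#' @param domains Interval set of domains.
#' @param universe Interval set of all genes (`name` = gene ID, `score` =
#'   expression when matching is on).
#' @param n_perm Number of permutations (>= 100).
#' @param alternative `"greater"` or `"less"`.
#' @param match_expression Draw nulls matched on the universe's expression
#'   `score` (default) or by simple random sampling.
#' @param exhaustive Enumerate all same-size subsets of the universe
#'   instead of sampling (matching disabled; only feasible for tiny
#'   problems).  The p-value is then the exact tail fraction.
#' @return List of class `overlap_test_result`: `observed`, `null_draws`,
#'   `z`, `p_emp`, `alternative`, `degenerate`.
#' @export
permutation_overlap_test <- function(targets, domains, universe,
                                     n_perm = 1000L,
                                     alternative = c("greater", "less"),
                                     match_expression = TRUE,
                                     exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  if (is.data.frame(targets)) targets <- targets$name
  validate_intervals(universe)
  if (!length(targets)) stop("empty target set")
  if (!nrow(universe)) stop("empty universe")
  if (!exhaustive && n_perm < 100L) stop("n_perm must be >= 100")
  uid <- universe$name
  ov <- rep(FALSE, nrow(universe))
  if (nrow(domains)) {
    ov <- IRanges::overlapsAny(as_granges(universe), as_granges(domains),
                               ignore.strand = TRUE)
  }
  names(ov) <- uid
  if (!all(targets %in% uid)) stop("target genes must be a subset of the universe")
  observed <- sum(ov[targets])
  k <- length(targets)
  if (exhaustive) {
    if (choose(length(uid), k) > 2e5) {
      stop("exhaustive enumeration infeasible: C(", length(uid), ", ", k,
           ") subsets")
    }
    subsets <- combn(length(uid), k)
    null_draws <- apply(subsets, 2L, function(idx) sum(ov[idx]))
  } else {
    null_draws <- integer(n_perm)
    for (i in seq_len(n_perm)) {
      smp <- if (match_expression) {
        expression_matched_sample(uid, universe$score, targets)
      } else {
        sample(uid, k, replace = FALSE)
      }
      null_draws[i] <- sum(ov[smp])
    }
  }
  mu <- mean(null_draws)
  s <- sd(null_draws)
  degenerate <- is.na(s) || s == 0
  z <- if (degenerate) 0 else (observed - mu) / s
  extreme <- if (alternative == "greater") null_draws >= observed else null_draws <= observed
  p_emp <- if (exhaustive) {
    sum(extreme) / length(null_draws)
  } else {
    (1 + sum(extreme)) / (1 + length(null_draws))
  }
  ss_log("permutation_overlap_test: |target| = ", k, ", observed = ", observed,
         ", null mean = ", round(mu, 2))
  structure(list(observed = observed, null_draws = null_draws, z = z,
                 p_emp = p_emp, alternative = alternative,
                 degenerate = degenerate),
            class = "overlap_test_result")
}

#' Wilcoxon rank-sum test for a domain-dependent fold-change shift
#'
#' Compares peak log2 fold changes inside vs. outside a domain class with
#' the Wilcoxon rank-sum test: exact enumeration when both groups have at
#' most 25 observations and no ties, tie-corrected normal approximation
#' with continuity correction otherwise.
#'
#' @param peak_log2fc Numeric per-peak log2 fold changes.
#' @param in_domain Logical per-peak domain membership.
#' @param alternative `"two.sided"`, `"greater"` (in-domain shifted up) or
#'   `"less"`.
#' @return List: `median_in`, `median_out`, `W`, `p`, `exact`.
#' @export
domain_shift_test <- function(peak_log2fc, in_domain,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(peak_log2fc) == length(in_domain))
  x <- peak_log2fc[in_domain]
  y <- peak_log2fc[!in_domain]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- length(x) <= 25L && length(y) <= 25L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact,
                correct = TRUE)
  )
  list(median_in = median(x), median_out = median(y),
       W = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Hypergeometric motif-in-domain enrichment
#'
#' Treats all peaks as the urn, peaks inside the domain as the draws and
#' motif-carrying peaks as the successes; returns the one-sided (greater)
#' upper-tail probability including the observed count.
#'
#' @param motif_flags Logical per-peak motif presence.
#' @param domain_flags Logical per-peak domain membership.
#' @return List: `observed` (motif peaks in domain), `expected`, `p`.
#' @export
motif_domain_enrichment <- function(motif_flags, domain_flags) {
  stopifnot(length(motif_flags) == length(domain_flags))
  N <- length(motif_flags)
  if (!N) stop("empty peak set")
  K <- sum(motif_flags)
  n <- sum(domain_flags)
  k <- sum(motif_flags & domain_flags)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(observed = k, expected = n * K / N, p = p)
}

#' Motif-by-domain interaction test on accessibility change
#'
#' Fits `log2FC ~ motif + domain + motif:domain` by ordinary least squares
#' and tests whether the interaction is positive (one-sided), i.e. whether
#' motif-carrying peaks inside the domain gain accessibility beyond the
#' additive expectation from motif and domain alone.
#'
#' @param peak_log2fc Numeric per-peak log2 fold changes.
#' @param motif_flag,domain_flag Logical per-peak indicators; all four
#'   cells of the implied 2x2 design must be non-empty.
#' @return List: `coefficients` (intercept, motif, domain, interaction),
#'   `se`, `t`, `p_interaction` (one-sided, interaction > 0).
#' @export
interaction_test <- function(peak_log2fc, motif_flag, domain_flag) {
  stopifnot(length(peak_log2fc) == length(motif_flag),
            length(peak_log2fc) == length(domain_flag))
  mf <- as.integer(motif_flag)
  df_ <- as.integer(domain_flag)
  cells <- table(factor(mf, levels = 0:1), factor(df_, levels = 0:1))
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(apply(empty, 1L, function(ij) {
           paste0("motif=", ij[1] - 1, ",domain=", ij[2] - 1)
         }), collapse = "; "))
  }
  fit <- lm(peak_log2fc ~ mf * df_)
  sm <- summary(fit)$coefficients
  co <- setNames(sm[, 1L], c("intercept", "motif", "domain", "interaction"))
  se <- setNames(sm[, 2L], names(co))
  tv <- setNames(sm[, 3L], names(co))
  p_one <- pt(tv[["interaction"]], df = fit$df.residual, lower.tail = FALSE)
  list(coefficients = co, se = se, t = tv, p_interaction = unname(p_one))
}
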