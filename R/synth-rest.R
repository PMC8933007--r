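#' Simulate a binary motif matrix with label-generating coefficients
#'
#' Motif presence is i.i.d. Bernoulli per (peak, motif); each peak's
#' accessibility-direction label is drawn
#' `Bernoulli(logistic(intercept + m_p . beta))` from its binary motif
#' vector, so the planted coefficient vector is the generative truth the
#' ridge model should recover.
#'
#' @param spec A [simulation_spec()].
#' @param n_peaks Number of peaks (rows); defaults to the ATAC peak count.
#' @return List: `matrix` (binary peak by motif), `label` (`"up"`/`"down"`
#'   per peak, named), `labels` (list form for the model functions),
#'   `truth_beta`, `intercept`.
#' @export
simulate_motif_labels <- function(spec, n_peaks = spec$atac$n_peaks) {
  stopifnot(inherits(spec, "simulation_spec"))
  mo <- spec$motif
  if (length(mo$beta) != mo$n_motifs) {
    stop("planted coefficient vector length must equal n_motifs")
  }
  set.seed(derive_seed(spec$seed, 33L))
  m <- matrix(rbinom(n_peaks * mo$n_motifs, 1L, mo$motif_freq),
              nrow = n_peaks,
              dimnames = list(sprintf("peak_%05d", seq_len(n_peaks)),
                              sprintf("motif_%03d", seq_len(mo$n_motifs))))
  eta <- mo$intercept + as.numeric(m %*% mo$beta)
  up <- rbinom(n_peaks, 1L, plogis(eta)) == 1L
  label <- ifelse(up, "up", "down")
  names(label) <- rownames(m)
  list(matrix = m, label = label,
       labels = list(up = rownames(m)[up], down = rownames(m)[!up]),
       truth_beta = setNames(mo$beta, colnames(m)),
       intercept = mo$intercept)
}

#' Simulate single cells ramping a senescence program with PDL
#'
#' Each cell draws a cell-cycle phase from a PDL-dependent schedule (the
#' G1 fraction grows linearly with PDL; S and G2M split the remainder) and
#' a senescence-program intensity that increases deterministically with
#' PDL plus per-cell noise; the intensity multiplies the program gene set
#' in every phase, so the program ramps gradually even in proliferating
#' cells.  Phase marker genes are boosted in their phase so that score-based
#' phase assignment is exercisable.  Counts are negative binomial.
#'
#' @param spec A [simulation_spec()].
#' @return List: `counts` (gene by cell), `cell_meta` (`cell_id`, `PDL`,
#'   `phase`, `program_intensity`), `gene_sets` (`program`, `s`, `g2m`),
#'   `truth` (per-cell phase and intensity).
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  cc <- spec$cells
  if (cc$program_size < 1L) stop("program gene set must be non-empty")
  set.seed(derive_seed(spec$seed, 44L))
  genes <- sprintf("gene_%04d", seq_len(cc$n_genes))
  program <- genes[seq_len(cc$program_size)]
  s_set <- genes[cc$program_size + seq_len(cc$n_phase_markers)]
  g2m_set <- genes[cc$program_size + cc$n_phase_markers +
                     seq_len(cc$n_phase_markers)]
  pdl <- rep(cc$pdl, each = cc$cells_per_pdl)
  x <- (pdl - min(cc$pdl)) / (max(cc$pdl) - min(cc$pdl))
  g1 <- cc$g1_frac_first + (cc$g1_frac_last - cc$g1_frac_first) * x
  n_cells <- length(pdl)
  phase <- vapply(seq_len(n_cells), function(i) {
    sample(c("G1", "S", "G2M"), 1L,
           prob = c(g1[i], (1 - g1[i]) / 2, (1 - g1[i]) / 2))
  }, "")
  intensity <- cc$program_slope * x + rnorm(n_cells, 0, cc$program_noise_sd)
  base <- rlnorm(cc$n_genes, cc$base_meanlog, cc$base_sdlog)
  cell_factor <- rlnorm(n_cells, 0, cc$cell_factor_sd)
  mu <- outer(base, cell_factor)
  prog_rows <- match(program, genes)
  mu[prog_rows, ] <- mu[prog_rows, ] * rep(2^intensity, each = length(prog_rows))
  s_rows <- match(s_set, genes)
  g2m_rows <- match(g2m_set, genes)
  mu[s_rows, phase == "S"] <- mu[s_rows, phase == "S"] * cc$marker_boost
  mu[g2m_rows, phase == "G2M"] <- mu[g2m_rows, phase == "G2M"] * cc$marker_boost
  counts <- if (cc$dispersion == 0) {
    matrix(rpois(length(mu), mu), nrow(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / cc$dispersion), nrow(mu))
  }
  ids <- sprintf("cell_%05d", seq_len(n_cells))
  dimnames(counts) <- list(genes, ids)
  cell_meta <- data.frame(cell_id = ids, PDL = pdl, phase = phase,
                          program_intensity = intensity,
                          stringsAsFactors = FALSE)
  ss_log("simulate_cells: ", cc$n_genes, " genes x ", n_cells,
         " cells over PDL ", min(cc$pdl), "-", max(cc$pdl),
         " (seed ", spec$seed, ")")
  list(counts = counts, cell_meta = cell_meta,
       gene_sets = list(program = program, s = s_set, g2m = g2m_set),
       truth = cell_meta)
}

#' Simulate paired WT/control metabolite panels with shared batch factors
#'
#' WT values follow `base_m * exp(slope_m * x_t + batch_t + noise)` with
#' the timepoint covariate `x_t` scaled to \[0, 1\] from the reference
#' (first) timepoint; the paired control is identical except its trend is
#' zero.  The per-timepoint batch factor is shared exactly between a WT
#' sample and its temporally paired control, which is what the paired
#' division removes.  Half the metabolites carry no trend; the rest draw
#' `|slope|` uniformly from the configured range with random sign
#' (natural-log units).
#'
#' @param spec A [simulation_spec()].
#' @return List: `wt`, `ctrl` (metabolite-by-sample matrices), `meta`,
#'   `truth` (`metabolite`, `slope`), `x` (named covariate per timepoint).
#' @export
simulate_metabolites <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  me <- spec$metab
  set.seed(derive_seed(spec$seed, 55L))
  tp <- me$timepoints
  x <- (tp - tp[1L]) / (max(tp) - tp[1L])
  mets <- sprintf("met_%03d", seq_len(me$n_metabolites))
  n_null <- round(me$frac_null * me$n_metabolites)
  slope <- c(rep(0, n_null),
             sample(c(-1, 1), me$n_metabolites - n_null, replace = TRUE) *
               runif(me$n_metabolites - n_null, me$slope_min, me$slope_max))
  slope <- sample(slope)   # shuffle which metabolites carry trend
  base <- rlnorm(me$n_metabolites, me$base_meanlog, me$base_sdlog)
  batch <- rnorm(length(tp), 0, me$batch_sd)
  cols <- expand.grid(rep = seq_len(me$n_reps), t = seq_along(tp))
  make_panel <- function(line, with_trend) {
    m <- matrix(NA_real_, me$n_metabolites, nrow(cols))
    ids <- character(nrow(cols))
    for (j in seq_len(nrow(cols))) {
      t <- cols$t[j]
      eff <- if (with_trend) slope * x[t] else 0
      m[, j] <- base * exp(eff + batch[t] +
                             rnorm(me$n_metabolites, 0, me$noise_sd))
      ids[j] <- sprintf("%s_T%02d_r%d", line, tp[t], cols$rep[j])
    }
    dimnames(m) <- list(mets, ids)
    m
  }
  wt <- make_panel("WT", TRUE)
  ctrl <- make_panel("ctrl", FALSE)
  meta <- sample_meta(c(colnames(wt), colnames(ctrl)),
                      rep(c("WT", "control"), each = nrow(cols)),
                      rep(tp[cols$t], 2L), rep(cols$rep, 2L))
  list(wt = wt, ctrl = ctrl, meta = meta,
       truth = data.frame(metabolite = mets, slope = slope,
                          stringsAsFactors = FALSE),
       x = setNames(x, tp))
}

#' Logistic-bump archetype profile
#'
#' Product of a rising and a falling logistic,
#' `plogis((t - rise) / s) * plogis((fall - t) / s)`, peaking midway
#' between `rise` and `fall`.
#'
#' @param t Pseudotime values.
#' @param rise,fall Positions of the rising and falling half-maxima.
#' @param steepness Logistic scale `s`.
#' @return Numeric profile values.
#' @export
logistic_bump <- function(t, rise, fall, steepness = 0.05) {
  plogis((t - rise) / steepness) * plogis((fall - t) / steepness)
}

#' Simulate pseudotime expression profiles from three archetypes
#'
#' Genes are split evenly over logistic-bump archetypes peaking in the
#' early, middle and late third of pseudotime; per-cell expression is the
#' archetype value at the cell's pseudotime plus Gaussian noise.
#'
#' @param spec A [simulation_spec()].
#' @return List: `expr` (gene by cell), `pseudotime` (per cell, uniform on
#'   \[0, 1\]), `truth` (`gene`, `archetype` in early/transition/late),
#'   `archetype_params` (data frame `archetype`, `rise`, `fall`,
#'   `steepness`).
#' @export
simulate_pseudotime_profiles <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  tr <- spec$traj
  set.seed(derive_seed(spec$seed, 66L))
  pars <- data.frame(archetype = c("early", "transition", "late"),
                     rise = c(-0.10, 0.35, 0.65),
                     fall = c(0.25, 0.65, 1.10),
                     steepness = tr$steepness,
                     stringsAsFactors = FALSE)
  pt <- runif(tr$n_cells)
  genes <- sprintf("tgene_%04d", seq_len(tr$n_genes))
  arch <- rep(pars$archetype, length.out = tr$n_genes)
  expr <- matrix(NA_real_, tr$n_genes, tr$n_cells,
                 dimnames = list(genes, sprintf("cell_%05d", seq_len(tr$n_cells))))
  for (i in seq_len(tr$n_genes)) {
    p <- pars[pars$archetype == arch[i], ]
    expr[i, ] <- logistic_bump(pt, p$rise, p$fall, p$steepness) +
      rnorm(tr$n_cells, 0, tr$noise_sd)
  }
  list(expr = expr, pseudotime = pt,
       truth = data.frame(gene = genes, archetype = arch,
                          stringsAsFactors = FALSE),
       archetype_params = pars)
}
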