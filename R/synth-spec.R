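#' Simulation specification with study-scale defaults
#'
#' Bundles every parameter the synthetic-data generators use.  Defaults
#' mirror the structure of a replicative-senescence multiomic time course
#' at desk scale: a 2 x 5 Mb genome tiled by 25 chromatin states with
#' NAD/LAD domains biased into the mark-free "undefined" state, 5,000 ATAC
#' peaks over PDL 20-50 with planted median log2 fold changes of 0.98
#' (NAD), 0.24 (LAD outside NADs) and 0 elsewhere, a 100-motif binary
#' matrix with one strongly predictive motif, single cells whose
#' senescence program ramps with PDL in every cell-cycle phase, paired
#' WT/control metabolite panels sharing per-timepoint batch factors, and
#' three pseudotime expression archetypes.
#'
#' @param seed Integer master seed; every generator derives its own
#'   sub-stream from it.
#' @param genome,atac,motif,cells,metab,traj Named lists overriding
#'   individual defaults of each component.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, genome = list(), atac = list(),
                            motif = list(), cells = list(), metab = list(),
                            traj = list()) {
  # segment-draw proportions; undefined segments are ~10x longer than the
  # rest, so state 25 ends up holding roughly half the genome in bp
  props <- c(rep(0.030, 4L),            # promoter states 1-4
             rep(0.035, 4L),            # transcription states 5-8
             rep(0.040, 10L),           # enhancer states 9-18
             rep(0.040, 6L), 0.100)     # miscellaneous 19-24, undefined 25
  names(props) <- as.character(1:25)
  spec <- list(
    seed = as.integer(seed),
    genome = modifyList(list(
      n_chrom = 2L, chrom_length = 5e6,
      state_proportions = props,
      n_NADs = 20L, n_LADs = 20L, placement_bias = 0.9,
      n_genes = 400L, gene_nad_keep_prob = 0.1,
      expr_meanlog = 2, expr_sdlog = 1
    ), genome),
    atac = modifyList(list(
      n_peaks = 5000L, peak_width = 500L,
      pdl = c(20, 25, 33, 37, 46, 50), n_reps = 3L,
      lfc_nad = 0.98, lfc_lad = 0.24, lfc_other = 0, lfc_sd = 0.25,
      dispersion = 0.1, lib_size = 5e6, lib_size_cv = 0.1,
      baseline_meanlog = log(2e-5), baseline_sdlog = 0.5
    ), atac),
    motif = modifyList(list(
      n_motifs = 100L, motif_freq = 0.15,
      beta = c(8, rep(0, 99L)), intercept = -4
    ), motif),
    cells = modifyList(list(
      pdl = c(25, 29, 33, 37, 46, 50), cells_per_pdl = 500L,
      n_genes = 2000L, program_size = 200L, n_phase_markers = 50L,
      program_slope = 1, program_noise_sd = 0.1,
      g1_frac_first = 0.6, g1_frac_last = 0.9,
      marker_boost = 4, dispersion = 0.3,
      base_meanlog = log(2), base_sdlog = 1, cell_factor_sd = 0.3
    ), cells),
    metab = modifyList(list(
      n_metabolites = 100L, timepoints = c(25, 33, 37, 46, 50),
      n_reps = 3L, frac_null = 0.5, slope_min = 0.5, slope_max = 2,
      batch_sd = 0.5, noise_sd = 0.1, base_meanlog = log(1e5),
      base_sdlog = 1
    ), metab),
    traj = modifyList(list(
      n_genes = 300L, n_cells = 3000L, noise_sd = 0.1,
      steepness = 0.05
    ), traj)
  )
  class(spec) <- "simulation_spec"
  validate_simulation_spec(spec)
}

validate_simulation_spec <- function(spec) {
  g <- spec$genome
  if (abs(sum(g$state_proportions) - 1) > 1e-8) {
    stop("state proportions must sum to 1")
  }
  if (g$placement_bias < 0 || g$placement_bias > 1) {
    stop("placement bias must lie in [0, 1]")
  }
  if (spec$atac$dispersion < 0 || spec$cells$dispersion < 0) {
    stop("negative-binomial dispersion must be >= 0")
  }
  if (spec$atac$lib_size <= 0) stop("library size must be positive")
  if (length(spec$motif$beta) != spec$motif$n_motifs) {
    stop("planted coefficient vector length must equal n_motifs")
  }
  if (spec$cells$program_size < 1) stop("program gene set must be non-empty")
  invisible(spec)
}

# deterministic 32-bit sub-stream seed per generator
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

#' Generate the synthetic genome fixture
#'
#' Tiles each chromosome with chromatin-state segments (the "undefined"
#' state forms long 50-200 kb blocks as heterochromatic domains do; other
#' states form 2-20 kb segments), places NADs and LADs with the configured
#' bias into undefined blocks, and scatters gene bodies that avoid NADs,
#' yielding the gene-poor, undefined-overlapping domain structure the
#' overlap analyses assume.  Gene expression scores are log-normal so
#' expression-matched sampling is exercisable.
#'
#' The placement bias is enforced as a hard guarantee: uniformly placed
#' domains are re-placed into undefined blocks until the fraction of
#' domain base pairs inside the undefined state reaches the bias.
#'
#' @param spec A [simulation_spec()].
#' @return List: `states` ([chromatin_state_map()]), `nads`, `lads`,
#'   `genes` (interval sets; `genes$score` holds expression).
#' @export
make_genome_fixture <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  g <- spec$genome
  set.seed(derive_seed(spec$seed, 11L))
  chroms <- paste0("chr", seq_len(g$n_chrom))
  seg <- list()
  for (ch in chroms) {
    pos <- 0
    starts <- ends <- numeric(0)
    states <- character(0)
    while (pos < g$chrom_length) {
      st <- sample(names(g$state_proportions), 1L,
                   prob = g$state_proportions)
      len <- if (st == "25") round(runif(1, 5e4, 2e5)) else round(runif(1, 2e3, 2e4))
      end <- min(pos + len, g$chrom_length)
      starts <- c(starts, pos); ends <- c(ends, end); states <- c(states, st)
      pos <- end
    }
    seg[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            name = states, stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, seg)
  state_intervals <- interval_set(seg$chrom, seg$start, seg$end, name = seg$name)
  undef <- state_intervals[state_intervals$name == "25", , drop = FALSE]
  place_domains <- function(n, prefix) {
    if (n == 0L) return(interval_set())
    big <- undef[undef$end - undef$start >= 6e4, , drop = FALSE]
    if (!nrow(big)) stop("no undefined block large enough to host a domain")
    used <- integer(0)
    pick_block <- function() {
      avail <- setdiff(seq_len(nrow(big)), used)
      j <- if (length(avail)) avail[sample.int(length(avail), 1L)]
           else sample.int(nrow(big), 1L)
      used <<- c(used, j)
      j
    }
    dom <- interval_set(rep("chr1", n), seq_len(n), seq_len(n) + 1L,
                        name = sprintf("%s_%02d", prefix, seq_len(n)))
    inside <- runif(n) < g$placement_bias
    set_inside <- function(i) {
      j <- pick_block()
      w <- big$end[j] - big$start[j]
      pad <- round(0.05 * w)
      dom$chrom[i] <<- big$chrom[j]
      dom$start[i] <<- big$start[j] + pad
      dom$end[i] <<- big$end[j] - pad
    }
    for (i in seq_len(n)) {
      if (inside[i]) {
        set_inside(i)
      } else {
        len <- round(runif(1, 5e4, 1.5e5))
        dom$chrom[i] <- chroms[sample.int(length(chroms), 1L)]
        dom$start[i] <- round(runif(1, 0, g$chrom_length - len))
        dom$end[i] <- dom$start[i] + len
      }
    }
    # hard bias guarantee: re-place uniform domains into undefined blocks
    # until the undefined bp fraction reaches the configured bias
    while (undefined_bp_fraction(dom, undef) < g$placement_bias - 1e-12 &&
           any(!inside)) {
      i <- which(!inside)[1L]
      set_inside(i)
      inside[i] <- TRUE
    }
    sort_intervals(dom)
  }
  nads <- place_domains(g$n_NADs, "NAD")
  lads <- place_domains(g$n_LADs, "LAD")
  # genes avoid NADs with high probability -> lower gene density inside;
  # candidates proposed in batches and thinned by rejection sampling
  nad_gr <- if (nrow(nads)) as_granges(nads) else NULL
  kept <- data.frame(chrom = character(), start = numeric(), end = numeric())
  while (nrow(kept) < g$n_genes) {
    nb <- 3L * g$n_genes
    len <- round(runif(nb, 2e3, 2e4))
    cand <- data.frame(chrom = sample(chroms, nb, replace = TRUE),
                       start = round(runif(nb, 0, g$chrom_length - len)))
    cand$end <- cand$start + len
    hit <- if (is.null(nad_gr)) rep(FALSE, nb) else {
      IRanges::overlapsAny(
        GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$start + 1L, cand$end)),
        nad_gr, ignore.strand = TRUE)
    }
    keep <- !hit | runif(nb) < g$gene_nad_keep_prob
    kept <- rbind(kept, cand[keep, , drop = FALSE])
  }
  kept <- kept[seq_len(g$n_genes), , drop = FALSE]
  genes <- interval_set(kept$chrom, kept$start, kept$end,
                        name = sprintf("gene_%04d", seq_len(g$n_genes)),
                        score = rlnorm(g$n_genes, g$expr_meanlog, g$expr_sdlog))
  ss_log("make_genome_fixture: ", nrow(state_intervals), " state segments, ",
         nrow(nads), " NADs, ", nrow(lads), " LADs, ", nrow(genes),
         " genes (seed ", spec$seed, ")")
  list(states = chromatin_state_map(state_intervals), nads = nads,
       lads = lads, genes = sort_intervals(genes))
}

undefined_bp_fraction <- function(domains, undef) {
  if (!nrow(domains)) return(1)
  dg <- as_granges(domains)
  ug <- GenomicRanges::reduce(as_granges(undef), ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(dg, ug, ignore.strand = TRUE)
  ov <- IRanges::pintersect(GenomicRanges::ranges(dg)[S4Vectors::queryHits(hits)],
                            GenomicRanges::ranges(ug)[S4Vectors::subjectHits(hits)])
  # per-domain overlap bp (ug is reduced, so no double counting within one domain)
  sum(as.numeric(IRanges::width(ov))) /
    sum(as.numeric(GenomicRanges::width(dg)))
}

#' Simulate an ATAC-seq peak count time course
#'
#' Places peaks uniformly across the synthetic genome and draws counts
#' `NB(mu, dispersion)` with `mu = L_s * b_p * 2^(f_p * x_s)`: `L_s` the
#' sample library-size factor, `b_p` a log-normal per-peak baseline, `x_s`
#' the PDL covariate scaled to \[0, 1\], and `f_p` a planted per-peak log2
#' fold change drawn around a domain-dependent centre (NAD peaks 0.98,
#' LAD-not-NAD peaks 0.24, others 0 by default).  Dispersion 0 falls back
#' to Poisson.  The per-peak truth table is returned for recovery tests.
#'
#' @param spec A [simulation_spec()].
#' @param genome Output of [make_genome_fixture()].
#' @return List: `peaks` (interval set), `counts` (peak by sample),
#'   `meta` ([sample_meta()]), `truth` (data frame `peak_id`, `in_nad`,
#'   `in_lad`, `domain`, `lfc`).
#' @export
simulate_atac <- function(spec, genome) {
  stopifnot(inherits(spec, "simulation_spec"))
  a <- spec$atac
  g <- spec$genome
  if (a$lib_size <= 0) stop("non-positive library size")
  set.seed(derive_seed(spec$seed, 22L))
  chroms <- paste0("chr", seq_len(g$n_chrom))
  ch <- sample(chroms, a$n_peaks, replace = TRUE)
  s <- round(runif(a$n_peaks, 0, g$chrom_length - a$peak_width))
  peaks <- sort_intervals(interval_set(ch, s, s + a$peak_width,
                                       name = sprintf("peak_%05d", seq_len(a$n_peaks))))
  pg <- as_granges(peaks)
  in_nad <- if (nrow(genome$nads)) {
    IRanges::overlapsAny(pg, as_granges(genome$nads), ignore.strand = TRUE)
  } else rep(FALSE, nrow(peaks))
  in_lad <- if (nrow(genome$lads)) {
    IRanges::overlapsAny(pg, as_granges(genome$lads), ignore.strand = TRUE)
  } else rep(FALSE, nrow(peaks))
  domain <- ifelse(in_nad, "NAD", ifelse(in_lad, "LAD", "other"))
  centre <- c(NAD = a$lfc_nad, LAD = a$lfc_lad, other = a$lfc_other)[domain]
  lfc <- rnorm(nrow(peaks), centre, a$lfc_sd)
  pdl <- rep(a$pdl, each = a$n_reps)
  repl <- rep(seq_len(a$n_reps), times = length(a$pdl))
  ids <- sprintf("WT_PDL%02d_r%d", pdl, repl)
  x <- (pdl - min(pdl)) / (max(pdl) - min(pdl))
  L <- a$lib_size * rlnorm(length(pdl), 0, a$lib_size_cv)
  b <- rlnorm(nrow(peaks), a$baseline_meanlog, a$baseline_sdlog)
  mu <- outer(b, L) * 2^outer(lfc, x)
  counts <- if (a$dispersion == 0) {
    matrix(rpois(length(mu), mu), nrow(mu))
  } else {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / a$dispersion), nrow(mu))
  }
  dimnames(counts) <- list(peaks$name, ids)
  meta <- sample_meta(ids, "WT", pdl, repl)
  ss_log("simulate_atac: ", nrow(peaks), " peaks x ", length(ids),
         " samples; NAD peaks ", sum(in_nad), ", LAD-only ",
         sum(in_lad & !in_nad), " (seed ", spec$seed, ")")
  list(peaks = peaks, counts = counts, meta = meta,
       lib_sizes = setNames(L, ids),
       truth = data.frame(peak_id = peaks$name, in_nad = in_nad,
                          in_lad = in_lad, domain = domain, lfc = lfc,
                          stringsAsFactors = FALSE))
}
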