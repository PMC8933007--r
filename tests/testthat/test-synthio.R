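# The generators define the study conditions every downstream test runs
# under; these tests pin their contracts: determinism, planted structure,
# and exact behaviour in degenerate limits.

small_genome <- list(n_chrom = 2L, chrom_length = 1e6, n_NADs = 5L,
                     n_LADs = 5L, n_genes = 100L)

test_that("every generator is a pure function of its spec", {
  spec <- simulation_spec(seed = 3, genome = small_genome,
                          atac = list(n_peaks = 200L),
                          cells = list(cells_per_pdl = 30L, n_genes = 150L,
                                       program_size = 20L, n_phase_markers = 10L),
                          traj = list(n_cells = 200L, n_genes = 30L))
  g1 <- make_genome_fixture(spec); g2 <- make_genome_fixture(spec)
  expect_identical(g1, g2)
  expect_identical(simulate_atac(spec, g1), simulate_atac(spec, g1))
  expect_identical(simulate_motif_labels(spec, 100L),
                   simulate_motif_labels(spec, 100L))
  expect_identical(simulate_cells(spec), simulate_cells(spec))
  expect_identical(simulate_metabolites(spec), simulate_metabolites(spec))
  expect_identical(simulate_pseudotime_profiles(spec),
                   simulate_pseudotime_profiles(spec))
})

test_that("genome fixture tiles chromosomes and plants domain/gene structure", {
  spec <- simulation_spec(seed = 5, genome = small_genome)
  gen <- make_genome_fixture(spec)
  si <- gen$states$intervals
  for (ch in unique(si$chrom)) {
    sub <- si[si$chrom == ch, ]
    expect_equal(sub$start[1], 0)
    expect_equal(sub$end[nrow(sub)], spec$genome$chrom_length)
    expect_equal(sub$start[-1], sub$end[-nrow(sub)])  # gap-free tiling
  }
  undef <- si[si$name == "25", ]
  frac <- senescape:::undefined_bp_fraction(gen$nads, undef)
  expect_gte(frac, spec$genome$placement_bias)

  # gene density strictly lower inside NADs
  gg <- as_granges(gen$genes)
  ng <- GenomicRanges::reduce(as_granges(gen$nads))
  nad_bp <- sum(as.numeric(GenomicRanges::width(ng)))
  tot_bp <- spec$genome$n_chrom * spec$genome$chrom_length
  n_in <- sum(IRanges::overlapsAny(gg, ng))
  dens_in <- n_in / nad_bp
  dens_out <- (nrow(gen$genes) - n_in) / (tot_bp - nad_bp)
  expect_lt(dens_in, dens_out)
})

test_that("placement bias 1 puts every domain base pair in the undefined state", {
  spec <- simulation_spec(seed = 2, genome = c(small_genome,
                                               list(placement_bias = 1.0)))
  gen <- make_genome_fixture(spec)
  undef <- gen$states$intervals[gen$states$intervals$name == "25", ]
  expect_equal(senescape:::undefined_bp_fraction(gen$nads, undef), 1)
  expect_equal(senescape:::undefined_bp_fraction(gen$lads, undef), 1)
})

test_that("a domain-free genome is a valid degenerate fixture", {
  spec <- simulation_spec(seed = 2, genome = c(small_genome[-(3:4)],
                                               list(n_NADs = 0L, n_LADs = 0L)))
  gen <- make_genome_fixture(spec)
  expect_equal(nrow(gen$nads), 0L)
  atac <- simulate_atac(spec, gen)
  expect_true(all(atac$truth$domain == "other"))
})

test_that("ATAC counts follow the mean model in the Poisson limit", {
  # no planted effect, no dispersion, high baseline: counts track library size
  spec <- simulation_spec(seed = 4, genome = small_genome,
                          atac = list(n_peaks = 50L, dispersion = 0,
                                      lfc_nad = 0, lfc_lad = 0, lfc_other = 0,
                                      lfc_sd = 0, baseline_meanlog = log(0.1),
                                      baseline_sdlog = 0, lib_size_cv = 0.2))
  gen <- make_genome_fixture(spec)
  atac <- simulate_atac(spec, gen)
  scaled <- sweep(atac$counts, 2L, atac$lib_sizes, `/`)
  rel <- sweep(scaled, 1L, rowMeans(scaled), `/`) - 1
  expect_lt(max(abs(rel)), 0.01)
})

test_that("a planted unit log2FC doubles expected counts across the course", {
  spec <- simulation_spec(seed = 4, genome = small_genome,
                          atac = list(n_peaks = 100L, dispersion = 0,
                                      pdl = c(20, 35, 50), n_reps = 1L,
                                      lfc_other = 1, lfc_nad = 1, lfc_lad = 1,
                                      lfc_sd = 0, baseline_meanlog = log(0.01),
                                      baseline_sdlog = 0, lib_size_cv = 0))
  gen <- make_genome_fixture(spec)
  atac <- simulate_atac(spec, gen)
  ratio <- atac$counts[, 3] / atac$counts[, 1]
  expect_equal(mean(ratio), 2, tolerance = 0.01)
})

test_that("motif labels follow the planted logistic model", {
  # null coefficients: label frequency is logistic(intercept)
  spec0 <- simulation_spec(seed = 9, motif = list(beta = rep(0, 100L),
                                                  intercept = 0))
  ml0 <- simulate_motif_labels(spec0, 5000L)
  expect_equal(mean(ml0$label == "up"), 0.5, tolerance = 0.03)

  # saturating coefficient: label equals motif presence almost surely
  spec1 <- simulation_spec(seed = 9, motif = list(beta = c(50, rep(0, 99L)),
                                                  intercept = -25))
  ml1 <- simulate_motif_labels(spec1, 2000L)
  expect_identical(unname(ml1$label == "up"), unname(ml1$matrix[, 1] == 1))
})

test_that("cell phase schedule is recovered from planted truth at 2000 cells/PDL", {
  spec <- simulation_spec(seed = 11,
                          cells = list(pdl = c(25, 37, 50),
                                       cells_per_pdl = 2000L, n_genes = 60L,
                                       program_size = 10L, n_phase_markers = 5L))
  sc <- simulate_cells(spec)
  cc <- spec$cells
  for (i in seq_along(cc$pdl)) {
    x <- (cc$pdl[i] - min(cc$pdl)) / diff(range(cc$pdl))
    g1_expect <- cc$g1_frac_first + (cc$g1_frac_last - cc$g1_frac_first) * x
    sub <- sc$cell_meta[sc$cell_meta$PDL == cc$pdl[i], ]
    expect_lt(abs(mean(sub$phase == "G1") - g1_expect), 0.03)
    expect_lt(abs(mean(sub$phase == "S") - (1 - g1_expect) / 2), 0.03)
  }
})

test_that("zero program slope leaves pseudobulk program expression flat", {
  spec <- simulation_spec(seed = 13,
                          cells = list(cells_per_pdl = 150L, n_genes = 300L,
                                       program_size = 50L, n_phase_markers = 20L,
                                       program_slope = 0))
  sc <- simulate_cells(spec)
  pb <- pseudobulk_by_group(sc$counts, sc$cell_meta, top_n_genes = 300L)
  fc <- cpm_log2fc(pb)
  prog <- intersect(spec_program <- sc$gene_sets$program, rownames(fc))
  prog_mean <- colMeans(fc[prog, , drop = FALSE])
  res <- linear_trend_test(matrix(prog_mean, 1L), pb$groups$PDL)
  expect_gt(res$p, 0.01)
})

test_that("metabolite generator satisfies its closed forms", {
  # noise 0, all-null trends: paired correction is exactly zero
  spec0 <- simulation_spec(seed = 21, metab = list(noise_sd = 0, frac_null = 1))
  mt0 <- simulate_metabolites(spec0)
  z <- paired_batch_correct(mt0$wt, mt0$ctrl, mt0$meta, reference_timepoint = 25)
  expect_lt(max(abs(z)), 1e-10)

  # noise 0, unit |slope|: corrected log2 ratio equals slope * x_t / ln 2
  spec1 <- simulation_spec(seed = 21,
                           metab = list(noise_sd = 0, frac_null = 0,
                                        slope_min = 1, slope_max = 1))
  mt1 <- simulate_metabolites(spec1)
  z1 <- paired_batch_correct(mt1$wt, mt1$ctrl, mt1$meta, reference_timepoint = 25)
  mw <- mt1$meta[match(colnames(z1), mt1$meta$sample_id), ]
  expected <- outer(mt1$truth$slope, mt1$x[as.character(mw$timepoint)]) / log(2)
  expect_equal(unname(z1), unname(expected), tolerance = 1e-10)
})

test_that("noiseless archetypes peak in their planted pseudotime third", {
  spec <- simulation_spec(seed = 31, traj = list(n_genes = 3L, n_cells = 2000L,
                                                 noise_sd = 0))
  pt <- simulate_pseudotime_profiles(spec)
  thirds <- c(early = 1L, transition = 2L, late = 3L)
  for (i in 1:3) {
    tr <- bin_smooth_trajectory(pt$expr[i, ], pt$pseudotime)
    peak_bin <- which.max(tr)
    expect_equal(ceiling(peak_bin / 20), unname(thirds[pt$truth$archetype[i]]))
  }
})

test_that("duplicated archetypes cluster perfectly at k = 3", {
  spec <- simulation_spec(seed = 31, traj = list(n_genes = 300L,
                                                 n_cells = 600L, noise_sd = 0))
  pt <- simulate_pseudotime_profiles(spec)
  st <- smooth_trajectories(pt$expr, pt$pseudotime)
  km <- kmedians_cosine(st$trajectories, k = 3L, seed = 1)
  tab <- table(km$assignment, pt$truth$archetype)
  expect_equal(sum(apply(tab, 1L, max)), nrow(pt$expr))
})
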