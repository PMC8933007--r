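#' Default analysis configuration
#'
#' All thresholds used across the pipeline live in one declarative list so a
#' whole analysis can be re-run from a single YAML file.  Values are the
#' defaults the package uses when a function argument is left `NULL`.
#'
#' @return Named list of configuration keys.
#' @export
default_config <- function() {
  list(
    peak_p_cutoff        = 0.001,  # significance cutoff for changing peaks
    de_p_cutoff          = 0.01,   # bulk differential-expression cutoff
    gene_window_bp       = 50000,  # peak-to-gene assignment window
    n_perm               = 1000,   # permutation overlap draws
    expr_bins            = 10,     # expression-matching bins (deciles)
    ridge_split_fraction = 2 / 3,  # train fraction for the held-out AUC fit
    ridge_n_models       = 10,     # bootstrap fits averaged for coefficients
    score_n_bins         = 24,     # module-score expression bins
    score_n_ctrl         = 100,    # control genes drawn per signature gene
    pseudobulk_min_cells = 15,     # groups kept only if cell count > this
    pseudobulk_top_genes = 8000,   # highest-expressed genes retained
    traj_n_bins          = 60,     # pseudotime bins
    traj_k               = 25,     # K-median clusters
    traj_boundaries      = c(20, 40),  # early/transition/late bin boundaries
    traj_p_cutoff        = 0.001,  # trajectory gene selection cutoff
    traj_top_n           = 5000,   # trajectory genes retained
    protein_norm_invert  = FALSE   # divide rather than multiply by the factor
  )
}

#' Read and validate a configuration file
#'
#' Reads a flat YAML file of `key: value` pairs and validates it against the
#' schema implied by [default_config()]: unknown keys are an error, as is a
#' value whose type or range is incompatible with its default.  Missing keys
#' fall back to the default.
#'
#' @param path Path to a YAML configuration file.
#' @return Named list with the same keys as [default_config()].
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (length(user)) {
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  num_keys <- c("peak_p_cutoff", "de_p_cutoff", "traj_p_cutoff")
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop("config key '", k, "' must be a single p-value cutoff in (0, 1]")
    }
  }
  int_keys <- c("gene_window_bp", "n_perm", "expr_bins", "ridge_n_models",
                "score_n_bins", "score_n_ctrl", "pseudobulk_min_cells",
                "pseudobulk_top_genes", "traj_n_bins", "traj_k", "traj_top_n")
  for (k in int_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop("config key '", k, "' must be a single positive integer")
    }
  }
  if (!is.numeric(cfg$ridge_split_fraction) ||
      cfg$ridge_split_fraction <= 0 || cfg$ridge_split_fraction >= 1) {
    stop("config key 'ridge_split_fraction' must lie in (0, 1)")
  }
  b <- cfg$traj_boundaries
  if (!is.numeric(b) || length(b) != 2L || b[1] >= b[2] ||
      b[2] >= cfg$traj_n_bins) {
    stop("config key 'traj_boundaries' must be two increasing bins < traj_n_bins")
  }
  if (!is.logical(cfg$protein_norm_invert) || length(cfg$protein_norm_invert) != 1L) {
    stop("config key 'protein_norm_invert' must be TRUE or FALSE")
  }
  invisible(cfg)
}

#' Toggle pipeline progress logging
#'
#' Every pipeline stage logs input sizes, filter in/out counts and the RNG
#' seed in use through [ss_log()]; logging is off by default.
#'
#' @param on Logical; enable or disable logging.
#' @export
senescape_verbose <- function(on = TRUE) {
  options(senescape.verbose = isTRUE(on))
  invisible(on)
}

ss_log <- function(...) {
  if (isTRUE(getOption("senescape.verbose", FALSE))) {
    message("[senescape] ", ...)
  }
  invisible(NULL)
}
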