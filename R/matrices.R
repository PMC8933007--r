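#' Read a feature-by-sample count matrix
#'
#' Two on-disk layouts are supported: a TSV with a header row of sample IDs
#' and feature IDs in the first column, and a MatrixMarket triplet file with
#' sidecar one-ID-per-line row/column name files (`<path>.rownames`,
#' `<path>.colnames` unless given explicitly).
#'
#' @param path Path to the TSV or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @param rownames_path,colnames_path Sidecar name files for `mtx` input.
#' @return A dense numeric matrix with feature row names and sample column
#'   names.
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"),
                        rownames_path = paste0(path, ".rownames"),
                        colnames_path = paste0(path, ".colnames")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else {
    stopifnot(file.exists(rownames_path), file.exists(colnames_path))
    sp <- Matrix::readMM(path)
    m <- as.matrix(sp)
    storage.mode(m) <- "double"   # zero-entry files read back as pattern
    rn <- readLines(rownames_path)
    cn <- readLines(colnames_path)
    if (nrow(m) != length(rn) || ncol(m) != length(cn)) {
      stop("matrix dimensions (", nrow(m), " x ", ncol(m),
           ") do not match sidecar name files (", length(rn), " x ",
           length(cn), ")")
    }
    dimnames(m) <- list(rn, cn)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate feature IDs: ",
         paste(head(unique(rownames(m)[duplicated(rownames(m))]), 5L),
               collapse = ", "))
  }
  if (anyNA(m)) stop("missing values are not allowed in a count matrix")
  m
}

#' Write a feature-by-sample matrix
#'
#' Inverse of [read_matrix()]: TSV with a `feature_id` first column, or
#' MatrixMarket triplet plus sidecar name files.
#'
#' @inheritParams read_matrix
#' @param m Numeric matrix with dimnames.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "mtx"),
                         rownames_path = paste0(path, ".rownames"),
                         colnames_path = paste0(path, ".colnames")) {
  format <- match.arg(format)
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (format == "tsv") {
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    writeLines(rownames(m), rownames_path)
    writeLines(colnames(m), colnames_path)
  }
  invisible(path)
}

#' Construct sample metadata for a time course
#'
#' Holds the covariates the trend and batch-correction stages need: cell
#' line (`WT` or `control`, the latter being the telomerase-immortalized
#' hTERT counterpart), the timepoint (PDL for WT, the temporally paired
#' PDL.ctrl for controls), replicate index, and optional batch and protein
#' concentration columns.
#'
#' @param sample_id Character sample identifiers.
#' @param line `"WT"` or `"control"` per sample.
#' @param timepoint Numeric PDL (or paired PDL.ctrl) per sample.
#' @param replicate Integer replicate index.
#' @param batch Optional categorical batch.
#' @param protein_conc Optional protein concentration (mg/mL).
#' @return A `data.frame` of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, line, timepoint, replicate,
                        batch = NA_character_, protein_conc = NA_real_) {
  if (!all(line %in% c("WT", "control"))) {
    stop("line must be 'WT' or 'control'")
  }
  x <- data.frame(sample_id = as.character(sample_id),
                  line = as.character(line),
                  timepoint = as.numeric(timepoint),
                  replicate = as.integer(replicate),
                  batch = rep_len(as.character(batch), length(sample_id)),
                  protein_conc = rep_len(as.numeric(protein_conc),
                                         length(sample_id)),
                  stringsAsFactors = FALSE)
  key <- paste(x$line, x$timepoint, x$replicate)
  if (anyDuplicated(key)) {
    stop("(line, timepoint, replicate) must be unique; duplicated: ",
         key[duplicated(key)][1L])
  }
  class(x) <- c("sample_meta", "data.frame")
  x
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `line`, `timepoint`,
#'   `replicate` and optionally `batch`, `protein_conc`.
#' @return A [sample_meta()] data frame.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("sample_id", "line", "timepoint", "replicate")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  sample_meta(df$sample_id, df$line, df$timepoint, df$replicate,
              batch = if ("batch" %in% names(df)) df$batch else NA_character_,
              protein_conc = if ("protein_conc" %in% names(df)) df$protein_conc else NA_real_)
}

#' Read a gene set file
#'
#' Accepts GMT (one set per line: name, description, genes...) or plain
#' one-gene-per-line text.
#'
#' @param path Path to the file.
#' @param format `"gmt"` or `"plain"`.
#' @return For GMT, a named list of character vectors; for plain text, a
#'   character vector.
#' @export
read_gene_sets <- function(path, format = c("gmt", "plain")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "plain") return(trimws(lines))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) stop("GMT lines need name, description, >=1 gene")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}
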