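#' Construct an interval set
#'
#' The package's common currency for genomic intervals (peaks, chromatin-state
#' instances, NADs, LADs, gene bodies) is a plain data frame in 0-based
#' half-open coordinates, mirroring BED.  `interval_set()` builds and
#' validates one; most functions accept any data frame with these columns.
#'
#' @param chrom Character vector of chromosome names (taken verbatim; no
#'   "chr" prefix manipulation is ever applied).
#' @param start,end Integer vectors; 0-based half-open, `start < end`.
#' @param name Optional character labels (need not be unique).
#' @param score Optional numeric scores.
#' @param strand Optional strand in `+`, `-`, `.`.
#' @return A `data.frame` of class `interval_set` with columns
#'   `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), name = NA_character_,
                         score = NA_real_, strand = NA_character_) {
  n <- length(chrom)
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  class(x) <- c("interval_set", "data.frame")
  validate_intervals(x)
}

validate_intervals <- function(x) {
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x))) {
    stop("interval set requires columns: ", paste(req, collapse = ", "))
  }
  if (nrow(x)) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end)) ||
        any(x$start != round(x$start)) || any(x$end != round(x$end))) {
      stop("interval coordinates must be integers")
    }
    if (any(x$start < 0)) stop("interval start coordinates must be >= 0")
    bad <- which(x$start >= x$end)
    if (length(bad)) {
      stop("interval start >= end at record(s): ",
           paste(head(bad, 5L), collapse = ", "))
    }
    if (!is.null(x$strand)) {
      s <- x$strand[!is.na(x$strand)]
      if (length(s) && !all(s %in% c("+", "-", "."))) {
        stop("strand must be one of '+', '-', '.'")
      }
    }
  }
  invisible(x)
}

#' Sort an interval set by (chrom, start, end, name)
#'
#' The ordering is total and stable given the four keys, so repeated sorting
#' of permuted copies yields byte-identical tables.
#'
#' @param x Interval set.
#' @return Sorted interval set with row names dropped.
#' @export
sort_intervals <- function(x) {
  validate_intervals(x)
  nm <- if (is.null(x$name)) rep("", nrow(x)) else ifelse(is.na(x$name), "", x$name)
  o <- order(x$chrom, x$start, x$end, nm, method = "radix")
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED file into an interval set
#'
#' BED is already 0-based half-open so coordinates are preserved verbatim.
#' Columns 4--6, when present, populate `name`, `score` and `strand`;
#' `track`, `browser` and `#` comment lines are skipped.
#'
#' @param path Path to a BED file.
#' @return An [interval_set()].
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(interval_set())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", idx[which(nf < 3L)[1]], ": fewer than 3 tab-separated fields")
  }
  getcol <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- getcol(1L)
  start <- suppressWarnings(as.numeric(getcol(2L)))
  end <- suppressWarnings(as.numeric(getcol(3L)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != round(start) | end != round(end))
  if (length(bad)) {
    stop("BED line ", idx[bad[1]], ": non-integer coordinate")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED line ", idx[bad[1]], ": start >= end")
  }
  name <- getcol(4L)
  score <- suppressWarnings(as.numeric(getcol(5L)))
  strand <- getcol(6L)
  interval_set(chrom, start, end,
               name = ifelse(is.na(name), NA_character_, name),
               score = score,
               strand = ifelse(is.na(strand), NA_character_, strand))
}

#' Write an interval set to BED
#'
#' Emits the minimal number of columns needed: 3 when no record carries a
#' name, 4/6 otherwise.  When strand is written but a record lacks a score,
#' the BED placeholder `0` is emitted so the column layout stays rectangular.
#' `read_bed(write_bed(x))` reproduces `x` record for record.
#'
#' @param x Interval set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  ncol_out <- 3L
  if (nrow(x)) {
    if (any(!is.na(x$strand))) ncol_out <- 6L
    else if (any(!is.na(x$score))) ncol_out <- 5L
    else if (any(!is.na(x$name))) ncol_out <- 4L
  }
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (ncol_out >= 4L) cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (ncol_out >= 5L) cols <- c(cols, list(ifelse(is.na(x$score), "0", as.character(x$score))))
  if (ncol_out >= 6L) cols <- c(cols, list(ifelse(is.na(x$strand), ".", x$strand)))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Convert an interval set to GRanges
#'
#' Internal coordinates are 0-based half-open; `GRanges` is 1-based closed,
#' so `start` is shifted by one at the boundary.  Zero-width contacts at
#' shared half-open boundaries therefore never register as overlap.
#'
#' @param x Interval set.
#' @return A [GenomicRanges::GRanges] with `name` and `score` metadata.
#' @export
as_granges <- function(x) {
  validate_intervals(x)
  str <- if (is.null(x$strand)) rep("*", nrow(x)) else ifelse(is.na(x$strand) | x$strand == ".", "*", x$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = str
  )
  S4Vectors::mcols(gr)$name <- if (is.null(x$name)) NA_character_ else x$name
  S4Vectors::mcols(gr)$score <- if (is.null(x$score)) NA_real_ else x$score
  gr
}

#' Default mapping of the 25 chromatin states to four broad categories
#'
#' States are grouped into promoter, enhancer, transcription and
#' miscellaneous categories; within miscellaneous, state 25 is the
#' designated mark-free "undefined" (quiescent) state.
#'
#' @return Named character vector mapping state "1".."25" to its category.
#' @export
default_state_categories <- function() {
  cat25 <- c(rep("promoter", 4L),       # 1-4   promoter/TSS states
             rep("transcription", 4L),  # 5-8   transcribed states
             rep("enhancer", 10L),      # 9-18  enhancer states
             rep("miscellaneous", 7L))  # 19-25 repressed/quiescent, 25 = undefined
  names(cat25) <- as.character(1:25)
  cat25
}

#' Construct a chromatin-state map
#'
#' A chromatin-state map is an interval set whose `name` column holds state
#' identifiers, together with a state-to-category mapping.  State instances
#' must tile without overlap within a chromosome.
#'
#' @param intervals Interval set of state instances; `name` holds the state.
#' @param categories Named character vector mapping each state to one of
#'   `promoter`, `enhancer`, `transcription`, `miscellaneous`.
#' @param undefined_state State identifier regarded as the mark-free
#'   "undefined" state (default `"25"`).
#' @return A list of class `chromatin_state_map` with elements `intervals`,
#'   `categories`, `undefined_state`.
#' @export
chromatin_state_map <- function(intervals,
                                categories = default_state_categories(),
                                undefined_state = "25") {
  validate_intervals(intervals)
  if (any(is.na(intervals$name))) stop("state instances must all be named")
  unknown <- setdiff(unique(intervals$name), names(categories))
  if (length(unknown)) {
    stop("state(s) without a category: ", paste(unknown, collapse = ", "))
  }
  if (!all(categories %in% c("promoter", "enhancer", "transcription",
                             "miscellaneous"))) {
    stop("categories must be promoter/enhancer/transcription/miscellaneous")
  }
  s <- sort_intervals(intervals)
  for (ch in unique(s$chrom)) {
    sub <- s[s$chrom == ch, ]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop("state instances overlap within chromosome ", ch)
    }
  }
  structure(list(intervals = s, categories = categories,
                 undefined_state = undefined_state),
            class = "chromatin_state_map")
}
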