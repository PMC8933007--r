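# Small in-code fixtures shared across test files.

# A two-chromosome toy state map: chr1 tiled by three states, chr2 by one.
toy_state_map <- function() {
  iv <- interval_set(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0, 1000, 2000, 0),
    end   = c(1000, 2000, 5000, 3000),
    name  = c("1", "9", "25", "25")
  )
  chromatin_state_map(iv)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_len = 1000L) {
  start <- sample.int(100000L, n)
  len <- sample.int(max_len, n, replace = TRUE)
  interval_set(sample(chroms, n, replace = TRUE), start, start + len,
               name = paste0("iv", seq_len(n)),
               score = round(runif(n), 3),
               strand = sample(c("+", "-", "."), n, replace = TRUE))
}

# brute-force per-basepair state labeling oracle for small fixtures
bp_state_oracle <- function(peak, states) {
  bps <- seq(peak$start + 1L, peak$end)  # 1-based bp covered (half-open)
  lab <- rep(NA_character_, length(bps))
  si <- states$intervals
  for (j in seq_len(nrow(si))) {
    if (si$chrom[j] != peak$chrom) next
    hit <- bps > si$start[j] & bps <= si$end[j]
    lab[hit] <- si$name[j]
  }
  states_touched <- unique(lab[!is.na(lab)])
  if (length(states_touched) != 1L) return(list(state = "discarded", relation = "discarded"))
  st <- states_touched
  # inside: every instance of st either fully covers the peak, or
  # the peak fully covers the instance (checked on intervals)
  js <- which(si$chrom == peak$chrom & si$name == st &
                si$end > peak$start & si$start < peak$end)
  if (any(si$start[js] <= peak$start & si$end[js] >= peak$end)) {
    return(list(state = st, relation = "inside"))
  }
  if (any(peak$start <= si$start[js] & peak$end >= si$end[js])) {
    return(list(state = st, relation = "inside_feature"))
  }
  list(state = "discarded", relation = "discarded")
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of rank assignments
wilcox_enum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(combn(n, n1), 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- mean(all_w)
  mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9)
}
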