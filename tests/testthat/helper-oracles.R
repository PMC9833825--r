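# Independent oracles used to freeze expected values: deliberately brute-force
# and structurally unrelated to the package implementations they check.

# all-windows OLS via lm(), one fit per window
oracle_max_slope <- function(curve, window = 20) {
  n <- nrow(curve)
  slopes <- vapply(seq_len(n - window + 1), function(i) {
    d <- curve[i:(i + window - 1), ]
    unname(coef(lm(log(od) ~ time, data = d))[2])
  }, numeric(1))
  max(slopes)
}

# reverse complement without Biostrings
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# plain substring scan over every offset, both strands
oracle_contains <- function(read, motif) {
  hit <- function(s) {
    lm_ <- nchar(motif)
    if (nchar(s) < lm_) return(FALSE)
    for (i in 1:(nchar(s) - lm_ + 1)) {
      if (substr(s, i, i + lm_ - 1) == motif) return(TRUE)
    }
    FALSE
  }
  hit(read) || hit(oracle_revcomp(read))
}

oracle_count_motifs <- function(seqs, motifs) {
  p0 <- motifs[motifs$role %in% c("ancestral", "evolved"), ]
  cont <- motifs[motifs$role == "contaminant", ]
  counts <- setNames(integer(nrow(p0)), p0$motif)
  excluded <- 0L; unassigned <- 0L
  for (s in seqs) {
    if (nrow(cont) > 0 && any(vapply(cont$sequence, function(m)
      oracle_contains(s, m), logical(1)))) {
      excluded <- excluded + 1L
      next
    }
    hits <- vapply(p0$sequence, function(m) oracle_contains(s, m), logical(1))
    if (sum(hits) == 1) counts[which(hits)] <- counts[which(hits)] + 1L
    else unassigned <- unassigned + 1L
  }
  list(counts = counts, excluded = excluded, unassigned = unassigned)
}

# small configurations used across tests (scaled for speed, not tuned)
test_protocol <- function(n_days = 12, k_cap = 1e6) {
  serial_protocol(k_cap = k_cap, n_days = n_days)
}

low_demand_config <- function(rates = rate_preset("IS+"), n_days = 12) {
  sim_config(env = demand_preset("low"), rates = rates,
             protocol = test_protocol(n_days))
}

high_demand_config <- function(rates = rate_preset("IS+"), n_days = 12) {
  sim_config(env = demand_preset("high"), rates = rates,
             protocol = test_protocol(n_days))
}

# pooled day-12 composition of an experiment
pool_final_day <- function(experiment) {
  d <- experiment[experiment$day == max(experiment$day), ]
  stats::aggregate(count ~ k + m, data = d, FUN = sum) |>
    (\(x) tibble::tibble(k = x$k, m = x$m, n = x$count))()
}
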