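# Independent oracles used to freeze expected values.

# Brute-force global alignment cost by recursive enumeration of all
# alignments; independent of the package's dynamic programme.
brute_align <- function(a, b, categories, gap = 0.75) {
  K <- length(categories)
  ia <- match(a, categories) - 1L
  ib <- match(b, categories) - 1L
  rec <- function(i, j) {
    if (i > length(ia) && j > length(ib)) return(0)
    best <- Inf
    if (i <= length(ia) && j <= length(ib)) {
      best <- min(best, abs(ia[i] - ib[j]) / (K - 1) + rec(i + 1, j + 1))
    }
    if (i <= length(ia)) best <- min(best, gap + rec(i + 1, j))
    if (j <= length(ib)) best <- min(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1) / max(length(a), length(b))
}

# Brute-force maximum-cardinality subset of diameter <= threshold.
brute_max_subset <- function(d, threshold) {
  n <- nrow(d)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(members) <= best) next
    if (length(members) < 2L ||
        max(d[members, members]) <= threshold + 1e-12) {
      best <- length(members)
    }
  }
  best
}

random_dist_matrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  dimnames(d) <- list(sprintf("c%02d", 1:n), sprintf("c%02d", 1:n))
  d
}

# Tiny canonical event log: one patient, four consecutive days of steps.
toy_log <- function() {
  event_log(data.frame(
    case_id = "P1", activity = "daily_steps",
    value = c(1000, 2000, 7000, 12000),
    timestamp = as.Date("2023-02-01") + 0:3
  ))
}

toy_patients <- function(ves, phq, case_id = "P1") {
  p <- data.frame(case_id = case_id, stringsAsFactors = FALSE)
  p$ves_scores <- list(ves)
  p$phq_scores <- list(phq)
  p
}
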