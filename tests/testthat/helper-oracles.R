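## Independent oracles kept deliberately naive: they re-derive expected
## values by enumeration / per-base summation, never by calling the code
## paths they check.

## exact one-sided rank-sum p by enumeration over all C(n, k) group
## assignments of the pooled ranks
oracle_ranksum_p <- function(fg, bg) {
  all <- c(fg, bg)
  k <- length(fg)
  r <- rank(all)
  u_obs <- sum(r[seq_len(k)]) - k * (k + 1) / 2
  combos <- utils::combn(length(all), k)
  u_all <- apply(combos, 2L, function(ix) sum(r[ix]) - k * (k + 1) / 2)
  mean(u_all >= u_obs)
}

## brute-force tangency: scale the ascending curve to the unit square, slide
## a slope-1 line up from below until it touches, report the touch point
## (largest index on ties)
oracle_tangency_rank <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- s / max(s)
  intercept <- Inf
  for (i in seq_len(n)) intercept <- min(intercept, y[i] - x[i])
  max(which(y - x - intercept < 1e-12))
}

## per-base signal area over [start, end)
oracle_track_area <- function(track, chrom, start, end) {
  tot <- 0
  for (pos in seq(start, end - 1)) {
    hit <- track$chrom == chrom & track$start <= pos & track$end > pos
    if (any(hit)) tot <- tot + track$value[which(hit)[1]]
  }
  tot
}

## small fixture: a peak set spread over two chromosomes
fixture_peaks <- function() {
  peak_set(c("chr1", "chr1", "chr1", "chr2"),
           start = c(100, 5000, 40000, 200),
           end = c(600, 5400, 41000, 900),
           name = c("p1", "p2", "p3", "p4"),
           summit = c(300, 5200, 40500, 500),
           signal = c(5, 2, 9, 1))
}

## tiny genome with known sequence content
fixture_genome <- function(len = 2000) {
  set.seed(99)
  g <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  c(chr1 = g)
}

small_sim_params <- function(seed = 11) {
  sim_params(seed = seed, n_genes = 80, n_typical_enhancers = 60,
             n_super_enhancers = 5, n_peaks_per_condition = 30,
             n_cobound = 5, n_deg_up = 10, n_deg_down = 6,
             n_promoter_peaks = 10, chrom_length = 3e6)
}
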