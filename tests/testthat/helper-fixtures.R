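# Shared fixtures, built in code at test time.

# random DNA string (no N unless asked)
rand_dna <- function(n, p_n = 0) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (p_n > 0) b[runif(n) < p_n] <- "N"
  paste(b, collapse = "")
}

# naive sliding-window motif scan (independent oracle)
naive_motif_scan <- function(seq, motif) {
  w <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(nchar(seq) - w + 1)) {
    if (substr(seq, i, i + w - 1) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# per-base boolean oracle for effective regions
naive_effective_fraction <- function(bin_start, bin_end, sites, flank) {
  covered <- rep(FALSE, bin_end - bin_start)
  for (s in sites[sites >= bin_start & sites < bin_end]) {
    lo <- max(s - flank, bin_start); hi <- min(s + flank, bin_end)
    if (hi > lo) covered[(lo - bin_start + 1):(hi - bin_start)] <- TRUE
  }
  mean(covered)
}

# hand-coded Cox-de Boor recursion (independent of splines::splineDesign)
cox_de_boor <- function(x, knots, order) {
  nb <- length(knots) - order
  B <- matrix(0, length(x), length(knots) - 1L)
  for (i in seq_len(length(knots) - 1L)) {
    B[, i] <- as.numeric(x >= knots[i] & x < knots[i + 1])
  }
  # half-open convention leaves the right boundary uncovered; close it
  rb <- max(knots)
  last_nz <- max(which(knots < rb))
  B[x == rb, last_nz] <- 1
  for (k in 2:order) {
    Bn <- matrix(0, length(x), length(knots) - k)
    for (i in seq_len(length(knots) - k)) {
      d1 <- knots[i + k - 1] - knots[i]
      d2 <- knots[i + k] - knots[i + 1]
      t1 <- if (d1 > 0) (x - knots[i]) / d1 * B[, i] else 0
      t2 <- if (d2 > 0) (knots[i + k] - x) / d2 * B[, i + 1] else 0
      Bn[, i] <- t1 + t2
    }
    B <- Bn
  }
  B[, seq_len(nb), drop = FALSE]
}

# small record table with given covariates for model tests
toy_records <- function(n, seed = 1, chrom = "chrT") {
  set.seed(seed)
  data.frame(chrom = chrom, i = seq_len(n), j = seq_len(n) + 1L,
             d = runif(n, 0, 2e6), y = 0L,
             gcz = rnorm(n), mapz = rnorm(n), excluded = FALSE)
}

# default scenario, small chromosome, fast
small_scenario <- function(seed = 1, ...) {
  simulation_scenario(seed = seed, chrom_sizes = c(chrS = 1.5e5), ...)
}

# build a small on-disk pairs+genome dataset for pipeline runs
make_run_inputs <- function(dir, seed = 71) {
  sc <- simulation_scenario(seed = seed, chrom_sizes = c(chrA = 1.8e5))
  g <- make_toy_genome(sc, dir = dir)
  ds <- simulate_dataset(sc, max_distance = 1e5)
  r <- ds$records[ds$records$y > 0, ]
  b <- ds$bins$chrA
  # one read pair per count, ends jittered near a site inside each bin
  set.seed(seed)
  near_site <- function(bid, k) {
    s <- g$sites$chrA
    lo <- b$start[match(bid, b$bin_id)]
    hi <- b$end[match(bid, b$bin_id)]
    base <- vapply(seq_along(bid), function(t) {
      ss <- s[s >= lo[t] & s < hi[t]]
      ss[1 + (k[t] %% length(ss))]
    }, 0)
    pmax(base + sample(-300:300, length(bid), TRUE), 0)
  }
  idx <- rep(seq_len(nrow(r)), r$y)
  k <- unlist(lapply(r$y, seq_len))
  pairs <- data.frame(chrom1 = "chrA", pos1 = near_site(r$i[idx], k),
                      strand1 = "+", chrom2 = "chrA",
                      pos2 = near_site(r$j[idx], k * 7 + 1), strand2 = "-")
  write.table(pairs, file.path(dir, "pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  sc
}

# brute-force hurdle upper tail by direct pmf summation
brute_upper_tail <- function(y, mu, alpha, pi0) {
  if (y == 0) return(1)
  1 - sum(hurdle_pmf(0:(y - 1), mu, alpha, pi0))
}
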