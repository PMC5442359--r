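test_that("restriction sites: exact matching, oracle agreement, validation", {
  expect_equal(find_restriction_sites("AAAAGATCAAAAGATCAAAA", "GATC"),
               c(4L, 12L))
  expect_equal(find_restriction_sites("AAAA", "GATC"), integer(0))
  set.seed(11)
  seq10k <- rand_dna(10000)
  expect_equal(find_restriction_sites(seq10k, "GATC"),
               naive_motif_scan(seq10k, "GATC"))
  # N never matches
  expect_equal(find_restriction_sites("GANC", "GATC"), integer(0))
  expect_error(find_restriction_sites("ACGT", ""), "non-empty")
  expect_error(find_restriction_sites("ACGT", "GAXC"), "A, C, G, T")
  expect_error(find_restriction_sites("ACGT", "GAT"), "palindromic")
  expect_equal(enzyme_motif("HindIII"), "AAGCTT")
  expect_equal(enzyme_motif("custom:GGCC"), "GGCC")
})

test_that("digestion tiles the chromosome exactly", {
  fr <- digest_to_fragments(20, c(4, 12))
  expect_equal(fr$start, c(0, 4, 12))
  expect_equal(fr$end, c(4, 12, 20))
  expect_equal(digest_to_fragments(20, integer(0)),
               data.frame(start = 0, end = 20))
  expect_error(digest_to_fragments(0, integer(0)), "positive")
  set.seed(12)
  for (k in 1:20) {
    L <- sample(1000:5000, 1)
    sites <- sort(sample(0:(L - 1), sample(0:30, 1)))
    fr <- digest_to_fragments(L, sites)
    expect_equal(sum(fr$end - fr$start), L)
    expect_equal(fr$start[-1], fr$end[-nrow(fr)])  # contiguity
  }
})

test_that("fragment merging keeps the remainder as a final short bin", {
  fr <- digest_to_fragments(2500, seq(100, 2400, by = 100))  # 25 fragments
  b <- merge_fragments(fr, 10)
  expect_equal(b$n_fragments, c(10L, 10L, 5L))
  expect_equal(b$end[3], 2500)
  expect_equal(b$bin_id, 1:3)
  b1 <- merge_fragments(digest_to_fragments(1000, seq(100, 900, 100)), 10)
  expect_equal(nrow(b1), 1L)
  expect_error(merge_fragments(fr, 0), ">= 1")
  # toy genome at MboI-like density: median bin width within 2x of 10 x mean
  set.seed(13)
  s <- rand_dna(60000)
  sites <- find_restriction_sites(s, "GATC")
  fr <- digest_to_fragments(60000, sites)
  b <- merge_fragments(fr, 10)
  expect_lt(median(b$end - b$start), 2 * 10 * mean(fr$end - fr$start))
  expect_gt(median(b$end - b$start), 0.5 * 10 * mean(fr$end - fr$start))
})

test_that("uniform bins truncate at the chromosome end", {
  b <- make_uniform_bins(12000, 5000)
  expect_equal(b$start, c(0, 5000, 10000))
  expect_equal(b$end, c(5000, 10000, 12000))
  expect_equal(nrow(make_uniform_bins(5000, 5000)), 1L)
  for (k in 1:10) {
    L <- sample(1e4:1e5, 1); w <- sample(c(1000, 2500, 7777), 1)
    expect_equal(nrow(make_uniform_bins(L, w)), ceiling(L / w))
  }
  expect_error(make_uniform_bins(1000, 0), ">= 1")
})

test_that("effective regions match the per-base boolean oracle", {
  er <- effective_regions(0, 5000, 2500, flank = 500)
  expect_equal(er$regions, data.frame(start = 2000, end = 3000))
  expect_equal(er$fraction, 0.2)
  er2 <- effective_regions(0, 800, 400, flank = 500)
  expect_equal(er2$regions, data.frame(start = 0, end = 800))
  expect_equal(er2$fraction, 1)
  expect_equal(effective_regions(0, 1000, integer(0))$fraction, 0)
  set.seed(14)
  for (k in 1:200) {
    st <- sample(0:5000, 1); en <- st + sample(500:4000, 1)
    sites <- sort(sample(0:(en + 1000), sample(0:8, 1)))
    fl <- sample(c(100, 300, 500), 1)
    expect_equal(effective_regions(st, en, sites, fl)$fraction,
                 naive_effective_fraction(st, en, sites, fl))
  }
})

test_that("bin features: GC and mappability over effective regions", {
  # all-G effective region
  s <- paste0(strrep("A", 100), "GATC", strrep("G", 496))
  b <- data.frame(chrom = "c", start = 0, end = 600, bin_id = 1,
                  midpoint = 300, n_fragments = 1)
  f <- bin_features(b, s, sites = 100, flank = 50)
  # effective region [50,150): bases 51..150 = 50 A's then GATC then G's
  sub <- substr(s, 51, 150)
  expect_equal(f$gc, lengths(regmatches(sub, gregexpr("[GC]", sub))) /
                 nchar(sub), ignore_attr = TRUE)
  expect_true(f$has_site)
  # character-count oracle with Ns excluded
  set.seed(15)
  s2 <- rand_dna(4000, p_n = 0.1)
  sites2 <- naive_motif_scan(s2, "GATC")
  b2 <- data.frame(chrom = "c", start = 0, end = 4000, bin_id = 1,
                   midpoint = 2000, n_fragments = 1)
  f2 <- bin_features(b2, s2, sites2, flank = 200)
  er <- effective_regions(0, 4000, sites2, 200)$regions
  chars <- unlist(strsplit(paste(substring(s2, er$start + 1, er$end),
                                 collapse = ""), ""))
  expect_equal(f2$gc, sum(chars %in% c("G", "C")) / sum(chars != "N"))
  # no-site bin gets NA features but stays in the table
  b3 <- data.frame(chrom = "c", start = 0, end = 100, bin_id = 1,
                   midpoint = 50, n_fragments = 1)
  f3 <- bin_features(b3, strrep("A", 100), integer(0))
  expect_true(is.na(f3$gc) && !f3$has_site && f3$effective_fraction == 0)
  # per-base mappability averaged over effective bases
  mp <- rep(c(0.25, 0.75), each = 300)
  f4 <- bin_features(data.frame(chrom = "c", start = 0, end = 600, bin_id = 1,
                                midpoint = 300, n_fragments = 1),
                     s, sites = 100, mappability = mp, flank = 50)
  expect_equal(f4$mappability, mean(mp[51:150]))
  expect_error(bin_features(b3, strrep("A", 100), 50, mappability = 2),
               "\\[0, 1\\]")
})

test_that("pair covariates standardize to mean 0 sd 1 per chromosome", {
  set.seed(16)
  rec <- rbind(toy_records(400, seed = 1, chrom = "c1"),
               toy_records(300, seed = 2, chrom = "c2"))
  rec$gc_raw <- runif(700, 0.1, 0.6)^2
  rec$map_raw <- runif(700, 0.3, 1)^2
  rec$gc_raw[5] <- 0  # zero raw feature -> excluded
  out <- pair_covariates(rec)
  expect_true(out$excluded[5])
  for (ch in c("c1", "c2")) {
    sel <- out$chrom == ch & !out$excluded
    expect_lt(abs(mean(out$gcz[sel])), 1e-6)
    expect_lt(abs(sd(out$gcz[sel]) - 1), 1e-6)
    expect_lt(abs(mean(out$mapz[sel])), 1e-6)
    expect_lt(abs(sd(out$mapz[sel]) - 1), 1e-6)
  }
  expect_named(attr(out, "standardization"), c("c1", "c2"))
})
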