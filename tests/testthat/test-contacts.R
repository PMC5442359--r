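mk_pairs <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                     unique1 = TRUE, unique2 = TRUE) {
  data.frame(chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
             chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
             unique1 = unique1, unique2 = unique2, stringsAsFactors = FALSE)
}

test_that("pair filtering applies the three rules in order", {
  sites <- list(c1 = c(1000L, 5000L))
  # byte-identical duplicates collapse to one survivor
  p <- mk_pairs(c("c1", "c1"), c(1000, 1000), "+", c("c1", "c1"),
                c(5000, 5000), "-")
  r <- filter_pairs(p, sites)
  expect_equal(nrow(r$pairs), 1L)
  expect_equal(unname(r$tally["duplicate"]), 1L)
  # swapped ends are the same molecule
  p2 <- rbind(p[1, ], mk_pairs("c1", 5000, "-", "c1", 1000, "+"))
  expect_equal(nrow(filter_pairs(p2, sites)$pairs), 1L)
  # RE-distance rule is a strict > flank cut
  p3 <- mk_pairs(c("c1", "c1"), c(1500, 1501), "+", c("c1", "c1"),
                 c(5000, 5000), "-")
  r3 <- filter_pairs(p3, sites, flank = 500)
  expect_equal(nrow(r3$pairs), 1L)
  expect_equal(unname(r3$tally["far_from_site"]), 1L)
  # non-unique ends removed first
  p4 <- mk_pairs("c1", 1000, "+", "c1", 5000, "-", unique1 = FALSE)
  expect_equal(unname(filter_pairs(p4, sites)$tally["non_unique"]), 1L)
})

test_that("filtering matches a rule-by-rule brute-force oracle and is idempotent", {
  set.seed(21)
  sites <- list(cA = sort(sample(0:49999, 150)),
                cB = sort(sample(0:29999, 80)))
  n <- 600
  ch1 <- sample(names(sites), n, replace = TRUE)
  p <- mk_pairs(ch1, sample(0:49999, n, replace = TRUE),
                sample(c("+", "-"), n, TRUE),
                sample(names(sites), n, replace = TRUE),
                sample(0:49999, n, replace = TRUE),
                sample(c("+", "-"), n, TRUE),
                unique1 = runif(n) > 0.1, unique2 = runif(n) > 0.1)
  p <- rbind(p, p[sample(n, 60), ])  # planted duplicates
  res <- filter_pairs(p, sites, flank = 400)
  # independent re-filter
  near <- function(ch, pos) {
    vapply(seq_along(pos), function(k) min(abs(sites[[ch[k]]] - pos[k])), 0)
  }
  q <- p[p$unique1 & p$unique2, ]
  sw <- q$chrom1 > q$chrom2 | (q$chrom1 == q$chrom2 & q$pos1 > q$pos2)
  qq <- q
  qq[sw, c("chrom1", "pos1", "strand1")] <- q[sw, c("chrom2", "pos2", "strand2")]
  qq[sw, c("chrom2", "pos2", "strand2")] <- q[sw, c("chrom1", "pos1", "strand1")]
  qq <- qq[!duplicated(qq[, 1:6]), ]
  qq <- qq[near(qq$chrom1, qq$pos1) <= 400 & near(qq$chrom2, qq$pos2) <= 400, ]
  expect_equal(nrow(res$pairs), nrow(qq))
  expect_equal(sort(paste(res$pairs$chrom1, res$pairs$pos1, res$pairs$pos2)),
               sort(paste(qq$chrom1, qq$pos1, qq$pos2)))
  # idempotence
  res2 <- filter_pairs(res$pairs, sites, flank = 400)
  expect_equal(res2$pairs, res$pairs)
  expect_equal(unname(res2$tally[c("non_unique", "duplicate",
                                   "far_from_site")]), c(0L, 0L, 0L))
})

test_that("pairs are counted into canonicalized bins", {
  bins <- list(c1 = make_uniform_bins(50000, 5000, "c1"))
  # both ends in bin 3 -> diagonal
  p <- mk_pairs("c1", 12000, "+", "c1", 14000, "-")
  tr <- assign_pairs_to_bins(p, bins)$triplets$c1
  expect_equal(tr, data.frame(i = 3L, j = 3L, y = 1L), ignore_attr = TRUE)
  # (2,7) and (7,2) both increment (2,7)
  p2 <- rbind(mk_pairs("c1", 6000, "+", "c1", 31000, "-"),
              mk_pairs("c1", 32000, "+", "c1", 7000, "-"))
  tr2 <- assign_pairs_to_bins(p2, bins)$triplets$c1
  expect_equal(tr2$i, 2L); expect_equal(tr2$j, 7L); expect_equal(tr2$y, 2L)
  # dictionary-count oracle on random pairs
  set.seed(22)
  n <- 5000
  p3 <- mk_pairs("c1", sample(0:49999, n, TRUE), "+", "c1",
                 sample(0:49999, n, TRUE), "-")
  tr3 <- assign_pairs_to_bins(p3, bins)$triplets$c1
  key <- paste(pmin(p3$pos1 %/% 5000, p3$pos2 %/% 5000) + 1,
               pmax(p3$pos1 %/% 5000, p3$pos2 %/% 5000) + 1)
  oracle <- table(key)
  expect_equal(sum(tr3$y), n)
  expect_equal(unname(tr3$y), unname(as.integer(oracle[paste(tr3$i, tr3$j)])))
  # inter-chromosomal and unassignable ends are tallied
  p4 <- rbind(mk_pairs("c1", 100, "+", "cX", 100, "-"),
              mk_pairs("c1", 100, "+", "c1", 70000, "-"))
  tl <- assign_pairs_to_bins(p4, bins)$tally
  expect_equal(unname(tl[c("inter", "unassigned")]), c(0L, 2L))
  # (cX unknown -> unassigned; beyond-end -> unassigned)
})

test_that("record enumeration includes zeros and respects the distance cap", {
  bins <- make_uniform_bins(25000, 5000, "c1")
  rec <- enumerate_interaction_bins(bins, NULL, max_distance = 12000,
                                    include_diagonal = FALSE)
  expect_equal(nrow(rec), 7L)   # (i,i+1) x4 and (i,i+2) x3
  rec_d <- enumerate_interaction_bins(bins, NULL, max_distance = 12000,
                                      include_diagonal = TRUE)
  expect_equal(nrow(rec_d), 12L)
  expect_true(all(rec$y == 0L))
  # counts land on the right records
  tr <- data.frame(i = c(1L, 2L), j = c(2L, 4L), y = c(5L, 7L))
  rec2 <- enumerate_interaction_bins(bins, tr, max_distance = 12000,
                                     include_diagonal = FALSE)
  expect_equal(rec2$y[rec2$i == 1 & rec2$j == 2], 5L)
  expect_equal(rec2$y[rec2$i == 2 & rec2$j == 4], 7L)
  expect_equal(sum(rec2$y), 12L)
  # O(n^2) oracle on non-uniform bins, order-independence of triplets
  set.seed(23)
  fr <- digest_to_fragments(40000, sort(sample(1:39999, 60)))
  nb <- merge_fragments(fr, 4, "c1")
  cap <- 15000
  oracle <- 0L
  for (a in seq_len(nrow(nb))) for (b in a:nrow(nb)) {
    if (nb$midpoint[b] - nb$midpoint[a] <= cap) oracle <- oracle + 1L
  }
  r1 <- enumerate_interaction_bins(nb, NULL, cap, include_diagonal = TRUE)
  expect_equal(nrow(r1), oracle)
  tr2 <- data.frame(i = c(3L, 1L), j = c(5L, 1L), y = c(2L, 9L))
  a1 <- enumerate_interaction_bins(nb, tr2, cap, TRUE)
  a2 <- enumerate_interaction_bins(nb, tr2[2:1, ], cap, TRUE)
  expect_identical(a1, a2)
})

test_that("count conservation holds through filter -> assign -> enumerate", {
  set.seed(24)
  L <- 60000
  s <- rand_dna(L)
  sites <- list(cZ = find_restriction_sites(s, "GATC"))
  n <- 3000
  jitter <- function(k) pmax(pmin(sites$cZ[sample(length(sites$cZ), k,
                                                  TRUE)] +
                                    sample(-600:600, k, TRUE), L - 1), 0)
  p <- mk_pairs("cZ", jitter(n), sample(c("+", "-"), n, TRUE), "cZ",
                jitter(n), sample(c("+", "-"), n, TRUE))
  flt <- filter_pairs(p, sites)
  bins <- bin_features(merge_fragments(digest_to_fragments(L, sites$cZ), 10,
                                       "cZ"), s, sites$cZ)
  asn <- assign_pairs_to_bins(flt$pairs, list(cZ = bins))
  cap <- 30000
  rec <- enumerate_interaction_bins(bins, asn$triplets$cZ, cap, TRUE)
  # pairs beyond the cap, computed independently from the triplets
  tr <- asn$triplets$cZ
  dd <- bins$midpoint[match(tr$j, bins$bin_id)] -
    bins$midpoint[match(tr$i, bins$bin_id)]
  beyond <- sum(tr$y[dd > cap])
  expect_identical(sum(rec$y) + beyond + unname(asn$tally["inter"]) +
                     unname(asn$tally["unassigned"]),
                   unname(flt$tally["kept"]))
})
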