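# random scored record set over nb bins on one chromosome
rand_scored_records <- function(nb = 30, n = 200, seed = 51, chrom = "cD") {
  set.seed(seed)
  i <- sample(nb, n, TRUE); j <- sample(nb, n, TRUE)
  rec <- data.frame(chrom = chrom, i = pmin(i, j), j = pmax(i, j))
  rec <- rec[!duplicated(rec[c("i", "j")]), ]
  rec$d <- (rec$j - rec$i) * 5000
  rec$y <- rpois(nrow(rec), 3)
  rec$p <- runif(nrow(rec))^2
  rec$q <- bh_adjust(rec$p)
  rec$q <- rec$q * runif(nrow(rec), 0.1, 1)  # spread q below p ordering
  rec$q <- pmax(rec$p, rec$q)
  rec
}

test_that("hotspot track equals the brute-force per-bin max scan", {
  rec <- data.frame(chrom = "c", i = c(4L, 2L), j = c(9L, 3L),
                    d = c(6e4, 5e3), y = c(9L, 9L),
                    p = c(1e-6, 1e-8), q = c(0.001, 0.001))
  hs <- hotspot_track(rec, fdr = 0.01, min_distance = 5e4)
  expect_equal(hs$score[hs$bin_id %in% c(4, 9)], c(6, 6))  # d filter drops (2,3)
  expect_false(any(hs$bin_id %in% c(2, 3)))
  # no significant records -> all zeros with a bin table
  bins <- make_uniform_bins(50000, 5000, "c")
  rec0 <- rec; rec0$q <- 0.5
  expect_true(all(hotspot_track(rec0, bins)$score == 0))
  # random set vs double loop
  rr <- rand_scored_records(seed = 52)
  hs2 <- hotspot_track(rr, fdr = 0.05, min_distance = 1e4)
  for (k in seq_len(nrow(hs2))) {
    b <- hs2$bin_id[k]
    inc <- rr[(rr$i == b | rr$j == b) & rr$q < 0.05 & rr$d > 1e4, ]
    expect_equal(hs2$score[k], max(-log10(inc$p)))
  }
})

test_that("bin annotation follows the precedence and distance rules", {
  bins <- data.frame(chrom = "c", start = c(10000, 0, 30000),
                     end = c(15000, 5000, 35000), bin_id = 1:3,
                     midpoint = c(12500, 2500, 32500), n_fragments = NA)
  tss <- data.frame(chrom = "c", pos = 16500)
  exons <- data.frame(chrom = "c", start = 1000, end = 1200)
  introns <- data.frame(chrom = "c", start = 1200, end = 4000)
  ann <- annotate_bins(bins, tss = tss, exons = exons, introns = introns)
  expect_equal(as.character(ann$genomic),
               c("promoter", "gene_body", "distal_intergenic"))
  # exon+intron overlap without nearby TSS is gene_body; 2 kb is inclusive
  tss2 <- data.frame(chrom = "c", pos = 17000)
  ann2 <- annotate_bins(bins, tss = tss2)
  expect_equal(as.character(ann2$genomic[1]), "promoter")  # exactly 2 kb gap
  tss3 <- data.frame(chrom = "c", pos = 17001)
  ann3 <- annotate_bins(bins, tss = tss3)
  expect_equal(as.character(ann3$genomic[1]), "distal_intergenic")
  # peaks give epigenomic labels; unknown chromosomes are skipped
  pk <- list(CTCF = data.frame(chrom = c("c", "cq"), start = c(12000, 1),
                               end = c(12100, 10)))
  expect_warning(ann4 <- annotate_bins(bins, peaks = pk), "unknown")
  expect_equal(ann4$CTCF, c(TRUE, FALSE, FALSE))
  expect_equal(ann4$unannotated, c(FALSE, TRUE, TRUE))
  # nested-loop oracle on random annotations
  set.seed(53)
  rb <- make_uniform_bins(3e5, 3000, "c")
  st <- sample(0:295000, 150)
  pk2 <- list(P = data.frame(chrom = "c", start = st, end = st + 800))
  annr <- annotate_bins(rb, peaks = pk2)
  oracle <- vapply(seq_len(nrow(rb)), function(k)
    any(pk2$P$start < rb$end[k] & pk2$P$end > rb$start[k]), TRUE)
  expect_equal(annr$P, oracle)
})

test_that("band enrichment reproduces the hypergeometric tail", {
  # construct a band with the spec'd 2x2 table (8,2,20,70)
  n <- 100
  rec <- data.frame(chrom = "c", i = 1:n, j = 2:(n + 1),
                    d = rep(15000, n), y = 1L,
                    q = c(rep(0.001, 10), rep(0.5, 90)))
  lab <- matrix(c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 20), rep(FALSE, 70)),
                ncol = 1, dimnames = list(NULL, "L-L"))
  be <- band_enrichment(rec, lab, band = 1e4, fdr = 0.01)
  expect_equal(unname(unlist(be[1, c("n_sig_lab", "n_sig_nolab", "n_ns_lab",
                                     "n_ns_nolab")])), c(8L, 2L, 20L, 70L))
  # direct hypergeometric tail sum: P(X >= 8) with 10 draws, 28 marked of 100
  oracle <- sum(dhyper(8:10, 28, 72, 10))
  expect_equal(be$fisher_p[1], oracle, tolerance = 1e-12)
  # degenerate margin: label on every record -> NA contract
  lab2 <- matrix(TRUE, n, 1, dimnames = list(NULL, "L-L"))
  be2 <- band_enrichment(rec, lab2, band = 1e4, fdr = 0.01)
  expect_true(is.na(be2$fisher_p))
  # shuffled labels are calibrated: ~5% of bands below 0.05
  set.seed(54)
  hits <- 0; tries <- 400
  for (t in seq_len(tries)) {
    l <- matrix(sample(lab), ncol = 1, dimnames = list(NULL, "L-L"))
    p <- band_enrichment(rec, l, band = 1e4, fdr = 0.01)$fisher_p
    hits <- hits + (!is.na(p) && p < 0.05)
  }
  expect_lt(hits / tries, 0.05 + 3 * sqrt(0.05 * 0.95 / tries))
})

test_that("pooled enrichment matches exact rank-sum enumeration", {
  bands <- data.frame(band_start = rep(seq(0, 9e4, 1e4), 2),
                      band_end = rep(seq(1e4, 1e5, 1e4), 2),
                      label = rep(c("A-A", "B-B"), each = 10),
                      fisher_p = c(runif(10, 0, 0.1), runif(10, 0.5, 1)))
  pe <- pooled_enrichment(bands, pool = 1e5)
  # focal uniformly smaller -> minimal achievable one-sided p for 10 vs 10
  expect_equal(pe$p[pe$label == "A-A"], 1 / choose(20, 10), tolerance = 1e-10)
  # identical values tie to p ~ 1-side contract (midranks)
  bands2 <- bands; bands2$fisher_p <- 0.5
  pe2 <- pooled_enrichment(bands2, pool = 1e5)
  expect_gt(min(pe2$p), 0.5)
  # exact enumeration oracle for small groups
  set.seed(55)
  for (rep in 1:5) {
    f <- runif(4); o <- runif(5)
    b3 <- data.frame(band_start = 0, band_end = 1e4,
                     label = c(rep("F-F", 4), rep("O-O", 5)),
                     fisher_p = c(f, o))
    pe3 <- pooled_enrichment(b3, pool = 1e5)
    # enumerate all assignments of ranks: P(W <= w_obs) for group size 4 of 9
    w_obs <- sum(rank(c(f, o))[1:4]) - 4 * 5 / 2
    combs <- combn(9, 4)
    r <- rank(c(f, o))
    ws <- apply(combs, 2, function(ix) sum(r[ix])) - 10
    expect_equal(pe3$p[pe3$label == "F-F"], mean(ws <= w_obs),
                 tolerance = 1e-10)
  }
  # single-band pools return NA
  b4 <- data.frame(band_start = 0, band_end = 1e4, label = "F-F",
                   fisher_p = 0.5)
  expect_true(is.na(pooled_enrichment(b4, pool = 1e5)$p))
})

test_that("compartment calls recover planted blocks and are orientation-stable", {
  planted <- function(seed, K = 30, ratio = 3) {
    set.seed(seed)
    member <- sample(rep(c("A", "B"), length.out = K))
    bins <- make_uniform_bins(K * 1e5, 1e5, "c")
    bins$gc <- ifelse(member == "A", 0.55, 0.40) + rnorm(K, 0, 0.01)
    bins$mappability <- 1; bins$effective_fraction <- 1; bins$has_site <- TRUE
    rec <- expand.grid(i = 1:K, j = 1:K)
    rec <- rec[rec$i <= rec$j, ]
    same <- member[rec$i] == member[rec$j]
    rec <- data.frame(chrom = "c", i = rec$i, j = rec$j,
                      d = (rec$j - rec$i) * 1e5,
                      y = rpois(nrow(rec), ifelse(same, 20 * ratio, 20)))
    list(bins = bins, rec = rec, member = member)
  }
  px <- planted(56)
  cc <- call_compartments(px$rec, px$bins, metabin = 1e5)
  expect_equal(cc$compartment, px$member)
  # orientation rule: flipping PC1 sign cannot change labels (A = high GC)
  px2 <- planted(57)
  bins_flip <- px2$bins
  bins_flip$gc <- 1 - bins_flip$gc  # invert openness -> labels must invert
  cc2 <- call_compartments(px2$rec, px2$bins, metabin = 1e5)
  cc2f <- call_compartments(px2$rec, bins_flip, metabin = 1e5)
  expect_equal(cc2$compartment,
               ifelse(cc2f$compartment == "A", "B", "A"))
  # DNase peak density orientation
  pk <- data.frame(chrom = "c",
                   start = (which(px2$member == "A") - 1) * 1e5 + 100)
  pk$end <- pk$start + 200
  cc3 <- call_compartments(px2$rec, px2$bins, metabin = 1e5, peaks = pk)
  expect_equal(cc3$compartment, px2$member)
  # guard rails
  expect_error(call_compartments(px$rec[1:10, ], px$bins[1:5, ],
                                 metabin = 1e5), "meta-bins")
  recc <- px$rec; recc$y <- 5L
  expect_error(call_compartments(recc, px$bins, metabin = 1e5), "constant")
})

test_that("downsampling is an exact without-replacement subsample", {
  rec <- rand_scored_records(seed = 58)
  expect_identical(downsample_matrix(rec, 1, seed = 1)$y, rec$y)
  for (f in c(0.75, 0.5, 0.25)) {
    dn <- downsample_matrix(rec, f, seed = 3)
    expect_equal(sum(dn$y), round(f * sum(rec$y)))
    expect_true(all(dn$y <= rec$y))
    expect_true(all(dn$y[rec$y == 0] == 0))
  }
  expect_error(downsample_matrix(rec, 0, 1), "fraction")
  expect_error(downsample_matrix(rec, 1.2, 1), "fraction")
  # hypergeometric mean: single record y=10 of N=100 at fraction 0.5
  rec2 <- data.frame(y = c(10L, 90L))
  draws <- vapply(1:3000, function(s) downsample_matrix(rec2, 0.5, s)$y[1], 0L)
  expect_lt(abs(mean(draws) - 5), 3 * sqrt(10 * .5 * .5 * 90 / 99 / 3000) + .1)
  # exchangeable over record order
  o <- c(2, 1)
  d1 <- downsample_matrix(rec2, 0.5, seed = 9)$y
  d2 <- downsample_matrix(rec2[o, , drop = FALSE], 0.5, seed = 9)$y
  expect_equal(sum(d1), sum(d2))
})

test_that("precision-recall evaluation matches hand computation", {
  # perfect ordering
  q_full <- c(rep(0.01, 5), rep(0.5, 5))
  expect_equal(pr_evaluation(q_full, 10:1)$aupr, 1)
  # mid-stratum records are excluded from the truth
  qm <- c(0.01, 0.07, 0.5)
  pr <- pr_evaluation(qm, c(3, 2, 1))
  expect_equal(pr$n_pos + pr$n_neg, 2)
  # hand-computed small case
  qf <- c(0.01, 0.01, 0.5, 0.5)
  sc <- c(4, 2, 3, 1)
  pr2 <- pr_evaluation(qf, sc)
  expect_equal(pr2$curve$precision, c(1, 1 / 2, 2 / 3, 2 / 4))
  expect_equal(pr2$curve$recall, c(1 / 2, 1 / 2, 1, 1))
  # invariant to strictly monotone transforms of the score
  pr3 <- pr_evaluation(qf, log(sc + 1))
  expect_equal(pr2$aupr, pr3$aupr)
  # random scores -> auPR near prevalence
  set.seed(59)
  qbig <- c(rep(0.01, 200), rep(0.5, 800))
  av <- mean(vapply(1:20, function(k)
    pr_evaluation(qbig, rnorm(1000))$aupr, 0))
  expect_lt(abs(av - 0.2), 0.05)
  expect_error(pr_evaluation(rep(0.5, 10), 1:10), "no positives")
})

test_that("long-range promoter networks match a brute-force filter", {
  set.seed(60)
  bins <- make_uniform_bins(4e6, 1e5, "c")
  bins$genomic <- factor(sample(c("promoter", "gene_body",
                                  "distal_intergenic"), nrow(bins), TRUE))
  rec <- rand_scored_records(nb = nrow(bins), n = 600, seed = 61, chrom = "c")
  rec$d <- (rec$j - rec$i) * 1e5
  net <- longrange_promoter_network(rec, bins, chrom_sizes = c(c = 4e6),
                                    dmin = 1.5e6, dmax = 2e6, fdr = 0.05)
  prom <- bins$bin_id[bins$genomic == "promoter"]
  oracle <- rec[rec$q < 0.05 & rec$d >= 1.5e6 & rec$d <= 2e6 &
                  rec$i %in% prom & rec$j %in% prom, ]
  expect_equal(nrow(net$edges), nrow(oracle))
  expect_equal(net$counts$n[net$counts$chrom == "c"], nrow(oracle))
  expect_equal(net$counts$per_mb, net$counts$n / 4)
  # planted clique forms one component of size 5
  bins$genomic[] <- "distal_intergenic"
  bins$genomic[1:5] <- "promoter"
  cl <- expand.grid(i = 1:5, j = 1:5)
  cl <- cl[cl$i < cl$j, ]
  recc <- data.frame(chrom = "c", i = cl$i, j = cl$j, d = 1.6e6, y = 5L,
                     p = 1e-5, q = 1e-4)
  net2 <- longrange_promoter_network(recc, bins, dmin = 1.5e6, dmax = 2e6)
  expect_equal(length(unique(net2$edges$component)), 1L)
  expect_equal(sort(unique(c(net2$edges$i, net2$edges$j))), 1:5)
  # no promoters -> empty
  bins$genomic[] <- "gene_body"
  expect_equal(nrow(longrange_promoter_network(recc, bins)$edges), 0L)
})
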