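# Downstream analyses over called interactions: hotspot tracks, annotation,
# distance-band enrichment, compartments, downsampling, promoter networks.

#' Per-bin interaction hotspot track
#'
#' For each bin, the maximum -log10(p) over its incident significant
#' records (q below \code{fdr}) at distance greater than
#' \code{min_distance}; bins with none score 0.
#'
#' @param records Scored record data frame (needs \code{p}, \code{q}).
#' @param bins Optional bin data frame (or named list); when given, every
#'   bin appears in the output.
#' @param fdr Significance threshold on \code{q} (default 0.01).
#' @param min_distance Minimum record distance in bp (strict, default 50 kb).
#' @return Data frame \code{chrom}, \code{bin_id}, \code{score} (plus
#'   \code{start}, \code{end} when \code{bins} is given).
#' @export
hotspot_track <- function(records, bins = NULL, fdr = 0.01,
                          min_distance = 5e4) {
  sig <- records[!is.na(records$q) & records$q < fdr &
                   records$d > min_distance, , drop = FALSE]
  inc <- rbind(data.frame(chrom = sig$chrom, bin = sig$i, p = sig$p),
               data.frame(chrom = sig$chrom, bin = sig$j, p = sig$p))
  inc$score <- -log10(pmax(inc$p, 1e-300))
  agg <- if (nrow(inc))
    stats::aggregate(score ~ chrom + bin, inc, max)
  else data.frame(chrom = character(0), bin = integer(0), score = numeric(0))
  if (is.null(bins)) {
    names(agg)[2] <- "bin_id"
    return(agg[order(agg$chrom, agg$bin_id), , drop = FALSE])
  }
  if (!is.data.frame(bins)) bins <- do.call(rbind, bins)
  out <- data.frame(chrom = bins$chrom, bin_id = bins$bin_id,
                    start = bins$start, end = bins$end, score = 0)
  m <- match(paste(out$chrom, out$bin_id), paste(agg$chrom, agg$bin))
  out$score[!is.na(m)] <- agg$score[m[!is.na(m)]]
  out
}

# any-overlap of bins with an interval set, per chromosome (0-based half-open)
.bins_overlap <- function(bins, intervals) {
  hit <- rep(FALSE, nrow(bins))
  for (ch in unique(bins$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (!nrow(iv)) next
    sel <- which(bins$chrom == ch)
    q <- IRanges::IRanges(start = bins$start[sel] + 1, end = bins$end[sel])
    s <- IRanges::IRanges(start = iv$start + 1, end = iv$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Annotate bins with epigenomic and genomic labels
#'
#' Epigenomic labels come from any-overlap with each named peak set (bins
#' matching none are "unannotated").  The genomic label follows the
#' precedence promoter > exon > intron > distal intergenic — a bin is a
#' promoter if a TSS lies within \code{tss_flank} bp of it — after which
#' exonic and intronic collapse to "gene_body".
#'
#' @param bins Bin data frame (any number of chromosomes).
#' @param peaks Named list of interval data frames (\code{chrom},
#'   \code{start}, \code{end}), e.g. CTCF / DNase / H3K27ac; may be NULL.
#' @param tss Data frame \code{chrom}, \code{pos} of transcription start
#'   sites (may be NULL).
#' @param exons,introns Interval data frames (may be NULL).
#' @param tss_flank Promoter distance rule (bp), default 2000.
#' @return \code{bins} with one logical column per peak set, a logical
#'   \code{unannotated}, and a \code{genomic} factor column
#'   (promoter/gene_body/distal_intergenic).
#' @export
annotate_bins <- function(bins, peaks = NULL, tss = NULL, exons = NULL,
                          introns = NULL, tss_flank = 2000) {
  known <- unique(bins$chrom)
  chk <- function(iv, what) {
    if (is.null(iv)) return(iv)
    drop <- !(iv$chrom %in% known)
    if (any(drop))
      warning(sprintf("%s: %d interval(s) on unknown chromosome skipped",
                      what, sum(drop)))
    iv[!drop, , drop = FALSE]
  }
  any_peak <- rep(FALSE, nrow(bins))
  for (nm in names(peaks)) {
    hit <- .bins_overlap(bins, chk(peaks[[nm]], nm))
    bins[[nm]] <- hit
    any_peak <- any_peak | hit
  }
  bins$unannotated <- !any_peak
  is_prom <- rep(FALSE, nrow(bins))
  if (!is.null(tss)) {
    tss <- chk(tss, "tss")
    tiv <- data.frame(chrom = tss$chrom, start = tss$pos, end = tss$pos + 1)
    ext <- bins
    ext$start <- pmax(bins$start - tss_flank, 0)
    ext$end <- bins$end + tss_flank + 1  # distance measured to the bin end
                                         # coordinate; <= flank is inclusive
    is_prom <- .bins_overlap(ext, tiv)
  }
  is_exon <- if (!is.null(exons)) .bins_overlap(bins, chk(exons, "exons"))
  else rep(FALSE, nrow(bins))
  is_intr <- if (!is.null(introns)) .bins_overlap(bins, chk(introns, "introns"))
  else rep(FALSE, nrow(bins))
  g <- ifelse(is_prom, "promoter",
              ifelse(is_exon | is_intr, "gene_body", "distal_intergenic"))
  bins$genomic <- factor(g, levels = c("promoter", "gene_body",
                                       "distal_intergenic"))
  bins
}

#' Label pairs borne by each contact
#'
#' A contact bears the unordered label pair (L1, L2) if one endpoint bears
#' L1 and the other bears L2 (both, when L1 == L2).
#'
#' @param records Record data frame.
#' @param bins Annotated bin data frame (from \code{\link{annotate_bins}}).
#' @param labels Character vector of bin label columns to combine (logical
#'   columns of \code{bins}, or levels of \code{bins$genomic}).
#' @return Logical matrix, one column per unordered label pair
#'   ("L1-L2").
#' @export
contact_label_pairs <- function(records, bins, labels) {
  key <- paste(bins$chrom, bins$bin_id)
  mi <- match(paste(records$chrom, records$i), key)
  mj <- match(paste(records$chrom, records$j), key)
  has <- function(lab) {
    if (lab %in% names(bins)) as.logical(bins[[lab]])
    else bins$genomic == lab
  }
  cols <- list()
  for (a in seq_along(labels)) for (b in a:length(labels)) {
    la <- has(labels[a]); lb <- has(labels[b])
    cols[[paste(labels[a], labels[b], sep = "-")]] <-
      (la[mi] & lb[mj]) | (lb[mi] & la[mj])
  }
  do.call(cbind, cols)
}

#' Distance-band enrichment of labels among significant contacts
#'
#' Contacts (self-ligating d = 0 excluded) are partitioned into distance
#' bands; per band and label pair, the 2x2 table of significant/not x
#' bearing/not is tested by a one-sided (enrichment) Fisher exact test.
#'
#' @param records Scored records (needs \code{d}, \code{q}).
#' @param label_matrix Logical matrix from
#'   \code{\link{contact_label_pairs}} (columns = label pairs).
#' @param band Band width (bp), default 10 kb.
#' @param fdr Significance threshold on q, default 0.01.
#' @param max_d Maximum distance, default 2 Mb.
#' @param alternative Fisher sidedness, default \code{"greater"}.
#' @return Data frame: \code{band_start}, \code{band_end}, \code{label},
#'   counts \code{n_sig_lab}, \code{n_sig_nolab}, \code{n_ns_lab},
#'   \code{n_ns_nolab}, \code{odds_ratio}, \code{fisher_p} (NA for empty or
#'   degenerate tables).
#' @export
band_enrichment <- function(records, label_matrix, band = 1e4, fdr = 0.01,
                            max_d = 2e6, alternative = "greater") {
  use <- records$d > 0 & records$d <= max_d & !is.na(records$q)
  rec <- records[use, , drop = FALSE]
  lm <- label_matrix[use, , drop = FALSE]
  bidx <- pmin(floor(rec$d / band), ceiling(max_d / band) - 1)
  sig <- rec$q < fdr
  out <- list()
  for (b in sort(unique(bidx))) {
    sel <- bidx == b
    for (lab in colnames(lm)) {
      l <- lm[sel, lab]
      tab <- c(n_sig_lab = sum(sig[sel] & l),
               n_sig_nolab = sum(sig[sel] & !l),
               n_ns_lab = sum(!sig[sel] & l),
               n_ns_nolab = sum(!sig[sel] & !l))
      m <- matrix(tab, 2, 2, byrow = TRUE)
      res <- if (sum(tab) == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0))
        list(estimate = NA_real_, p.value = NA_real_)
      else stats::fisher.test(m, alternative = alternative)
      out[[length(out) + 1L]] <-
        data.frame(band_start = b * band, band_end = (b + 1) * band,
                   label = lab, t(tab),
                   odds_ratio = unname(res$estimate),
                   fisher_p = res$p.value)
    }
  }
  do.call(rbind, out)
}

#' Pooled relative enrichment across distance bands
#'
#' Bands are pooled into contiguous regions (e.g. 10 bands of 10 kb per
#' 100 kb pool); per pool and focal label pair, a one-sided Wilcoxon
#' rank-sum test compares that pair's band Fisher P values against all
#' other pairs' band P values in the same pool (smaller P = relatively
#' enriched).
#'
#' @param bands Output of \code{\link{band_enrichment}}.
#' @param pool Pool width (bp), default 100 kb.
#' @return Data frame \code{pool_start}, \code{pool_end}, \code{label},
#'   \code{statistic}, \code{p} (NA when fewer than 2 usable band values).
#' @export
pooled_enrichment <- function(bands, pool = 1e5) {
  pidx <- floor(bands$band_start / pool)
  out <- list()
  for (pb in sort(unique(pidx))) {
    sel <- pidx == pb
    for (lab in unique(bands$label)) {
      focal <- bands$fisher_p[sel & bands$label == lab]
      other <- bands$fisher_p[sel & bands$label != lab]
      focal <- focal[!is.na(focal)]; other <- other[!is.na(other)]
      res <- if (length(focal) < 1 || length(other) < 1 ||
                 length(focal) + length(other) < 2)
        list(statistic = NA_real_, p.value = NA_real_)
      else suppressWarnings(stats::wilcox.test(focal, other,
                                               alternative = "less"))
      out[[length(out) + 1L]] <-
        data.frame(pool_start = pb * pool, pool_end = (pb + 1) * pool,
                   label = lab, statistic = unname(res$statistic),
                   p = res$p.value)
    }
  }
  do.call(rbind, out)
}

#' Call A/B compartments from the contact matrix
#'
#' Aggregates counts into 100 kb meta-bins, computes the row-correlation
#' matrix of the coarse contact matrix (zero-variance rows dropped with NA
#' labels), takes the first principal component, and labels meta-bins by
#' the sign of PC1.  The sign is oriented so the group with the higher mean
#' openness covariate — DNase peak density if \code{peaks} is given, else
#' GC content — is called "A".
#'
#' @param records Record data frame with counts \code{y} (one or more
#'   chromosomes; computed per chromosome).
#' @param bins Bin data frame covering the records.
#' @param metabin Meta-bin width (bp), default 100 kb.
#' @param peaks Optional interval data frame of open-chromatin peaks used
#'   for orientation.
#' @param min_metabins Minimum meta-bins per chromosome (default 10).
#' @return Data frame \code{chrom}, \code{start}, \code{end}, \code{pc1},
#'   \code{compartment} ("A"/"B"/NA).
#' @export
call_compartments <- function(records, bins, metabin = 1e5, peaks = NULL,
                              min_metabins = 10L) {
  out <- list()
  for (ch in unique(records$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    rec <- records[records$chrom == ch, , drop = FALSE]
    mb <- floor(b$midpoint / metabin)
    mlev <- seq(0, max(mb))
    K <- length(mlev)
    if (K < min_metabins)
      stop(sprintf("chromosome %s has %d meta-bins; need >= %d", ch, K,
                   min_metabins))
    a <- mb[match(rec$i, b$bin_id)] + 1L
    bb <- mb[match(rec$j, b$bin_id)] + 1L
    M <- matrix(0, K, K)
    for (r in seq_len(nrow(rec))) {
      M[a[r], bb[r]] <- M[a[r], bb[r]] + rec$y[r]
      if (a[r] != bb[r]) M[bb[r], a[r]] <- M[bb[r], a[r]] + rec$y[r]
    }
    keep <- apply(M, 1, stats::sd) > 0
    if (sum(keep) < 3) stop("contact matrix is (near-)constant; no compartments")
    C <- suppressWarnings(stats::cor(t(M[keep, keep, drop = FALSE])))
    C[!is.finite(C)] <- 0
    pc1 <- eigen(C, symmetric = TRUE)$vectors[, 1]
    lab <- ifelse(pc1 >= 0, "A", "B")
    # orient: A = open (higher DNase peak density, else higher GC)
    open_cov <- if (!is.null(peaks)) {
      pk <- peaks[peaks$chrom == ch, , drop = FALSE]
      vapply(mlev[keep], function(m) {
        lo <- m * metabin; hi <- (m + 1) * metabin
        sum(pmin(pk$end, hi) - pmax(pk$start, lo) > 0)
      }, 0)
    } else {
      vapply(mlev[keep], function(m)
        mean(b$gc[mb == m], na.rm = TRUE), 0)
    }
    mA <- mean(open_cov[lab == "A"], na.rm = TRUE)
    mB <- mean(open_cov[lab == "B"], na.rm = TRUE)
    if (is.finite(mA) && is.finite(mB) && mB > mA)
      lab <- ifelse(lab == "A", "B", "A")
    full <- rep(NA_character_, K)
    full_pc <- rep(NA_real_, K)
    full[keep] <- lab
    full_pc[keep] <- pc1
    out[[ch]] <- data.frame(chrom = ch, start = mlev * metabin,
                            end = (mlev + 1) * metabin, pc1 = full_pc,
                            compartment = full)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Downsample a contact matrix
#'
#' Draws \code{round(fraction * N)} of the \code{N} reads without
#' replacement across all records (a multivariate hypergeometric draw, done
#' sequentially), preserving the total exactly; zero records stay zero.
#'
#' @param records Record data frame with counts \code{y}.
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return \code{records} with resampled \code{y}.
#' @export
downsample_matrix <- function(records, fraction, seed) {
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  y <- as.integer(records$y)
  N <- sum(y)
  m <- round(fraction * N)
  if (fraction == 1) return(records)
  set.seed(seed)
  newy <- integer(length(y))
  rest <- N
  left <- m
  for (k in seq_along(y)) {
    if (left == 0L) break
    rest <- rest - y[k]
    newy[k] <- stats::rhyper(1, y[k], rest, left)
    left <- left - newy[k]
  }
  records$y <- newy
  records
}

#' Precision-recall evaluation against full-depth calls
#'
#' Truth comes from the full-depth adjusted P values: positives below
#' \code{pos_thr}, negatives above \code{neg_thr}, the stratum in between
#' excluded.  The score (e.g. -log10 p from a downsampled fit) is swept
#' over its distinct values to produce the precision-recall curve; auPR is
#' the trapezoid area over recall.
#'
#' @param q_full Full-depth adjusted P values (vector).
#' @param score Prediction scores, larger = more significant (same order).
#' @param pos_thr,neg_thr Truth thresholds (defaults 0.05 / 0.1).
#' @return List: \code{curve} (data frame \code{threshold},
#'   \code{precision}, \code{recall}), \code{aupr}, \code{n_pos},
#'   \code{n_neg}.
#' @export
pr_evaluation <- function(q_full, score, pos_thr = 0.05, neg_thr = 0.1) {
  keep <- !is.na(q_full) & !is.na(score) &
    (q_full < pos_thr | q_full > neg_thr)
  truth <- q_full[keep] < pos_thr
  s <- score[keep]
  n_pos <- sum(truth)
  if (n_pos == 0) stop("no positives in the truth set; auPR undefined")
  o <- order(s, decreasing = TRUE)
  truth <- truth[o]; s <- s[o]
  tp <- cumsum(truth)
  fp <- cumsum(!truth)
  last <- !duplicated(s, fromLast = TRUE)  # threshold = each distinct score
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / n_pos
  curve <- data.frame(threshold = s[last], precision = prec, recall = rec)
  r <- c(0, curve$recall)
  p <- c(curve$precision[1], curve$precision)
  aupr <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  list(curve = curve, aupr = aupr, n_pos = n_pos, n_neg = sum(!truth))
}

# connected components of an undirected edge list over integer node ids
.components <- function(nodes, from, to) {
  # union-find with path halving over index space
  parent <- seq_along(nodes)
  idx <- function(v) match(v, nodes)
  root <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]
    i <- parent[i] }; i }
  fi <- idx(from); ti <- idx(to)
  for (e in seq_along(fi)) {
    ra <- root(fi[e]); rb <- root(ti[e])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_along(nodes), root, 0L)
}

#' Long-range promoter-promoter interaction network
#'
#' Filters significant records (q below \code{fdr}) in the distance window
#' \code{[dmin, dmax]} whose both endpoints are promoter-labelled, and
#' reports per-chromosome counts (raw and per Mb) plus the promoter-bin
#' edge list with connected-component membership.
#'
#' @param records Scored records.
#' @param bins Annotated bins (needs \code{genomic}).
#' @param chrom_sizes Named vector of chromosome lengths (bp) for the
#'   per-Mb normalization (optional).
#' @param dmin,dmax Distance window (bp), defaults 1.5 and 2 Mb.
#' @param fdr Significance threshold, default 0.01.
#' @return List: \code{counts} (data frame \code{chrom}, \code{n},
#'   \code{per_mb}), \code{edges} (data frame \code{chrom}, \code{i},
#'   \code{j}, \code{q}, \code{component}).
#' @export
longrange_promoter_network <- function(records, bins, chrom_sizes = NULL,
                                       dmin = 1.5e6, dmax = 2e6, fdr = 0.01) {
  key <- paste(bins$chrom, bins$bin_id)
  prom <- bins$genomic == "promoter"
  pi_ <- prom[match(paste(records$chrom, records$i), key)]
  pj <- prom[match(paste(records$chrom, records$j), key)]
  sel <- !is.na(records$q) & records$q < fdr & records$d >= dmin &
    records$d <= dmax & !is.na(pi_) & !is.na(pj) & pi_ & pj
  ed <- records[sel, c("chrom", "i", "j", "q"), drop = FALSE]
  rownames(ed) <- NULL
  chroms <- unique(bins$chrom)
  n <- vapply(chroms, function(ch) sum(ed$chrom == ch), 0L)
  per_mb <- if (!is.null(chrom_sizes)) n / (chrom_sizes[chroms] / 1e6)
  else rep(NA_real_, length(chroms))
  ed$component <- rep(NA_integer_, nrow(ed))
  for (ch in unique(ed$chrom)) {
    s <- ed$chrom == ch
    nodes <- sort(unique(c(ed$i[s], ed$j[s])))
    comp <- .components(nodes, ed$i[s], ed$j[s])
    ed$component[s] <- comp[match(ed$i[s], nodes)]
  }
  list(counts = data.frame(chrom = chroms, n = n, per_mb = unname(per_mb)),
       edges = ed)
}
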