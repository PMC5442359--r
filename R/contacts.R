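# Read-pair filtering, contact counting and interaction-record enumeration.
#
# Pairs-file dialect: tab-separated chrom1 pos1 strand1 chrom2 pos2 strand2
# [unique1 unique2], '#'-comment lines allowed; positions are the 0-based
# 5' mapped coordinate of each end.  Pre-binned sparse triplets
# (bin_i bin_j count) are also accepted to skip this stage.

#' Read a Hi-C pairs file
#'
#' @param path Path to a tab-separated pairs file (see the package dialect:
#'   chrom1 pos1 strand1 chrom2 pos2 strand2, with optional 0/1 columns
#'   unique1 unique2; \code{#} comments allowed).
#' @return Data frame of read pairs; malformed lines are dropped with a
#'   warning.
#' @export
read_pairs <- function(path) {
  raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, fill = TRUE,
                           col.names = paste0("V", 1:8),
                           colClasses = "character")
  out <- data.frame(chrom1 = raw$V1, pos1 = suppressWarnings(as.numeric(raw$V2)),
                    strand1 = raw$V3, chrom2 = raw$V4,
                    pos2 = suppressWarnings(as.numeric(raw$V5)),
                    strand2 = raw$V6,
                    unique1 = ifelse(raw$V7 %in% c("", NA), TRUE, raw$V7 != "0"),
                    unique2 = ifelse(raw$V8 %in% c("", NA), TRUE, raw$V8 != "0"),
                    stringsAsFactors = FALSE)
  ok <- !is.na(out$pos1) & !is.na(out$pos2) &
    out$strand1 %in% c("+", "-") & out$strand2 %in% c("+", "-")
  if (any(!ok))
    warning(sum(!ok), " malformed pair line(s) skipped")
  out[ok, , drop = FALSE]
}

#' Read a sparse contact triplet file
#'
#' @param path Tab-separated file with columns bin_i, bin_j, count (a header
#'   line starting with \code{#} or column names \code{i j y} is accepted).
#' @return Data frame with columns \code{i}, \code{j}, \code{y}.
#' @export
read_triplets <- function(path) {
  tr <- utils::read.table(path, sep = "\t", comment.char = "#",
                          header = FALSE, stringsAsFactors = FALSE)
  if (is.character(tr[[1]])) tr <- tr[-1, , drop = FALSE]  # header row
  tr <- data.frame(i = as.integer(tr[[1]]), j = as.integer(tr[[2]]),
                   y = as.integer(tr[[3]]))
  sw <- tr$i > tr$j
  if (any(sw)) { tmp <- tr$i[sw]; tr$i[sw] <- tr$j[sw]; tr$j[sw] <- tmp }
  stats::aggregate(y ~ i + j, tr, sum)
}

# distance from each position to its nearest restriction site
.dist_to_nearest_site <- function(pos, sites) {
  if (!length(sites)) return(rep(Inf, length(pos)))
  sites <- sort(sites)
  idx <- findInterval(pos, sites)
  left <- ifelse(idx >= 1, pos - sites[pmax(idx, 1)], Inf)
  right <- ifelse(idx < length(sites), sites[pmin(idx + 1, length(sites))] - pos,
                  Inf)
  pmin(abs(left), abs(right))
}

#' Filter Hi-C read pairs
#'
#' Applies the standard preprocessing rules in order: (1) keep pairs where
#' both ends mapped uniquely; (2) collapse PCR duplicates — pairs identical
#' in (chrom, pos, strand) of both ends after canonical end ordering;
#' (3) drop pairs where either end lies more than \code{flank} bp from the
#' nearest restriction site on its chromosome.
#'
#' @param pairs Data frame from \code{\link{read_pairs}}.
#' @param sites Named list: per-chromosome sorted 0-based site positions.
#' @param flank Maximum distance to a restriction site (bp), default 500;
#'   the comparison is strict (a distance of exactly \code{flank} is kept).
#' @return List with \code{pairs} (the survivors, canonically end-ordered)
#'   and \code{tally} (named counts removed per rule, in rule order).
#' @export
filter_pairs <- function(pairs, sites, flank = 500) {
  n0 <- nrow(pairs)
  keep <- pairs$unique1 & pairs$unique2
  n_unique <- sum(!keep)
  pairs <- pairs[keep, , drop = FALSE]

  # canonical end ordering by (chrom, pos)
  sw <- pairs$chrom1 > pairs$chrom2 |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
  if (any(sw)) {
    tmp <- pairs[sw, c("chrom2", "pos2", "strand2")]
    pairs[sw, c("chrom2", "pos2", "strand2")] <-
      pairs[sw, c("chrom1", "pos1", "strand1")]
    pairs[sw, c("chrom1", "pos1", "strand1")] <- tmp
  }
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  pairs <- pairs[!dup, , drop = FALSE]

  near <- function(chrom, pos) {
    d <- rep(Inf, length(pos))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      d[sel] <- .dist_to_nearest_site(pos[sel], sites[[ch]])
    }
    d
  }
  ok <- near(pairs$chrom1, pairs$pos1) <= flank &
    near(pairs$chrom2, pairs$pos2) <= flank
  n_re <- sum(!ok)
  pairs <- pairs[ok, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       tally = c(input = n0, non_unique = n_unique, duplicate = n_dup,
                 far_from_site = n_re, kept = nrow(pairs)))
}

#' Count filtered pairs into interaction bins
#'
#' Each intra-chromosomal pair increments the (i, j) cell whose bins contain
#' its two end positions, with i <= j canonicalized.  Inter-chromosomal
#' pairs and ends falling outside every bin are tallied and discarded.
#'
#' @param pairs Filtered pair data frame.
#' @param bins Named list of per-chromosome bin data frames (or a single
#'   data frame with a \code{chrom} column).
#' @return List with \code{triplets} (named list per chromosome of data
#'   frames \code{i}, \code{j}, \code{y}) and \code{tally}
#'   (\code{intra}, \code{inter}, \code{unassigned}).
#' @export
assign_pairs_to_bins <- function(pairs, bins) {
  if (is.data.frame(bins)) bins <- split(bins, bins$chrom)
  locate <- function(chrom, pos) {
    out <- rep(NA_integer_, length(pos))
    for (ch in unique(chrom)) {
      b <- bins[[ch]]
      if (is.null(b)) next
      sel <- chrom == ch
      idx <- findInterval(pos[sel], b$start)
      inside <- idx >= 1 & idx <= nrow(b) & pos[sel] < b$end[pmax(idx, 1)]
      out[sel][inside] <- b$bin_id[idx[inside]]
    }
    out
  }
  b1 <- locate(pairs$chrom1, pairs$pos1)
  b2 <- locate(pairs$chrom2, pairs$pos2)
  unassigned <- is.na(b1) | is.na(b2)
  inter <- !unassigned & pairs$chrom1 != pairs$chrom2
  use <- !unassigned & !inter
  i <- pmin(b1[use], b2[use])
  j <- pmax(b1[use], b2[use])
  ch <- pairs$chrom1[use]
  triplets <- lapply(split(data.frame(i = i, j = j), ch), function(df) {
    agg <- stats::aggregate(list(y = rep(1L, nrow(df))), df, sum)
    agg[order(agg$i, agg$j), , drop = FALSE]
  })
  list(triplets = triplets,
       tally = c(intra = sum(use), inter = sum(inter),
                 unassigned = sum(unassigned)))
}

#' Enumerate the zero-inclusive interaction record table
#'
#' One record per bin pair (i, j), i <= j, on the same chromosome with
#' midpoint distance at most \code{max_distance} (inclusive), including
#' pairs with zero observed counts.  Raw pair features (products of the two
#' bins' GC, mappability and, when \code{use_effective = TRUE}, effective
#' fraction) are attached; records touching a degenerate bin are flagged
#' \code{excluded}.  Call \code{\link{pair_covariates}} afterwards to add
#' the standardized covariates.
#'
#' @param bins Bin data frame for one chromosome, with feature columns from
#'   \code{\link{bin_features}}.
#' @param triplets Data frame \code{i}, \code{j}, \code{y} of observed
#'   counts (missing pairs are zeros); may be \code{NULL} for all-zero.
#' @param max_distance Midpoint distance cap in bp (default 2 Mb).
#' @param include_diagonal Include i == j records (default TRUE; the
#'   diagonal is dropped only for comparisons with methods that filter it).
#' @param use_effective Attach the effective-fraction product covariate
#'   (uniform-bin mode).
#' @return Record data frame: \code{chrom}, \code{i}, \code{j}, \code{d},
#'   \code{y}, raw features and \code{excluded}.
#' @export
enumerate_interaction_bins <- function(bins, triplets = NULL,
                                       max_distance = 2e6,
                                       include_diagonal = TRUE,
                                       use_effective = FALSE) {
  stopifnot(!is.unsorted(bins$midpoint))
  mid <- bins$midpoint
  nb <- nrow(bins)
  ii <- jj <- vector("list", nb)
  for (k in seq_len(nb)) {
    jmax <- findInterval(mid[k] + max_distance + 1e-9, mid)
    j0 <- if (include_diagonal) k else k + 1L
    if (jmax >= j0) { ii[[k]] <- rep.int(k, jmax - j0 + 1L); jj[[k]] <- j0:jmax }
  }
  i <- unlist(ii); j <- unlist(jj)
  rec <- data.frame(chrom = bins$chrom[1], i = bins$bin_id[i],
                    j = bins$bin_id[j], d = mid[j] - mid[i],
                    y = 0L, stringsAsFactors = FALSE)
  if (!is.null(triplets) && nrow(triplets)) {
    key <- paste(rec$i, rec$j)
    tkey <- paste(triplets$i, triplets$j)
    hit <- match(tkey, key)
    ok <- !is.na(hit)
    rec$y[hit[ok]] <- as.integer(triplets$y[ok])
  }
  feat <- function(col) if (is.null(bins[[col]])) rep(1, nb) else bins[[col]]
  rec$gc_raw <- feat("gc")[i] * feat("gc")[j]
  rec$map_raw <- feat("mappability")[i] * feat("mappability")[j]
  if (use_effective)
    rec$eff_raw <- feat("effective_fraction")[i] * feat("effective_fraction")[j]
  rec$excluded <- !is.finite(rec$gc_raw) | !is.finite(rec$map_raw) |
    rec$gc_raw <= 0 | rec$map_raw <= 0
  if (use_effective)
    rec$excluded <- rec$excluded | !is.finite(rec$eff_raw) | rec$eff_raw <= 0
  rec
}
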