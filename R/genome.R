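# Genome partitioning and bias covariates.
#
# Coordinates are 0-based, half-open throughout ([start, end)), BED-style.
# A restriction site is the motif start position; fragments break at motif
# starts (the cut-offset within the recognition sequence is ignored, which
# is well inside the 500 bp flank tolerance of the effective-region rule).

.known_enzymes <- c(MboI = "GATC", HindIII = "AAGCTT", NcoI = "CCATGG")

.check_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L)
    stop("'motif' must be a non-empty character string")
  if (grepl("[^ACGT]", motif))
    stop("'motif' must contain only A, C, G, T")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  if (rc != motif)
    stop("only palindromic restriction motifs are supported")
  motif
}

#' Resolve a restriction enzyme name to its recognition motif
#'
#' Built-in enzymes: MboI (GATC), HindIII (AAGCTT), NcoI (CCATGG); a custom
#' palindromic motif can be given as \code{"custom:MOTIF"} or directly as a
#' plain ACGT string.
#'
#' @param enzyme Enzyme name or motif string.
#' @return The recognition motif (uppercase).
#' @export
enzyme_motif <- function(enzyme) {
  if (enzyme %in% names(.known_enzymes)) return(unname(.known_enzymes[enzyme]))
  if (startsWith(enzyme, "custom:"))
    return(.check_motif(toupper(sub("^custom:", "", enzyme))))
  .check_motif(toupper(enzyme))
}

#' Find restriction sites in a sequence
#'
#' Exact forward-strand matches of the (palindromic) recognition motif;
#' positions are 0-based motif-start offsets.  \code{N} bases never match.
#'
#' @param sequence A character string or \code{Biostrings::DNAString}.
#' @param motif Palindromic recognition motif (uppercase ACGT).
#' @return Sorted integer vector of 0-based site positions.
#' @examples
#' find_restriction_sites("AAAAGATCAAAAGATCAAAA", "GATC")  # 4, 12
#' @export
find_restriction_sites <- function(sequence, motif) {
  .check_motif(motif)
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  m <- Biostrings::matchPattern(motif, sequence, fixed = TRUE)
  sort(BiocGenerics::start(m)) - 1L
}

#' Digest a chromosome into restriction fragments
#'
#' Fragments are the consecutive disjoint intervals with restriction sites
#' as breakpoints: \code{[0,s1), [s1,s2), ..., [sk, L)}.
#'
#' @param chrom_length Chromosome length (bp), > 0.
#' @param sites Sorted 0-based site positions within \code{[0, chrom_length)}.
#' @return Data frame with columns \code{start}, \code{end}.
#' @export
digest_to_fragments <- function(chrom_length, sites) {
  if (length(chrom_length) != 1L || !is.finite(chrom_length) ||
      chrom_length <= 0)
    stop("'chrom_length' must be a positive scalar")
  sites <- sort(unique(as.numeric(sites)))
  if (length(sites) && (min(sites) < 0 || max(sites) >= chrom_length))
    stop("sites must lie in [0, chrom_length)")
  sites <- sites[sites > 0]  # a site at 0 adds no breakpoint
  bk <- c(0, sites, chrom_length)
  data.frame(start = bk[-length(bk)], end = bk[-1])
}

#' Merge consecutive restriction fragments into bins
#'
#' Bin k spans fragments \code{[k*n, (k+1)*n)}; a final remainder bin keeps
#' the leftover (< n) fragments at the chromosome end.
#'
#' @param fragments Data frame from \code{\link{digest_to_fragments}}.
#' @param n_per_bin Fragments per bin (default 10).
#' @param chrom Chromosome name recorded in the output.
#' @return Bin data frame: \code{chrom}, \code{start}, \code{end},
#'   \code{bin_id} (consecutive from 1), \code{midpoint},
#'   \code{n_fragments}.
#' @export
merge_fragments <- function(fragments, n_per_bin = 10L, chrom = "chr1") {
  if (n_per_bin < 1L) stop("'n_per_bin' must be >= 1")
  k <- nrow(fragments)
  grp <- (seq_len(k) - 1L) %/% as.integer(n_per_bin)
  start <- tapply(fragments$start, grp, min)
  end <- tapply(fragments$end, grp, max)
  data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
             bin_id = seq_along(start), midpoint = (as.numeric(start) +
                                                      as.numeric(end)) / 2,
             n_fragments = as.integer(table(grp)), row.names = NULL)
}

#' Uniform genomic bins
#'
#' @param chrom_length Chromosome length (bp).
#' @param width Bin width (bp), >= 1; the last bin is truncated at the
#'   chromosome end.
#' @param chrom Chromosome name.
#' @return Bin data frame as in \code{\link{merge_fragments}}
#'   (\code{n_fragments} = NA).
#' @export
make_uniform_bins <- function(chrom_length, width, chrom = "chr1") {
  if (width < 1L) stop("'width' must be >= 1")
  if (chrom_length <= 0) stop("'chrom_length' must be positive")
  start <- (seq_len(ceiling(chrom_length / width)) - 1) * width
  end <- pmin(start + width, chrom_length)
  data.frame(chrom = chrom, start = start, end = end,
             bin_id = seq_along(start), midpoint = (start + end) / 2,
             n_fragments = NA_integer_)
}

#' Effective regions of a bin
#'
#' The union over restriction sites inside the bin of \code{[s - flank,
#' s + flank)}, clipped to the bin.  Reads can only arise near a restriction
#' site, so bin-level features are averaged over these regions and the
#' effective fraction (used as a covariate with uniform bins) is their total
#' length divided by the bin length.
#'
#' @param bin_start,bin_end Bin interval (0-based half-open).
#' @param sites 0-based site positions (whole chromosome; filtered to the
#'   bin internally).
#' @param flank Flank size in bp (default 500).
#' @return List with \code{regions} (data frame \code{start}, \code{end},
#'   disjoint and sorted) and \code{fraction} (0 when the bin has no site).
#' @export
effective_regions <- function(bin_start, bin_end, sites, flank = 500) {
  if (flank < 0) stop("'flank' must be >= 0")
  s <- sites[sites >= bin_start & sites < bin_end]
  if (!length(s))
    return(list(regions = data.frame(start = numeric(0), end = numeric(0)),
                fraction = 0))
  ir <- IRanges::reduce(IRanges::restrict(
    IRanges::IRanges(start = s - flank + 1, end = s + flank),  # 1-based closed
    start = bin_start + 1, end = bin_end))
  reg <- data.frame(start = BiocGenerics::start(ir) - 1,
                    end = BiocGenerics::end(ir))
  list(regions = reg,
       fraction = sum(reg$end - reg$start) / (bin_end - bin_start))
}

#' Per-bin bias features
#'
#' GC content and mappability averaged over the effective regions (within
#' \code{flank} bp of a restriction site) of each bin.  \code{N} bases are
#' excluded from both the numerator and denominator of GC.  Bins with no
#' restriction site, an all-\code{N} effective region, or zero mappability
#' get \code{NA} features; such degenerate bins are kept in the bin table
#' but their interaction records are excluded from model fitting.
#'
#' @param bins Bin data frame for one chromosome.
#' @param sequence Chromosome sequence (character or \code{DNAString}).
#' @param sites 0-based restriction site positions.
#' @param mappability Either a single number in [0, 1] applied everywhere
#'   (default 1), or a per-base numeric vector of chromosome length.
#' @param flank Effective-region flank (bp), default 500.
#' @return \code{bins} with columns \code{gc}, \code{mappability},
#'   \code{effective_fraction}, \code{has_site} appended.
#' @export
bin_features <- function(bins, sequence, sites, mappability = 1, flank = 500) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  per_base_map <- length(mappability) > 1L
  if (any(mappability < 0 | mappability > 1))
    stop("mappability values must lie in [0, 1]")
  n <- nrow(bins)
  gc <- map <- eff <- numeric(n)
  has <- logical(n)
  for (k in seq_len(n)) {
    er <- effective_regions(bins$start[k], bins$end[k], sites, flank)
    eff[k] <- er$fraction
    has[k] <- nrow(er$regions) > 0
    if (!has[k]) { gc[k] <- NA; map[k] <- NA; next }
    v <- Biostrings::Views(sequence, start = er$regions$start + 1,
                           end = er$regions$end)
    af <- colSums(Biostrings::alphabetFrequency(v,
                                                baseOnly = TRUE)[, 1:4,
                                                                 drop = FALSE])
    tot <- sum(af)
    gc[k] <- if (tot == 0) NA_real_ else (af["C"] + af["G"]) / tot
    if (per_base_map) {
      idx <- unlist(lapply(seq_len(nrow(er$regions)), function(i)
        (er$regions$start[i] + 1):er$regions$end[i]))
      map[k] <- mean(mappability[idx])
    } else map[k] <- mappability
    if (!is.na(map[k]) && map[k] == 0) map[k] <- NA_real_
  }
  bins$gc <- gc
  bins$mappability <- map
  bins$effective_fraction <- eff
  bins$has_site <- has
  bins
}

#' Standardize pair-level covariates
#'
#' The raw pair feature for GC, mappability and (uniform-bin mode) effective
#' fraction is the product of the two bins' values; covariates are z-scores
#' of the log-transformed products, standardized per chromosome over all
#' enumerated records.  Records whose raw feature is zero or undefined are
#' flagged \code{excluded} and receive \code{NA} covariates.
#'
#' @param records Interaction record data frame with raw feature columns
#'   \code{gc_raw}, \code{map_raw} and optionally \code{eff_raw} (as built
#'   by \code{\link{enumerate_interaction_bins}}).
#' @return \code{records} with standardized columns \code{gcz}, \code{mapz}
#'   (and \code{effz}), an updated \code{excluded} flag, and the per-
#'   chromosome standardization statistics in
#'   \code{attr(, "standardization")}.
#' @export
pair_covariates <- function(records) {
  zcols <- c(gc_raw = "gcz", map_raw = "mapz", eff_raw = "effz")
  zcols <- zcols[names(zcols) %in% names(records)]
  bad <- rep(FALSE, nrow(records))
  for (rc in names(zcols))
    bad <- bad | !is.finite(records[[rc]]) | records[[rc]] <= 0
  records$excluded <- records$excluded | bad
  stats_list <- list()
  for (ch in unique(records$chrom)) {
    sel <- records$chrom == ch & !records$excluded
    for (rc in names(zcols)) {
      lv <- log(records[[rc]][sel])
      m <- mean(lv); s <- stats::sd(lv)
      if (!is.finite(s) || s == 0) s <- 1
      z <- rep(NA_real_, nrow(records))
      z[sel] <- (lv - m) / s
      if (is.null(records[[zcols[[rc]]]])) records[[zcols[[rc]]]] <- NA_real_
      records[[zcols[[rc]]]][sel] <- z[sel]
      stats_list[[ch]][[zcols[[rc]]]] <- c(mean = m, sd = s)
    }
  }
  attr(records, "standardization") <- stats_list
  records
}
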