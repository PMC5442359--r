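# End-to-end orchestration: bin -> count -> call -> outputs, and the
# downstream enrichment bundle.

.cfg_error <- function(msg) stop(structure(class = c("hicnull_config_error",
                                                     "error", "condition"),
                                           list(message = msg, call = NULL)))

#' Assemble a run configuration
#'
#' Flat key-value configuration for \code{\link{run_call}} /
#' \code{\link{run_enrich}}; unspecified values take the defaults below.
#' Round-trips losslessly through JSON.
#'
#' @param ... Named fields overriding the defaults: \code{fasta},
#'   \code{mappability}, \code{pairs}, \code{triplets}, \code{enzyme},
#'   \code{binning} ("fragments"/"uniform"), \code{merge_n},
#'   \code{bin_width}, \code{flank}, \code{max_distance},
#'   \code{include_diagonal}, \code{sample_frac}, \code{outlier_q},
#'   \code{fdr}, \code{seed}, \code{bh}, \code{out_prefix}, and for
#'   enrichment \code{peaks} (named list of BED paths), \code{tss},
#'   \code{exons}, \code{introns}, \code{band}, \code{pool},
#'   \code{metabin}, \code{dmin}, \code{dmax}.
#' @param file Optional JSON config file read first (flags in \code{...}
#'   override file values).
#' @return Named list of class \code{"hicnull_config"}.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(fasta = NULL, mappability = NULL, pairs = NULL, triplets = NULL,
              enzyme = "MboI", binning = "fragments", merge_n = 10L,
              bin_width = 5000, flank = 500, max_distance = 2e6,
              include_diagonal = TRUE, sample_frac = 0.01, outlier_q = 0.975,
              fdr = 0.01, seed = 1L, bh = "pooled", out_prefix = "hicnull",
              peaks = NULL, tss = NULL, exons = NULL, introns = NULL,
              band = 1e4, pool = 1e5, metabin = 1e5, dmin = 1.5e6,
              dmax = 2e6)
  if (!is.null(file)) {
    if (!file.exists(file)) .cfg_error(sprintf("config file not found: %s",
                                               file))
    fromfile <- jsonlite::read_json(file, simplifyVector = TRUE)
    cfg[names(fromfile)] <- fromfile
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  bad <- c(cfg$sample_frac <= 0 || cfg$sample_frac > 1,
           cfg$outlier_q <= 0.5 || cfg$outlier_q >= 1,
           cfg$fdr <= 0 || cfg$fdr >= 1, cfg$max_distance <= 0,
           cfg$flank < 0)
  if (any(bad)) .cfg_error("configuration value out of range")
  structure(cfg, class = c("hicnull_config", "list"))
}

.log_line <- function(con, fmt, ...) {
  msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 ...)
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run the full interaction-calling pipeline
#'
#' Reads the genome, partitions it into bins, computes bias features,
#' filters and counts read pairs (or consumes pre-binned triplets),
#' enumerates the zero-inclusive record table up to the distance cap, fits
#' the per-chromosome null models and writes the output bundle:
#' \code{<prefix>_bins.tsv}, \code{<prefix>_records.tsv},
#' \code{<prefix>_fits.json}, \code{<prefix>_significant.bedpe},
#' \code{<prefix>_hotspots.bedGraph}, \code{<prefix>_summary.json} and
#' \code{<prefix>_run.log}.  Deterministic given the configuration
#' (including its seed).
#'
#' @param config A \code{\link{run_config}} (or plain named list).
#' @return Invisibly, a list with \code{calls} (the \code{"hic_calls"}
#'   object), \code{bins}, \code{tally} and the output paths.
#' @export
run_call <- function(config) {
  cfg <- if (inherits(config, "hicnull_config")) config
  else do.call(run_config, config)
  for (f in c("fasta", "pairs", "triplets", "mappability")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      .cfg_error(sprintf("input '%s' not found: %s", f, cfg[[f]]))
  }
  if (is.null(cfg$fasta)) .cfg_error("'fasta' input is required")
  if (is.null(cfg$pairs) && is.null(cfg$triplets))
    .cfg_error("either 'pairs' or 'triplets' input is required")
  dir.create(dirname(paste0(cfg$out_prefix, "_x")), recursive = TRUE,
             showWarnings = FALSE)
  logcon <- file(paste0(cfg$out_prefix, "_run.log"), "w")
  on.exit(close(logcon))
  .log_line(logcon, "run_call start; seed=%d enzyme=%s binning=%s",
            cfg$seed, cfg$enzyme, cfg$binning)

  seqs <- read_fasta(cfg$fasta)
  motif <- enzyme_motif(cfg$enzyme)
  mapg <- if (!is.null(cfg$mappability)) read_bedgraph(cfg$mappability)
  sites <- lapply(seqs, find_restriction_sites, motif = motif)
  bins <- list()
  for (ch in names(seqs)) {
    L <- nchar(seqs[[ch]])
    b <- if (cfg$binning == "fragments")
      merge_fragments(digest_to_fragments(L, sites[[ch]]),
                      cfg$merge_n, chrom = ch)
    else make_uniform_bins(L, cfg$bin_width, chrom = ch)
    mp <- if (!is.null(mapg) && !is.null(mapg[[ch]]))
      .mappability_per_base(mapg[[ch]], L) else 1
    bins[[ch]] <- bin_features(b, seqs[[ch]], sites[[ch]], mappability = mp,
                               flank = cfg$flank)
    .log_line(logcon, "chromosome %s: %d sites, %d bins", ch,
              length(sites[[ch]]), nrow(b))
  }

  tally <- NULL
  if (!is.null(cfg$pairs)) {
    pairs <- read_pairs(cfg$pairs)
    flt <- filter_pairs(pairs, sites, flank = cfg$flank)
    asn <- assign_pairs_to_bins(flt$pairs, bins)
    triplets <- asn$triplets
    tally <- c(flt$tally, asn$tally)
    .log_line(logcon, "pairs: %s",
              paste(names(tally), tally, sep = "=", collapse = " "))
  } else {
    triplets <- stats::setNames(list(read_triplets(cfg$triplets)),
                                names(seqs)[1])
    if (length(seqs) > 1)
      .log_line(logcon, "triplet input assigned to chromosome %s",
                names(seqs)[1])
  }

  recs <- list()
  for (ch in names(bins)) {
    recs[[ch]] <- enumerate_interaction_bins(
      bins[[ch]], triplets[[ch]], max_distance = cfg$max_distance,
      include_diagonal = isTRUE(cfg$include_diagonal),
      use_effective = cfg$binning == "uniform")
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  records <- pair_covariates(records)
  calls <- call_interactions(records, sample_frac = cfg$sample_frac,
                             outlier_q = cfg$outlier_q, seed = cfg$seed,
                             fdr = cfg$fdr, max_distance = cfg$max_distance,
                             bh = cfg$bh)
  for (ch in names(calls$fits)) {
    f <- calls$fits[[ch]]
    .log_line(logcon, "fit %s: %s", ch,
              if (is.null(f)) "FAILED (records kept with NA p)"
              else sprintf("converged=%s alpha=%.3f outliers_removed=%d",
                           f$fit$converged, f$fit$alpha,
                           f$n_outliers_removed))
  }

  paths <- list(bins = paste0(cfg$out_prefix, "_bins.tsv"),
                records = paste0(cfg$out_prefix, "_records.tsv"),
                fits = paste0(cfg$out_prefix, "_fits.json"),
                bedpe = paste0(cfg$out_prefix, "_significant.bedpe"),
                hotspots = paste0(cfg$out_prefix, "_hotspots.bedGraph"),
                summary = paste0(cfg$out_prefix, "_summary.json"))
  write_bins(bins, paths$bins)
  write_records(calls$records, paths$records, bins = bins)
  write_fit_json(calls$fits, paths$fits)
  write_bedpe(calls$records, bins, paths$bedpe)
  hs <- hotspot_track(calls$records, bins, fdr = cfg$fdr)
  write_bedgraph(data.frame(chrom = hs$chrom, start = hs$start, end = hs$end,
                            value = hs$score), paths$hotspots,
                 name = "interaction_hotspots")
  jsonlite::write_json(list(config = unclass(cfg), tally = as.list(tally),
                            n_records = nrow(calls$records),
                            n_significant = sum(calls$records$significant),
                            converged = lapply(calls$fits, function(f)
                              if (is.null(f)) NA else f$fit$converged)),
                       paths$summary, auto_unbox = TRUE, digits = NA,
                       null = "null")
  .log_line(logcon, "run_call done: %d records, %d significant at FDR<%g",
            nrow(calls$records), sum(calls$records$significant), cfg$fdr)
  invisible(list(calls = calls, bins = bins, tally = tally, paths = paths,
                 config = cfg))
}

#' Run the downstream enrichment bundle
#'
#' Annotates bins with any supplied peak and gene-model tracks and writes
#' enrichment tables, A/B compartment calls and the long-range
#' promoter-promoter network.  Analyses whose annotations are missing are
#' skipped with a warning; the others still run.
#'
#' @param called Result of \code{\link{run_call}} (or a list with
#'   \code{calls} and \code{bins}).
#' @param config The \code{\link{run_config}} (annotation paths:
#'   \code{peaks} named list of BEDs, \code{tss} BED of TSS positions,
#'   \code{exons}/\code{introns} BEDs).
#' @return Invisibly, a list of the produced tables and paths.
#' @export
run_enrich <- function(called, config = called$config) {
  cfg <- config
  records <- called$calls$records
  bins_all <- do.call(rbind, called$bins)
  rownames(bins_all) <- NULL
  peaks <- lapply(cfg$peaks, read_bed)
  tssd <- if (!is.null(cfg$tss)) {
    tb <- read_bed(cfg$tss); data.frame(chrom = tb$chrom, pos = tb$start)
  }
  exons <- if (!is.null(cfg$exons)) read_bed(cfg$exons)
  introns <- if (!is.null(cfg$introns)) read_bed(cfg$introns)
  ann <- annotate_bins(bins_all, peaks = peaks, tss = tssd, exons = exons,
                       introns = introns)
  out <- list(bins = ann)
  pfx <- cfg$out_prefix

  if (length(peaks)) {
    lm <- contact_label_pairs(records, ann, c(names(peaks), "unannotated"))
    be <- band_enrichment(records, lm, band = cfg$band, fdr = cfg$fdr,
                          max_d = cfg$max_distance)
    pe <- pooled_enrichment(be, pool = cfg$pool)
    utils::write.table(be, paste0(pfx, "_epigenomic_bands.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(pe, paste0(pfx, "_epigenomic_pooled.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$epigenomic <- list(bands = be, pooled = pe)
  } else warning("no peak files supplied; epigenomic enrichment skipped")

  glm_ <- contact_label_pairs(records, ann,
                              c("promoter", "gene_body", "distal_intergenic"))
  gbe <- band_enrichment(records, glm_, band = cfg$band, fdr = cfg$fdr,
                         max_d = cfg$max_distance)
  gpe <- pooled_enrichment(gbe, pool = cfg$pool / 2)
  utils::write.table(gbe, paste0(pfx, "_genomic_bands.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gpe, paste0(pfx, "_genomic_pooled.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out$genomic <- list(bands = gbe, pooled = gpe)

  comp <- tryCatch(call_compartments(records, bins_all,
                                     metabin = cfg$metabin,
                                     peaks = if (length(peaks)) peaks[[1]]),
                   error = function(e) {
                     warning("compartment analysis skipped: ",
                             conditionMessage(e))
                     NULL
                   })
  if (!is.null(comp)) {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%g", comp$chrom,
                       as.integer(comp$start), as.integer(comp$end),
                       ifelse(is.na(comp$compartment), ".",
                              comp$compartment),
                       ifelse(is.na(comp$pc1), 0, comp$pc1)),
               paste0(pfx, "_compartments.bed"))
    out$compartments <- comp
  }

  net <- longrange_promoter_network(records, ann, dmin = cfg$dmin,
                                    dmax = cfg$dmax, fdr = cfg$fdr)
  utils::write.table(net$counts, paste0(pfx, "_promoter_network_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$edges, paste0(pfx, "_promoter_network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$network <- net
  invisible(out)
}
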