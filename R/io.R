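# Readers and writers for the standard text formats used by the pipeline.
# Coordinates in all BED-family output are 0-based half-open.

#' Read a (multi-record) FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector or list.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph path (4 columns: chrom start end value; track/comment
#'   lines ignored).
#' @return Named list per chromosome of data frames \code{start}, \code{end},
#'   \code{value}.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
  df <- utils::read.table(text = lines, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  lapply(split(df[c("start", "end", "value")], df$chrom),
         function(x) x[order(x$start), , drop = FALSE])
}

#' Write a bedGraph track
#'
#' @param track Named list per chromosome of data frames \code{start},
#'   \code{end}, \code{value}, or a single data frame with a \code{chrom}
#'   column.
#' @param path Output path.
#' @param name Track name header (omitted if NULL).
#' @export
write_bedgraph <- function(track, path, name = NULL) {
  if (is.data.frame(track)) track <- split(track[setdiff(names(track),
                                                         "chrom")],
                                           track$chrom)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(name))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  for (ch in names(track)) {
    x <- track[[ch]]
    writeLines(sprintf("%s\t%d\t%d\t%g", ch, as.integer(x$start),
                       as.integer(x$end), x$value), con)
  }
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' @param path BED path (first three columns chrom, start, end; extra
#'   columns kept as \code{name}, \code{score}, ...).
#' @return Data frame with at least \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df
}

#' Write bins (with features) as BED-style TSV
#'
#' @param bins Bin data frame or named list of them.
#' @param path Output path.
#' @export
write_bins <- function(bins, path) {
  if (!is.data.frame(bins)) bins <- do.call(rbind, bins)
  utils::write.table(format(bins, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write interaction records as TSV
#'
#' Columns include the bin coordinates of both anchors when a bin table is
#' supplied.
#'
#' @param records Record data frame.
#' @param path Output path.
#' @param bins Optional named list of per-chromosome bin data frames used to
#'   attach \code{start_i}, \code{end_i}, \code{start_j}, \code{end_j}.
#' @export
write_records <- function(records, path, bins = NULL) {
  out <- records
  if (!is.null(bins)) {
    co <- .record_anchors(records, bins)
    out <- cbind(out[, "chrom", drop = FALSE], co,
                 out[, setdiff(names(out), "chrom"), drop = FALSE])
  }
  num <- vapply(out, is.numeric, TRUE)
  for (cn in names(out)[num]) out[[cn]] <- signif(out[[cn]], 10)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# anchor coordinates for records from the per-chromosome bin tables
.record_anchors <- function(records, bins) {
  if (is.data.frame(bins)) bins <- split(bins, bins$chrom)
  out <- data.frame(start_i = NA_real_, end_i = NA_real_,
                    start_j = NA_real_, end_j = NA_real_)[rep(1, nrow(records)), ]
  rownames(out) <- NULL
  for (ch in unique(records$chrom)) {
    b <- bins[[ch]]
    sel <- records$chrom == ch
    mi <- match(records$i[sel], b$bin_id)
    mj <- match(records$j[sel], b$bin_id)
    out$start_i[sel] <- b$start[mi]; out$end_i[sel] <- b$end[mi]
    out$start_j[sel] <- b$start[mj]; out$end_j[sel] <- b$end[mj]
  }
  out
}

#' Write significant interactions as BEDPE
#'
#' One line per significant record: chrom1 start1 end1 chrom2 start2 end2
#' name score (score = -log10 p, name = q value).
#'
#' @param records Scored record data frame (needs \code{significant},
#'   \code{p}, \code{q}).
#' @param bins Named list of per-chromosome bin tables.
#' @param path Output path.
#' @export
write_bedpe <- function(records, bins, path) {
  sig <- records[!is.na(records$significant) & records$significant, ,
                 drop = FALSE]
  co <- .record_anchors(sig, bins)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(sig))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\tq=%.3g\t%.4f",
                       sig$chrom, as.integer(co$start_i), as.integer(co$end_i),
                       sig$chrom, as.integer(co$start_j), as.integer(co$end_j),
                       sig$q, -log10(pmax(sig$p, 1e-300))), con)
  invisible(path)
}

#' Serialize a fitted null model to JSON
#'
#' Records coefficient names and values for both parts, the dispersion, the
#' knot vector, standardization statistics, seed and tolerances, so a fit
#' can be audited or reapplied.
#'
#' @param null A \code{"hic_null"} object (or a named list of them).
#' @param path Output path.
#' @export
write_fit_json <- function(null, path) {
  one <- function(nf) {
    if (is.null(nf)) return(NULL)
    list(chrom = nf$chrom, model = nf$model,
         beta = as.list(nf$fit$coefficients$count),
         gamma = as.list(nf$fit$coefficients$zero),
         alpha = nf$fit$alpha,
         loglik = nf$fit$loglik, converged = nf$fit$converged,
         inner_knots = nf$spec$inner_knots,
         boundary_knots = nf$spec$boundary_knots,
         order = nf$spec$order,
         seed = nf$seed, sample_frac = nf$sample_frac,
         outlier_q = nf$outlier_q,
         n_train = nf$n_train, n_outliers_removed = nf$n_outliers_removed,
         standardization = nf$standardization,
         tolerances = nf$fit$control[c("reltol", "grad_tol")])
  }
  obj <- if (inherits(null, "hic_null")) one(null) else lapply(null, one)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
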