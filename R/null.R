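# Per-chromosome null model estimation and interaction significance.

#' Build the null-model design matrix for interaction records
#'
#' Columns: intercept, distance B-spline basis (first basis function
#' dropped; see \code{\link{spline_design}}), standardized GC and
#' mappability covariates and, when present, the standardized effective-
#' fraction covariate.  Distances are clamped to the spline boundary.
#'
#' @param records Record data frame with \code{d}, \code{gcz}, \code{mapz}
#'   (and optional \code{effz}).
#' @param spec A \code{\link{spline_spec}}.
#' @return Numeric design matrix.
#' @export
null_design <- function(records, spec) {
  d <- pmin(pmax(records$d, spec$boundary_knots[1]), spec$boundary_knots[2])
  x <- cbind(`(Intercept)` = 1, spline_design(d, spec),
             gcz = records$gcz, mapz = records$mapz)
  if (!is.null(records$effz)) x <- cbind(x, effz = records$effz)
  x
}

#' Estimate the null model for one chromosome (two-pass trimmed fit)
#'
#' Implements the two-iteration training scheme: (1) draw a seeded simple
#' random sample of the usable records (default 1\%); (2) fit the hurdle
#' ZTNB regression; (3) flag sampled records whose upper-tail probability
#' under their fitted hurdle distribution is below \code{1 - outlier_q}
#' (default: the 2.5\% upper tail) as candidate true interactions and drop
#' them; (4) refit on the remainder.  Inner spline knots are placed at
#' distance quantiles of the pass-1 sample and reused in pass 2.
#'
#' @param records Record data frame for a single chromosome, with
#'   standardized covariates from \code{\link{pair_covariates}}.
#' @param sample_frac Training sample fraction in (0, 1], default 0.01.
#' @param outlier_q Null quantile above which sampled records are trimmed
#'   (default 0.975).
#' @param seed Integer seed for the training sample (required; recorded).
#' @param knots Optional \code{\link{spline_spec}} overriding the
#'   quantile-derived knots.
#' @param max_distance Spline boundary (bp), default 2 Mb.
#' @param model Passed to \code{\link{fit_hurdle_glm}}.
#' @param control See \code{\link{hurdle_control}}.
#' @return An object of class \code{"hic_null"}: list with the pass-1 and
#'   pass-2 fits (\code{fit1}, \code{fit}), the \code{spec}, training
#'   metadata (\code{n_train}, \code{n_outliers_removed}, \code{seed},
#'   \code{sample_frac}, \code{outlier_q}, \code{chrom}).
#' @export
estimate_null <- function(records, sample_frac = 0.01, outlier_q = 0.975,
                          seed, knots = NULL, max_distance = 2e6,
                          model = c("ztnb_hurdle", "poisson"),
                          control = hurdle_control()) {
  model <- match.arg(model)
  if (missing(seed)) stop("'seed' is required (training-sample randomness)")
  if (sample_frac <= 0 || sample_frac > 1)
    stop("'sample_frac' must be in (0, 1]")
  if (outlier_q <= 0.5 || outlier_q >= 1)
    stop("'outlier_q' must be in (0.5, 1)")
  if (length(unique(records$chrom)) != 1L)
    stop("'records' must come from a single chromosome")
  usable <- which(!records$excluded & is.finite(records$gcz) &
                    is.finite(records$mapz))
  n_usable <- length(usable)
  n_s <- max(1L, round(sample_frac * n_usable))
  set.seed(seed)
  train_idx <- sort(sample(usable, n_s, replace = FALSE))
  train <- records[train_idx, , drop = FALSE]
  if (is.null(knots))
    knots <- spline_spec_from_distances(train$d,
                                        boundary_knots = c(0, max_distance))
  x <- null_design(train, knots)
  if (n_s < 10 * (ncol(x) + 1))
    stop(sprintf(paste("training sample too small to fit (%d records for %d",
                       "parameters); increase 'sample_frac'"),
                 n_s, ncol(x) + 1L))
  fit1 <- fit_hurdle_glm(x, train$y, model = model, control = control)
  tail1 <- .record_tail_prob(train$y, x, fit1)
  keep <- tail1 >= (1 - outlier_q)
  fit2 <- fit_hurdle_glm(x[keep, , drop = FALSE], train$y[keep],
                         model = model, control = control)
  structure(list(fit = fit2, fit1 = fit1, spec = knots, model = model,
                 chrom = records$chrom[1], seed = seed,
                 sample_frac = sample_frac, outlier_q = outlier_q,
                 n_usable = n_usable, n_train = sum(keep),
                 n_outliers_removed = sum(!keep),
                 standardization = attr(records, "standardization")),
            class = "hic_null")
}

# upper-tail probability P(Y >= y) of each record under its fitted law
.record_tail_prob <- function(y, x, fit) {
  mu <- exp(pmin(drop(x %*% fit$coefficients$count), 500))
  if (fit$model == "poisson")
    return(ifelse(y == 0, 1,
                  stats::ppois(y - 1, lambda = mu, lower.tail = FALSE)))
  pi0 <- stats::plogis(drop(x %*% fit$coefficients$zero))
  hurdle_upper_tail(y, mu, fit$alpha, pi0)
}

#' @export
print.hic_null <- function(x, ...) {
  cat(sprintf("Hi-C null model for %s (%s)\n", x$chrom, x$model))
  cat(sprintf("  trained on %d of %d usable records (frac %.3g, seed %d)\n",
              x$n_train + x$n_outliers_removed, x$n_usable, x$sample_frac,
              x$seed))
  cat(sprintf("  pass-2 fit after removing %d outliers (tail > %.3g)\n",
              x$n_outliers_removed, x$outlier_q))
  print(x$fit)
  invisible(x)
}

#' Plot the fitted distance decay of a null model
#'
#' Expected hurdle mean as a function of genomic distance with the other
#' covariates at their (standardized) mean of zero, for the pass-1 and
#' pass-2 fits.
#'
#' @param x A \code{"hic_null"} object.
#' @param n Number of distance grid points.
#' @param ... Passed to \code{plot}.
#' @export
plot.hic_null <- function(x, n = 200, ...) {
  d <- seq(x$spec$boundary_knots[1], x$spec$boundary_knots[2], length.out = n)
  grid <- data.frame(d = d, gcz = 0, mapz = 0)
  if ("effz" %in% colnames(x$fit$x)) grid$effz <- 0
  xm <- null_design(grid, x$spec)
  m2 <- predict(x$fit, xm, type = "mean")
  m1 <- predict(x$fit1, xm, type = "mean")
  graphics::plot(d / 1e3, m2, type = "l", col = "blue", log = "y",
                 xlab = "genomic distance (kb)", ylab = "expected count",
                 main = sprintf("Distance decay, %s", x$chrom), ...)
  graphics::lines(d / 1e3, m1, col = "darkgreen", lty = 2)
  graphics::legend("topright", c("pass 2 (trimmed)", "pass 1"),
                   col = c("blue", "darkgreen"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Upper-tail P values for interaction records
#'
#' Each non-excluded record gets \code{p = P(Y >= y)} under its fitted
#' hurdle distribution — one minus the summed probabilities of all counts
#' below the observed one — so \code{y = 0} gives \code{p = 1} and
#' \code{y = 1} gives \code{1 - pi0}.
#'
#' @param records Record data frame (one chromosome, standardized
#'   covariates).
#' @param null A \code{"hic_null"} fit for the same chromosome.
#' @return \code{records} with columns \code{mu}, \code{pi0} and \code{p}
#'   appended (NA for excluded records).
#' @export
interaction_pvalue <- function(records, null) {
  ok <- !records$excluded & is.finite(records$gcz) & is.finite(records$mapz)
  records$mu <- records$pi0 <- records$p <- NA_real_
  if (any(ok)) {
    x <- null_design(records[ok, , drop = FALSE], null$spec)
    fit <- null$fit
    records$mu[ok] <- exp(pmin(drop(x %*% fit$coefficients$count), 500))
    if (fit$model == "poisson") {
      records$pi0[ok] <- exp(-records$mu[ok])
    } else {
      records$pi0[ok] <- stats::plogis(drop(x %*% fit$coefficients$zero))
    }
    records$p[ok] <- .record_tail_prob(records$y[ok], x, fit)
  }
  records
}

#' Benjamini-Hochberg adjusted P values
#'
#' Standard step-up BH with monotonicity enforcement; \code{NA}s are passed
#' through and do not count toward the number of tests.
#'
#' @param p Vector of P values in (0, 1], possibly with NAs.
#' @return Vector of q values, same length and order.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Observed/expected normalization
#'
#' Divides the observed count by the expected count under the fitted null:
#' the mean of the full hurdle distribution,
#' \code{E[Y] = (1 - pi0) * mu / (1 - NB(0; mu, alpha))}.
#'
#' @param records Records with \code{mu} and \code{pi0} columns (from
#'   \code{\link{interaction_pvalue}}).
#' @param null The \code{"hic_null"} fit.
#' @return \code{records} with an \code{oe} column appended.
#' @export
oe_normalize <- function(records, null) {
  e <- if (null$fit$model == "poisson") records$mu
  else hurdle_mean(records$mu, null$fit$alpha, records$pi0)
  bad <- is.finite(e) & e == 0
  if (any(bad)) {
    warning("expected count of zero; O/E set to NA")
    e[bad] <- NA_real_
  }
  records$oe <- records$y / e
  records
}

#' Call significant interactions genome-wide
#'
#' Orchestrates the per-chromosome two-pass null fits, upper-tail P values,
#' O/E normalization and a genome-wide (pooled) BH adjustment.  A
#' chromosome whose fit fails is reported with a warning and its records
#' keep NA P values; the other chromosomes are unaffected.
#'
#' @param records Record data frame over one or more chromosomes with
#'   standardized covariates (\code{\link{pair_covariates}}).
#' @param sample_frac,outlier_q,knots,max_distance,model,control Passed to
#'   \code{\link{estimate_null}}.
#' @param seed Base integer seed; chromosome k uses \code{seed + k - 1}.
#' @param fdr FDR threshold recorded for \code{significant}.
#' @param bh \code{"pooled"} (genome-wide, default) or
#'   \code{"per-chromosome"}.
#' @return List of class \code{"hic_calls"}: \code{records} (with
#'   \code{mu}, \code{pi0}, \code{p}, \code{q}, \code{oe},
#'   \code{significant}), \code{fits} (per-chromosome \code{"hic_null"}
#'   objects or NULL on failure), \code{fdr}.
#' @export
call_interactions <- function(records, sample_frac = 0.01, outlier_q = 0.975,
                              seed, fdr = 0.01, knots = NULL,
                              max_distance = 2e6,
                              model = c("ztnb_hurdle", "poisson"),
                              bh = c("pooled", "per-chromosome"),
                              control = hurdle_control()) {
  model <- match.arg(model)
  bh <- match.arg(bh)
  if (missing(seed)) stop("'seed' is required")
  chroms <- unique(records$chrom)
  fits <- stats::setNames(vector("list", length(chroms)), chroms)
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    rec_k <- records[records$chrom == chroms[k], , drop = FALSE]
    attr(rec_k, "standardization") <- attr(records, "standardization")
    res <- tryCatch({
      nf <- estimate_null(rec_k, sample_frac = sample_frac,
                          outlier_q = outlier_q, seed = seed + k - 1L,
                          knots = knots, max_distance = max_distance,
                          model = model, control = control)
      rec_k <- interaction_pvalue(rec_k, nf)
      rec_k <- oe_normalize(rec_k, nf)
      list(rec = rec_k, fit = nf)
    }, error = function(e) {
      warning(sprintf("chromosome %s skipped: %s", chroms[k],
                      conditionMessage(e)))
      rec_k$mu <- rec_k$pi0 <- rec_k$p <- rec_k$oe <- NA_real_
      list(rec = rec_k, fit = NULL)
    })
    fits[[k]] <- res$fit
    out[[k]] <- res$rec
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  if (bh == "pooled") {
    rec$q <- bh_adjust(rec$p)
  } else {
    rec$q <- NA_real_
    for (ch in chroms) {
      sel <- rec$chrom == ch
      rec$q[sel] <- bh_adjust(rec$p[sel])
    }
  }
  rec$significant <- !is.na(rec$q) & rec$q < fdr
  structure(list(records = rec, fits = fits, fdr = fdr, seed = seed,
                 model = model, bh = bh),
            class = "hic_calls")
}

#' @export
print.hic_calls <- function(x, ...) {
  r <- x$records
  cat(sprintf("Hi-C interaction calls: %d records on %d chromosome(s)\n",
              nrow(r), length(x$fits)))
  cat(sprintf("  %d significant at FDR < %g (%s BH), %d with NA p\n",
              sum(r$significant), x$fdr, x$bh, sum(is.na(r$p))))
  invisible(x)
}
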