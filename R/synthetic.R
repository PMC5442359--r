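# Synthetic toy genomes and hurdle-NB contact data with known ground truth.
#
# One scenario seed drives a documented set of substreams (stage codes:
# 0 sequence, 1 mappability, 2 counts, 3 spikes), so each stage is
# individually reproducible.  Stage seeds are scrambled through an LCG step
# rather than used as seed + offset: Mersenne-Twister streams started from
# adjacent seeds are not reliably independent, and with per-stage offsets the
# covariate stream of one replicate can be the count stream of another.

# deterministic stage seed, scrambled away from neighbouring base seeds
.substream_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 1299721) %% 2147483647)
}

#' Define a simulation scenario
#'
#' Bundles every parameter of the synthetic world: toy chromosome sizes, the
#' restriction motif and its target fragment spacing, smooth sinusoidal GC
#' and mappability fields, the true hurdle-model coefficients, dispersion,
#' and the spike-in (true interaction) settings.  Defaults emulate an
#' MboI-digested mammalian genome: ~256 bp fragments, GC around 0.41 with
#' isochore-scale (100 kb) variation, high but locally dipping mappability,
#' a distance decay from ~20 expected reads at short range to well below 1
#' beyond 1 Mb, zero inflation growing with distance, and NB2 dispersion
#' 0.3.
#'
#' @param seed Integer scenario seed.
#' @param chrom_sizes Named vector of chromosome lengths (bp), each >= 100 kb.
#' @param motif Restriction motif (palindromic), default MboI "GATC".
#' @param target_spacing Target mean fragment length (bp), default 256.
#' @param gc_mean,gc_amp,gc_period Mean, amplitude and period (bp) of the
#'   sinusoidal GC field.
#' @param map_base,map_amp,map_period,map_noise,map_tile Mappability field:
#'   base level, sinusoidal amplitude, period, tile-level Gaussian noise and
#'   tile width (bp).
#' @param beta True count-part coefficients, named like the model design
#'   (intercept, s1..s5 spline, gcz, mapz).
#' @param gamma True zero-part coefficients (same columns; logit P(zero)).
#' @param alpha True NB2 dispersion (>= 0).
#' @param beta_eff,gamma_eff Effective-space coefficients appended in
#'   uniform-bin mode.
#' @param spike_frac Fraction of eligible records spiked as true
#'   interactions.
#' @param spike_fold Fold change (>= 1) of the spiked mean.
#' @param spike_range Distance range (bp) eligible for spikes.
#' @return An object of class \code{"sim_scenario"} (a list).
#' @export
simulation_scenario <- function(seed = 1L,
                                chrom_sizes = c(chrS = 4e5),
                                motif = "GATC",
                                target_spacing = 256,
                                gc_mean = 0.41, gc_amp = 0.07,
                                gc_period = 1e5,
                                map_base = 0.9, map_amp = 0.08,
                                map_period = 7e4, map_noise = 0.03,
                                map_tile = 1000,
                                beta = c(`(Intercept)` = 3.0, s1 = -1.0,
                                         s2 = -2.0, s3 = -3.0, s4 = -3.8,
                                         s5 = -4.4, gcz = 0.3, mapz = 0.5),
                                gamma = c(`(Intercept)` = -2.0, s1 = 0.8,
                                          s2 = 1.6, s3 = 2.4, s4 = 3.0,
                                          s5 = 3.4, gcz = -0.2, mapz = -0.3),
                                alpha = 0.3,
                                beta_eff = 0.4, gamma_eff = -0.2,
                                spike_frac = 0.01, spike_fold = 5,
                                spike_range = c(2e4, 1e6)) {
  if (any(chrom_sizes < 1e5)) stop("chromosome sizes must be >= 100 kb")
  if (spike_fold < 1) stop("'spike_fold' must be >= 1")
  if (is.null(names(chrom_sizes)))
    names(chrom_sizes) <- paste0("chr", seq_along(chrom_sizes))
  structure(as.list(environment()), class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Synthetic Hi-C scenario (seed", x$seed, ")\n")
  cat("  chromosomes:", paste(sprintf("%s=%g", names(x$chrom_sizes),
                                      x$chrom_sizes), collapse = ", "), "\n")
  cat(sprintf("  motif %s, target spacing %g bp; alpha %.2f; spikes %g%% x%g\n",
              x$motif, x$target_spacing, x$alpha, 100 * x$spike_frac,
              x$spike_fold))
  invisible(x)
}

# sample a random base sequence with position-dependent GC probability
.sim_sequence <- function(L, scenario) {
  x <- seq_len(L)
  pgc <- scenario$gc_mean +
    scenario$gc_amp * sin(2 * pi * x / scenario$gc_period)
  pgc <- pmin(pmax(pgc, 0.2), 0.7)
  is_gc <- stats::runif(L) < pgc
  second <- stats::runif(L) < 0.5
  base <- ifelse(is_gc, ifelse(second, "G", "C"), ifelse(second, "A", "T"))
  base
}

# adjust restriction-site density toward the target spacing
.adjust_sites <- function(base, motif, target_spacing) {
  L <- length(base)
  m <- strsplit(motif, "")[[1]]
  w <- length(m)
  seq1 <- paste(base, collapse = "")
  sites <- find_restriction_sites(seq1, motif)
  n_target <- round(L / target_spacing)
  if (length(sites) > n_target) {
    kill <- sample(sites, length(sites) - n_target)
    swap <- c(A = "T", C = "G", G = "C", T = "A")
    base[kill + 1L] <- swap[base[kill + 1L]]  # mutate motif start base
  } else if (length(sites) < n_target) {
    need <- n_target - length(sites)
    cand <- sample.int(L - w, min(4L * need, L - w))
    cand <- cand[!(cand %in% as.vector(outer(sites, (-w):(w), `+`)))]
    cand <- cand[seq_len(min(need, length(cand)))]
    for (p in cand) base[(p + 1):(p + w)] <- m
  }
  base
}

#' Generate a toy genome with bias fields
#'
#' Per chromosome: a random sequence with smoothly varying GC, restriction
#' sites adjusted to the target fragment spacing, and a tiled mappability
#' field (sinusoid + noise, clipped to [0.5, 1]).  Deterministic per
#' scenario seed.  Optionally writes FASTA, bedGraph and a truth JSON.
#'
#' @param scenario A \code{\link{simulation_scenario}}.
#' @param dir Optional output directory; when given, writes
#'   \code{genome.fa}, \code{mappability.bedGraph}, \code{chrom.sizes} and
#'   \code{truth.json}.
#' @return List with \code{sequences} (named character), \code{sites}
#'   (per-chromosome 0-based positions), \code{mappability} (per-chromosome
#'   data frame \code{start}, \code{end}, \code{value}), and
#'   \code{scenario}.
#' @export
make_toy_genome <- function(scenario, dir = NULL) {
  seqs <- list(); sites <- list(); mapg <- list()
  for (ch in names(scenario$chrom_sizes)) {
    L <- scenario$chrom_sizes[[ch]]
    set.seed(.substream_seed(scenario$seed,
             0L + match(ch, names(scenario$chrom_sizes)) * 101L))
    base <- .sim_sequence(L, scenario)
    base <- .adjust_sites(base, scenario$motif, scenario$target_spacing)
    seqs[[ch]] <- paste(base, collapse = "")
    sites[[ch]] <- find_restriction_sites(seqs[[ch]], scenario$motif)
    set.seed(.substream_seed(scenario$seed,
             1L + match(ch, names(scenario$chrom_sizes)) * 101L))
    k <- ceiling(L / scenario$map_tile)
    start <- (seq_len(k) - 1) * scenario$map_tile
    val <- scenario$map_base +
      scenario$map_amp * sin(2 * pi * start / scenario$map_period) +
      stats::rnorm(k, 0, scenario$map_noise)
    mapg[[ch]] <- data.frame(start = start, end = pmin(start +
                                                         scenario$map_tile, L),
                             value = pmin(pmax(val, 0.5), 1))
  }
  out <- list(sequences = seqs, sites = sites, mappability = mapg,
              scenario = scenario)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(seqs, file.path(dir, "genome.fa"))
    write_bedgraph(mapg, file.path(dir, "mappability.bedGraph"))
    utils::write.table(data.frame(names(scenario$chrom_sizes),
                                  scenario$chrom_sizes),
                       file.path(dir, "chrom.sizes"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(scenario[setdiff(names(scenario),
                                          character(0))],
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  out
}

# expand a tiled mappability data frame to per-base values
.mappability_per_base <- function(mg, L) {
  rep(mg$value, times = mg$end - mg$start)[seq_len(L)]
}

#' Simulate null contact counts for enumerated records
#'
#' Draws each record's count from the true hurdle law: zero with probability
#' \code{plogis(x . gamma)}, otherwise a zero-truncated NB2 draw with mean
#' \code{exp(x . beta)} and dispersion \code{alpha}, where \code{x} is the
#' record's null-model design row.  Inner spline knots are taken from the
#' distance quantiles of the usable records (or a supplied spec) and stored,
#' with the true parameters, in \code{attr(, "truth")}.
#'
#' @param records Enumerated records with standardized covariates.
#' @param scenario A \code{\link{simulation_scenario}}.
#' @param spec Optional \code{\link{spline_spec}}; default from the records'
#'   distance quantiles.
#' @param max_distance Spline boundary, default 2 Mb.
#' @return \code{records} with simulated \code{y} and a \code{"truth"}
#'   attribute (list \code{beta}, \code{gamma}, \code{alpha}, \code{spec},
#'   true \code{mu} and \code{pi0} vectors).
#' @export
simulate_null_counts <- function(records, scenario, spec = NULL,
                                 max_distance = 2e6) {
  ok <- !records$excluded & is.finite(records$gcz) & is.finite(records$mapz)
  if (is.null(spec))
    spec <- spline_spec_from_distances(records$d[ok],
                                       boundary_knots = c(0, max_distance))
  x <- null_design(records[ok, , drop = FALSE], spec)
  beta <- scenario$beta; gamma <- scenario$gamma
  if ("effz" %in% colnames(x)) {
    beta <- c(beta, effz = scenario$beta_eff)
    gamma <- c(gamma, effz = scenario$gamma_eff)
  }
  if (!all(colnames(x) %in% names(beta)))
    stop("scenario coefficients do not cover the design columns")
  eta_mu <- drop(x %*% beta[colnames(x)])
  eta_pi <- drop(x %*% gamma[colnames(x)])
  if (any(!is.finite(eta_mu)) || any(!is.finite(eta_pi)))
    stop("non-finite linear predictor in scenario")
  mu <- exp(eta_mu)
  pi0 <- stats::plogis(eta_pi)
  set.seed(.substream_seed(scenario$seed, 2L))
  records$y <- 0L
  records$y[ok] <- rhurdle(sum(ok), mu, scenario$alpha, pi0)
  tmu <- tpi <- rep(NA_real_, nrow(records))
  tmu[ok] <- mu; tpi[ok] <- pi0
  attr(records, "truth") <- list(beta = beta, gamma = gamma,
                                 alpha = scenario$alpha, spec = spec,
                                 mu = tmu, pi0 = tpi)
  records
}

#' Spike in true interactions
#'
#' Chooses \code{round(spike_frac * n_eligible)} eligible records (usable,
#' within the spike distance range) uniformly at random and redraws their
#' counts from the full hurdle law with the mean multiplied by
#' \code{spike_fold} (the zero gate is kept, so \code{spike_fold = 1}
#' reproduces the null exactly).
#'
#' @param records Records carrying a \code{"truth"} attribute from
#'   \code{\link{simulate_null_counts}}.
#' @param scenario The \code{\link{simulation_scenario}}.
#' @param n_spikes Optional explicit number of spikes (overrides
#'   \code{spike_frac}).
#' @return \code{records} with updated \code{y} and a logical \code{spiked}
#'   column; the truth attribute is preserved and gains \code{spike_fold}.
#' @export
spike_interactions <- function(records, scenario, n_spikes = NULL) {
  truth <- attr(records, "truth")
  if (is.null(truth)) stop("records must carry a 'truth' attribute")
  eligible <- which(!records$excluded & is.finite(truth$mu) &
                      records$d >= scenario$spike_range[1] &
                      records$d <= scenario$spike_range[2])
  if (is.null(n_spikes))
    n_spikes <- round(scenario$spike_frac * length(eligible))
  if (n_spikes > length(eligible))
    stop("more spikes requested than eligible records")
  set.seed(.substream_seed(scenario$seed, 3L))
  idx <- sample(eligible, n_spikes)
  records$spiked <- FALSE
  records$spiked[idx] <- TRUE
  if (n_spikes > 0)
    records$y[idx] <- rhurdle(n_spikes, scenario$spike_fold * truth$mu[idx],
                              scenario$alpha, truth$pi0[idx])
  truth$spike_fold <- scenario$spike_fold
  attr(records, "truth") <- truth
  records
}

#' Simulate bare interaction records from the model
#'
#' Lightweight generator for statistical tests: distances uniform over
#' \code{d_range} (at genome scale the enumerated distance distribution is
#' close to uniform below the cap), standardized GC and mappability
#' covariates standard normal, counts from the true hurdle law.  Every
#' spline basis column has support, so all coefficients are identifiable.
#'
#' @param scenario A \code{\link{simulation_scenario}}.
#' @param n Number of records.
#' @param d_range Distance range (bp), default \code{c(0, 2e6)}.
#' @param seed Optional seed override (default \code{scenario$seed}).
#' @return Record data frame with a \code{"truth"} attribute as in
#'   \code{\link{simulate_null_counts}}.
#' @export
simulate_records <- function(scenario, n, d_range = c(0, 2e6), seed = NULL) {
  if (is.null(seed)) seed <- scenario$seed
  set.seed(seed)
  rec <- data.frame(chrom = "chrS", i = seq_len(n), j = seq_len(n),
                    d = stats::runif(n, d_range[1], d_range[2]),
                    y = 0L, gcz = stats::rnorm(n), mapz = stats::rnorm(n),
                    excluded = FALSE)
  rec$j <- rec$i + as.integer(round(rec$d / 1e3))
  spec <- spline_spec_from_distances(rec$d, boundary_knots = c(0, d_range[2]))
  sc2 <- scenario
  sc2$seed <- seed
  simulate_null_counts(rec, sc2, spec = spec, max_distance = d_range[2])
}

#' Build a ready-to-model synthetic record set
#'
#' Convenience wrapper: toy genome, restriction-fragment (or uniform) bins,
#' bin features, zero-inclusive enumeration, covariate standardization and
#' null count simulation, with optional spikes.
#'
#' @param scenario A \code{\link{simulation_scenario}}.
#' @param binning \code{"fragments"} (merge-10) or \code{"uniform"}.
#' @param n_per_bin,bin_width Binning parameters.
#' @param max_distance Enumeration cap (bp).
#' @param spikes Add spiked true interactions?
#' @return List: \code{records} (with truth attribute), \code{bins} (named
#'   list per chromosome), \code{genome}.
#' @export
simulate_dataset <- function(scenario, binning = c("fragments", "uniform"),
                             n_per_bin = 10L, bin_width = 5000,
                             max_distance = 2e6, spikes = FALSE) {
  binning <- match.arg(binning)
  g <- make_toy_genome(scenario)
  bins <- list(); recs <- list()
  for (ch in names(g$sequences)) {
    L <- scenario$chrom_sizes[[ch]]
    b <- if (binning == "fragments")
      merge_fragments(digest_to_fragments(L, g$sites[[ch]]), n_per_bin,
                      chrom = ch)
    else make_uniform_bins(L, bin_width, chrom = ch)
    b <- bin_features(b, g$sequences[[ch]], g$sites[[ch]],
                      mappability = .mappability_per_base(g$mappability[[ch]],
                                                          L))
    bins[[ch]] <- b
    recs[[ch]] <- enumerate_interaction_bins(b, NULL,
                                             max_distance = max_distance,
                                             use_effective =
                                               binning == "uniform")
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  records <- pair_covariates(records)
  std <- attr(records, "standardization")
  records <- simulate_null_counts(records, scenario,
                                  max_distance = max_distance)
  if (spikes) records <- spike_interactions(records, scenario)
  attr(records, "standardization") <- std
  list(records = records, bins = bins, genome = g)
}
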