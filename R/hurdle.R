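# Hurdle zero-truncated negative binomial distribution and regression.
#
# Parameterization: the zero probability pi0 gates a zero-truncated NB2
# distribution for positive counts; NB2 variance = mu + alpha * mu^2, so
# alpha = 0 is the (zero-truncated) Poisson limit.  All tail quantities are
# computed in log space.

## ---- distribution -------------------------------------------------------

# log P(Y_nb = 0) for NB2(mu, alpha); Poisson limit for tiny alpha
.lp0_nb <- function(mu, alpha) {
  n <- max(length(mu), length(alpha))
  mu <- rep_len(mu, n)
  alpha <- rep_len(alpha, n)
  out <- -log1p(alpha * mu) / alpha
  small <- alpha < 1e-12
  out[small] <- -mu[small]
  out
}

.check_hurdle_par <- function(mu, alpha, pi0) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("'mu' must be finite and > 0")
  if (any(!is.finite(alpha)) || any(alpha < 0))
    stop("'alpha' must be finite and >= 0")
  if (any(!is.finite(pi0)) || any(pi0 < 0) || any(pi0 > 1))
    stop("'pi0' must lie in [0, 1]")
}

#' Hurdle zero-truncated negative binomial probability mass function
#'
#' \code{P(Y = 0) = pi0}; for \code{y >= 1},
#' \code{P(Y = y) = (1 - pi0) * NB(y; mu, alpha) / (1 - NB(0; mu, alpha))},
#' where NB is the NB2 negative binomial with mean \code{mu} and variance
#' \code{mu + alpha * mu^2}.  \code{alpha = 0} gives the zero-truncated
#' Poisson limit.
#'
#' @param y Non-negative integer counts (vector).
#' @param mu Positive NB mean (recycled).
#' @param alpha Dispersion >= 0 (recycled).
#' @param pi0 Zero probability in [0, 1] (recycled).
#' @param log Return log probabilities?
#' @return Vector of probabilities.
#' @examples
#' hurdle_pmf(0:5, mu = 2, alpha = 0.3, pi0 = 0.4)
#' @export
hurdle_pmf <- function(y, mu, alpha, pi0, log = FALSE) {
  .check_hurdle_par(mu, alpha, pi0)
  if (any(y < 0) || any(y != floor(y)))
    stop("'y' must contain non-negative integers")
  n <- max(length(y), length(mu), length(alpha), length(pi0))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  alpha <- rep_len(alpha, n); pi0 <- rep_len(pi0, n)
  lp0 <- .lp0_nb(mu, alpha)
  ldnb <- ifelse(alpha < 1e-12,
                 stats::dpois(y, lambda = mu, log = TRUE),
                 stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  lp <- log1p(-pi0) + ldnb - log(-expm1(lp0))
  lp[y == 0] <- log(pi0[y == 0])
  if (log) lp else exp(lp)
}

#' Upper-tail probability of the hurdle distribution
#'
#' \code{P(Y >= y)}; equals 1 at \code{y = 0} and \code{1 - pi0} at
#' \code{y = 1}.
#'
#' @inheritParams hurdle_pmf
#' @return Vector of upper-tail probabilities in (0, 1].
#' @export
hurdle_upper_tail <- function(y, mu, alpha, pi0) {
  .check_hurdle_par(mu, alpha, pi0)
  n <- max(length(y), length(mu), length(alpha), length(pi0))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  alpha <- rep_len(alpha, n); pi0 <- rep_len(pi0, n)
  out <- rep(1, n)
  pos <- y >= 1
  if (any(pos)) {
    yp <- y[pos]; mup <- mu[pos]; ap <- alpha[pos]
    lp0 <- .lp0_nb(mup, ap)
    # P_nb(Y >= y) on the untruncated NB, then renormalize over y >= 1
    ltail <- ifelse(ap < 1e-12,
                    stats::ppois(yp - 1, lambda = mup, lower.tail = FALSE,
                                 log.p = TRUE),
                    stats::pnbinom(yp - 1, size = 1 / ap, mu = mup,
                                   lower.tail = FALSE, log.p = TRUE))
    out[pos] <- exp(log1p(-pi0[pos]) + ltail - log(-expm1(lp0)))
  }
  pmin(out, 1)
}

#' Mean of the hurdle distribution
#'
#' \code{E[Y] = (1 - pi0) * mu / (1 - NB(0; mu, alpha))}.
#'
#' @inheritParams hurdle_pmf
#' @return Vector of means.
#' @export
hurdle_mean <- function(mu, alpha, pi0) {
  .check_hurdle_par(mu, alpha, pi0)
  n <- max(length(mu), length(alpha), length(pi0))
  mu <- rep_len(mu, n); alpha <- rep_len(alpha, n); pi0 <- rep_len(pi0, n)
  (1 - pi0) * mu / (-expm1(.lp0_nb(mu, alpha)))
}

# Variance of the hurdle distribution (for Pearson residuals)
hurdle_var <- function(mu, alpha, pi0) {
  p0 <- exp(.lp0_nb(mu, alpha))
  m2_nb <- mu + alpha * mu^2 + mu^2            # E_nb[Y^2]
  ey2 <- (1 - pi0) * m2_nb / (1 - p0)
  ey <- hurdle_mean(mu, alpha, pi0)
  pmax(ey2 - ey^2, 0)
}

#' Draw from the hurdle distribution
#'
#' Vectorized sampler: zero with probability \code{pi0}, otherwise an exact
#' inverse-CDF draw from the zero-truncated NB.
#'
#' @param n Number of draws.
#' @inheritParams hurdle_pmf
#' @return Integer vector of length \code{n}.
#' @export
rhurdle <- function(n, mu, alpha, pi0) {
  .check_hurdle_par(mu, alpha, pi0)
  mu <- rep_len(mu, n); alpha <- rep_len(alpha, n); pi0 <- rep_len(pi0, n)
  z <- stats::runif(n) < pi0
  p0 <- exp(.lp0_nb(mu, alpha))
  u <- p0 + stats::runif(n) * (1 - p0)  # uniform on (P(0), 1): truncation
  y <- ifelse(alpha < 1e-12,
              stats::qpois(pmin(u, 1 - 1e-16), lambda = mu),
              stats::qnbinom(pmin(u, 1 - 1e-16), size = 1 / alpha, mu = mu))
  y[z] <- 0L
  as.integer(y)
}

## ---- zero-truncated NB likelihood ---------------------------------------

# negative log-likelihood and gradient for the ZTNB count part.
# par = c(beta, log(alpha)); x: design (n x p); y: positive counts.
.ztnb_negll <- function(par, x, y) {
  p <- ncol(x)
  eta <- drop(x %*% par[seq_len(p)])
  s <- par[p + 1L]
  if (any(eta > 500)) return(1e10)
  mu <- exp(eta)
  a <- exp(-s)                       # NB size = 1/alpha
  lp0 <- -a * log1p(mu / a)
  ll <- stats::dnbinom(y, size = a, mu = mu, log = TRUE) - log(-expm1(lp0))
  v <- -sum(ll)
  if (!is.finite(v)) 1e10 else v
}

.ztnb_neggrad <- function(par, x, y) {
  p <- ncol(x)
  eta <- drop(x %*% par[seq_len(p)])
  eta <- pmin(eta, 500)
  mu <- exp(eta)
  s <- par[p + 1L]
  a <- exp(-s)
  lp0 <- -a * log1p(mu / a)
  p0 <- exp(lp0)
  om <- -expm1(lp0)                  # 1 - p0
  dmu <- y / mu - (y + a) / (a + mu) - p0 * a / (om * (a + mu))
  gbeta <- drop(crossprod(x, mu * dmu))
  dlogp0_da <- log(a / (a + mu)) + 1 - a / (a + mu)
  dlognb_da <- digamma(y + a) - digamma(a) + dlogp0_da - y / (a + mu)
  dl_da <- dlognb_da + p0 * dlogp0_da / om
  gs <- -a * sum(dl_da)
  -c(gbeta, gs)
}

## ---- IRLS logistic zero part --------------------------------------------

# Ridge-penalized IRLS for P(zero) = plogis(x %*% gamma).  The small fixed
# ridge keeps the fit finite under complete separation (e.g. no zeros).
.logit_irls <- function(x, z, ridge = 1e-6, maxit = 100L, tol = 1e-10) {
  p <- ncol(x)
  gamma <- numeric(p)
  pen <- diag(ridge, p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% gamma)
    prob <- stats::plogis(eta)
    w <- pmax(prob * (1 - prob), 1e-12)
    zwork <- eta + (z - prob) / w
    xtw <- t(x * w)
    newg <- tryCatch(drop(solve(xtw %*% x + pen, xtw %*% zwork)),
                     error = function(e) NULL)
    if (is.null(newg)) break
    if (max(abs(newg - gamma)) < tol * (1 + max(abs(gamma)))) {
      gamma <- newg; converged <- TRUE; break
    }
    gamma <- newg
  }
  eta <- drop(x %*% gamma)
  prob <- stats::plogis(eta)
  w <- pmax(prob * (1 - prob), 1e-12)
  info <- t(x * w) %*% x + pen
  ll <- sum(z * log(pmax(prob, 1e-300)) + (1 - z) * log(pmax(1 - prob, 1e-300)))
  list(coefficients = gamma, vcov = solve(info), loglik = ll,
       converged = converged, fitted = prob)
}

## ---- fitting front ends -------------------------------------------------

#' Control parameters for hurdle model fitting
#'
#' @param maxit Maximum BFGS iterations per restart for the count part.
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param grad_tol Max-norm tolerance for the per-observation mean score at
#'   the optimum; fits exceeding it are flagged \code{converged = FALSE}.
#' @param alpha_init Initial dispersion.
#' @param log_alpha_bounds Bounds for log(alpha) (box applied by clamping).
#' @param ridge Ridge penalty for the logistic zero part.
#' @return A list of control values.
#' @export
hurdle_control <- function(maxit = 500L, reltol = 1e-12, grad_tol = 1e-6,
                           alpha_init = 0.5, log_alpha_bounds = c(-20, 10),
                           ridge = 1e-6) {
  list(maxit = maxit, reltol = reltol, grad_tol = grad_tol,
       alpha_init = alpha_init, log_alpha_bounds = log_alpha_bounds,
       ridge = ridge)
}

#' Fit the hurdle ZTNB regression from a design matrix
#'
#' The two parts of the hurdle likelihood are separable and fit
#' independently: a ridge-guarded logistic regression of the zero indicator
#' on the design (coefficients \code{gamma}), and a zero-truncated NB2
#' regression of the positive counts on the same design (\code{beta} with
#' log link, plus dispersion \code{alpha}), maximized by BFGS with analytic
#' gradients on \code{(beta, log alpha)}.  \code{beta} is initialized from a
#' Poisson log-linear fit to the positive counts.
#'
#' @param x Design matrix including an intercept column.
#' @param y Non-negative integer counts.
#' @param model \code{"ztnb_hurdle"} (default) or \code{"poisson"} — the
#'   latter is the deliberately non-overdispersed, non-hurdle variant (plain
#'   Poisson GLM on all counts) used for model comparison.
#' @param control See \code{\link{hurdle_control}}.
#' @return An object of class \code{"hurdle_ztnb"}; see
#'   \code{\link{hurdle_ztnb}} for the components.
#' @export
fit_hurdle_glm <- function(x, y, model = c("ztnb_hurdle", "poisson"),
                           control = hurdle_control()) {
  model <- match.arg(model)
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- c("(Intercept)", paste0("x", seq_len(ncol(x) - 1L)))
  if (!all(is.finite(x))) stop("non-finite entries in the design matrix")
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)")
  if (any(y < 0) || any(y != floor(y)))
    stop("'y' must contain non-negative integer counts")
  if (all(y == 0)) stop("degenerate data: all counts are zero")

  if (model == "poisson") {
    pf <- stats::glm.fit(x, y, family = stats::poisson())
    fit <- list(model = "poisson",
                coefficients = list(count = pf$coefficients, zero = NULL),
                alpha = 0,
                loglik = sum(stats::dpois(y, fitted(pf), log = TRUE)),
                converged = pf$converged, n = length(y),
                n_positive = sum(y > 0), x = x, y = y,
                vcov = list(count = tryCatch(
                  solve(t(x * fitted(pf)) %*% x), error = function(e) NULL),
                  zero = NULL),
                control = control)
    class(fit) <- "hurdle_ztnb"
    return(fit)
  }

  pos <- y > 0
  if (!any(pos)) stop("degenerate data: no positive counts")
  zero_fit <- .logit_irls(x, as.numeric(y == 0), ridge = control$ridge)
  if (all(pos))
    warning("no zero counts: zero-part coefficients determined by the ridge guard")

  xp <- x[pos, , drop = FALSE]
  yp <- y[pos]
  # init from Poisson on positives
  b0 <- tryCatch(stats::glm.fit(xp, yp, family = stats::poisson())$coefficients,
                 error = function(e) NULL)
  if (is.null(b0) || any(!is.finite(b0))) {
    b0 <- numeric(ncol(x)); b0[1] <- log(mean(yp))
  }
  par <- c(b0, log(control$alpha_init))
  lab <- control$log_alpha_bounds
  best <- NULL
  for (round in 1:3) {
    opt <- stats::optim(par, .ztnb_negll, .ztnb_neggrad, x = xp, y = yp,
                        method = "BFGS",
                        control = list(maxit = control$maxit,
                                       reltol = control$reltol))
    opt$par[length(opt$par)] <- min(max(opt$par[length(opt$par)], lab[1]), lab[2])
    g <- .ztnb_neggrad(opt$par, xp, yp)
    if (!is.null(best) &&
        abs(best$value - opt$value) <= control$reltol * (abs(opt$value) + 1e-8) ||
        max(abs(g)) / length(yp) < control$grad_tol) {
      best <- opt
      break
    }
    best <- opt
    par <- opt$par
  }
  g <- .ztnb_neggrad(best$par, xp, yp)
  count_converged <- max(abs(g)) / length(yp) < control$grad_tol
  if (!count_converged)
    warning("count part did not meet the gradient tolerance; converged = FALSE")
  p <- ncol(x)
  beta <- best$par[seq_len(p)]
  names(beta) <- colnames(x)
  alpha <- exp(best$par[p + 1L])
  hess <- tryCatch(stats::optimHess(best$par, .ztnb_negll, .ztnb_neggrad,
                                    x = xp, y = yp),
                   error = function(e) NULL)
  vc_count <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  gamma <- zero_fit$coefficients
  names(gamma) <- colnames(x)
  loglik <- zero_fit$loglik - best$value

  fit <- list(model = "ztnb_hurdle",
              coefficients = list(count = beta, zero = gamma),
              alpha = alpha, log_alpha = best$par[p + 1L],
              loglik = loglik, loglik_count = -best$value,
              loglik_zero = zero_fit$loglik,
              converged = count_converged && zero_fit$converged,
              n = length(y), n_positive = sum(pos),
              x = x, y = y,
              vcov = list(count = vc_count, zero = zero_fit$vcov),
              control = control)
  class(fit) <- "hurdle_ztnb"
  fit
}

#' Hurdle zero-truncated negative binomial regression
#'
#' Fits the two-part null model for overdispersed, zero-inflated count data:
#' a logistic model for the probability that a count is zero and a
#' zero-truncated NB2 model for the positive counts, both with the same
#' linear predictor.  This is the statistical core of the Hi-C interaction
#' caller, where the design holds a B-spline distance basis plus GC-content
#' and mappability covariates, but the fitter is generic.
#'
#' @param formula Model formula for the counts, e.g. \code{y ~ s1 + s2 + gcz}.
#' @param data Data frame holding the variables.
#' @param model,control Passed to \code{\link{fit_hurdle_glm}}.
#' @return An object of class \code{"hurdle_ztnb"} with components
#'   \code{coefficients} (list \code{count} = beta, \code{zero} = gamma),
#'   \code{alpha} (dispersion), \code{loglik}, \code{converged}, \code{vcov},
#'   \code{n}, \code{n_positive}, and the model frame pieces; supports
#'   \code{print}, \code{summary}, \code{coef}, \code{vcov}, \code{logLik},
#'   \code{predict}, \code{fitted}, \code{residuals}, \code{simulate} and
#'   \code{plot}.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(500))
#' mu <- exp(1 + 0.5 * d$x)
#' d$y <- rhurdle(500, mu, alpha = 0.4, pi0 = 0.3)
#' fit <- hurdle_ztnb(y ~ x, d)
#' coef(fit)
#' @export
hurdle_ztnb <- function(formula, data, model = c("ztnb_hurdle", "poisson"),
                        control = hurdle_control()) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- fit_hurdle_glm(x, y, model = match.arg(model), control = control)
  fit$call <- match.call()
  fit$formula <- formula
  fit$terms <- attr(mf, "terms")
  fit
}

## ---- methods ------------------------------------------------------------

#' @export
coef.hurdle_ztnb <- function(object, part = c("count", "zero", "full"), ...) {
  part <- match.arg(part)
  if (part == "full") {
    cc <- object$coefficients$count
    cz <- object$coefficients$zero
    out <- c(stats::setNames(cc, paste0("count_", names(cc))),
             if (!is.null(cz)) stats::setNames(cz, paste0("zero_", names(cz))),
             alpha = object$alpha)
    return(out)
  }
  object$coefficients[[part]]
}

#' @export
vcov.hurdle_ztnb <- function(object, part = c("count", "zero"), ...) {
  part <- match.arg(part)
  object$vcov[[part]]
}

#' @export
logLik.hurdle_ztnb <- function(object, ...) {
  p <- length(object$coefficients$count) +
    length(object$coefficients$zero) + (object$model == "ztnb_hurdle")
  structure(object$loglik, df = p, nobs = object$n, class = "logLik")
}

#' Predictions from a fitted hurdle model
#'
#' @param object A \code{"hurdle_ztnb"} fit.
#' @param newdata Optional data frame (formula fits) or design matrix.
#' @param type \code{"mean"} (expected count under the full hurdle law),
#'   \code{"mu"} (NB mean of the count part), \code{"pi0"} (zero
#'   probability).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.hurdle_ztnb <- function(object, newdata = NULL,
                                type = c("mean", "mu", "pi0"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x
  else if (is.matrix(newdata)) newdata
  else stats::model.matrix(stats::delete.response(object$terms), newdata)
  mu <- exp(pmin(drop(x %*% object$coefficients$count), 500))
  if (object$model == "poisson") {
    if (type == "pi0") return(exp(-mu))
    return(mu)
  }
  if (type == "mu") return(mu)
  pi0 <- stats::plogis(drop(x %*% object$coefficients$zero))
  if (type == "pi0") return(pi0)
  hurdle_mean(mu, object$alpha, pi0)
}

#' @export
fitted.hurdle_ztnb <- function(object, ...) predict(object, type = "mean")

#' @export
residuals.hurdle_ztnb <- function(object, type = c("pearson", "response"),
                                  ...) {
  type <- match.arg(type)
  m <- fitted(object)
  r <- object$y - m
  if (type == "response") return(r)
  if (object$model == "poisson") return(r / sqrt(m))
  v <- hurdle_var(predict(object, type = "mu"), object$alpha,
                  predict(object, type = "pi0"))
  r / sqrt(pmax(v, 1e-12))
}

#' @export
simulate.hurdle_ztnb <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, type = "mu")
  pi0 <- if (object$model == "poisson") 0 else predict(object, type = "pi0")
  out <- as.data.frame(replicate(nsim, rhurdle(object$n, mu, object$alpha, pi0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.hurdle_ztnb <- function(x, ...) {
  cat(sprintf("Hurdle %s regression (n = %d, %d positive)\n",
              if (x$model == "poisson") "Poisson (non-hurdle variant)"
              else "zero-truncated negative binomial",
              x$n, x$n_positive))
  cat("Count part coefficients:\n")
  print(round(x$coefficients$count, 4))
  if (!is.null(x$coefficients$zero)) {
    cat("Zero part coefficients (logit P(zero)):\n")
    print(round(x$coefficients$zero, 4))
    cat(sprintf("Dispersion alpha: %.4f\n", x$alpha))
  }
  cat(sprintf("logLik: %.2f   converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' @export
summary.hurdle_ztnb <- function(object, ...) {
  mk <- function(est, vc) {
    se <- if (is.null(vc)) rep(NA_real_, length(est))
    else sqrt(pmax(diag(vc)[seq_along(est)], 0))
    z <- est / se
    cbind(Estimate = est, `Std. Error` = se, `z value` = z,
          `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  }
  out <- list(model = object$model,
              count = mk(object$coefficients$count, object$vcov$count),
              zero = if (!is.null(object$coefficients$zero))
                mk(object$coefficients$zero, object$vcov$zero),
              alpha = object$alpha, loglik = object$loglik,
              converged = object$converged, n = object$n)
  class(out) <- "summary.hurdle_ztnb"
  out
}

#' @export
print.summary.hurdle_ztnb <- function(x, ...) {
  cat("Count part:\n"); stats::printCoefmat(x$count)
  if (!is.null(x$zero)) {
    cat("\nZero part (logit P(zero)):\n"); stats::printCoefmat(x$zero)
    cat(sprintf("\nDispersion alpha: %.4f\n", x$alpha))
  }
  cat(sprintf("logLik: %.2f on n = %d   converged: %s\n",
              x$loglik, x$n, x$converged))
  invisible(x)
}

#' @export
plot.hurdle_ztnb <- function(x, ...) {
  r <- residuals(x)
  m <- fitted(x)
  graphics::plot(m, r, xlab = "fitted mean", ylab = "Pearson residual",
                 main = "Hurdle ZTNB fit", log = "x", pch = ".", ...)
  graphics::abline(h = 0, col = "red")
  invisible(x)
}
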