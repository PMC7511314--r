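## Negative-binomial (NB2) regression with log link, fit by alternating
## Fisher-scoring IRLS for the coefficients with profile optimization of the
## dispersion, plus the pseudo-R-squared and FDR machinery used by the
## association and PTRS stages.

nb2_loglik <- function(y, mu, phi) {
  if (phi <= 0) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

#' Fit a negative-binomial GLM (NB2, log link)
#'
#' Maximum likelihood under `Var = mu + phi mu^2`: Fisher-scoring IRLS for
#' the coefficients alternated with profile optimization of the dispersion on
#' the log scale, until the log-likelihood changes by less than `tol`.  When
#' the dispersion estimate collapses to zero (data at or under Poisson
#' dispersion), the Poisson-limit fit is reported with `phi = 0`.  Wald
#' standard errors come from the Fisher information at the optimum; two-sided
#' p-values use the normal approximation.
#'
#' @param y nonnegative integer response.
#' @param X design matrix including an intercept column.
#' @param tol log-likelihood convergence tolerance (1e-8).
#' @param max_iter outer iteration cap (100).
#' @return object of class `nb_glm` with `coefficients`, `se`, `z`, `p`,
#'   `dispersion`, `log_lik`, `fitted`, `converged`, `n`, `df`.
#' @export
fit_nb_glm <- function(y, X, tol = 1e-8, max_iter = 100L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop("y and X disagree on sample count", call. = FALSE)
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("y must contain nonnegative integers", call. = FALSE)
  if (all(y == 0)) stop("response is identically zero", call. = FALSE)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  y <- as.numeric(round(y))

  irls <- function(beta, phi, n_steps = 25L) {
    for (i in seq_len(n_steps)) {
      eta <- drop(X %*% beta)
      mu <- pmin(exp(eta), 1e10)
      w <- mu / (1 + phi * mu)
      z <- eta + (y - mu) / mu
      XtW <- t(X * w)
      beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                           error = function(e)
                             stop("IRLS normal equations singular (separation?)",
                                  call. = FALSE))
      delta <- max(abs(beta_new - beta))
      beta <- drop(beta_new)
      if (delta < 1e-10) break
    }
    beta
  }

  ## Poisson start
  init <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  beta <- init$coefficients
  mu <- pmin(exp(drop(X %*% beta)), 1e10)
  phi <- max((sum((y - mu)^2 / mu) - (n - ncol(X))) / sum(mu), 1e-4)

  ll_old <- nb2_loglik(y, mu, phi)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    beta <- irls(beta, phi)
    mu <- pmin(exp(drop(X %*% beta)), 1e10)
    opt <- stats::optimize(function(lphi) nb2_loglik(y, mu, exp(lphi)),
                           interval = c(log(1e-8), log(100)), maximum = TRUE)
    phi <- exp(opt$maximum)
    ll <- opt$objective
    if (abs(ll - ll_old) < tol) { converged <- TRUE; ll_old <- ll; break }
    ll_old <- ll
  }

  if (phi < 1e-6) {
    ## Poisson limit
    fitp <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
    beta <- fitp$coefficients
    mu <- fitp$fitted.values
    phi <- 0
    ll_old <- nb2_loglik(y, mu, 0)
    converged <- fitp$converged
  } else {
    beta <- irls(beta, phi)
    mu <- pmin(exp(drop(X %*% beta)), 1e10)
    ll_old <- nb2_loglik(y, mu, phi)
  }

  w <- mu / (1 + phi * mu)
  info <- t(X * w) %*% X
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 z = stats::setNames(z, colnames(X)),
                 p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
                 dispersion = phi, log_lik = ll_old, fitted = mu,
                 converged = converged, n = n, df = ncol(X)),
            class = "nb_glm")
}

#' @export
print.nb_glm <- function(x, ...) {
  cat(sprintf("NB2 GLM (log link): n = %d, dispersion = %.4g, logLik = %.3f%s\n",
              x$n, x$dispersion, x$log_lik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(round(cbind(beta = x$coefficients, se = x$se, z = x$z, p = x$p), 5))
  invisible(x)
}

#' @export
summary.nb_glm <- function(object, ...) {
  out <- data.frame(term = names(object$coefficients),
                    beta = unname(object$coefficients), se = unname(object$se),
                    z = unname(object$z), p = unname(object$p))
  attr(out, "dispersion") <- object$dispersion
  attr(out, "log_lik") <- object$log_lik
  out
}

#' @export
coef.nb_glm <- function(object, ...) object$coefficients

#' @export
logLik.nb_glm <- function(object, ...) {
  structure(object$log_lik, df = object$df + (object$dispersion > 0),
            class = "logLik")
}

#' Nagelkerke pseudo R-squared of nested likelihood fits
#'
#' `R2_CS = 1 - exp((2/n)(ll0 - ll1))` rescaled by its maximum
#' `1 - exp((2/n) ll0)` to the unit interval.
#'
#' @param fit,null_fit full and nested null model fits (`nb_glm` objects or
#'   anything with `log_lik` and `n` fields).
#' @return Nagelkerke R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit, null_fit) {
  if (fit$n != null_fit$n)
    stop("fits were made on different sample sizes", call. = FALSE)
  ll1 <- fit$log_lik; ll0 <- null_fit$log_lik; n <- fit$n
  if (ll1 < ll0 - 1e-6)
    stop("full-model log-likelihood below the null: models are not nested",
         call. = FALSE)
  r2_cs <- 1 - exp((2 / n) * (ll0 - ll1))
  r2_max <- 1 - exp((2 / n) * ll0)
  if (r2_max <= 0) return(0)
  min(max(r2_cs / r2_max, 0), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} (m p_(j) / j)` clipped at 1,
#' returned in input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
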