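# Univariate Gaussian mixture fitting with EM, plus the skewness/kurtosis
# non-Gaussianity criterion used to select the number of components. The
# mixture is the package's model for observed fish-instance lengths: valid
# single-fish instances form one (dominant) component, while merged
# double-fish instances and truncated partial instances form their own
# components at inflated/deflated lengths.

log_gauss <- function(x, mean, var) {
  -0.5 * (log(2 * pi * var) + (x - mean)^2 / var)
}

# log p(x) and responsibilities for current parameters, via log-sum-exp
e_step <- function(x, w, mu, var) {
  lp <- vapply(seq_along(w),
               function(i) log(w[i]) + log_gauss(x, mu[i], var[i]),
               numeric(length(x)))
  lp <- matrix(lp, nrow = length(x))
  m <- apply(lp, 1, max)
  lse <- m + log(rowSums(exp(lp - m)))
  list(loglik = sum(lse), resp = exp(lp - lse))
}

#' Fit a univariate Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a `c`-component Gaussian mixture
#' `p(x) = sum_i w_i N(x; mu_i, sigma_i^2)` to scalar samples (fish-instance
#' lengths, in this package). Components are initialised from k-means on the
#' samples; `n_init` restarts are run and the fit with the best final
#' log-likelihood is kept. EM iterates until the relative log-likelihood
#' change drops below `tol` or `max_iter` is reached. Variances are floored
#' at `var_floor` to prevent component collapse. For `c = 1` the
#' maximum-likelihood solution (sample mean, variance with denominator n) is
#' returned in closed form.
#'
#' Components are reported sorted by increasing mean.
#'
#' @param x numeric samples; at least `c` of them.
#' @param c number of components, 1..5.
#' @param seed optional RNG seed for the k-means restarts.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param n_init number of k-means restarts (default 10).
#' @param var_floor variance floor in squared units (default 1e-6).
#' @return An object of class `gmm_fit`: `c`, `weights`, `means`, `vars`,
#'   `loglik`, `loglik_trace` (per accepted iteration), `n_iter`, `n`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(200, 10, 1), rnorm(100, 30, 1))
#' fit_gmm(x, 2, seed = 1)
#' @export
fit_gmm <- function(x, c, seed = NULL, tol = 1e-8, max_iter = 500L,
                    n_init = 10L, var_floor = 1e-6) {
  x <- as.numeric(x)
  n <- length(x)
  if (c < 1L || c > 5L) abort("component count must be 1..5", "domain_error")
  if (n < c) abort("fewer samples than mixture components", "insufficient_data")
  if (c == 1L) {
    v <- max(mean((x - mean(x))^2), var_floor)
    ll <- sum(log_gauss(x, mean(x), v))
    return(structure(list(c = 1L, weights = 1, means = mean(x), vars = v,
                          loglik = ll, loglik_trace = ll, n_iter = 0L, n = n),
                     class = "gmm_fit"))
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (rep in seq_len(n_init)) {
    init <- tryCatch(stats::kmeans(x, centers = c, nstart = 1L),
                     error = function(e) NULL)
    if (is.null(init)) {
      # ties in x can defeat k-means seeding; fall back to jittered quantiles
      mu <- stats::quantile(x, probs = (seq_len(c) - 0.5) / c, names = FALSE) +
        stats::rnorm(c, 0, stats::sd(x) * 0.01 + 1e-9)
      vr <- rep(max(stats::var(x), var_floor), c)
      w <- rep(1 / c, c)
    } else {
      mu <- as.numeric(init$centers)
      vr <- vapply(seq_len(c), function(i) {
        xi <- x[init$cluster == i]
        if (length(xi) > 1L) mean((xi - mean(xi))^2) else var_floor
      }, 0)
      vr <- pmax(vr, var_floor)
      w <- as.numeric(table(factor(init$cluster, levels = seq_len(c)))) / n
      w <- pmax(w, 1e-6); w <- w / sum(w)
    }
    es <- e_step(x, w, mu, vr)
    trace <- es$loglik
    for (it in seq_len(max_iter)) {
      nk <- colSums(es$resp)
      w <- nk / n
      mu <- colSums(es$resp * x) / nk
      vr <- pmax(colSums(es$resp * (outer(x, mu, `-`))^2) / nk, var_floor)
      es2 <- e_step(x, w, mu, vr)
      trace <- c(trace, es2$loglik)
      done <- abs(es2$loglik - es$loglik) < tol * (abs(es$loglik) + 1e-12)
      es <- es2
      if (done) break
    }
    if (is.null(best) || es$loglik > best$loglik) {
      best <- list(w = w, mu = mu, vr = vr, loglik = es$loglik,
                   trace = trace, n_iter = length(trace) - 1L)
    }
  }
  ord <- order(best$mu)
  structure(list(c = as.integer(c), weights = best$w[ord], means = best$mu[ord],
                 vars = best$vr[ord], loglik = best$loglik,
                 loglik_trace = best$trace, n_iter = best$n_iter, n = n),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: %d component(s), n = %d, loglik = %.4f\n",
              x$c, x$n, x$loglik))
  print(data.frame(weight = round(x$weights, 4), mean = round(x$means, 4),
                   sd = round(sqrt(x$vars), 4)))
  if (!is.null(x$phi)) cat(sprintf("Phi(c) = %.4f\n", x$phi))
  invisible(x)
}

#' Posterior component membership
#'
#' `p(G_i | x) = w_i N(x; mu_i, sigma_i^2) / sum_j w_j N(x; mu_j, sigma_j^2)`.
#' A sample is assigned to the component with the largest posterior.
#'
#' @param x numeric samples.
#' @param fit a [fit_gmm()] result.
#' @return Matrix (length(x) rows, `fit$c` columns) of posterior
#'   probabilities; rows sum to 1.
#' @export
posterior_membership <- function(x, fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  e_step(as.numeric(x), fit$weights, fit$means, fit$vars)$resp
}

hard_assignment <- function(x, fit) {
  resp <- posterior_membership(x, fit)
  max.col(resp, ties.method = "first")
}

#' Non-Gaussianity criterion of a mixture fit
#'
#' Scores how Gaussian each fitted component looks on the samples assigned
#' to it (hard assignment by largest posterior):
#' `Phi(c) = (1/c) sum_i ( |skew_i| + |kurt_i - 3| )`, where for component
#' `i` with fitted `mu_i`, `sigma_i`,
#' `skew_i = mean((x - mu_i)^3) / sigma_i^3` and
#' `kurt_i = mean((x - mu_i)^4) / sigma_i^4` over its assigned samples.
#' A component with fewer than 4 assigned samples cannot support these
#' moments and disqualifies the fit (`Phi = Inf`).
#'
#' Lower is better: a correctly specified mixture leaves each component's
#' residuals looking Gaussian (skewness 0, kurtosis 3).
#'
#' @param fit a [fit_gmm()] result.
#' @param x the samples the fit was trained on.
#' @return Scalar Phi, dimensionless; Inf when any component has < 4
#'   members.
#' @export
nongaussianity <- function(fit, x) {
  stopifnot(inherits(fit, "gmm_fit"))
  x <- as.numeric(x)
  assign <- hard_assignment(x, fit)
  contrib <- vapply(seq_len(fit$c), function(i) {
    xi <- x[assign == i]
    if (length(xi) < 4L) return(Inf)
    s <- sqrt(fit$vars[i])
    skew <- mean((xi - fit$means[i])^3) / s^3
    kurt <- mean((xi - fit$means[i])^4) / s^4
    abs(skew) + abs(kurt - 3)
  }, 0)
  mean(contrib)
}

#' Select the mixture order by minimum non-Gaussianity
#'
#' Fits mixtures with `c` ranging over `c_range` (default 1..5) and returns
#' the fit minimising [nongaussianity()]; ties break toward smaller `c`.
#'
#' @param x numeric samples (at least 5).
#' @param c_range candidate component counts (default 1:5).
#' @param seed optional RNG seed, reused for every candidate fit.
#' @param ... passed to [fit_gmm()].
#' @return The selected `gmm_fit`, with the score attached as `$phi`.
#' @export
select_model <- function(x, c_range = 1:5, seed = NULL, ...) {
  if (length(x) < 5L) abort("need at least 5 samples for model selection", "insufficient_data")
  fits <- lapply(c_range, function(ci) {
    f <- tryCatch(fit_gmm(x, ci, seed = seed, ...), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    f$phi <- nongaussianity(f, x)
    f
  })
  fits <- Filter(Negate(is.null), fits)
  phis <- vapply(fits, `[[`, 0, "phi")
  if (!length(phis) || all(!is.finite(phis))) {
    abort("every candidate mixture was disqualified", "model_selection_failure")
  }
  fits[[which.min(phis)]]  # which.min returns the first minimum: smaller c wins ties
}

#' Index of the single-fish component
#'
#' The component with the largest mixture weight is taken to contain the
#' valid single-fish instances (merged and partial instances are assumed to
#' be the rarer contaminants). Weight ties break toward the component with
#' the smaller mean.
#'
#' @param fit a [fit_gmm()] result (components are sorted by mean).
#' @return Integer component index.
#' @export
single_fish_component <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  which.max(fit$weights)  # components sorted by mean, so first max = smallest mean
}
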