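## Two-component Student's-t mixture thresholding of per-adenine log-IPD
## residuals: EM fitting, the equal-likelihood methylation cutoff, and the
## three adenine-usability filters.

#' Construct a two-component Student's-t mixture
#'
#' @param weights Two mixing proportions (nonnegative, summing to 1).
#' @param means Two location parameters.
#' @param scales Two positive scale parameters.
#' @param dfs Two positive degrees-of-freedom.
#' @return An object of class `t_mixture`.
#' @export
t_mixture <- function(weights, means, scales, dfs) {
  obj <- structure(list(weights = as.numeric(weights),
                        means = as.numeric(means),
                        scales = as.numeric(scales),
                        dfs = as.numeric(dfs)),
                   class = "t_mixture")
  validate_t_mixture(obj)
  obj
}

#' Validate a `t_mixture`
#' @param mixture Object to check.
#' @return The mixture, invisibly; errors on violation.
#' @export
validate_t_mixture <- function(mixture) {
  stopifnot(inherits(mixture, "t_mixture"))
  with(mixture, {
    if (length(weights) != 2L || length(means) != 2L ||
        length(scales) != 2L || length(dfs) != 2L)
      stop("t_mixture components must all have length 2")
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
      stop("weights must be nonnegative and sum to 1")
    if (any(scales <= 0)) stop("scales must be positive")
    if (any(dfs <= 0)) stop("dfs must be positive")
  })
  invisible(mixture)
}

#' @export
print.t_mixture <- function(x, ...) {
  cat(sprintf(
    "<t_mixture> w=(%.3f, %.3f) mu=(%.3f, %.3f) sigma=(%.3f, %.3f) df=(%.2f, %.2f)\n",
    x$weights[1], x$weights[2], x$means[1], x$means[2],
    x$scales[1], x$scales[2], x$dfs[1], x$dfs[2]))
  invisible(x)
}

## location-scale t log-density
dt_ls <- function(x, mean, scale, df, log = FALSE) {
  ld <- dt((x - mean) / scale, df = df, log = TRUE) - log(scale)
  if (log) ld else exp(ld)
}

#' Mixture density of a `t_mixture`
#' @param x Numeric vector of evaluation points.
#' @param mixture A `t_mixture`.
#' @return Density values.
#' @export
dtmix <- function(x, mixture) {
  validate_t_mixture(mixture)
  mixture$weights[1L] * dt_ls(x, mixture$means[1L], mixture$scales[1L], mixture$dfs[1L]) +
    mixture$weights[2L] * dt_ls(x, mixture$means[2L], mixture$scales[2L], mixture$dfs[2L])
}

## per-component weighted log-densities, n x 2
tmix_comp_logdens <- function(x, mix) {
  cbind(log(mix$weights[1L]) + dt_ls(x, mix$means[1L], mix$scales[1L], mix$dfs[1L], log = TRUE),
        log(mix$weights[2L]) + dt_ls(x, mix$means[2L], mix$scales[2L], mix$dfs[2L], log = TRUE))
}

tmix_loglik <- function(x, mix) {
  ld <- tmix_comp_logdens(x, mix)
  m <- pmax(ld[, 1L], ld[, 2L])
  sum(m + log(exp(ld[, 1L] - m) + exp(ld[, 2L] - m)))
}

## ECM degrees-of-freedom update: solve the standard digamma equation for
## nu in [df_min, df_max]; falls back to the nearer bound if no sign change.
solve_df <- function(resp_k, u_k, df_old, df_min = 1, df_max = 300) {
  n_k <- sum(resp_k)
  cst <- 1 + sum(resp_k * (log(u_k) - u_k)) / n_k +
    digamma((df_old + 1) / 2) - log((df_old + 1) / 2)
  f <- function(nu) -digamma(nu / 2) + log(nu / 2) + cst
  flo <- f(df_min); fhi <- f(df_max)
  if (is.na(flo) || is.na(fhi)) return(df_old)
  if (flo < 0) return(df_min)
  if (fhi > 0) return(df_max)
  uniroot(f, c(df_min, df_max), tol = 1e-8)$root
}

#' Fit a two-component Student's-t mixture by EM
#'
#' ECM algorithm with the usual latent-gamma formulation: E-step computes
#' component responsibilities and the gamma weights
#' `u = (df + 1) / (df + z^2)`; M-step updates weights, weighted means and
#' scales; degrees of freedom are updated by solving the digamma equation
#' (lower bound 1), or held fixed via `fix_df`. Components are returned
#' sorted by ascending mean. Initialization is a seeded 2-means split.
#'
#' @param residuals A `residual_sample` or numeric vector.
#' @param tol Convergence tolerance on the log-likelihood change
#'   (default `1e-6`).
#' @param max_iter Maximum EM iterations.
#' @param seed Optional integer seed controlling initialization.
#' @param fix_df If non-`NULL`, hold both degrees of freedom at this value.
#' @return A `t_mixture` with attributes `loglik` (per-iteration trace),
#'   `iterations`, and `converged`.
#' @export
fit_t_mixture <- function(residuals, tol = 1e-6, max_iter = 1000L,
                          seed = NULL, fix_df = NULL) {
  x <- if (inherits(residuals, "residual_sample")) residuals$values else
    as.numeric(residuals)
  stopifnot(all(is.finite(x)), tol > 0)
  if (length(unique(x)) < 2L)
    stop("degenerate residuals: need at least 2 distinct values")
  km <- with_seed(seed, kmeans(x, centers = 2L, nstart = 5L))
  ord <- order(km$centers)
  mu <- as.numeric(km$centers[ord])
  sig <- vapply(ord, function(k) {
    s <- sd(x[km$cluster == k])
    if (!is.finite(s) || s < 1e-6) s <- sd(x) / 2
    s
  }, 0)
  w <- as.numeric(table(factor(km$cluster, levels = ord)) / length(x))
  nu <- if (is.null(fix_df)) c(10, 10) else rep(fix_df, 2L)
  mix <- t_mixture(w, mu, sig, nu)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- tmix_comp_logdens(x, mix)
    m <- pmax(ld[, 1L], ld[, 2L])
    lse <- m + log(exp(ld[, 1L] - m) + exp(ld[, 2L] - m))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(ld - lse)                     # n x 2 responsibilities
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    for (k in 1:2) {
      z2 <- ((x - mix$means[k]) / mix$scales[k])^2
      u <- (mix$dfs[k] + 1) / (mix$dfs[k] + z2)
      rk <- resp[, k]
      sw <- sum(rk * u)
      mix$means[k] <- sum(rk * u * x) / sw
      s2 <- sum(rk * u * (x - mix$means[k])^2) / sum(rk)
      mix$scales[k] <- sqrt(max(s2, 1e-12))
      if (is.null(fix_df))
        mix$dfs[k] <- solve_df(rk, u, mix$dfs[k])
    }
    mix$weights <- pmax(colMeans(resp), 1e-12)
    mix$weights <- mix$weights / sum(mix$weights)
  }
  if (!converged)
    warning("EM did not converge within max_iter; returning best estimate")
  ord <- order(mix$means)
  out <- t_mixture(mix$weights[ord], mix$means[ord], mix$scales[ord],
                   mix$dfs[ord])
  attr(out, "loglik") <- ll_trace
  attr(out, "iterations") <- length(ll_trace)
  attr(out, "converged") <- converged
  out
}

#' Equal-likelihood methylation cutoff of a two-component t mixture
#'
#' Finds the residual value between the two component means at which the
#' value is equally likely to originate from either component. With
#' `weighted = TRUE` (default) this is the point of equal weighted component
#' densities, i.e. posterior responsibility 1/2; with `weighted = FALSE`
#' mixing weights are ignored and raw component densities are equated.
#'
#' @param mixture A `t_mixture` with distinct means.
#' @param bracket Search interval; defaults to the interval between the
#'   component means.
#' @param weighted Use mixing weights (posterior-1/2 reading)?
#' @return The cutoff, a single numeric value.
#' @export
equal_likelihood_cutoff <- function(mixture, bracket = NULL, weighted = TRUE) {
  validate_t_mixture(mixture)
  if (abs(diff(mixture$means)) < 1e-12)
    stop("component means must be distinct")
  if (is.null(bracket)) bracket <- sort(mixture$means)
  g <- function(c) {
    lw <- if (weighted) log(mixture$weights) else c(0, 0)
    (lw[1L] + dt_ls(c, mixture$means[1L], mixture$scales[1L], mixture$dfs[1L], log = TRUE)) -
      (lw[2L] + dt_ls(c, mixture$means[2L], mixture$scales[2L], mixture$dfs[2L], log = TRUE))
  }
  if (g(bracket[1L]) * g(bracket[2L]) > 0)
    stop("no equal-likelihood root in bracket")
  uniroot(g, bracket, tol = .Machine$double.eps^0.75)$root
}

#' Assess whether an adenine's cutoff is informative enough to use
#'
#' Three usability criteria: (1) at least one component mean above zero;
#' (2) the gap between the component means at least `min_mean_gap`;
#' (3) at least `min_frac_above` of the training residuals above the
#' cutoff. All three must hold for the adenine to be usable.
#'
#' @param mixture Fitted `t_mixture` for this adenine.
#' @param cutoff Equal-likelihood cutoff for this adenine.
#' @param train The training `residual_sample` (or numeric vector).
#' @param min_mean_gap Minimum mean separation (conventional range 0.1-0.3;
#'   default 0.2).
#' @param min_frac_above Minimum fraction of training data above the cutoff
#'   (default 0.02).
#' @return A list (class `usability_decision`) with `usable`, `cutoff`
#'   (`NA` when unusable), and `reasons` (subset of `"no_positive_mean"`,
#'   `"mean_gap_too_small"`, `"too_few_above_cutoff"`).
#' @export
assess_adenine_usability <- function(mixture, cutoff, train,
                                     min_mean_gap = 0.2,
                                     min_frac_above = 0.02) {
  validate_t_mixture(mixture)
  x <- if (inherits(train, "residual_sample")) train$values else
    as.numeric(train)
  reasons <- character(0)
  if (!any(mixture$means > 0)) reasons <- c(reasons, "no_positive_mean")
  if (abs(diff(mixture$means)) < min_mean_gap)
    reasons <- c(reasons, "mean_gap_too_small")
  if (mean(x > cutoff) < min_frac_above)
    reasons <- c(reasons, "too_few_above_cutoff")
  usable <- length(reasons) == 0L
  structure(list(usable = usable,
                 cutoff = if (usable) cutoff else NA_real_,
                 reasons = reasons),
            class = "usability_decision")
}

#' Call methylation from residuals at a cutoff
#'
#' A residual is called methylated iff it is strictly above the cutoff
#' (boundary ties are called unmethylated).
#'
#' @param residuals A `residual_sample` or numeric vector.
#' @param cutoff Finite numeric cutoff.
#' @return Integer vector of binary calls.
#' @export
call_methylation <- function(residuals, cutoff) {
  stopifnot(is.finite(cutoff))
  x <- if (inherits(residuals, "residual_sample")) residuals$values else
    as.numeric(residuals)
  as.integer(x > cutoff)
}
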