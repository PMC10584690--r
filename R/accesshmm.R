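## Two-state-per-adenine chain HMM: accessible vs inaccessible, Bernoulli
## methylation emissions, geometric distance-dependent transitions, Viterbi
## decoding and per-base interpolation.

#' Smoothed emission fractions from control counts
#'
#' Converts per-adenine methylated counts among control molecules into
#' emission probabilities as `(k + 0.5) / (n + 0.5)`, avoiding exact zeros.
#'
#' @param methylated_count Per-adenine count of control molecules called
#'   methylated.
#' @param total_count Per-adenine total number of control molecules.
#' @return Per-adenine probabilities.
#' @export
emissions_from_controls <- function(methylated_count, total_count) {
  k <- as.numeric(methylated_count)
  n <- as.numeric(total_count)
  if (any(k < 0) || any(n < 1)) stop("counts must satisfy n >= 1, k >= 0")
  if (any(k > n)) stop("methylated_count exceeds total_count")
  (k + 0.5) / (n + 0.5)
}

#' Construct an accessibility HMM
#'
#' Two hidden states (accessible / inaccessible) at every usable adenine.
#' Emissions are Bernoulli: `p_meth_acc[i]` is the probability of observing
#' a methylation call at adenine i in the accessible state, `p_meth_inacc[i]`
#' in the inaccessible state. For an expected state run length of `L` bp the
#' per-base switch probability is `1/L`, so the probability of staying in
#' the same state across an inter-adenine gap of `B` bases is
#' `(1 - 1/L)^B`. The initial state is accessible with probability
#' `initial_accessible`.
#'
#' @param positions Strictly increasing 0-based adenine positions.
#' @param p_meth_acc,p_meth_inacc Per-adenine emission probabilities,
#'   satisfying `0 < p_meth_inacc <= p_meth_acc <= 1`.
#' @param expected_run_length Expected run length `L` in bp (default 1000;
#'   deliberately long so that switching states requires a high burden of
#'   evidence, minimizing spurious switching).
#' @param initial_accessible Initial probability of the accessible state.
#' @param epsilon_cap Optional cap applied to emission probabilities of
#'   exactly 1 (replaced by `1 - epsilon_cap`) for log-space safety;
#'   default `NULL` (off): saturated controls legitimately give 1.
#' @return An object of class `access_hmm`.
#' @export
access_hmm <- function(positions, p_meth_acc, p_meth_inacc,
                       expected_run_length = 1000, initial_accessible = 0.5,
                       epsilon_cap = NULL) {
  positions <- as.integer(positions)
  n <- length(positions)
  if (n < 1L) stop("need at least one usable adenine")
  stopifnot(length(p_meth_acc) == n, length(p_meth_inacc) == n,
            expected_run_length > 1,
            initial_accessible > 0, initial_accessible < 1)
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (!is.null(epsilon_cap)) {
    p_meth_acc <- pmin(p_meth_acc, 1 - epsilon_cap)
    p_meth_inacc <- pmin(p_meth_inacc, 1 - epsilon_cap)
  }
  if (any(p_meth_inacc <= 0) || any(p_meth_acc > 1) ||
      any(p_meth_inacc > p_meth_acc))
    stop("emissions must satisfy 0 < p_meth_inacc <= p_meth_acc <= 1")
  structure(list(positions = positions,
                 p_meth_acc = as.numeric(p_meth_acc),
                 p_meth_inacc = as.numeric(p_meth_inacc),
                 expected_run_length = as.numeric(expected_run_length),
                 initial_accessible = as.numeric(initial_accessible)),
            class = "access_hmm")
}

#' @export
print.access_hmm <- function(x, ...) {
  cat(sprintf("<access_hmm> %d adenines over [%d, %d], L = %g bp\n",
              length(x$positions), min(x$positions), max(x$positions),
              x$expected_run_length))
  invisible(x)
}

#' Probability of staying in the same state across a gap
#'
#' `(1 - 1/L)^B` for inter-adenine distance `B` (vectorized).
#'
#' @param gap Inter-adenine distance(s) in bases, `>= 1`.
#' @param expected_run_length Expected run length `L` in bp.
#' @return Stay probabilities.
#' @export
stay_probability <- function(gap, expected_run_length) {
  stopifnot(all(gap >= 1), expected_run_length > 1)
  (1 - 1 / expected_run_length)^gap
}

#' Build an accessibility HMM from a rate map or from control molecules
#'
#' In "genomic" use, per-adenine rate maps (standing in for predicted
#' control methylation rates) supply the emissions directly. In
#' "homogeneous" use, [build_hmm_from_controls()] tallies observed control
#' calls and smooths them with [emissions_from_controls()].
#'
#' @param rates A `rate_map`.
#' @param expected_run_length Expected run length `L` in bp.
#' @param usable Optional logical mask over the rate map's adenines;
#'   unusable adenines are skipped in the chain and their gap lengths are
#'   absorbed into the inter-adenine distances.
#' @param ... Passed to [access_hmm()].
#' @return An `access_hmm`.
#' @export
build_hmm <- function(rates, expected_run_length = 1000, usable = NULL, ...) {
  stopifnot(inherits(rates, "rate_map"))
  keep <- if (is.null(usable)) rep(TRUE, length(rates$adenine_positions)) else
    as.logical(usable)
  if (!any(keep)) stop("no usable adenines")
  access_hmm(rates$adenine_positions[keep], rates$p_acc[keep],
             rates$p_inacc[keep], expected_run_length, ...)
}

#' @rdname build_hmm
#' @param positive,negative Lists of control `methylation_calls` (fully
#'   methylated naked DNA and unmethylated molecules respectively), all on
#'   the same adenine positions.
#' @export
build_hmm_from_controls <- function(positive, negative,
                                    expected_run_length = 1000,
                                    usable = NULL, ...) {
  stopifnot(length(positive) >= 1L, length(negative) >= 1L)
  pos_mat <- vapply(positive, `[[`, positive[[1L]]$calls, "calls")
  neg_mat <- vapply(negative, `[[`, negative[[1L]]$calls, "calls")
  p_acc <- emissions_from_controls(rowSums(pos_mat), ncol(pos_mat))
  p_inacc <- emissions_from_controls(rowSums(neg_mat), ncol(neg_mat))
  ## the HMM invariant requires p_inacc <= p_acc; sampling noise in small
  ## control sets can invert an adenine, which is then unusable
  keep <- if (is.null(usable)) rep(TRUE, length(p_acc)) else as.logical(usable)
  keep <- keep & p_inacc <= p_acc
  if (!any(keep)) stop("no usable adenines")
  access_hmm(positive[[1L]]$positions[keep], p_acc[keep], p_inacc[keep],
             expected_run_length, ...)
}

## per-adenine emission log-likelihoods for a call vector under both states
emission_loglik <- function(hmm, calls) {
  la <- ifelse(calls == 1L, log(hmm$p_meth_acc), log1p(-hmm$p_meth_acc))
  li <- ifelse(calls == 1L, log(hmm$p_meth_inacc), log1p(-hmm$p_meth_inacc))
  cbind(accessible = la, inaccessible = li)
}

align_calls <- function(hmm, calls) {
  if (inherits(calls, "methylation_calls")) {
    if (length(calls$positions) == length(hmm$positions) &&
        all(calls$positions == hmm$positions)) return(calls$calls)
    idx <- match(hmm$positions, calls$positions)
    if (anyNA(idx))
      stop("calls are not aligned to the HMM's adenine positions")
    return(calls$calls[idx])
  }
  calls <- as.integer(calls)
  if (length(calls) != length(hmm$positions))
    stop("calls length does not match HMM adenine count")
  calls
}

#' Viterbi decoding of molecule-wide accessibility
#'
#' Maximum-a-posteriori state path under the chain model, in log space and
#' linear time. Exact ties are broken toward the inaccessible state
#' (conservative footprint calling).
#'
#' @param hmm An `access_hmm`.
#' @param calls A `methylation_calls` aligned to the HMM's adenines, or a
#'   bare binary vector of the same length.
#' @return A `state_path`: list with `states` (integer, 1 = accessible,
#'   0 = inaccessible, one per adenine) and `log_probability` (maximized
#'   joint log-probability of path and observations).
#' @export
viterbi_decode <- function(hmm, calls) {
  stopifnot(inherits(hmm, "access_hmm"))
  obs <- align_calls(hmm, calls)
  n <- length(obs)
  em <- emission_loglik(hmm, obs)           # n x 2: accessible, inaccessible
  lstay <- c(NA, log(stay_probability(diff(hmm$positions),
                                      hmm$expected_run_length)))
  lswitch <- c(NA, log1p(-stay_probability(diff(hmm$positions),
                                           hmm$expected_run_length)))
  delta <- matrix(-Inf, n, 2L)
  psi <- matrix(0L, n, 2L)
  delta[1L, ] <- c(log(hmm$initial_accessible),
                   log1p(-hmm$initial_accessible)) + em[1L, ]
  if (n > 1L) for (t in 2:n) {
    for (s in 1:2) {
      from_same <- delta[t - 1L, s] + lstay[t]
      from_other <- delta[t - 1L, 3L - s] + lswitch[t]
      ## ties resolved toward the inaccessible predecessor (state 2)
      if (from_same > from_other || (from_same == from_other && s == 2L)) {
        delta[t, s] <- from_same + em[t, s]
        psi[t, s] <- s
      } else {
        delta[t, s] <- from_other + em[t, s]
        psi[t, s] <- 3L - s
      }
    }
  }
  ## backtrack; tie at the end prefers inaccessible (state 2)
  states <- integer(n)
  states[n] <- if (delta[n, 1L] > delta[n, 2L]) 1L else 2L
  if (n > 1L) for (t in (n - 1L):1L) states[t] <- psi[t + 1L, states[t + 1L]]
  structure(list(states = ifelse(states == 1L, 1L, 0L),
                 log_probability = max(delta[n, ])),
            class = "state_path")
}

#' Exhaustive decoding oracle
#'
#' Enumerates all `2^n` state paths (n <= 20) and returns the maximizer and
#' its joint log-probability. Intended as an independent correctness oracle
#' for [viterbi_decode()] on small instances.
#'
#' @inheritParams viterbi_decode
#' @return A `state_path` as in [viterbi_decode()].
#' @export
brute_force_decode <- function(hmm, calls) {
  stopifnot(inherits(hmm, "access_hmm"))
  obs <- align_calls(hmm, calls)
  n <- length(obs)
  if (n > 20L) stop("brute_force_decode supports at most 20 adenines")
  em <- emission_loglik(hmm, obs)
  gaps <- diff(hmm$positions)
  lstay <- log(stay_probability(gaps, hmm$expected_run_length))
  lswitch <- log1p(-stay_probability(gaps, hmm$expected_run_length))
  best_lp <- -Inf
  best <- NULL
  for (code in 0:(2^n - 1)) {
    ## bit 1 = accessible at that adenine
    acc <- as.integer(bitwAnd(bitwShiftR(code, 0:(n - 1L)), 1L))
    lp <- ifelse(acc[1L] == 1L, log(hmm$initial_accessible),
                 log1p(-hmm$initial_accessible)) +
      sum(ifelse(acc == 1L, em[, 1L], em[, 2L]))
    if (n > 1L) {
      same <- acc[-1L] == acc[-n]
      lp <- lp + sum(ifelse(same, lstay, lswitch))
    }
    if (lp > best_lp) {
      best_lp <- lp
      best <- acc
    }
  }
  structure(list(states = best, log_probability = best_lp),
            class = "state_path")
}

#' Interpolate a decoded state path to a per-base accessibility track
#'
#' Decoded adenines contribute 1 (accessible) or 0 (inaccessible);
#' non-adenine and uncalled bases between consecutive decoded adenines are
#' interpolated (`"linear"` by default, `"nearest"` as an option); bases
#' before the first and after the last decoded adenine take the nearest
#' decoded value.
#'
#' @param path A `state_path`.
#' @param positions 0-based positions of the decoded adenines.
#' @param template_length Output track length in bp.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return Numeric per-base accessibility track in `[0, 1]`.
#' @export
interpolate_track <- function(path, positions, template_length,
                              method = c("linear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(path, "state_path"))
  positions <- as.integer(positions)
  if (!length(path$states)) stop("empty state path")
  stopifnot(length(positions) == length(path$states),
            !is.unsorted(positions, strictly = TRUE),
            positions[1L] >= 0L, positions[length(positions)] < template_length)
  if (length(positions) == 1L)
    return(rep(as.numeric(path$states), template_length))
  if (method == "nearest") {
    ## split each inter-adenine interval at its midpoint; ties go 3'
    cuts <- positions[-1L] - diff(positions) / 2
    idx <- findInterval(0:(template_length - 1L), cuts) + 1L
    return(as.numeric(path$states)[idx])
  }
  approx(positions, as.numeric(path$states), xout = 0:(template_length - 1L),
         method = "linear", rule = 2L)$y
}

#' Decode one molecule to a per-base accessibility track
#'
#' Convenience wrapper: [viterbi_decode()] then [interpolate_track()].
#'
#' @inheritParams viterbi_decode
#' @param template_length Track length in bp.
#' @param method Interpolation method, see [interpolate_track()].
#' @return Numeric per-base accessibility track.
#' @export
decode_molecule <- function(hmm, calls, template_length,
                            method = c("linear", "nearest")) {
  path <- viterbi_decode(hmm, calls)
  interpolate_track(path, hmm$positions, template_length, match.arg(method))
}
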