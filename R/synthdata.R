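## Synthetic methylation observations, control molecules, and IPD-residual
## samples with the statistical structure the downstream stages assume.

#' Build a per-adenine methylation rate map
#'
#' Emulates sequence-context variability of nonspecific adenine
#' methyltransferase efficiency along a template. Adenine positions are
#' drawn by independent inclusion at `adenine_fraction` (default 0.5: an
#' A-T pair has an adenine on exactly one strand, and both strands are
#' collapsed onto one coordinate track). Each adenine carries a probability
#' of an observed methylation call when accessible (`p_acc`, Beta-drawn,
#' default mean 0.40) and when inaccessible (`p_inacc`, default mean 0.02).
#'
#' @param template_length Template length in bp.
#' @param adenine_fraction Probability that a position carries an adenine.
#' @param acc_beta,inacc_beta Length-2 shape parameters of the Beta laws for
#'   `p_acc` and `p_inacc`.
#' @param seed Optional integer seed.
#' @param template_id Character identifier.
#' @return An object of class `rate_map` with fields `template_id`,
#'   `template_length`, `adenine_positions` (0-based, strictly increasing),
#'   `p_acc`, `p_inacc`.
#' @export
make_rate_map <- function(template_length, adenine_fraction = 0.5,
                          acc_beta = c(8, 12), inacc_beta = c(2, 98),
                          seed = NULL, template_id = "template") {
  stopifnot(adenine_fraction > 0, adenine_fraction <= 1,
            length(acc_beta) == 2L, length(inacc_beta) == 2L,
            all(acc_beta > 0), all(inacc_beta > 0))
  template_length <- as.integer(template_length)
  with_seed(seed, {
    keep <- runif(template_length) < adenine_fraction
    pos <- which(keep) - 1L
    n <- length(pos)
    if (n == 0L) stop("no adenine positions sampled; increase adenine_fraction")
    p_acc <- rbeta(n, acc_beta[1L], acc_beta[2L])
    p_inacc <- rbeta(n, inacc_beta[1L], inacc_beta[2L])
    ## clip to the invariant 0 < p_inacc < p_acc <= 1
    eps <- 1e-6
    p_acc <- pmin(pmax(p_acc, 2 * eps), 1)
    p_inacc <- pmin(pmax(p_inacc, eps), p_acc - eps)
    if (any(p_inacc >= p_acc) || any(p_inacc <= 0))
      stop("could not satisfy 0 < p_inacc < p_acc after clipping")
    structure(list(template_id = as.character(template_id),
                   template_length = template_length,
                   adenine_positions = pos, p_acc = p_acc, p_inacc = p_inacc),
              class = "rate_map")
  })
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map '%s'> %d bp, %d adenines; mean p_acc=%.3f, mean p_inacc=%.3f\n",
              x$template_id, x$template_length, length(x$adenine_positions),
              mean(x$p_acc), mean(x$p_inacc)))
  invisible(x)
}

#' Construct a methylation-call object
#'
#' Per-adenine binary methylation observations for one molecule.
#'
#' @param positions Strictly increasing 0-based adenine positions.
#' @param calls Binary vector (1 = called methylated), same length.
#' @param molecule_id,template_id Identifiers.
#' @param usable Logical usability mask per adenine (default all `TRUE`).
#' @return An object of class `methylation_calls`.
#' @export
methylation_calls <- function(positions, calls, molecule_id = "molecule",
                              template_id = "template", usable = NULL) {
  positions <- as.integer(positions)
  calls <- as.integer(calls)
  if (is.null(usable)) usable <- rep(TRUE, length(positions))
  stopifnot(length(calls) == length(positions),
            length(usable) == length(positions),
            all(calls %in% c(0L, 1L)),
            !is.unsorted(positions, strictly = TRUE))
  structure(list(molecule_id = as.character(molecule_id),
                 template_id = as.character(template_id),
                 positions = positions, calls = calls,
                 usable = as.logical(usable)),
            class = "methylation_calls")
}

#' Simulate methylation calls for one chromatinized molecule
#'
#' Forward model of the chain-HMM's generative assumptions: at each adenine
#' the call is Bernoulli(`p_inacc`) if the position lies inside a nucleosome
#' footprint and Bernoulli(`p_acc`) otherwise.
#'
#' @param fiber A `fiber_template` (the planted footprints).
#' @param rates A `rate_map` on the same template length.
#' @param seed Optional integer seed.
#' @param molecule_id Identifier for the simulated molecule.
#' @return A `methylation_calls` object (all adenines usable).
#' @export
simulate_molecule <- function(fiber, rates, seed = NULL,
                              molecule_id = "molecule") {
  validate_fiber_template(fiber)
  stopifnot(inherits(rates, "rate_map"))
  if (rates$template_length != fiber$template_length)
    stop("fiber and rate map template lengths differ")
  inside <- occupancy_track(fiber)[rates$adenine_positions + 1L] == 0
  p <- ifelse(inside, rates$p_inacc, rates$p_acc)
  calls <- with_seed(seed, rbinom(length(p), 1L, p))
  methylation_calls(rates$adenine_positions, calls, molecule_id,
                    rates$template_id)
}

#' Simulate control molecules
#'
#' Positive controls emulate fully methylated naked DNA (every adenine
#' methylated at its accessible-state rate); negative controls emulate
#' unmethylated molecules (every adenine at its inaccessible-state rate).
#'
#' @param rates A `rate_map`.
#' @param n_molecules Number of control molecules.
#' @param kind `"positive"` or `"negative"`.
#' @param seed Optional integer seed.
#' @return A list of `methylation_calls`.
#' @export
simulate_controls <- function(rates, n_molecules, kind = c("positive", "negative"),
                              seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(rates, "rate_map"), n_molecules >= 1)
  p <- if (kind == "positive") rates$p_acc else rates$p_inacc
  with_seed(seed, {
    lapply(seq_len(n_molecules), function(i)
      methylation_calls(rates$adenine_positions,
                        rbinom(length(p), 1L, p),
                        sprintf("%s_ctrl_%04d", kind, i), rates$template_id))
  })
}

#' Simulate log-IPD residuals from a two-component t mixture
#'
#' Fixture generator for the mixture-thresholding stage: a large positive
#' residual (slower polymerase kinetics than the sequence context predicts)
#' is evidence of methylation.
#'
#' @param n Number of residuals.
#' @param mixture A [t_mixture()].
#' @param seed Optional integer seed.
#' @return An object of class `residual_sample`: list with `values` and
#'   integer component `truth` labels (1 or 2).
#' @export
simulate_residuals <- function(n, mixture, seed = NULL) {
  stopifnot(n >= 1)
  validate_t_mixture(mixture)
  with_seed(seed, {
    comp <- 1L + (runif(n) >= mixture$weights[1L])
    values <- mixture$means[comp] +
      mixture$scales[comp] * rt(n, df = mixture$dfs[comp])
    structure(list(values = values, truth = comp), class = "residual_sample")
  })
}

#' Write methylation calls as TSV
#'
#' Columns: `molecule_id`, `position`, `call`, `usable`.
#'
#' @param calls A list of `methylation_calls` (or a single object).
#' @param path Output file path.
#' @export
write_calls_tsv <- function(calls, path) {
  if (inherits(calls, "methylation_calls")) calls <- list(calls)
  dat <- do.call(rbind, lapply(calls, function(m)
    data.frame(molecule_id = m$molecule_id, position = m$positions,
               call = m$calls, usable = as.integer(m$usable))))
  write.table(dat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read methylation calls from TSV written by [write_calls_tsv()]
#'
#' @param path Input file path.
#' @param template_id Template identifier to attach.
#' @return A list of `methylation_calls`, one per molecule.
#' @export
read_calls_tsv <- function(path, template_id = "template") {
  dat <- read.delim(path)
  lapply(split(dat, dat$molecule_id), function(d)
    methylation_calls(d$position, d$call, d$molecule_id[1L], template_id,
                      usable = d$usable == 1L))
}

#' Write a rate map as TSV (`position`, `p_acc`, `p_inacc`)
#' @param rates A `rate_map`.
#' @param path Output file path.
#' @export
write_rate_map_tsv <- function(rates, path) {
  write.table(data.frame(position = rates$adenine_positions,
                         p_acc = rates$p_acc, p_inacc = rates$p_inacc),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
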