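## shared fixtures built in code

## a regular array with fixed entry-to-entry repeat on a long template
regular_fiber <- function(nrl, n_nucs, template_length = NULL, offset = 0L) {
  entries <- offset + nrl * (seq_len(n_nucs) - 1L)
  if (is.null(template_length))
    template_length <- max(entries) + 147L + nrl
  fiber_template(entries, template_length)
}

## a small random HMM instance for oracle-equivalence checks
random_hmm_instance <- function(n_max = 12L) {
  n <- sample.int(n_max, 1L)
  pos <- sort(sample(0:299, n))
  p_acc <- runif(n, 0.2, 1)
  p_inacc <- runif(n, 1e-3, pmin(p_acc, 0.4))
  hmm <- access_hmm(pos, p_acc, p_inacc,
                    expected_run_length = sample(c(2, 50, 1000), 1L))
  list(hmm = hmm, calls = rbinom(n, 1L, 0.5))
}

## the reference two-component residual mixture used across tests
reference_mixture <- function() {
  t_mixture(weights = c(0.5, 0.5), means = c(0, 1.2),
            scales = c(0.3, 0.3), dfs = c(4, 4))
}

## two planted fiber populations (regular arrays of a fixed repeat, phase
## jitter +/- 10 nt), pushed through the full simulate -> decode pipeline so
## the clustered autocorrelograms carry realistic measurement noise
planted_population_tracks <- function(n_per_pop = 200L, seed = 9773L,
                                      template_length = 2712L) {
  set.seed(seed)
  mk_fib <- function(nrl, n, count, jitter = 10L) lapply(seq_len(count), function(i) {
    off <- (template_length - ((n - 1L) * nrl + 147L)) %/% 2L
    e <- off + nrl * (0:(n - 1L)) + sample(seq(-jitter, jitter), n, replace = TRUE)
    fiber_template(e, template_length)
  })
  fibers <- c(mk_fib(180L, 13L, n_per_pop), mk_fib(300L, 8L, n_per_pop))
  rm <- make_rate_map(template_length, 0.5, seed = seed + 1L)
  hmm <- build_hmm(rm)
  tracks <- lapply(seq_along(fibers), function(i)
    decode_molecule(hmm, simulate_molecule(fibers[[i]], rm, seed = seed + 10L + i),
                    template_length))
  list(tracks = tracks,
       truth = rep(c("nrl180", "nrl300"), each = n_per_pop))
}
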