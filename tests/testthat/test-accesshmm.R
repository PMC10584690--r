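test_that("emission and transition formulas are exact", {
  expect_equal(emissions_from_controls(0, 10), 0.5 / 10.5)
  expect_equal(emissions_from_controls(3, 7), 3.5 / 7.5)
  expect_equal(emissions_from_controls(10, 10), 1.0)
  expect_error(emissions_from_controls(-1, 10))
  expect_error(emissions_from_controls(11, 10), "exceeds")

  expect_equal(stay_probability(1, 1000), 0.999)
  expect_equal(stay_probability(2, 1000), 0.998001)
  expect_equal(stay_probability(1, 2), 0.5)
})

test_that("obvious evidence decodes to the matching constant state", {
  hmm <- access_hmm(seq(0, 90, 10), rep(0.9, 10), rep(0.05, 10))
  expect_true(all(viterbi_decode(hmm, rep(1L, 10))$states == 1L))
  expect_true(all(viterbi_decode(hmm, rep(0L, 10))$states == 0L))
})

test_that("Viterbi equals the exhaustive-enumeration oracle", {
  set.seed(101)
  for (i in 1:100) {
    inst <- random_hmm_instance(12L)
    v <- viterbi_decode(inst$hmm, inst$calls)
    b <- brute_force_decode(inst$hmm, inst$calls)
    expect_lt(abs(v$log_probability - b$log_probability), 1e-9)
  }
})

test_that("brute force oracle handles closed-form cases", {
  h1 <- access_hmm(0L, 0.9, 0.05)
  b1 <- brute_force_decode(h1, 1L)
  expect_identical(b1$states, 1L)
  expect_equal(b1$log_probability, log(0.5 * 0.9))

  ## zero-information emissions (p_acc = p_inacc): any path ties; the
  ## maximum is a constant path with all stay transitions
  pos <- c(0L, 3L, 7L)
  h2 <- access_hmm(pos, rep(0.3, 3), rep(0.3, 3), expected_run_length = 50)
  calls <- c(1L, 0L, 1L)
  b2 <- brute_force_decode(h2, calls)
  expected <- log(0.5) + log(0.3) + log(0.7) + log(0.3) +
    sum(log((1 - 1 / 50)^diff(pos)))
  expect_equal(b2$log_probability, expected)
  ## Viterbi ties agree on probability
  expect_equal(viterbi_decode(h2, calls)$log_probability, expected)

  expect_error(brute_force_decode(
    access_hmm(0:20, rep(.9, 21), rep(.1, 21)), rep(1L, 21)), "at most")
})

test_that("larger expected run length never increases decoded switching", {
  set.seed(7)
  for (i in 1:20) {
    n <- 60L
    pos <- sort(sample(0:999, n))
    p_acc <- runif(n, 0.3, 0.9)
    p_inacc <- runif(n, 0.01, 0.1)
    calls <- rbinom(n, 1L, 0.4)
    switches <- vapply(c(10, 100, 1000, 10000), function(L) {
      s <- viterbi_decode(access_hmm(pos, p_acc, p_inacc,
                                     expected_run_length = L), calls)$states
      sum(diff(s) != 0L)
    }, 0)
    expect_true(all(diff(switches) <= 0))
  }
})

test_that("interpolation follows the stated linear rule", {
  path <- structure(list(states = c(1L, 0L), log_probability = 0),
                    class = "state_path")
  tr <- interpolate_track(path, c(10L, 20L), 30L)
  expect_identical(tr[1:11], rep(1, 11))       # positions 0..10
  expect_equal(tr[16], 0.5)                    # position 15
  expect_identical(tr[21:30], rep(0, 10))      # positions 20..29
  expect_true(all(tr >= 0 & tr <= 1))

  ## single decoded adenine: constant track
  single <- structure(list(states = 1L, log_probability = 0),
                      class = "state_path")
  expect_identical(interpolate_track(single, 5L, 20L), rep(1, 20))

  ## nearest-neighbor option is a step function
  trn <- interpolate_track(path, c(10L, 20L), 30L, method = "nearest")
  expect_true(all(trn %in% c(0, 1)))

  empty <- structure(list(states = integer(0), log_probability = 0),
                     class = "state_path")
  expect_error(interpolate_track(empty, integer(0), 30L), "empty")
})

test_that("build_hmm_from_controls smooths observed control fractions", {
  rm <- make_rate_map(300, 0.5, seed = 5)
  pos <- simulate_controls(rm, 30, "positive", seed = 1)
  neg <- simulate_controls(rm, 30, "negative", seed = 2)
  hmm <- build_hmm_from_controls(pos, neg)
  expect_true(all(hmm$positions %in% rm$adenine_positions))
  expect_true(all(hmm$p_meth_acc > 0 & hmm$p_meth_acc <= 1))
  expect_true(all(hmm$p_meth_inacc <= hmm$p_meth_acc))
  ## emissions equal the smoothed observed fractions (k + 0.5)/(n + 0.5)
  kpos <- rowSums(vapply(pos, `[[`, pos[[1]]$calls, "calls"))
  idx <- match(hmm$positions, rm$adenine_positions)
  expect_equal(hmm$p_meth_acc, (kpos[idx] + 0.5) / 30.5)
})

test_that("noiseless molecules decode to the planted footprints exactly", {
  ## near-noiseless limit: p_acc ~ 1, p_inacc ~ 1e-6
  rm <- make_rate_map(2712, 0.5, acc_beta = c(1e6, 1e-6),
                      inacc_beta = c(1e-6, 1e6), seed = 8)
  hmm <- build_hmm(rm)
  for (seed in 1:5) {
    fib <- place_nucleosomes(2712, 8, 10, seed = seed)
    mol <- simulate_molecule(fib, rm, seed = seed + 100)
    track <- decode_molecule(hmm, mol, 2712)
    fp <- call_inaccessible_regions(track)
    expect_identical(nrow(fp), 8L)
    ## every planted boundary recovered within one inter-adenine gap: the
    ## tolerance is the gap between the adenines bracketing the edge
    pos <- rm$adenine_positions
    local_gap <- function(edge) {
      i <- findInterval(edge - 0.5, pos)
      if (i >= 1L && i < length(pos)) pos[i + 1L] - pos[i] else 2L
    }
    for (j in seq_along(fib$entries)) {
      b_start <- fib$entries[j]
      b_end <- fib$entries[j] + 147L
      expect_lte(abs(fp$start[j] - b_start), local_gap(b_start))
      expect_lte(abs(fp$end[j] - b_end), local_gap(b_end))
    }
  }
})

test_that("decoding on noisy synthetic molecules is highly accurate", {
  rm <- make_rate_map(2712, 0.5, seed = 13)   # p_acc ~ .4, p_inacc ~ .02
  hmm <- build_hmm(rm)
  acc <- counts_ok <- numeric(0)
  ens <- simulate_fiber_ensemble(1L, rep(5:12, length.out = 30L), seed = 77)
  for (seed in 1:30) {
    fib <- ens$fibers[[seed]]
    mol <- simulate_molecule(fib, rm, seed = seed + 500)
    track <- decode_molecule(hmm, mol, 2712)
    truth <- occupancy_track(fib)
    acc <- c(acc, mean((track > 0.5) == (truth > 0.5)))
    fp <- count_nucleosomes(call_inaccessible_regions(track))
    counts_ok <- c(counts_ok, sum(fp$nuc_count) == length(fib$entries))
  }
  expect_gte(mean(acc), 0.95)
  expect_gte(mean(counts_ok), 0.9)
})
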