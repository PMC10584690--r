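test_that("place_nucleosomes respects counts, linkers and the packing limit", {
  expect_length(place_nucleosomes(500, 0, 10, seed = 1)$entries, 0L)
  expect_error(place_nucleosomes(300, 3, 10, 1e4, seed = 1), "packing")

  fib <- place_nucleosomes(2712, 13, 10, 1e5, seed = 1)
  expect_length(fib$entries, 13L)
  expect_true(all(diff(fib$entries) - 147 >= 10))
  expect_lte(max(fib$entries), 2712 - 147)
  expect_no_error(validate_fiber_template(fib, min_linker = 10))

  ## seeded determinism
  expect_identical(place_nucleosomes(2712, 8, 10, seed = 7)$entries,
                   place_nucleosomes(2712, 8, 10, seed = 7)$entries)
})

test_that("fiber_template rejects invalid configurations", {
  expect_error(fiber_template(c(0, 100), 600), "overlap")
  expect_error(fiber_template(c(100, 100), 600), "increasing")
  expect_error(fiber_template(500, 600), "within")
  expect_error(fiber_template(-1, 600), "within")
})

test_that("clamp remodeling follows the visibility/ruler rule", {
  cfg <- remodel_config("clamp", ruler = 20, ruler_sd = 0, visibility = 183)
  ## visible pair: linker 153 <= 183, slid to exit + 20
  expect_identical(
    remodel_clamp(fiber_template(c(0, 300), 600), cfg)$entries,
    c(0L, 167L))
  ## invisible pair: linker 253 > 183, untouched
  expect_identical(
    remodel_clamp(fiber_template(c(0, 400), 600), cfg)$entries,
    c(0L, 400L))
  ## sequential pass uses updated exits
  expect_identical(
    remodel_clamp(fiber_template(c(0, 180, 360), 600), cfg)$entries,
    c(0L, 167L, 334L))
})

test_that("clamp with zero jitter sets every visited visible linker to the ruler", {
  cfg <- remodel_config("clamp", ruler = 20, ruler_sd = 0, visibility = 183)
  for (seed in 1:5) {
    fib <- place_nucleosomes(2712, 10, 10, seed = seed)
    before <- fib$entries
    out <- remodel_clamp(fib, cfg)
    expect_length(out$entries, length(before))
    linkers <- diff(out$entries) - 147
    ## every final linker is either exactly the ruler (pair was visible when
    ## visited) or an untouched linker (> visibility at visit time)
    expect_true(all(linkers == 20 | linkers > 183))
  }
})

test_that("length-sensing moves only when a flank allows it and never overlaps", {
  ## single nucleosome, only the 5' flank sufficient: moves 10 nt 5'-ward
  cfg <- remodel_config("length_sensing", flank_cutoff = 48, step = 10,
                        n_sweeps = 1)
  fib <- fiber_template(100, 267)   # flanks 100 and 20
  expect_identical(remodel_length_sensing(fib, cfg, seed = 1)$entries, 90L)
  ## neither flank sufficient: no move
  fib2 <- fiber_template(30, 197)   # flanks 30 and 20
  expect_identical(remodel_length_sensing(fib2, cfg, seed = 1)$entries, 30L)

  ## dense fiber, many sweeps: count preserved, never any overlap
  cfg2 <- remodel_config("length_sensing", flank_cutoff = 48, step = 1,
                         n_sweeps = 500)
  for (seed in 1:3) {
    fib <- simulate_fiber_ensemble(1L, 12L, seed = seed)$fibers[[1L]]
    out <- remodel_length_sensing(fib, cfg2, seed = seed)
    expect_length(out$entries, 12L)
    expect_true(all(diff(out$entries) >= 147))
    expect_no_error(validate_fiber_template(out))
  }
  ## determinism
  fib <- place_nucleosomes(2712, 8, 10, seed = 4)
  expect_identical(remodel_length_sensing(fib, cfg2, seed = 9)$entries,
                   remodel_length_sensing(fib, cfg2, seed = 9)$entries)
})

test_that("an unconstrained nucleosome random-walks symmetrically between gates", {
  ## flanks 100 and 147 with cutoff 48: the entry can wander over the region
  ## where at least one flank is >= 48; the long-run mean sits near the
  ## midpoint of the feasible region by symmetry
  cfg <- remodel_config("length_sensing", flank_cutoff = 48, step = 1,
                        n_sweeps = 2000)
  finals <- vapply(1:60, function(s)
    remodel_length_sensing(fiber_template(100, 394), cfg, seed = s)$entries,
    integer(1))
  feasible_mid <- (0 + (394 - 147)) / 2
  expect_lt(abs(mean(finals) - feasible_mid), 25)
  expect_gt(sd(finals), 0)
})

test_that("occupancy_track encodes footprints as 0 and linkers as 1", {
  tr <- occupancy_track(fiber_template(10, 300))
  expect_identical(which(tr == 0), 11:157)    # 0-based [10, 157)
  expect_identical(occupancy_track(fiber_template(integer(0), 50)), rep(1, 50))
  fib <- place_nucleosomes(2712, 9, 10, seed = 2)
  expect_identical(sum(occupancy_track(fib) == 0), 9L * 147L)
})

test_that("fiber BED round-trips through text", {
  fibers <- lapply(1:3, function(s) place_nucleosomes(1000, 4, 10, seed = s,
                                                      template_id = "S1"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_fiber_bed(fibers, path)
  back <- read_fiber_bed(path)
  expect_length(back, 3L)
  expect_setequal(unname(vapply(back, function(f) f$entries[1L], integer(1))),
                  vapply(fibers, function(f) f$entries[1L], integer(1)))
  expect_identical(back[[1L]]$template_length, 1000L)
})
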