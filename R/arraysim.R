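## Nucleosome array simulation and in-silico remodeling.
## Coordinates are 0-based, half-open throughout: a nucleosome with entry e
## occupies [e, e + nucleosome_length).

#' Construct a fiber template
#'
#' A fiber template is a fixed-length DNA molecule carrying a set of
#' non-overlapping 147-bp nucleosome footprints, identified by their entry
#' (start) positions.
#'
#' @param entries Integer vector of 0-based nucleosome entry positions,
#'   strictly increasing.
#' @param template_length Template length in bp.
#' @param template_id Character identifier for the template sequence.
#' @param nucleosome_length Footprint length in bp (147 for a canonical
#'   nucleosome core).
#' @return An object of class `fiber_template`.
#' @export
fiber_template <- function(entries, template_length, template_id = "template",
                           nucleosome_length = 147L) {
  obj <- structure(
    list(template_id = as.character(template_id),
         template_length = as.integer(template_length),
         nucleosome_length = as.integer(nucleosome_length),
         entries = as.integer(entries)),
    class = "fiber_template")
  validate_fiber_template(obj)
  obj
}

#' Validate a fiber template
#'
#' Checks that entries are strictly increasing, lie within the template and
#' define pairwise-disjoint footprints. Optionally enforces a minimum
#' internal linker length (used immediately after initial placement; the
#' minimum-linker rule is an initialization constraint, not preserved by
#' remodeling).
#'
#' @param fiber A `fiber_template`.
#' @param min_linker If non-`NULL`, additionally require every internal
#'   linker (next entry minus previous exit) to be at least this many bp.
#' @return The fiber, invisibly; errors on violation.
#' @export
validate_fiber_template <- function(fiber, min_linker = NULL) {
  stopifnot(inherits(fiber, "fiber_template"))
  e <- fiber$entries
  w <- fiber$nucleosome_length
  L <- fiber$template_length
  if (L < 1L || w < 1L) stop("template_length and nucleosome_length must be positive")
  if (length(e)) {
    if (anyNA(e)) stop("NA nucleosome entries")
    if (is.unsorted(e, strictly = TRUE)) stop("entries must be strictly increasing")
    if (e[1L] < 0L || e[length(e)] > L - w)
      stop("nucleosome footprints must lie within [0, template_length)")
    if (length(e) > 1L) {
      linkers <- e[-1L] - (e[-length(e)] + w)
      if (any(linkers < 0L)) stop("overlapping nucleosome footprints")
      if (!is.null(min_linker) && any(linkers < min_linker))
        stop("internal linker shorter than min_linker")
    }
  }
  invisible(fiber)
}

#' @export
print.fiber_template <- function(x, ...) {
  cat(sprintf("<fiber_template '%s'> %d bp, %d nucleosome(s) of %d bp\n",
              x$template_id, x$template_length, length(x$entries),
              x$nucleosome_length))
  if (length(x$entries))
    cat("entries:", paste(utils::head(x$entries, 20L), collapse = " "),
        if (length(x$entries) > 20L) "..." else "", "\n")
  invisible(x)
}

#' Randomly place nucleosomes on a template
#'
#' Random sequential adsorption: candidate entry positions are drawn
#' uniformly and accepted only if the new footprint overlaps no previously
#' placed footprint and keeps every internal linker at least `min_linker`
#' bp. Because nucleosomes are never removed, packing is subject to the
#' Renyi (random sequential adsorption) limit: near-saturating densities can
#' jam, in which case the function fails after `max_attempts` consecutive
#' rejections.
#'
#' @param template_length Template length in bp.
#' @param n_nucleosomes Number of nucleosomes to place.
#' @param min_linker Minimum internal linker at placement time (bp).
#' @param max_attempts Maximum consecutive rejected candidates before a
#'   packing error is raised.
#' @param seed Optional integer seed for reproducibility.
#' @param template_id,nucleosome_length Passed to [fiber_template()].
#' @return A `fiber_template` with exactly `n_nucleosomes` entries.
#' @export
place_nucleosomes <- function(template_length, n_nucleosomes, min_linker = 10L,
                              max_attempts = 1e5, seed = NULL,
                              template_id = "template",
                              nucleosome_length = 147L) {
  template_length <- as.integer(template_length)
  n_nucleosomes <- as.integer(n_nucleosomes)
  stopifnot(n_nucleosomes >= 0L, min_linker >= 0L, max_attempts >= 1)
  if (template_length < n_nucleosomes * nucleosome_length)
    stop("packing error: template too short for requested nucleosome count")
  with_seed(seed, {
    entries <- integer(0)
    n_slots <- template_length - nucleosome_length + 1L
    while (length(entries) < n_nucleosomes) {
      ## draw candidates in blocks; acceptance needs min_linker clearance
      ## from every placed footprint (template ends are unconstrained)
      placed <- FALSE
      attempts <- 0
      while (!placed) {
        cand <- sample.int(n_slots, 1L) - 1L
        ok <- !length(entries) ||
          all(cand >= entries + nucleosome_length + min_linker |
              entries >= cand + nucleosome_length + min_linker)
        if (ok) {
          entries <- sort(c(entries, cand))
          placed <- TRUE
        } else {
          attempts <- attempts + 1
          if (attempts >= max_attempts)
            stop(sprintf(
              "packing error: %d consecutive rejections placing nucleosome %d of %d (Renyi packing limit)",
              as.integer(attempts), length(entries) + 1L, n_nucleosomes))
        }
      }
    }
    fiber_template(entries, template_length, template_id, nucleosome_length)
  })
}

#' Remodeling configuration
#'
#' Parameters for the two in-silico remodeling processes. `clamp` mode
#' slides any "visible" 3' nucleosome against its 5' neighbor to a fixed
#' ruler distance; `length_sensing` mode iteratively translocates
#' nucleosomes toward whichever flank offers at least `flank_cutoff` nt of
#' extranucleosomal DNA.
#'
#' @param mode `"clamp"` or `"length_sensing"`.
#' @param ruler Clamp target linker length in nt (values of biological
#'   interest: 20 and 48).
#' @param ruler_sd Standard deviation of normal jitter on the ruler draw
#'   (nt); draws are truncated at 0. Default 0 (deterministic ruler).
#' @param visibility Maximum linker length (nt) at which a 3' nucleosome is
#'   "visible" to the clamp; default 183.
#' @param flank_cutoff Minimum flanking DNA (nt) required for the
#'   length-sensing remodeler to slide toward that flank (values of
#'   biological interest: 20 and 48).
#' @param step Translocation step per visit (nt).
#' @param n_sweeps Number of 5'-to-3' sweeps for length-sensing remodeling.
#' @param until_blocked If `TRUE`, each length-sensing visit slides the
#'   nucleosome in its chosen direction until that flank drops below
#'   `flank_cutoff`; if `FALSE` (default), one step per visit.
#' @return An object of class `remodel_config`.
#' @export
remodel_config <- function(mode = c("clamp", "length_sensing"), ruler = 20L,
                           ruler_sd = 0, visibility = 183L, flank_cutoff = 48L,
                           step = 1L, n_sweeps = 500L, until_blocked = FALSE) {
  mode <- match.arg(mode)
  stopifnot(ruler >= 0, ruler_sd >= 0, visibility > 0, step >= 1,
            flank_cutoff >= step, n_sweeps >= 1)
  structure(list(mode = mode, ruler = as.integer(ruler),
                 ruler_sd = as.numeric(ruler_sd),
                 visibility = as.integer(visibility),
                 flank_cutoff = as.integer(flank_cutoff),
                 step = as.integer(step), n_sweeps = as.integer(n_sweeps),
                 until_blocked = isTRUE(until_blocked)),
            class = "remodel_config")
}

#' Clamp ("ruler") remodeling
#'
#' A single 5'-to-3' pass over adjacent nucleosome pairs. For pair
#' (i, i+1), if the current linker (entry of i+1 minus exit of i) is at most
#' `visibility`, the 3' nucleosome is slid against the 5' nucleosome (the
#' "barrier") to a linker of `d ~ Normal(ruler, ruler_sd)` truncated at 0
#' and rounded to the nearest nt. Exits are updated as the pass proceeds, so
#' a clamped nucleosome can make its 3' neighbor visible in turn. Nucleosome
#' count is always preserved; slid nucleosomes are kept within the template
#' and never pushed into their 3' neighbor.
#'
#' @param fiber A valid `fiber_template`.
#' @param config A `remodel_config` with `mode = "clamp"`.
#' @param seed Optional integer seed (only consumed when `ruler_sd > 0`).
#' @return The remodeled `fiber_template`.
#' @export
remodel_clamp <- function(fiber, config = remodel_config("clamp"), seed = NULL) {
  validate_fiber_template(fiber)
  stopifnot(inherits(config, "remodel_config"), config$mode == "clamp")
  e <- fiber$entries
  w <- fiber$nucleosome_length
  L <- fiber$template_length
  n <- length(e)
  if (n < 2L) return(fiber)
  with_seed(seed, {
    for (i in seq_len(n - 1L)) {
      exit_i <- e[i] + w
      linker <- e[i + 1L] - exit_i
      if (linker <= config$visibility) {
        d <- if (config$ruler_sd > 0)
          max(0, round(rnorm(1L, config$ruler, config$ruler_sd)))
        else config$ruler
        new_entry <- exit_i + as.integer(d)
        upper <- if (i + 2L <= n) min(L - w, e[i + 2L] - w) else L - w
        e[i + 1L] <- min(new_entry, upper)
      }
    }
  })
  fiber_template(e, L, fiber$template_id, w)
}

#' Length-sensing remodeling
#'
#' Runs `n_sweeps` sweeps; within each sweep nucleosomes are visited 5' to
#' 3'. For each nucleosome the 5' flank (distance to the 5' neighbor's exit,
#' or to the template start) and the 3' flank (distance to the 3' neighbor's
#' entry, or to the template end) are computed from current positions. If
#' both flanks are at least `flank_cutoff` the sliding direction is a fair
#' coin flip; if exactly one is, the nucleosome slides that way; otherwise
#' it does not move. A move shifts the entry by `step` nt (or repeatedly
#' until the chosen flank is exhausted when `until_blocked = TRUE`).
#' Ordering and nucleosome count are preserved and no overlaps are ever
#' created (`flank_cutoff >= step` guarantees this).
#'
#' @inheritParams remodel_clamp
#' @param config A `remodel_config` with `mode = "length_sensing"`.
#' @return The remodeled `fiber_template`.
#' @export
remodel_length_sensing <- function(fiber,
                                   config = remodel_config("length_sensing"),
                                   seed = NULL) {
  validate_fiber_template(fiber)
  stopifnot(inherits(config, "remodel_config"),
            config$mode == "length_sensing")
  if (!length(fiber$entries)) return(fiber)
  e <- with_seed(seed,
    ls_sweeps_cpp(fiber$entries, fiber$template_length,
                  fiber$nucleosome_length, config$flank_cutoff, config$step,
                  config$n_sweeps, config$until_blocked))
  fiber_template(e, fiber$template_length, fiber$template_id,
                 fiber$nucleosome_length)
}

#' Remodel a fiber according to a configuration
#'
#' Dispatches to [remodel_clamp()] or [remodel_length_sensing()] based on
#' `config$mode`.
#'
#' @inheritParams remodel_clamp
#' @export
remodel <- function(fiber, config, seed = NULL) {
  switch(config$mode,
         clamp = remodel_clamp(fiber, config, seed),
         length_sensing = remodel_length_sensing(fiber, config, seed))
}

#' Per-base occupancy/accessibility track of a fiber
#'
#' Returns a numeric vector of length `template_length` with 0 inside
#' nucleosome footprints (inaccessible) and 1 elsewhere (accessible),
#' following the convention that accessible bases are 1.
#'
#' @param fiber A valid `fiber_template`.
#' @return Numeric vector in \{0, 1\} of length `template_length`.
#' @export
occupancy_track <- function(fiber) {
  validate_fiber_template(fiber)
  track <- rep(1, fiber$template_length)
  for (e in fiber$entries)
    track[(e + 1L):(e + fiber$nucleosome_length)] <- 0
  track
}

#' Simulate an ensemble of random fibers
#'
#' Draws `n_fibers` independent fibers at each requested nucleosome count.
#' A draw that jams against the packing limit (see [place_nucleosomes()]) is
#' discarded and redrawn from a fresh substream, up to `max_retries` times
#' per fiber, so near-saturating densities can still be sampled.
#'
#' @param n_fibers Fibers per density.
#' @param n_nucleosomes Integer vector of per-fiber nucleosome counts
#'   (densities) to simulate.
#' @param template_length Template length in bp (default the 2,712-bp S1
#'   template).
#' @param min_linker,max_attempts,nucleosome_length Passed to
#'   [place_nucleosomes()].
#' @param max_retries Redraws allowed per jammed fiber.
#' @param seed Optional master seed; per-fiber seeds are derived from it.
#' @return A list with `fibers` (list of `fiber_template`) and `density`
#'   (integer vector of planted nucleosome counts, parallel to `fibers`).
#' @export
simulate_fiber_ensemble <- function(n_fibers, n_nucleosomes,
                                    template_length = 2712L, min_linker = 10L,
                                    max_attempts = 1e5, max_retries = 20L,
                                    nucleosome_length = 147L, seed = NULL) {
  total <- n_fibers * length(n_nucleosomes)
  seeds <- stage_seeds(seed, total * (max_retries + 1L))
  density <- rep(as.integer(n_nucleosomes), each = n_fibers)
  fibers <- vector("list", total)
  si <- 1L
  for (i in seq_len(total)) {
    fib <- NULL
    for (r in seq_len(max_retries + 1L)) {
      fib <- tryCatch(
        place_nucleosomes(template_length, density[i], min_linker,
                          max_attempts, seed = seeds[si],
                          template_id = sprintf("fiber_%04d", i),
                          nucleosome_length = nucleosome_length),
        error = function(e) NULL)
      si <- si + 1L
      if (!is.null(fib)) break
    }
    if (is.null(fib))
      stop(sprintf("fiber %d: packing failed after %d redraws", i, max_retries))
    fibers[[i]] <- fib
  }
  list(fibers = fibers, density = density)
}

#' Write fibers as BED3+ text
#'
#' One row per footprint: `molecule_id`, `start`, `end` (0-based,
#' half-open), preceded by a header line recording the template id, length
#' and nucleosome length.
#'
#' @param fibers List of `fiber_template` objects sharing one template.
#' @param path Output file path.
#' @export
write_fiber_bed <- function(fibers, path) {
  stopifnot(length(fibers) >= 1L)
  tl <- fibers[[1L]]$template_length
  nl <- fibers[[1L]]$nucleosome_length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#template_id=%s\ttemplate_length=%d\tnucleosome_length=%d",
                     fibers[[1L]]$template_id, tl, nl), con)
  for (i in seq_along(fibers)) {
    f <- fibers[[i]]
    if (!length(f$entries)) next
    write.table(data.frame(molecule_id = sprintf("mol_%05d", i),
                           start = f$entries,
                           end = f$entries + f$nucleosome_length),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read fibers from BED3+ text written by [write_fiber_bed()]
#'
#' @param path Input file path.
#' @return A list of `fiber_template` objects.
#' @export
read_fiber_bed <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#"))
    stop("missing #template header line")
  kv <- strsplit(strsplit(sub("^#", "", header), "\t")[[1L]], "=")
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  tl <- as.integer(meta[["template_length"]])
  nl <- as.integer(meta[["nucleosome_length"]])
  dat <- read.delim(path, header = FALSE, comment.char = "#",
                    col.names = c("molecule_id", "start", "end"))
  lapply(split(dat$start, dat$molecule_id),
         fiber_template, template_length = tl,
         template_id = meta[["template_id"]], nucleosome_length = nl)
}
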