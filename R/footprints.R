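## From per-base accessibility tracks to inaccessible regions, per-region
## nucleosome counts, per-fiber density and horizon-plot histograms.

#' Call inaccessible regions from an accessibility track
#'
#' Maximal runs of consecutive bases with accessibility at or below the
#' threshold (inclusive, `<= 0.5` by default) are returned as 0-based
#' half-open intervals.
#'
#' @param track Per-base accessibility values in `[0, 1]`.
#' @param threshold Inclusive accessibility threshold (default 0.5).
#' @param molecule_id Identifier attached to the regions.
#' @return A `data.frame` (class `footprint_set`) with columns
#'   `molecule_id`, `start`, `end`, `length`, `midpoint`.
#' @export
call_inaccessible_regions <- function(track, threshold = 0.5,
                                      molecule_id = "molecule") {
  stopifnot(is.numeric(track), length(track) >= 1L)
  r <- rle(track <= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  out <- data.frame(molecule_id = rep(molecule_id, sum(keep)),
                    start = starts[keep], end = ends[keep])
  out$length <- out$end - out$start
  out$midpoint <- (out$start + out$end) / 2
  class(out) <- c("footprint_set", "data.frame")
  out
}

#' Nucleosome-count cutoff ladder
#'
#' Maps inaccessible-region lengths to nucleosome counts. Regions shorter
#' than `sub_max` are subnucleosomal (count 0; short footprints are
#' suggestive of nonspecific histone-DNA contacts rather than full
#' nucleosomes); region lengths are then classified as 1, 2, 3, ...
#' nucleosomes by the increasing `boundaries`, and lengths beyond the last
#' boundary add one nucleosome per `increment` bp. The defaults
#' (100 / 280 / 450 / 620 bp, then +170 bp) are a documented heuristic built
#' from the 147-bp core and typical mono-footprint lengths (~120-160 nt);
#' for real data the ladder should be calibrated on the region-length
#' histogram (see [suggest_nuc_cutoffs()]).
#'
#' @param sub_max Lengths strictly below this count 0 nucleosomes.
#' @param boundaries Strictly increasing upper bounds (exclusive) for 1, 2,
#'   3, ... nucleosomes.
#' @param increment Extra bp per additional nucleosome beyond the last
#'   boundary.
#' @return An object of class `nuc_count_cutoffs`.
#' @export
nuc_count_cutoffs <- function(sub_max = 100, boundaries = c(280, 450, 620),
                              increment = 170) {
  stopifnot(sub_max > 0, length(boundaries) >= 1L,
            !is.unsorted(boundaries, strictly = TRUE),
            sub_max < boundaries[1L], increment > 0)
  structure(list(sub_max = sub_max, boundaries = boundaries,
                 increment = increment),
            class = "nuc_count_cutoffs")
}

#' Count nucleosomes per inaccessible region
#'
#' Applies a [nuc_count_cutoffs()] ladder to each region's length and adds
#' a `nuc_count` column.
#'
#' @param fp A `footprint_set`.
#' @param cutoffs A `nuc_count_cutoffs` ladder.
#' @return The `footprint_set` with a `nuc_count` column.
#' @export
count_nucleosomes <- function(fp, cutoffs = nuc_count_cutoffs()) {
  stopifnot(inherits(fp, "footprint_set"), inherits(cutoffs, "nuc_count_cutoffs"))
  len <- fp$length
  nb <- length(cutoffs$boundaries)
  count <- findInterval(len, c(cutoffs$sub_max, cutoffs$boundaries))
  over <- len >= cutoffs$boundaries[nb]
  count[over] <- nb + 1L +
    (len[over] - cutoffs$boundaries[nb]) %/% cutoffs$increment
  fp$nuc_count <- as.integer(count)
  fp
}

#' Per-fiber nucleosome density
#'
#' Total nucleosome count per template, scaled to nucleosomes per kbp.
#'
#' @param fp A `footprint_set` with a `nuc_count` column (see
#'   [count_nucleosomes()]), or a bare total count.
#' @param template_length Template length in bp.
#' @return Nucleosomes per kbp.
#' @export
fiber_density <- function(fp, template_length) {
  stopifnot(template_length > 0)
  total <- if (is.data.frame(fp)) {
    if (is.null(fp$nuc_count)) stop("run count_nucleosomes() first")
    sum(fp$nuc_count)
  } else as.numeric(fp)
  total * 1000 / template_length
}

#' Horizon-plot histogram of footprints
#'
#' 2-D histogram of (region midpoint, region length) pooled over molecules,
#' the "horizon plot" view of footprint architecture along a template.
#'
#' @param fps A `footprint_set` or list of them.
#' @param template_length Template length in bp.
#' @param length_bins,position_bins Bin edges (numeric vectors) or a single
#'   bin width in bp (default 10-bp bins).
#' @return An integer matrix of counts (rows = midpoint bins, columns =
#'   length bins) whose total equals the number of regions.
#' @export
horizon_histogram <- function(fps, template_length, length_bins = 10,
                              position_bins = 10) {
  if (is.data.frame(fps)) fps <- list(fps)
  stopifnot(length(fps) >= 1L)
  regions <- do.call(rbind, lapply(fps, function(f)
    f[, c("midpoint", "length")]))
  if (length(position_bins) == 1L)
    position_bins <- seq(0, template_length + position_bins, by = position_bins)
  max_len <- max(regions$length, 1)
  if (length(length_bins) == 1L)
    length_bins <- seq(0, max_len + length_bins, by = length_bins)
  mid_bin <- cut(regions$midpoint, position_bins, right = FALSE,
                 include.lowest = TRUE)
  len_bin <- cut(regions$length, length_bins, right = FALSE,
                 include.lowest = TRUE)
  table(midpoint = mid_bin, length = len_bin)
}

#' Suggest nucleosome-count cutoffs from a region-length histogram
#'
#' Locates valleys (local minima of a kernel density estimate) between the
#' periodic peaks of the inaccessible-region length distribution, as
#' candidate boundaries for [nuc_count_cutoffs()].
#'
#' @param lengths Inaccessible-region lengths in bp.
#' @param bw Kernel bandwidth in bp.
#' @param max_cutoffs Maximum number of valley positions to return.
#' @return Numeric vector of suggested boundaries (bp), possibly empty.
#' @export
suggest_nuc_cutoffs <- function(lengths, bw = 20, max_cutoffs = 6L) {
  stopifnot(length(lengths) >= 10L)
  d <- density(lengths, bw = bw, from = 0, to = max(lengths))
  y <- d$y
  n <- length(y)
  mid <- y[2:(n - 1L)]
  valley <- which(mid < y[1:(n - 2L)] & mid < y[3:n]) + 1L
  head(d$x[valley], max_cutoffs)
}
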