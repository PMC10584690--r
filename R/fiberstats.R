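## Single-molecule autocorrelograms, peak (internucleosomal spacing / NRL)
## estimation, per-density averaging, Leiden clustering and UMAP embedding.

#' Autocorrelogram of an accessibility track
#'
#' Normalized autocorrelation
#' `r(k) = sum((x_t - xbar)(x_(t+k) - xbar)) / sum((x_t - xbar)^2)` for
#' `k = 0..max_lag`. The peak of an autocorrelogram in a suitable lag window
#' estimates the average internucleosomal distance of the fiber; averaged or
#' clustered autocorrelograms estimate the nucleosome repeat length (NRL).
#'
#' @param track Per-base accessibility values; must be non-constant and
#'   longer than `max_lag`.
#' @param max_lag Maximum lag in bp (default 1000).
#' @return Numeric vector of length `max_lag + 1`; element `k + 1` is
#'   `r(k)`, with `r(0) = 1`.
#' @export
autocorrelogram <- function(track, max_lag = 1000L) {
  stopifnot(is.numeric(track))
  if (length(track) <= max_lag)
    stop("track must be longer than max_lag")
  if (var(track) == 0)
    stop("constant track: autocorrelation normalization undefined")
  as.numeric(acf(track, lag.max = max_lag, plot = FALSE, demean = TRUE,
                 type = "correlation")$acf)
}

#' Autocorrelogram matrix for a set of tracks
#'
#' @param tracks List of per-base accessibility tracks.
#' @param max_lag Maximum lag in bp.
#' @return Numeric matrix, one row per molecule, `max_lag + 1` columns.
#' @export
autocorrelogram_matrix <- function(tracks, max_lag = 1000L) {
  t(vapply(tracks, autocorrelogram, numeric(max_lag + 1L),
           max_lag = max_lag))
}

#' Primary peak of an autocorrelogram
#'
#' Argmax of `r(k)` within the search window, required to be a local
#' maximum (strictly above at least one neighbor and not below either);
#' plateau ties return the smaller lag. Returns `NA` when no local maximum
#' exists in the window (e.g. a monotonically decaying autocorrelogram).
#'
#' @param ac Autocorrelogram vector from [autocorrelogram()].
#' @param window Length-2 `(min_lag, max_lag)` search window in bp; the
#'   default 100-500 covers typical in vivo NRLs.
#' @return Peak lag in bp, or `NA_integer_`.
#' @export
find_peak <- function(ac, window = c(100L, 500L)) {
  max_lag <- length(ac) - 1L
  stopifnot(length(window) == 2L, window[1L] >= 1L, window[1L] < window[2L])
  if (window[2L] > max_lag)
    stop("window exceeds computed lags")
  lags <- window[1L]:window[2L]
  v <- ac[lags + 1L]
  left <- ac[lags]                                   # r(k-1)
  right <- ac[pmin(lags + 2L, max_lag + 1L)]         # r(k+1)
  right[lags == max_lag] <- Inf                      # edge lag can't be a peak
  is_locmax <- v >= left & v >= right & (v > left | v > right)
  if (!any(is_locmax)) return(NA_integer_)
  cand <- lags[is_locmax]
  cand[which.max(ac[cand + 1L])]
}

#' Per-density averaged autocorrelogram profiles
#'
#' Groups molecules by their per-fiber nucleosome count ("density"),
#' averages autocorrelograms pointwise within each group, and locates the
#' primary peak of each average.
#'
#' @param tracks List of per-base accessibility tracks, or a precomputed
#'   autocorrelogram matrix.
#' @param densities Integer per-molecule nucleosome counts, parallel to
#'   `tracks`.
#' @param window Peak search window, see [find_peak()].
#' @param max_lag Maximum lag in bp (ignored for a precomputed matrix).
#' @return A list (class `density_profiles`) with `profiles` (data.frame of
#'   `density`, `peak_lag`, `n_molecules`) and `mean_ac` (matrix of mean
#'   autocorrelograms, one row per density).
#' @export
per_density_profiles <- function(tracks, densities, window = c(100L, 500L),
                                 max_lag = 1000L) {
  acm <- if (is.matrix(tracks)) tracks else
    autocorrelogram_matrix(tracks, max_lag)
  stopifnot(nrow(acm) == length(densities))
  dens <- sort(unique(densities))
  mean_ac <- t(vapply(dens, function(d)
    colMeans(acm[densities == d, , drop = FALSE]), numeric(ncol(acm))))
  rownames(mean_ac) <- dens
  profiles <- data.frame(
    density = dens,
    peak_lag = vapply(seq_along(dens), function(i)
      as.integer(find_peak(mean_ac[i, ], window)), integer(1L)),
    n_molecules = vapply(dens, function(d) sum(densities == d), integer(1L)))
  structure(list(profiles = profiles, mean_ac = mean_ac, window = window),
            class = "density_profiles")
}

#' @export
print.density_profiles <- function(x, ...) {
  cat("<density_profiles>\n")
  print(x$profiles)
  invisible(x)
}

#' Plot per-density profiles
#'
#' Average autocorrelograms, one line per density, peaks marked.
#'
#' @param x A `density_profiles`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.density_profiles <- function(x, ...) {
  lags <- seq_len(ncol(x$mean_ac)) - 1L
  graphics::matplot(lags, t(x$mean_ac), type = "l", lty = 1,
                    xlab = "lag (bp)", ylab = "mean autocorrelation", ...)
  ok <- !is.na(x$profiles$peak_lag)
  graphics::points(x$profiles$peak_lag[ok],
                   x$mean_ac[cbind(which(ok), x$profiles$peak_lag[ok] + 1L)],
                   pch = 19)
  invisible(x)
}

#' Correlation between per-density peak positions and density
#'
#' Pearson and Spearman correlation of the average-autocorrelogram peak lag
#' against nucleosome density. A strongly negative correlation is the
#' signature of length-sensing (density-dependent) remodeling; near-zero
#' slope with constant peaks is the signature of clamping. Degenerate input
#' (constant peaks) returns `r = 0`, `p = 1` by convention.
#'
#' @param profiles A `density_profiles` (or its `profiles` data.frame).
#' @return A list with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, and `n` (profiles with peaks used).
#' @export
density_peak_correlation <- function(profiles) {
  df <- if (inherits(profiles, "density_profiles")) profiles$profiles else
    profiles
  ok <- !is.na(df$peak_lag)
  if (sum(ok) < 3L) stop("need at least 3 profiles with peaks")
  x <- df$density[ok]
  y <- df$peak_lag[ok]
  if (sd(y) == 0 || sd(x) == 0)
    return(list(pearson_r = 0, pearson_p = 1, spearman_rho = 0,
                spearman_p = 1, n = sum(ok)))
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = sum(ok))
}

## symmetric kNN graph on rows of a matrix (Euclidean)
knn_graph <- function(mat, k = 15L) {
  n <- nrow(mat)
  k <- min(k, n - 1L)
  d <- as.matrix(dist(mat))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(k + 1L)]
    cbind(i, nb)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Leiden clustering of single-molecule autocorrelograms
#'
#' Builds a k-nearest-neighbor graph (Euclidean distance on autocorrelogram
#' vectors) and applies Leiden community detection, then removes the
#' smallest clusters while their cumulative share of molecules stays below
#' `min_total_frac` (in practice this trims the long tail of very small
#' clusters). Retained clusters always jointly cover at least
#' `1 - min_total_frac` of molecules.
#'
#' @param ac_matrix Molecules x lags autocorrelogram matrix.
#' @param resolution Leiden resolution parameter (default 0.4).
#' @param min_total_frac Cumulative size fraction below which the smallest
#'   clusters are filtered out (default 0.05).
#' @param k Neighbors for the kNN graph. The default (`NULL`) scales with
#'   the dataset: `max(15, min(100, n/8))`. A small fixed k makes the
#'   modularity objective fragment homogeneous fiber populations along
#'   incidental low-dimensional continua (offset, count); a neighborhood
#'   that grows with n keeps genuine populations intact while still
#'   separating distinct array types.
#' @param seed Optional integer seed.
#' @return A list (class `cluster_assignment`) with `labels` (integer per
#'   molecule, `NA` for filtered-out molecules), `sizes` (per retained
#'   cluster), `resolution`.
#' @export
cluster_fibers <- function(ac_matrix, resolution = 0.4, min_total_frac = 0.05,
                           k = NULL, seed = NULL) {
  stopifnot(is.matrix(ac_matrix))
  n <- nrow(ac_matrix)
  if (n < 2L) stop("need at least 2 molecules")
  if (is.null(k)) k <- max(15L, min(100L, as.integer(round(n / 8))))
  g <- knn_graph(ac_matrix, k)
  memb <- with_seed(seed,
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 5L)))
  labels <- as.integer(memb)
  sizes <- sort(table(labels))                     # ascending
  cum <- cumsum(sizes) / n
  drop_ids <- as.integer(names(sizes)[cum < min_total_frac])
  labels[labels %in% drop_ids] <- NA_integer_
  ## relabel retained clusters 1..m by descending size
  kept <- sort(table(labels), decreasing = TRUE)
  relab <- setNames(seq_along(kept), names(kept))
  labels <- unname(relab[as.character(labels)])
  structure(list(labels = as.integer(labels),
                 sizes = as.integer(kept),
                 resolution = resolution),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d molecules, %d retained cluster(s), resolution %.2f\n",
              length(x$labels), length(x$sizes), x$resolution))
  cat("sizes:", paste(x$sizes, collapse = " "),
      sprintf(" (filtered: %d)\n", sum(is.na(x$labels))))
  invisible(x)
}

#' UMAP embedding of autocorrelograms
#'
#' 2-D embedding for visualization only; seeded and single-threaded for
#' reproducibility.
#'
#' @param ac_matrix Molecules x lags autocorrelogram matrix (>= 10 rows).
#' @param seed Optional integer seed.
#' @param n_neighbors UMAP neighborhood size.
#' @return Numeric matrix with one (x, y) row per molecule.
#' @export
umap_embed <- function(ac_matrix, seed = NULL, n_neighbors = 15L) {
  stopifnot(is.matrix(ac_matrix))
  if (nrow(ac_matrix) < 10L) stop("need at least 10 molecules")
  with_seed(seed,
    uwot::umap(ac_matrix, n_neighbors = min(n_neighbors, nrow(ac_matrix) - 1L),
               n_threads = 1L, n_sgd_threads = 1L, batch = TRUE))
}
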