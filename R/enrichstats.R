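## Cluster-by-domain enrichment testing, Storey q-values, differential
## odds-ratio matrices, PCA/density correlation, log-odds density
## enrichment and weighted interval scheduling for repeat-match resolution.

#' Fisher's exact cluster-by-domain enrichment
#'
#' For every (cluster, domain) pair a 2x2 table of molecule membership is
#' tested with the two-sided exact test (sum of all table probabilities at
#' most that of the observed table). The sample odds ratio `ad/bc` is
#' reported (infinities preserved; empty margins give `NaN`, flagged not
#' dropped). All tests in one call form a single family for the Storey
#' q-value correction.
#'
#' @param cluster_labels Per-molecule cluster labels (`NA` allowed for
#'   filtered molecules; those are excluded).
#' @param domain_labels Per-molecule domain labels, same length.
#' @param q_cutoff Significance cutoff on q (default 0.05).
#' @return A list (class `enrichment_result`) of cluster x domain matrices:
#'   `odds_ratio`, `p_value`, `q_value`, `significant`, plus `undefined`
#'   (logical matrix flagging empty-margin cells).
#' @export
fisher_enrichment <- function(cluster_labels, domain_labels, q_cutoff = 0.05) {
  stopifnot(length(cluster_labels) == length(domain_labels))
  keep <- !is.na(cluster_labels) & !is.na(domain_labels)
  cl <- factor(cluster_labels[keep])
  dm <- factor(domain_labels[keep])
  n <- length(cl)
  or <- p <- matrix(NA_real_, nlevels(cl), nlevels(dm),
                    dimnames = list(levels(cl), levels(dm)))
  undef <- matrix(FALSE, nlevels(cl), nlevels(dm),
                  dimnames = dimnames(or))
  for (i in seq_len(nlevels(cl))) for (j in seq_len(nlevels(dm))) {
    inc <- cl == levels(cl)[i]
    ind <- dm == levels(dm)[j]
    a <- sum(inc & ind); b <- sum(inc & !ind)
    cc <- sum(!inc & ind); dd <- sum(!inc & !ind)
    or[i, j] <- (a * dd) / (b * cc)          # Inf and NaN preserved
    undef[i, j] <- (a + b) == 0L || (cc + dd) == 0L ||
      (a + cc) == 0L || (b + dd) == 0L
    p[i, j] <- fisher.test(matrix(c(a, b, cc, dd), 2L, byrow = TRUE))$p.value
  }
  q <- matrix(storey_qvalues(as.vector(p)), nrow(p), ncol(p),
              dimnames = dimnames(p))
  structure(list(odds_ratio = or, p_value = p, q_value = q,
                 significant = q < q_cutoff, undefined = undef),
            class = "enrichment_result")
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the null proportion `pi0` estimated
#' over a lambda grid with a cubic smoothing-spline smoother (the published
#' q-value procedure). For small families (fewer than `min_m` p-values) or
#' with `pi0 = 1` supplied, the procedure reduces exactly to
#' Benjamini-Hochberg adjustment.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param lambda Grid for the pi0 estimator.
#' @param pi0 Optional fixed null proportion; `NULL` (default) estimates it.
#' @param min_m Below this family size pi0 falls back to 1.
#' @return Numeric q-values, same length and order as `p_values`.
#' @export
storey_qvalues <- function(p_values, lambda = seq(0.05, 0.95, 0.05),
                           pi0 = NULL, min_m = 100L) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < min_m) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  stopifnot(pi0 > 0, pi0 <= 1)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / rank(p[o], ties.method = "max")
  q <- pmin(1, cummin(q))[ro]
  q
}

#' Differential odds-ratio matrix between two conditions
#'
#' Elementwise subtraction of matched enrichment matrices (condition A
#' minus condition B); optionally on the log-odds scale, where infinite
#' odds ratios would otherwise dominate (infinite or undefined cells
#' propagate as `Inf`/`NaN` rather than being imputed).
#'
#' @param or_a,or_b Matched cluster x domain odds-ratio matrices (or
#'   `enrichment_result` objects).
#' @param log_odds Subtract `log(or)` instead of raw odds ratios.
#' @return Matrix of differences.
#' @export
differential_matrix <- function(or_a, or_b, log_odds = FALSE) {
  if (inherits(or_a, "enrichment_result")) or_a <- or_a$odds_ratio
  if (inherits(or_b, "enrichment_result")) or_b <- or_b$odds_ratio
  if (!all(dim(or_a) == dim(or_b))) stop("matrix shapes differ")
  if (log_odds) log(or_a) - log(or_b) else or_a - or_b
}

#' PCA of a differential matrix and correlation of PC1 with density
#'
#' Treats domains as observations (columns of the cluster x domain
#' differential matrix), performs column-centered PCA to at most 4
#' components, and correlates the PC1 score of each domain with its mean
#' per-fiber nucleosome density (Pearson and Spearman, two-sided).
#'
#' @param diff Cluster x domain differential matrix (finite values).
#' @param mean_density_per_domain Numeric vector, one mean density per
#'   domain (column).
#' @return A list with `scores` (domains x components), `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, and `rank_deficient` flag.
#' @export
pca_density_correlation <- function(diff, mean_density_per_domain) {
  stopifnot(is.matrix(diff), ncol(diff) == length(mean_density_per_domain))
  if (ncol(diff) < 3L) stop("need at least 3 domains")
  if (any(!is.finite(diff)))
    stop("differential matrix contains non-finite values; mask infinite odds ratios first")
  obs <- t(diff)                                 # domains x clusters
  pc <- prcomp(obs, center = TRUE, scale. = FALSE,
               rank. = min(4L, ncol(obs), nrow(obs) - 1L))
  rank_deficient <- sum(pc$sdev > 1e-10) < 1L
  pc1 <- pc$x[, 1L]
  if (sd(pc1) == 0 || sd(mean_density_per_domain) == 0) {
    return(list(scores = pc$x, pearson_r = 0, pearson_p = 1,
                spearman_rho = 0, spearman_p = 1,
                rank_deficient = TRUE))
  }
  pe <- cor.test(pc1, mean_density_per_domain, method = "pearson")
  sp <- suppressWarnings(cor.test(pc1, mean_density_per_domain,
                                  method = "spearman"))
  list(scores = pc$x, pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       rank_deficient = rank_deficient)
}

#' Log-odds nucleosome-density enrichment of a cluster
#'
#' Estimates binned probability distributions for cluster-specific and
#' background per-fiber densities and returns
#' `log(P_cluster(bin) / P_background(bin))` with additive smoothing so all
#' values are finite.
#'
#' @param cluster_densities Densities of molecules in the cluster.
#' @param background_densities Densities of all molecules.
#' @param bins Common bin edges, or a bin count (default 20 equal-width
#'   bins over the pooled range).
#' @param pseudo Additive smoothing pseudo-count per bin.
#' @return A data.frame with `bin_lo`, `bin_hi`, `log_odds`.
#' @export
log_odds_density_enrichment <- function(cluster_densities,
                                        background_densities, bins = 20L,
                                        pseudo = 0.5) {
  stopifnot(length(cluster_densities) >= 1L,
            length(background_densities) >= 1L)
  if (length(bins) == 1L) {
    rng <- range(c(cluster_densities, background_densities))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    bins <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  }
  nb <- length(bins) - 1L
  count_in <- function(x) {
    idx <- findInterval(x, bins, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = nb)
  }
  pc <- count_in(cluster_densities) + pseudo
  pb <- count_in(background_densities) + pseudo
  data.frame(bin_lo = bins[-length(bins)], bin_hi = bins[-1L],
             log_odds = log((pc / sum(pc)) / (pb / sum(pb))))
}

#' Weighted interval scheduling
#'
#' Exact dynamic program selecting the maximum-total-score subset of
#' pairwise non-overlapping intervals (half-open overlap test: intervals
#' `[a, b)` and `[b, c)` are compatible). Intervals are sorted by end then
#' start; predecessor lookup is by binary search, so the whole computation
#' is `O(n log n)`. Used to resolve overlapping BLAST repeat matches by
#' maximizing the summed bitscore.
#'
#' @param intervals A data.frame with columns `start`, `end` (0-based,
#'   half-open) and nonnegative `score`; other columns (e.g. a repeat-class
#'   `label`) are carried through.
#' @return A list with `selected` (the chosen rows, in genomic order) and
#'   `total_score`.
#' @export
weighted_interval_schedule <- function(intervals) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0L)
    return(list(selected = intervals, total_score = 0))
  stopifnot(all(c("start", "end", "score") %in% names(intervals)),
            all(intervals$end > intervals$start))
  if (any(intervals$score < 0)) stop("negative scores are not allowed")
  iv <- intervals[order(intervals$end, intervals$start), , drop = FALSE]
  n <- nrow(iv)
  ## p[j]: number of intervals (in sorted order) ending at or before start_j
  p <- findInterval(iv$start, iv$end)
  opt <- numeric(n + 1L)
  take <- logical(n)
  for (j in seq_len(n)) {
    with_j <- iv$score[j] + opt[p[j] + 1L]
    if (with_j > opt[j]) {                   # strict: ties prefer exclusion
      opt[j + 1L] <- with_j
      take[j] <- TRUE
    } else {
      opt[j + 1L] <- opt[j]
    }
  }
  sel <- logical(n)
  j <- n
  while (j >= 1L) {
    if (take[j]) {
      sel[j] <- TRUE
      j <- p[j]
    } else j <- j - 1L
  }
  list(selected = iv[sel, , drop = FALSE], total_score = opt[n + 1L])
}

#' Read interval hits from BLAST tabular output (outfmt 6)
#'
#' Standard 12-column tabular output. Query coordinates (1-based,
#' inclusive, possibly reversed) are converted to 0-based half-open
#' intervals; the subject id becomes the `label` and the bitscore the
#' `score`, ready for [weighted_interval_schedule()].
#'
#' @param path Path to a BLAST outfmt-6 file.
#' @return A data.frame with `start`, `end`, `score`, `label` plus the raw
#'   columns.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  dat <- read.delim(path, header = FALSE, col.names = cols)
  lo <- pmin(dat$qstart, dat$qend)
  hi <- pmax(dat$qstart, dat$qend)
  data.frame(start = lo - 1L, end = hi, score = dat$bitscore,
             label = dat$sseqid, dat)
}
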