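## direct hypergeometric two-sided p for a 2x2 table (independent oracle)
fisher_p_oracle <- function(a, b, cc, dd) {
  m <- a + b          # row 1 total (cluster members)
  n <- cc + dd        # row 2 total
  k <- a + cc         # column 1 total (domain members)
  x <- max(0L, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("fisher_enrichment reports sample odds ratios and exact p-values", {
  ## one cluster vs rest, one domain vs rest: a=20 b=80 c=10 d=90
  cl <- rep(c("c1", "c2"), c(100, 100))
  dm <- c(rep(c("d1", "d2"), c(20, 80)), rep(c("d1", "d2"), c(10, 90)))
  res <- fisher_enrichment(cl, dm)
  expect_equal(res$odds_ratio["c1", "d1"], (20 * 90) / (80 * 10))  # 2.25
  expect_equal(res$p_value["c1", "d1"], fisher_p_oracle(20, 80, 10, 90))
  ## symmetric complements share the same 2x2 table
  expect_equal(res$p_value["c1", "d1"], res$p_value["c2", "d2"])
})

test_that("fisher p-values match hypergeometric enumeration on random tables", {
  set.seed(17)
  for (i in 1:50) {
    tot <- sample(20:200, 1)
    a <- sample(0:tot, 1); rest <- tot - a
    b <- sample(0:rest, 1); rest <- rest - b
    cc <- sample(0:rest, 1); dd <- rest - cc
    if ((a + b) == 0 || (cc + dd) == 0 || (a + cc) == 0 || (b + dd) == 0) next
    p_pkg <- fisher.test(matrix(c(a, b, cc, dd), 2, byrow = TRUE))$p.value
    expect_lt(abs(p_pkg - fisher_p_oracle(a, b, cc, dd)), 1e-10)
  }
})

test_that("null labels give approximately uniform p and nominal FPR", {
  set.seed(23)
  n <- 400
  reps <- 200
  pvals <- vapply(seq_len(reps), function(r) {
    cl <- sample(c("c1", "c2"), n, replace = TRUE)
    dm <- sample(c("d1", "d2"), n, replace = TRUE)
    fisher.test(table(cl, dm))$p.value
  }, 0)
  ## exact-test conservatism keeps the FPR at or below ~5% plus noise
  expect_lte(mean(pvals < 0.05), 0.08)
  expect_gt(mean(pvals), 0.3)
})

test_that("Storey q-values reduce to BH at pi0 = 1 and estimate pi0 near 1 under the null", {
  set.seed(5)
  p <- runif(200)
  expect_equal(storey_qvalues(p, pi0 = 1), p.adjust(p, "BH"))
  ## small families fall back to pi0 = 1 automatically
  expect_equal(storey_qvalues(p[1:20]), p.adjust(p[1:20], "BH"))

  expect_true(all(storey_qvalues(rep(1, 150)) == 1))

  p_null <- runif(1e4)
  q <- storey_qvalues(p_null)
  ## recover implied pi0 = q_max relative to BH
  pi0_hat <- max(q / p.adjust(p_null, "BH"), na.rm = TRUE)
  expect_gt(pi0_hat, 0.9)
  expect_lte(pi0_hat, 1.1)

  ## q is monotone in sorted p
  o <- order(p_null)
  expect_true(all(diff(storey_qvalues(p_null)[o]) >= -1e-12))

  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("FDR is controlled near the nominal level on null+signal simulations", {
  set.seed(31)
  fdp <- replicate(100, {
    p <- c(runif(90), rbeta(10, 0.05, 1))       # 90 nulls, 10 signals
    q <- storey_qvalues(p)
    disc <- which(q < 0.1)
    if (!length(disc)) 0 else mean(disc <= 90)
  })
  expect_lte(mean(fdp), 0.15)
})

test_that("differential matrices subtract elementwise with antisymmetry", {
  a <- matrix(runif(12, 0.5, 2), 3)
  b <- matrix(runif(12, 0.5, 2), 3)
  expect_equal(differential_matrix(a, a), matrix(0, 3, 4))
  expect_equal(differential_matrix(a, b), -differential_matrix(b, a))
  expect_equal(differential_matrix(a, b, log_odds = TRUE), log(a) - log(b))
  expect_error(differential_matrix(a, b[1:2, ]), "shapes")
})

test_that("a planted enrichment shows up in exactly one differential cell", {
  set.seed(11)
  n <- 2000
  dm <- sample(paste0("d", 1:4), n, replace = TRUE)
  ## condition B: cluster independent of domain
  cl_b <- sample(paste0("c", 1:3), n, replace = TRUE)
  ## condition A: molecules in d2 strongly prefer c1
  cl_a <- cl_b
  cl_a[dm == "d2"] <- sample(paste0("c", 1:3), sum(dm == "d2"),
                             replace = TRUE, prob = c(0.8, 0.1, 0.1))
  diff <- differential_matrix(fisher_enrichment(cl_a, dm),
                              fisher_enrichment(cl_b, dm))
  expect_identical(unname(which(abs(diff) == max(abs(diff)), arr.ind = TRUE)[1, ]),
                   c(which(rownames(diff) == "c1"), which(colnames(diff) == "d2")))
  expect_gt(diff["c1", "d2"], 0)
})

test_that("PC1 correlates with density when the differential is density-driven", {
  ## rank-1 matrix whose domain loadings are proportional to density
  dens <- c(2, 3.5, 4, 5.1, 6, 7.2)
  diff <- outer(c(1, -0.5, 0.3, -1, 0.8), dens - mean(dens))
  out <- pca_density_correlation(diff, dens)
  expect_equal(abs(out$pearson_r), 1, tolerance = 1e-8)
  ## PC1 dominates the variance
  v <- apply(out$scores, 2, var)
  expect_gte(v[1], max(v))

  ## permuting the density vector destroys the correlation on average
  set.seed(9)
  noise <- diff + matrix(rnorm(30, sd = 0.05), 5)
  rs <- replicate(50, pca_density_correlation(noise, sample(dens))$pearson_r)
  expect_lt(abs(mean(rs)), 0.3)

  expect_error(pca_density_correlation(diff[, 1:2], dens[1:2]), "at least 3")
  bad <- diff; bad[1, 1] <- Inf
  expect_error(pca_density_correlation(bad, dens), "non-finite")
})

test_that("log-odds density enrichment behaves at the edges", {
  bg <- c(rep(1, 50), rep(2, 50))
  lo0 <- log_odds_density_enrichment(bg, bg, bins = 4)
  expect_true(all(abs(lo0$log_odds) < 1e-12))

  shifted <- rep(2, 60)
  lo1 <- log_odds_density_enrichment(shifted, bg, bins = 4)
  expect_gt(lo1$log_odds[nrow(lo1)], 0)
  expect_lt(min(lo1$log_odds), 0)
  expect_true(all(is.finite(lo1$log_odds)))
})

test_that("weighted interval scheduling is exact against subset enumeration", {
  ## worked example: best non-overlapping pair
  iv <- data.frame(start = c(0, 5, 12), end = c(10, 15, 20), score = c(5, 7, 4))
  out <- weighted_interval_schedule(iv)
  expect_equal(out$total_score, 9)
  expect_identical(out$selected$start, c(0, 12))

  expect_equal(weighted_interval_schedule(iv[0, ])$total_score, 0)
  expect_identical(nrow(weighted_interval_schedule(iv[2, ])$selected), 1L)
  expect_error(weighted_interval_schedule(
    data.frame(start = 0, end = 5, score = -1)), "negative")

  ## exhaustive oracle on 200 random instances
  brute_best <- function(iv) {
    n <- nrow(iv)
    best <- 0
    for (code in 0:(2^n - 1)) {
      idx <- which(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L) == 1L)
      if (length(idx) > 1L) {
        s <- iv[idx, ][order(iv$start[idx]), ]
        if (any(s$end[-nrow(s)] > s$start[-1L])) next
      }
      best <- max(best, sum(iv$score[idx]))
    }
    best
  }
  set.seed(77)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    st <- sample(0:80, n, replace = TRUE)
    iv <- data.frame(start = st, end = st + sample(1:30, n, replace = TRUE),
                     score = round(runif(n, 0, 50), 1))
    expect_equal(weighted_interval_schedule(iv)$total_score, brute_best(iv))
  }
})

test_that("BLAST tabular hits are converted to half-open scored intervals", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "mol1\tmajor_sat\t95.2\t100\t4\t1\t11\t110\t1\t100\t1e-30\t181.5",
    "mol1\tminor_sat\t88.0\t60\t7\t0\t179\t120\t60\t1\t1e-10\t77.0",
    "mol1\ttelomere\t100.0\t30\t0\t0\t200\t229\t1\t30\t1e-5\t55.1"),
    path)
  hits <- read_blast_tab(path)
  expect_identical(hits$start, c(10L, 119L, 199L))  # reversed hit normalized
  expect_identical(hits$end, c(110L, 179L, 229L))
  expect_equal(hits$score, c(181.5, 77.0, 55.1))
  expect_identical(as.character(hits$label),
                   c("major_sat", "minor_sat", "telomere"))
  sched <- weighted_interval_schedule(hits)
  expect_equal(sched$total_score, 181.5 + 77.0 + 55.1)
})
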