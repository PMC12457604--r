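# Independent high-precision Welch reference: explicit statistic, the
# Welch-Satterthwaite df formula, and the Student-t survival function.
welch_reference <- function(x, y) {
  vx <- stats::var(x); vy <- stats::var(y)
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

test_that("welch_t matches the explicit-formula reference to 1e-10", {
  x <- c(27.5, 27.9, 28.1, 28.6)
  y <- c(29.1, 29.4, 30.0)
  got <- welch_t(x, y)
  # frozen values computed from the reference formula
  expect_equal(got$t, -4.21787386794917, tolerance = 1e-10)
  expect_equal(got$df, 4.449017624653, tolerance = 1e-10)
  expect_equal(got$p, 0.010756224542921, tolerance = 1e-10)
  ref <- welch_reference(x, y)
  expect_equal(got$t, ref$t, tolerance = 1e-12)
  expect_equal(got$df, ref$df, tolerance = 1e-12)
  expect_equal(got$p, ref$p, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:25) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1), 0.3)
    g <- welch_t(a, b); r <- welch_reference(a, b)
    expect_equal(g$t, r$t, tolerance = 1e-12)
    expect_equal(g$df, r$df, tolerance = 1e-12)
    expect_equal(g$p, r$p, tolerance = 1e-12)
  }
})

test_that("welch_t degenerate and limiting cases", {
  x <- c(2.1, 2.2, 2.3)
  same <- welch_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  far <- welch_t(x, x + 10)
  expect_lt(far$p, 1e-6)
  # n < 2 gives a missing result, never an error
  expect_true(is.na(welch_t(1, c(1, 2))$p))
  # both samples constant
  expect_equal(welch_t(c(5, 5), c(5, 5, 5)), list(t = 0, df = 3, p = 1))
  zc <- welch_t(c(5, 5), c(6, 6))
  expect_equal(zc$p, 0)
  expect_true(is.infinite(zc$t))
})

test_that("welch_t is antisymmetric in its arguments", {
  set.seed(20)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(6, 0.5)
    f <- welch_t(a, b); g <- welch_t(b, a)
    expect_equal(f$t, -g$t)
    expect_equal(f$p, g$p)
    expect_equal(f$df, g$df)
  }
})

test_that("split_groups partitions strictly at the threshold", {
  mats <- c(a = 28, b = 30, c = 29, d = NaN)
  sp <- split_groups(mats)
  expect_equal(sp$below, c("a", "c"))   # 29 exactly goes below
  expect_equal(sp$above, "b")
  expect_equal(length(sp$below) + length(sp$above), 3L)
})

test_that("compare_all emits one row per stratum x group with flags", {
  set.seed(44)
  n <- 40
  tab <- data.frame(
    city_id = paste0("c", 1:n),
    continent = rep(c("Africa", "Asia"), each = n / 2),
    mat = c(rnorm(n / 2, 28), rnorm(n / 2, 30)),
    bare_natural = runif(n), green = runif(n))
  res <- compare_all(tab, c("bare_natural", "green"))
  expect_equal(nrow(res), 3L * 2L)     # ALL + 2 continents, 2 groups
  expect_setequal(unique(res$continent), c("ALL", "Africa", "Asia"))
  expect_equal(res$n_below + res$n_above,
               rep(c(n, n / 2, n / 2), each = 2))
  expect_true(all(res$p >= 0 & res$p <= 1, na.rm = TRUE))
  expect_equal(res$significant, !is.na(res$p) & res$p < 0.05)
})

test_that("a stratum with no exceeders yields missing tests, not errors", {
  tab <- data.frame(city_id = paste0("c", 1:6),
                    continent = "Europe",
                    mat = rep(25, 6),
                    green = runif(6))
  res <- compare_all(tab, "green")
  expect_equal(nrow(res), 2L)
  expect_true(all(is.na(res$t)))
  expect_true(all(!res$significant))
  expect_equal(res$n_above, c(0L, 0L))
})

test_that("a planted bare-surface effect is detected with high power", {
  # start from identical regimes, then shift bare soil (F, code 16) so the
  # hot-regime E+F expectation sits exactly +8pp above cool; the shift on F
  # is scaled up slightly because the proportional compensation also
  # shrinks E (code 15)
  cfg <- world_config(seed = 1L)
  cfg$lcz_hot <- cfg$lcz_cool
  p <- cfg$lcz_cool / sum(cfg$lcz_cool)
  delta <- 0.08 / (1 - p[["15"]] / (1 - p[["16"]]))
  cfg_eff <- perturb_group_shares(cfg, delta, 16L)
  p_hot <- cfg_eff$lcz_hot / sum(cfg_eff$lcz_hot)
  p_cool <- cfg_eff$lcz_cool / sum(cfg_eff$lcz_cool)
  expect_equal(sum(p_hot[15:16]) - sum(p_cool[15:16]), 0.08,
               tolerance = 1e-9)
  hits <- 0L
  set.seed(101)
  for (r in 1:100) {
    hot <- sample_lcz_shares(cfg_eff, "hot", 25)
    cool <- sample_lcz_shares(cfg_eff, "cool", 25)
    wt <- welch_t(rowSums(cool[, 15:16]), rowSums(hot[, 15:16]))
    if (!is.na(wt$p) && wt$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("the type-I error rate under a planted null is nominal", {
  cfg <- world_config(seed = 1L)
  cfg$lcz_hot <- cfg$lcz_cool   # null: regimes identical
  hits <- 0L
  set.seed(202)
  for (r in 1:100) {
    a <- sample_lcz_shares(cfg, "hot", 25)
    b <- sample_lcz_shares(cfg, "cool", 25)
    wt <- welch_t(rowSums(a[, 15:16]), rowSums(b[, 15:16]))
    if (!is.na(wt$p) && wt$p < 0.05) hits <- hits + 1L
  }
  # exact binomial 95% band around 0.05 at 100 replicates: [1, 10]
  band <- qbinom(c(0.025, 0.975), 100, 0.05)
  expect_gte(hits, band[1])
  expect_lte(hits, band[2])
})

test_that("null p-values are approximately uniform", {
  set.seed(303)
  ps <- replicate(500, welch_t(rnorm(15), rnorm(15))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("median-position diagnostic counts strict comparisons only", {
  tab <- data.frame(
    city_id = paste0("c", 1:8),
    continent = rep(c("Africa", "Asia"), each = 4),
    mat = c(30, 30, 25, 25, 30, 30, 25, 25),
    bare_natural = c(0.5, 0.1, 0.2, 0.3, 0.9, 0.2, 0.4, 0.5))
  # Africa median over all 4 = 0.25; exceeders 0.5 (above), 0.1 (not)
  # Asia   median over all 4 = 0.45; exceeders 0.9 (above), 0.2 (not)
  expect_equal(median_position_diagnostic(tab, "bare_natural", "above"),
               0.5)
  expect_equal(median_position_diagnostic(tab, "bare_natural", "below"),
               0.5)
  # ties never count: every exceeder share equal to its continent median
  tie <- data.frame(city_id = c("a", "b"), continent = "Asia",
                    mat = c(30, 30), green = c(0.2, 0.2))
  expect_equal(median_position_diagnostic(tie, "green", "above"), 0)
  none <- transform(tie, mat = c(20, 20))
  expect_warning(out <- median_position_diagnostic(none, "green", "above"),
                 "no exceeding")
  expect_true(is.na(out))
})

test_that("median-position diagnostic matches a per-city oracle", {
  set.seed(55)
  for (i in 1:20) {
    n <- 30
    tab <- data.frame(
      city_id = paste0("c", 1:n),
      continent = sample(c("Africa", "Asia", "Europe"), n, TRUE),
      mat = runif(n, 25, 33),
      bare_natural = runif(n))
    got <- suppressWarnings(
      median_position_diagnostic(tab, "bare_natural", "above"))
    exc <- tab[tab$mat > 29, ]
    if (!nrow(exc)) next
    hits <- vapply(seq_len(nrow(exc)), function(j) {
      med <- median(tab$bare_natural[tab$continent == exc$continent[j]])
      exc$bare_natural[j] > med
    }, logical(1))
    expect_equal(got, mean(hits))
  }
})
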