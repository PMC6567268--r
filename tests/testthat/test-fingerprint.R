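test_that("fingerprint parameters are exact on noiseless lines", {
  pts <- data.frame(k = 1:6, vol_pct = c(2, 4, 6, 8, 10, 12),
                    nhv95 = c(10, 8, 6, 4, 2, 0))
  fp <- suppressWarnings(fit_fingerprint(pts))  # lm warns on perfect fits
  expect_equal(fp$slope, -1)
  expect_equal(fp$r2, 1)
  expect_equal(coef(fp)[c("a", "b", "e", "f", "d", "g")],
               c(a = 2, b = 10, e = 12, f = 0, d = 10, g = 10))
  # horizontal line: slope 0, no Y-projection
  ph <- data.frame(k = 1:6, vol_pct = 1:6, nhv95 = rep(3, 6))
  fh <- suppressWarnings(fit_fingerprint(ph))
  expect_equal(fh$slope, 0)
  expect_equal(fh$g, 0)
  expect_error(fit_fingerprint(data.frame(k = 1:3, vol_pct = rep(2, 3),
                                          nhv95 = 1:3)), "degenerate")
})

test_that("parameter identities and shift equivariance hold on noisy fits", {
  set.seed(61)
  for (i in 1:10) {
    n_stacks <- sample(1:3, 1)
    pts <- do.call(rbind, lapply(seq_len(n_stacks), function(s)
      data.frame(k = 1:6, vol_pct = sort(runif(6, 1, 10)),
                 nhv95 = rnorm(6, 20, 4))))
    fp <- fit_fingerprint(pts)
    expect_equal(fp$d, fp$e - fp$a)
    expect_equal(fp$g, fp$b - fp$f)
    if (fp$slope < 0) expect_equal(fp$g, fp$b - fp$f)
    expect_gte(fp$r2, 0)
    expect_lte(fp$r2, 1)
    # shifting all nhv95 by c shifts b, f, intercept; slope, d, g, r2 fixed
    sh <- pts
    sh$nhv95 <- sh$nhv95 + 5
    fs <- fit_fingerprint(sh)
    expect_equal(fs$slope, fp$slope)
    expect_equal(fs$intercept, fp$intercept + 5)
    expect_equal(fs$b, fp$b + 5)
    expect_equal(fs$f, fp$f + 5)
    expect_equal(fs$d, fp$d)
    expect_equal(fs$g, fp$g)
    expect_equal(fs$r2, fp$r2)
  }
})

test_that("OLS recovers a known generating slope within sampling error", {
  set.seed(62)
  true_slope <- -2.5
  hits <- 0L
  for (i in 1:40) {
    pts <- data.frame(k = rep(1:6, 3), vol_pct = rep(seq(2, 12, 2), 3))
    pts$nhv95 <- 30 + true_slope * pts$vol_pct + rnorm(nrow(pts), 0, 1.5)
    fp <- fit_fingerprint(pts)
    se <- summary(fp$fit)$coefficients["vol_pct", "Std. Error"]
    if (abs(fp$slope - true_slope) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 36L)  # ~99.7% nominal coverage, allow sampling slack
})

test_that("slope F-test: identical groups give F = 0, separated slopes p ~ 0", {
  pts <- data.frame(k = rep(1:6, 2), vol_pct = rep(1:6, 2))
  pts$nhv95 <- 20 - 2 * pts$vol_pct + rep(c(0, 0.5), each = 6)
  cs <- compare_slopes(pts, pts)
  expect_equal(cs$F, 0)
  expect_equal(cs$p, 1)
  a <- data.frame(k = 1:6, vol_pct = 1:6, nhv95 = 20 - 1 * (1:6))
  b <- data.frame(k = 1:6, vol_pct = 1:6, nhv95 = 20 - 3 * (1:6))
  cs2 <- compare_slopes(a, b)
  expect_true(is.infinite(cs2$F) || cs2$F > 1e6)
  expect_lt(cs2$p, 1e-10)
  expect_error(compare_slopes(a[1:2, ], b), "3 points")
})

test_that("slope F-test holds its nominal size on independent-noise points", {
  set.seed(63)
  nrep <- 400
  rej <- 0L
  x <- rep(seq(2, 12, 2), 4)
  for (i in seq_len(nrep)) {
    a <- data.frame(k = rep(1:6, 4), vol_pct = x,
                    nhv95 = 25 - 2 * x + rnorm(length(x), 0, 2))
    b <- data.frame(k = rep(1:6, 4), vol_pct = x,
                    nhv95 = 25 - 2 * x + rnorm(length(x), 0, 2))
    if (compare_slopes(a, b)$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / nrep, 0.05 - 0.025)
  expect_lt(rej / nrep, 0.05 + 0.025)
})

test_that("Mann-Whitney Gaussian approximation matches the closed form", {
  # fully separated {1..4} vs {5..8}: U = 0, z = -8/sqrt(12)
  mw <- mann_whitney_gauss(1:4, 5:8, correct = FALSE)
  expect_equal(mw$U, 0)
  expect_equal(mw$z, -8 / sqrt(16 * 9 / 12))
  expect_equal(mw$p, 2 * pnorm(-abs(-2.309401)), tolerance = 1e-4)
  # continuity correction shrinks |z|
  mwc <- mann_whitney_gauss(1:4, 5:8, correct = TRUE)
  expect_lt(abs(mwc$z), abs(mw$z))
  # agreement with stats::wilcox.test normal approximation
  set.seed(64)
  x <- rnorm(8); y <- rnorm(9, 0.8)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mann_whitney_gauss(x, y, correct = TRUE)$p, ref$p.value)
})

test_that("parameter comparison applies the prescribed test per parameter", {
  pa <- data.frame(a = c(1, 2, 3, 4), b = c(10, 11, 12, 13),
                   d = c(5, 6, 7, 8), e = c(6, 8, 10, 12),
                   f = c(1, 2, 3, 4), g = c(9, 9, 9, 10))
  pc <- compare_parameters(pa, pa)
  tab <- pc$table
  expect_setequal(tab$parameter, c("a", "b", "d", "e", "f", "g"))
  expect_equal(tab$test[tab$parameter %in% c("a", "d", "e")], rep("t", 3))
  expect_equal(tab$test[tab$parameter %in% c("b", "f", "g")],
               rep("mann-whitney", 3))
  # identical groups: t statistics 0, p = 1, nothing significant
  expect_equal(tab$statistic[tab$test == "t"], rep(0, 3))
  expect_equal(tab$p[tab$test == "t"], rep(1, 3))
  expect_false(any(tab$significant))
  # zero-variance difference is flagged as degenerate, not an infinite t
  pb <- pa
  pb$a <- pa$a * 0 + 9
  pa0 <- pa
  pa0$a <- pa$a * 0 + 1
  tab2 <- compare_parameters(pa0, pb)$table
  expect_true(tab2$degenerate[tab2$parameter == "a"])
  # t-test matches stats::t.test with pooled variance
  pb2 <- pa + 1.3
  tab3 <- compare_parameters(pa, pb2)$table
  ref <- stats::t.test(pa$d, pb2$d, var.equal = TRUE)
  expect_equal(tab3$statistic[tab3$parameter == "d"], unname(ref$statistic))
  expect_equal(tab3$p[tab3$parameter == "d"], ref$p.value)
})
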