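#' Fit the angioarchitecture fingerprint line
#'
#' Each unit's progressive architectures yield points (Vol%, nHv95); their
#' ordinary-least-squares line is the fingerprint. Seven interdependent
#' parameters are read off the line:
#' \describe{
#'   \item{a}{X of the left-end point: mean Vol% of the first (largest
#'     caliber, k = 1) architecture across the unit's stacks.}
#'   \item{b}{Y of the left-end point: the fitted line evaluated at `a`
#'     (dispersion of the largest vessels).}
#'   \item{c (slope)}{rate of change of intervascular dispersion as smaller
#'     calibers are added; steeper (more negative) = more rarefied.}
#'   \item{d}{X-projection length `e - a`: volume contributed by vessels
#'     smaller than the largest class.}
#'   \item{e}{X of the right-end point: mean Vol% of the complete analyzed
#'     architecture (k = n_classes).}
#'   \item{f}{Y of the right-end point: fitted line at `e`.}
#'   \item{g}{Y-projection length `b - f`: dispersion contributed by the
#'     smaller vessels.}
#' }
#'
#' @param points data.frame with columns `k` (architecture index), `vol_pct`
#'   and `nhv95`; optionally `unit_id`, `stack_id`. Needs >= 2 points with
#'   >= 2 distinct `vol_pct` values.
#' @param n_classes index of the final (complete) architecture; default the
#'   largest `k` present.
#' @param endpoint_y `"line"` (default) reads b and f off the fitted line at
#'   a and e; `"raw"` uses the mean observed nhv95 at k = 1 and k = n_classes.
#' @return An object of class `fingerprint_line` with the seven parameters,
#'   `intercept`, `r2`, `n_points` and the underlying `lm` fit.
#' @examples
#' pts <- data.frame(k = 1:6, vol_pct = c(2, 4, 6, 8, 10, 12),
#'                   nhv95 = c(10, 8, 6, 4, 2, 0))
#' fit_fingerprint(pts)
#' @export
fit_fingerprint <- function(points, n_classes = max(points$k),
                            endpoint_y = c("line", "raw")) {
  endpoint_y <- match.arg(endpoint_y)
  points <- check_points(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  if (length(unique(points$vol_pct)) < 2L)
    stop("degenerate X: all vol_pct values identical")
  fit <- stats::lm(nhv95 ~ vol_pct, data = points)
  co <- stats::coef(fit)
  r2 <- summary(fit)$r.squared
  first <- points$k == 1L
  last <- points$k == n_classes
  if (!any(first) || !any(last))
    stop("points must include the first (k = 1) and last (k = n_classes) architectures")
  a <- mean(points$vol_pct[first])
  e <- mean(points$vol_pct[last])
  if (endpoint_y == "line") {
    b <- unname(co[1] + co[2] * a)
    f <- unname(co[1] + co[2] * e)
  } else {
    b <- mean(points$nhv95[first])
    f <- mean(points$nhv95[last])
  }
  structure(
    list(slope = unname(co[2]), intercept = unname(co[1]), r2 = r2,
         a = a, b = b, d = e - a, e = e, f = f, g = b - f,
         n_points = nrow(points), endpoint_y = endpoint_y,
         points = points, fit = fit),
    class = "fingerprint_line"
  )
}

check_points <- function(points) {
  points <- as.data.frame(points)
  need <- c("k", "vol_pct", "nhv95")
  miss <- setdiff(need, names(points))
  if (length(miss) > 0L)
    stop("points lack column(s): ", paste(miss, collapse = ", "))
  points <- points[stats::complete.cases(points[, need]), , drop = FALSE]
  points
}

#' @export
print.fingerprint_line <- function(x, ...) {
  cat(sprintf("fingerprint_line (%d points, R^2 = %.4f)\n", x$n_points, x$r2))
  cat(sprintf("  slope (c) %9.4f   intercept %9.4f\n", x$slope, x$intercept))
  cat(sprintf("  left  end (a, b) = (%.4f, %.4f)\n", x$a, x$b))
  cat(sprintf("  right end (e, f) = (%.4f, %.4f)\n", x$e, x$f))
  cat(sprintf("  projections d = %.4f (X), g = %.4f (Y)\n", x$d, x$g))
  invisible(x)
}

#' @export
coef.fingerprint_line <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept, a = object$a,
    b = object$b, d = object$d, e = object$e, f = object$f, g = object$g)
}

#' @export
predict.fingerprint_line <- function(object, vol_pct = NULL, ...) {
  if (is.null(vol_pct)) return(stats::predict(object$fit))
  object$intercept + object$slope * as.numeric(vol_pct)
}

#' @export
residuals.fingerprint_line <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.fingerprint_line <- function(x, ..., ci = TRUE) {
  pts <- x$points
  graphics::plot(pts$vol_pct, pts$nhv95, xlab = "Vol %", ylab = "nHv 95%",
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope)
  if (ci && nrow(pts) > 2L) {
    xs <- seq(min(pts$vol_pct), max(pts$vol_pct), length.out = 50)
    pr <- stats::predict(x$fit, newdata = data.frame(vol_pct = xs),
                         interval = "confidence")
    graphics::lines(xs, pr[, "lwr"], lty = 3)
    graphics::lines(xs, pr[, "upr"], lty = 3)
  }
  graphics::points(c(x$a, x$e), c(x$b, x$f), pch = 4, cex = 1.5)
  invisible(x)
}

#' Compare group regression slopes by F-test
#'
#' Points from all units of a group are pooled into one regression per group;
#' the test contrasts the full model (separate intercepts and slopes) with
#' the reduced model (common slope, separate intercepts). The statistic is
#' F = (RSS_reduced - RSS_full) / (RSS_full / (n - 4)) on (1, n - 4) degrees
#' of freedom, n = total points.
#'
#' @param pointsA,pointsB data.frames of fingerprint points (columns `k`,
#'   `vol_pct`, `nhv95`) for the two groups; each needs >= 3 points.
#' @return A list of class `slope_comparison`: `F`, `p`, `df`, per-group
#'   slopes and the pooled fits.
#' @export
compare_slopes <- function(pointsA, pointsB) {
  pointsA <- check_points(pointsA)
  pointsB <- check_points(pointsB)
  if (nrow(pointsA) < 3L || nrow(pointsB) < 3L)
    stop("each group needs at least 3 points")
  dat <- rbind(
    data.frame(vol_pct = pointsA$vol_pct, nhv95 = pointsA$nhv95, group = "A"),
    data.frame(vol_pct = pointsB$vol_pct, nhv95 = pointsB$nhv95, group = "B")
  )
  dat$group <- factor(dat$group)
  full <- stats::lm(nhv95 ~ vol_pct * group, data = dat)
  red <- stats::lm(nhv95 ~ vol_pct + group, data = dat)
  rss_f <- sum(stats::residuals(full)^2)
  rss_r <- sum(stats::residuals(red)^2)
  n <- nrow(dat)
  df2 <- n - 4L
  if (df2 < 1L) stop("insufficient points for the slope F-test")
  num <- rss_r - rss_f
  eps <- 1e-10 * max(1, rss_r)
  if (num <= eps) {
    Fstat <- 0; p <- 1
  } else if (rss_f <= eps) {
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- num / (rss_f / df2)
    if (Fstat < 0) Fstat <- 0
    p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  }
  slopes <- vapply(split(dat, dat$group),
                   function(d) unname(stats::coef(stats::lm(nhv95 ~ vol_pct, d))[2]),
                   numeric(1))
  structure(list(F = Fstat, p = p, df = c(1L, df2),
                 slope_A = slopes[["A"]], slope_B = slopes[["B"]],
                 fit_full = full, fit_reduced = red),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("slope F-test: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat(sprintf("  slope A = %.4f, slope B = %.4f\n", x$slope_A, x$slope_B))
  invisible(x)
}

#' Mann-Whitney U test with Gaussian approximation
#'
#' Rank-sum test whose p-value comes from the normal approximation to the U
#' statistic. The continuity correction is applied by default and the tie
#' correction is off by default (ties have probability zero for continuous
#' indices); both are toggleable.
#'
#' @param x,y numeric samples.
#' @param correct apply the 0.5 continuity correction.
#' @param tie_correction adjust the variance for ties.
#' @return List with `U` (for sample `x`), `z`, `p` (two-sided).
#' @export
mann_whitney_gauss <- function(x, y, correct = TRUE, tie_correction = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  v <- n1 * n2 * (n1 + n2 + 1) / 12
  if (tie_correction) {
    nt <- table(c(x, y))
    N <- n1 + n2
    v <- n1 * n2 / 12 * ((N + 1) - sum(nt^3 - nt) / (N * (N - 1)))
  }
  if (v <= 0) return(list(U = U, z = 0, p = 1))
  dlt <- U - mu
  if (correct) dlt <- sign(dlt) * max(0, abs(dlt) - 0.5)
  z <- dlt / sqrt(v)
  list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare per-unit fingerprint parameters between groups
#'
#' Signal-amount parameters (a, d, e: positions and projection on the Vol%
#' axis) are compared by two-sided unpaired t-tests; dispersion parameters
#' (b, f, g: positions and projection on the nHv axis) by two-sided
#' Mann-Whitney tests with Gaussian approximation. Zero pooled variance in a
#' t-test is flagged as degenerate rather than reported as an infinite
#' statistic. Differences are flagged at p < `alpha`.
#'
#' @param paramsA,paramsB data.frames of per-unit parameters, one row per
#'   unit, containing (a subset of) columns `a`, `b`, `d`, `e`, `f`, `g`,
#'   `slope`.
#' @param alpha significance level for flagging (default 0.05).
#' @param correct,tie_correction passed to [mann_whitney_gauss()].
#' @return An object of class `param_comparison`: data.frame with one row
#'   per parameter (`parameter`, `test`, `statistic`, `p`, `significant`,
#'   `degenerate`, group means).
#' @export
compare_parameters <- function(paramsA, paramsB, alpha = 0.05,
                               correct = TRUE, tie_correction = FALSE) {
  paramsA <- as.data.frame(paramsA)
  paramsB <- as.data.frame(paramsB)
  # slope is compared by the pooled F-test (compare_slopes), not here;
  # per-unit slopes are descriptive only
  t_params <- c("a", "d", "e")
  pars <- intersect(c("a", "b", "d", "e", "f", "g"),
                    intersect(names(paramsA), names(paramsB)))
  if (length(pars) == 0L) stop("no shared parameter columns")
  rows <- lapply(pars, function(pn) {
    x <- paramsA[[pn]]; y <- paramsB[[pn]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (pn %in% t_params) {
      if (length(x) < 2L || length(y) < 2L)
        stop("t-test needs >= 2 units per group (parameter ", pn, ")")
      s2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
        (length(x) + length(y) - 2)
      if (s2 <= 0) {
        if (mean(x) == mean(y)) {
          stat <- 0; p <- 1; degen <- FALSE
        } else {
          stat <- Inf * sign(mean(x) - mean(y)); p <- 0; degen <- TRUE
        }
      } else {
        tt <- stats::t.test(x, y, var.equal = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value; degen <- FALSE
      }
      data.frame(parameter = pn, test = "t", statistic = stat, p = p,
                 degenerate = degen, mean_A = mean(x), mean_B = mean(y))
    } else {
      mw <- mann_whitney_gauss(x, y, correct = correct,
                               tie_correction = tie_correction)
      data.frame(parameter = pn, test = "mann-whitney", statistic = mw$z,
                 p = mw$p, degenerate = FALSE,
                 mean_A = mean(x), mean_B = mean(y))
    }
  })
  tab <- do.call(rbind, rows)
  tab$significant <- tab$p < alpha
  structure(list(table = tab, alpha = alpha), class = "param_comparison")
}

#' @export
print.param_comparison <- function(x, ...) {
  cat(sprintf("parameter comparison (flagged at p < %g):\n", x$alpha))
  tab <- x$table
  tab$statistic <- signif(tab$statistic, 4)
  tab$p <- signif(tab$p, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
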