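#' Fit a one-phase exponential decay to a time course
#'
#' Least-squares fit of `N(t) = N0 * exp(-k * t)` to a transcription-
#' blockade (actinomycin D) series, initialized from the log-linear
#' regression slope and polished by nonlinear least squares. The
#' half-life is `t_half = ln(2) / k`. Non-decaying data (fitted
#' `k <= 0`) is flagged and reported with `t_half = Inf`.
#'
#' @param times Hours, strictly increasing, starting at 0.
#' @param abundance Positive relative abundance (typically % of t = 0).
#' @return List with `k` (per hour), `t_half` (hours), `n0`, and logical
#'   `decaying`.
#' @export
fit_decay <- function(times, abundance) {
  if (length(times) < 3L) stop("need at least 3 time points")
  if (length(times) != length(abundance)) stop("length mismatch")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (times[1L] != 0) stop("series must include t = 0")
  if (any(abundance <= 0)) stop("abundance must be positive")
  ll <- stats::lm.fit(cbind(1, times), log(abundance))
  k0 <- -ll$coefficients[2L]
  n0_0 <- exp(ll$coefficients[1L])
  sse <- function(p) sum((abundance - p[1L] * exp(-p[2L] * times))^2)
  fit <- stats::optim(c(n0_0, max(k0, 1e-6)), sse, method = "L-BFGS-B",
                      lower = c(1e-9, -Inf),
                      control = list(factr = 1e1, maxit = 500))
  # polish with an unconstrained pass from the solution
  fit2 <- stats::optim(fit$par, sse, method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 500))
  if (fit2$value <= fit$value) fit <- fit2
  k <- unname(fit$par[2L]); n0 <- unname(fit$par[1L])
  if (k <= 0) {
    return(list(k = k, t_half = Inf, n0 = n0, decaying = FALSE))
  }
  list(k = k, t_half = log(2) / k, n0 = n0, decaying = TRUE)
}

#' Fit a four-parameter log-logistic (4PL) dose-response curve
#'
#' Models inhibition as
#' `y(d) = floor + (ceiling - floor) / (1 + (midpoint/d)^slope)`
#' with `y(0) = floor`; with positive slope the curve is monotone
#' increasing and invertible on `(floor, ceiling)`.
#'
#' @param doses Non-negative doses (>= 4 distinct values including 0).
#' @param responses Inhibition percentages in `[0, 100]`.
#' @return An object of class `DoseResponseFit` with elements `floor`,
#'   `ceiling`, `midpoint`, `slope`, `degenerate` (flat-response flag),
#'   plus `predict` and `inverse` functions.
#' @export
fit_dose_response <- function(doses, responses) {
  if (length(doses) != length(responses)) stop("length mismatch")
  if (length(unique(doses)) < 4L || !any(doses == 0))
    stop("need >= 4 distinct doses including 0")
  if (any(responses < -1e-9) || any(responses > 100 + 1e-9))
    stop("responses must lie in [0, 100]")
  rng <- range(responses)
  if (diff(rng) < 1e-8) {
    fit <- .dr_fit_obj(rng[1L], rng[1L], stats::median(doses[doses > 0]), 1,
                       degenerate = TRUE)
    return(fit)
  }
  pos <- doses > 0
  mid0 <- exp(stats::weighted.mean(log(doses[pos]),
                                   w = abs(responses[pos] - mean(rng)) + 1e-6))
  p0 <- c(floor = max(rng[1L], 0), ceiling = min(rng[2L], 100),
          lmid = log(mid0), lslope = 0)
  sse <- function(p) {
    y <- .dr_curve(doses, p[1L], p[2L], exp(p[3L]), exp(p[4L]))
    sum((responses - y)^2)
  }
  fit <- stats::optim(p0, sse, method = "L-BFGS-B",
                      lower = c(0, 0, log(1e-12), log(1e-3)),
                      upper = c(100, 100, log(1e12), log(1e3)),
                      control = list(factr = 1e1, maxit = 2000))
  fit2 <- stats::optim(fit$par, sse, method = "Nelder-Mead",
                       control = list(reltol = 1e-15, maxit = 5000))
  if (fit2$value < fit$value) fit <- fit2
  fit3 <- stats::optim(fit$par, sse, method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 1000))
  if (fit3$value < fit$value) fit <- fit3
  p <- fit$par
  .dr_fit_obj(unname(p[1L]), unname(p[2L]), exp(unname(p[3L])),
              exp(unname(p[4L])), degenerate = FALSE)
}

.dr_curve <- function(d, floor, ceiling, midpoint, slope) {
  y <- rep(floor, length(d))
  pos <- d > 0
  y[pos] <- floor + (ceiling - floor) / (1 + (midpoint / d[pos])^slope)
  y
}

.dr_fit_obj <- function(floor, ceiling, midpoint, slope, degenerate) {
  obj <- list(floor = floor, ceiling = ceiling, midpoint = midpoint,
              slope = slope, degenerate = degenerate)
  obj$predict <- function(d) .dr_curve(d, floor, ceiling, midpoint, slope)
  # inverse only defined on (floor, ceiling)
  obj$inverse <- function(y) {
    out <- rep(NA_real_, length(y))
    ok <- y > floor & y < ceiling
    out[ok] <- midpoint * ((y[ok] - floor) / (ceiling - y[ok]))^(1 / slope)
    out
  }
  class(obj) <- "DoseResponseFit"
  obj
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  cat(sprintf("DoseResponseFit: floor=%.3g ceiling=%.3g midpoint=%.4g slope=%.3g%s\n",
              x$floor, x$ceiling, x$midpoint, x$slope,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Construct a dose-response matrix
#'
#' @param doses_a,doses_b Dose grids, each including 0.
#' @param response Matrix of inhibition % (`length(doses_a)` rows x
#'   `length(doses_b)` columns); row `dose_b = 0` and column
#'   `dose_a = 0` are the monotherapies.
#' @return An object of class `DoseResponseMatrix`.
#' @export
dose_response_matrix <- function(doses_a, doses_b, response) {
  if (!any(doses_a == 0) || !any(doses_b == 0))
    stop("dose grids must include 0")
  response <- as.matrix(response)
  if (nrow(response) != length(doses_a) || ncol(response) != length(doses_b))
    stop("response matrix dimensions must match dose grids")
  structure(list(doses_a = doses_a, doses_b = doses_b, response = response),
            class = "DoseResponseMatrix")
}

#' Read a dose-response matrix from TSV text
#'
#' Layout: first row holds drug-B doses (first cell empty or a label),
#' first column drug-A doses, body the readings. Viability readings are
#' converted to inhibition as `100 - viability` when
#' `values = "viability"`.
#'
#' @param stream Path or character vector of TSV lines.
#' @param values `"inhibition"` (default) or `"viability"`.
#' @return A `DoseResponseMatrix` (inhibition scale).
#' @export
read_dose_matrix <- function(stream, values = c("inhibition", "viability")) {
  values <- match.arg(values)
  lines <- if (length(stream) == 1L && !grepl("[\t\n]", stream) &&
               file.exists(stream)) readLines(stream) else
    unlist(strsplit(stream, "\n", fixed = TRUE), use.names = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  doses_b <- as.numeric(rows[[1L]][-1L])
  body <- do.call(rbind, lapply(rows[-1L], function(r) as.numeric(r)))
  doses_a <- body[, 1L]
  resp <- body[, -1L, drop = FALSE]
  if (values == "viability") resp <- 100 - resp
  dose_response_matrix(doses_a, doses_b, resp)
}

#' Loewe-additivity expected inhibition for each combination cell
#'
#' Under Loewe additivity the expected combination effect y at doses
#' `(d1, d2)` solves the isobole equation
#' `d1 / D1(y) + d2 / D2(y) = 1`, where `Di(y)` is the dose of drug i
#' alone producing effect y (the inverse monotherapy curve). The
#' equation is solved by bisection on the overlap of the two curves'
#' response ranges (tolerance 1e-6, max 200 iterations). Monotherapy
#' cells reduce to the corresponding fitted curve; cells whose solution
#' lies outside both invertible ranges are `NA` (undefined).
#'
#' @param drm A `DoseResponseMatrix`.
#' @param fit_a,fit_b `DoseResponseFit` monotherapy fits for drugs A
#'   (rows) and B (columns).
#' @param tol Bisection tolerance on the response scale.
#' @return Numeric matrix of expected inhibition, same shape as
#'   `drm$response`.
#' @export
loewe_reference <- function(drm, fit_a, fit_b, tol = 1e-6) {
  stopifnot(inherits(drm, "DoseResponseMatrix"))
  if (fit_a$degenerate || fit_b$degenerate)
    stop("monotherapy fit is degenerate; Loewe reference undefined")
  da <- drm$doses_a; db <- drm$doses_b
  lo <- max(fit_a$floor, fit_b$floor)
  hi <- min(fit_a$ceiling, fit_b$ceiling)
  exp_mat <- matrix(NA_real_, length(da), length(db))
  for (i in seq_along(da)) {
    for (j in seq_along(db)) {
      d1 <- da[i]; d2 <- db[j]
      if (d1 == 0 && d2 == 0) { exp_mat[i, j] <- 0; next }
      if (d2 == 0) { exp_mat[i, j] <- fit_a$predict(d1); next }
      if (d1 == 0) { exp_mat[i, j] <- fit_b$predict(d2); next }
      if (hi <= lo) next
      f <- function(y) d1 / fit_a$inverse(y) + d2 / fit_b$inverse(y) - 1
      a <- lo + (hi - lo) * 1e-9
      b <- hi - (hi - lo) * 1e-9
      fa <- f(a); fb <- f(b)
      if (!is.finite(fa) || !is.finite(fb) || fa < 0 || fb > 0) {
        # no root inside the joint invertible range -> undefined cell
        next
      }
      for (it in seq_len(200L)) {
        m <- (a + b) / 2
        fm <- f(m)
        if (!is.finite(fm)) break
        if (abs(b - a) < tol) break
        if (fm > 0) a <- m else b <- m
      }
      exp_mat[i, j] <- (a + b) / 2
    }
  }
  exp_mat
}

#' Score a dose-response matrix against the Loewe reference
#'
#' Per-cell excess is observed minus Loewe-expected inhibition
#' (percentage points). The overall score is the mean excess over
#' defined combination cells only (monotherapy rows/columns excluded),
#' classified by the standard thresholds: score > 10 synergistic,
#' score < -10 antagonistic, otherwise additive.
#'
#' @param drm A `DoseResponseMatrix` (observed inhibition).
#' @param expected Loewe expected matrix from [loewe_reference()].
#' @return An object of class `SynergyResult`: list with `excess`
#'   (matrix, `NA` on monotherapy/undefined cells), `score` (mean
#'   excess), `classification`, `n_cells` (defined combination cells).
#' @export
synergy_score_and_classify <- function(drm, expected) {
  stopifnot(inherits(drm, "DoseResponseMatrix"))
  combo <- outer(drm$doses_a > 0, drm$doses_b > 0, `&`)
  excess <- drm$response - expected
  excess[!combo] <- NA_real_
  defined <- combo & !is.na(expected)
  if (!any(defined)) stop("no defined combination cell")
  score <- mean(excess[defined])
  cls <- if (score > 10) "synergistic" else if (score < -10) "antagonistic" else "additive"
  structure(list(excess = excess, score = score, classification = cls,
                 n_cells = sum(defined)),
            class = "SynergyResult")
}

#' @export
print.SynergyResult <- function(x, ...) {
  cat(sprintf("SynergyResult: overall score %.2f (%s) over %d combination cell(s)\n",
              x$score, x$classification, x$n_cells))
  invisible(x)
}
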