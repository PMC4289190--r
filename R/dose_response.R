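# Dose-response readout of a classified plate.
#
# Survival fraction = 1 - Dead fraction per concentration; teratogenicity
# response = fraction of surviving larvae that are not Normal. Both are
# fitted with a four-parameter log-logistic curve on log10 concentration
# (the untreated control is mapped to a pseudo-log floor two decades below
# the lowest dose), by weighted least squares with binomial weights; the
# midpoints give LC50 and EC50 and the teratogenicity index is
# TI = LC50 / EC50.

#' Tabulate per-concentration counts from classified label sets
#'
#' @param concentration numeric vector, one entry per larva.
#' @param labels list of label sets (or `;`-separated strings), one per
#'   larva.
#' @return A data frame with columns `concentration`, `n` (larvae), `dead`
#'   and `normal` (Normal calls among survivors).
#' @export
plate_counts <- function(concentration, labels) {
  if (is.character(labels)) labels <- parse_labels(labels)
  dead <- vapply(labels, function(s) "Dead" %in% s, logical(1))
  normal <- vapply(labels, function(s) "Normal" %in% s, logical(1)) & !dead
  agg <- function(v) as.numeric(tapply(v, concentration, sum))
  conc <- sort(unique(concentration))
  data.frame(concentration = conc,
             n = as.numeric(table(factor(concentration, levels = conc))),
             dead = agg(dead), normal = agg(normal))
}

# 4PL on log10 dose: f(x) = cl + (cu - cl) / (1 + 10^(h * (m - x)))
four_pl <- function(x, cl, cu, m, h) cl + (cu - cl) / (1 + 10^(h * (m - x)))

# Weighted least-squares 4PL fit of an increasing fractional response.
# y = k/n fractions; weights n / (p(1-p)) with continuity-corrected p, and
# parameter covariance taken unscaled (the sampling variance of each
# fraction is known from its denominator, so the residual mean square is
# not used to scale it).
fit_4pl <- function(x, y, n, hill_range = c(0.05, 5)) {
  ok <- is.finite(y) & n > 0
  x <- x[ok]
  y <- y[ok]
  n <- n[ok]
  if (length(x) < 4) {
    return(list(converged = FALSE, reason = "fewer than 4 usable points"))
  }
  pt <- (y * n + 0.5) / (n + 1)
  w <- n / (pt * (1 - pt))
  m0 <- {
    mid <- (min(y) + max(y)) / 2
    x[which.min(abs(y - mid))]
  }
  starts <- expand.grid(h = unique(pmin(pmax(c(0.7, 1.5, 3, 6), hill_range[1]),
                                        hill_range[2] * 0.9)),
                        m = unique(c(m0, stats::median(x))))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ four_pl(x, cl, cu, m, h),
      start = list(cl = max(min(y), 0), cu = min(max(y), 1),
                   m = starts$m[s], h = starts$h[s]),
      lower = c(0, 0, min(x) - 3, hill_range[1]),
      upper = c(1, 1, max(x) + 3, hill_range[2]),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(list(converged = FALSE, reason = "no start converged"))
  }
  fit <- best$fit
  par <- coef(fit)
  cov_unscaled <- try(summary(fit)$cov.unscaled, silent = TRUE)
  se_m <- if (inherits(cov_unscaled, "try-error")) NA_real_ else {
    sqrt(pmax(cov_unscaled["m", "m"], 0))
  }
  list(converged = TRUE, par = par, se_log10_mid = se_m,
       cov_unscaled = if (inherits(cov_unscaled, "try-error")) NULL else cov_unscaled,
       x = x, y = y, n = n)
}

#' Fit dose-response curves and derive LC50, EC50 and TI
#'
#' @param counts data frame from [plate_counts()] (columns `concentration`,
#'   `n`, `dead`, `normal`); needs at least 4 concentrations including an
#'   untreated control (`concentration == 0`) and at least one larva per
#'   concentration.
#' @param control_floor_decades how many decades below the lowest non-zero
#'   dose the control is placed on the log axis.
#' @param hill_range plausibility bounds for the Hill slope. Sparse
#'   log-spaced designs often leave the slope unidentified upward; an
#'   unbounded slope then produces step-like interpolating fits with a
#'   degenerate parameter covariance, so the slope is kept within a
#'   toxicologically plausible range by default.
#' @return An object of class `dose_response_fit` with the
#'   per-concentration fractions (`$table`), the two fitted curves
#'   (`$survival_fit` for mortality, `$terato_fit` for the abnormal
#'   fraction among survivors), `LC50`, `EC50`, `TI` and their `log10`
#'   summaries with standard errors (delta method for TI). When a curve
#'   fails to converge the raw fractions are still returned and the
#'   corresponding estimates are `NA`.
#' @export
dose_response <- function(counts, control_floor_decades = 2,
                          hill_range = c(0.05, 5)) {
  need <- c("concentration", "n", "dead", "normal")
  if (!all(need %in% names(counts))) {
    zs_stop(paste0("counts needs columns: ", paste(need, collapse = ", ")),
            "zs_data_error")
  }
  counts <- counts[order(counts$concentration), , drop = FALSE]
  if (nrow(counts) < 4 || !any(counts$concentration == 0)) {
    zs_stop("need >= 4 concentrations including an untreated control",
            "zs_data_error")
  }
  if (any(counts$n < 1)) zs_stop("need >= 1 larva per concentration", "zs_data_error")
  if (any(counts$dead > counts$n) ||
      any(counts$normal > counts$n - counts$dead)) {
    zs_stop("inconsistent counts (dead > n, or normal > survivors)",
            "zs_data_error")
  }
  lowest <- min(counts$concentration[counts$concentration > 0])
  x <- ifelse(counts$concentration > 0, log10(counts$concentration),
              log10(lowest) - control_floor_decades)
  surviving <- counts$n - counts$dead
  tab <- data.frame(
    concentration = counts$concentration, log10_dose = x, n = counts$n,
    dead = counts$dead, surviving = surviving,
    survival_frac = 1 - counts$dead / counts$n,
    normal = counts$normal,
    terato_frac = ifelse(surviving > 0, 1 - counts$normal / surviving, NA)
  )
  sfit <- fit_4pl(x, counts$dead / counts$n, counts$n,
                  hill_range) # mortality, increasing
  tfit <- fit_4pl(x, tab$terato_frac, surviving, hill_range)
  log10_lc50 <- if (sfit$converged) unname(sfit$par["m"]) else NA_real_
  log10_ec50 <- if (tfit$converged) unname(tfit$par["m"]) else NA_real_
  se_l <- if (sfit$converged) sfit$se_log10_mid else NA_real_
  se_e <- if (tfit$converged) tfit$se_log10_mid else NA_real_
  out <- list(
    table = tab,
    survival_fit = sfit,
    terato_fit = tfit,
    LC50 = 10^log10_lc50,
    EC50 = 10^log10_ec50,
    TI = 10^log10_lc50 / 10^log10_ec50,
    log10 = c(LC50 = log10_lc50, EC50 = log10_ec50,
              TI = log10_lc50 - log10_ec50),
    log10_se = c(LC50 = se_l, EC50 = se_e,
                 TI = sqrt(se_l^2 + se_e^2)), # delta method, independent fits
    control_floor_decades = control_floor_decades
  )
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Dose-response fit (4-parameter log-logistic, weighted least squares)\n")
  fmt <- function(v, se) {
    if (is.na(v)) "fit failed" else sprintf("%.3f +/- %.3f", v, se)
  }
  cat("  log10(LC50):", fmt(x$log10["LC50"], x$log10_se["LC50"]), "\n")
  cat("  log10(EC50):", fmt(x$log10["EC50"], x$log10_se["EC50"]), "\n")
  cat("  log10(TI):  ", fmt(x$log10["TI"], x$log10_se["TI"]), "\n")
  invisible(x)
}

#' @export
summary.dose_response_fit <- function(object, ...) {
  print(object)
  cat("\nPer-concentration fractions:\n")
  print(object$table, row.names = FALSE)
  invisible(object)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(LC50 = unname(object$LC50), EC50 = unname(object$EC50),
    TI = unname(object$TI))
}

#' Predicted survival and teratogenicity fractions at given doses
#'
#' @param object a [dose_response()] fit.
#' @param concentration numeric vector of doses (> 0).
#' @param ... unused.
#' @export
predict.dose_response_fit <- function(object, concentration, ...) {
  x <- log10(concentration)
  sv <- if (object$survival_fit$converged) {
    1 - four_pl(x, object$survival_fit$par["cl"], object$survival_fit$par["cu"],
                object$survival_fit$par["m"], object$survival_fit$par["h"])
  } else rep(NA_real_, length(x))
  tr <- if (object$terato_fit$converged) {
    four_pl(x, object$terato_fit$par["cl"], object$terato_fit$par["cu"],
            object$terato_fit$par["m"], object$terato_fit$par["h"])
  } else rep(NA_real_, length(x))
  data.frame(concentration = concentration, survival_frac = sv,
             terato_frac = tr)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  tab <- x$table
  plot(tab$log10_dose, tab$survival_frac, ylim = c(0, 1), pch = 16,
       xlab = "log10 concentration", ylab = "fraction",
       main = "Dose-response", ...)
  points(tab$log10_dose, tab$terato_frac, pch = 17, col = "firebrick")
  xs <- seq(min(tab$log10_dose), max(tab$log10_dose), length.out = 200)
  if (x$survival_fit$converged) {
    p <- x$survival_fit$par
    lines(xs, 1 - four_pl(xs, p["cl"], p["cu"], p["m"], p["h"]))
  }
  if (x$terato_fit$converged) {
    p <- x$terato_fit$par
    lines(xs, four_pl(xs, p["cl"], p["cu"], p["m"], p["h"]), col = "firebrick")
  }
  legend("left", legend = c("survival", "teratogenicity"),
         col = c("black", "firebrick"), pch = c(16, 17), bty = "n")
  invisible(x)
}
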