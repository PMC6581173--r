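#' Fit a three-parameter logistic growth model
#'
#' Least-squares fit of the logistic
#' \eqn{N(t) = K N_0 e^{\mu t} / (K + N_0 (e^{\mu t} - 1))}
#' to one culture's density time series.  The residual is taken on
#' ln-density, matching the multiplicative error structure of cell counts.
#' Optimisation is bounded L-BFGS-B over \eqn{(\mu, \ln K, \ln N_0)},
#' initialised from the data: \eqn{K} at 1.05 times the maximum observed
#' density, \eqn{N_0} at the first observation and \eqn{\mu} at the
#' exponential-window slope.
#'
#' @param data Data frame with columns `time_d` (days, strictly increasing)
#'   and `cells_per_ml` (positive), one replicate curve.  At least 4 points
#'   spanning at least a 2-fold density range.
#' @return A `logistic_fit` object with elements `mu` (per day), `K`, `N0`
#'   (cells/ml), `rss` (residual sum of squares on ln-density), `converged`
#'   and `n`.  On optimiser failure `converged` is `FALSE` and the parameters
#'   are the best point reached, never silent garbage.  A series spanning
#'   less than a 2-fold density range (including a constant series) carries
#'   no logistic signal and returns `mu = 0` with `converged = FALSE`.
#' @seealso [exponential_growth_rate()], [tidy.logistic_fit()]
#' @examples
#' cfg <- sim_config(noise_cv = 0, seed = 1)
#' curve <- dplyr::filter(simulate_growth_curves(cfg, n_rep = 1),
#'   substrate == "phosphate")
#' fit_logistic(curve)
#' @export
fit_logistic <- function(data) {
  d <- check_curve(data, min_points = 4)
  if (max(d$cells_per_ml) < 2 * min(d$cells_per_ml)) {
    # no growth signal to fit: report a flagged degenerate fit, not garbage
    return(structure(
      list(
        mu = 0, K = max(d$cells_per_ml), N0 = d$cells_per_ml[1],
        rss = NA_real_, converged = FALSE, n = nrow(d)
      ),
      class = "logistic_fit"
    ))
  }
  ln_n <- log(d$cells_per_ml)
  mu0 <- exponential_growth_rate(d)$mu
  theta0 <- c(mu = max(mu0, 1e-3), lnK = log(1.05 * max(d$cells_per_ml)),
              lnN0 = ln_n[1])
  t <- d$time_d
  obj <- function(th) {
    pred <- logistic_density(t, th[1], exp(th[2]), exp(th[3]))
    sum((ln_n - log(pred))^2)
  }
  grad <- function(th) {
    mu <- th[1]
    K <- exp(th[2])
    N0 <- exp(th[3])
    E <- exp(mu * t)
    D <- K + N0 * (E - 1)
    r <- ln_n - (th[2] + th[3] + mu * t - log(D))
    c(
      -2 * sum(r * (t - N0 * t * E / D)),
      -2 * sum(r * (1 - K / D)),
      -2 * sum(r * (1 - N0 * (E - 1) / D))
    )
  }
  lower <- c(0, log(0.5 * max(d$cells_per_ml)), log(.Machine$double.xmin))
  upper <- c(20, log(1e3 * max(d$cells_per_ml)), log(max(d$cells_per_ml)))
  fit <- tryCatch(
    optim(theta0, obj, grad,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 2000, factr = 10, pgtol = 0)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    res <- list(mu = mu0, K = max(d$cells_per_ml), N0 = d$cells_per_ml[1],
                rss = NA_real_, converged = FALSE, n = nrow(d))
  } else {
    res <- list(
      mu = unname(fit$par[1]), K = unname(exp(fit$par[2])),
      N0 = unname(exp(fit$par[3])), rss = fit$value,
      converged = fit$convergence == 0, n = nrow(d)
    )
  }
  structure(res, class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> mu = %.4g /d, K = %.4g cells/ml, N0 = %.4g cells/ml\n",
    x$mu, x$K, x$N0
  ))
  cat(sprintf(
    "  ln-density RSS %.4g over %d points; converged: %s\n",
    x$rss, x$n, x$converged
  ))
  invisible(x)
}

#' Tidy a logistic growth fit
#'
#' @param x A [fit_logistic()] result.
#' @param ... Unused.
#' @return One row per parameter (`mu`, `K`, `N0`) with its estimate.
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(
    term = c("mu", "K", "N0"),
    estimate = c(x$mu, x$K, x$N0),
    unit = c("per day", "cells/ml", "cells/ml")
  )
}

#' @rdname tidy.logistic_fit
#' @return `glance()`: a one-row tibble with fit diagnostics.
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, converged = x$converged)
}

#' Specific growth rate from the exponential window
#'
#' Estimates the specific growth rate as the ordinary least-squares slope of
#' ln-density versus time over a contiguous "exponential" window.  The window
#' is chosen deterministically: all contiguous windows of at least 4 points
#' (or all points when only 3 are supplied) whose densities stay at or below
#' half the maximum observed density are scanned, and the window with the
#' highest r-squared wins; ties go to the longer window, then the earlier
#' start.  If no window clears the half-maximum cap (the series never
#' approaches saturation), all windows compete, which reduces to the full
#' series for clean exponential data.
#'
#' @param data Data frame with columns `time_d` and `cells_per_ml`
#'   (>= 3 points).
#' @return A `rate_estimate` object: `mu` (per day), `window` (start and end
#'   row indices), `r2` and `n_points`.  A constant series returns `mu = 0`
#'   with `r2 = NA`, flagged via `degenerate = TRUE`.
#' @examples
#' doubling <- tibble::tibble(
#'   time_d = 0:3,
#'   cells_per_ml = c(1, 2, 4, 8) * 1e6
#' )
#' exponential_growth_rate(doubling)$mu # log(2)
#' @export
exponential_growth_rate <- function(data) {
  d <- check_curve(data, min_points = 3)
  n <- nrow(d)
  ln_n <- log(d$cells_per_ml)
  if (diff(range(ln_n)) == 0) {
    return(structure(
      list(mu = 0, window = c(1L, n), r2 = NA_real_, n_points = n,
           degenerate = TRUE),
      class = "rate_estimate"
    ))
  }
  min_len <- min(4L, n)
  cap <- max(d$cells_per_ml) / 2
  wins <- window_candidates(n, min_len)
  in_cap <- purrr::map_lgl(wins, function(w) {
    max(d$cells_per_ml[w[1]:w[2]]) <= cap
  })
  if (any(in_cap)) wins <- wins[in_cap]
  stats <- vapply(wins, function(w) {
    i <- w[1]:w[2]
    c(w[1], w[2], length(i), ols_slope_r2(d$time_d[i], ln_n[i]))
  }, numeric(5))
  ord <- order(-round(stats[5, ], 12), -stats[3, ], stats[1, ])
  best <- stats[, ord[1]]
  structure(
    list(
      mu = best[4], window = c(best[1], best[2]), r2 = best[5],
      n_points = as.integer(best[3]), degenerate = FALSE
    ),
    class = "rate_estimate"
  )
}

# closed-form simple OLS; r2 = 1 for a perfectly flat window (zero residual)
ols_slope_r2 <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  syy <- sum(yc^2)
  sxy <- sum(xc * yc)
  slope <- sxy / sxx
  r2 <- if (syy == 0) 1 else sxy^2 / (sxx * syy)
  c(slope, r2)
}

window_candidates <- function(n, min_len) {
  out <- list()
  for (s in seq_len(n - min_len + 1)) {
    for (e in seq(s + min_len - 1, n)) out[[length(out) + 1]] <- c(s, e)
  }
  out
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<rate_estimate> mu = %.4g /d over points %d-%d (r2 = %.4f)\n",
    x$mu, x$window[1], x$window[2],
    if (is.na(x$r2)) NA else x$r2
  ))
  invisible(x)
}

#' @rdname tidy.logistic_fit
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble(
    term = "mu", estimate = x$mu, unit = "per day",
    r2 = x$r2, n_points = x$n_points,
    window_start = x$window[1], window_end = x$window[2]
  )
}

#' Growth-rate and yield summary per substrate and replicate
#'
#' Applies [exponential_growth_rate()] and (optionally) [fit_logistic()] to
#' every substrate-replicate curve of a long density table and returns a
#' tidy table of estimates.
#'
#' @param data Data frame with columns `substrate`, `replicate`, `time_d`,
#'   `cells_per_ml` (the growth-curve CSV schema).
#' @param model `"window"` for the log-linear window estimator alone, or
#'   `"logistic"` to add logistic parameter estimates per curve.
#' @return A tibble with one row per substrate x replicate: `mu_window`,
#'   `r2`, `max_density`, and for `model = "logistic"` also `mu_logistic`,
#'   `K`, `N0`, `converged`.
#' @examples
#' curves <- simulate_growth_curves(sim_config(seed = 1))
#' growth_rates(curves)
#' @export
growth_rates <- function(data, model = c("window", "logistic")) {
  model <- match.arg(model)
  need <- c("substrate", "replicate", "time_d", "cells_per_ml")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns substrate, replicate, time_d, cells_per_ml.")
  }
  data %>%
    group_by(.data$substrate, .data$replicate) %>%
    dplyr::group_modify(function(d, key) {
      w <- exponential_growth_rate(d)
      out <- tibble(
        mu_window = w$mu, r2 = w$r2, max_density = max(d$cells_per_ml)
      )
      if (model == "logistic") {
        f <- fit_logistic(d)
        out <- mutate(out,
          mu_logistic = f$mu, K = f$K, N0 = f$N0, converged = f$converged
        )
      }
      out
    }) %>%
    ungroup()
}

#' Mean maximum cell yield across replicate curves
#'
#' @param data Growth-curve table (`substrate`, `replicate`, `time_d`,
#'   `cells_per_ml`); may hold several substrates.
#' @return A tibble with one row per substrate: `max_yield` is the mean over
#'   replicates of each curve's maximum density (cells/ml), `n_rep` the
#'   replicate count.
#' @examples
#' curves <- simulate_growth_curves(sim_config(noise_cv = 0, seed = 1))
#' max_yield(curves)
#' @export
max_yield <- function(data) {
  need <- c("substrate", "replicate", "cells_per_ml")
  if (!all(need %in% names(data)) || nrow(data) == 0) {
    abort("`data` must be a non-empty growth-curve table.")
  }
  data %>%
    group_by(.data$substrate, .data$replicate) %>%
    summarise(peak = max(.data$cells_per_ml), .groups = "drop_last") %>%
    summarise(max_yield = mean(.data$peak), n_rep = n(), .groups = "drop")
}

check_curve <- function(data, min_points) {
  if (!all(c("time_d", "cells_per_ml") %in% names(data))) {
    abort("curve data needs columns `time_d` and `cells_per_ml`.")
  }
  d <- as_tibble(data)[, c("time_d", "cells_per_ml")]
  if (nrow(d) < min_points) {
    abort(sprintf("at least %d time points are required.", min_points))
  }
  if (any(diff(d$time_d) <= 0)) abort("`time_d` must be strictly increasing.")
  if (any(!is.finite(d$cells_per_ml)) || any(d$cells_per_ml <= 0)) {
    abort("densities must be finite and positive.")
  }
  d
}

#' Plot growth curves with fitted trajectories
#'
#' @param data Growth-curve table (long format).
#' @param fit Add the per-substrate logistic fit as a dashed line?
#' @return A ggplot: ln-scaled density against time, coloured by substrate.
#' @export
plot_growth_curves <- function(data, fit = TRUE) {
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$time_d, y = .data$cells_per_ml, colour = .data$substrate)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Time (days)", y = "Cell density (cells/ml)", colour = "P source"
    ) +
    ggplot2::theme_minimal()
  if (fit) {
    fits <- data %>%
      group_by(.data$substrate) %>%
      dplyr::group_modify(function(d, key) {
        f <- fit_logistic(arrange(d, .data$time_d) %>%
          group_by(.data$time_d) %>%
          summarise(cells_per_ml = mean(.data$cells_per_ml), .groups = "drop"))
        tt <- seq(min(d$time_d), max(d$time_d), length.out = 100)
        tibble(time_d = tt, cells_per_ml = logistic_density(tt, f$mu, f$K, f$N0))
      }) %>%
      ungroup()
    p <- p + ggplot2::geom_line(
      data = fits, linetype = "dashed", alpha = 0.8
    )
  }
  p
}
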