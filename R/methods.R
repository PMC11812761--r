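#' @export
print.ems_sim <- function(x, ...) {
  cat("Lives saved by introducing the ambulance service\n")
  cat(sprintf("  scenario: %s; beta = %g min, s = %g\n",
              x$scenario$choice_rule, x$params$beta, x$params$s))
  cat(sprintf("  mean %.2f lives/year (95%% CrI %.2f to %.2f) from %d replications\n",
              x$mean_delta, x$cri_low, x$cri_high, x$n_reps))
  if (x$n_unreachable > 0)
    cat(sprintf("  %d unreachable cells contributed nothing under either mode\n",
                x$n_unreachable))
  invisible(x)
}

#' @export
summary.ems_sim <- function(object, ...) {
  qs <- if (!is.null(object$draws)) {
    stats::quantile(object$draws, c(0.025, 0.25, 0.5, 0.75, 0.975))
  } else NULL
  out <- list(mean_delta = object$mean_delta, cri_low = object$cri_low,
              cri_high = object$cri_high, quantiles = qs,
              n_reps = object$n_reps, n_unreachable = object$n_unreachable,
              scenario = object$scenario, params = object$params)
  class(out) <- "summary.ems_sim"
  out
}

#' @export
print.summary.ems_sim <- function(x, ...) {
  cat("Monte Carlo lives-saved estimate\n")
  cat(sprintf("  replications: %d; scenario: %s\n", x$n_reps,
              x$scenario$choice_rule))
  cat(sprintf("  mean: %.3f lives/year; 95%% CrI [%.3f, %.3f]\n",
              x$mean_delta, x$cri_low, x$cri_high))
  if (!is.null(x$quantiles)) {
    cat("  replication quantiles:\n")
    print(round(x$quantiles, 3))
  }
  cat(sprintf("  unreachable cells excluded: %d\n", x$n_unreachable))
  print(x$params)
  invisible(x)
}

#' Plot a lives-saved simulation
#'
#' `type = "map"` draws the per-cell mean lives-saved surface;
#' `type = "draws"` a histogram of the replication distribution with the
#' mean and 95% credible bounds marked.
#'
#' @param x An `ems_sim` object.
#' @param type `"map"` or `"draws"`.
#' @param ... Passed to the underlying plotting function.
#' @export
plot.ems_sim <- function(x, type = c("map", "draws"), ...) {
  type <- match.arg(type)
  if (type == "map") {
    plot(x$mean_map, main = "mean lives saved per cell per year", ...)
  } else {
    if (is.null(x$draws)) stop("draws were not kept; rerun with keep_draws = TRUE")
    graphics::hist(x$draws, breaks = 50, main = "replication distribution",
                   xlab = "lives saved per year", ...)
    graphics::abline(v = c(x$cri_low, x$mean_delta, x$cri_high),
                     lty = c(2, 1, 2), col = "red")
  }
  invisible(x)
}

#' @export
print.ems_grid <- function(x, ...) {
  cat(sprintf("Lives saved per year (scenario: %s, %d replications)\n",
              attr(x, "scenario"), attr(x, "n_reps")))
  print.data.frame(cbind(x[, c("beta", "s")],
                         round(x[, c("mean", "cri_low", "cri_high")], 2)),
                   row.names = FALSE)
  invisible(x)
}
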