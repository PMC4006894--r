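#' @export
print.thermo_fit <- function(x, ...) {
  cat("Hierarchical thermodynamic growth-rate model fit\n")
  cat(sprintf("  %d strains in %d group(s); %d records\n",
              length(x$strain_ids), length(x$groups), nrow(x$records)))
  cat(sprintf("  %d iterations (burn-in %.0f%%, thin %d, seed %d), %.1f s\n",
              x$iterations, 100 * x$burn_in, x$thin, x$seed, x$runtime))
  u <- x$posterior[grepl("^u\\.", x$posterior$parameter), ]
  cat("  Universal parameters (posterior mean [99% HPDI]):\n")
  for (i in seq_len(nrow(u)))
    cat(sprintf("    %-10s %s\n", sub("^u\\.", "", u$parameter[i]),
                format_hpdi(u$mean[i], u$lower99[i], u$upper99[i])))
  invisible(x)
}

#' @export
summary.thermo_fit <- function(object, ...) {
  keep <- !grepl("^strain\\.", object$posterior$parameter)
  out <- list(posterior = object$posterior[keep, ],
              strains = object$posterior[!keep, ],
              acceptance = object$acceptance,
              iterations = object$iterations, burn_in = object$burn_in)
  class(out) <- "summary.thermo_fit"
  out
}

#' @export
print.summary.thermo_fit <- function(x, ...) {
  cat("Posterior summary (universal, group-level and precision parameters):\n")
  df <- x$posterior
  df$mean <- signif(df$mean, 5); df$sd <- signif(df$sd, 3)
  df$lower99 <- signif(df$lower99, 5); df$upper99 <- signif(df$upper99, 5)
  df$rhat <- round(df$rhat, 3); df$ess <- round(df$ess)
  print(df, row.names = FALSE)
  cat(sprintf("\nAcceptance rates: strain %.2f, group %.2f, tau %.2f, universal %.2f\n",
              x$acceptance[["strain"]], x$acceptance[["group"]],
              x$acceptance[["tau"]], x$acceptance[["universal"]]))
  invisible(x)
}

#' Posterior-mean coefficients
#'
#' @param object a [thermo_fit] object.
#' @param which one of `"universal"`, `"group"`, `"strain"`, `"tau"`,
#'   `"all"`.
#' @param ... unused.
#' @return Named numeric vector of posterior means.
#' @export
coef.thermo_fit <- function(object, which = c("all", "universal", "group",
                                              "strain", "tau"), ...) {
  which <- match.arg(which)
  p <- object$posterior
  sel <- switch(which,
                all = rep(TRUE, nrow(p)),
                universal = grepl("^u\\.", p$parameter),
                group = grepl("^mu\\.", p$parameter),
                strain = grepl("^strain\\.", p$parameter),
                tau = grepl("^tau", p$parameter))
  stats::setNames(p$mean[sel], p$parameter[sel])
}

.fit_universal <- function(object) {
  u <- coef(object, "universal")
  universal_params(u[["u.dH_star"]], u[["u.dS_star"]], u[["u.T_H"]],
                   u[["u.T_S"]])
}

.fit_strain <- function(object, id) {
  cf <- coef(object, "strain")
  g <- object$assignment$group[match(id, object$assignment$strain_id)]
  strain_params(exp(cf[[paste0("strain.", id, ".log_c")]]),
                cf[[paste0("strain.", id, ".dH_act")]],
                cf[[paste0("strain.", id, ".dCp")]],
                cf[[paste0("strain.", id, ".n")]], group = g)
}

#' Predicted growth rates at posterior means
#'
#' @param object a [thermo_fit] object.
#' @param newdata data.frame with `strain_id` and `temperature_K`; defaults
#'   to the fitted records.
#' @param ... unused.
#' @return Numeric vector of modelled standardized rates.
#' @export
predict.thermo_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$records
  u <- .fit_universal(object)
  out <- numeric(nrow(newdata))
  for (id in unique(as.character(newdata$strain_id))) {
    w <- newdata$strain_id == id
    out[w] <- growth_rate(newdata$temperature_K[w], u, .fit_strain(object, id))
  }
  out
}

#' Square-root-scale residuals at posterior means
#'
#' @param object a [thermo_fit] object.
#' @param ... unused.
#' @return `sqrt(rate_std) - sqrt(fitted rate)` for every record.
#' @export
residuals.thermo_fit <- function(object, ...) {
  sqrt(object$records$rate_std) - sqrt(predict(object))
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws parameter vectors from the retained posterior sample and simulates
#' new standardized rates at the observed temperatures through the
#' square-root-scale observation model.
#'
#' @param object a [thermo_fit] object.
#' @param nsim number of posterior-predictive datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A matrix with one column per simulated dataset (rows follow
#'   `object$records`).
#' @export
simulate.thermo_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  draws <- posterior_draws(object)
  rec <- object$records
  idx <- sample.int(nrow(draws), nsim, replace = TRUE)
  out <- matrix(NA_real_, nrow(rec), nsim)
  for (j in seq_len(nsim)) {
    d <- draws[idx[j], ]
    u <- .u_list(d[1:4])
    m <- numeric(nrow(rec))
    for (id in unique(as.character(rec$strain_id))) {
      w <- rec$strain_id == id
      th <- c(d[[paste0("strain.", id, ".log_c")]],
              d[[paste0("strain.", id, ".dH_act")]],
              d[[paste0("strain.", id, ".dCp")]],
              d[[paste0("strain.", id, ".n")]])
      m[w] <- .sqrt_rate(rec$temperature_K[w], u, th)
    }
    out[, j] <- pmax(0, m + stats::rnorm(nrow(rec), 0,
                                         1 / sqrt(d[["tau_obs"]])))^2
  }
  out
}

#' Plot a fitted thermodynamic growth model
#'
#' `type = "fit"` draws each strain's standardized observations with the
#' fitted rate curve at posterior means; `type = "trace"` shows trace plots
#' of the universal parameters.
#'
#' @param x a [thermo_fit] object.
#' @param type `"fit"` or `"trace"`.
#' @param strains optional subset of strain ids to plot.
#' @param ... passed to plotting primitives.
#' @export
plot.thermo_fit <- function(x, type = c("fit", "trace"), strains = NULL, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (p in paste0("u.", c("dH_star", "dS_star", "T_H", "T_S"))) {
      graphics::plot(x$chain[, p], type = "l", xlab = "stored iteration",
                     ylab = p, main = p, ...)
      graphics::abline(v = x$retained_rows[1], col = "grey", lty = 2)
    }
    return(invisible(x))
  }
  ids <- if (is.null(strains)) x$strain_ids else strains
  nc <- ceiling(sqrt(length(ids)))
  op <- graphics::par(mfrow = c(ceiling(length(ids) / nc), nc),
                      mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  u <- .fit_universal(x)
  for (id in ids) {
    w <- x$records$strain_id == id
    Tw <- x$records$temperature_K[w]
    grid <- seq(min(Tw) - 2, max(Tw) + 2, length.out = 200)
    s <- .fit_strain(x, id)
    graphics::plot(Tw, x$records$rate_std[w], pch = 19, cex = 0.6,
                   xlab = "T (K)", ylab = "rate", main = id, ...)
    graphics::lines(grid, growth_rate(grid, u, s), col = "steelblue")
  }
  invisible(x)
}

#' Format a posterior estimate as "mean (lower, upper)"
#'
#' @param mean,lower,upper numeric scalars.
#' @param digits significant digits.
#' @return Character scalar, e.g. `"17.0 (16.9, 17.1)"`.
#' @export
format_hpdi <- function(mean, lower, upper, digits = 4) {
  dec <- max(0, digits - 1 - floor(log10(max(abs(c(mean, lower, upper)), 1e-12))))
  fmt <- function(v) formatC(v, format = "f", digits = dec)
  sprintf("%s (%s, %s)", fmt(mean), fmt(lower), fmt(upper))
}
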