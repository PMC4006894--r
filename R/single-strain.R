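#' Nonlinear least-squares fit of the growth model to one strain
#'
#' Fits the thermodynamic rate model to a single strain's records by
#' nonlinear least squares on the square-root rate scale
#' (Levenberg-Marquardt), with a user-chosen subset of parameters held
#' fixed.  By default the two convergence temperatures and the entropy
#' change are fixed (the usual scheme needed for convergence with
#' single-strain data), leaving `c`, `dH_act`, `dCp`, `dH_star` and `n`
#' free; any of these may also be fixed via `fixed`.
#'
#' The scaling constant is estimated on the log scale.  Estimates of the
#' thermodynamic parameters are invariant to rescaling the rate units; only
#' `c` changes.
#'
#' @param records data.frame with columns `temperature_K` and `rate_obs`
#'   (or `rate_std`) for a single strain; at least 6 records spanning the
#'   rate peak.
#' @param u a [universal_params] object providing the fixed universal
#'   values.
#' @param fixed named numeric vector of parameters to hold fixed, chosen
#'   from `dH_star`, `dS_star`, `T_H`, `T_S`, `dH_act`, `dCp`, `n`,
#'   `log_c`.  Defaults to fixing `T_H`, `T_S` and `dS_star` at the values
#'   in `u`.
#' @param start optional named list of starting values for the free
#'   parameters.
#' @param control passed to [minpack.lm::nls.lm.control()].
#' @return List of class `"thermo_nls"` with elements `coefficients` (all
#'   eight parameters, fixed and estimated), `free` (names of estimated
#'   parameters), `fit` (the underlying `nls.lm` object), `fitted`,
#'   `residuals` (sqrt scale) and `convergence`.
#' @export
fit_single_strain <- function(records, u = default_universal_params(),
                              fixed = NULL, start = NULL,
                              control = minpack.lm::nls.lm.control(maxiter = 200)) {
  rate_col <- if ("rate_std" %in% names(records)) "rate_std" else "rate_obs"
  stopifnot("temperature_K" %in% names(records),
            rate_col %in% names(records))
  Tv <- records$temperature_K
  y <- sqrt(records[[rate_col]])
  if (length(Tv) < 6) stop("need at least 6 records for a single-strain fit")
  if (is.null(fixed))
    fixed <- c(T_H = u$T_H, T_S = u$T_S, dS_star = u$dS_star)

  all_names <- c("log_c", "dH_act", "dCp", "n", "dH_star", "dS_star",
                 "T_H", "T_S")
  free <- setdiff(all_names, names(fixed))

  # data-informed defaults for the free parameters
  To_hat <- Tv[which.max(y)]
  defaults <- list(dH_act = 7e4, dCp = 60, n = 400,
                   dH_star = u$dH_star, dS_star = u$dS_star,
                   T_H = u$T_H, T_S = u$T_S, log_c = 0)
  full0 <- utils::modifyList(defaults, as.list(fixed))
  if (!is.null(start)) full0 <- utils::modifyList(full0, as.list(start))
  # profile the scaling so the starting curve peaks near the observed max
  if (!("log_c" %in% names(fixed)) && is.null(start$log_c)) {
    lr0 <- .single_log_rate(To_hat, full0)
    full0$log_c <- 2 * log(max(y, 1e-3)) - (lr0 - full0$log_c)
  }

  resid_fun <- function(par) {
    full <- full0
    full[free] <- as.list(par)
    if (any(unlist(full[c("dH_act", "dCp", "n", "dH_star", "dS_star")]) <= 0))
      return(rep(1e6, length(y)))
    y - exp(0.5 * .single_log_rate(Tv, full))
  }
  fit <- minpack.lm::nls.lm(par = unlist(full0[free]), fn = resid_fun,
                            control = control)
  if (fit$info %in% c(0, 9))
    stop("single-strain fit did not converge: ", fit$message,
         "\nparameter trace: ", paste(signif(fit$par, 5), collapse = ", "))
  full <- full0
  full[free] <- as.list(unname(fit$par))
  cf <- unlist(full)[all_names]
  res <- resid_fun(fit$par)
  structure(list(coefficients = cf, free = free, fit = fit,
                 fitted = (y - res)^2, residuals = res,
                 convergence = fit$info, message = fit$message),
            class = "thermo_nls")
}

.single_log_rate <- function(T, p) {
  dG <- p$dH_star + p$dCp * (T - p$T_H) - T * (p$dS_star + p$dCp * log(T / p$T_S))
  p$log_c + log(T) - p$dH_act / (.R_GAS * T) +
    stats::plogis(p$n * dG / (.R_GAS * T), log.p = TRUE)
}

#' @export
print.thermo_nls <- function(x, ...) {
  cat("Single-strain nonlinear least-squares fit (sqrt-rate scale)\n")
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("  residual SS: %.4g\n", sum(x$residuals^2)))
  invisible(x)
}

#' @export
coef.thermo_nls <- function(object, ...) object$coefficients
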