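#' Characteristic time of sphericity decay
#'
#' Sphericity trajectories of fingering tumors have a quasi-Gaussian profile;
#' fitting \deqn{s(t) = s_0 \exp\{-(t/\tau)^2\}} by least squares yields the
#' characteristic time tau (days), which measures how fast the tumor develops
#' fingers (small tau = fast fingering). The fit needs at least 5 points;
#' degenerate inputs (e.g. constant s) are reported as non-converged with
#' diagnostics rather than silently falling back.
#'
#' @param day numeric vector of times (days).
#' @param s numeric vector of sphericities (same length).
#' @return An object of class `cpm_tau_fit`: list with `tau` (days),
#'   `amplitude` (s0), `rss`, `n`, `converged`, and `message` when not
#'   converged.
#' @examples
#' t <- seq(0, 40, by = 2)
#' s <- 0.9 * exp(-(t / 20)^2)
#' fit_characteristic_time(t, s)$tau  # ~20
#' @export
fit_characteristic_time <- function(day, s) {
  keep <- is.finite(day) & is.finite(s)
  day <- day[keep]; s <- s[keep]
  if (length(day) < 5)
    stop("need at least 5 (day, s) points to fit the characteristic time")
  out <- list(tau = NA_real_, amplitude = NA_real_, rss = NA_real_,
              n = length(day), converged = FALSE, message = NULL)
  class(out) <- "cpm_tau_fit"
  s0_init <- max(s)
  # initial tau: time where s first drops below s0/e, else beyond the data
  drop <- which(s <= s0_init * exp(-1))
  tau_init <- if (length(drop)) max(day[min(drop)], 1e-6) else max(day) * 2
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ s0 * exp(-(day / tau)^2),
                      start = list(s0 = s0_init, tau = tau_init),
                      lower = c(s0 = 1e-8, tau = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  cf <- coef(fit)
  out$tau <- unname(cf[["tau"]])
  out$amplitude <- unname(cf[["s0"]])
  out$rss <- sum(residuals(fit)^2)
  # a tau far beyond the observed window is unidentified (flat trajectory)
  if (!is.finite(out$tau) || out$tau > 50 * max(day)) {
    out$converged <- FALSE
    out$message <- "tau is unidentified on this window (trajectory too flat)"
  } else {
    out$converged <- TRUE
  }
  out
}

#' @export
print.cpm_tau_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Quasi-Gaussian sphericity fit: s(t) = %.3f * exp(-(t/%.2f d)^2)  [n = %d, rss = %.2e]\n",
                x$amplitude, x$tau, x$n, x$rss))
  } else {
    cat(sprintf("Characteristic-time fit did not converge (n = %d): %s\n",
                x$n, x$message %||% "unknown reason"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
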