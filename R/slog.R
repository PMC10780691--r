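#' Sigma-lognormal stroke decomposition
#'
#' The kinematic theory of rapid human movements models any movement as a
#' superposition of primitives ("strokes") whose speed profile is a
#' 3-parameter lognormal impulse response:
#' \deqn{v(t) = \frac{D}{\sigma\sqrt{2\pi}\,(t - t_0)}
#'   \exp\!\left(-\frac{(\ln(t - t_0) - \mu)^2}{2\sigma^2}\right),
#'   \quad t > t_0,}
#' with amplitude \eqn{D} (the distance covered by the stroke), onset time
#' \eqn{t_0}, log-time delay \eqn{\mu} and log-response time \eqn{\sigma}.
#' Decomposing a gait speed profile yields the stroke count and per-stroke
#' parameters used as global gait descriptors.
#'
#' Extraction is greedy: locate the largest remaining mode of the residual
#' speed profile, fit one lognormal by bounded nonlinear least squares
#' (Levenberg-Marquardt) seeded from the mode's location and width,
#' subtract, and repeat until the residual energy falls below a fraction of
#' the original or a stroke budget is hit. The direction angles
#' `theta_start` / `theta_end` are read from the trajectory tangent angle at
#' the stroke's 1st and 99th percentile times.
#'
#' @param speed non-negative speed profile on a uniform time grid.
#' @param t time grid in seconds (uniform spacing required).
#' @param tangent optional tangent-angle series aligned with `speed`, used
#'   for `theta_start` / `theta_end` (zeros if omitted).
#' @param max_strokes stroke budget (default 8).
#' @param residual_frac stop when residual energy is below this fraction of
#'   the input energy (default 0.05).
#' @param min_peak_frac ignore residual modes below this fraction of the
#'   original peak speed (default 0.05).
#' @return an object of class `sigma_lognormal_params`: a list with
#'   `strokes` (data frame with columns `D`, `t0`, `mu`, `sigma`,
#'   `theta_start`, `theta_end`) and `stroke_count`.
#' @export
sigma_lognormal_decompose <- function(speed, t, tangent = NULL,
                                      max_strokes = 8L,
                                      residual_frac = 0.05,
                                      min_peak_frac = 0.05) {
  stopifnot(length(speed) == length(t), all(speed >= 0 | is.na(speed)))
  if (length(t) >= 3) {
    steps <- diff(t)
    if (max(steps) - min(steps) > 1e-9 * max(abs(t))) {
      stop("non-uniform time grid")
    }
  }
  speed[is.na(speed)] <- 0
  strokes <- data.frame(D = numeric(0), t0 = numeric(0), mu = numeric(0),
                        sigma = numeric(0), theta_start = numeric(0),
                        theta_end = numeric(0))
  e0 <- sum(speed^2)
  if (e0 == 0) {
    return(structure(list(strokes = strokes, stroke_count = 0L),
                     class = "sigma_lognormal_params"))
  }
  resid <- speed
  vmax0 <- max(speed)
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  for (s in seq_len(max_strokes)) {
    if (sum(resid^2) < residual_frac * e0) break
    ipk <- which.max(resid)
    vpk <- resid[ipk]
    if (vpk < min_peak_frac * vmax0) break
    fit <- fit_one_lognormal(pmax(resid, 0), t, ipk, dt)
    if (is.null(fit) || fit$D <= 0) break
    prof <- lognormal_profile(t, fit$D, fit$t0, fit$mu, fit$sigma)
    # accept only if the stroke explains something
    if (sum(prof^2) < 1e-12 * e0) break
    th <- stroke_angles(t, fit, tangent)
    strokes <- rbind(strokes,
                     data.frame(D = fit$D, t0 = fit$t0, mu = fit$mu,
                                sigma = fit$sigma,
                                theta_start = th[1], theta_end = th[2]))
    resid <- resid - prof
  }
  structure(list(strokes = strokes, stroke_count = nrow(strokes)),
            class = "sigma_lognormal_params")
}

#' Lognormal speed profile of a single stroke
#' @param t time grid.
#' @param D,t0,mu,sigma stroke parameters (see
#'   [sigma_lognormal_decompose()]).
#' @return numeric vector, zero for `t <= t0`.
#' @export
lognormal_profile <- function(t, D, t0, mu, sigma) {
  out <- numeric(length(t))
  pos <- t > t0
  tt <- t[pos] - t0
  out[pos] <- D / (sigma * sqrt(2 * pi) * tt) *
    exp(-(log(tt) - mu)^2 / (2 * sigma^2))
  out
}

# Bounded LM fit of one lognormal to the residual profile, seeded from the
# mode at index ipk. Parameterized by (log D, t0, mu, log sigma) with box
# bounds keeping t0 before the mode and sigma in a plausible band.
fit_one_lognormal <- function(resid, t, ipk, dt) {
  tpk <- t[ipk]
  vpk <- resid[ipk]
  # crude width from half-maximum crossing
  above <- resid >= vpk / 2
  w <- max(sum(above) * dt, 2 * dt)
  sigma0 <- 0.3
  t00 <- tpk - w            # onset guess before the mode
  mu0 <- log(max(tpk - t00, dt)) + sigma0^2  # mode at t0 + exp(mu - sigma^2)
  D0 <- vpk * sigma0 * sqrt(2 * pi) * max(tpk - t00, dt) *
    exp(sigma0^2 / 2 - sigma0^2)  # approximate amplitude from peak height
  par0 <- c(logD = log(max(D0, 1e-8)), t0 = t00, mu = mu0,
            logsig = log(sigma0))
  lower <- c(log(1e-10), t[1] - 5 * w - 10 * dt, -8, log(0.05))
  upper <- c(log(max(D0, 1e-8) * 1e4), tpk - dt / 2, 4, log(1.5))
  fn <- function(p) {
    lognormal_profile(t, exp(p[1]), p[2], p[3], exp(p[4])) - resid
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  list(D = exp(p[[1]]), t0 = p[[2]], mu = p[[3]], sigma = exp(p[[4]]))
}

# theta_start / theta_end: tangent angle at the stroke's 1% and 99% times
# (lognormal quantiles of t - t0).
stroke_angles <- function(t, fit, tangent) {
  if (is.null(tangent)) return(c(0, 0))
  q <- fit$t0 + exp(fit$mu + fit$sigma * stats::qnorm(c(0.01, 0.99)))
  idx <- pmin(pmax(findInterval(q, t), 1L), length(t))
  c(tangent[idx[1]], tangent[idx[2]])
}

#' @export
print.sigma_lognormal_params <- function(x, ...) {
  cat(sprintf("Sigma-lognormal decomposition: %d stroke(s)\n", x$stroke_count))
  if (x$stroke_count) print(x$strokes, ...)
  invisible(x)
}

#' Write a sigma-lognormal decomposition as a JSON sidecar
#' @param slog a `sigma_lognormal_params`.
#' @param path JSON path.
#' @export
write_slog_json <- function(slog, path) {
  stopifnot(inherits(slog, "sigma_lognormal_params"))
  jsonlite::write_json(
    list(type = "sigma_lognormal", stroke_count = slog$stroke_count,
         strokes = slog$strokes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
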