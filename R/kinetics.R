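#' Simulate 1:1 Langmuir SPR sensorgrams
#'
#' For each analyte concentration C the association phase follows
#' `R(t) = Req (1 - exp(-(kon C + koff) t))` with
#' `Req = Rmax C / (C + Kd)` and `Kd = koff / kon`; the dissociation phase
#' decays as `R(t) = R_end exp(-koff (t - t_assoc))`. Gaussian noise of the
#' stated standard deviation is added reproducibly under `seed`.
#'
#' @param kon Association rate constant, 1/(M s).
#' @param koff Dissociation rate constant, 1/s.
#' @param rmax Surface capacity, RU.
#' @param conc Analyte concentrations, molar (vector allowed: one curve
#'   each).
#' @param t_assoc,t_dissoc Phase durations, seconds.
#' @param dt Sampling interval, seconds.
#' @param noise_sd Gaussian noise standard deviation, RU.
#' @param seed Optional integer seed for the noise.
#'
#' @return A sensorgram tibble: `time` (s), `response` (RU), `conc` (M),
#'   `phase` (`"association"`/`"dissociation"`).
#' @export
simulate_sensorgram <- function(kon, koff, rmax, conc,
                                t_assoc = 120, t_dissoc = 180, dt = 1,
                                noise_sd = 0, seed = NULL) {
  stopifnot(kon > 0, koff > 0, rmax > 0, all(conc > 0),
            t_assoc > 0, t_dissoc > 0)
  build <- function() {
    purrr::map_dfr(conc, function(C) {
      ta <- seq(0, t_assoc, by = dt)
      td <- seq(dt, t_dissoc, by = dt)
      req <- rmax * C / (C + koff / kon)
      ra <- req * (1 - exp(-(kon * C + koff) * ta))
      r_end <- ra[length(ra)]
      rd <- r_end * exp(-koff * td)
      out <- tibble(
        time = c(ta, t_assoc + td),
        response = c(ra, rd),
        conc = C,
        phase = c(rep("association", length(ta)),
                  rep("dissociation", length(td))))
      if (noise_sd > 0) {
        out$response <- out$response + rnorm(nrow(out), 0, noise_sd)
      }
      out
    })
  }
  if (!is.null(seed)) withr::with_seed(seed, build()) else build()
}

langmuir_response <- function(p, curve) {
  kon <- p[["kon"]]; koff <- p[["koff"]]; rmax <- p[["rmax"]]
  C <- curve$conc[1]
  req <- rmax * C / (C + koff / kon)
  t0 <- max(curve$time[curve$phase == "association"])
  r <- numeric(nrow(curve))
  ia <- curve$phase == "association"
  r[ia] <- req * (1 - exp(-(kon * C + koff) * curve$time[ia]))
  r_end <- req * (1 - exp(-(kon * C + koff) * t0))
  r[!ia] <- r_end * exp(-koff * (curve$time[!ia] - t0))
  r
}

#' Global 1:1 kinetic fit of a sensorgram set
#'
#' Fits a single (kon, koff, Rmax) triple to all curves simultaneously by
#' Levenberg-Marquardt least squares on log-scale parameters, started from
#' a fixed multistart grid (kon in 1e3-1e7 per molar-second, koff in
#' 1e-4-1e-1 per second) to avoid local minima. Curves are
#' baseline-subtracted first when a `baseline` phase is present.
#'
#' @param sensorgrams A sensorgram tibble (as from
#'   [simulate_sensorgram()], or read from CSV with columns `time`,
#'   `response`, `conc`, `phase`); multiple concentrations are fitted
#'   globally.
#'
#' @return A `pef_kinetic_fit`: list with `kon`, `koff`, `kd`
#'   (= koff/kon), `rmax`, `residual_rms` (per-curve tibble) and the
#'   optimiser object. Access tidily via [tidy()] / [glance()].
#' @export
fit_kinetic <- function(sensorgrams) {
  d <- as_tibble(sensorgrams)
  needed <- c("time", "response", "conc", "phase")
  if (!all(needed %in% names(d))) {
    abort("sensorgram table needs columns time, response, conc, phase")
  }
  base <- d[d$phase == "baseline", ]
  if (nrow(base) > 0) {
    d <- d |>
      group_by(.data$conc) |>
      mutate(response = .data$response -
               mean(.data$response[.data$phase == "baseline"])) |>
      ungroup()
    d <- d[d$phase != "baseline", ]
  }
  curves <- split(d, d$conc)
  rmax0 <- max(d$response)
  resid_fun <- function(logp) {
    p <- exp(logp); names(p) <- c("kon", "koff", "rmax")
    unlist(lapply(curves, function(cv) cv$response - langmuir_response(p, cv)))
  }
  grid <- expand.grid(kon = 10^c(3, 5, 7), koff = 10^c(-4, -2.5, -1))
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    start <- log(c(grid$kon[g], grid$koff[g], rmax0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) abort("kinetic fit failed to converge from every start")
  p <- exp(best$par); names(p) <- c("kon", "koff", "rmax")
  per_curve <- purrr::map_dfr(curves, function(cv) {
    r <- cv$response - langmuir_response(p, cv)
    tibble(conc = cv$conc[1], n = nrow(cv), rms = sqrt(mean(r^2)))
  })
  structure(list(kon = unname(p["kon"]), koff = unname(p["koff"]),
                 kd = unname(p["koff"] / p["kon"]),
                 rmax = unname(p["rmax"]),
                 residual_rms = per_curve,
                 data = d, optim = best),
            class = "pef_kinetic_fit")
}

#' @export
print.pef_kinetic_fit <- function(x, ...) {
  cat(sprintf(paste0("# 1:1 Langmuir kinetic fit\n",
                     "  kon  = %.3g 1/(M s)\n  koff = %.3g 1/s\n",
                     "  Kd   = %.3g M\n  Rmax = %.3g RU\n"),
              x$kon, x$koff, x$kd, x$rmax))
  invisible(x)
}

#' @export
tidy.pef_kinetic_fit <- function(x, ...) {
  tibble(term = c("kon", "koff", "kd", "rmax"),
         estimate = c(x$kon, x$koff, x$kd, x$rmax),
         unit = c("1/(M.s)", "1/s", "M", "RU"))
}

#' @export
glance.pef_kinetic_fit <- function(x, ...) {
  tibble(kd = x$kd, kon = x$kon, koff = x$koff, rmax = x$rmax,
         n_curves = nrow(x$residual_rms),
         rms = sqrt(mean(x$residual_rms$rms^2)))
}

#' Steady-state (equilibrium) affinity fit with Scatchard comparison
#'
#' Fits the binding isotherm `Req = Rmax C / (C + Kd)` to plateau responses
#' by nonlinear least squares, and also reports the classical Scatchard
#' linearisation (`Req/C` against `Req`; slope `-1/Kd`, intercept
#' `Rmax/Kd`) for comparison. On exact data both routes agree; under noise
#' the nonlinear fit is the better-behaved estimator.
#'
#' @param plateaus A tibble with columns `conc` (M) and `req` (RU).
#'
#' @return A `pef_steady_state`: list with `kd`, `rmax`, `kd_scatchard`,
#'   `rmax_scatchard` and the `nls` fit.
#' @export
fit_steady_state <- function(plateaus) {
  d <- as_tibble(plateaus)
  if (!all(c("conc", "req") %in% names(d))) {
    abort("plateau table needs columns conc, req")
  }
  if (nrow(d) < 3) abort("steady-state fit needs at least 3 concentrations")
  if (sd(d$req) < 1e-12) abort("all plateau responses equal: no curvature to fit")
  sc <- lm(I(req / conc) ~ req, data = d)
  kd_sc <- -1 / coef(sc)[["req"]]
  rmax_sc <- coef(sc)[["(Intercept)"]] * kd_sc
  start <- list(kd = if (is.finite(kd_sc) && kd_sc > 0) kd_sc else stats::median(d$conc),
                rmax = if (is.finite(rmax_sc) && rmax_sc > 0) rmax_sc else max(d$req) * 1.5)
  fit <- minpack.lm::nlsLM(req ~ rmax * conc / (conc + kd), data = d,
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  structure(list(kd = est[["kd"]], rmax = est[["rmax"]],
                 kd_scatchard = kd_sc, rmax_scatchard = rmax_sc,
                 fit = fit, data = d),
            class = "pef_steady_state")
}

#' @export
print.pef_steady_state <- function(x, ...) {
  cat(sprintf(paste0("# steady-state affinity fit\n",
                     "  Kd   = %.3g M (Scatchard: %.3g M)\n",
                     "  Rmax = %.3g RU\n"),
              x$kd, x$kd_scatchard, x$rmax))
  invisible(x)
}

#' @export
tidy.pef_steady_state <- function(x, ...) {
  tibble(term = c("kd", "rmax", "kd_scatchard", "rmax_scatchard"),
         estimate = c(x$kd, x$rmax, x$kd_scatchard, x$rmax_scatchard),
         unit = c("M", "RU", "M", "RU"))
}

#' @export
glance.pef_steady_state <- function(x, ...) {
  tibble(kd = x$kd, rmax = x$rmax, kd_scatchard = x$kd_scatchard,
         n = nrow(x$data))
}

#' Plot a kinetic fit over its sensorgrams
#'
#' @param object A `pef_kinetic_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed responses (points) and the fitted 1:1
#'   model (lines), one colour per concentration.
#' @export
autoplot.pef_kinetic_fit <- function(object, ...) {
  p <- c(kon = object$kon, koff = object$koff, rmax = object$rmax)
  d <- object$data |>
    group_by(.data$conc) |>
    dplyr::group_modify(function(cv, key) {
      cv$fitted <- langmuir_response(p, mutate(cv, conc = key$conc))
      cv
    }) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, colour = factor(.data$conc))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$response), size = 0.4,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "time (s)", y = "response (RU)", colour = "conc (M)") +
    ggplot2::theme_minimal()
}
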