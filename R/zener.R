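#' Creep time constant of the modified Zener model
#'
#' The modified Zener (standard linear solid plus series dashpot) model
#' relaxes towards its long-time creep with time constant
#' \deqn{\tau = \eta_0 (k_0 + k_1) / (k_0 k_1),}
#' the harmonic mean of the two spring constants weighted by the parallel
#' dashpot viscosity. It measures how fast the oocyte keeps deforming after
#' the instantaneous elastic jump.
#'
#' @param k0,k1 Spring constants in N/m.
#' @param eta0 Parallel dashpot viscosity in N s/m.
#' @return Time constant in seconds.
#' @export
#' @examples
#' creep_time_constant(0.02, 0.01, 0.005) # 0.75 s
creep_time_constant <- function(k0, k1, eta0) {
  check_positive(k0, "k0")
  check_positive(k1, "k1")
  check_positive(eta0, "eta0")
  eta0 * (k0 + k1) / (k0 * k1)
}

#' Mechanical parameter set of the modified Zener model
#'
#' Bundles the four free parameters of the creep model with the derived time
#' constant and, after fitting, the residual sum of squares and a convergence
#' flag. All parameters are in SI units (N/m and N s/m).
#'
#' @param k0,k1 Spring constants in N/m (elastic, "instant elongation").
#' @param eta0,eta1 Dashpot viscosities in N s/m (viscous, liquid-like flow).
#' @param sse Residual sum of squares of a fit, in squared micrometers.
#' @param converged Logical convergence flag of a fit.
#' @return An object of class `zener_params`.
#' @export
zener_params <- function(k0, k1, eta0, eta1, sse = NA_real_, converged = NA) {
  check_positive(k0, "k0")
  check_positive(k1, "k1")
  check_positive(eta0, "eta0")
  check_positive(eta1, "eta1")
  structure(
    list(k0 = k0, k1 = k1, eta0 = eta0, eta1 = eta1,
         tau = creep_time_constant(k0, k1, eta0),
         sse = sse, converged = converged),
    class = "zener_params"
  )
}

#' @export
print.zener_params <- function(x, ...) {
  cat("Modified Zener parameters (SI units):\n")
  cat(sprintf("  k0   = %.4g N/m\n  k1   = %.4g N/m\n", x$k0, x$k1))
  cat(sprintf("  eta0 = %.4g N s/m\n  eta1 = %.4g N s/m\n", x$eta0, x$eta1))
  cat(sprintf("  tau  = %.4g s\n", x$tau))
  if (!is.na(x$sse)) {
    cat(sprintf("  SSE  = %.4g um^2 (converged: %s)\n", x$sse, x$converged))
  }
  invisible(x)
}

# Pa per p.s.i.; exact conversion used throughout.
PSI_TO_PA <- 6894.757

#' Aspiration force from suction pressure and pipette geometry
#'
#' The constant force pulling the zona pellucida into the pipette lumen is
#' the suction pressure times the lumen cross-section:
#' \deqn{F_0 = p \cdot 6894.757 \,\mathrm{Pa/psi} \cdot \pi (d/2 \cdot 10^{-6})^2}
#' with `p` the suction magnitude in p.s.i. and `d` the pipette inner
#' diameter in micrometers.
#'
#' @param suction_psi Suction magnitude in p.s.i. (positive; the instrument
#'   logs suction as negative pressure, pass its magnitude).
#' @param inner_diameter_um Pipette inner diameter in micrometers.
#' @return Force in newtons.
#' @export
#' @examples
#' applied_force(0.1, 50) # ~1.354e-6 N
applied_force <- function(suction_psi, inner_diameter_um) {
  check_positive(suction_psi, "suction_psi")
  check_positive(inner_diameter_um, "inner_diameter_um")
  suction_psi * PSI_TO_PA * pi * (inner_diameter_um / 2 * 1e-6)^2
}

#' Aspiration force from a recorded pressure trace
#'
#' When a pressure log is available, the force uses the mean suction
#' magnitude recorded during the analysis window rather than the nominal
#' set-point.
#'
#' @param trace A [pressure_trace()].
#' @param window Time window `c(start, end)` in seconds over which to average;
#'   defaults to the samples with non-zero suction.
#' @inheritParams applied_force
#' @return Force in newtons.
#' @export
applied_force_from_trace <- function(trace, inner_diameter_um, window = NULL) {
  stopifnot(inherits(trace, "pressure_trace"))
  suction <- pmax(trace$balance_pressure - trace$pressures, 0)
  keep <- if (is.null(window)) suction > 0 else
    trace$times >= window[1] & trace$times <= window[2]
  if (!any(keep) || mean(suction[keep]) <= 0) {
    stop_oomech("no suction recorded in the measurement window",
                "oomech_invalid_input")
  }
  applied_force(mean(suction[keep]), inner_diameter_um)
}

#' Creep response of the modified Zener model
#'
#' Aspiration depth under a constant force \eqn{F_0} applied at \eqn{t = 0}:
#' \deqn{d(t) = \frac{F_0}{k_1}\left(1 - \frac{k_0}{k_0 + k_1}
#'   e^{-t/\tau}\right) + \frac{F_0\,t}{\eta_1}}
#' an instantaneous elastic jump \eqn{d(0) = F_0/(k_0 + k_1)}, an exponential
#' approach to \eqn{F_0/k_1} with time constant \eqn{\tau}, and a linear
#' viscous drift through the series dashpot \eqn{\eta_1}.
#'
#' @param t Time(s) in seconds, `>= 0`.
#' @param params A [zener_params()] object.
#' @param F0 Applied force in newtons (see [applied_force()]).
#' @return Depth(s) in micrometers.
#' @export
zener_depth <- function(t, params, F0) {
  stopifnot(inherits(params, "zener_params"))
  if (any(t < 0)) stop_oomech("t must be non-negative", "oomech_invalid_input")
  if (F0 < 0) stop_oomech("F0 must be non-negative", "oomech_invalid_input")
  d_m <- (F0 / params$k1) *
    (1 - (params$k0 / (params$k0 + params$k1)) * exp(-t / params$tau)) +
    F0 * t / params$eta1
  d_m * 1e6
}

# Depth in um for raw SI parameter vector p = c(k0, k1, eta0, eta1).
zener_depth_raw <- function(t, p, F0) {
  tau <- p[3] * (p[1] + p[2]) / (p[1] * p[2])
  ((F0 / p[2]) * (1 - (p[1] / (p[1] + p[2])) * exp(-t / tau)) +
     F0 * t / p[4]) * 1e6
}

#' Fit the modified Zener model to an aspiration curve
#'
#' Minimises the sum of squared errors (in squared micrometers) between the
#' measured and modelled aspiration depth with the BFGS quasi-Newton
#' algorithm. Optimisation runs in log-parameter space so all four
#' parameters stay positive by construction; the applied force is fixed, not
#' fitted, because a joint rescaling of \eqn{F_0} and all stiffness/viscosity
#' parameters leaves \eqn{d(t)} unchanged.
#'
#' Initialisation from the data: the instantaneous jump gives
#' \eqn{k_0 + k_1 = F_0 / d(0)} (split equally), the time constant starts at
#' one third of the record length, and \eqn{\eta_1} comes from the terminal
#' slope. The search restarts from the current optimum until the SSE stops
#' improving, which in practice recovers noiseless parameters to well below
#' 0.1 percent.
#'
#' @param curve An [aspiration_curve()] with at least 5 samples.
#' @param F0 Applied force in newtons.
#' @param init Optional [zener_params()] initialisation.
#' @param bounds Length-2 positive box applied to each SI parameter at
#'   initialisation and on the returned estimate.
#' @param max_iter Maximum BFGS iterations per pass.
#' @return A [zener_params()] with `sse` (um^2) and `converged` filled in.
#' @export
fit_zener <- function(curve, F0, init = NULL, bounds = c(1e-6, 1e3),
                      max_iter = 500L) {
  stopifnot(inherits(curve, "aspiration_curve"))
  check_positive(F0, "F0")
  t <- curve$times
  d <- curve$depths
  if (length(t) < 5L) {
    stop_oomech("curve must have at least 5 samples", "oomech_invalid_input")
  }
  if (stats::sd(d) < sqrt(.Machine$double.eps) || all(d <= 0)) {
    stop_oomech("flat or non-positive curve cannot constrain the model",
                "oomech_degenerate_fit")
  }

  clamp <- function(x) pmin(pmax(x, bounds[1]), bounds[2])
  if (is.null(init)) {
    d0_m <- max(d[1], 0.25 * max(d)) * 1e-6   # jump estimate, guard tiny d(0)
    ksum <- F0 / d0_m
    tau0 <- (t[length(t)] - t[1]) / 3
    k0 <- k1 <- ksum / 2
    eta0 <- tau0 * k0 * k1 / ksum
    n <- length(t)
    tail_i <- max(2L, n - 4L):n
    slope <- stats::coef(stats::lm(d[tail_i] ~ t[tail_i]))[2] * 1e-6  # m/s
    eta1 <- if (is.finite(slope) && slope > 0) F0 / slope else 100 * eta0
    p0 <- clamp(c(k0, k1, eta0, eta1))
  } else {
    stopifnot(inherits(init, "zener_params"))
    p0 <- clamp(c(init$k0, init$k1, init$eta0, init$eta1))
  }

  # finite-guarded objective with a soft penalty outside the parameter box,
  # so quasi-Newton steps can never produce non-finite values
  lb <- log(bounds[1]); ub <- log(bounds[2])
  sse_log <- function(lp) {
    if (any(!is.finite(lp))) return(1e12)
    over <- pmax(lp - ub, 0) + pmax(lb - lp, 0)
    r <- d - zener_depth_raw(t, exp(pmin(pmax(lp, lb - 2), ub + 2)), F0)
    if (any(!is.finite(r))) return(1e12)
    sum(r * r) + 1e6 * sum(over^2)
  }

  # quasi-Newton descent, interleaved with simplex polish passes that step
  # BFGS out of premature flat spots; stops when the SSE stops improving
  lp <- log(p0)
  best <- sse_log(lp)
  converged <- FALSE
  for (pass in 1:8) {
    method <- if (pass %% 2L == 1L) "BFGS" else "Nelder-Mead"
    fit <- stats::optim(lp, sse_log, method = method,
                        control = list(maxit = max_iter, reltol = 1e-15))
    improved <- best - fit$value
    if (fit$value < best) {
      lp <- fit$par
      best <- fit$value
      if (method == "BFGS") converged <- fit$convergence == 0L
    }
    if (pass >= 2L && improved < max(1e-12, 1e-10 * best)) break
  }

  p <- clamp(exp(lp))
  r <- d - zener_depth_raw(t, p, F0)
  zener_params(p[1], p[2], p[3], p[4], sse = sum(r * r), converged = converged)
}
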