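#' Default pharmacokinetic configuration
#'
#' Returns the default configuration for the Lu-177 DOTATATE compartmental
#' model: six compartments (central "rest of body", kidneys, liver, spleen,
#' tumour, excreted), first-order transfer rates in 1/h, an administered
#' activity of 7400 MBq, the Lu-177 half-life, the compartment volumes used
#' for concentration conversion (mL), and the clinical imaging timepoints
#' (hours post administration).
#'
#' The transfer-rate values are illustrative defaults chosen to produce
#' clinically plausible kinetics (organ uptake peaking within hours,
#' effective washout half-lives of tens of hours); they are not fitted to
#' patient data and every value can be overridden through the config.
#'
#' @return A named list with elements `compartments`, `rates` (data frame
#'   `from`, `to`, `rate`), `A0_MBq`, `half_life_h`, `volumes_mL`,
#'   `timepoints_h`, `background_volume_mL`.
#' @export
pk_default_config <- function() {
  list(
    compartments = c("central", "kidneys", "liver", "spleen", "tumour", "excreted"),
    rates = data.frame(
      from = c("central", "central", "central", "central",
               "kidneys", "liver", "spleen", "tumour", "central"),
      to   = c("kidneys", "liver", "spleen", "tumour",
               "central", "central", "central", "central", "excreted"),
      rate = c(0.040, 0.080, 0.010, 0.005,
               0.020, 0.025, 0.030, 0.010, 0.150),
      stringsAsFactors = FALSE
    ),
    A0_MBq = 7400,
    half_life_h = lu177_half_life_h(),
    volumes_mL = c(
      liver = 1306.7, spleen = 124.9, tumour = 15.9,
      `cortex-L` = 90.9, `cortex-R` = 75.7,
      `medulla-L` = 42.9, `medulla-R` = 35.7
    ),
    background_volume_mL = 8297,
    timepoints_h = c(1, 4, 24, 40, 72, 144)
  )
}

#' Build a linear compartmental pharmacokinetic model
#'
#' Assembles the transfer-rate matrix `K` of the linear system
#' `dA/dt = K A` from a configuration (see [pk_default_config()]).
#' Off-diagonal `K[j, i]` is the rate from compartment `i` to `j`; the
#' diagonal holds minus the total outflow, so every column sums to zero and
#' biological mass balance (all compartments plus excreted) holds exactly.
#' Physical decay is kept out of `K`: the solved series is biological
#' (decay-corrected), with the physical decay constant attached so the
#' physical series is derivable by multiplication.
#'
#' @param config a configuration list; missing entries are filled from
#'   [pk_default_config()].
#' @return An object of class `compartment_model`.
#' @examples
#' m <- build_model()
#' m$A0_MBq
#' @export
build_model <- function(config = list()) {
  cfg <- pk_default_config()
  cfg[names(config)] <- config  # top-level replacement, never recursive
  comps <- cfg$compartments
  rates <- cfg$rates
  if (!all(c("from", "to", "rate") %in% names(rates)))
    stop("rates must have columns from, to, rate")
  unknown <- setdiff(unique(c(rates$from, rates$to)), comps)
  if (length(unknown))
    stop("rate specification references unknown compartment(s): ",
         paste(unknown, collapse = ", "))
  if (any(rates$rate < 0))
    stop("transfer rates must be non-negative; offending: ",
         paste(sprintf("%s->%s", rates$from[rates$rate < 0],
                       rates$to[rates$rate < 0]), collapse = ", "))
  if (!is.numeric(cfg$A0_MBq) || cfg$A0_MBq <= 0)
    stop("administered activity A0_MBq must be positive")
  if (cfg$half_life_h <= 0) stop("half_life_h must be positive")

  n <- length(comps)
  K <- matrix(0, n, n, dimnames = list(comps, comps))
  for (r in seq_len(nrow(rates))) {
    K[rates$to[r], rates$from[r]] <- K[rates$to[r], rates$from[r]] + rates$rate[r]
  }
  diag(K) <- diag(K) - colSums(K)
  structure(list(
    compartments = comps,
    K = K,
    A0_MBq = cfg$A0_MBq,
    lambda_phys = log(2) / cfg$half_life_h,
    half_life_h = cfg$half_life_h,
    volumes_mL = cfg$volumes_mL,
    background_volume_mL = cfg$background_volume_mL,
    timepoints_h = cfg$timepoints_h
  ), class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat("Compartmental PK model:", paste(x$compartments, collapse = ", "), "\n")
  cat("  administered activity:", x$A0_MBq, "MBq\n")
  cat("  physical half-life:   ", format(x$half_life_h), "h\n")
  invisible(x)
}

#' Solve the compartmental model by classical fixed-step RK4
#'
#' Integrates `dA/dt = K A` from `t = 0` (all activity in the central
#' compartment) to `t_end` with the classical fourth-order Runge-Kutta
#' scheme at fixed step `dt`. Because the system is linear and autonomous,
#' the four RK4 stages collapse to a single per-step update matrix
#' `Phi = I + hK + h^2 K^2/2 + h^3 K^3/6 + h^4 K^4/24`, applied repeatedly;
#' this is algebraically identical to stage-by-stage classical RK4. The
#' column sums of `Phi` are exactly 1, so biological mass balance is
#' conserved to floating-point accuracy at every step.
#'
#' @param model a [build_model()] result.
#' @param t_end end of the integration horizon in hours (default 2400 h,
#'   i.e. 100 days).
#' @param dt fixed step in hours (default 1/60, i.e. 1 minute).
#' @return An object of class `activity_schedule`: uniform time grid `time_h`,
#'   matrix `A_MBq` (rows = grid points, columns = compartments) holding the
#'   decay-corrected (biological) activities, plus the model's physical decay
#'   constant and volumes.
#' @export
solve_rk4 <- function(model, t_end = 2400, dt = 1 / 60) {
  stopifnot(inherits(model, "compartment_model"))
  if (t_end <= 0) stop("t_end must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (dt > t_end) stop("dt must not exceed t_end")
  n_steps <- ceiling(t_end / dt - 1e-9)
  K <- model$K
  h <- dt
  n <- nrow(K)
  I <- diag(n)
  K2 <- K %*% K
  K3 <- K2 %*% K
  Phi <- I + h * K + (h^2 / 2) * K2 + (h^3 / 6) * K3 + (h^4 / 24) * K3 %*% K
  A <- matrix(0, n_steps + 1L, n,
              dimnames = list(NULL, model$compartments))
  a <- numeric(n)
  a[match("central", model$compartments)] <- model$A0_MBq
  A[1L, ] <- a
  for (s in seq_len(n_steps)) {
    a <- Phi %*% a
    A[s + 1L, ] <- a
  }
  structure(list(
    time_h = h * (0:n_steps),
    A_MBq = A,
    dt_h = h,
    lambda_phys = model$lambda_phys,
    half_life_h = model$half_life_h,
    A0_MBq = model$A0_MBq,
    volumes_mL = model$volumes_mL,
    background_volume_mL = model$background_volume_mL,
    timepoints_h = model$timepoints_h
  ), class = "activity_schedule")
}

#' @export
print.activity_schedule <- function(x, ...) {
  cat("Activity schedule:", length(x$time_h), "grid points, dt =",
      format(x$dt_h * 60), "min, horizon", max(x$time_h), "h\n")
  invisible(x)
}

# linear interpolation of one compartment's activity at arbitrary times
schedule_activity_at <- function(schedule, compartment, times, physical = FALSE) {
  comp <- match.arg(compartment, colnames(schedule$A_MBq))
  rng <- range(schedule$time_h)
  if (any(times < rng[1] - 1e-9 | times > rng[2] + 1e-9))
    stop("requested time outside the solved range [", rng[1], ", ", rng[2], "] h")
  a <- stats::approx(schedule$time_h, schedule$A_MBq[, comp], xout = times,
                     rule = 1)$y
  if (physical) a <- a * exp(-schedule$lambda_phys * times)
  a
}

#' Activity concentrations at given timepoints
#'
#' Converts the solved schedule into the per-compartment activity
#' concentrations used for phantom filling. The single kidney compartment is
#' split across the four anatomical kidney regions under the constraint that
#' the medulla concentration is one third of the cortex concentration and
#' that left and right cortices share one concentration: with total cortex
#' volume `Vc` and total medulla volume `Vm`,
#' `c_cortex = A_kidneys / (Vc + Vm/3)`. The background concentration is the
#' central ("rest of body") activity divided by the configured background
#' volume. Other organs are activity / volume.
#'
#' @param schedule an [solve_rk4()] result.
#' @param times timepoints in hours (default: the model's clinical
#'   timepoints). Must lie within the solved range.
#' @param physical if `TRUE`, report physically decaying concentrations
#'   (biological series multiplied by `exp(-lambda_phys * t)`); if `FALSE`
#'   (default), decay-corrected concentrations.
#' @return A long data frame with columns `time_h`, `compartment`
#'   (liver, spleen, tumour, cortex-L/R, medulla-L/R, background) and
#'   `conc_MBq_per_mL`.
#' @export
concentrations_at <- function(schedule, times = schedule$timepoints_h,
                              physical = FALSE) {
  stopifnot(inherits(schedule, "activity_schedule"))
  V <- schedule$volumes_mL
  Vc <- V[["cortex-L"]] + V[["cortex-R"]]
  Vm <- V[["medulla-L"]] + V[["medulla-R"]]
  a_kid <- schedule_activity_at(schedule, "kidneys", times, physical)
  c_cortex <- a_kid / (Vc + Vm / 3)
  c_medulla <- c_cortex / 3
  a_central <- schedule_activity_at(schedule, "central", times, physical)
  rows <- list(
    liver = schedule_activity_at(schedule, "liver", times, physical) / V[["liver"]],
    spleen = schedule_activity_at(schedule, "spleen", times, physical) / V[["spleen"]],
    tumour = schedule_activity_at(schedule, "tumour", times, physical) / V[["tumour"]],
    `cortex-L` = c_cortex, `cortex-R` = c_cortex,
    `medulla-L` = c_medulla, `medulla-R` = c_medulla,
    background = a_central / schedule$background_volume_mL
  )
  data.frame(
    time_h = rep(times, times = length(rows)),
    compartment = rep(names(rows), each = length(times)),
    conc_MBq_per_mL = unlist(rows, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Time-integrated activity of one compartment
#'
#' Trapezoidal integral of the activity curve over the solved grid plus an
#' analytic mono-exponential tail beyond the horizon, with the tail rate
#' fitted by log-linear least squares over the last 10% of the horizon.
#' This is the quantity that feeds absorbed-dose (S-factor) calculations.
#'
#' @param schedule an [solve_rk4()] result.
#' @param compartment compartment name.
#' @param physical integrate the physically decaying series (`TRUE`) or the
#'   decay-corrected one (`FALSE`).
#' @param tail include the analytic tail (default `TRUE`).
#' @return Integral in MBq·h.
#' @export
time_integrated_activity <- function(schedule, compartment, physical = FALSE,
                                     tail = TRUE) {
  stopifnot(inherits(schedule, "activity_schedule"))
  t <- schedule$time_h
  a <- schedule_activity_at(schedule, compartment, t, physical)
  n <- length(t)
  integral <- sum(diff(t) * (a[-1] + a[-n]) / 2)
  if (!tail) return(integral)
  a_end <- a[n]
  if (a_end <= 0) return(integral)
  win <- t >= t[n] - 0.10 * (t[n] - t[1])
  tw <- t[win]; aw <- a[win]
  if (any(aw <= 0)) return(integral)
  fit <- stats::lm.fit(cbind(1, tw), log(aw))
  lambda_eff <- -unname(fit$coefficients[2])
  if (lambda_eff <= 0)
    stop("late-phase curve is not decaying; time-integrated activity diverges")
  integral + a_end / lambda_eff
}

#' Export an activity schedule as a long CSV table
#'
#' Writes one row per (timepoint, compartment) with both decay-corrected and
#' physical concentrations.
#'
#' @param schedule an [solve_rk4()] result.
#' @param path output CSV path.
#' @param times timepoints in hours.
#' @return The exported data frame, invisibly.
#' @export
write_schedule_csv <- function(schedule, path, times = schedule$timepoints_h) {
  bio <- concentrations_at(schedule, times, physical = FALSE)
  phys <- concentrations_at(schedule, times, physical = TRUE)
  out <- data.frame(bio[, c("time_h", "compartment")],
                    conc_decay_corrected_MBq_per_mL = bio$conc_MBq_per_mL,
                    conc_physical_MBq_per_mL = phys$conc_MBq_per_mL)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
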