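#' Stock-solution calibration
#'
#' Describes the radionuclide stock solution: its activity concentration
#' (with relative standard uncertainty from the calibrator chain) at a
#' reference time, and a free-text traceability note.
#'
#' @param conc_MBq_per_mL activity concentration at `ref_time_h`, `> 0`.
#' @param rel_u relative standard uncertainty of the calibrated
#'   concentration (default 0.03).
#' @param ref_time_h reference timestamp in hours on the experiment clock
#'   (default 0).
#' @param note traceability note.
#' @return An object of class `stock_calibration`.
#' @export
stock_calibration <- function(conc_MBq_per_mL, rel_u = 0.03, ref_time_h = 0,
                              note = "") {
  if (conc_MBq_per_mL <= 0) stop("stock concentration must be positive")
  if (rel_u < 0) stop("relative uncertainty must be >= 0")
  structure(list(
    conc = uvalue(conc_MBq_per_mL, rel_u * conc_MBq_per_mL, "MBq/mL"),
    rel_u = rel_u,
    ref_time_h = ref_time_h,
    note = note
  ), class = "stock_calibration")
}

#' Plan the dispensing of one compartment
#'
#' Implements the filling protocol: the activity required at scan time
#' (target concentration times compartment volume) is decay-corrected back
#' to dispensing time; 110% of it is drawn from the stock; the draw is
#' pre-diluted to 105% of the compartment volume and then topped up, to
#' within 0.01 mL, to the final volume at which the solution concentration
#' equals the target (i.e. draw activity divided by the target concentration
#' at dispensing time — 110% of the compartment volume when exactly 110% is
#' drawn). Dispensing the compartment volume from that solution then
#' reproduces the modelled concentration at scan time by construction.
#'
#' @param target_conc target activity concentration at scan time, MBq/mL.
#' @param compartment_volume compartment (STL) volume in mL.
#' @param stock a [stock_calibration()].
#' @param scan_time_h scan start time in hours; must be `>=` the stock
#'   reference time.
#' @param half_life_h radionuclide half-life in hours.
#' @param dispense_time_h dispensing time; defaults to the stock reference
#'   time.
#' @param compartment compartment label carried in the record.
#' @param draw_factor activity surplus factor (default 1.10).
#' @param predilution_factor pre-dilution volume factor (default 1.05).
#' @param topup_tol_mL top-up volume tolerance (default 0.01 mL).
#' @return An object of class `dispense_record` holding the plan; measured
#'   weights are added later with [record_weights()].
#' @export
plan_dispense <- function(target_conc, compartment_volume, stock,
                          scan_time_h, half_life_h = lu177_half_life_h(),
                          dispense_time_h = stock$ref_time_h,
                          compartment = "", draw_factor = 1.10,
                          predilution_factor = 1.05, topup_tol_mL = 0.01) {
  stopifnot(inherits(stock, "stock_calibration"))
  if (target_conc <= 0 || compartment_volume <= 0)
    stop("target concentration and compartment volume must be positive")
  if (scan_time_h < stock$ref_time_h)
    stop("scan time must not precede the stock reference time")

  dt_scan <- scan_time_h - dispense_time_h
  required_scan <- target_conc * compartment_volume
  required_dispense <- decay_correct(required_scan, dt_scan, half_life_h)
  draw_activity <- draw_factor * required_dispense
  stock_conc_dispense <- decay_apply(stock$conc$value,
                                     dispense_time_h - stock$ref_time_h,
                                     half_life_h)
  stock_draw_volume <- draw_activity / stock_conc_dispense
  predilution_volume <- predilution_factor * compartment_volume
  target_conc_dispense <- decay_correct(target_conc, dt_scan, half_life_h)
  final_volume <- draw_activity / target_conc_dispense  # = draw_factor * V
  if (stock_draw_volume > predilution_volume)
    stop("stock concentration insufficient: draw volume ",
         format(stock_draw_volume), " mL exceeds pre-dilution volume ",
         format(predilution_volume), " mL")

  structure(list(
    compartment = compartment,
    target_conc_MBq_per_mL = target_conc,
    compartment_volume_mL = compartment_volume,
    scan_time_h = scan_time_h,
    dispense_time_h = dispense_time_h,
    half_life_h = half_life_h,
    stock_rel_u = stock$rel_u,
    required_activity_scan_MBq = required_scan,
    required_activity_dispense_MBq = required_dispense,
    draw_activity_MBq = draw_activity,
    stock_draw_volume_mL = stock_draw_volume,
    predilution_volume_mL = predilution_volume,
    final_solution_volume_mL = final_volume,
    topup_tol_mL = topup_tol_mL,
    solution_conc_dispense_MBq_per_mL = target_conc_dispense,
    w_empty_g = NA_real_, w_full_g = NA_real_,
    readability_g = NA_real_, density_g_per_mL = NA_real_,
    dispensed_volume = NULL
  ), class = "dispense_record")
}

#' @export
print.dispense_record <- function(x, ...) {
  cat("Dispense plan", if (nzchar(x$compartment)) paste0("[", x$compartment, "]"),
      ":\n  target", format(x$target_conc_MBq_per_mL), "MBq/mL in",
      format(x$compartment_volume_mL), "mL at T =", x$scan_time_h, "h\n")
  cat("  draw", format(x$draw_activity_MBq), "MBq =",
      format(x$stock_draw_volume_mL), "mL stock; pre-dilute to",
      format(x$predilution_volume_mL), "mL; top up to",
      format(x$final_solution_volume_mL), "mL (+/-", x$topup_tol_mL, "mL)\n")
  if (!is.na(x$w_full_g))
    cat("  dispensed:", format_concise(x$dispensed_volume), "mL\n")
  invisible(x)
}

#' Gravimetric volume from empty/full weights
#'
#' Volume is `(w_full - w_empty) / density`. Each balance reading carries a
#' rectangular-distribution standard uncertainty `readability / sqrt(12)`;
#' the two independent readings combine in quadrature, giving
#' `u = sqrt(2) * (readability / sqrt(12)) / density`.
#'
#' @param w_empty_g,w_full_g weights in grams, `w_full_g >= w_empty_g`.
#' @param density_g_per_mL solution density (default 1.000 g/mL, adequate
#'   for dilute HCl).
#' @param readability_g balance readability in grams.
#' @return A [uvalue] in mL.
#' @export
gravimetric_volume <- function(w_empty_g, w_full_g, density_g_per_mL = 1.0,
                               readability_g = 0.01) {
  if (density_g_per_mL <= 0) stop("density must be positive")
  if (w_full_g < w_empty_g)
    stop("full weight below empty weight: measurement error")
  v <- (w_full_g - w_empty_g) / density_g_per_mL
  u <- sqrt(2) * (readability_g / sqrt(12)) / density_g_per_mL
  uvalue(v, u, "mL")
}

#' Record the weighing of a filled compartment
#'
#' Completes a [plan_dispense()] record with the empty/full weights of the
#' physical compartment, deriving the gravimetrically dispensed volume and
#' hence the achieved activity.
#'
#' @param record a `dispense_record`.
#' @param w_empty_g,w_full_g weights in grams.
#' @param readability_g balance readability in grams (0 for an idealized
#'   exact weighing, as in closed-loop simulation tests).
#' @param density_g_per_mL solution density.
#' @return The completed `dispense_record`.
#' @export
record_weights <- function(record, w_empty_g, w_full_g, readability_g = 0.01,
                           density_g_per_mL = 1.0) {
  stopifnot(inherits(record, "dispense_record"))
  record$w_empty_g <- w_empty_g
  record$w_full_g <- w_full_g
  record$readability_g <- readability_g
  record$density_g_per_mL <- density_g_per_mL
  record$dispensed_volume <- gravimetric_volume(w_empty_g, w_full_g,
                                                density_g_per_mL, readability_g)
  record
}

#' Fill fraction of a compartment
#'
#' Dispensed volume as a percentage of the design (STL) volume. Values above
#' 100% are permitted and flagged as overfill via the `"overfill"` attribute.
#'
#' @param v_fill dispensed volume: a [uvalue] or a plain number (mL).
#' @param v_stl design volume in mL, `> 0`.
#' @return A [uvalue] in percent with logical attribute `overfill`.
#' @export
fill_fraction <- function(v_fill, v_stl) {
  if (!is.numeric(v_stl) || v_stl <= 0) stop("STL volume must be positive")
  if (!inherits(v_fill, "uvalue")) v_fill <- uvalue(v_fill, 0, "mL")
  out <- uv_scale(v_fill, 100 / v_stl, unit = "%")
  attr(out, "overfill") <- out$value > 100
  out
}

#' Achieved activity concentration of a filled compartment
#'
#' The activity dispensed into the compartment is the beaker solution
#' concentration at dispensing time multiplied by the gravimetric dispensed
#' volume; it is decay-adjusted to `at_time_h` and divided by the dispensed
#' volume, so the volume cancels in the concentration but not in its
#' uncertainty budget. Relative uncertainties of the calibrated stock
#' concentration and of the gravimetric volume combine in quadrature.
#'
#' @param record a completed `dispense_record` (see [record_weights()]).
#' @param at_time_h time at which the concentration is reported (default:
#'   the record's scan time).
#' @return A [uvalue] in MBq/mL.
#' @export
achieved_concentration <- function(record, at_time_h = record$scan_time_h) {
  stopifnot(inherits(record, "dispense_record"))
  if (is.na(record$w_full_g) || is.na(record$w_empty_g))
    stop("incomplete record: empty/full weights not recorded")
  v <- record$dispensed_volume
  act_dispense <- record$solution_conc_dispense_MBq_per_mL * v$value
  act_at <- decay_apply(act_dispense, at_time_h - record$dispense_time_h,
                        record$half_life_h)
  conc <- act_at / v$value
  rel_v <- if (v$value > 0) v$u / v$value else 0
  uv_combine_rel(conc, c(record$stock_rel_u, rel_v), unit = "MBq/mL")
}

#' Achieved activity of a filled compartment at a given time
#'
#' @inheritParams achieved_concentration
#' @return A [uvalue] in MBq.
#' @export
achieved_activity <- function(record, at_time_h = record$scan_time_h) {
  conc <- achieved_concentration(record, at_time_h)
  uv_scale(conc, record$dispensed_volume$value, unit = "MBq")
}

#' Plan dispensing for a whole schedule timepoint
#'
#' Convenience wrapper: one [plan_dispense()] per compartment of a
#' concentration table (as from [concentrations_at()]) at one timepoint,
#' using the given design volumes.
#'
#' @param conc_table long concentration table with columns `time_h`,
#'   `compartment`, `conc_MBq_per_mL`, restricted to one timepoint.
#' @param volumes_mL named vector of design volumes, mL; names must cover
#'   the table's compartments.
#' @param stock a [stock_calibration()].
#' @param half_life_h radionuclide half-life in hours.
#' @param ... passed to [plan_dispense()].
#' @return A named list of `dispense_record`s.
#' @export
plan_timepoint <- function(conc_table, volumes_mL, stock,
                           half_life_h = lu177_half_life_h(), ...) {
  if (length(unique(conc_table$time_h)) != 1L)
    stop("conc_table must hold exactly one timepoint")
  missing_v <- setdiff(conc_table$compartment, names(volumes_mL))
  if (length(missing_v))
    stop("no design volume for compartment(s): ",
         paste(missing_v, collapse = ", "))
  scan_t <- conc_table$time_h[1]
  recs <- lapply(seq_len(nrow(conc_table)), function(i) {
    plan_dispense(conc_table$conc_MBq_per_mL[i],
                  volumes_mL[[conc_table$compartment[i]]],
                  stock, scan_time_h = scan_t, half_life_h = half_life_h,
                  compartment = conc_table$compartment[i], ...)
  })
  stats::setNames(recs, conc_table$compartment)
}
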