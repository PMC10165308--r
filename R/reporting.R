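#' Reference fill-fraction measurements of the physical phantom
#'
#' The measured fill fractions (dispensed volume as percent of the design
#' STL volume, with standard uncertainties on the last digits) for the
#' eight compartments of the default phantom design over the six imaging
#' scans, together with the design STL volumes. Packaged as the reference
#' dataset behind the reporting examples and checks.
#'
#' @return Data frame with columns `compartment`, `stl_volume_mL`, `scan`,
#'   `fill_pct`, `fill_u_pct`.
#' @export
reference_fill_fractions <- function() {
  organs <- c("liver", "spleen", "tumour", "cortex-L", "medulla-L",
              "cortex-R", "medulla-R", "background")
  stl <- c(1306.7, 124.9, 15.9, 90.9, 42.9, 75.7, 35.7, 8297)
  fills <- rbind(
    c(100.08, 99.84, 100.04, 99.95, 100.13, 99.89),
    c(99.43, 99.45, 99.40, 99.21, 99.29, 99.23),
    c(99.6, 99.4, 99.2, 99.5, 99.7, 94.8),
    c(97.69, 96.48, 98.92, 98.14, 98.33, 98.40),
    c(99.05, 97.19, 102.04, 97.47, 97.72, 97.19),
    c(99.29, 98.89, 99.59, 98.65, 99.48, 98.72),
    c(96.20, 97.06, 96.56, 96.45, 97.32, 97.60),
    c(98.25, 98.25, 98.25, 98.35, 98.28, 98.24))
  us <- c(0.01, 0.02, 0.1, 0.02, 0.05, 0.03, 0.06, 0.03)
  data.frame(
    compartment = rep(organs, each = 6),
    stl_volume_mL = rep(stl, each = 6),
    scan = rep(1:6, times = 8),
    fill_pct = as.vector(t(fills)),
    fill_u_pct = rep(us, each = 6),
    stringsAsFactors = FALSE
  )
}

#' Reference SPECT-calibration inserts
#'
#' Gravimetric volumes of the six sphere inserts of the calibration body
#' phantom, with a nominal stock concentration of 2.00(6) MBq/mL, used for
#' quantitative-imaging calibration fill planning.
#'
#' @return List with `sphere_volumes_mL` (a list of [uvalue]s) and
#'   `stock_conc` (a [uvalue], MBq/mL).
#' @export
reference_calibration_data <- function() {
  vols <- c(0.53, 1.17, 2.54, 5.58, 11.59, 26.7)
  us <- c(0.02, 0.02, 0.02, 0.02, 0.02, 0.2)
  list(
    sphere_volumes_mL = Map(uvalue, vols, us, "mL"),
    stock_conc = uvalue(2.00, 0.06, "MBq/mL")
  )
}

#' Compare achieved against modelled concentrations
#'
#' Per (compartment, scan) entry, computes the percent deviation
#' `100 (achieved - model) / model`, its uncertainty (the achieved value's
#' relative uncertainty scaled accordingly), and an agreement flag
#' `|deviation| <= coverage * u`. The summary is the arithmetic mean of the
#' deviations with the sample standard deviation as its quoted uncertainty.
#'
#' @param achieved data frame with columns `compartment`, `scan`, `value`,
#'   `u` (achieved concentrations and standard uncertainties).
#' @param model data frame with columns `compartment`, `scan`, `value`
#'   (modelled concentrations).
#' @param coverage coverage factor for the agreement flag (default 2).
#' @return An object of class `fill_report`: list with `rows` (per-entry
#'   data frame) and `mean_deviation` (a [uvalue], percent).
#' @export
deviation_report <- function(achieved, model, coverage = 2) {
  key_a <- paste(achieved$compartment, achieved$scan)
  key_m <- paste(model$compartment, model$scan)
  miss_in_m <- setdiff(key_a, key_m)
  miss_in_a <- setdiff(key_m, key_a)
  if (length(miss_in_m) || length(miss_in_a))
    stop("alignment error: keys missing from ",
         if (length(miss_in_m)) paste0("model: ", paste(miss_in_m, collapse = "; ")),
         if (length(miss_in_m) && length(miss_in_a)) " and ",
         if (length(miss_in_a)) paste0("achieved: ", paste(miss_in_a, collapse = "; ")))
  m_val <- model$value[match(key_a, key_m)]
  dev <- 100 * (achieved$value - m_val) / m_val
  dev_u <- 100 * achieved$u / m_val
  rows <- data.frame(
    compartment = achieved$compartment,
    scan = achieved$scan,
    achieved = achieved$value,
    achieved_u = achieved$u,
    model = m_val,
    deviation_pct = dev,
    deviation_u_pct = dev_u,
    agrees = abs(dev) <= coverage * dev_u,
    stringsAsFactors = FALSE
  )
  sd_dev <- if (length(dev) > 1) stats::sd(dev) else 0
  structure(list(rows = rows,
                 mean_deviation = uvalue(mean(dev), sd_dev, "%"),
                 coverage = coverage),
            class = "fill_report")
}

#' @export
print.fill_report <- function(x, ...) {
  cat("Fill deviation report:", nrow(x$rows), "entries;",
      sum(x$rows$agrees), "within k =", x$coverage, "agreement\n")
  cat("Mean deviation from model:", format_concise(x$mean_deviation), "%\n")
  invisible(x)
}

#' Underfill range of one compartment across scans
#'
#' Underfill is `100 - fill fraction` in percent. Overfilled scans
#' (negative underfill) are excluded from the range and reported
#' separately. The range is rounded to 2 decimals (round-half-even).
#'
#' @param fill_pct numeric vector of fill fractions in percent (one per
#'   scan), or a list of [uvalue]s.
#' @return List with `range` (`c(min, max)` underfill percent, or `NULL`
#'   if every scan was overfilled) and `overfill_pct` (the overfill
#'   magnitudes of excluded scans).
#' @export
underfill_range <- function(fill_pct) {
  if (is.list(fill_pct)) fill_pct <- vapply(fill_pct, `[[`, numeric(1), "value")
  if (!length(fill_pct)) stop("at least one fill fraction is required")
  under <- 100 - fill_pct
  over <- -under[under < 0]
  under <- under[under >= 0]
  list(
    range = if (length(under)) round(range(under), 2) else NULL,
    overfill_pct = round(over, 2)
  )
}

#' Fill-fraction summary table
#'
#' One row per compartment: the design STL volume followed by the fill
#' fraction of each scan in concise parenthesis notation, matching the
#' layout used to report phantom-filling accuracy.
#'
#' @param fills data frame as from [reference_fill_fractions()]: columns
#'   `compartment`, `stl_volume_mL`, `scan`, `fill_pct`, `fill_u_pct`.
#' @return An object of class `fill_table`: character matrix `text` (one
#'   column per scan) plus the input data; prints as aligned text and can
#'   be written with [write_fill_table_csv()].
#' @export
fill_table <- function(fills) {
  need <- c("compartment", "stl_volume_mL", "scan", "fill_pct", "fill_u_pct")
  if (!all(need %in% names(fills)))
    stop("fills must have columns: ", paste(need, collapse = ", "))
  if (nrow(fills) == 0L)
    stop("alignment error: no fill records to tabulate")
  comps <- unique(fills$compartment)
  scans <- sort(unique(fills$scan))
  per_comp <- split(fills, fills$compartment)
  bad <- names(per_comp)[vapply(per_comp, function(d)
    !identical(sort(d$scan), scans), logical(1))]
  if (length(bad))
    stop("alignment error: inconsistent scan sets for compartment(s): ",
         paste(bad, collapse = ", "))
  txt <- matrix("", length(comps), length(scans),
                dimnames = list(comps, paste0("scan", scans)))
  for (i in seq_len(nrow(fills))) {
    txt[fills$compartment[i], paste0("scan", fills$scan[i])] <-
      format_concise(uvalue(fills$fill_pct[i], fills$fill_u_pct[i], "%"))
  }
  stl <- fills$stl_volume_mL[match(comps, fills$compartment)]
  structure(list(text = txt, stl_volume_mL = stats::setNames(stl, comps),
                 data = fills), class = "fill_table")
}

#' @export
print.fill_table <- function(x, ...) {
  df <- data.frame(STL_mL = format(x$stl_volume_mL, trim = TRUE),
                   x$text, check.names = FALSE)
  print(df)
  invisible(x)
}

#' @rdname fill_table
#' @param table a `fill_table`.
#' @param path output CSV path.
#' @export
write_fill_table_csv <- function(table, path) {
  stopifnot(inherits(table, "fill_table"))
  df <- data.frame(compartment = rownames(table$text),
                   stl_volume_mL = as.numeric(table$stl_volume_mL),
                   table$text, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Parse a rendered fill table back to numbers
#'
#' Inverse of [fill_table()] at displayed precision; used for round-trip
#' verification of report rendering.
#'
#' @param table a `fill_table`.
#' @return Data frame in the same layout as [reference_fill_fractions()].
#' @export
parse_fill_table <- function(table) {
  stopifnot(inherits(table, "fill_table"))
  txt <- table$text
  out <- do.call(rbind, lapply(rownames(txt), function(comp) {
    uv <- lapply(txt[comp, ], parse_concise)
    data.frame(compartment = comp,
               stl_volume_mL = as.numeric(table$stl_volume_mL[comp]),
               scan = seq_len(ncol(txt)),
               fill_pct = vapply(uv, `[[`, numeric(1), "value"),
               fill_u_pct = vapply(uv, `[[`, numeric(1), "u"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export a voxel activity-concentration map
#'
#' Assigns each labelled voxel the activity concentration of its
#' compartment role at one timepoint, yielding the digital ground-truth
#' counterpart of the filled phantom. Total activity is conserved exactly:
#' the sum of voxel values times voxel volume equals the sum over
#' compartments of concentration times compartment voxel volume.
#'
#' @param phantom a `voxel_phantom`.
#' @param conc_table long concentration table (one timepoint) with columns
#'   `compartment` and `conc_MBq_per_mL`; the `body` role takes the
#'   `background` concentration.
#' @param path optional NIfTI output path (`.nii` / `.nii.gz`); spacing is
#'   written into the header.
#' @return 3-D numeric array of MBq/mL, invisibly when `path` is given.
#' @export
export_activity_map <- function(phantom, conc_table, path = NULL) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (length(unique(conc_table$time_h %||% 0)) > 1)
    stop("conc_table must hold exactly one timepoint")
  conc <- stats::setNames(conc_table$conc_MBq_per_mL, conc_table$compartment)
  ot <- phantom$organ_table
  present <- ot[ot$id %in% unique(as.vector(phantom$labels)), , drop = FALSE]
  lookup_role <- ifelse(present$role == "body", "background", present$role)
  missing_roles <- present$role[!lookup_role %in% names(conc)]
  if (length(missing_roles))
    stop("mapping error: no concentration for compartment(s): ",
         paste(missing_roles, collapse = ", "))
  lut <- numeric(max(ot$id) + 1L)  # index = label + 1; label 0 -> 0
  lut[present$id + 1L] <- conc[lookup_role]
  map <- array(lut[phantom$labels + 1L], dim = dim(phantom$labels))
  if (!is.null(path)) {
    img <- RNifti::asNifti(map)
    RNifti::pixdim(img) <- phantom$spacing
    RNifti::writeNifti(img, path)
    return(invisible(map))
  }
  map
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON run summary for provenance
#'
#' Records package and R versions, a hash of the configuration, and any
#' named inputs, so that exported datasets carry their provenance.
#'
#' @param path output JSON path.
#' @param inputs named list of input descriptions.
#' @param config configuration list to hash (YAML-serialized, MD5).
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(path, inputs = list(), config = NULL) {
  cfg_hash <- NULL
  if (!is.null(config)) {
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    yaml::write_yaml(config, tf)
    cfg_hash <- unname(tools::md5sum(tf))
  }
  summary <- list(
    package = "phantomforge",
    package_version = as.character(utils::packageVersion("phantomforge")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = cfg_hash,
    inputs = inputs
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
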