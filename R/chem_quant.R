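#' Fit a linear calibration curve
#'
#' Ordinary least-squares line through (standard level, instrument response)
#' pairs, e.g. monosaccharide standards over 2.5-200 uM or glucose standards
#' over 0-2 mg for the DNS assay.
#'
#' @param levels Standard concentrations or masses (>= 3 distinct values).
#' @param responses Instrument responses, same length.
#' @param analyte Analyte label.
#' @param unit Unit of the standard levels (e.g. "uM", "mg").
#' @return Object of class \code{calibration_curve}: slope, intercept,
#'   \code{r_squared}, \code{range} (of the standards), plus the inputs.
#'   Warns when R-squared falls below 0.99.
#' @export
fit_calibration <- function(levels, responses, analyte = "", unit = "") {
  if (length(levels) != length(responses)) stopf("levels/responses mismatch")
  if (length(levels) < 3) stopf("at least 3 calibration standards are required")
  if (length(unique(levels)) < 2) stopf("calibration levels must be distinct")
  fit <- stats::lm(responses ~ levels)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stopf("calibration slope is zero")
  sst <- sum((responses - mean(responses))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  if (r2 < 0.99) warnf("calibration R^2 = %.4f below 0.99 for %s", r2, analyte)
  structure(list(analyte = analyte, unit = unit,
                 levels = levels, responses = responses,
                 slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, range = range(levels)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("calibration_curve", if (nzchar(x$analyte)) paste0("(", x$analyte, ")"),
      ": response =", signif(x$slope, 6), "x level +",
      signif(x$intercept, 6), "\n")
  cat("  R^2 =", signif(x$r_squared, 6), "| valid range",
      paste(x$range, collapse = "-"), x$unit, "\n")
  invisible(x)
}

#' Predict the response of a calibration curve at given levels
#' @param object A \code{calibration_curve}.
#' @param levels Standard levels.
#' @param ... Unused.
#' @export
predict.calibration_curve <- function(object, levels, ...) {
  object$intercept + object$slope * levels
}

#' Quantify a signal against a calibration curve
#'
#' Inverts the calibration line: \code{level = (signal - intercept) / slope
#' * dilution}, normalized per unit sample mass. Values outside 0.5x-2x the
#' calibration range are flagged \code{"extrapolated"}; negative computed
#' levels are clamped to 0 and flagged \code{"clamped"}.
#'
#' @param signal Instrument signal(s).
#' @param curve A [fit_calibration()] object.
#' @param dilution Dilution factor applied to the computed level.
#' @param mass Sample mass (the per-mg denominator); must be positive.
#' @return Data frame \code{quantity} (level x dilution / mass) and
#'   \code{flag}.
#' @export
quantify <- function(signal, curve, dilution = 1, mass = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(mass <= 0)) stopf("sample mass must be positive")
  level <- (signal - curve$intercept) / curve$slope * dilution
  flag <- rep("", length(level))
  lo <- 0.5 * curve$range[1]
  hi <- 2 * curve$range[2]
  raw_level <- (signal - curve$intercept) / curve$slope
  flag[!is.na(raw_level) & (raw_level < lo | raw_level > hi)] <- "extrapolated"
  neg <- !is.na(level) & level < 0
  level[neg] <- 0
  flag[neg] <- trimws(paste(flag[neg], "clamped"))
  data.frame(quantity = level / mass, flag = flag, stringsAsFactors = FALSE)
}

#' Acetyl-bromide soluble lignin (%ABSL)
#'
#' Beer-Lambert quantification of lignin from the 280 nm absorbance of an
#' acetyl-bromide digest:
#' \deqn{\%ABSL = 100 \times \frac{A_{280}}{\varepsilon \cdot path} \times
#'   \frac{volume}{mass}}
#' with the default extinction coefficient 18.19509 g^-1 L cm^-1, the average
#' of known commelinid coefficients.
#'
#' @param a280 Absorbance at 280 nm (>= 0).
#' @param mass_g Sample mass in grams (> 0).
#' @param volume_l Extract volume in litres (> 0).
#' @param path_cm Cuvette path length in cm (> 0, default 1).
#' @param epsilon Extinction coefficient in g^-1 L cm^-1.
#' @return Percent lignin by mass.
#' @examples
#' acetyl_bromide_lignin(0.910, mass_g = 0.005, volume_l = 0.005)  # ~5.0%
#' @export
acetyl_bromide_lignin <- function(a280, mass_g, volume_l, path_cm = 1,
                                  epsilon = 18.19509) {
  if (any(a280 < 0)) stopf("absorbance must be nonnegative")
  if (any(mass_g <= 0) || any(volume_l <= 0) || any(path_cm <= 0)) {
    stopf("mass, volume and path length must be positive")
  }
  if (epsilon <= 0) stopf("extinction coefficient must be positive")
  100 * (a280 / (epsilon * path_cm)) * volume_l / mass_g
}

#' Saccharification efficiency from a DNS time series
#'
#' Converts DNS absorbances at 0/24/48/72 h to glucose-equivalent mass via a
#' glucose calibration curve, subtracts the pre-incubation (T0) value, and
#' reports net released sugar per mg biomass. Negative net release is
#' floored at 0 and flagged; missing timepoints yield NA.
#'
#' @param signals Named numeric vector of DNS signals; names are hours
#'   ("0", "24", "48", "72"). A T0 ("0") entry is required.
#' @param glucose_curve Calibration curve on glucose standards (mg).
#' @param mass_mg Sample biomass in mg.
#' @param times Expected timepoints in hours.
#' @return Data frame \code{time_h}, \code{glucose}, \code{net_release}
#'   (per mg biomass), \code{flag}.
#' @export
saccharification_efficiency <- function(signals, glucose_curve, mass_mg,
                                        times = c(0, 24, 48, 72)) {
  stopifnot(inherits(glucose_curve, "calibration_curve"))
  if (any(mass_mg <= 0)) stopf("biomass must be positive")
  nm <- as.numeric(names(signals))
  if (!0 %in% nm) stopf("a T0 (0 h) measurement is required")
  s <- signals[match(times, nm)]
  q <- quantify(as.numeric(s), glucose_curve)
  glu <- q$quantity
  t0 <- glu[times == 0]
  net <- (glu - t0) / mass_mg
  flag <- q$flag
  neg <- !is.na(net) & net < 0
  net[neg] <- 0
  flag[neg] <- trimws(paste(flag[neg], "floored"))
  flag[is.na(glu)] <- "missing"
  data.frame(time_h = times, glucose = glu, net_release = net,
             flag = flag, stringsAsFactors = FALSE)
}

#' Read / write analyte tables
#'
#' Long-format TSV with columns analyte, tissue, genotype, condition, week,
#' replicate, quantity, and optionally unit; unit mismatches within an
#' analyte are rejected at load time.
#'
#' @param path TSV path.
#' @param table Analyte table data frame.
#' @return \code{read_analyte_table} returns the data frame.
#' @export
read_analyte_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("analyte", "tissue", "genotype", "condition", "week",
              "replicate", "quantity")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) stopf("analyte table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (any(tab$quantity < 0, na.rm = TRUE)) stopf("quantities must be nonnegative")
  if ("unit" %in% names(tab)) {
    per <- tapply(tab$unit, tab$analyte, function(u) length(unique(u)))
    if (any(per > 1)) {
      stopf("inconsistent units for analyte(s): %s",
            paste(names(per)[per > 1], collapse = ", "))
    }
  }
  tab
}

#' @rdname read_analyte_table
#' @export
write_analyte_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
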