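#' @include photometry.R
NULL

.quantReport <- function(molar_nM, mac, legacy_ug_ml = NA_real_,
                         fit = list(), volume_ul = NA_real_) {
  mass <- molar_nM * mac@mol_weight * 1e-6      # nM x g/mol -> ng/uL
  total_umol <- if (is.na(volume_ul)) NA_real_ else molar_nM * volume_ul * 1e-9
  total_ug <- if (is.na(volume_ul)) NA_real_ else mass * volume_ul * 1e-3
  new("QuantReport", molar_nM = molar_nM, mass_ng_ul = mass,
      total_umol = total_umol, total_ug = total_ug, volume_ul = volume_ul,
      legacy_ug_ml = legacy_ug_ml, mac = mac, fit = fit)
}

#' Stock concentration from a single A260 reading
#'
#' Beer-Lambert: stock molar concentration
#' `(a260 / (mac_260 x path_length)) x dilution`, reported in nM; the mass
#' concentration follows via the molecular weight. The legacy 40 ug/mL
#' estimate is carried alongside for comparison.
#'
#' @param a260 absorbance at 260 nm of the measured (diluted) aliquot.
#' @param mac a [MacResult-class] for the construct.
#' @param dilution fold-dilution of the aliquot relative to stock
#'   (default 1).
#' @param path_length cuvette path in cm (default 1; microvolume
#'   instruments that normalize internally report 1 cm equivalents).
#' @return a [QuantReport-class] (totals NA until [totals()] is applied).
#' @export
#' @examples
#' tbl <- loadNucleosideTable()
#' mac <- macResult(seqComposition(strrep("ACGU", 25)), tbl)
#' concentrationFromA260(0.25, mac, dilution = 20)
concentrationFromA260 <- function(a260, mac, dilution = 1, path_length = 1) {
  stopifnot(is(mac, "MacResult"))
  if (!is.finite(a260) || a260 < 0)
    stopValidation("a260 must be finite and >= 0")
  if (!is.finite(dilution) || dilution < 1)
    stopValidation("dilution must be finite and >= 1")
  if (!is.finite(path_length) || path_length <= 0)
    stopValidation("path_length must be > 0")
  if (mac@mac_260 <= 0)
    stopValidation("MAC260 is 0 (empty sequence?): concentration undefined")
  molar_nM <- a260 / (mac@mac_260 * path_length) * dilution * 1e9
  .quantReport(molar_nM, mac,
               legacy_ug_ml = legacyMassConcentration(a260, dilution))
}

#' Construct a dilution series
#'
#' @param dilution numeric vector of fold-dilution factors, one per
#'   replicate reading (replicates repeat the factor).
#' @param a260 numeric vector of absorbance readings (parallel).
#' @param path_length cuvette path in cm.
#' @param truth optional list of generator ground truth.
#' @return a [DilutionSeries-class].
#' @export
dilutionSeries <- function(dilution, a260, path_length = 1, truth = list()) {
  if (length(dilution) != length(a260))
    stopValidation("dilution and a260 must have equal length")
  new("DilutionSeries",
      measurements = data.frame(dilution = as.numeric(dilution),
                                a260 = as.numeric(a260)),
      path_length = path_length, truth = truth)
}

#' Read a dilution-series CSV
#'
#' Expected dialect: header `dilution,a260`, one row per replicate
#' reading.
#'
#' @param path CSV file path.
#' @param path_length cuvette path in cm.
#' @return a [DilutionSeries-class].
#' @export
readSeriesCSV <- function(path, path_length = 1) {
  if (!file.exists(path)) stopIO("series file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stopIO("cannot read series CSV '", path,
                                            "': ", conditionMessage(e)))
  if (!all(c("dilution", "a260") %in% names(df)))
    stopValidation("series CSV must have header columns 'dilution' and ",
                   "'a260'; found: ", paste(names(df), collapse = ", "))
  dilutionSeries(df$dilution, df$a260, path_length = path_length)
}

#' @describeIn readSeriesCSV write a series in the same dialect.
#' @param series a [DilutionSeries-class].
#' @return `path`, invisibly.
#' @export
writeSeriesCSV <- function(series, path) {
  stopifnot(is(series, "DilutionSeries"))
  write.csv(series@measurements[, c("dilution", "a260")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit a serial-dilution series and report the stock concentration
#'
#' Averages replicate A260 readings per dilution point (unless
#' `pooled = TRUE`, which regresses every replicate) and fits an
#' ordinary-least-squares line of A260 against 1/dilution, with
#' intercept. Under Beer-Lambert the slope equals
#' `mac_260 x path_length x stock concentration`, so the slope yields the
#' stock concentration while spreading handling error across the whole
#' ladder; the intercept is a blank/baseline diagnostic and a fitted
#' intercept beyond +/-0.005 AU raises a warning. A series with a single
#' dilution point falls back to [concentrationFromA260()] on the mean
#' reading.
#'
#' @param series a [DilutionSeries-class].
#' @param mac a [MacResult-class].
#' @param pooled regress per-replicate instead of per-point means.
#' @param intercept_tol absolute intercept (AU) beyond which the baseline
#'   warning fires (default 0.005).
#' @return a [QuantReport-class] with fit diagnostics (slope, intercept,
#'   Pearson r, residuals).
#' @export
fitDilutionSeries <- function(series, mac, pooled = FALSE,
                              intercept_tol = 0.005) {
  stopifnot(is(series, "DilutionSeries"), is(mac, "MacResult"))
  validObject(series)
  if (mac@mac_260 <= 0)
    stopValidation("MAC260 is 0 (empty sequence?): concentration undefined")
  m <- series@measurements
  ladder <- sort(unique(m$dilution))
  if (length(ladder) == 1L) {
    rep <- concentrationFromA260(mean(m$a260), mac, dilution = ladder,
                                 path_length = series@path_length)
    return(rep)
  }
  if (pooled) {
    x <- 1 / m$dilution
    y <- m$a260
  } else {
    means <- tapply(m$a260, m$dilution, mean)
    x <- 1 / as.numeric(names(means))
    y <- as.numeric(means)
  }
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  r <- cor(x, y)
  warn <- is.finite(intercept) && abs(intercept) > intercept_tol
  if (warn)
    warning(sprintf(paste0("fitted intercept %.4f AU exceeds +/-%.3f: ",
                           "check blanks/baseline"), intercept, intercept_tol),
            call. = FALSE)
  molar_nM <- slope / (mac@mac_260 * series@path_length) * 1e9
  .quantReport(molar_nM, mac,
               fit = list(slope = slope, intercept = intercept, r = r,
                          residuals = unname(residuals(fit)),
                          n_points = length(x),
                          intercept_warning = warn))
}

#' Fit a molar absorption coefficient from calibration data
#'
#' Estimates epsilon from measurements of known concentrations:
#' ordinary-least-squares regression of absorbance on molar concentration;
#' the slope divided by the path length is the coefficient, and the
#' Pearson correlation reports linearity (a sound calibration exceeds
#' r = 0.9999). Readings above 1.0 AU trigger a linear-range warning.
#'
#' @param concentrations known molar concentrations (M).
#' @param absorbances measured absorbances (parallel vector).
#' @param path_length cuvette path in cm.
#' @return list with `epsilon_hat` (M^-1 cm^-1), `r`, `slope`,
#'   `intercept`.
#' @export
#' @examples
#' conc <- seq(1e-5, 1e-4, length.out = 8)
#' fitBeerLambert(conc, 9000 * conc)
fitBeerLambert <- function(concentrations, absorbances, path_length = 1) {
  if (length(concentrations) != length(absorbances))
    stopValidation("concentrations and absorbances must have equal length")
  if (length(unique(concentrations)) < 2L)
    stopValidation("degenerate design: need >= 2 distinct concentrations")
  if (any(!is.finite(concentrations)) || any(!is.finite(absorbances)))
    stopValidation("concentrations and absorbances must be finite")
  if (any(absorbances > 1))
    warning("absorbance readings above 1.0 AU are outside the stated ",
            "linear range", call. = FALSE)
  fit <- lm(absorbances ~ concentrations)
  slope <- unname(coef(fit)[2])
  list(epsilon_hat = slope / path_length,
       r = cor(concentrations, absorbances),
       slope = slope,
       intercept = unname(coef(fit)[1]))
}

#' Add total amounts to a report
#'
#' Multiplies the stock concentrations by the stock volume:
#' total amount in umol (`nM x uL x 1e-9`) and total mass in ug
#' (`ng/uL x uL x 1e-3`).
#'
#' @param report a [QuantReport-class].
#' @param stock_volume_ul stock volume in uL (> 0).
#' @return the report with totals filled in.
#' @export
totals <- function(report, stock_volume_ul) {
  stopifnot(is(report, "QuantReport"))
  if (!is.finite(stock_volume_ul) || stock_volume_ul <= 0)
    stopValidation("stock volume must be > 0 uL")
  .quantReport(report@molar_nM, report@mac,
               legacy_ug_ml = report@legacy_ug_ml, fit = report@fit,
               volume_ul = stock_volume_ul)
}

#' Serialize a report
#'
#' @param report a [QuantReport-class].
#' @return named list of all report fields at full precision (JSON-ready).
#' @export
reportAsList <- function(report) {
  stopifnot(is(report, "QuantReport"))
  out <- list(
    molar_nM = report@molar_nM,
    mass_ng_ul = report@mass_ng_ul,
    total_umol = report@total_umol,
    total_ug = report@total_ug,
    volume_ul = report@volume_ul,
    legacy_ug_ml = report@legacy_ug_ml,
    mac_260 = report@mac@mac_260,
    mol_weight = report@mac@mol_weight,
    mass_extinction = report@mac@mass_extinction)
  if (length(report@fit))
    out$fit <- report@fit[c("slope", "intercept", "r", "n_points",
                            "intercept_warning")]
  out
}

setMethod("show", "DilutionSeries", function(object) {
  m <- object@measurements
  cat("DilutionSeries: ", length(unique(m$dilution)), " dilution point(s), ",
      nrow(m), " reading(s), path ", object@path_length, " cm\n", sep = "")
  if (length(object@truth))
    cat("  simulated truth: stock ", format(object@truth$stock_nM),
        " nM, CV ", format(object@truth$cv), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "QuantReport", function(object) {
  cat("QuantReport\n")
  fmt <- function(x) format(signif(x, 4), big.mark = ",")
  cat(sprintf("  stock conc.: %s nM = %s ng/uL\n",
              fmt(object@molar_nM), fmt(object@mass_ng_ul)))
  if (!is.na(object@volume_ul))
    cat(sprintf("  totals (%s uL): %s umol, %s ug\n", fmt(object@volume_ul),
                fmt(object@total_umol), fmt(object@total_ug)))
  if (!is.na(object@legacy_ug_ml))
    cat(sprintf("  legacy 40 ug/mL estimate: %s ug/mL\n",
                fmt(object@legacy_ug_ml)))
  if (length(object@fit))
    cat(sprintf("  fit: slope %s, intercept %s AU, r = %.6f%s\n",
                fmt(object@fit$slope), fmt(object@fit$intercept),
                object@fit$r,
                if (isTRUE(object@fit$intercept_warning))
                  " [baseline warning]" else ""))
  invisible(NULL)
})
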