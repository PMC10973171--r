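#' @include rnaMAC-package.R
NULL

#' NucleosideTable: photometric and mass constants for nucleosides and caps
#'
#' Holds one row per nucleoside code (`A`, `C`, `G`, `U`, `T`, `Y`
#' (pseudouridine), `m1Y` (N1-methylpseudouridine), `m5C`, `m7G`, ...) with
#' its absorption peak wavelength (`lambda_max`, nm), molar absorption
#' coefficient at the peak (`eps_max`) and at 260 nm (`eps_260`), both in
#' M^-1 cm^-1, and the average mass of the internal monophosphate residue
#' (`residue_mass`, g/mol); plus one row per cap code (`none`, `cap0`,
#' `cap1`) with the additional 260 nm absorption (`eps_260_add`) and mass
#' (`mass_add`) contributed by the cap moiety.
#'
#' Validity enforces: positive coefficients, `eps_260 <= eps_max`,
#' `lambda_max` within 200-300 nm, positive residue masses, unique codes,
#' the mandatory code set, zero absorption for the `none` cap, identical
#' `eps_260_add` for cap0/cap1 (2'-O-methylation adds no chromophore), and
#' a one-methyl mass difference between cap1 and cap0.
#'
#' @slot entries data.frame of nucleoside rows (code, name, lambda_max,
#'   eps_max, eps_260, residue_mass, source).
#' @slot caps data.frame of cap rows (code, eps_260_add, mass_add, source).
#' @slot source character(1), provenance ("builtin" or a file path).
#' @seealso [loadNucleosideTable()], [nucleosides()], [capSpecs()]
#' @export
setClass("NucleosideTable",
  representation(entries = "data.frame",
                 caps = "data.frame",
                 source = "character"))

.REQUIRED_CODES <- c("A", "C", "G", "U", "T", "Y", "m1Y", "m5C")
.CAP_CODES <- c("none", "cap0", "cap1")

setValidity("NucleosideTable", function(object) {
  e <- object@entries
  k <- object@caps
  msgs <- character()
  need <- c("code", "name", "lambda_max", "eps_max", "eps_260", "residue_mass")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(e$code))
    msgs <- c(msgs, paste0("duplicate nucleoside code(s): ",
                           paste(unique(e$code[duplicated(e$code)]), collapse = ", ")))
  for (i in seq_len(nrow(e))) {
    r <- e[i, ]
    bad <- function(msg) sprintf("nucleoside '%s': %s", r$code, msg)
    if (!is.finite(r$eps_max) || r$eps_max <= 0) msgs <- c(msgs, bad("eps_max must be > 0"))
    if (!is.finite(r$eps_260) || r$eps_260 <= 0) msgs <- c(msgs, bad("eps_260 must be > 0"))
    if (is.finite(r$eps_260) && is.finite(r$eps_max) && r$eps_260 > r$eps_max)
      msgs <- c(msgs, bad("eps_260 must not exceed eps_max"))
    if (!is.finite(r$lambda_max) || r$lambda_max < 200 || r$lambda_max > 300)
      msgs <- c(msgs, bad("lambda_max must lie in [200, 300] nm"))
    if (!is.finite(r$residue_mass) || r$residue_mass <= 0)
      msgs <- c(msgs, bad("residue_mass must be > 0"))
  }
  missing <- setdiff(.REQUIRED_CODES, e$code)
  if (length(missing))
    msgs <- c(msgs, paste0("missing mandatory nucleoside code(s): ",
                           paste(missing, collapse = ", ")))
  if (!all(c("code", "eps_260_add", "mass_add") %in% names(k)))
    return("caps must have columns: code, eps_260_add, mass_add")
  miscap <- setdiff(.CAP_CODES, k$code)
  if (length(miscap))
    msgs <- c(msgs, paste0("missing cap code(s): ", paste(miscap, collapse = ", ")))
  if (anyDuplicated(k$code))
    msgs <- c(msgs, "duplicate cap code(s)")
  if ("none" %in% k$code) {
    r <- k[k$code == "none", ]
    if (r$eps_260_add != 0 || r$mass_add != 0)
      msgs <- c(msgs, "cap 'none' must have eps_260_add = 0 and mass_add = 0")
  }
  if (all(c("cap0", "cap1") %in% k$code)) {
    c0 <- k[k$code == "cap0", ]; c1 <- k[k$code == "cap1", ]
    if (abs((c1$mass_add - c0$mass_add) - .MASS_METHYL) > 0.05)
      msgs <- c(msgs, "cap1.mass_add - cap0.mass_add must equal one methyl mass (~14.03)")
    if (c1$eps_260_add != c0$eps_260_add)
      msgs <- c(msgs, "cap1 and cap0 must share eps_260_add (no added chromophore)")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' ModScheme: canonical-to-modified substitution rules
#'
#' A set of substitutions, each replacing a fraction of one canonical
#' residue by a modified residue (e.g. all U by m1Y). At most one rule per
#' canonical code; fractions in \[0, 1\].
#'
#' @slot canonical character vector of canonical codes.
#' @slot modified character vector of modified codes (parallel).
#' @slot fraction numeric vector of substitution fractions (parallel).
#' @seealso [modScheme()], [parseScheme()], [applyScheme()]
#' @export
setClass("ModScheme",
  representation(canonical = "character",
                 modified = "character",
                 fraction = "numeric"))

setValidity("ModScheme", function(object) {
  n <- length(object@canonical)
  if (length(object@modified) != n || length(object@fraction) != n)
    return("canonical, modified and fraction must have equal length")
  if (anyDuplicated(object@canonical))
    return("at most one substitution rule per canonical code")
  if (any(object@canonical == object@modified))
    return("modified code must differ from canonical code")
  if (any(!is.finite(object@fraction)) ||
      any(object@fraction < 0) || any(object@fraction > 1))
    return("substitution fractions must lie in [0, 1]")
  TRUE
})

#' Composition: residue counts of a construct
#'
#' Residue counts after (optional) modification-scheme application, plus
#' the cap identity. Counts are kept real-valued internally so that MAC260
#' is exactly linear in the substitution fraction; [discreteCounts()]
#' rounds half-up when an integer report is wanted.
#'
#' @slot counts named numeric vector, residue code -> non-negative count.
#' @slot cap character(1), one of `none`, `cap0`, `cap1`.
#' @seealso [seqComposition()], [applyScheme()], [residueCounts()]
#' @export
setClass("Composition",
  representation(counts = "numeric", cap = "character"))

setValidity("Composition", function(object) {
  if (length(object@counts) && is.null(names(object@counts)))
    return("counts must be named by residue code")
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    return("counts must be finite and non-negative")
  if (length(object@cap) != 1L || !object@cap %in% .CAP_CODES)
    return(paste0("cap must be one of: ", paste(.CAP_CODES, collapse = ", ")))
  TRUE
})

#' MacResult: photometric summary of one construct
#'
#' @slot mac_260 molar absorption coefficient at 260 nm, M^-1 cm^-1.
#' @slot mol_weight average molecular weight, g/mol.
#' @slot mass_extinction mass concentration per absorbance unit at 1 cm
#'   path, ug/mL per AU (= 1000 x mol_weight / mac_260).
#' @slot composition the [Composition-class] snapshot it was computed from.
#' @slot five_prime character(1), the 5'-end convention used for the mass.
#' @seealso [macResult()]
#' @export
setClass("MacResult",
  representation(mac_260 = "numeric", mol_weight = "numeric",
                 mass_extinction = "numeric", composition = "Composition",
                 five_prime = "character"))

setValidity("MacResult", function(object) {
  if (object@mac_260 < 0) return("mac_260 must be >= 0")
  if (sum(object@composition@counts) > 0 && object@mol_weight <= 0)
    return("mol_weight must be > 0 for a non-empty composition")
  if (object@mac_260 > 0) {
    implied <- 1000 * object@mol_weight / object@mac_260
    if (abs(implied - object@mass_extinction) >
        1e-9 * max(1, abs(implied)))
      return("mass_extinction inconsistent with mol_weight / mac_260")
  }
  TRUE
})

#' DilutionSeries: replicate A260 readings over a dilution ladder
#'
#' Long-format measurements: one row per replicate reading, columns
#' `dilution` (fold factor >= 1) and `a260` (absorbance units >= 0).
#' Dilution factors must be distinct across ladder points (replicates at
#' the same factor share a row group).
#'
#' @slot measurements data.frame with columns dilution, a260.
#' @slot path_length cuvette path in cm (default 1).
#' @slot truth list, optional generator ground truth (stock_nM, cv, seed).
#' @seealso [dilutionSeries()], [readSeriesCSV()], [fitDilutionSeries()]
#' @export
setClass("DilutionSeries",
  representation(measurements = "data.frame", path_length = "numeric",
                 truth = "list"))

setValidity("DilutionSeries", function(object) {
  m <- object@measurements
  if (!all(c("dilution", "a260") %in% names(m)))
    return("measurements must have columns dilution and a260")
  if (nrow(m) < 1L) return("at least one measurement is required")
  if (any(!is.finite(m$dilution)) || any(m$dilution < 1))
    return("dilution factors must be finite and >= 1")
  if (any(!is.finite(m$a260)) || any(m$a260 < 0))
    return("a260 values must be finite and >= 0")
  if (length(object@path_length) != 1L || object@path_length <= 0)
    return("path_length must be a single positive number (cm)")
  TRUE
})

#' QuantReport: concentrations and totals for one construct
#'
#' Stock concentration in nM and ng/uL, total amounts in umol and ug
#' (NA until a stock volume is supplied via [totals()]), the legacy
#' 40 ug/mL-per-AU estimate for comparison, and regression diagnostics
#' when a dilution series was fitted.
#'
#' @slot molar_nM stock molar concentration, nM.
#' @slot mass_ng_ul stock mass concentration, ng/uL.
#' @slot total_umol total amount, umol (NA without volume).
#' @slot total_ug total mass, ug (NA without volume).
#' @slot volume_ul stock volume, uL (NA if not given).
#' @slot legacy_ug_ml legacy 40 x A260 x dilution estimate, ug/mL (NA for
#'   series fits, where no single A260 applies).
#' @slot mac the [MacResult-class] used.
#' @slot fit list of regression diagnostics (slope, intercept, r,
#'   residuals, n_points, intercept_warning) or empty for single readings.
#' @seealso [concentrationFromA260()], [fitDilutionSeries()], [totals()]
#' @export
setClass("QuantReport",
  representation(molar_nM = "numeric", mass_ng_ul = "numeric",
                 total_umol = "numeric", total_ug = "numeric",
                 volume_ul = "numeric", legacy_ug_ml = "numeric",
                 mac = "MacResult", fit = "list"))

setValidity("QuantReport", function(object) {
  mw <- object@mac@mol_weight
  if (mw > 0 && is.finite(object@molar_nM) && object@molar_nM > 0) {
    implied <- object@molar_nM * mw * 1e-6   # nM -> ng/uL
    if (abs(implied - object@mass_ng_ul) > 1e-9 * max(1, abs(implied)))
      return("mass_ng_ul inconsistent with molar_nM x mol_weight")
  }
  TRUE
})
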