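#' @include AllClasses.R
NULL

# Unicode spellings accepted on input; canonical ASCII tokens stored.
.CODE_ALIASES <- c(
  "Ψ" = "Y",            # Psi
  "ψ" = "Y",
  "m1Ψ" = "m1Y", "m1ψ" = "m1Y",
  "m¹Ψ" = "m1Y", "m¹ψ" = "m1Y",
  "m⁵C" = "m5C",
  "m⁷G" = "m7G")

#' Normalize a nucleoside code token
#'
#' Maps Unicode spellings (psi, superscripts) onto the ASCII registry
#' tokens (`Y`, `m1Y`, `m5C`, `m7G`); other tokens pass through unchanged.
#'
#' @param code character vector of tokens.
#' @return character vector of canonical tokens.
#' @export
#' @examples
#' normalizeCode(c("Ψ", "U", "m1Ψ"))
normalizeCode <- function(code) {
  hit <- code %in% names(.CODE_ALIASES)
  code[hit] <- .CODE_ALIASES[code[hit]]
  code
}

.NUC_FIELDS <- c("code", "name", "lambda_max", "eps_max", "eps_260",
                 "residue_mass", "source")
.NUC_NUMERIC <- c("lambda_max", "eps_max", "eps_260", "residue_mass")
.CAP_FIELDS <- c("code", "eps_260_add", "mass_add", "source")
.CAP_NUMERIC <- c("eps_260_add", "mass_add")

.parseConfigDCF <- function(path) {
  if (!file.exists(path)) stopIO("config file not found: ", path)
  mat <- tryCatch(read.dcf(path, all = FALSE),
                  error = function(e)
                    stopValidation("cannot parse config file '", path,
                                   "': ", conditionMessage(e)))
  if (nrow(mat) == 0L) stopValidation("config file '", path, "' has no blocks")
  blocks <- lapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    as.list(v[!is.na(v)])
  })
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (is.null(b$code))
      stopValidation("config block ", i, ": missing required key 'code'")
    type <- if (is.null(b$type)) "nucleoside" else b$type
    if (!type %in% c("nucleoside", "cap"))
      stopValidation("config block ", i, " (code ", b$code,
                     "): unknown type '", type, "'")
    num_keys <- intersect(names(b),
                          if (type == "cap") .CAP_NUMERIC else .NUC_NUMERIC)
    for (k in num_keys) {
      val <- suppressWarnings(as.numeric(b[[k]]))
      if (is.na(val))
        stopValidation("config block ", i, " (code ", b$code, "): key '", k,
                       "' is not numeric: '", b[[k]], "'")
      blocks[[i]][[k]] <- val
    }
    blocks[[i]]$type <- type
  }
  codes <- vapply(blocks, function(b) paste0(b$type, ":", b$code), "")
  if (anyDuplicated(codes))
    stopValidation("duplicate code(s) within '", path, "': ",
                   paste(unique(sub("^[a-z]+:", "", codes[duplicated(codes)])),
                         collapse = ", "))
  blocks
}

.emptyEntries <- function() {
  data.frame(code = character(), name = character(),
             lambda_max = numeric(), eps_max = numeric(),
             eps_260 = numeric(), residue_mass = numeric(),
             source = character(), stringsAsFactors = FALSE)
}

.emptyCaps <- function() {
  data.frame(code = character(), eps_260_add = numeric(),
             mass_add = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

# overlay parsed blocks onto (possibly empty) base tables, field-wise per code
.mergeBlocks <- function(entries, caps, blocks, origin) {
  for (b in blocks) {
    code <- normalizeCode(b$code)
    if (b$type == "nucleoside") {
      fields <- setdiff(intersect(names(b), .NUC_FIELDS), "code")
      i <- match(code, entries$code)
      if (is.na(i)) {
        missing <- setdiff(setdiff(.NUC_FIELDS, c("source")),
                           c("code", fields))
        if (length(missing))
          stopValidation("new nucleoside '", code, "' in ", origin,
                         " is missing field(s): ",
                         paste(missing, collapse = ", "))
        entries <- rbind(entries, data.frame(
          code = code, name = b$name, lambda_max = b$lambda_max,
          eps_max = b$eps_max, eps_260 = b$eps_260,
          residue_mass = b$residue_mass,
          source = if (is.null(b$source)) origin else b$source,
          stringsAsFactors = FALSE))
      } else {
        for (f in fields) entries[i, f] <- b[[f]]
      }
    } else {
      fields <- setdiff(intersect(names(b), .CAP_FIELDS), "code")
      i <- match(code, caps$code)
      if (is.na(i)) {
        missing <- setdiff(c("eps_260_add", "mass_add"), fields)
        if (length(missing))
          stopValidation("new cap '", code, "' in ", origin,
                         " is missing field(s): ",
                         paste(missing, collapse = ", "))
        caps <- rbind(caps, data.frame(
          code = code, eps_260_add = b$eps_260_add, mass_add = b$mass_add,
          source = if (is.null(b$source)) origin else b$source,
          stringsAsFactors = FALSE))
      } else {
        for (f in fields) caps[i, f] <- b[[f]]
      }
    }
  }
  list(entries = entries, caps = caps)
}

#' Load the nucleoside photometric table
#'
#' Reads the builtin table of photometric constants (lambda_max, eps_max,
#' eps_260) and residue masses for the standard residues A/C/G/U, the
#' modified residues Y (pseudouridine), m1Y (N1-methylpseudouridine), m5C,
#' T (5-methyluridine), the cap chromophore m7G, and the cap structures
#' none/cap0/cap1. An optional user config (same block format, see
#' [writeNucleosideTable()] for the schema) is overlaid per code and per
#' field, so a file containing only `code: U` and `eps_260: 9800` changes
#' exactly that one value.
#'
#' The builtin coefficients describe nucleosides in neutral aqueous buffer
#' (pH 7.4); no temperature, pH, or ionic-strength dependence is modelled.
#'
#' @param config_path optional path to an override config file.
#' @return a validated [NucleosideTable-class].
#' @export
#' @examples
#' tbl <- loadNucleosideTable()
#' nucleosides(tbl)[, c("code", "eps_260")]
loadNucleosideTable <- function(config_path = NULL) {
  builtin <- system.file("extdata", "nucleosides.dcf", package = "rnaMAC",
                         mustWork = TRUE)
  base <- .mergeBlocks(.emptyEntries(), .emptyCaps(),
                       .parseConfigDCF(builtin), "builtin")
  src <- "builtin"
  if (!is.null(config_path)) {
    base <- .mergeBlocks(base$entries, base$caps,
                         .parseConfigDCF(config_path), config_path)
    src <- config_path
  }
  rownames(base$entries) <- NULL
  rownames(base$caps) <- NULL
  new("NucleosideTable", entries = base$entries, caps = base$caps,
      source = src)
}

#' Write a nucleoside table to the config format
#'
#' Serializes a [NucleosideTable-class] as Debian-control-style blocks
#' (`key: value` lines, blank-line separated), one block per nucleoside or
#' cap. Reloading the file with [loadNucleosideTable()] as an override of
#' an empty base reproduces the table field-for-field; the format doubles
#' as the schema for user overrides.
#'
#' @param tbl a [NucleosideTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNucleosideTable <- function(tbl, path) {
  stopifnot(is(tbl, "NucleosideTable"))
  e <- tbl@entries
  e <- cbind(type = "nucleoside", e)
  k <- tbl@caps
  k <- cbind(type = "cap", k)
  con <- file(path, "w")
  on.exit(close(con))
  writeBlock <- function(row) {
    for (f in names(row)) {
      val <- row[[f]]
      if (is.numeric(val)) val <- format(val, digits = 15)
      cat(f, ": ", val, "\n", sep = "", file = con)
    }
    cat("\n", file = con)
  }
  for (i in seq_len(nrow(e))) writeBlock(as.list(e[i, ]))
  for (i in seq_len(nrow(k))) writeBlock(as.list(k[i, ]))
  invisible(path)
}

#' @describeIn loadNucleosideTable nucleoside entries as a data.frame.
#' @param tbl a [NucleosideTable-class].
#' @export
nucleosides <- function(tbl) tbl@entries

#' @describeIn loadNucleosideTable cap entries as a data.frame.
#' @export
capSpecs <- function(tbl) tbl@caps

#' Look up one nucleoside entry
#'
#' @param tbl a [NucleosideTable-class].
#' @param code nucleoside code (Unicode aliases accepted).
#' @return one-row data.frame with the entry's fields.
#' @export
getNucleoside <- function(tbl, code) {
  code <- normalizeCode(code)
  i <- match(code, tbl@entries$code)
  if (is.na(i)) stopLookup(code)
  tbl@entries[i, ]
}

#' Look up one cap entry
#'
#' @inheritParams getNucleoside
#' @param code cap code (`none`, `cap0`, `cap1`).
#' @return one-row data.frame with eps_260_add and mass_add.
#' @export
getCap <- function(tbl, code) {
  i <- match(code, tbl@caps$code)
  if (is.na(i)) stopLookup(code, "cap table")
  tbl@caps[i, ]
}

#' Percent difference in molar absorption between two nucleosides
#'
#' Computes `100 * (eps_mod - eps_ref) / eps_ref` at 260 nm
#' (`mode = "at260"`) or at the respective absorption maxima
#' (`mode = "at_max"`). Negative values mean the modified nucleoside is
#' hypochromic relative to the reference; e.g. m1Y vs U at 260 nm is about
#' -39.8.
#'
#' @param tbl a [NucleosideTable-class].
#' @param ref_code reference nucleoside code.
#' @param mod_code modified nucleoside code.
#' @param mode `"at260"` (default) or `"at_max"`.
#' @return signed percent (full precision; round for display).
#' @export
#' @examples
#' tbl <- loadNucleosideTable()
#' round(deltaEpsilonPercent(tbl, "C", "m5C"), 1)   # -20.8
#' round(deltaEpsilonPercent(tbl, "U", "m1Y"), 1)   # -39.8
deltaEpsilonPercent <- function(tbl, ref_code, mod_code,
                                mode = c("at260", "at_max")) {
  mode <- match.arg(mode)
  field <- if (mode == "at260") "eps_260" else "eps_max"
  ref <- getNucleoside(tbl, ref_code)[[field]]
  mod <- getNucleoside(tbl, mod_code)[[field]]
  100 * (mod - ref) / ref
}

#' Shift of the absorption peak between two nucleosides
#'
#' `lambda_max(mod) - lambda_max(ref)` in nm; positive values are
#' bathochromic (peak moves to longer wavelengths), as seen for the
#' 5-methyl and N1-methyl pyrimidine modifications.
#'
#' @inheritParams deltaEpsilonPercent
#' @return signed shift in nm.
#' @export
#' @examples
#' tbl <- loadNucleosideTable()
#' deltaLambdaMax(tbl, "C", "m5C")   # +7
#' deltaLambdaMax(tbl, "Y", "m1Y")   # +9
deltaLambdaMax <- function(tbl, ref_code, mod_code) {
  getNucleoside(tbl, mod_code)$lambda_max -
    getNucleoside(tbl, ref_code)$lambda_max
}

setMethod("show", "NucleosideTable", function(object) {
  cat("NucleosideTable (", object@source, "): ",
      nrow(object@entries), " nucleosides, ",
      nrow(object@caps), " caps\n", sep = "")
  e <- object@entries
  print(data.frame(code = e$code, lambda_max = e$lambda_max,
                   eps_max = e$eps_max, eps_260 = e$eps_260,
                   residue_mass = e$residue_mass), row.names = FALSE)
  invisible(NULL)
})
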