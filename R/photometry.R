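#' @include sequence-io.R
NULL

#' Molar absorption coefficient at 260 nm of a construct
#'
#' The MAC260 of a hydrolyzed construct is the composition-weighted sum of
#' the nucleoside coefficients plus the cap chromophore contribution:
#' `sum_i n_i * eps_260(i) + eps_260_add(cap)`. The model assumes the
#' sample is hydrolyzed to mononucleotides, so folding-induced
#' hypochromicity is absent and absorption is strictly additive (and
#' therefore exactly linear in every residue count and in any substitution
#' fraction).
#'
#' @param comp a [Composition-class].
#' @param tbl a [NucleosideTable-class].
#' @return MAC260 in M^-1 cm^-1.
#' @export
#' @examples
#' tbl <- loadNucleosideTable()
#' mac260(seqComposition("ACGU"), tbl)
mac260 <- function(comp, tbl) {
  stopifnot(is(comp, "Composition"), is(tbl, "NucleosideTable"))
  counts <- comp@counts
  if (!length(counts)) return(getCap(tbl, comp@cap)$eps_260_add + 0)
  idx <- match(names(counts), tbl@entries$code)
  if (anyNA(idx)) stopLookup(names(counts)[which(is.na(idx))[1]])
  sum(counts * tbl@entries$eps_260[idx]) + getCap(tbl, comp@cap)$eps_260_add
}

#' Average molecular weight of a construct
#'
#' Closed formula over average residue masses (free-acid convention):
#' `sum_i n_i * residue_mass(i) + H2O + end`, where the end term depends
#' on the 5' end: `+2 x HPO3` (159.96) for a triphosphate (the default;
#' what uncapped T7 transcription yields), `0` for a 5'-monophosphate, and
#' `-HPO3` (-79.98) for a 5'-hydroxyl. For capped constructs the cap's
#' `mass_add` (m7G moiety plus bridging phosphates) replaces the 5'-end
#' term. Average (not monoisotopic) masses are used so values reconcile
#' with vendor oligo calculators.
#'
#' @param comp a [Composition-class].
#' @param tbl a [NucleosideTable-class].
#' @param five_prime 5'-end convention for uncapped constructs:
#'   `"triphosphate"` (default), `"monophosphate"`, or `"hydroxyl"`.
#' @return molecular weight in g/mol (0 for an empty, uncapped
#'   composition).
#' @export
molecularWeight <- function(comp, tbl,
                            five_prime = c("triphosphate", "monophosphate",
                                           "hydroxyl")) {
  stopifnot(is(comp, "Composition"), is(tbl, "NucleosideTable"))
  five_prime <- match.arg(five_prime)
  counts <- comp@counts
  if (!length(counts) && comp@cap == "none") return(0)
  idx <- match(names(counts), tbl@entries$code)
  if (anyNA(idx)) stopLookup(names(counts)[which(is.na(idx))[1]])
  core <- sum(counts * tbl@entries$residue_mass[idx]) + .MASS_WATER
  if (comp@cap != "none") {
    core + getCap(tbl, comp@cap)$mass_add
  } else {
    core + switch(five_prime,
                  triphosphate = 2 * .MASS_HPO3,
                  monophosphate = 0,
                  hydroxyl = -.MASS_HPO3)
  }
}

#' Photometric summary (MAC260, MW, mass extinction) of a construct
#'
#' Bundles [mac260()] and [molecularWeight()] with the derived mass
#' extinction, the mass concentration corresponding to one absorbance
#' unit at 1 cm path: `1000 x mol_weight / mac_260` in ug/mL per AU.
#' For typical mRNA this lands near 30-40 ug/mL, which is why the legacy
#' 40 ug/mL rule of thumb works roughly for unmodified ssRNA and
#' under-estimates modified constructs.
#'
#' @inheritParams molecularWeight
#' @return a [MacResult-class].
#' @export
#' @examples
#' tbl <- loadNucleosideTable()
#' macResult(seqComposition("ACGU"), tbl)
macResult <- function(comp, tbl,
                      five_prime = c("triphosphate", "monophosphate",
                                     "hydroxyl")) {
  five_prime <- match.arg(five_prime)
  eps <- mac260(comp, tbl)
  mw <- molecularWeight(comp, tbl, five_prime)
  me <- if (eps > 0) 1000 * mw / eps else NA_real_
  new("MacResult", mac_260 = eps, mol_weight = mw, mass_extinction = me,
      composition = comp, five_prime = five_prime)
}

#' @describeIn macResult MAC260 of a result, M^-1 cm^-1.
#' @param x a [MacResult-class].
#' @export
macOf <- function(x) x@mac_260

#' @describeIn macResult molecular weight of a result, g/mol.
#' @export
molWeight <- function(x) x@mol_weight

#' @describeIn macResult mass extinction, ug/mL per absorbance unit.
#' @export
massExtinction <- function(x) x@mass_extinction

#' Predicted hypochromicity ratio of a modified construct
#'
#' Ratio of the MAC260 of the scheme-modified construct to that of the
#' unmodified isosequence, caps identical on both sides:
#' `mac260(modified) / mac260(unmodified)`. At most 1 when every
#' substitution is hypochromic at 260 nm; for a poly-U sequence under full
#' U -> m1Y substitution it collapses to `eps_260(m1Y)/eps_260(U)`
#' (about 0.602).
#'
#' @param sequence validated sequence string.
#' @param scheme a [ModScheme-class].
#' @param cap cap code.
#' @param tbl a [NucleosideTable-class].
#' @return dimensionless ratio.
#' @export
#' @examples
#' tbl <- loadNucleosideTable()
#' hypochromicityRatio("UUUU", modScheme("U", "m1Y"), "none", tbl)
hypochromicityRatio <- function(sequence, scheme, cap = "none", tbl) {
  comp <- seqComposition(sequence, cap)
  ref <- mac260(comp, tbl)
  if (ref == 0)
    stopValidation("hypochromicity ratio undefined: unmodified MAC260 is 0 ",
                   "(empty sequence)")
  mac260(applyScheme(comp, scheme), tbl) / ref
}

#' Concentration under-estimation from ignoring modification
#'
#' `100 * (1 - hypochromicityRatio(...))`: the percent by which the
#' concentration of a modified construct is under-estimated when the
#' unmodified coefficient is applied to its A260. For mRNAs with typical
#' uridine content fully substituted by m1Y this spans roughly 5-15%,
#' growing with the uridine fraction.
#'
#' @inheritParams hypochromicityRatio
#' @return percent.
#' @export
underestimationPercent <- function(sequence, scheme, cap = "none", tbl) {
  100 * (1 - hypochromicityRatio(sequence, scheme, cap, tbl))
}

#' Legacy 40 ug/mL-per-AU mass concentration estimate
#'
#' The conventional single-stranded RNA rule of thumb: mass concentration
#' `40 x A260 x dilution` in ug/mL, carried in reports for side-by-side
#' comparison with the composition-based estimate.
#'
#' @param a260 absorbance at 260 nm (>= 0).
#' @param dilution fold-dilution of the measured aliquot (>= 1).
#' @return mass concentration in ug/mL.
#' @export
#' @examples
#' legacyMassConcentration(1.0)        # 40
#' legacyMassConcentration(0.5, 2)     # 40
legacyMassConcentration <- function(a260, dilution = 1) {
  if (any(!is.finite(a260)) || any(a260 < 0))
    stopValidation("a260 must be finite and >= 0")
  if (any(!is.finite(dilution)) || any(dilution < 1))
    stopValidation("dilution must be finite and >= 1")
  40 * a260 * dilution
}

setMethod("show", "MacResult", function(object) {
  cat("MacResult\n")
  cat(sprintf("  MAC260:          %s M^-1 cm^-1\n",
              format(signif(object@mac_260, 4), big.mark = ",")))
  cat(sprintf("  mol. weight:     %s g/mol\n",
              format(signif(object@mol_weight, 4), big.mark = ",")))
  cat(sprintf("  mass extinction: %s ug/mL per AU\n",
              format(signif(object@mass_extinction, 4))))
  cat(sprintf("  composition:     %d residues, cap %s, 5' %s\n",
              round(sum(object@composition@counts)),
              object@composition@cap, object@five_prime))
  invisible(NULL)
})
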