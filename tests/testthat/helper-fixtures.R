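# Shared fixtures: the builtin table, an independent per-residue summation
# oracle for MAC260, and a hand-built MacResult for unit arithmetic tests.

TBL <- loadNucleosideTable()

# brute-force oracle: walk the sequence one residue at a time and add the
# table coefficient; deliberately loop-based and independent of mac260()'s
# vectorized count path
oracleMac260 <- function(sequence, tbl, cap = "none") {
  total <- 0
  if (nchar(sequence) > 0) {
    for (ch in strsplit(sequence, "", fixed = TRUE)[[1]]) {
      total <- total + getNucleoside(tbl, ch)$eps_260
    }
  }
  total + getCap(tbl, cap)$eps_260_add
}

fakeMac <- function(eps, mw = 3e5) {
  new("MacResult", mac_260 = eps, mol_weight = mw,
      mass_extinction = 1000 * mw / eps,
      composition = composition(c(A = 1)), five_prime = "triphosphate")
}

# report with a prescribed stock molar concentration (bypasses absorbance)
.quantReportForTest <- function(molar_nM, mac) {
  rnaMAC:::.quantReport(molar_nM, mac)
}

writeConfig <- function(...) {
  path <- tempfile(fileext = ".dcf")
  writeLines(c(...), path)
  path
}
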