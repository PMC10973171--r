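#' @include quantify.R
NULL

# run expr under a fixed RNG seed without disturbing the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a random RNA sequence with given base composition
#'
#' Multinomial draw over the residue alphabet at the given fractions,
#' reproducible from the seed (a pure function of its arguments).
#'
#' @param length sequence length (>= 0).
#' @param fractions named non-negative fractions summing to 1 (default
#'   uniform over A/C/G/U).
#' @param seed integer RNG seed.
#' @return sequence string of the requested length.
#' @export
#' @examples
#' randomSequence(20, c(A = 0.3, C = 0.2, G = 0.2, U = 0.3), seed = 1)
randomSequence <- function(length,
                           fractions = c(A = 0.25, C = 0.25,
                                         G = 0.25, U = 0.25),
                           seed = 1) {
  if (!is.numeric(length) || length < 0 || length != round(length))
    stopValidation("length must be a non-negative integer")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stopValidation("fractions must be named by residue code")
  if (any(!is.finite(fractions)) || any(fractions < 0))
    stopValidation("fractions must be finite and non-negative")
  if (abs(sum(fractions) - 1) > 1e-9)
    stopValidation("fractions must sum to 1 (got ", format(sum(fractions)),
                   ")")
  if (length == 0) return("")
  .withSeed(seed, paste(sample(names(fractions), length, replace = TRUE,
                               prob = fractions), collapse = ""))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Simulate a serial-dilution measurement series
#'
#' Generates replicate A260 readings for a stock of known concentration:
#' `a260 = mac_260 x path x (stock / dilution) x (1 + N(0, cv))` per
#' replicate. Noise is multiplicative (constant coefficient of variation)
#' because photometric replicate error scales with the signal. The ground
#' truth (stock, cv, seed) is embedded in the returned series' `truth`
#' metadata.
#'
#' @param mac a [MacResult-class] for the construct.
#' @param stock_nM true stock molar concentration in nM (> 0).
#' @param dilutions vector of fold-dilution factors (>= 1).
#' @param replicates readings per dilution point (>= 1).
#' @param cv coefficient of variation of the multiplicative noise (>= 0;
#'   0 gives exact Beer-Lambert points).
#' @param seed integer RNG seed.
#' @param path_length cuvette path in cm.
#' @return a [DilutionSeries-class] with truth metadata.
#' @export
#' @examples
#' tbl <- loadNucleosideTable()
#' mac <- macResult(seqComposition(strrep("ACGU", 250)), tbl)
#' simulateSeries(mac, stock_nM = 500, cv = 0.01, seed = 7)
simulateSeries <- function(mac, stock_nM,
                           dilutions = c(10, 20, 40, 80, 160, 320),
                           replicates = 3, cv = 0, seed = 1,
                           path_length = 1) {
  stopifnot(is(mac, "MacResult"))
  if (!is.finite(stock_nM) || stock_nM <= 0)
    stopValidation("stock_nM must be > 0")
  if (any(!is.finite(dilutions)) || any(dilutions < 1))
    stopValidation("dilutions must be >= 1")
  if (!is.finite(cv) || cv < 0)
    stopValidation("noise CV must be >= 0")
  if (replicates < 1) stopValidation("replicates must be >= 1")
  dil <- rep(dilutions, each = replicates)
  ideal <- mac@mac_260 * path_length * (stock_nM * 1e-9) / dil
  a260 <- .withSeed(seed, ideal * (1 + rnorm(length(ideal), 0, cv)))
  a260 <- pmax(a260, 0)
  dilutionSeries(dil, a260, path_length = path_length,
                 truth = list(stock_nM = stock_nM, cv = cv, seed = seed,
                              replicates = replicates))
}
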