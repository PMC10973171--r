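#' @include registry.R
NULL

#' Read mRNA sequences from FASTA or pasted text
#'
#' Accepts multi-record FASTA (wrapped lines) or headerless raw text (one
#' record, id `seq1`). Input is normalized the way wet-lab copy/paste
#' requires: whitespace, digits and GenBank-style numbering are stripped
#' and letters upper-cased. `T` is mapped to `U` with a warning (users
#' paste DNA template sequences); `strict = TRUE` rejects it instead.
#' Remaining characters must be A/C/G/U, plus the single-letter modified
#' code `Y` (pseudouridine) when `extended = TRUE`.
#'
#' @param file path to a FASTA or plain-text file.
#' @param text literal sequence text instead of a file (one of the two).
#' @param strict reject `T` instead of converting to `U`.
#' @param extended allow inline modified residue letters (currently `Y`).
#' @return named character vector of validated sequences (names = record
#'   ids).
#' @export
#' @examples
#' readRNASequences(text = ">x\nacg u\n")
readRNASequences <- function(file = NULL, text = NULL, strict = FALSE,
                             extended = FALSE) {
  if (is.null(file) == is.null(text))
    stopValidation("supply exactly one of 'file' or 'text'")
  if (!is.null(file)) {
    if (!file.exists(file)) stopIO("sequence file not found: ", file)
    raw <- readChar(file, file.info(file)$size, useBytes = FALSE)
  } else {
    raw <- paste(text, collapse = "\n")
  }
  if (!nzchar(trimws(raw)))
    stopValidation("empty input: no sequence records found")
  if (grepl("^\\s*>", raw)) {
    tf <- tempfile(fileext = ".fa")
    writeLines(raw, tf)
    on.exit(unlink(tf))
    set <- Biostrings::readBStringSet(tf)
    if (length(set) == 0L)
      stopValidation("empty input: no sequence records found")
    ids <- sub("\\s.*$", "", names(set))
    seqs <- as.character(set)
  } else {
    ids <- "seq1"
    seqs <- raw
  }
  cleaned <- vapply(seq_along(seqs), function(i)
    .cleanSequence(seqs[[i]], ids[[i]], strict = strict,
                   extended = extended), "")
  names(cleaned) <- ids
  cleaned
}

.cleanSequence <- function(s, id, strict = FALSE, extended = FALSE) {
  s <- toupper(gsub("[\\s0-9]+", "", s, perl = TRUE))
  if (grepl("T", s, fixed = TRUE)) {
    if (strict)
      stopValidation("record '", id, "': 'T' not allowed in strict mode ",
                     "(RNA alphabet is A/C/G/U)")
    warning(sprintf("record '%s': 'T' converted to 'U' (DNA-style input)", id),
            call. = FALSE)
    s <- gsub("T", "U", s, fixed = TRUE)
  }
  alphabet <- c("A", "C", "G", "U", if (extended) "Y")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    shown <- utils::head(bad, 10L)
    stopValidation("record '", id, "': invalid character(s) ",
                   paste(sprintf("'%s' at position %d", chars[shown], shown),
                         collapse = ", "),
                   if (length(bad) > 10L) sprintf(" (and %d more)",
                                                  length(bad) - 10L))
  }
  s
}

#' Residue composition of a sequence
#'
#' Counts each residue code in a validated sequence. The cap is recorded
#' but not counted as a residue; the first transcribed nucleotide is part
#' of the sequence itself.
#'
#' @param sequence validated sequence string (see [readRNASequences()]).
#' @param cap cap code: `none` (default), `cap0`, or `cap1`.
#' @return a [Composition-class].
#' @export
#' @examples
#' seqComposition("ACGU")
seqComposition <- function(sequence, cap = "none") {
  if (!is.character(sequence) || length(sequence) != 1L)
    stopValidation("sequence must be a single character string")
  if (nchar(sequence) == 0L)
    return(new("Composition", counts = setNames(numeric(0), character(0)),
               cap = cap))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  tab <- table(chars)
  counts <- as.numeric(tab)
  names(counts) <- normalizeCode(names(tab))
  new("Composition", counts = counts, cap = cap)
}

#' Construct a composition from counts
#'
#' @param counts named numeric vector (residue code -> count); real-valued
#'   counts are allowed (fractional substitution).
#' @param cap cap code.
#' @return a [Composition-class].
#' @export
composition <- function(counts = numeric(0), cap = "none") {
  if (length(counts)) names(counts) <- normalizeCode(names(counts))
  new("Composition", counts = counts, cap = cap)
}

#' @describeIn composition residue counts (possibly real-valued).
#' @param comp a [Composition-class].
#' @export
residueCounts <- function(comp) comp@counts

#' @describeIn composition counts rounded half-up to integers, for
#'   discrete reports.
#' @export
discreteCounts <- function(comp) {
  x <- floor(comp@counts + 0.5)
  x[x > 0 | comp@counts == 0]
}

#' @describeIn composition cap code of the construct.
#' @export
capCode <- function(comp) comp@cap

#' @describeIn composition total residue count (sum of counts).
#' @export
seqLength <- function(comp) sum(comp@counts)

#' Build a modification scheme
#'
#' @param canonical canonical residue code(s), e.g. `"U"`.
#' @param modified modified residue code(s), e.g. `"m1Y"`.
#' @param fraction substitution fraction(s) in \[0, 1\] (default 1: full
#'   substitution, the usual IVT case where the modified triphosphate
#'   replaces the canonical one entirely).
#' @return a [ModScheme-class].
#' @export
#' @examples
#' modScheme("U", "m1Y")          # full U -> m1Y substitution
#' modScheme("U", "m1Y", 0.5)     # half the U residues
modScheme <- function(canonical = character(0), modified = character(0),
                      fraction = 1) {
  n <- length(canonical)
  fraction <- rep_len(fraction, n)
  new("ModScheme", canonical = normalizeCode(canonical),
      modified = normalizeCode(modified), fraction = fraction)
}

#' Parse a scheme string
#'
#' Grammar: `CANON:MOD[:FRACTION]`, comma-separated for multiple rules,
#' e.g. `"U:m1Y"` or `"U:m1Y:0.5,C:m5C"`. Fraction defaults to 1.
#'
#' @param spec scheme string; `""` or `NULL` yields the empty scheme.
#' @return a [ModScheme-class].
#' @export
parseScheme <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(modScheme())
  rules <- strsplit(spec, ",", fixed = TRUE)[[1]]
  parts <- strsplit(trimws(rules), ":", fixed = TRUE)
  canon <- character(0); mod <- character(0); frac <- numeric(0)
  for (p in parts) {
    if (length(p) < 2L || length(p) > 3L || any(!nzchar(p[1:2])))
      stopValidation("malformed scheme rule '", paste(p, collapse = ":"),
                     "': expected CANON:MOD[:FRACTION]")
    f <- if (length(p) == 3L) suppressWarnings(as.numeric(p[3])) else 1
    if (is.na(f))
      stopValidation("malformed scheme rule: fraction '", p[3],
                     "' is not numeric")
    canon <- c(canon, p[1]); mod <- c(mod, p[2]); frac <- c(frac, f)
  }
  modScheme(canon, mod, frac)
}

#' Apply a modification scheme to a composition
#'
#' For each rule `(canonical, modified, fraction)`, moves
#' `fraction x count(canonical)` residues to the modified code. Counts
#' stay real-valued so the resulting MAC260 is exactly linear in the
#' fraction; total length is conserved. Rules whose canonical residue is
#' absent are no-ops.
#'
#' @param comp a [Composition-class].
#' @param scheme a [ModScheme-class].
#' @return a new [Composition-class].
#' @export
#' @examples
#' applyScheme(composition(c(U = 10)), modScheme("U", "m1Y", 0.5))
applyScheme <- function(comp, scheme) {
  stopifnot(is(comp, "Composition"), is(scheme, "ModScheme"))
  validObject(scheme)
  counts <- comp@counts
  for (i in seq_along(scheme@canonical)) {
    canon <- scheme@canonical[i]; mod <- scheme@modified[i]
    f <- scheme@fraction[i]
    if (!canon %in% names(counts)) next
    moved <- f * counts[[canon]]
    counts[[canon]] <- counts[[canon]] - moved
    counts[[mod]] <- (if (mod %in% names(counts)) counts[[mod]] else 0) + moved
  }
  counts <- counts[counts > 0]
  new("Composition", counts = counts, cap = comp@cap)
}

setMethod("show", "Composition", function(object) {
  cat("Composition: length ", format(sum(object@counts)),
      ", cap ", object@cap, "\n", sep = "")
  if (length(object@counts)) print(object@counts)
  invisible(NULL)
})

setMethod("show", "ModScheme", function(object) {
  if (!length(object@canonical)) {
    cat("ModScheme: empty (no substitutions)\n")
  } else {
    cat("ModScheme:\n")
    for (i in seq_along(object@canonical))
      cat(sprintf("  %s -> %s @ %.3g\n", object@canonical[i],
                  object@modified[i], object@fraction[i]))
  }
  invisible(NULL)
})
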