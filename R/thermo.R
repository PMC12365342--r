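#' Construct a nearest-neighbor thermodynamic parameter set
#'
#' Builds a [ThermoParameters-class] object from a stack table and
#' reaction conditions. The default table is the unified nearest-neighbor
#' parameter set of SantaLucia (1998), shipped as a plain-text file so
#' alternative tables can be swapped in
#' (`system.file("extdata", "nn_santalucia1998.tsv", package = "SSRseqDesign")`).
#'
#' Defaults model a typical PCR-screening condition: 50 mM monovalent
#' salt, 250 nM total oligo, dimer free energies evaluated at 37 C, and a
#' minimum scoreable complementary stretch of 3 bp. All dimer/Tm
#' acceptance thresholds downstream are configurable, so the parameter
#' set can be recalibrated against any reference predictor.
#'
#' @param nnTable path to a TSV with columns `stack`, `dH` (kcal/mol),
#'   `dS` (cal/(mol K)); rows `init_GC` / `init_AT` carry duplex
#'   initiation terms. `NULL` uses the packaged SantaLucia (1998) table.
#' @param saltMilliM monovalent cation concentration in mmol/L.
#' @param oligoNanoM total oligo concentration in nmol/L.
#' @param dimerMinStretch shortest complementary run (bp) scored as a dimer.
#' @param dgTemperatureC temperature (Celsius) for dimer delta-G evaluation.
#' @return a [ThermoParameters-class] object.
#' @examples
#' p <- thermoParameters()
#' meltingTemperature("AGCGTCTGAGACCTGGATCC", p)
#' @export
thermoParameters <- function(nnTable = NULL, saltMilliM = 50,
                             oligoNanoM = 250, dimerMinStretch = 3L,
                             dgTemperatureC = 37) {
  if (is.null(nnTable)) {
    nnTable <- system.file("extdata", "nn_santalucia1998.tsv",
                           package = "SSRseqDesign", mustWork = TRUE)
  }
  tab <- read.delim(nnTable, stringsAsFactors = FALSE)
  initGC <- as.numeric(tab[tab$stack == "init_GC", c("dH", "dS")])
  initAT <- as.numeric(tab[tab$stack == "init_AT", c("dH", "dS")])
  if (length(initGC) != 2L || length(initAT) != 2L) {
    stop("nnTable must contain init_GC and init_AT rows")
  }
  stacks <- tab[!grepl("^init_", tab$stack), , drop = FALSE]
  rownames(stacks) <- NULL
  new("ThermoParameters",
      stacks = stacks, initGC = initGC, initAT = initAT,
      saltM = saltMilliM / 1000, oligoM = oligoNanoM * 1e-9,
      dimerMinStretch = as.integer(dimerMinStretch),
      dgTempK = dgTemperatureC + 273.15)
}

setMethod("show", "ThermoParameters", function(object) {
  cat("ThermoParameters (nearest-neighbor model)\n")
  cat("  stacks:          ", nrow(object@stacks), "dinucleotide entries\n")
  cat("  monovalent salt: ", object@saltM * 1000, "mM\n")
  cat("  oligo conc:      ", object@oligoM * 1e9, "nM\n")
  cat("  dimer dG at:     ", object@dgTempK - 273.15, "C, min stretch",
      object@dimerMinStretch, "bp\n")
})

# Expand the 10 unique stacks to all 16 top-strand dinucleotides: a stack
# read on the complementary strand has identical parameters, so missing
# dinucleotides inherit from their reverse complement.
.stackLookup <- function(params) {
  tab <- params@stacks
  dH <- structure(tab$dH, names = tab$stack)
  dS <- structure(tab$dS, names = tab$stack)
  all16 <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  for (d in all16) {
    if (!(d %in% names(dH))) {
      rc <- .revcomp(d)
      dH[[d]] <- dH[[rc]]
      dS[[d]] <- dS[[rc]]
    }
  }
  list(dH = dH, dS = dS)
}

# Per-stack free energies (kcal/mol) at the screening temperature.
.stackDeltaG <- function(params) {
  lk <- .stackLookup(params)
  lk$dH - params@dgTempK * lk$dS / 1000
}

.initDeltaG <- function(params, base) {
  hs <- if (base %in% c("G", "C")) params@initGC else params@initAT
  hs[1L] - params@dgTempK * hs[2L] / 1000
}

#' GC content of a DNA sequence
#'
#' Fraction of G and C bases. Ambiguous bases are rejected because the
#' function is used on primer sequences, where any non-ACGT character is
#' a design error.
#'
#' @param seq character vector of DNA sequences (A/C/G/T only).
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' gcContent("ATGC")  # 0.5
#' @export
gcContent <- function(seq) {
  vapply(seq, function(s) {
    chars <- .checkACGT(s, "primer sequence")
    sum(chars %in% c("G", "C")) / length(chars)
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Nearest-neighbor melting temperature
#'
#' Two-state nearest-neighbor melting temperature:
#' \deqn{T_m = \frac{\Delta H^\circ \times 1000}
#'   {\Delta S^\circ + 0.368\,(n-1)\ln[\mathrm{Na}^+] + R \ln(C_T/x)} - 273.15}
#' where the stack and initiation enthalpies/entropies come from the
#' parameter table, the entropic salt correction follows SantaLucia
#' (1998), \eqn{R = 1.9872} cal/(mol K), \eqn{C_T} is the total strand
#' concentration, and \eqn{x = 4} for non-self-complementary duplexes
#' (\eqn{x = 1} with a symmetry entropy of -1.4 cal/(mol K) for
#' self-complementary sequences).
#'
#' @param seq character vector of primer sequences (length >= 8 each).
#' @param params a [ThermoParameters-class] object.
#' @return melting temperatures in degrees Celsius.
#' @examples
#' p <- thermoParameters()
#' meltingTemperature(c("ATATATATATAT", "GCGCGCGCGCGC"), p)
#' @export
meltingTemperature <- function(seq, params = thermoParameters()) {
  lk <- .stackLookup(params)
  vapply(seq, function(s) {
    chars <- .checkACGT(s, "primer sequence")
    n <- length(chars)
    if (n < 8L) stop("melting temperature requires sequences of >= 8 bases")
    stacks <- paste0(chars[-n], chars[-1L])
    dH <- sum(lk$dH[stacks])
    dS <- sum(lk$dS[stacks])
    for (endBase in chars[c(1L, n)]) {
      hs <- if (endBase %in% c("G", "C")) params@initGC else params@initAT
      dH <- dH + hs[1L]
      dS <- dS + hs[2L]
    }
    upper <- paste(chars, collapse = "")
    selfComp <- identical(upper, .revcomp(upper))
    x <- if (selfComp) 1 else 4
    if (selfComp) dS <- dS - 1.4
    dS <- dS + 0.368 * (n - 1L) * log(params@saltM)
    dH * 1000 / (dS + 1.9872 * log(params@oligoM / x)) - 273.15
  }, numeric(1L), USE.NAMES = FALSE)
}

# Core dimer scan shared by self/cross dimer energies. Slides `a`
# (5'->3') along `b` read 3'->5' (antiparallel, ungapped), finds
# contiguous Watson-Crick complementary runs of at least
# `dimerMinStretch` bp, scores each run as the sum of its stack free
# energies plus the two terminal initiation terms, and returns the most
# negative run over all offsets.
.dimerScan <- function(a, b, params) {
  ca <- .checkACGT(a, "oligo a")
  cb <- .checkACGT(b, "oligo b")
  dg <- .stackDeltaG(params)
  rb <- rev(cb)                      # b read 3'->5'
  na <- length(ca)
  nb <- length(cb)
  minRun <- params@dimerMinStretch
  best <- 0
  bestOffset <- NA_integer_
  bestSpan <- ""
  compA <- DNA_COMPLEMENT[ca]
  for (offset in (-(nb - 1L)):(na - 1L)) {
    i <- max(1L, 1L + offset):min(na, nb + offset)
    j <- i - offset
    paired <- compA[i] == rb[j]
    if (!any(paired)) next
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= minRun)) {
      ii <- i[starts[k]:ends[k]]     # positions in a, ascending
      L <- length(ii)
      stacks <- paste0(ca[ii[-L]], ca[ii[-1L]])
      e <- sum(dg[stacks]) +
        .initDeltaG(params, ca[ii[1L]]) + .initDeltaG(params, ca[ii[L]])
      if (e < best) {
        best <- e
        bestOffset <- offset
        bestSpan <- sprintf("a[%d-%d] x b[%d-%d]", ii[1L], ii[L],
                            nb + 1L - (ii[L] - offset), nb + 1L - (ii[1L] - offset))
      }
    }
  }
  list(energy = min(best, 0), offset = bestOffset, span = bestSpan)
}

#' Cross-dimer interaction energy between two oligos
#'
#' Screens every ungapped antiparallel alignment of `a` against `b` for
#' contiguous complementary runs of at least `dimerMinStretch` bases
#' (default 3 bp). Each run is scored as the sum of its nearest-neighbor
#' stack free energies at the screening temperature plus the two duplex
#' initiation terms; the reported energy is the most negative run over
#' all offsets, or 0 when no run reaches the minimum stretch. The scan is
#' symmetric in its arguments. This is a dimer *screen* (as used to
#' vet multiplex compatibility), not a full hybridization partition
#' function: bulges and mismatched duplex extension are not modeled.
#'
#' @param a,b oligo sequences (character scalars, A/C/G/T).
#' @param params a [ThermoParameters-class] object.
#' @return interaction free energy in kcal/mol (<= 0).
#' @examples
#' p <- thermoParameters()
#' crossDimerEnergy("ACGTACGTACGT", "ACGTACGTACGT", p)  # self-partners
#' crossDimerEnergy("AAAAAAAA", "CCCCCCCC", p)          # 0, never pairs
#' @export
crossDimerEnergy <- function(a, b, params = thermoParameters()) {
  .dimerScan(a, b, params)$energy
}

#' Self-dimer energy of an oligo
#'
#' [crossDimerEnergy()] of a sequence against itself.
#'
#' @param seq oligo sequence (character scalar, A/C/G/T).
#' @inheritParams crossDimerEnergy
#' @return free energy in kcal/mol (<= 0).
#' @export
selfDimerEnergy <- function(seq, params = thermoParameters()) {
  vapply(seq, function(s) .dimerScan(s, s, params)$energy,
         numeric(1L), USE.NAMES = FALSE)
}

#' Detailed dimer report for one oligo pair
#'
#' Like [crossDimerEnergy()] but also reports the alignment offset and
#' the matched stretch of the best (most negative) duplex.
#'
#' @inheritParams crossDimerEnergy
#' @return list with elements `energy` (kcal/mol), `offset` (alignment
#'   offset of the best run, `NA` if none), `span` (description of the
#'   matched stretch).
#' @export
dimerReport <- function(a, b, params = thermoParameters()) {
  .dimerScan(a, b, params)
}
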