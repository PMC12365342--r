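#' Per-motif-length minimum repeat thresholds for SSR scanning
#'
#' Defaults are the characterization thresholds used throughout primate
#' SSR surveys: ten repeats for mononucleotide motifs, five for
#' dinucleotides, four for trinucleotides, and three for tetra-, penta-
#' and hexanucleotides.
#'
#' @param mono,di,tri,tetra,penta,hexa minimum repeat count for each
#'   motif length (all >= 2).
#' @return named integer vector with names `"1"` to `"6"`.
#' @examples
#' scanThresholds()
#' @export
scanThresholds <- function(mono = 10L, di = 5L, tri = 4L, tetra = 3L,
                           penta = 3L, hexa = 3L) {
  thr <- c(`1` = mono, `2` = di, `3` = tri, `4` = tetra, `5` = penta,
           `6` = hexa)
  thr <- vapply(thr, as.integer, integer(1L))
  if (any(thr < 2L)) stop("all minimum repeat counts must be >= 2")
  thr
}

#' Canonical form of a repeat motif
#'
#' The lexicographically smallest cyclic rotation of the motif, so that
#' all phases of the same repeat (GATA/ATAG/TAGA/AGAT) map to one class.
#' Reverse complements are kept as separate classes (MISA-style
#' grouping), so plus- and minus-strand descriptions of the same tract
#' remain distinguishable.
#'
#' @param motif character vector of repeat units (1-6 bp, A/C/G/T).
#' @return character vector of canonical motifs; idempotent.
#' @examples
#' canonicalMotif("GATA")  # "AGAT"
#' @export
canonicalMotif <- function(motif) {
  vapply(motif, function(m) {
    chars <- .checkACGT(m, "motif")
    n <- length(chars)
    if (n > 6L) stop("motif length must be 1-6")
    rot <- vapply(seq_len(n), function(k) {
      paste(chars[c(k:n, seq_len(k - 1L))[seq_len(n)]], collapse = "")
    }, character(1L))
    min(rot)
  }, character(1L), USE.NAMES = FALSE)
}

# Scan one character vector for maximal perfect tandem repeats of period
# m. Returns a data.frame of runs (region start, whole-copy count).
.scanPeriod <- function(chars, valid, m, minRepeats) {
  L <- length(chars)
  if (L < 2L * m) return(NULL)
  idx <- seq_len(L - m)
  eq <- chars[idx] == chars[idx + m] & valid[idx] & valid[idx + m]
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + m) %/% m >= minRepeats
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep],
             repeats = (r$lengths[keep] + m) %/% m,
             motif_length = m)
}

#' Detect perfect microsatellites in one contig
#'
#' Finds every maximal perfect tandem repeat of a 1-6 bp motif whose
#' repeat count meets the per-motif-length threshold. A tract whose
#' repeat unit is itself a repetition of a shorter unit is reported only
#' under its shortest period (`ATATATAT...` is a dinucleotide AT locus,
#' never a tetranucleotide ATAT one). `N` or any other non-ACGT
#' character breaks a tract and can never sit inside a motif. Lowercase
#' input is accepted and uppercased; soft-masking case is deliberately
#' ignored (repeat masking travels on a separate interval channel, see
#' [extractCandidates()]).
#'
#' Tracts are reported from the leftmost base at which the periodicity
#' begins, spanning the whole motif copies that fit; coordinates are
#' 1-based inclusive.
#'
#' @param sequence contig sequence (character scalar or `DNAString`).
#' @param id contig identifier recorded in the output.
#' @param thresholds named vector from [scanThresholds()].
#' @return data.frame with columns `contig_id`, `start`, `end`, `motif`
#'   (canonical), `motif_length`, `repeats`, `tract_length`, sorted by
#'   `start`.
#' @examples
#' scanContig(paste0("GCTGACGT", strrep("AGAT", 4), "CGTCAGTC"), "c1")
#' @export
scanContig <- function(sequence, id = "contig", thresholds = scanThresholds()) {
  chars <- .seqChars(sequence)
  empty <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      motif_length = integer(), repeats = integer(),
                      tract_length = integer(), stringsAsFactors = FALSE)
  if (length(chars) == 0L) return(empty)
  valid <- chars %in% DNA_BASES
  hits <- list()
  for (m in 1:6) {
    runs <- .scanPeriod(chars, valid, m, thresholds[[as.character(m)]])
    if (is.null(runs)) next
    unit <- vapply(runs$start, function(a) {
      paste(chars[a:(a + m - 1L)], collapse = "")
    }, character(1L))
    primitive <- !vapply(unit, .isPowerOfShorter, logical(1L))
    runs <- runs[primitive, , drop = FALSE]
    unit <- unit[primitive]
    if (nrow(runs) == 0L) next
    runs$motif <- canonicalMotif(unit)
    hits[[length(hits) + 1L]] <- runs
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- data.frame(contig_id = id,
                    start = out$start,
                    end = out$start + out$repeats * out$motif_length - 1L,
                    motif = out$motif,
                    motif_length = out$motif_length,
                    repeats = out$repeats,
                    tract_length = out$repeats * out$motif_length,
                    stringsAsFactors = FALSE)
  out[order(out$start, out$motif_length), , drop = FALSE]
}

#' Scan a set of contigs (or a FASTA file) for microsatellites
#'
#' Applies [scanContig()] per record, streaming one contig at a time, and
#' tallies loci by motif length.
#'
#' @param contigs a `DNAStringSet`, a named character vector, or the path
#'   to a (multi-record) FASTA file.
#' @param thresholds named vector from [scanThresholds()].
#' @return list with elements `loci` (a `GRanges`, seqnames = contig ids,
#'   metadata columns `motif`, `motif_length`, `repeats`, `tract_length`)
#'   and `summary` (data.frame `motif_length`, `count`, plus attribute
#'   `total`; see [ssrSummary()]).
#' @examples
#' ctg <- c(c1 = paste0(strrep("GACT", 1), strrep("A", 12), "GCGTGT"))
#' scanGenome(ctg)$summary
#' @export
scanGenome <- function(contigs, thresholds = scanThresholds()) {
  contigs <- .asContigSet(contigs)
  ids <- names(contigs)
  perContig <- lapply(seq_along(contigs), function(i) {
    scanContig(contigs[[i]], ids[i], thresholds)
  })
  tab <- do.call(rbind, c(perContig, list(scanContig("", "drop")[0, ])))
  loci <- GenomicRanges::GRanges(
    seqnames = if (nrow(tab)) tab$contig_id else character(),
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    motif = tab$motif, motif_length = tab$motif_length,
    repeats = tab$repeats, tract_length = tab$tract_length
  )
  list(loci = loci, summary = ssrSummary(loci))
}

#' Summarize SSR loci by motif length
#'
#' @param loci a `GRanges` from [scanGenome()] (or a data.frame with a
#'   `motif_length` column).
#' @return data.frame with columns `motif_length` (1-6) and `count`;
#'   attribute `total` holds the overall locus count.
#' @export
ssrSummary <- function(loci) {
  ml <- if (is.data.frame(loci)) loci$motif_length else S4Vectors::mcols(loci)$motif_length
  counts <- vapply(1:6, function(m) sum(ml == m), integer(1L))
  out <- data.frame(motif_length = 1:6, count = counts)
  attr(out, "total") <- sum(counts)
  out
}

#' Keep only design-grade SSR loci
#'
#' Restricts scanned loci to the motif lengths used for primer design
#' and applies per-length minimum repeat counts. Defaults target
#' stutter-resistant loci for degraded-sample genotyping: tetra- and
#' pentanucleotide motifs with at least 12 and 10 repeats respectively.
#'
#' @param loci `GRanges` (or data.frame) of scanned loci.
#' @param motifLengths motif lengths retained.
#' @param minRepeats named numeric vector: minimum repeats per motif
#'   length (names are motif lengths).
#' @return the filtered object, input order preserved.
#' @examples
#' # a tetranucleotide locus needs >= 12 repeats to survive:
#' tab <- scanContig(paste0("GCTGACGTGC", strrep("AGAT", 12), "CGTCAGTCGT"), "c1")
#' nrow(filterForDesign(tab))
#' @export
filterForDesign <- function(loci, motifLengths = c(4L, 5L),
                            minRepeats = c(`4` = 12L, `5` = 10L)) {
  df <- is.data.frame(loci)
  ml <- if (df) loci$motif_length else S4Vectors::mcols(loci)$motif_length
  rc <- if (df) loci$repeats else S4Vectors::mcols(loci)$repeats
  keep <- ml %in% motifLengths
  need <- rep(Inf, length(ml))
  for (m in names(minRepeats)) need[ml == as.integer(m)] <- minRepeats[[m]]
  keep <- keep & rc >= need
  loci[keep, ]
}

.asContigSet <- function(contigs) {
  if (is.character(contigs) && length(contigs) == 1L && is.null(names(contigs)) &&
      file.exists(contigs)) {
    return(readContigs(contigs))
  }
  if (is.character(contigs)) {
    if (is.null(names(contigs))) stop("character contigs must be named")
    return(Biostrings::DNAStringSet(toupper(contigs)))
  }
  if (methods::is(contigs, "DNAStringSet")) {
    if (is.null(names(contigs))) stop("contig set must carry names")
    if (anyDuplicated(names(contigs))) stop("contig ids must be unique")
    return(contigs)
  }
  stop("unsupported contig container: ", class(contigs)[1L])
}
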