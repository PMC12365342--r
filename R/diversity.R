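# Coerce an alignment (DNAStringSet, DNAMultipleAlignment, named
# character vector, or character matrix) to an uppercase character
# matrix, rows = sequences, cols = alignment columns.
.asAlignmentMatrix <- function(alignment) {
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    if (methods::is(alignment, "DNAMultipleAlignment")) {
      alignment <- methods::as(alignment, "DNAStringSet")
    }
    if (methods::is(alignment, "DNAStringSet")) {
      alignment <- as.character(alignment)
    }
    if (!is.character(alignment)) {
      stop("unsupported alignment container: ", class(alignment)[1L])
    }
    alignment <- toupper(alignment)
    w <- unique(nchar(alignment))
    if (length(w) != 1L) stop("alignment rows must have equal length")
    m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
    rownames(m) <- names(alignment)
  }
  if (nrow(m) < 2L) stop("an alignment needs at least 2 sequences")
  m
}

# Per-pair difference and valid-site counts over a column range, using
# pairwise deletion: a column counts for a pair only when both rows hold
# an unambiguous base there.
.pairCounts <- function(mat, cols) {
  n <- nrow(mat)
  pairs <- utils::combn(n, 2L)
  valid <- matrix(mat[, cols, drop = FALSE] %in% DNA_BASES, nrow = n)
  diffs <- integer(ncol(pairs))
  valids <- integer(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    ok <- valid[i, ] & valid[j, ]
    valids[k] <- sum(ok)
    diffs[k] <- sum(mat[i, cols][ok] != mat[j, cols][ok])
  }
  list(diffs = diffs, valids = valids)
}

#' Nucleotide diversity of an alignment interval
#'
#' Average per-site proportion of pairwise differences (pi) over a set
#' of alignment columns, with pairwise deletion: a column is counted for
#' a sequence pair only when both rows carry an unambiguous A/C/G/T
#' there (gaps and Ns are skipped per pair, not per column, so gappy
#' alignments are not discarded wholesale). Each pair contributes its
#' differences divided by its own valid-site count; pi is the mean over
#' pairs with at least one valid site, and 0 when no pair has any.
#'
#' @param alignment `DNAStringSet`, `DNAMultipleAlignment`, named
#'   character vector, or character matrix of equal-length aligned
#'   sequences.
#' @param columns optional 1-based inclusive column interval
#'   `c(start, end)`; default spans the whole alignment.
#' @return per-site nucleotide diversity (a single number in `[0, 1]`).
#' @examples
#' aln <- c(a = paste(rep("A", 100), collapse = ""),
#'          b = paste(c("G", rep("A", 99)), collapse = ""))
#' pairwisePi(aln)  # one difference in 100 sites: 0.01
#' @export
pairwisePi <- function(alignment, columns = NULL) {
  mat <- .asAlignmentMatrix(alignment)
  if (is.null(columns)) columns <- c(1L, ncol(mat))
  if (columns[1L] < 1L || columns[2L] > ncol(mat) || columns[1L] > columns[2L]) {
    stop("column interval outside the alignment")
  }
  pc <- .pairCounts(mat, columns[1L]:columns[2L])
  use <- pc$valids > 0L
  if (!any(use)) return(0)
  mean(pc$diffs[use] / pc$valids[use])
}

#' Sliding-window nucleotide diversity profile
#'
#' Computes [pairwisePi()] in windows of `window` columns advancing by
#' `step` (defaults 100 bp / 25 bp). Windows start at columns 1, 1+step,
#' 1+2*step, ... while a full window fits; a trailing partial window is
#' dropped, not rescaled. Window midpoints are
#' `start + floor(window/2) - 1`. High-diversity (hotspot) regions are
#' the merged spans of windows whose pi strictly exceeds
#' `hotspotFactor` times the median window pi.
#'
#' @inheritParams pairwisePi
#' @param window window size in alignment columns.
#' @param step interval between window starts.
#' @param hotspotFactor multiplier on the median window pi defining the
#'   hotspot threshold.
#' @return a [DiversityProfile-class] object.
#' @examples
#' aln <- c(a = strrep("ACGT", 50), b = strrep("ACGT", 50))
#' profile <- slidingPi(aln)     # identical rows: all windows pi = 0
#' length(hotspots(profile))     # threshold 0 is never strictly exceeded
#' @export
slidingPi <- function(alignment, window = 100L, step = 25L,
                      hotspotFactor = 2) {
  mat <- .asAlignmentMatrix(alignment)
  L <- ncol(mat)
  if (window > L) stop("window is larger than the alignment (", L, " columns)")
  if (step < 1L) stop("step must be positive")
  starts <- seq.int(1L, L - window + 1L, by = step)
  wins <- data.frame(
    midpoint = starts + window %/% 2L - 1L,
    start = starts,
    end = starts + window - 1L)
  res <- lapply(starts, function(s) {
    cols <- s:(s + window - 1L)
    pc <- .pairCounts(mat, cols)
    use <- pc$valids > 0L
    pi <- if (any(use)) mean(pc$diffs[use] / pc$valids[use]) else 0
    c(pi = pi, n = sum(colSums(matrix(mat[, cols] %in% DNA_BASES,
                                      nrow = nrow(mat))) == nrow(mat)))
  })
  wins$pi <- vapply(res, `[[`, numeric(1L), "pi")
  wins$n_valid_sites <- as.integer(vapply(res, `[[`, numeric(1L), "n"))
  med <- stats::median(wins$pi)
  thr <- hotspotFactor * med
  hot <- wins[wins$pi > thr, , drop = FALSE]
  hotRanges <- IRanges::reduce(IRanges::IRanges(start = hot$start,
                                                end = hot$end))
  new("DiversityProfile", windows = wins, medianPi = med,
      hotspotFactor = hotspotFactor, threshold = thr,
      hotspots = hotRanges, alignmentLength = as.integer(L))
}

setMethod("show", "DiversityProfile", function(object) {
  cat("DiversityProfile:", nrow(object@windows), "windows over",
      object@alignmentLength, "columns\n")
  cat(sprintf("  median pi %.5g; hotspot threshold %.5g (%g x median)\n",
              object@medianPi, object@threshold, object@hotspotFactor))
  cat("  hotspots:", length(object@hotspots), "interval(s)\n")
})

#' @rdname DiversityProfile-class
#' @export
setMethod("windows", "DiversityProfile", function(x) x@windows)

#' @rdname DiversityProfile-class
#' @export
setMethod("hotspots", "DiversityProfile", function(x) x@hotspots)

#' @rdname DiversityProfile-class
#' @export
setMethod("hotspotThreshold", "DiversityProfile", function(x) x@threshold)

#' Median window diversity of a profile
#'
#' @param x a [DiversityProfile-class].
#' @return the median per-window pi.
#' @export
medianPi <- function(x) {
  stopifnot(methods::is(x, "DiversityProfile"))
  x@medianPi
}

#' Select the most diverse short amplicon region
#'
#' Scans every alignment-column interval whose length lies within
#' `targetLength` plus/minus `lengthTolerance` and returns the one with
#' the highest mean per-site diversity ([pairwisePi()] over the
#' interval), ties broken by leftmost start then shortest length.
#' Intended for placing short barcode amplicons (for example ~199 bp for
#' short-read sequencing of a mitochondrial hypervariable fragment) over
#' the most informative stretch of an alignment.
#'
#' @inheritParams pairwisePi
#' @param targetLength desired amplicon length (alignment columns).
#' @param lengthTolerance allowed deviation from `targetLength`.
#' @return list with `start`, `end` (1-based inclusive columns),
#'   `length`, `mean_pi`; or `NULL` when no interval fits.
#' @export
selectAmplicon <- function(alignment, targetLength = 199L,
                           lengthTolerance = 10L) {
  mat <- .asAlignmentMatrix(alignment)
  L <- ncol(mat)
  lengths <- seq.int(max(1L, targetLength - lengthTolerance),
                     targetLength + lengthTolerance)
  lengths <- lengths[lengths <= L]
  if (length(lengths) == 0L) return(NULL)
  # visit lengths closest to the target first, so equal-diversity ties
  # resolve to the target length (then leftmost start)
  lengths <- lengths[order(abs(lengths - targetLength), lengths)]
  # cumulative per-pair difference/valid counts make every interval O(pairs)
  n <- nrow(mat)
  pairs <- utils::combn(n, 2L)
  valid <- matrix(mat %in% DNA_BASES, nrow = n)
  nP <- ncol(pairs)
  cumDiff <- matrix(0, nrow = nP, ncol = L + 1L)
  cumValid <- matrix(0, nrow = nP, ncol = L + 1L)
  for (k in seq_len(nP)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    ok <- valid[i, ] & valid[j, ]
    d <- as.integer(ok & (mat[i, ] != mat[j, ]))
    cumDiff[k, ] <- c(0L, cumsum(d))
    cumValid[k, ] <- c(0L, cumsum(as.integer(ok)))
  }
  best <- NULL
  for (len in lengths) {
    starts <- seq_len(L - len + 1L)
    for (s in starts) {
      d <- cumDiff[, s + len] - cumDiff[, s]
      v <- cumValid[, s + len] - cumValid[, s]
      use <- v > 0L
      mp <- if (any(use)) mean(d[use] / v[use]) else 0
      if (is.null(best) || mp > best$mean_pi) {
        best <- list(start = s, end = s + len - 1L, length = len, mean_pi = mp)
      }
    }
  }
  best
}

#' Columns fixed for different states between two groups
#'
#' Diagnostic sites: alignment columns where every sequence within each
#' of two groups carries the same unambiguous base, and the two groups
#' carry different bases. Used to verify that a selected barcode
#' amplicon can distinguish two taxa (for example two congeneric
#' species).
#'
#' @inheritParams pairwisePi
#' @param groupLabels character/factor of length `nrow(alignment)` with
#'   exactly two levels, labeling each sequence.
#' @return integer vector of 1-based diagnostic column indices.
#' @export
speciesDiagnosticSites <- function(alignment, groupLabels) {
  mat <- .asAlignmentMatrix(alignment)
  groupLabels <- as.character(groupLabels)
  if (length(groupLabels) != nrow(mat)) {
    stop("groupLabels must label every sequence")
  }
  lv <- unique(groupLabels)
  if (length(lv) != 2L) stop("exactly two groups are required")
  g1 <- mat[groupLabels == lv[1L], , drop = FALSE]
  g2 <- mat[groupLabels == lv[2L], , drop = FALSE]
  if (nrow(g1) == 0L || nrow(g2) == 0L) stop("each group needs >= 1 sequence")
  fixedState <- function(g) {
    apply(g, 2L, function(col) {
      if (all(col %in% DNA_BASES) && length(unique(col)) == 1L) col[1L]
      else NA_character_
    })
  }
  s1 <- fixedState(g1)
  s2 <- fixedState(g2)
  which(!is.na(s1) & !is.na(s2) & s1 != s2)
}

#' Export a diversity profile's windows as TSV
#'
#' Columns `midpoint`, `start`, `end`, `pi`, `n_valid_sites` (1-based
#' inclusive alignment columns).
#'
#' @param profile a [DiversityProfile-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDiversityTSV <- function(profile, path) {
  writeTSV(windows(profile), path)
}

#' Export a profile's hotspots as BED
#'
#' @param profile a [DiversityProfile-class].
#' @param path output path.
#' @param name sequence name used in the BED records.
#' @return the path, invisibly.
#' @export
writeHotspotsBED <- function(profile, path, name = "alignment") {
  gr <- GenomicRanges::GRanges(rep(name, length(hotspots(profile))),
                               hotspots(profile))
  writeBED(gr, path)
}
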