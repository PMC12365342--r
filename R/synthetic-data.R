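#' Specify a synthetic genome with planted microsatellites
#'
#' Describes contigs of given lengths and background GC, with perfect
#' SSR tracts planted at known positions. The planted registry is the
#' ground truth against which the scanner and the design filter cascade
#' are audited.
#'
#' @param lengths integer vector of contig lengths (bp); contig ids are
#'   `contig1`, `contig2`, ...
#' @param gc background GC fraction of the flanking sequence.
#' @param planted data.frame with columns `contig_id`, `start` (1-based),
#'   `motif` (primitive 1-6 bp A/C/G/T unit) and `repeats`; may have zero
#'   rows.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated spec (list) for [generateGenome()].
#' @export
syntheticGenomeSpec <- function(lengths, gc = 0.4, planted = NULL,
                                seed = 1L) {
  if (any(lengths < 1L)) stop("contig lengths must be >= 1")
  if (!.isScalarNumber(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (!.isScalarInt(seed)) stop("seed must be a single integer")
  ids <- sprintf("contig%d", seq_along(lengths))
  if (is.null(planted)) {
    planted <- data.frame(contig_id = character(), start = integer(),
                          motif = character(), repeats = integer(),
                          stringsAsFactors = FALSE)
  }
  planted <- as.data.frame(planted, stringsAsFactors = FALSE)
  if (nrow(planted) > 0L) {
    need <- c("contig_id", "start", "motif", "repeats")
    if (!all(need %in% names(planted))) {
      stop("planted must have columns: ", paste(need, collapse = ", "))
    }
    if (!all(planted$contig_id %in% ids)) {
      stop("planted SSRs reference unknown contigs")
    }
    for (i in seq_len(nrow(planted))) {
      chars <- .checkACGT(planted$motif[i], "planted motif")
      if (length(chars) > 6L) stop("planted motifs must be 1-6 bp")
      if (.isPowerOfShorter(planted$motif[i])) {
        stop("planted motif ", planted$motif[i],
             " is a power of a shorter unit; plant the shortest period")
      }
      if (planted$repeats[i] < 1L) stop("repeat counts must be >= 1")
      len <- structure(lengths, names = ids)[[planted$contig_id[i]]]
      tractEnd <- planted$start[i] +
        planted$repeats[i] * nchar(planted$motif[i]) - 1L
      if (planted$start[i] < 1L || tractEnd > len) {
        stop("planted SSR ", i, " does not fit its contig")
      }
    }
    # same-contig tracts must be separated by at least one non-repeat base
    for (ctg in unique(planted$contig_id)) {
      p <- planted[planted$contig_id == ctg, , drop = FALSE]
      if (nrow(p) < 2L) next
      s <- p$start
      e <- p$start + p$repeats * nchar(p$motif) - 1L
      o <- order(s)
      s <- s[o]; e <- e[o]
      for (k in seq_len(length(s) - 1L)) {
        if (s[k + 1L] <= e[k] + 1L) {
          stop(sprintf(
            "planted SSRs overlap or touch on %s: [%d-%d] and [%d-%d]",
            ctg, s[k], e[k], s[k + 1L], e[k + 1L]))
        }
      }
    }
  }
  list(ids = ids, lengths = as.integer(lengths), gc = gc,
       planted = planted, seed = as.integer(seed))
}

.sampleBases <- function(n, gc) {
  if (n == 0L) return(character(0L))
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a synthetic genome with planted SSR ground truth
#'
#' Builds each contig by planting the specified repeat tracts verbatim
#' at their declared positions and filling all other positions with
#' i.i.d. bases at the background GC. Flanks are rejection-sampled: the
#' finished contig is re-scanned and regenerated until the scanner
#' (at `thresholds`) reports exactly the planted loci that meet the
#' thresholds — no accidental SSR, no tract extended or shifted by its
#' flank. Identical spec and seed give byte-identical output.
#'
#' @param spec a [syntheticGenomeSpec()].
#' @param thresholds [scanThresholds()] the contigs are certified
#'   against.
#' @param maxRetries per-contig resampling cap; generation fails loudly
#'   beyond it rather than emitting an uncertified contig.
#' @return list with `contigs` (`DNAStringSet`) and `registry`
#'   (data.frame `contig_id`, `start`, `end`, `motif`, `repeats`,
#'   1-based inclusive).
#' @examples
#' spec <- syntheticGenomeSpec(
#'   lengths = 2000,
#'   planted = data.frame(contig_id = "contig1", start = 901,
#'                        motif = "AGAT", repeats = 12),
#'   seed = 7)
#' g <- generateGenome(spec)
#' substr(as.character(g$contigs[["contig1"]]), 901, 948)
#' @export
generateGenome <- function(spec, thresholds = scanThresholds(),
                           maxRetries = 1000L) {
  registry <- spec$planted
  if (nrow(registry) > 0L) {
    registry$end <- registry$start + registry$repeats * nchar(registry$motif) - 1L
    registry <- registry[, c("contig_id", "start", "end", "motif", "repeats")]
  } else {
    registry <- data.frame(contig_id = character(), start = integer(),
                           end = integer(), motif = character(),
                           repeats = integer(), stringsAsFactors = FALSE)
  }
  contigs <- withSeed(spec$seed, {
    lapply(seq_along(spec$ids), function(ci) {
      id <- spec$ids[ci]
      L <- spec$lengths[ci]
      p <- registry[registry$contig_id == id, , drop = FALSE]
      fixed <- rep(NA_character_, L)
      for (k in seq_len(nrow(p))) {
        tract <- strsplit(strrep(p$motif[k], p$repeats[k]), "")[[1L]]
        fixed[p$start[k]:p$end[k]] <- tract
      }
      free <- which(is.na(fixed))
      # expectation: exactly the planted loci that meet the thresholds
      expected <- p[p$repeats >= thresholds[nchar(p$motif)], , drop = FALSE]
      expKey <- sort(sprintf("%d:%d:%s:%d", expected$start, expected$end,
                             canonicalMotif(expected$motif), expected$repeats))
      for (try in seq_len(maxRetries)) {
        chars <- fixed
        chars[free] <- .sampleBases(length(free), spec$gc)
        seqStr <- paste(chars, collapse = "")
        found <- scanContig(seqStr, id, thresholds)
        foundKey <- sort(sprintf("%d:%d:%s:%d", found$start, found$end,
                                 found$motif, found$repeats))
        if (identical(foundKey, expKey)) return(seqStr)
      }
      stop("could not certify contig ", id, " within ", maxRetries,
           " resampling attempts; lower the planted density or GC bias")
    })
  })
  contigs <- Biostrings::DNAStringSet(unlist(contigs))
  names(contigs) <- spec$ids
  list(contigs = contigs, registry = registry)
}

#' Write a planted-SSR registry as TSV
#'
#' Header `contig_id`, `start`, `end`, `motif`, `repeats`; 1-based
#' inclusive coordinates.
#'
#' @param registry the registry from [generateGenome()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRegistryTSV <- function(registry, path) {
  writeTSV(registry, path)
}

#' Specify a synthetic alignment with a diversity hotspot
#'
#' Sequence 1 is the reference; every other sequence differs from it at
#' sites drawn independently with `backgroundRate` outside the hotspot
#' interval and `hotspotRate` inside it. Substitutions are
#' site-independent and gap-free (gap handling is exercised separately
#' with hand-built alignments).
#'
#' @param nSequences number of sequences (>= 2).
#' @param length alignment length (columns).
#' @param backgroundRate per-site substitution probability outside the
#'   hotspot.
#' @param hotspot 1-based inclusive interval `c(start, end)`, or `NULL`
#'   for no hotspot.
#' @param hotspotRate per-site substitution probability inside the
#'   hotspot (>= `backgroundRate`).
#' @param seed integer seed.
#' @return a validated spec (list) for [generateAlignment()].
#' @export
syntheticAlignmentSpec <- function(nSequences, length, backgroundRate = 0,
                                   hotspot = NULL, hotspotRate = backgroundRate,
                                   seed = 1L) {
  if (nSequences < 2L) stop("an alignment needs at least 2 sequences")
  if (length < 1L) stop("length must be positive")
  for (r in c(backgroundRate, hotspotRate)) {
    if (!.isScalarNumber(r) || r < 0 || r > 1) {
      stop("substitution rates must lie in [0, 1]")
    }
  }
  if (hotspotRate < backgroundRate) {
    stop("hotspotRate must be >= backgroundRate")
  }
  if (!is.null(hotspot)) {
    if (length(hotspot) != 2L || hotspot[1L] < 1L || hotspot[2L] > length ||
        hotspot[1L] > hotspot[2L]) {
      stop("hotspot interval must lie within [1, length]")
    }
  }
  if (!.isScalarInt(seed)) stop("seed must be a single integer")
  list(n = as.integer(nSequences), length = as.integer(length),
       backgroundRate = backgroundRate, hotspot = hotspot,
       hotspotRate = hotspotRate, seed = as.integer(seed))
}

#' Generate a synthetic alignment with a localized diversity hotspot
#'
#' @param spec a [syntheticAlignmentSpec()].
#' @return a `DNAStringSet` of `n` equal-length gap-free sequences named
#'   `seq1` (the reference) to `seqN`.
#' @examples
#' spec <- syntheticAlignmentSpec(8, 600, backgroundRate = 0,
#'                                hotspot = c(201, 300), hotspotRate = 0.2,
#'                                seed = 11)
#' aln <- generateAlignment(spec)
#' @export
generateAlignment <- function(spec) {
  rate <- rep(spec$backgroundRate, spec$length)
  if (!is.null(spec$hotspot)) {
    rate[spec$hotspot[1L]:spec$hotspot[2L]] <- spec$hotspotRate
  }
  rows <- withSeed(spec$seed, {
    ref <- sample(DNA_BASES, spec$length, replace = TRUE)
    out <- vector("list", spec$n)
    out[[1L]] <- ref
    for (i in 2:spec$n) {
      s <- ref
      hit <- which(runif(spec$length) < rate)
      for (p in hit) s[p] <- sample(setdiff(DNA_BASES, ref[p]), 1L)
      out[[i]] <- s
    }
    out
  })
  aln <- Biostrings::DNAStringSet(vapply(rows, paste, character(1L),
                                         collapse = ""))
  names(aln) <- sprintf("seq%d", seq_len(spec$n))
  aln
}

# First complementary run of >= minLen between a and b (antiparallel,
# ungapped), or NULL. Positions are 1-based in each original sequence.
.complementaryRun <- function(ca, cb, minLen) {
  rb <- rev(cb)
  na <- length(ca)
  nb <- length(cb)
  compA <- DNA_COMPLEMENT[ca]
  for (offset in (-(nb - 1L)):(na - 1L)) {
    i <- max(1L, 1L + offset):min(na, nb + offset)
    paired <- compA[i] == rb[i - offset]
    if (!any(paired)) next
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- which(r$values & r$lengths >= minLen)
    if (length(k) > 0L) {
      ii <- i[starts[k[1L]]:ends[k[1L]]]
      return(list(apos = ii, bpos = nb + 1L - (ii - offset)))
    }
  }
  NULL
}

#' Generate a primer panel with engineered dimer conflicts
#'
#' Emits `n` oligos whose melting temperatures lie in `tmRange`. Each
#' requested conflict edge gets a pair of mutually complementary 8 bp
#' 3'-region tags so that the two oligos form a cross-dimer below
#' -5 kcal/mol under [crossDimerEnergy()]; all other oligo pairs are
#' verified free of complementary stretches of 4 bp or more.
#'
#' Construction uses a purine body alphabet (A/G), which cannot
#' base-pair with itself; edge tags come from a fixed codebook of
#' purine 8-mers whose 4-mer substring sets are pairwise disjoint (two
#' protected tag segments can only form a 4 bp complementary run if the
#' underlying tags share a 4-mer, so the codebook rules that out by
#' construction), and residual runs between a pyrimidine tag complement
#' and a purine body are broken by an iterative repair loop on
#' unprotected body bases. An unconstructible request (more than 3
#' edges, more than 2 edges on one oligo, or the retry cap exhausted)
#' fails loudly.
#'
#' @param n number of oligos.
#' @param conflictEdges list of length-2 integer vectors (1-based oligo
#'   indices) that must conflict; at most 3 edges in total and 2 per
#'   oligo.
#' @param seed integer seed.
#' @param params [ThermoParameters-class] used to verify energies.
#' @param tmRange length-2 numeric melting-temperature window (C) every
#'   oligo must satisfy.
#' @param tmBand length-2 numeric target band (within `tmRange`, at most
#'   5 C wide) the oligos are tuned into, so that a panel with no
#'   requested edges is also free of melting-temperature-gap conflicts.
#' @param maxRetries construction retry cap.
#' @return data.frame `id`, `sequence`, `length`, `tm`; attribute
#'   `conflict_edges` echoes the engineered edges as id pairs.
#' @examples
#' pan <- generatePrimerPanel(3, conflictEdges = list(), seed = 5)
#' pan$tm
#' @export
generatePrimerPanel <- function(n, conflictEdges = list(), seed = 1L,
                                params = thermoParameters(),
                                tmRange = c(48, 62), tmBand = c(53, 58),
                                maxRetries = 200L) {
  if (tmBand[1L] < tmRange[1L] || tmBand[2L] > tmRange[2L]) {
    stop("tmBand must lie within tmRange")
  }
  if (n < 1L) stop("n must be >= 1")
  deg <- integer(n)
  for (e in conflictEdges) {
    if (length(e) != 2L || any(e < 1L) || any(e > n) || e[1L] == e[2L]) {
      stop("conflict edges must be distinct 1-based index pairs within 1..n")
    }
    deg[e[1L]] <- deg[e[1L]] + 1L
    deg[e[2L]] <- deg[e[2L]] + 1L
  }
  tagLen <- 8L
  if (length(conflictEdges) > 3L) {
    stop("unconstructible: at most 3 conflict edges are supported ",
         "(the orthogonal tag codebook has 3 entries)")
  }
  if (max(deg, 0L) * tagLen + max(max(deg, 0L) - 1L, 0L) + 3L > 24L) {
    stop("unconstructible: an oligo carries too many conflict edges (",
         max(deg), ") for the 24 bp primer-length cap")
  }
  withSeed(seed, {
    for (try in seq_len(maxRetries)) {
      oligos <- .buildConflictPanel(n, conflictEdges, deg, tagLen, params,
                                    tmBand)
      if (!is.null(oligos)) {
        out <- data.frame(id = sprintf("oligo%02d", seq_len(n)),
                          sequence = vapply(oligos, function(o)
                            paste(o$chars, collapse = ""), character(1L)),
                          stringsAsFactors = FALSE)
        out$length <- nchar(out$sequence)
        out$tm <- meltingTemperature(out$sequence, params)
        attr(out, "conflict_edges") <- lapply(conflictEdges, function(e) {
          out$id[e]
        })
        return(out)
      }
    }
    stop("could not construct a conflict panel within ", maxRetries,
         " attempts; relax the edge set or Tm window")
  })
}

# One construction attempt; NULL on failure. Each oligo is a list of
# chars plus a logical `protected` mask covering engineered tag bases.
#
# Cleanliness is constructive rather than search-based. Pairing between a
# purine (A/G) stretch and a pyrimidine tag complement reduces to the
# stretch sharing a contiguous 4-mer with the underlying codebook tag, so:
#   - untagged oligos are purine block sequences (run lengths >= 3) whose
#     4-mers never coincide with a codebook 4-mer;
#   - tagged oligos have few free bases (body + inter-tag spacers), and
#     every assignment is enumerated to find one that is self-clean,
#     avoids codebook 4-mers outside protected tags, and sits in the Tm
#     band.
.tagCodebook <- c("GAAGAAGA", "AGGAGGAG", "AGAGAGAG")

# All compositions of `total` into alternating A/G blocks of length 3-5,
# as character vectors; clean against the codebook by the run-length
# structure (every 4-window has at most one letter change, and no
# codebook tag has that form).
.blockBodies <- function(total) {
  out <- list()
  rec <- function(remaining, lens) {
    if (remaining == 0L) {
      out[[length(out) + 1L]] <<- lens
      return(invisible())
    }
    for (b in 3:5) {
      if (remaining >= b && (remaining - b == 0L || remaining - b >= 3L)) {
        rec(remaining - b, c(lens, b))
      }
    }
  }
  rec(total, integer())
  seqs <- character()
  for (lens in out) {
    for (first in c("A", "G")) {
      letters <- rep(c(first, setdiff(c("A", "G"), first)),
                     length.out = length(lens))
      seqs <- c(seqs, paste(rep(letters, lens), collapse = ""))
    }
  }
  unique(seqs)
}

# TRUE when every 4-window of a purine stretch that touches an
# unprotected base avoids the codebook 4-mers.
.purineWindowsClean <- function(chars, protected, grams) {
  isPur <- chars %in% c("A", "G")
  n <- length(chars)
  for (st in seq_len(max(n - 3L, 0L))) {
    win <- st:(st + 3L)
    if (!all(isPur[win])) next
    if (all(protected[win])) next
    if (paste(chars[win], collapse = "") %in% grams) return(FALSE)
  }
  TRUE
}

.buildConflictPanel <- function(n, conflictEdges, deg, tagLen, params,
                                tmBand) {
  maxDeg <- max(deg, 0L)
  targetLen <- min(24L, max(20L, maxDeg * tagLen + max(maxDeg - 1L, 0L) + 6L))

  # scaffold: protected tags (one unprotected spacer between tags), with
  # pyrimidine complements balanced across each edge
  oligos <- lapply(seq_len(n), function(i) {
    list(chars = rep(NA_character_, targetLen),
         protected = rep(FALSE, targetLen))
  })
  cursor3 <- rep(0L, n)
  rcLoad <- rep(0L, n)
  rcCarrier <- integer(length(conflictEdges))
  for (ei in seq_along(conflictEdges)) {
    e <- conflictEdges[[ei]]
    tag <- strsplit(.tagCodebook[ei], "")[[1L]]
    rcTag <- rev(DNA_COMPLEMENT[tag])
    rcSide <- if (rcLoad[e[1L]] < rcLoad[e[2L]]) 1L else 2L
    rcLoad[e[rcSide]] <- rcLoad[e[rcSide]] + 1L
    rcCarrier[ei] <- e[rcSide]
    for (side in 1:2) {
      idx <- e[side]
      put <- if (side == rcSide) rcTag else tag
      to <- targetLen - cursor3[idx]
      from <- to - tagLen + 1L
      if (from < 1L) return(NULL)
      oligos[[idx]]$chars[from:to] <- put
      oligos[[idx]]$protected[from:to] <- TRUE
      cursor3[idx] <- cursor3[idx] + tagLen + 1L
    }
  }

  edgeKey <- vapply(conflictEdges, function(e) {
    paste(sort(e), collapse = "-")
  }, character(1L))
  isEdge <- function(i, j) paste(sort(c(i, j)), collapse = "-") %in% edgeKey
  # a purine window of oligo i matching a 4-mer of tag T_e can pair with
  # rc(T_e); that matters only when rc(T_e) lives in i itself or in a
  # non-edge partner
  gramsFor <- function(i) {
    out <- character()
    for (ei in seq_along(conflictEdges)) {
      j <- rcCarrier[ei]
      if (j == i || !isEdge(i, j)) {
        tag <- .tagCodebook[ei]
        for (k in seq_len(nchar(tag) - 3L)) {
          out <- c(out, substr(tag, k, k + 3L))
        }
      }
    }
    unique(out)
  }
  blockCands <- NULL   # shared across untagged oligos
  for (i in seq_len(n)) {
    grams <- gramsFor(i)
    free <- which(is.na(oligos[[i]]$chars))
    if (length(free) == targetLen) {
      # untagged oligo: purine block sequence with Tm in band
      if (is.null(blockCands)) {
        cands <- .blockBodies(targetLen)
        tms <- meltingTemperature(cands, params)
        blockCands <- cands[tms >= tmBand[1L] & tms <= tmBand[2L]]
        if (length(blockCands) == 0L) return(NULL)
      }
      pick <- if (length(blockCands) == 1L) blockCands else
        sample(blockCands, 1L)
      oligos[[i]]$chars <- strsplit(pick, "")[[1L]]
      next
    }
    # tagged oligo: search the free A/G assignments in seed-shuffled
    # order, keeping the first self-clean, codebook-clean, in-band one
    if (length(free) > 12L) return(NULL)
    found <- FALSE
    masks <- sample(0L:(2L^length(free) - 1L))
    for (mask in masks) {
      chars <- oligos[[i]]$chars
      chars[free] <- ifelse(bitwAnd(mask, 2L^(seq_along(free) - 1L)) > 0L,
                            "G", "A")
      if (!.purineWindowsClean(chars, oligos[[i]]$protected, grams)) next
      if (!is.null(.complementaryRun(chars, chars, 4L))) next
      tm <- meltingTemperature(paste(chars, collapse = ""), params)
      if (tm < tmBand[1L] || tm > tmBand[2L]) next
      oligos[[i]]$chars <- chars
      found <- TRUE
      break
    }
    if (!found) return(NULL)
  }

  # full verification: Tm window, engineered energies, cleanliness of all
  # non-edge pairs (including each oligo against itself)
  seqs <- vapply(oligos, function(o) paste(o$chars, collapse = ""),
                 character(1L))
  tm <- meltingTemperature(seqs, params)
  if (any(tm < tmBand[1L] | tm > tmBand[2L])) return(NULL)
  for (e in conflictEdges) {
    if (crossDimerEnergy(seqs[e[1L]], seqs[e[2L]], params) >= -5) return(NULL)
  }
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i != j && isEdge(i, j)) next
      if (!is.null(.complementaryRun(oligos[[i]]$chars,
                                     oligos[[j]]$chars, 4L))) {
        return(NULL)
      }
    }
  }
  oligos
}

#' Lift a generated oligo table to a multiplex panel fixture
#'
#' Convenience for testing multiplex design against
#' [generatePrimerPanel()] output: each oligo stands in for both the
#' forward and reverse primer of one panel entry.
#'
#' @param oligos data.frame from [generatePrimerPanel()].
#' @return panel data.frame (see [asPanel()]).
#' @export
panelFromOligos <- function(oligos) {
  asPanel(data.frame(id = oligos$id, fwd_seq = oligos$sequence,
                     rev_seq = oligos$sequence, stringsAsFactors = FALSE))
}
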