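#' Extract primer-design candidate regions around design-grade SSR loci
#'
#' Keeps loci on contigs longer than `minContig` (short contigs are
#' excluded so selected loci are not physically clustered) and with a
#' repeat tract (allele) no longer than `alleleCap` (short alleles
#' amplify reliably from degraded, non-invasively collected DNA). Each
#' kept locus is returned with flanking sequence long enough to host any
#' amplicon up to the design maximum (at least `maxAmplicon - tract` bp
#' per side, truncated at contig ends).
#'
#' @param loci design-filtered loci ([filterForDesign()] output; `GRanges`
#'   or SSR table data.frame).
#' @param contigs `DNAStringSet`, named character vector, or FASTA path.
#' @param minContig contigs must be strictly longer than this (bp).
#' @param alleleCap maximum repeat-tract length (bp).
#' @param maxAmplicon largest amplicon the design may use (bp); sets the
#'   flank length.
#' @return data.frame with one row per candidate: locus columns plus
#'   `allele_size`, `window_start`, `window_end` (1-based inclusive
#'   extraction window on the contig), `window_seq`, `flank_left`,
#'   `flank_right`.
#' @export
extractCandidates <- function(loci, contigs, minContig = 10000L,
                              alleleCap = 150L, maxAmplicon = 250L) {
  tab <- .lociAsTable(loci)
  contigs <- .asContigSet(contigs)
  unknown <- setdiff(unique(tab$contig_id), names(contigs))
  if (length(unknown) > 0L) {
    stop("loci reference unknown contigs: ", paste(unknown, collapse = ", "))
  }
  lens <- structure(Biostrings::width(contigs), names = names(contigs))
  keep <- lens[tab$contig_id] > minContig & tab$tract_length <= alleleCap
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    return(cbind(tab, data.frame(allele_size = integer(),
                                 window_start = integer(),
                                 window_end = integer(),
                                 window_seq = character(),
                                 flank_left = character(),
                                 flank_right = character())))
  }
  flankLen <- pmax(maxAmplicon - tab$tract_length, 0L)
  ws <- pmax(1L, tab$start - flankLen)
  we <- pmin(lens[tab$contig_id], tab$end + flankLen)
  seqStr <- as.character(contigs[tab$contig_id])
  out <- tab
  out$allele_size <- tab$tract_length
  out$window_start <- as.integer(ws)
  out$window_end <- as.integer(we)
  out$window_seq <- substr(seqStr, ws, we)
  out$flank_left <- substr(seqStr, ws, tab$start - 1L)
  out$flank_right <- substr(seqStr, tab$end + 1L, we)
  rownames(out) <- NULL
  out
}

#' Remove duplicated candidate regions
#'
#' Drops candidates whose extraction-window sequence exactly duplicates
#' (or is the exact reverse complement of) an earlier candidate's window;
#' the reverse-complement rule is needed because an assembler may emit
#' either strand of the same region. First occurrence kept; order
#' otherwise preserved.
#'
#' @param candidates data.frame from [extractCandidates()].
#' @return the deduplicated data.frame.
#' @export
dedupeCandidates <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  seen <- character()
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    w <- candidates$window_seq[i]
    if (w %in% seen || .revcomp(w) %in% seen) next
    keep[i] <- TRUE
    seen <- c(seen, w)
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude slippage-prone candidate motifs
#'
#' Drops candidates whose realized repeat tract contains three or more
#' consecutive adenines (evaluated on the tract as written, so runs
#' spanning motif junctions are caught) or whose motif alphabet is a
#' subset of \{A, T\}. Both patterns are error-prone targets for
#' sequencing-based genotyping of low-quality samples. Optionally the
#' adenine rule is also applied to the complement strand (TTT in the
#' tract); off by default since the rule targets adenine runs on the
#' reported strand.
#'
#' @param candidates data.frame from [extractCandidates()] /
#'   [dedupeCandidates()].
#' @param checkComplementTTT also exclude tracts containing `TTT`.
#' @return the filtered data.frame.
#' @export
applyExclusions <- function(candidates, checkComplementTTT = FALSE) {
  if (nrow(candidates) == 0L) return(candidates)
  # realized tract: the repeat copies actually present in the contig
  tract <- vapply(seq_len(nrow(candidates)), function(i) {
    substr(candidates$window_seq[i],
           candidates$start[i] - candidates$window_start[i] + 1L,
           candidates$end[i] - candidates$window_start[i] + 1L)
  }, character(1L))
  hasAAA <- grepl("AAA", tract, fixed = TRUE)
  if (checkComplementTTT) hasAAA <- hasAAA | grepl("TTT", tract, fixed = TRUE)
  atOnly <- !grepl("[CG]", candidates$motif)
  out <- candidates[!(hasAAA | atOnly), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE where the 1-based contig interval [s, e] overlaps a mask interval.
.maskedInterval <- function(contig, s, e, mask) {
  if (is.null(mask) || length(mask) == 0L) return(rep(FALSE, length(s)))
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start = s, end = e))
  IRanges::overlapsAny(q, mask)
}

#' Enumerate admissible primer oligos in a candidate's flanks
#'
#' Tests every window of length `primerLen[1]`..`primerLen[2]` in each
#' flank against all design constraints: melting temperature in
#' `tmRange`, GC fraction in `gcRange`, the primer edge nearest the
#' repeat tract at least `minDistance` bp away from it, no overlap with a
#' masked (repeat / transposable-element) interval, and no
#' mononucleotide run of `maxMonoRun + 1` or more inside the primer (a
#' guard against slippage during amplification). Reverse primers are
#' reported 5'->3' on the minus strand.
#'
#' @param candidate one row of the candidate data.frame.
#' @param mask optional `GRanges` of masked intervals (1-based
#'   inclusive; use [readMaskBED()] for BED input).
#' @param params [ThermoParameters-class] for Tm computation.
#' @param primerLen length-2 integer: min/max primer length (bp).
#' @param tmRange length-2 numeric: allowed melting temperature (C).
#' @param gcRange length-2 numeric: allowed GC fraction.
#' @param minDistance minimum gap (bp) between primer and repeat tract.
#' @param maxMonoRun longest tolerated mononucleotide run in a primer.
#' @return list with data.frames `forward` and `reverse`; columns
#'   `sequence` (5'->3'), `start`, `end` (contig, 1-based inclusive),
#'   `length`, `tm`, `gc`, `distance` (bp to the tract). Either may have
#'   zero rows.
#' @export
enumeratePrimers <- function(candidate, mask = NULL,
                             params = thermoParameters(),
                             primerLen = c(17L, 24L), tmRange = c(48, 62),
                             gcRange = c(0.35, 0.50), minDistance = 20L,
                             maxMonoRun = 4L) {
  stopifnot(nrow(candidate) == 1L)
  emptyOligos <- data.frame(sequence = character(), start = integer(),
                            end = integer(), length = integer(),
                            tm = numeric(), gc = numeric(),
                            distance = integer(), stringsAsFactors = FALSE)
  oneStrand <- function(flank, flankStart, forward) {
    n <- nchar(flank)
    rows <- list()
    for (len in primerLen[1L]:primerLen[2L]) {
      if (n < len) next
      starts <- seq_len(n - len + 1L)
      s <- flankStart + starts - 1L
      e <- s + len - 1L
      # distance from the tract-proximal primer edge to the tract boundary
      dist <- if (forward) candidate$start - e - 1L else s - candidate$end - 1L
      ok <- dist >= minDistance
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <-
        data.frame(start = s[ok], end = e[ok], length = len,
                   distance = as.integer(dist[ok]))
    }
    if (length(rows) == 0L) return(emptyOligos)
    win <- do.call(rbind, rows)
    slice <- substr(rep(flank, nrow(win)),
                    win$start - flankStart + 1L, win$end - flankStart + 1L)
    ok <- !grepl("[^ACGT]", slice)
    ok <- ok & !grepl(strrep("A", maxMonoRun + 1L), slice) &
      !grepl(strrep("C", maxMonoRun + 1L), slice) &
      !grepl(strrep("G", maxMonoRun + 1L), slice) &
      !grepl(strrep("T", maxMonoRun + 1L), slice)
    win <- win[ok, , drop = FALSE]; slice <- slice[ok]
    if (nrow(win) == 0L) return(emptyOligos)
    gc <- vapply(slice, function(x) gcContent(x), numeric(1L), USE.NAMES = FALSE)
    ok <- gc >= gcRange[1L] & gc <= gcRange[2L]
    win <- win[ok, , drop = FALSE]; slice <- slice[ok]; gc <- gc[ok]
    if (nrow(win) == 0L) return(emptyOligos)
    seqs <- if (forward) slice else .revcomp(slice)
    tm <- meltingTemperature(seqs, params)
    ok <- tm >= tmRange[1L] & tm <= tmRange[2L]
    win <- win[ok, , drop = FALSE]; seqs <- seqs[ok]
    gc <- gc[ok]; tm <- tm[ok]
    if (nrow(win) == 0L) return(emptyOligos)
    ok <- !.maskedInterval(candidate$contig_id, win$start, win$end, mask)
    data.frame(sequence = seqs[ok], start = win$start[ok], end = win$end[ok],
               length = win$length[ok], tm = tm[ok], gc = gc[ok],
               distance = win$distance[ok], stringsAsFactors = FALSE)
  }
  list(forward = oneStrand(candidate$flank_left, candidate$window_start, TRUE),
       reverse = oneStrand(candidate$flank_right, candidate$end + 1L, FALSE))
}

#' Pair forward and reverse oligos into ranked primer pairs
#'
#' Forms every forward x reverse combination whose amplicon (forward 5'
#' start to reverse 3' end on the contig, inclusive) falls inside
#' `ampliconRange`, scores each pair, and ranks ascending by penalty:
#' \deqn{penalty = |T_{m,f} - T_{m,r}| + w_1 \sum \max(0, -5 - \Delta G_{self})
#'   + w_2\,|L - L_{mid}|/100}
#' i.e. the Tm mismatch, any self-dimer energy of either oligo beyond
#' -5 kcal/mol, and the distance of the amplicon length from the middle
#' of the allowed range. Ties are broken by amplicon length, then
#' forward position, so the ranking is deterministic.
#'
#' @param forward,reverse oligo data.frames from [enumeratePrimers()].
#' @param ampliconRange length-2 numeric: allowed amplicon length (bp).
#' @param params [ThermoParameters-class] for self-dimer scoring.
#' @param w1,w2 penalty weights (self-dimer deficit; length centering).
#' @param selfDimerSoftCut self-dimer energy (kcal/mol) beyond which the
#'   deficit penalty accrues.
#' @return data.frame of pairs ranked by `pair_penalty`, with forward and
#'   reverse oligo columns (`fwd_*`, `rev_*`), `amplicon_start`,
#'   `amplicon_end`, `amplicon_length`.
#' @export
pairPrimers <- function(forward, reverse, ampliconRange = c(90L, 250L),
                        params = thermoParameters(), w1 = 1, w2 = 0.5,
                        selfDimerSoftCut = -5) {
  empty <- data.frame(fwd_seq = character(), fwd_start = integer(),
                      fwd_end = integer(), fwd_tm = numeric(),
                      fwd_gc = numeric(), fwd_self_dimer = numeric(),
                      rev_seq = character(), rev_start = integer(),
                      rev_end = integer(), rev_tm = numeric(),
                      rev_gc = numeric(), rev_self_dimer = numeric(),
                      amplicon_start = integer(), amplicon_end = integer(),
                      amplicon_length = integer(), pair_penalty = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(forward) == 0L || nrow(reverse) == 0L) return(empty)
  grid <- expand.grid(f = seq_len(nrow(forward)), r = seq_len(nrow(reverse)))
  len <- reverse$end[grid$r] - forward$start[grid$f] + 1L
  ok <- len >= ampliconRange[1L] & len <= ampliconRange[2L]
  grid <- grid[ok, , drop = FALSE]
  len <- len[ok]
  if (nrow(grid) == 0L) return(empty)
  # self-dimer energies only for oligos that appear in a legal pair
  sdF <- rep(NA_real_, nrow(forward))
  sdR <- rep(NA_real_, nrow(reverse))
  for (i in unique(grid$f)) sdF[i] <- selfDimerEnergy(forward$sequence[i], params)
  for (i in unique(grid$r)) sdR[i] <- selfDimerEnergy(reverse$sequence[i], params)
  mid <- mean(ampliconRange)
  deficit <- pmax(0, selfDimerSoftCut - sdF[grid$f]) +
    pmax(0, selfDimerSoftCut - sdR[grid$r])
  penalty <- abs(forward$tm[grid$f] - reverse$tm[grid$r]) +
    w1 * deficit + w2 * abs(len - mid) / 100
  out <- data.frame(
    fwd_seq = forward$sequence[grid$f], fwd_start = forward$start[grid$f],
    fwd_end = forward$end[grid$f], fwd_tm = forward$tm[grid$f],
    fwd_gc = forward$gc[grid$f], fwd_self_dimer = sdF[grid$f],
    rev_seq = reverse$sequence[grid$r], rev_start = reverse$start[grid$r],
    rev_end = reverse$end[grid$r], rev_tm = reverse$tm[grid$r],
    rev_gc = reverse$gc[grid$r], rev_self_dimer = sdR[grid$r],
    amplicon_start = forward$start[grid$f],
    amplicon_end = reverse$end[grid$r],
    amplicon_length = as.integer(len), pair_penalty = penalty,
    stringsAsFactors = FALSE)
  out <- out[order(out$pair_penalty, out$amplicon_length, out$fwd_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top-ranked primer pair
#'
#' Head of a ranked pair table, or `NULL` when no pair exists (the locus
#' is then reported as having no primer found).
#'
#' @param pairs ranked data.frame from [pairPrimers()].
#' @return a one-row data.frame, or `NULL`.
#' @export
selectBestPair <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(NULL)
  pairs[1L, , drop = FALSE]
}

#' Design one primer pair per candidate locus
#'
#' Runs [enumeratePrimers()], [pairPrimers()] and [selectBestPair()] over
#' a candidate table and assembles the final primer table (one row per
#' locus that obtained a pair). Loci with no admissible pair are listed
#' in the `no_primer` attribute.
#'
#' @param candidates data.frame of candidate regions (post-exclusion).
#' @param mask optional `GRanges` of masked intervals.
#' @param params [ThermoParameters-class].
#' @param ... constraint arguments passed to [enumeratePrimers()] and
#'   `ampliconRange` passed to [pairPrimers()].
#' @param ampliconRange length-2 numeric amplicon bounds (bp).
#' @return data.frame with columns `locus_id`, `contig`, `motif`,
#'   `repeats`, `allele_size`, `fwd_seq`, `fwd_tm`, `fwd_gc`, `rev_seq`,
#'   `rev_tm`, `rev_gc`, `amplicon_start`, `amplicon_end`,
#'   `amplicon_length` (plus oligo positions and self-dimer energies);
#'   attribute `no_primer` holds locus ids that failed.
#' @export
designPrimers <- function(candidates, mask = NULL,
                          params = thermoParameters(),
                          ampliconRange = c(90L, 250L), ...) {
  rows <- list()
  failed <- character()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, , drop = FALSE]
    locusId <- sprintf("%s:%d-%d", cand$contig_id, cand$start, cand$end)
    oligos <- enumeratePrimers(cand, mask = mask, params = params, ...)
    best <- selectBestPair(pairPrimers(oligos$forward, oligos$reverse,
                                       ampliconRange = ampliconRange,
                                       params = params))
    if (is.null(best)) {
      failed <- c(failed, locusId)
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(locus_id = locusId, contig = cand$contig_id,
                 motif = cand$motif, repeats = cand$repeats,
                 allele_size = cand$allele_size, stringsAsFactors = FALSE),
      best)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(data.frame(locus_id = character(), contig = character(),
                     motif = character(), repeats = integer(),
                     allele_size = integer(), stringsAsFactors = FALSE),
          pairPrimers(data.frame(), data.frame())[0, ])
  rownames(out) <- NULL
  attr(out, "no_primer") <- failed
  out
}
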