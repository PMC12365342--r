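params <- thermoParameters()

# one design-grade candidate on a certified synthetic contig
makeCandidate <- function(motif = "AGAT", repeats = 12L, contigLen = 11000L,
                          start = 5001L, seed = 31L) {
  spec <- syntheticGenomeSpec(
    lengths = contigLen,
    planted = data.frame(contig_id = "contig1", start = start,
                         motif = motif, repeats = repeats),
    gc = 0.42, seed = seed)
  g <- generateGenome(spec)
  loci <- filterForDesign(scanGenome(g$contigs)$loci)
  list(candidates = extractCandidates(loci, g$contigs), contigs = g$contigs)
}

test_that("candidate extraction enforces contig length and allele cap", {
  ok <- makeCandidate()$candidates
  expect_equal(nrow(ok), 1L)
  expect_equal(ok$allele_size, 48L)
  # same locus on a 9 kb contig is dropped
  short <- makeCandidate(contigLen = 9000L)$candidates
  expect_equal(nrow(short), 0L)
  # a 155 bp pentanucleotide allele exceeds the 150 bp cap
  long <- makeCandidate(motif = "AGGAT", repeats = 31L, seed = 33L)$candidates
  expect_equal(nrow(long), 0L)
  # flanks are long enough to host any legal amplicon
  expect_gte(nchar(ok$flank_left), 250L - ok$allele_size)
})

test_that("candidate extraction rejects loci on unknown contigs", {
  mc <- makeCandidate()
  loci <- mc$candidates[, c("contig_id", "start", "end", "motif",
                            "motif_length", "repeats", "tract_length")]
  loci$contig_id <- "elsewhere"
  expect_error(extractCandidates(loci, mc$contigs), "unknown contig")
})

test_that("deduplication removes exact and reverse-complement window duplicates", {
  mc <- makeCandidate()$candidates
  dup <- rbind(mc, mc)
  dup$contig_id[2] <- "contigX"
  expect_equal(nrow(dedupeCandidates(dup)), 1L)
  rcdup <- rbind(mc, mc)
  rcdup$window_seq[2] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(mc$window_seq)))
  expect_equal(nrow(dedupeCandidates(rcdup)), 1L)
  distinct <- rbind(mc, makeCandidate(seed = 35L)$candidates)
  expect_equal(nrow(dedupeCandidates(distinct)), 2L)
})

test_that("motif exclusions catch adenine runs (including junctions) and AT-only motifs", {
  aaa <- makeCandidate(motif = "AAAT", seed = 37L)$candidates
  expect_equal(nrow(applyExclusions(aaa)), 0L)
  # ATAA has no AAA inside one copy, but ATAA|ATAA spans an AAA junction
  junction <- makeCandidate(motif = "ATCG", seed = 38L)$candidates
  junction$motif <- "ATAA"
  junction$window_seq <- paste0(
    substr(junction$window_seq, 1L, junction$start - junction$window_start),
    strrep("ATAA", junction$repeats),
    substr(junction$window_seq,
           junction$end - junction$window_start + 2L,
           nchar(junction$window_seq)))
  expect_equal(nrow(applyExclusions(junction)), 0L)
  atOnly <- makeCandidate(motif = "ATTA", seed = 39L)$candidates
  expect_equal(nrow(applyExclusions(atOnly)), 0L)
  kept <- makeCandidate(motif = "AGAT", seed = 40L)$candidates
  expect_equal(nrow(applyExclusions(kept)), 1L)
  # complement-strand adenine check is off by default, available by flag
  ttt <- makeCandidate(motif = "AGAT", seed = 41L)$candidates
  ttt$window_seq <- sub(strrep("AGAT", 12), strrep("GTTT", 12),
                        ttt$window_seq, fixed = TRUE)
  expect_equal(nrow(applyExclusions(ttt)), 1L)
  expect_equal(nrow(applyExclusions(ttt, checkComplementTTT = TRUE)), 0L)
})

test_that("every enumerated oligo independently satisfies every constraint", {
  mc <- makeCandidate()
  cand <- mc$candidates
  oligos <- enumeratePrimers(cand, params = params)
  expect_gt(nrow(oligos$forward), 0L)
  expect_gt(nrow(oligos$reverse), 0L)
  pick <- function(n) {
    if (n <= 25L) seq_len(n) else unique(round(seq(1L, n, length.out = 25L)))
  }
  for (i in pick(nrow(oligos$forward))) {
    expect_true(auditOligo(oligos$forward[i, ], cand, TRUE, params))
  }
  for (i in pick(nrow(oligos$reverse))) {
    expect_true(auditOligo(oligos$reverse[i, ], cand, FALSE, params))
  }
})

test_that("masking removes overlapping oligos; full mask empties the flank", {
  mc <- makeCandidate()
  cand <- mc$candidates
  free <- enumeratePrimers(cand, params = params)
  fullMask <- GenomicRanges::GRanges(
    cand$contig_id, IRanges::IRanges(cand$window_start, cand$window_end))
  masked <- enumeratePrimers(cand, mask = fullMask, params = params)
  expect_equal(nrow(masked$forward), 0L)
  expect_equal(nrow(masked$reverse), 0L)
  # partial mask: no surviving oligo overlaps it
  partial <- GenomicRanges::GRanges(
    cand$contig_id,
    IRanges::IRanges(free$forward$start[1L], free$forward$end[1L]))
  part <- enumeratePrimers(cand, mask = partial, params = params)
  expect_lt(nrow(part$forward), nrow(free$forward))
  bad <- .maskedInterval(cand$contig_id, part$forward$start,
                         part$forward$end, partial)
  expect_false(any(bad))
})

test_that("widening the Tm window never removes a previously returned oligo", {
  cand <- makeCandidate()$candidates
  narrow <- enumeratePrimers(cand, params = params, tmRange = c(50, 58))
  wide <- enumeratePrimers(cand, params = params, tmRange = c(48, 62))
  expect_true(all(narrow$forward$sequence %in% wide$forward$sequence))
  expect_true(all(narrow$reverse$sequence %in% wide$reverse$sequence))
})

test_that("pairing respects amplicon bounds, arithmetic and deterministic ranking", {
  mc <- makeCandidate()
  cand <- mc$candidates
  oligos <- enumeratePrimers(cand, params = params)
  pairs <- pairPrimers(oligos$forward, oligos$reverse, params = params)
  expect_gt(nrow(pairs), 0L)
  expect_true(all(pairs$amplicon_length >= 90L & pairs$amplicon_length <= 250L))
  expect_true(all(diff(pairs$pair_penalty) >= 0))
  # amplicon arithmetic against the extracted sequence
  contigSeq <- as.character(mc$contigs[[cand$contig_id]])
  for (i in head(seq_len(nrow(pairs)), 5L)) {
    amplicon <- substr(contigSeq, pairs$amplicon_start[i], pairs$amplicon_end[i])
    expect_equal(nchar(amplicon), pairs$amplicon_length[i])
    expect_true(startsWith(amplicon, pairs$fwd_seq[i]))
    expect_true(endsWith(amplicon, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(pairs$rev_seq[i])))))
    # the amplicon spans the whole repeat tract
    expect_lte(pairs$amplicon_start[i], cand$start - 1L)
    expect_gte(pairs$amplicon_end[i], cand$end + 1L)
  }
  # impossible bounds produce no pair
  none <- pairPrimers(oligos$forward, oligos$reverse,
                      ampliconRange = c(5L, 10L), params = params)
  expect_equal(nrow(none), 0L)
  # re-ranking is reproducible
  pairs2 <- pairPrimers(oligos$forward, oligos$reverse, params = params)
  expect_identical(pairs, pairs2)
})

test_that("best-pair selection takes the ranking head or reports nothing", {
  oligos <- enumeratePrimers(makeCandidate()$candidates, params = params)
  pairs <- pairPrimers(oligos$forward, oligos$reverse, params = params)
  expect_identical(selectBestPair(pairs), pairs[1L, ])
  expect_null(selectBestPair(pairs[0L, ]))
  expect_null(selectBestPair(NULL))
  single <- pairs[3L, , drop = FALSE]
  rownames(single) <- NULL
  expect_identical(selectBestPair(single)$fwd_seq, single$fwd_seq)
})

test_that("full primer design emits one audited pair per designable locus", {
  spec <- syntheticGenomeSpec(
    lengths = c(11000, 11000),
    planted = data.frame(contig_id = c("contig1", "contig2"),
                         start = c(5001, 5001),
                         motif = c("AGAT", "AGGAT"),
                         repeats = c(12, 10)),
    gc = 0.42, seed = 51)
  g <- generateGenome(spec)
  loci <- filterForDesign(scanGenome(g$contigs)$loci)
  cands <- applyExclusions(dedupeCandidates(extractCandidates(loci, g$contigs)))
  primers <- designPrimers(cands, params = params)
  expect_equal(nrow(primers) + length(attr(primers, "no_primer")), nrow(cands))
  expect_true(all(primers$amplicon_length >= 90L &
                    primers$amplicon_length <= 250L))
  expect_true(all(table(primers$locus_id) == 1L))
})
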