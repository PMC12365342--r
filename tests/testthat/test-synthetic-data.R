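test_that("genome spec validation rejects bad plants and names overlapping pairs", {
  expect_error(syntheticGenomeSpec(0), ">= 1")
  expect_error(syntheticGenomeSpec(100, gc = 1.5), "gc")
  expect_error(
    syntheticGenomeSpec(100, planted = data.frame(
      contig_id = "contig1", start = 90, motif = "AGAT", repeats = 5)),
    "does not fit")
  expect_error(
    syntheticGenomeSpec(100, planted = data.frame(
      contig_id = "contig1", start = 10, motif = "ATAT", repeats = 3)),
    "shortest period")
  expect_error(
    syntheticGenomeSpec(500, planted = data.frame(
      contig_id = c("contig1", "contig1"), start = c(101, 120),
      motif = c("AGAT", "AGGC"), repeats = c(6, 6))),
    "overlap.*\\[101-124\\].*\\[120-143\\]")
})

test_that("planted tracts appear verbatim and flanks carry no accidental SSR", {
  spec <- syntheticGenomeSpec(
    lengths = 10500,
    planted = data.frame(contig_id = "contig1", start = 5001,
                         motif = "AGAT", repeats = 12),
    seed = 61)
  g <- generateGenome(spec)
  expect_identical(substr(as.character(g$contigs[[1L]]), 5001, 5048),
                   strrep("AGAT", 12))
  found <- scanContig(as.character(g$contigs[[1L]]), "contig1")
  expect_equal(nrow(found), 1L)
  # zero plants: the scanner finds nothing anywhere
  empty <- generateGenome(syntheticGenomeSpec(c(3000, 3000), seed = 62))
  expect_equal(attr(scanGenome(empty$contigs)$summary, "total"), 0L)
})

test_that("genome generation is byte-deterministic for a fixed spec and seed", {
  spec <- syntheticGenomeSpec(
    lengths = c(2000, 1500),
    planted = data.frame(contig_id = "contig1", start = 501,
                         motif = "AAG", repeats = 6),
    seed = 63)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  writeFasta(generateGenome(spec)$contigs, f1)
  writeFasta(generateGenome(spec)$contigs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and independent of the caller's RNG state
  set.seed(999); g1 <- generateGenome(spec)
  set.seed(123); g2 <- generateGenome(spec)
  expect_identical(as.character(g1$contigs), as.character(g2$contigs))
})

test_that("below-threshold plants are tolerated and reported only in the registry", {
  spec <- syntheticGenomeSpec(
    lengths = 3000,
    planted = data.frame(contig_id = c("contig1", "contig1"),
                         start = c(501, 1501),
                         motif = c("AGAT", "AGAT"),
                         repeats = c(12, 2)),
    seed = 64)
  g <- generateGenome(spec)
  expect_equal(nrow(g$registry), 2L)
  found <- scanContig(as.character(g$contigs[[1L]]), "contig1")
  expect_equal(found$start, 501L)
})

test_that("alignment spec validation and zero-rate degenerate case", {
  expect_error(syntheticAlignmentSpec(1, 100), "at least 2")
  expect_error(syntheticAlignmentSpec(4, 100, backgroundRate = 0.5,
                                      hotspotRate = 0.1), ">=")
  expect_error(syntheticAlignmentSpec(4, 100, hotspot = c(50, 150),
                                      hotspotRate = 0.2), "within")
  aln <- generateAlignment(syntheticAlignmentSpec(5, 400, seed = 65))
  expect_equal(length(unique(as.character(aln))), 1L)
  prof <- slidingPi(as.character(aln))
  expect_true(all(windows(prof)$pi == 0))
})

test_that("alignment substitutions are gap-free, seed-stable and hotspot-enriched", {
  spec <- syntheticAlignmentSpec(8, 600, backgroundRate = 0.02,
                                 hotspot = c(201, 300), hotspotRate = 0.25,
                                 seed = 66)
  aln <- as.character(generateAlignment(spec))
  expect_false(any(grepl("[^ACGT]", aln)))
  expect_identical(aln, as.character(generateAlignment(spec)))
  ref <- strsplit(aln[[1L]], "")[[1L]]
  inHot <- outHot <- 0L
  for (i in 2:8) {
    s <- strsplit(aln[[i]], "")[[1L]]
    d <- which(s != ref)
    inHot <- inHot + sum(d >= 201 & d <= 300)
    outHot <- outHot + sum(d < 201 | d > 300)
  }
  # 100 hotspot sites at 0.25 vs 500 background sites at 0.02
  expect_gt(inHot / 100, outHot / 500)
})

test_that("per-site substitution counts follow the binomial model (chi-squared)", {
  n <- 20L
  rate <- 0.1
  spec <- syntheticAlignmentSpec(n, 2000, backgroundRate = rate, seed = 67)
  aln <- as.character(generateAlignment(spec))
  mat <- do.call(rbind, strsplit(aln, ""))
  hits <- colSums(mat[-1L, , drop = FALSE] !=
                    matrix(mat[1L, ], n - 1L, 2000L, byrow = TRUE))
  # number of mutated sequences per site ~ Binomial(n-1, rate)
  breaks <- 0:5
  obs <- c(vapply(breaks, function(k) sum(hits == k), integer(1L)),
           sum(hits > 5))
  prob <- c(stats::dbinom(breaks, n - 1L, rate),
            stats::pbinom(5, n - 1L, rate, lower.tail = FALSE))
  chi <- stats::chisq.test(obs, p = prob)
  expect_gt(chi$p.value, 1e-3)
})

test_that("two-sequence single-difference alignment gives pi = 0.01", {
  spec <- syntheticAlignmentSpec(2, 100, seed = 68)
  aln <- as.character(generateAlignment(spec))
  chars <- strsplit(aln[[2L]], "")[[1L]]
  chars[37] <- setdiff(c("A", "C", "G", "T"), chars[37])[1L]
  aln[2L] <- paste(chars, collapse = "")
  expect_identical(pairwisePi(aln), 0.01)
})

test_that("conflict panels honor Tm windows, engineered edges and cleanliness", {
  params <- thermoParameters()
  pan <- generatePrimerPanel(5, conflictEdges = list(c(1, 2), c(4, 5)),
                             seed = 69, params = params)
  expect_equal(nrow(pan), 5L)
  expect_true(all(nchar(pan$sequence) >= 17L & nchar(pan$sequence) <= 24L))
  expect_true(all(pan$tm >= 48 & pan$tm <= 62))
  expect_lt(crossDimerEnergy(pan$sequence[1], pan$sequence[2], params), -5)
  expect_lt(crossDimerEnergy(pan$sequence[4], pan$sequence[5], params), -5)
  # every non-edge pair is free of complementary stretches >= 4 bp
  for (i in 1:4) {
    for (j in (i + 1):5) {
      if ((i == 1 && j == 2) || (i == 4 && j == 5)) next
      run <- SSRseqDesign:::.complementaryRun(
        strsplit(pan$sequence[i], "")[[1L]],
        strsplit(pan$sequence[j], "")[[1L]], 4L)
      expect_null(run)
    }
  }
})

test_that("degenerate and unconstructible panel requests are handled", {
  solo <- generatePrimerPanel(1, seed = 70)
  expect_equal(nrow(solo), 1L)
  part <- partitionMultiplex(
    SSRseqDesign:::.annotatePanel(panelFromOligos(solo), thermoParameters()),
    data.frame(a = character(), b = character(), reason = character(),
               value = numeric()))
  expect_equal(part$set_id, 1L)
  expect_error(generatePrimerPanel(2, conflictEdges = list(c(1, 5))),
               "within 1..n")
  expect_error(generatePrimerPanel(6, conflictEdges = list(c(1, 2), c(1, 3),
                                                           c(1, 4), c(5, 6))),
               "unconstructible")
})
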