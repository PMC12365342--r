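params <- thermoParameters()

# purine-only oligos cannot base-pair with one another, so panels built
# from them have no dimer conflicts; Tm columns are supplied directly
# where a test needs exact melting temperatures.
purinePanel <- function(n, tms) {
  withr::with_seed(7, {
    panel <- asPanel(data.frame(
      id = sprintf("P%02d", seq_len(n)),
      fwd_seq = vapply(seq_len(n), function(i)
        paste(sample(c("A", "G"), 20, replace = TRUE), collapse = ""),
        character(1L)),
      rev_seq = vapply(seq_len(n), function(i)
        paste(sample(c("A", "G"), 20, replace = TRUE), collapse = ""),
        character(1L))))
  })
  panel$fwd_tm <- tms
  panel$rev_tm <- tms
  panel$fwd_self_dimer <- 0
  panel$rev_self_dimer <- 0
  panel
}

test_that("prefilter applies strict self-dimer and Tm-floor rules with reasons", {
  panel <- purinePanel(4, c(55, 55, 55, 55))
  panel$fwd_self_dimer <- c(-6.5, 0, 0, -2)
  panel$rev_tm <- c(55, 47.9, 48.0, 55)
  res <- prefilterPanel(panel, selfDimerCut = -6, tmFloor = 48, params)
  expect_setequal(res$excluded$id, c("P01", "P02"))
  expect_equal(res$excluded$reason[res$excluded$id == "P01"], "self_dimer")
  expect_equal(res$excluded$reason[res$excluded$id == "P02"], "tm_floor")
  # Tm of exactly 48.0 is kept: the rule is strictly "lower than"
  expect_true("P03" %in% res$kept$id)
  # an all-passing panel excludes nothing
  clean <- prefilterPanel(purinePanel(3, c(55, 55, 55)), params = params)
  expect_equal(nrow(clean$excluded), 0L)
})

test_that("prefilter excludes an entry whose computed self-dimer is strongly negative", {
  panel <- asPanel(data.frame(
    id = c("bad", "good"),
    fwd_seq = c("ACGTGGGGGGCCCCCCAGA", "AGAGGAAGAGGGAGAGGAAG"),
    rev_seq = c("AGAGGAAGAGGGAGAGGAAG", "AGGAGAAGGGAGAGGAAGAG")))
  res <- prefilterPanel(panel, params = params)
  expect_true("bad" %in% res$excluded$id)
  expect_match(res$excluded$reason[res$excluded$id == "bad"], "self_dimer")
})

test_that("conflict graph flags engineered cross-dimers and Tm gaps, never self-edges", {
  pan <- generatePrimerPanel(3, conflictEdges = list(c(1, 2)), seed = 13,
                             params = params)
  edges <- buildConflictGraph(panelFromOligos(pan), params = params)
  expect_true(any(edges$a == "oligo01" & edges$b == "oligo02" &
                    edges$reason == "cross_dimer"))
  expect_false(any(edges$a == edges$b))
  # oracle agreement on the engineered stretch
  expect_lt(crossDimerEnergy(pan$sequence[1], pan$sequence[2], params), -5)
  expect_lt(oracleDimer(pan$sequence[1], pan$sequence[2]), -5)

  gap <- purinePanel(2, c(50, 58))
  gap$rev_tm <- c(51, 59)
  e2 <- buildConflictGraph(gap, params = params)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$reason, "tm_gap")
  expect_equal(e2$value, 9)

  # a duplicated entry's twin conflicts with it only via real edges,
  # and an entry never conflicts with itself
  solo <- purinePanel(1, 55)
  expect_equal(nrow(buildConflictGraph(solo, params = params)), 0L)
})

test_that("greedy partitioning matches known chromatic structure", {
  # empty conflict graph, 10 vertices, cap 12: one set
  free <- purinePanel(10, rep(55, 10))
  e0 <- buildConflictGraph(free, params = params)
  expect_equal(nrow(e0), 0L)
  p0 <- partitionMultiplex(free, e0)
  expect_equal(max(p0$set_id), 1L)
  # triangle: 3 sets (= brute-force chromatic number of K3)
  tri <- purinePanel(3, rep(55, 3))
  eTri <- data.frame(a = c("P01", "P01", "P02"), b = c("P02", "P03", "P03"),
                     reason = "cross_dimer", value = -6)
  expect_equal(oracleChromatic(3, list(c(1, 2), c(1, 3), c(2, 3))), 3L)
  pTri <- partitionMultiplex(tri, eTri)
  expect_equal(max(pTri$set_id), 3L)
  # 13 mutually compatible entries under a cap of 12: sets of 12 and 1
  big <- purinePanel(13, rep(55, 13))
  pBig <- partitionMultiplex(big, big0 <- e0[0, ], maxSetSize = 12L)
  expect_equal(sort(as.integer(table(pBig$set_id)), decreasing = TRUE),
               c(12L, 1L))
  expect_error(partitionMultiplex(free, e0, maxSetSize = 0L), "at least 1")
})

test_that("partitioning also honors the whole-set Tm span", {
  # pairwise gaps below the window can still exceed it set-wide
  panel <- purinePanel(3, c(50, 53, 56))
  panel$rev_tm <- panel$fwd_tm
  edges <- data.frame(a = character(), b = character(),
                      reason = character(), value = numeric())
  part <- partitionMultiplex(panel, edges, tmWindow = 5)
  audit <- validatePanel(part, panel, edges, tmWindow = 5)
  expect_true(attr(audit, "all_pass"))
  expect_gt(max(part$set_id), 1L)
})

test_that("partition output is independent of input record order", {
  withr::with_seed(19, {
    panel <- purinePanel(8, runif(8, 53, 57))
    edges <- data.frame(a = c("P01", "P03"), b = c("P05", "P07"),
                        reason = "cross_dimer", value = -6)
    direct <- partitionMultiplex(panel, edges)
    shuffled <- panel[sample(nrow(panel)), , drop = FALSE]
    again <- partitionMultiplex(shuffled, edges)
    expect_identical(direct[order(direct$id), ]$set_id,
                     again[order(again$id), ]$set_id)
  })
})

test_that("the auditor passes partitioner output and flags hand-built violations", {
  tri <- purinePanel(3, rep(55, 3))
  eTri <- data.frame(a = c("P01", "P01", "P02"), b = c("P02", "P03", "P03"),
                     reason = "cross_dimer", value = -6)
  good <- validatePanel(partitionMultiplex(tri, eTri), tri, eTri)
  expect_true(attr(good, "all_pass"))
  forced <- data.frame(id = tri$id, set_id = c(1L, 1L, 2L))
  bad <- validatePanel(forced, tri, eTri)
  expect_false(attr(bad, "all_pass"))
  expect_false(bad$pass[bad$set_id == 1L])
  empty <- validatePanel(data.frame(id = character(), set_id = integer()),
                         tri, eTri)
  expect_true(attr(empty, "all_pass"))
})

test_that("auditor passes over randomized conflict graphs (property)", {
  withr::with_seed(23, {
    for (rep in 1:25) {
      n <- sample(3:9, 1)
      panel <- purinePanel(n, runif(n, 50, 60))
      pairs <- utils::combn(n, 2L)
      pick <- which(runif(ncol(pairs)) < 0.3)
      edges <- data.frame(
        a = sprintf("P%02d", pairs[1L, pick]),
        b = sprintf("P%02d", pairs[2L, pick]),
        reason = rep("cross_dimer", length(pick)),
        value = rep(-6, length(pick)), stringsAsFactors = FALSE)
      part <- partitionMultiplex(panel, edges,
                                 maxSetSize = sample(2:12, 1))
      audit <- validatePanel(part, panel, edges, maxSetSize = 12L)
      expect_true(all(audit$internal_conflicts == 0L))
    }
  })
})

test_that("greedy coloring is near-optimal on small random graphs", {
  withr::with_seed(29, {
    for (rep in 1:15) {
      n <- sample(4:9, 1)
      panel <- purinePanel(n, rep(55, n))
      pairs <- utils::combn(n, 2L)
      pick <- runif(ncol(pairs)) < 0.35
      edgeList <- lapply(which(pick), function(k) pairs[, k])
      edges <- data.frame(
        a = sprintf("P%02d", vapply(edgeList, `[`, integer(1L), 1L)),
        b = sprintf("P%02d", vapply(edgeList, `[`, integer(1L), 2L)),
        reason = "cross_dimer", value = -6, stringsAsFactors = FALSE)
      if (nrow(edges) == 0L) next
      part <- partitionMultiplex(panel, edges, maxSetSize = n, tmWindow = 5)
      expect_lte(max(part$set_id), oracleChromatic(n, edgeList) + 1L)
    }
  })
})

test_that("end-to-end multiplex design returns a coherent audited object", {
  pan <- generatePrimerPanel(6, conflictEdges = list(c(1, 2), c(3, 4)),
                             seed = 31, params = params)
  mp <- designMultiplex(panelFromOligos(pan), params = params)
  expect_s4_class(mp, "MultiplexPanel")
  expect_true(all(panelTable(mp)$set_id >= 1L))
  expect_gte(max(panelTable(mp)$set_id), 2L)
  sets <- multiplexSets(mp)
  expect_true(all(sets$tm_span <= 5))
  rep <- panelReport(mp, params)
  expect_equal(length(rep$sets), nrow(sets))
  expect_true(all(vapply(rep$sets, function(s) s$worst_cross_dimer, 0) >= -5))
  expect_output(show(mp), "MultiplexPanel")
})
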