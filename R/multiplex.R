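#' Build a multiplex panel table from a primer table
#'
#' Converts [designPrimers()] output (or an external-primer table with
#' columns `id`, `kind`, `fwd_seq`, `rev_seq` and optionally
#' `amplicon_length`) into the panel schema used by multiplex design.
#' External mtDNA-barcode and sex-determination primers enter the same
#' panel with no special treatment.
#'
#' @param primers primer table (`locus_id`/`id`, `fwd_seq`, `rev_seq`,
#'   optional `amplicon_length`).
#' @param kind entry kind recorded when the table has no `kind` column
#'   (one of `"SSR"`, `"mtDNA"`, `"sex"`).
#' @return data.frame with columns `id`, `kind`, `fwd_seq`, `rev_seq`,
#'   `amplicon_length`.
#' @export
asPanel <- function(primers, kind = "SSR") {
  id <- if ("id" %in% names(primers)) primers$id else primers$locus_id
  if (is.null(id)) stop("primer table needs an id or locus_id column")
  if (anyDuplicated(id)) stop("panel ids must be unique")
  data.frame(
    id = as.character(id),
    kind = if ("kind" %in% names(primers)) primers$kind
           else rep(kind, length(id)),
    fwd_seq = primers$fwd_seq,
    rev_seq = primers$rev_seq,
    amplicon_length = if ("amplicon_length" %in% names(primers))
      primers$amplicon_length else rep(NA_integer_, length(id)),
    stringsAsFactors = FALSE)
}

# Ensure per-oligo Tm and self-dimer columns are present.
.annotatePanel <- function(panel, params) {
  if (nrow(panel) == 0L) {
    for (col in c("fwd_tm", "rev_tm", "fwd_self_dimer", "rev_self_dimer")) {
      if (is.null(panel[[col]])) panel[[col]] <- numeric(0L)
    }
    return(panel)
  }
  if (is.null(panel$fwd_tm)) panel$fwd_tm <- meltingTemperature(panel$fwd_seq, params)
  if (is.null(panel$rev_tm)) panel$rev_tm <- meltingTemperature(panel$rev_seq, params)
  if (is.null(panel$fwd_self_dimer)) {
    panel$fwd_self_dimer <- selfDimerEnergy(panel$fwd_seq, params)
  }
  if (is.null(panel$rev_self_dimer)) {
    panel$rev_self_dimer <- selfDimerEnergy(panel$rev_seq, params)
  }
  panel
}

#' Prefilter a primer panel on self-dimer energy and melting temperature
#'
#' Excludes a panel entry when either of its oligos has a self-dimer
#' energy strictly below `selfDimerCut` or a melting temperature
#' strictly below `tmFloor` (both thresholds are strict inequalities).
#' Exclusion reasons are recorded per entry.
#'
#' @param panel panel data.frame (see [asPanel()]).
#' @param selfDimerCut self-dimer energy cut, kcal/mol.
#' @param tmFloor minimum melting temperature, Celsius.
#' @param params [ThermoParameters-class].
#' @return list with `kept` (annotated panel) and `excluded` (entries
#'   with a `reason` column: `self_dimer`, `tm_floor`, or both).
#' @export
prefilterPanel <- function(panel, selfDimerCut = -6, tmFloor = 48,
                           params = thermoParameters()) {
  panel <- .annotatePanel(panel, params)
  if (nrow(panel) == 0L) {
    return(list(kept = panel, excluded = cbind(panel, reason = character(0L))))
  }
  badDimer <- panel$fwd_self_dimer < selfDimerCut |
    panel$rev_self_dimer < selfDimerCut
  badTm <- panel$fwd_tm < tmFloor | panel$rev_tm < tmFloor
  reason <- ifelse(badDimer & badTm, "self_dimer;tm_floor",
                   ifelse(badDimer, "self_dimer",
                          ifelse(badTm, "tm_floor", "")))
  excluded <- panel[badDimer | badTm, , drop = FALSE]
  excluded$reason <- reason[badDimer | badTm]
  kept <- panel[!(badDimer | badTm), , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Build the pairwise primer-incompatibility graph
#'
#' Two panel entries conflict (cannot share a multiplex reaction) when
#' the most negative cross-dimer energy over the four oligo pairings
#' (fwd-fwd, fwd-rev, rev-fwd, rev-rev) is strictly below `crossCut`, or
#' when the melting-temperature gap between any oligo of one entry and
#' any oligo of the other exceeds `tmWindow`. Each edge is annotated
#' with the triggering value.
#'
#' @param panel prefiltered, annotated panel data.frame.
#' @param crossCut cross-dimer energy cut, kcal/mol.
#' @param tmWindow maximum tolerated Tm difference, Celsius.
#' @param params [ThermoParameters-class].
#' @return data.frame of undirected edges: `a`, `b` (ids, a < b),
#'   `reason` (`cross_dimer` or `tm_gap`), `value`.
#' @export
buildConflictGraph <- function(panel, crossCut = -5, tmWindow = 5,
                               params = thermoParameters()) {
  panel <- .annotatePanel(panel, params)
  edges <- data.frame(a = character(), b = character(),
                      reason = character(), value = numeric(),
                      stringsAsFactors = FALSE)
  n <- nrow(panel)
  if (n < 2L) return(edges)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      oi <- c(panel$fwd_seq[i], panel$rev_seq[i])
      oj <- c(panel$fwd_seq[j], panel$rev_seq[j])
      cross <- min(vapply(oi, function(x) {
        vapply(oj, function(y) crossDimerEnergy(x, y, params), numeric(1L))
      }, numeric(2L)))
      tmGap <- max(abs(outer(c(panel$fwd_tm[i], panel$rev_tm[i]),
                             c(panel$fwd_tm[j], panel$rev_tm[j]), "-")))
      if (cross < crossCut) {
        edges[nrow(edges) + 1L, ] <- list(panel$id[i], panel$id[j],
                                          "cross_dimer", cross)
      } else if (tmGap > tmWindow) {
        edges[nrow(edges) + 1L, ] <- list(panel$id[i], panel$id[j],
                                          "tm_gap", tmGap)
      }
    }
  }
  edges
}

# Per-entry vector of oligo Tms, as a list keyed by id.
.entryTms <- function(panel) {
  tms <- Map(c, panel$fwd_tm, panel$rev_tm)
  names(tms) <- panel$id
  tms
}

#' Partition a primer panel into compatible multiplex sets
#'
#' Deterministic greedy graph coloring: entries are processed by
#' conflict degree (descending, ties by id), and each is placed into the
#' lowest-numbered set where (i) it has no conflict edge to a member,
#' (ii) the set stays within `maxSetSize`, and (iii) the set's overall
#' melting-temperature span (max oligo Tm minus min oligo Tm, over all
#' members) stays within `tmWindow`. The whole-set span re-check is
#' needed because pairwise Tm edges alone cannot bound the span. An
#' entry incompatible with every open set opens a new one, so
#' partitioning never fails.
#'
#' @param panel annotated panel data.frame.
#' @param edges conflict-edge data.frame from [buildConflictGraph()].
#' @param maxSetSize maximum number of primer pairs per multiplex
#'   reaction (must be >= 1).
#' @param tmWindow maximum within-set Tm span, Celsius.
#' @return data.frame `id`, `kind`, `set_id` (sets numbered from 1), in
#'   input panel order.
#' @export
partitionMultiplex <- function(panel, edges, maxSetSize = 12L, tmWindow = 5) {
  if (maxSetSize < 1L) stop("maxSetSize must be at least 1")
  ids <- sort(panel$id)   # id-sorted base order: input order never matters
  if (length(ids) == 0L) {
    return(data.frame(id = character(), kind = character(),
                      set_id = integer(), stringsAsFactors = FALSE))
  }
  deg <- structure(integer(length(ids)), names = ids)
  for (k in seq_len(nrow(edges))) {
    deg[[edges$a[k]]] <- deg[[edges$a[k]]] + 1L
    deg[[edges$b[k]]] <- deg[[edges$b[k]]] + 1L
  }
  visitOrder <- ids[order(-deg, ids)]
  conflictsOf <- function(id) {
    c(edges$b[edges$a == id], edges$a[edges$b == id])
  }
  tms <- .entryTms(panel)
  sets <- list()
  setOf <- structure(integer(length(ids)), names = ids)
  for (id in visitOrder) {
    foes <- conflictsOf(id)
    placed <- FALSE
    for (s in seq_along(sets)) {
      members <- sets[[s]]
      if (length(members) >= maxSetSize) next
      if (any(members %in% foes)) next
      span <- diff(range(unlist(tms[c(members, id)])))
      if (span > tmWindow) next
      sets[[s]] <- c(members, id)
      setOf[[id]] <- s
      placed <- TRUE
      break
    }
    if (!placed) {
      sets[[length(sets) + 1L]] <- id
      setOf[[id]] <- length(sets)
    }
  }
  data.frame(id = panel$id, kind = panel$kind,
             set_id = as.integer(setOf[panel$id]),
             stringsAsFactors = FALSE)
}

#' Independently audit a multiplex partition
#'
#' Re-checks every multiplex-set invariant from scratch, without reusing
#' any state from the partitioner: within-set Tm span at most
#' `tmWindow`, no conflict edge between two members of a set, and set
#' size at most `maxSetSize`.
#'
#' @param assignment data.frame `id`, `set_id` from
#'   [partitionMultiplex()] (or hand-built).
#' @param panel annotated panel data.frame.
#' @param edges conflict-edge data.frame.
#' @param maxSetSize,tmWindow the constraints to audit against.
#' @return data.frame per set: `set_id`, `size`, `tm_span`,
#'   `internal_conflicts`, `pass`; attribute `all_pass` is the overall
#'   verdict.
#' @export
validatePanel <- function(assignment, panel, edges, maxSetSize = 12L,
                          tmWindow = 5) {
  tms <- .entryTms(panel)
  setIds <- sort(unique(assignment$set_id))
  out <- data.frame(set_id = integer(), size = integer(), tm_span = numeric(),
                    internal_conflicts = integer(), pass = logical())
  for (s in setIds) {
    members <- assignment$id[assignment$set_id == s]
    span <- if (length(members)) diff(range(unlist(tms[members]))) else 0
    internal <- 0L
    if (nrow(edges) > 0L) {
      internal <- sum(edges$a %in% members & edges$b %in% members)
    }
    out[nrow(out) + 1L, ] <- list(
      s, length(members), span, internal,
      length(members) <= maxSetSize & span <= tmWindow & internal == 0L)
  }
  attr(out, "all_pass") <- all(out$pass)
  out
}

#' Design multiplex PCR sets for a primer panel
#'
#' End-to-end multiplex design: annotate oligo thermodynamics, apply the
#' self-dimer/Tm prefilter, build the conflict graph, partition into
#' sets, and audit the result. Returns a [MultiplexPanel-class] object.
#'
#' @param panel panel data.frame (see [asPanel()]); SSR, mtDNA and sex
#'   primer entries are treated identically.
#' @param params [ThermoParameters-class].
#' @param crossDimerCut,selfDimerCut dimer energy cuts, kcal/mol
#'   (strict `<`).
#' @param tmFloor minimum oligo melting temperature, Celsius (strict `<`
#'   excludes).
#' @param tmWindow maximum within-set Tm span, Celsius.
#' @param maxSetSize maximum primer pairs per multiplex set.
#' @return a [MultiplexPanel-class]; the audit must pass (an internal
#'   error is raised otherwise).
#' @examples
#' pan <- asPanel(data.frame(
#'   id = c("L1", "L2"),
#'   fwd_seq = c("AGCGTCTGAGACCTGGATCC", "TGGCAGGAGGACTTGGCATA"),
#'   rev_seq = c("CCATGGTGGCTTGGTCTGAG", "AGGATGCCGTGGAAGGTTGA")))
#' designMultiplex(pan)
#' @export
designMultiplex <- function(panel, params = thermoParameters(),
                            crossDimerCut = -5, selfDimerCut = -6,
                            tmFloor = 48, tmWindow = 5, maxSetSize = 12L) {
  pre <- prefilterPanel(panel, selfDimerCut, tmFloor, params)
  edges <- buildConflictGraph(pre$kept, crossDimerCut, tmWindow, params)
  assignment <- partitionMultiplex(pre$kept, edges, maxSetSize, tmWindow)
  audit <- validatePanel(assignment, pre$kept, edges, maxSetSize, tmWindow)
  if (!attr(audit, "all_pass")) {
    stop("internal error: multiplex partition failed its own audit")
  }
  kept <- pre$kept
  kept$set_id <- assignment$set_id[match(kept$id, assignment$id)]
  sets <- audit[, c("set_id", "size", "tm_span")]
  new("MultiplexPanel", panel = kept, excluded = pre$excluded,
      conflicts = edges, sets = sets,
      parameters = list(crossDimerCut = crossDimerCut,
                        selfDimerCut = selfDimerCut, tmFloor = tmFloor,
                        tmWindow = tmWindow, maxSetSize = maxSetSize))
}

setMethod("show", "MultiplexPanel", function(object) {
  cat("MultiplexPanel:", nrow(object@panel), "entries in",
      nrow(object@sets), "multiplex set(s);",
      nrow(object@excluded), "excluded by prefilter;",
      nrow(object@conflicts), "conflict edge(s)\n")
  if (nrow(object@sets) > 0L) {
    for (i in seq_len(nrow(object@sets))) {
      cat(sprintf("  set %d: %d pair(s), Tm span %.2f C\n",
                  object@sets$set_id[i], object@sets$size[i],
                  object@sets$tm_span[i]))
    }
  }
})

#' @rdname MultiplexPanel-class
#' @export
setMethod("multiplexSets", "MultiplexPanel", function(x) x@sets)

#' @rdname MultiplexPanel-class
#' @export
setMethod("panelTable", "MultiplexPanel", function(x) x@panel)

#' @rdname MultiplexPanel-class
#' @export
setMethod("conflictEdges", "MultiplexPanel", function(x) x@conflicts)

#' @rdname MultiplexPanel-class
#' @export
setMethod("excludedEntries", "MultiplexPanel", function(x) x@excluded)

#' JSON-ready report for a multiplex panel
#'
#' Per-set members, Tm span, and the worst internal cross-dimer energy,
#' plus prefilter exclusions with reasons. Write with
#' [writeJSONReport()].
#'
#' @param x a [MultiplexPanel-class].
#' @param params [ThermoParameters-class] used to recompute within-set
#'   worst cross-dimer energies.
#' @return a list.
#' @export
panelReport <- function(x, params = thermoParameters()) {
  panel <- panelTable(x)
  sets <- multiplexSets(x)
  perSet <- lapply(seq_len(nrow(sets)), function(i) {
    s <- sets$set_id[i]
    members <- panel$id[panel$set_id == s]
    sub <- panel[panel$set_id == s, , drop = FALSE]
    # worst dimer between different entries (a pair's own fwd x rev
    # necessarily co-occur and are not part of the compatibility rule)
    worst <- 0
    if (nrow(sub) > 1L) {
      for (a in seq_len(nrow(sub) - 1L)) {
        for (b in (a + 1L):nrow(sub)) {
          for (x in c(sub$fwd_seq[a], sub$rev_seq[a])) {
            for (y in c(sub$fwd_seq[b], sub$rev_seq[b])) {
              worst <- min(worst, crossDimerEnergy(x, y, params))
            }
          }
        }
      }
    }
    list(set_id = s, members = members, size = sets$size[i],
         tm_span = sets$tm_span[i], worst_cross_dimer = worst)
  })
  list(sets = perSet,
       excluded = lapply(seq_len(nrow(excludedEntries(x))), function(i) {
         e <- excludedEntries(x)[i, ]
         list(id = e$id, reason = e$reason)
       }),
       parameters = x@parameters)
}
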