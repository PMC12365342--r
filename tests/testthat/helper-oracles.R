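# Independent oracles used to cross-check the package implementation.
# Each one is written with different machinery from the code path it
# audits, and kept deliberately simple.

randomDNA <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Smallest cyclic rotation by explicit enumeration.
oracleCanonical <- function(motif) {
  n <- nchar(motif)
  doubled <- paste0(motif, motif)
  min(vapply(seq_len(n), function(k) substr(doubled, k, k + n - 1L),
             character(1L)))
}

oraclePrimitive <- function(unit) {
  n <- nchar(unit)
  for (d in seq_len(max(n - 1L, 0L))) {
    if (n %% d == 0L && strrep(substr(unit, 1L, d), n %/% d) == unit) {
      return(FALSE)
    }
  }
  TRUE
}

# Brute-force SSR enumerator: tests every (start, motif length) and
# extends copy by copy. A start qualifies only if it is the leftmost
# base of its periodic region (the position one base left does not
# continue the period), the unit is primitive and pure ACGT, and the
# whole-copy count meets the threshold.
oracleScan <- function(seq, thresholds = scanThresholds()) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  out <- list()
  for (m in 1:6) {
    thr <- thresholds[[as.character(m)]]
    if (L < 2L * m) next
    starts <- seq_len(L - 2L * m + 1L)
    units <- substring(seq, starts, starts + m - 1L)
    nextBlock <- substring(seq, starts + m, starts + 2L * m - 1L)
    unitOK <- !grepl("[^ACGT]", units)
    leftMax <- starts == 1L |
      !(valid[pmax(starts - 1L, 1L)] & valid[pmax(starts - 1L, 1L) + m] &
          chars[pmax(starts - 1L, 1L)] == chars[pmax(starts - 1L, 1L) + m])
    cand <- which(unitOK & leftMax & units == nextBlock)
    for (a in cand) {
      unit <- units[a]
      if (!oraclePrimitive(unit)) next
      k <- 2L
      repeat {
        from <- a + k * m
        if (from + m - 1L > L) break
        if (substr(seq, from, from + m - 1L) != unit) break
        k <- k + 1L
      }
      if (k >= thr) {
        out[[length(out) + 1L]] <- data.frame(
          start = a, end = a + k * m - 1L, motif = oracleCanonical(unit),
          motif_length = m, repeats = k, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), motif_length = integer(),
                      repeats = integer(), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, out)
  tab[order(tab$start, tab$motif_length), , drop = FALSE]
}

lociKey <- function(tab) {
  sort(sprintf("%d:%d:%s:%d", tab$start, tab$end, tab$motif, tab$repeats))
}

# Brute-force nucleotide diversity: explicit loop over sequence pairs
# and over every column, counting per-pair differences and valid sites
# one character at a time.
oraclePi <- function(rows, cols = NULL) {
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  if (is.null(cols)) cols <- seq_len(ncol(mat))
  n <- nrow(mat)
  acgt <- c("A", "C", "G", "T")
  vals <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- 0L; v <- 0L
      for (c in cols) {
        a <- mat[i, c]; b <- mat[j, c]
        if (a %in% acgt && b %in% acgt) {
          v <- v + 1L
          if (a != b) d <- d + 1L
        }
      }
      if (v > 0L) vals <- c(vals, d / v)
    }
  }
  if (length(vals) == 0L) 0 else mean(vals)
}

# Brute-force dimer oracle: every offset of a against reversed b, every
# contiguous sub-run of aligned complementary positions, energy summed
# stack by stack from the packaged parameter file.
oracleDimer <- function(a, b, minStretch = 3L, tempC = 37) {
  tab <- read.delim(system.file("extdata", "nn_santalucia1998.tsv",
                                package = "SSRseqDesign"))
  TK <- tempC + 273.15
  dg <- structure(tab$dH - TK * tab$dS / 1000, names = tab$stack)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rcKey <- function(d) {
    paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
  }
  stackDG <- function(d) if (d %in% names(dg)) dg[[d]] else dg[[rcKey(d)]]
  initDG <- function(base) {
    if (base %in% c("G", "C")) dg[["init_GC"]] else dg[["init_AT"]]
  }
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  rb <- rev(cb)
  best <- 0
  for (off in (-(length(cb) - 1L)):(length(ca) - 1L)) {
    lo <- max(1L, 1L + off); hi <- min(length(ca), length(cb) + off)
    if (lo > hi) next
    for (s in lo:hi) {
      for (e in s:hi) {
        ok <- TRUE
        for (p in s:e) {
          if (comp[[ca[p]]] != rb[p - off]) { ok <- FALSE; break }
        }
        if (!ok) break  # runs must be contiguous from s
        if (e - s + 1L >= minStretch) {
          en <- initDG(ca[s]) + initDG(ca[e])
          if (e > s) {
            for (p in s:(e - 1L)) en <- en + stackDG(paste0(ca[p], ca[p + 1L]))
          }
          best <- min(best, en)
        }
      }
    }
  }
  best
}

# Exact chromatic number by exhaustive assignment (graphs of <= 10
# vertices). Edges are 1-based index pairs.
oracleChromatic <- function(n, edges) {
  if (n == 0L) return(0L)
  conflict <- matrix(FALSE, n, n)
  for (e in edges) {
    conflict[e[1L], e[2L]] <- TRUE
    conflict[e[2L], e[1L]] <- TRUE
  }
  feasible <- function(k) {
    colors <- integer(n)
    rec <- function(v) {
      if (v > n) return(TRUE)
      for (c in seq_len(k)) {
        if (!any(conflict[v, seq_len(v - 1L)] &
                 colors[seq_len(v - 1L)] == c)) {
          colors[v] <<- c
          if (rec(v + 1L)) return(TRUE)
        }
      }
      colors[v] <<- 0L
      FALSE
    }
    rec(1L)
  }
  for (k in seq_len(n)) if (feasible(k)) return(k)
  n
}

# Re-validate a primer oligo against every design constraint from
# scratch (independent auditor used by the primer-design tests).
auditOligo <- function(oligo, candidate, forward, params,
                       primerLen = c(17L, 24L), tmRange = c(48, 62),
                       gcRange = c(0.35, 0.50), minDistance = 20L,
                       maxMonoRun = 4L, mask = NULL) {
  len <- nchar(oligo$sequence)
  contigSeq <- candidate$window_seq
  off <- candidate$window_start - 1L
  slice <- substr(contigSeq, oligo$start - off, oligo$end - off)
  onContig <- if (forward) oligo$sequence else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(oligo$sequence)))
  dist <- if (forward) candidate$start - oligo$end - 1L
          else oligo$start - candidate$end - 1L
  masked <- FALSE
  if (!is.null(mask) && length(mask) > 0L) {
    q <- GenomicRanges::GRanges(candidate$contig_id,
                                IRanges::IRanges(oligo$start, oligo$end))
    masked <- IRanges::overlapsAny(q, mask)
  }
  all(
    len >= primerLen[1L], len <= primerLen[2L],
    oligo$end - oligo$start + 1L == len,
    identical(onContig, slice),
    !grepl("(A{5}|C{5}|G{5}|T{5})", oligo$sequence),
    gcContent(oligo$sequence) >= gcRange[1L],
    gcContent(oligo$sequence) <= gcRange[2L],
    meltingTemperature(oligo$sequence, params) >= tmRange[1L],
    meltingTemperature(oligo$sequence, params) <= tmRange[2L],
    dist >= minDistance,
    !masked
  )
}
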