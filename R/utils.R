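#' @import methods
#' @importFrom stats median runif
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
.isScalarInt <- function(x) .isScalarNumber(x) && x == as.integer(x)
.isScalarString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Character-vector view of a sequence; accepts character scalar,
# DNAString or any object with a sensible as.character method.
.seqChars <- function(seq) {
  s <- toupper(as.character(seq))
  if (length(s) != 1L) stop("expected a single sequence")
  strsplit(s, "", fixed = TRUE)[[1L]]
}

.checkACGT <- function(seq, what = "sequence") {
  chars <- .seqChars(seq)
  if (length(chars) == 0L) stop(what, " is empty")
  bad <- setdiff(unique(chars), DNA_BASES)
  if (length(bad) > 0L) {
    stop(what, " contains non-ACGT characters: ", paste(bad, collapse = ", "))
  }
  chars
}

.revcomp <- function(seq) {
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1L), USE.NAMES = FALSE)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
# All generator randomness flows through this; nothing touches the global
# stream.
withSeed <- function(seed, code) {
  if (!.isScalarInt(seed)) stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Atomic write: emit to a temp file in the same directory, then rename,
# so partial runs never leave truncated tables.
atomicWrite <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".part")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file onto ", path)
  invisible(path)
}

# Longest run of a single repeated base in a primer sequence.
.maxMonoRun <- function(chars) {
  if (length(chars) == 0L) return(0L)
  max(rle(chars)$lengths)
}

# Is `s` a power of a strictly shorter string? (non-primitive repeat unit)
.isPowerOfShorter <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(FALSE)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L && strrep(substr(s, 1L, d), n %/% d) == s) return(TRUE)
  }
  FALSE
}
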