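#' Read genome contigs from FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet` that uppercases
#' sequences, truncates ids at the first whitespace, and validates
#' uniqueness. Malformed records are rejected with the reader's record
#' context.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @return a `DNAStringSet` with unique names.
#' @export
readContigs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  names(set) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(set))) {
    stop("duplicate contig ids in ", path, ": ",
         paste(unique(names(set)[duplicated(names(set))]), collapse = ", "))
  }
  Biostrings::DNAStringSet(toupper(set))
}

#' Write sequences to FASTA
#'
#' Atomic write (temp file then rename), 70-column wrapping, stable
#' record order — identical input always yields byte-identical output.
#'
#' @param seqs `DNAStringSet` or named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  atomicWrite(path, function(tmp) {
    Biostrings::writeXStringSet(seqs, tmp, width = 70L)
  })
}

#' Write / read an SSR locus table as TSV
#'
#' Columns: `contig_id`, `start`, `end`, `motif`, `motif_length`,
#' `repeats`, `tract_length`; coordinates 1-based inclusive.
#'
#' @param loci `GRanges` from [scanGenome()] or a data.frame in the same
#'   schema.
#' @param path TSV path.
#' @return `writeSSRTable`: the path, invisibly. `readSSRTable`: a
#'   data.frame.
#' @export
writeSSRTable <- function(loci, path) {
  tab <- .lociAsTable(loci)
  atomicWrite(path, function(tmp) {
    write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' @rdname writeSSRTable
#' @export
readSSRTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig_id", "start", "end", "motif", "motif_length",
            "repeats", "tract_length")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("SSR table ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  tab
}

.lociAsTable <- function(loci) {
  if (is.data.frame(loci)) return(loci)
  data.frame(contig_id = as.character(GenomicRanges::seqnames(loci)),
             start = GenomicRanges::start(loci),
             end = GenomicRanges::end(loci),
             motif = S4Vectors::mcols(loci)$motif,
             motif_length = S4Vectors::mcols(loci)$motif_length,
             repeats = S4Vectors::mcols(loci)$repeats,
             tract_length = S4Vectors::mcols(loci)$tract_length,
             stringsAsFactors = FALSE)
}

.lociAsGRanges <- function(loci) {
  if (methods::is(loci, "GRanges")) return(loci)
  GenomicRanges::GRanges(
    seqnames = loci$contig_id,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    motif = loci$motif, motif_length = loci$motif_length,
    repeats = loci$repeats, tract_length = loci$tract_length)
}

#' Export SSR loci as GFF3
#'
#' Feature type `microsatellite`, 1-based inclusive coordinates per the
#' GFF3 standard; motif and repeat count carried as attributes.
#'
#' @param loci `GRanges` or SSR table data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSSRGFF3 <- function(loci, path) {
  gr <- .lociAsGRanges(loci)
  gr$type <- "microsatellite"
  atomicWrite(path, function(tmp) {
    rtracklayer::export(gr, tmp, format = "gff3")
  })
}

#' Read repeat-mask intervals from BED
#'
#' BED is 0-based half-open; `rtracklayer` converts to the 1-based
#' inclusive `GRanges` convention used throughout this package.
#'
#' @param path BED file of masked (repeat / transposable-element)
#'   intervals.
#' @return a `GRanges` of masked intervals.
#' @export
readMaskBED <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  rtracklayer::import(path, format = "bed")
}

#' Write hotspot (or any) intervals as BED
#'
#' @param gr a `GRanges` (1-based inclusive); written 0-based half-open
#'   per the BED standard.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBED <- function(gr, path) {
  atomicWrite(path, function(tmp) {
    rtracklayer::export(gr, tmp, format = "bed")
  })
}

#' Write a generic table as TSV (atomic)
#'
#' @param tab data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTSV <- function(tab, path) {
  atomicWrite(path, function(tmp) {
    write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Write a list as JSON (atomic)
#'
#' @param x list or other jsonlite-serializable object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeJSONReport <- function(x, path) {
  atomicWrite(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
}
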