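#' Pipeline configuration
#'
#' Collects every tunable threshold of the marker-design and diversity
#' workflows in one validated, flat list. Defaults are the package's
#' study conditions: SSR characterization thresholds of 10/5/4/3/3/3
#' repeats for mono- through hexanucleotide motifs; design restricted to
#' tetra-/pentanucleotide loci with at least 12/10 repeats on contigs
#' longer than 10 kb, alleles at most 150 bp and amplicons of 90-250 bp;
#' primers of 17-24 bp with Tm 48-62 C, GC 35-50% and at least 20 bp of
#' clearance from the repeat tract; multiplexing with self-dimer cut
#' -6 kcal/mol, cross-dimer cut -5 kcal/mol, Tm floor 48 C, Tm window
#' 5 C and at most 12 pairs per set; diversity profiling with 100 bp
#' windows, 25 bp steps, a 2x-median hotspot threshold and a 199 bp
#' barcode amplicon target.
#'
#' @param ... overrides for any default (names as in the returned list).
#' @return a named list with class `pipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(max_set_size = 10)
#' cfg$max_set_size
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    mono = 10L, di = 5L, tri = 4L, tetra = 3L, penta = 3L, hexa = 3L,
    design_tetra_min = 12L, design_penta_min = 10L,
    min_contig = 10000L, allele_max = 150L,
    amplicon_min = 90L, amplicon_max = 250L,
    primer_min = 17L, primer_max = 24L,
    tm_min = 48, tm_max = 62, gc_min = 0.35, gc_max = 0.50,
    flank_distance = 20L, max_mono_run = 4L,
    self_dimer_cut = -6, cross_dimer_cut = -5,
    tm_floor = 48, tm_window = 5, max_set_size = 12L,
    pi_window = 100L, pi_step = 25L, hotspot_factor = 2,
    amplicon_target = 199L, amplicon_tolerance = 10L,
    salt_mM = 50, oligo_nM = 250, dimer_min_stretch = 3L,
    dg_temperature_C = 37)
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(override)] <- override
  ranges <- list(c("primer_min", "primer_max"), c("tm_min", "tm_max"),
                 c("gc_min", "gc_max"), c("amplicon_min", "amplicon_max"))
  for (r in ranges) {
    if (cfg[[r[1L]]] > cfg[[r[2L]]]) {
      stop("empty range: ", r[1L], " > ", r[2L])
    }
  }
  structure(cfg, class = "pipelineConfig")
}

.configThermo <- function(cfg) {
  thermoParameters(saltMilliM = cfg$salt_mM, oligoNanoM = cfg$oligo_nM,
                   dimerMinStretch = cfg$dimer_min_stretch,
                   dgTemperatureC = cfg$dg_temperature_C)
}

.manifest <- function(config, stages, inputs = character(), seed = NA) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  list(tool = "SSRseqDesign",
       version = as.character(utils::packageVersion("SSRseqDesign")),
       seed = seed,
       config = unclass(config),
       input_digests = digests,
       stages = stages)
}

.stageRow <- function(stage, n_in, n_out) {
  data.frame(stage = stage, n_in = n_in, n_out = n_out,
             stringsAsFactors = FALSE)
}

#' Run the full marker-design pipeline
#'
#' Orchestrates scan, design filter, candidate extraction,
#' deduplication, motif exclusions, primer design, panel prefilter,
#' conflict graph and multiplex partitioning over a genome, recording
#' per-stage counts in a run manifest. An empty result at any stage is a
#' valid outcome, not an error. The design cascade is monotone
#' non-increasing by construction, and this is asserted at run time.
#'
#' @param genome `DNAStringSet`, named character vector, or FASTA path.
#' @param config a [pipelineConfig()].
#' @param mask optional repeat-mask intervals: a `GRanges` or a BED path.
#' @param extraPrimers optional externally designed primers to
#'   co-multiplex (for example mtDNA-barcode and sex-determination
#'   pairs): a data.frame or TSV path with columns `id`, `kind`,
#'   `fwd_seq`, `rev_seq`, optional `amplicon_length`.
#' @param outDir optional directory; when given, writes `ssr_loci.tsv`,
#'   `primers.tsv`, `multiplex.tsv`, `panel_report.json` and
#'   `manifest.json` (all writes are atomic).
#' @return list with `loci` (`GRanges`), `candidates`, `primers`
#'   (data.frame), `multiplex` ([MultiplexPanel-class]) and `manifest`.
#' @export
runDesignPipeline <- function(genome, config = pipelineConfig(),
                              mask = NULL, extraPrimers = NULL,
                              outDir = NULL) {
  contigs <- .asContigSet(genome)
  if (is.character(mask) && length(mask) == 1L) mask <- readMaskBED(mask)
  if (is.character(extraPrimers) && length(extraPrimers) == 1L) {
    extraPrimers <- read.delim(extraPrimers, stringsAsFactors = FALSE)
  }
  params <- .configThermo(config)
  thresholds <- scanThresholds(config$mono, config$di, config$tri,
                               config$tetra, config$penta, config$hexa)

  scan <- scanGenome(contigs, thresholds)
  designGrade <- filterForDesign(
    scan$loci, motifLengths = c(4L, 5L),
    minRepeats = c(`4` = config$design_tetra_min,
                   `5` = config$design_penta_min))
  candidates <- extractCandidates(designGrade, contigs,
                                  minContig = config$min_contig,
                                  alleleCap = config$allele_max,
                                  maxAmplicon = config$amplicon_max)
  unique_ <- dedupeCandidates(candidates)
  kept <- applyExclusions(unique_)
  primers <- designPrimers(
    kept, mask = mask, params = params,
    ampliconRange = c(config$amplicon_min, config$amplicon_max),
    primerLen = c(config$primer_min, config$primer_max),
    tmRange = c(config$tm_min, config$tm_max),
    gcRange = c(config$gc_min, config$gc_max),
    minDistance = config$flank_distance,
    maxMonoRun = config$max_mono_run)
  panel <- asPanel(primers, kind = "SSR")
  if (!is.null(extraPrimers) && nrow(extraPrimers) > 0L) {
    panel <- rbind(panel, asPanel(extraPrimers))
  }
  multiplex <- designMultiplex(panel, params = params,
                               crossDimerCut = config$cross_dimer_cut,
                               selfDimerCut = config$self_dimer_cut,
                               tmFloor = config$tm_floor,
                               tmWindow = config$tm_window,
                               maxSetSize = config$max_set_size)

  stages <- rbind(
    .stageRow("scan", length(contigs), length(scan$loci)),
    .stageRow("design_filter", length(scan$loci), length(designGrade)),
    .stageRow("extract_candidates", length(designGrade), nrow(candidates)),
    .stageRow("dedupe", nrow(candidates), nrow(unique_)),
    .stageRow("exclusions", nrow(unique_), nrow(kept)),
    .stageRow("primer_design", nrow(kept), nrow(primers)),
    .stageRow("panel_prefilter", nrow(panel),
              nrow(panelTable(multiplex))),
    .stageRow("multiplex", nrow(panelTable(multiplex)),
              nrow(panelTable(multiplex))))
  cascade <- stages$n_out[2:6]
  if (any(diff(cascade) > 0L)) {
    stop("internal error: design cascade counts increased at a stage")
  }
  manifest <- .manifest(config, stages,
                        inputs = if (is.character(genome)) genome else character())
  if (!is.null(outDir)) {
    writeSSRTable(scan$loci, file.path(outDir, "ssr_loci.tsv"))
    writeTSV(primers, file.path(outDir, "primers.tsv"))
    writeTSV(panelTable(multiplex)[, c("id", "kind", "set_id")],
             file.path(outDir, "multiplex.tsv"))
    writeJSONReport(panelReport(multiplex, params),
                    file.path(outDir, "panel_report.json"))
    manifest$stages <- stages
    writeJSONReport(manifest, file.path(outDir, "manifest.json"))
  }
  list(loci = scan$loci, summary = scan$summary, candidates = kept,
       primers = primers, multiplex = multiplex, manifest = manifest)
}

#' Run the diversity / barcode-selection pipeline
#'
#' Sliding-window nucleotide diversity over a pre-aligned FASTA,
#' hotspot calling, selection of the most diverse short amplicon, and
#' (optionally) diagnostic fixed-difference sites between two labeled
#' groups.
#'
#' @param alignment aligned sequences: `DNAStringSet`, named character
#'   vector, character matrix, or FASTA path (gaps as `-`).
#' @param config a [pipelineConfig()].
#' @param groupLabels optional two-group labels (one per sequence) for
#'   [speciesDiagnosticSites()].
#' @param outDir optional directory; writes `diversity_windows.tsv`,
#'   `hotspots.bed`, `amplicon.json` and `manifest.json`.
#' @return list with `profile` ([DiversityProfile-class]), `amplicon`,
#'   `diagnosticSites` (or `NULL`) and `manifest`.
#' @export
runDiversityPipeline <- function(alignment, config = pipelineConfig(),
                                 groupLabels = NULL, outDir = NULL) {
  src <- if (is.character(alignment) && length(alignment) == 1L &&
             file.exists(alignment)) alignment else character()
  if (length(src)) alignment <- readContigs(src)
  mat <- .asAlignmentMatrix(alignment)
  profile <- slidingPi(mat, window = config$pi_window,
                       step = config$pi_step,
                       hotspotFactor = config$hotspot_factor)
  amplicon <- selectAmplicon(mat, targetLength = config$amplicon_target,
                             lengthTolerance = config$amplicon_tolerance)
  diagnostic <- NULL
  if (!is.null(groupLabels)) {
    diagnostic <- speciesDiagnosticSites(mat, groupLabels)
  }
  stages <- rbind(
    .stageRow("sliding_pi", ncol(mat), nrow(windows(profile))),
    .stageRow("hotspots", nrow(windows(profile)), length(hotspots(profile))),
    .stageRow("amplicon", length(hotspots(profile)),
              if (is.null(amplicon)) 0L else 1L))
  manifest <- .manifest(config, stages, inputs = src)
  if (!is.null(outDir)) {
    writeDiversityTSV(profile, file.path(outDir, "diversity_windows.tsv"))
    writeHotspotsBED(profile, file.path(outDir, "hotspots.bed"))
    writeJSONReport(
      if (is.null(amplicon)) list(found = FALSE)
      else c(list(found = TRUE), amplicon),
      file.path(outDir, "amplicon.json"))
    writeJSONReport(manifest, file.path(outDir, "manifest.json"))
  }
  list(profile = profile, amplicon = amplicon,
       diagnosticSites = diagnostic, manifest = manifest)
}
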