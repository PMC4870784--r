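#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand mcols mcols<- findOverlaps countOverlaps reduce distance
#'   granges sort.GenomicRanges
#' @importFrom IRanges IRanges ranges overlapsAny pintersect subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame Rle
NULL

# ---------------------------------------------------------------------------
# GenomeAnnotation
# ---------------------------------------------------------------------------

#' Container for a (real or simulated) genome annotation
#'
#' Holds everything the analyses need to know about the genome: chromosome
#' lengths, gene bodies with their exons, pseudogenes, CpG islands, repeats
#' (with a repeat-class label) and strain-informative SNPs. All interval slots
#' use 1-based closed [GenomicRanges::GRanges] coordinates internally; BED
#' input/output converts at the boundary (see [readBed()]).
#'
#' @slot chromLengths named numeric, chromosome lengths in bp.
#' @slot genes `GRanges` with `mcols` column `gene_id`.
#' @slot exons `GRangesList` keyed by `gene_id`; exons nest inside their gene.
#' @slot pseudogenes `GRanges`.
#' @slot cgis `GRanges` of CpG islands.
#' @slot repeats `GRanges` with `mcols` column `repClass`, one of
#'   LTR, LINE, SINE, DNA, Simple, Other.
#' @slot snps width-1 `GRanges` (1-based positions) with `mcols` columns
#'   `ref`, `alt` (allele labels) and `strain` (origin of the alt allele).
#'
#' @seealso [simulateAnnotation()]
#' @export
setClass("GenomeAnnotation", slots = c(
  chromLengths = "numeric",
  genes = "GRanges",
  exons = "GRangesList",
  pseudogenes = "GRanges",
  cgis = "GRanges",
  repeats = "GRanges",
  snps = "GRanges"
))

.repClasses <- c("LTR", "LINE", "SINE", "DNA", "Simple", "Other")

.checkWithin <- function(gr, lens, what) {
  if (length(gr) == 0L) return(NULL)
  chr <- as.character(seqnames(gr))
  if (!all(chr %in% names(lens))) {
    return(sprintf("%s on chromosome(s) absent from chromLengths", what))
  }
  if (any(start(gr) < 1L) || any(end(gr) > lens[chr])) {
    return(sprintf("%s intervals exceed chromosome bounds", what))
  }
  NULL
}

setValidity("GenomeAnnotation", function(object) {
  msgs <- character()
  lens <- object@chromLengths
  if (is.null(names(lens)) || any(!nzchar(names(lens))) || any(lens <= 0)) {
    msgs <- c(msgs, "chromLengths must be named and positive")
  }
  for (w in c("genes", "pseudogenes", "cgis", "repeats", "snps")) {
    m <- .checkWithin(slot(object, w), lens, w)
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  if (length(object@genes) && is.null(object@genes$gene_id)) {
    msgs <- c(msgs, "genes must carry a gene_id metadata column")
  }
  if (length(object@repeats) &&
      (is.null(object@repeats$repClass) ||
       !all(object@repeats$repClass %in% .repClasses))) {
    msgs <- c(msgs, sprintf("repeats$repClass must be one of: %s",
                            paste(.repClasses, collapse = ", ")))
  }
  if (length(object@snps)) {
    if (any(width(object@snps) != 1L)) msgs <- c(msgs, "snps must have width 1")
    key <- paste(as.character(seqnames(object@snps)), start(object@snps))
    if (anyDuplicated(key)) msgs <- c(msgs, "SNP positions must be unique per chromosome")
  }
  if (length(object@exons)) {
    ug <- unlist(object@exons, use.names = FALSE)
    gid <- rep(names(object@exons), lengths(object@exons))
    gmap <- setNames(seq_along(object@genes), object@genes$gene_id)
    if (!all(gid %in% names(gmap))) {
      msgs <- c(msgs, "exon list names must match gene ids")
    } else {
      par <- object@genes[gmap[gid]]
      if (any(as.character(seqnames(ug)) != as.character(seqnames(par))) ||
          any(start(ug) < start(par)) || any(end(ug) > end(par))) {
        msgs <- c(msgs, "exons must nest within their gene")
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn GenomeAnnotation chromosome length lookup
#' @param object,x a `GenomeAnnotation`
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))
#' @export
setMethod("chromLengths", "GenomeAnnotation", function(x) x@chromLengths)

#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @export
setMethod("geneRanges", "GenomeAnnotation", function(x) x@genes)

#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @export
setMethod("exonRanges", "GenomeAnnotation", function(x) x@exons)

#' @export
setGeneric("pseudogeneRanges", function(x) standardGeneric("pseudogeneRanges"))
#' @export
setMethod("pseudogeneRanges", "GenomeAnnotation", function(x) x@pseudogenes)

#' @export
setGeneric("cgiRanges", function(x) standardGeneric("cgiRanges"))
#' @export
setMethod("cgiRanges", "GenomeAnnotation", function(x) x@cgis)

#' @export
setGeneric("repeatRanges", function(x) standardGeneric("repeatRanges"))
#' @export
setMethod("repeatRanges", "GenomeAnnotation", function(x) x@repeats)

#' @export
setGeneric("snpRanges", function(x) standardGeneric("snpRanges"))
#' @export
setMethod("snpRanges", "GenomeAnnotation", function(x) x@snps)

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation with", length(object@chromLengths), "chromosome(s),",
      sum(object@chromLengths) / 1e6, "Mb total\n")
  cat("  genes:", length(object@genes),
      " pseudogenes:", length(object@pseudogenes),
      " CGIs:", length(object@cgis),
      " repeats:", length(object@repeats),
      " SNPs:", length(object@snps), "\n")
})

# ---------------------------------------------------------------------------
# BinnedTrack
# ---------------------------------------------------------------------------

#' Fixed-width windowed quantitation along chromosomes
#'
#' A `BinnedTrack` stores per-window values (read counts or normalized
#' quantities) on a regular grid: windows of `windowWidth` bp advancing by
#' `stepWidth` bp from position 0 of each chromosome (sliding when
#' `stepWidth < windowWidth`). Values live in the `score` metadata column of
#' the window ranges.
#'
#' @slot bins `GRanges` of windows with numeric `score`.
#' @slot windowWidth window width in bp.
#' @slot stepWidth step in bp, at most `windowWidth`.
#' @slot normalization one of `raw`, `library`, `match`, `h3_subtracted`.
#' @export
setClass("BinnedTrack", slots = c(
  bins = "GRanges",
  windowWidth = "numeric",
  stepWidth = "numeric",
  normalization = "character"
))

setValidity("BinnedTrack", function(object) {
  msgs <- character()
  if (length(object@windowWidth) != 1L || object@windowWidth <= 0) {
    msgs <- c(msgs, "windowWidth must be a positive scalar")
  }
  if (length(object@stepWidth) != 1L || object@stepWidth <= 0 ||
      object@stepWidth > object@windowWidth) {
    msgs <- c(msgs, "stepWidth must be in (0, windowWidth]")
  }
  if (!object@normalization %in% c("raw", "library", "match", "h3_subtracted")) {
    msgs <- c(msgs, "normalization must be raw/library/match/h3_subtracted")
  }
  if (length(object@bins) && is.null(object@bins$score)) {
    msgs <- c(msgs, "bins must carry a numeric score column")
  }
  if (length(object@bins)) {
    off <- (start(object@bins) - 1L) %% object@stepWidth
    if (any(off != 0L)) msgs <- c(msgs, "windows must start on the step grid (offset 0)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a BinnedTrack
#' @param bins `GRanges` with `score`
#' @param windowWidth,stepWidth window geometry in bp
#' @param normalization provenance tag of the values
#' @return a [BinnedTrack-class] object
#' @export
BinnedTrack <- function(bins, windowWidth, stepWidth = windowWidth,
                        normalization = "raw") {
  new("BinnedTrack", bins = bins, windowWidth = windowWidth,
      stepWidth = stepWidth, normalization = normalization)
}

#' @export
setGeneric("trackBins", function(x) standardGeneric("trackBins"))
#' @export
setMethod("trackBins", "BinnedTrack", function(x) x@bins)

#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @export
setMethod("trackValues", "BinnedTrack", function(x) x@bins$score)

#' @export
setGeneric("windowWidth", function(x) standardGeneric("windowWidth"))
#' @export
setMethod("windowWidth", "BinnedTrack", function(x) x@windowWidth)

#' @export
setGeneric("stepWidth", function(x) standardGeneric("stepWidth"))
#' @export
setMethod("stepWidth", "BinnedTrack", function(x) x@stepWidth)

#' @export
setGeneric("normalization", function(x) standardGeneric("normalization"))
#' @export
setMethod("normalization", "BinnedTrack", function(x) x@normalization)

setMethod("show", "BinnedTrack", function(object) {
  cat(sprintf("BinnedTrack: %d windows of %g bp (step %g bp), normalization=%s\n",
              length(object@bins), object@windowWidth, object@stepWidth,
              object@normalization))
})

# ---------------------------------------------------------------------------
# PeakSet
# ---------------------------------------------------------------------------

#' A set of called peaks for one mark and sample group
#'
#' Peaks are sorted, non-overlapping intervals; `score` holds the peak's
#' \eqn{-\log_{10} p} (the maximum over its constituent significant windows).
#'
#' @slot peaks `GRanges` with numeric `score`.
#' @slot mark assay/mark name (e.g. "H3K27me3").
#' @slot sampleGroup free-text group label (e.g. "female").
#' @export
setClass("PeakSet", slots = c(
  peaks = "GRanges",
  mark = "character",
  sampleGroup = "character"
))

setValidity("PeakSet", function(object) {
  msgs <- character()
  gr <- object@peaks
  if (length(gr) > 1L) {
    bychr <- split(gr, as.character(seqnames(gr)))
    for (g in bychr) {
      if (length(g) > 1L) {
        o <- order(start(g))
        if (any(start(g)[o][-1L] <= end(g)[o][-length(g)])) {
          msgs <- c(msgs, "peaks must be non-overlapping within a set")
          break
        }
      }
    }
  }
  if (length(gr) && is.null(gr$score)) msgs <- c(msgs, "peaks must carry a score column")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PeakSet
#' @param peaks `GRanges` with `score` (-log10 p)
#' @param mark,sampleGroup labels
#' @export
PeakSet <- function(peaks, mark = "mark", sampleGroup = "all") {
  peaks <- peaks[order(as.character(seqnames(peaks)), start(peaks))]
  new("PeakSet", peaks = peaks, mark = mark, sampleGroup = sampleGroup)
}

#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))
#' @export
setMethod("peakRanges", "PeakSet", function(x) x@peaks)

#' @export
setGeneric("peakMark", function(x) standardGeneric("peakMark"))
#' @export
setMethod("peakMark", "PeakSet", function(x) x@mark)

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet (%s, %s): %d peaks, %g kb total\n", object@mark,
              object@sampleGroup, length(object@peaks),
              sum(width(object@peaks)) / 1e3))
})

setMethod("length", "PeakSet", function(x) length(x@peaks))

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' Planted truth accompanying simulated data
#'
#' Every simulator returns, next to its data, the entities it planted effects
#' into, so downstream stages have parameter-recovery oracles.
#'
#' @slot reactivatingGenes gene ids planted to escape silencing under knockdown.
#' @slot enrichedRegions `GRangesList` of planted enriched regions per mark.
#' @slot demethylatedCgis `GRanges` of CGIs planted to lose methylation.
#' @slot screenHits hairpin ids planted as enriched in the sorted population.
#' @slot ifPeakPositions per-cell list of per-channel planted apex indices.
#' @export
setClass("GroundTruth", slots = c(
  reactivatingGenes = "character",
  enrichedRegions = "GRangesList",
  demethylatedCgis = "GRanges",
  screenHits = "character",
  ifPeakPositions = "list"
))

GroundTruth <- function(reactivatingGenes = character(),
                        enrichedRegions = GRangesList(),
                        demethylatedCgis = GRanges(),
                        screenHits = character(),
                        ifPeakPositions = list()) {
  new("GroundTruth", reactivatingGenes = reactivatingGenes,
      enrichedRegions = enrichedRegions, demethylatedCgis = demethylatedCgis,
      screenHits = screenHits, ifPeakPositions = ifPeakPositions)
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:",
      length(object@reactivatingGenes), "reactivating genes;",
      length(object@enrichedRegions), "mark(s) with enriched regions;",
      length(object@demethylatedCgis), "demethylated CGIs;",
      length(object@screenHits), "screen hits;",
      length(object@ifPeakPositions), "IF cells\n")
})
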