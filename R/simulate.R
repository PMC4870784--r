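# synthetic-data generator: every analysis stage gets inputs with planted
# ground truth, so null calibration and parameter recovery are testable
# without any external download.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' desk-scale study conditions used throughout the test-suite: a 10-Mb X plus
#' four 10-Mb autosomes, ~200 X-linked genes in alternating gene-dense /
#' gene-poor 500-kb blocks, an Xi silencing trajectory of 0.5 / 0.3 / 0.1
#' (expected Xi fraction of expression at day 0 / 3 / 5), 15% of genes planted
#' to reactivate at a 3-fold Xi lift under knockdown at day 5, 10-fold
#' chromatin enrichment of H3K27me3 in gene-dense and H3K9me3 in gene-poor
#' blocks with an unenriched H3 control, Xi-hypermethylated CGIs (80% vs 5%
#' mC) with a 20-percentage-point planted loss at 20% of CGIs, a 1000-hairpin
#' screen with 1% hits at 8-fold enrichment, and 100 two-channel
#' immunofluorescence cross-sections with 3 peaks per cell.
#'
#' @slot seed integer master seed; all simulators are deterministic given it.
#' @slot nChromAutosome number of autosomes (each `chromLengthBp` long).
#' @slot chromLengthBp chromosome length in bp.
#' @slot nGenesX,nGenesAutosome genes per chromosome.
#' @slot fracGeneDenseBins fraction of 500-kb blocks that are gene-dense.
#' @slot geneDensityInDenseBlocks fraction of a gene-dense block covered by
#'   gene bodies.
#' @slot snpDensityGenic,snpDensityIntergenic SNPs per kb inside gene bodies /
#'   elsewhere (gene-poor blocks are SNP-poor, mirroring the low informative
#'   SNP density of repeat-rich regions).
#' @slot xiSilencingTrajectory named numeric (day0, day3, day5): expected Xi
#'   fraction of expression at each timepoint.
#' @slot reactivatingGeneFraction fraction of X genes planted as knockdown
#'   reactivators.
#' @slot reactivationEffect multiplicative lift of Xi expression for planted
#'   genes (knockdown samples, day 5 only).
#' @slot marks data.frame(mark, regionClass, fold): chromatin enrichment fold
#'   per mark in its region class ("gene_dense" or "gene_poor").
#' @slot xiChipFold Xi:Xa odds of allele-tagged ChIP reads inside female peaks.
#' @slot meanCoverageRna mean allelic read depth per exonic SNP and sample.
#' @slot meanCoverageChip mean ChIP read-start rate, reads per bp.
#' @slot meanCoverageCpg mean bisulphite coverage per CpG and replicate.
#' @slot dispersion negative-binomial dispersion of sequencing depth.
#' @slot cgiXiMethLevel,cgiXaMethLevel mean %mC of CGI CpGs on Xi / Xa.
#' @slot methLossCgiFraction fraction of X CGIs planted to lose methylation
#'   under knockdown.
#' @slot methLossDelta planted loss in %mC points (uniform across the CGI).
#' @slot screenNHairpins,screenHitFraction,screenHitFold,screenDepth pooled
#'   screen geometry: library size, planted-hit fraction, GFP+ enrichment
#'   fold, reads per sample.
#' @slot ifNCells,ifPeaksPerCell,ifColocProb,ifProfileLength,ifNoiseSd
#'   immunofluorescence profile geometry: cells, planted peaks per cell,
#'   channel co-location probability, observations per cross-section,
#'   additive Gaussian noise sd.
#' @seealso [simulateAnnotation()], [simulateAllelicRnaseq()],
#'   [simulateChip()], [simulateErrbs()], [simulateScreen()],
#'   [simulateIfProfiles()]
#' @export
setClass("SimConfig", slots = c(
  seed = "numeric",
  nChromAutosome = "numeric",
  chromLengthBp = "numeric",
  nGenesX = "numeric",
  nGenesAutosome = "numeric",
  fracGeneDenseBins = "numeric",
  geneDensityInDenseBlocks = "numeric",
  snpDensityGenic = "numeric",
  snpDensityIntergenic = "numeric",
  xiSilencingTrajectory = "numeric",
  reactivatingGeneFraction = "numeric",
  reactivationEffect = "numeric",
  marks = "data.frame",
  xiChipFold = "numeric",
  meanCoverageRna = "numeric",
  meanCoverageChip = "numeric",
  meanCoverageCpg = "numeric",
  dispersion = "numeric",
  cgiXiMethLevel = "numeric",
  cgiXaMethLevel = "numeric",
  methLossCgiFraction = "numeric",
  methLossDelta = "numeric",
  screenNHairpins = "numeric",
  screenHitFraction = "numeric",
  screenHitFold = "numeric",
  screenDepth = "numeric",
  ifNCells = "numeric",
  ifPeaksPerCell = "numeric",
  ifColocProb = "numeric",
  ifProfileLength = "numeric",
  ifNoiseSd = "numeric"
))

setValidity("SimConfig", function(object) {
  msgs <- character()
  fr <- c(fracGeneDenseBins = object@fracGeneDenseBins,
          geneDensityInDenseBlocks = object@geneDensityInDenseBlocks,
          reactivatingGeneFraction = object@reactivatingGeneFraction,
          methLossCgiFraction = object@methLossCgiFraction,
          screenHitFraction = object@screenHitFraction,
          ifColocProb = object@ifColocProb)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad)) msgs <- c(msgs, paste("fractions outside [0,1]:",
                                         paste(bad, collapse = ", ")))
  if (any(object@xiSilencingTrajectory < 0 | object@xiSilencingTrajectory > 1)) {
    msgs <- c(msgs, "xiSilencingTrajectory entries must lie in [0,1]")
  }
  if (is.null(names(object@xiSilencingTrajectory))) {
    msgs <- c(msgs, "xiSilencingTrajectory must be named by timepoint")
  }
  folds <- c(object@reactivationEffect, object@xiChipFold,
             object@screenHitFold, object@marks$fold)
  if (any(folds < 1)) msgs <- c(msgs, "folds must be >= 1")
  cov <- c(object@meanCoverageRna, object@meanCoverageChip, object@meanCoverageCpg)
  if (any(cov <= 0)) msgs <- c(msgs, "coverages must be positive")
  if (!all(c("mark", "regionClass", "fold") %in% names(object@marks))) {
    msgs <- c(msgs, "marks must have columns mark, regionClass, fold")
  } else if (!all(object@marks$regionClass %in% c("gene_dense", "gene_poor"))) {
    msgs <- c(msgs, "marks$regionClass must be gene_dense or gene_poor")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname SimConfig-class
#' @param ... slot overrides, by name (see slots of [SimConfig-class]).
#' @return a validated `SimConfig`
#' @examples
#' cfg <- simConfig(seed = 1, nChromAutosome = 0, nGenesX = 20,
#'                  chromLengthBp = 1e6)
#' @export
simConfig <- function(...) {
  defaults <- list(
    seed = 1,
    nChromAutosome = 4,
    chromLengthBp = 1e7,
    nGenesX = 200,
    nGenesAutosome = 200,
    fracGeneDenseBins = 0.5,
    geneDensityInDenseBlocks = 0.7,
    snpDensityGenic = 4,
    snpDensityIntergenic = 0.4,
    xiSilencingTrajectory = c(day0 = 0.5, day3 = 0.3, day5 = 0.1),
    reactivatingGeneFraction = 0.15,
    reactivationEffect = 3,
    marks = data.frame(mark = c("H3K27me3", "H3K9me3"),
                       regionClass = c("gene_dense", "gene_poor"),
                       fold = c(10, 10)),
    xiChipFold = 2,
    meanCoverageRna = 30,
    meanCoverageChip = 0.1,
    meanCoverageCpg = 50,
    dispersion = 0.2,
    cgiXiMethLevel = 80,
    cgiXaMethLevel = 5,
    methLossCgiFraction = 0.2,
    methLossDelta = 20,
    screenNHairpins = 1000,
    screenHitFraction = 0.01,
    screenHitFold = 8,
    screenDepth = 5e6,
    ifNCells = 100,
    ifPeaksPerCell = 3,
    ifColocProb = 0.5,
    ifProfileLength = 400,
    ifNoiseSd = 0.05
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) {
    stop("unknown SimConfig field(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(ov)] <- ov
  do.call(new, c(list(Class = "SimConfig"), defaults))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig (seed %d): X + %d autosome(s) x %g Mb, %d X genes\n",
    "  Xi trajectory: %s; reactivating %g%% at %gx\n"),
    as.integer(object@seed), object@nChromAutosome, object@chromLengthBp / 1e6,
    object@nGenesX,
    paste(sprintf("%s=%.2f", names(object@xiSilencingTrajectory),
                  object@xiSilencingTrajectory), collapse = " "),
    100 * object@reactivatingGeneFraction, object@reactivationEffect))
})

.blockBp <- 5e5  # width of alternating gene-dense / gene-poor blocks

# ---------------------------------------------------------------------------
# annotation
# ---------------------------------------------------------------------------

#' Simulate a genome annotation with banded gene density
#'
#' Chromosomes are partitioned into 500-kb blocks; a configured fraction are
#' gene-dense (genes side by side with a CpG island at each promoter), the
#' rest gene-poor (pseudogenes and repeats). Strain-informative SNPs are laid
#' down at a higher density inside gene bodies than outside, so gene-poor
#' blocks are SNP-poor, as in repeat-rich chromatin.
#'
#' @param config a [SimConfig-class]
#' @return a [GenomeAnnotation-class]; deterministic given `config@seed`.
#' @export
simulateAnnotation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(.subSeed(config@seed, 1L))
  L <- config@chromLengthBp
  chroms <- c("chrX", if (config@nChromAutosome > 0)
    paste0("chr", seq_len(config@nChromAutosome)))
  lens <- setNames(rep(L, length(chroms)), chroms)

  geneL <- list(); exonL <- list(); pseudoL <- list(); cgiL <- list()
  repL <- list(); snpL <- list(); denseL <- list()

  for (chrom in chroms) {
    nGenes <- if (chrom == "chrX") config@nGenesX else config@nGenesAutosome
    nBlocks <- floor(L / .blockBp)
    if (nBlocks < 2) stop("chromosome too short for block structure")
    nDense <- max(1L, round(config@fracGeneDenseBins * nBlocks))
    if (nGenes > 0 && nDense < 1) stop("chromosome too short for requested genes")
    dense <- sort(sample.int(nBlocks, nDense))
    blockStart <- (dense - 1L) * .blockBp  # 0-based
    denseL[[chrom]] <- GRanges(chrom, IRanges(blockStart + 1L, blockStart + .blockBp))

    # genes: evenly split across dense blocks; bodies cover
    # geneDensityInDenseBlocks of each block
    perBlock <- ceiling(nGenes / nDense)
    gs <- integer(0); ge <- integer(0)
    geneBp <- config@geneDensityInDenseBlocks * .blockBp
    glen <- floor(geneBp / perBlock)
    if (glen < 600) stop("chromosome too short for requested genes")
    gapBp <- floor((.blockBp - perBlock * glen) / (perBlock + 1L))
    for (b in blockStart) {
      off <- b + gapBp
      for (k in seq_len(perBlock)) {
        gs <- c(gs, off + 1L)
        ge <- c(ge, off + glen)
        off <- off + glen + gapBp
      }
    }
    gs <- gs[seq_len(min(length(gs), nGenes))]
    ge <- ge[seq_len(length(gs))]
    ids <- sprintf("%s_g%04d", sub("chr", "", chrom), seq_along(gs))
    genes <- GRanges(chrom, IRanges(gs, ge), strand = rep(c("+", "-"),
                                                          length.out = length(gs)))
    genes$gene_id <- ids

    # 3 exons covering ~20% of the body (introns dominate real genes):
    # one exon at the start, middle and end third
    third <- floor((ge - gs + 1L) / 3)
    exw <- pmax(150L, floor(0.2 * third))
    exn <- GRangesList(lapply(seq_along(gs), function(i) {
      s <- gs[i] + c(0L, third[i], 2L * third[i])
      GRanges(chrom, IRanges(s, s + exw[i] - 1L))
    }))
    names(exn) <- ids

    # CGI at each promoter: first kb of the gene body
    cgis <- GRanges(chrom, IRanges(gs, gs + 999L))

    # gene-poor blocks: pseudogenes + repeats
    poor <- setdiff(seq_len(nBlocks), dense)
    ps <- integer(0); pe <- integer(0); rs <- integer(0); re <- integer(0)
    rc <- character(0)
    for (b in (poor - 1L) * .blockBp) {
      np <- 3L
      s <- b + sort(sample.int(.blockBp - 6000L, np))
      ps <- c(ps, s + 1L); pe <- c(pe, s + sample(2000:5000, np, replace = TRUE))
      nr <- rpois(1L, 20L)
      if (nr > 0) {
        s <- b + sort(sample.int(.blockBp - 7000L, nr))
        w <- sample(300:6000, nr, replace = TRUE)
        rs <- c(rs, s + 1L); re <- c(re, s + w)
        rc <- c(rc, sample(.repClasses, nr, replace = TRUE,
                           prob = c(.25, .3, .2, .1, .1, .05)))
      }
    }
    pseudo <- GRanges(chrom, IRanges(ps, pmin(pe, L)))
    reps <- if (length(rs)) {
      r <- GRanges(chrom, IRanges(rs, pmin(re, L))); r$repClass <- rc; r
    } else {
      r <- GRanges(); r$repClass <- character(0); r
    }

    # SNPs: genic density inside gene bodies, intergenic elsewhere
    genicBp <- sum(width(genes))
    nGenic <- rpois(1L, config@snpDensityGenic / 1000 * genicBp)
    gpos <- integer(0)
    if (nGenic > 0 && genicBp > 0) {
      offs <- sort(sample.int(genicBp, min(nGenic, genicBp)))  # 1-based genic offsets
      cw <- cumsum(width(genes))
      gi <- findInterval(offs - 0.5, c(0, cw)) # gene containing each offset
      gpos <- start(genes)[gi] + (offs - c(0, cw)[gi]) - 1L
    }
    interBp <- L - genicBp
    nInter <- rpois(1L, config@snpDensityIntergenic / 1000 * interBp)
    ipos <- integer(0)
    if (nInter > 0) {
      cand <- sample.int(L, min(nInter * 2L, L))
      cand <- cand[!overlapsAny(GRanges(chrom, IRanges(cand, cand)), genes)]
      ipos <- cand[seq_len(min(nInter, length(cand)))]
    }
    pos <- sort(unique(c(gpos, ipos)))
    pos <- pos[pos >= 1 & pos <= L]
    if (length(pos)) {
      alle <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"), ncol = 2)
      pick <- sample.int(4L, length(pos), replace = TRUE)
      snp <- GRanges(chrom, IRanges(pos, pos))
      snp$ref <- alle[pick, 1]; snp$alt <- alle[pick, 2]
      snp$strain <- "castaneus"
    } else {
      snp <- GRanges(); snp$ref <- character(0); snp$alt <- character(0)
      snp$strain <- character(0)
    }

    geneL[[chrom]] <- genes; exonL[[chrom]] <- exn; pseudoL[[chrom]] <- pseudo
    cgiL[[chrom]] <- cgis; repL[[chrom]] <- reps; snpL[[chrom]] <- snp
  }

  ann <- new("GenomeAnnotation",
             chromLengths = lens,
             genes = do.call(c, unname(geneL)),
             exons = do.call(c, unname(exonL)),
             pseudogenes = do.call(c, unname(pseudoL)),
             cgis = do.call(c, unname(cgiL)),
             repeats = do.call(c, unname(repL)),
             snps = do.call(c, unname(snpL)))
  attr(ann, "geneDenseBlocks") <- do.call(c, unname(denseL))
  ann
}

#' Gene-dense blocks of a simulated annotation
#'
#' @param annotation a [GenomeAnnotation-class] from [simulateAnnotation()]
#' @return `GRanges` of the gene-dense 500-kb blocks
#' @export
geneDenseBlocks <- function(annotation) {
  gd <- attr(annotation, "geneDenseBlocks")
  if (is.null(gd)) stop("annotation carries no gene-dense block attribute")
  gd
}

# ---------------------------------------------------------------------------
# allelic RNA-seq
# ---------------------------------------------------------------------------

#' Simulate allele-specific RNA-seq SNP counts over a differentiation course
#'
#' For each exonic X-linked SNP and sample, total depth is negative binomial
#' around `meanCoverageRna` and the Xi read count is binomial with success
#' probability equal to the timepoint's expected Xi fraction. For planted
#' reactivating genes, Xi expression is lifted `reactivationEffect`-fold (on
#' the Xi:Xa odds scale) in knockdown samples at day 5 only.
#'
#' @param annotation a [GenomeAnnotation-class] with exonic SNPs on chrX
#' @param config a [SimConfig-class]
#' @param conditions shRNA conditions simulated per replicate
#' @param replicates replicate labels
#' @param timepoints subset of `names(config@xiSilencingTrajectory)`
#' @return list with `counts` (data.frame: chrom, pos, gene_id, exonic,
#'   sample_id, condition, timepoint, replicate, xi_count, xa_count) and
#'   `truth` (a [GroundTruth-class] listing planted genes)
#' @export
simulateAllelicRnaseq <- function(annotation, config,
                                  conditions = c("Nons", "shSetdb1.4", "shSetdb1.6"),
                                  replicates = 1:2,
                                  timepoints = names(config@xiSilencingTrajectory)) {
  stopifnot(is(annotation, "GenomeAnnotation"), is(config, "SimConfig"))
  set.seed(.subSeed(config@seed, 2L))
  snps <- snpRanges(annotation)
  snps <- snps[as.character(seqnames(snps)) == "chrX"]
  exons <- unlist(exonRanges(annotation), use.names = FALSE)
  exons$gene_id <- rep(names(exonRanges(annotation)),
                       lengths(exonRanges(annotation)))
  ov <- findOverlaps(snps, exons)
  exSnps <- snps[queryHits(ov)]
  exSnps$gene_id <- exons$gene_id[subjectHits(ov)]
  exSnps <- exSnps[!duplicated(start(exSnps))]
  if (length(exSnps) == 0L) stop("annotation has no exonic SNPs on chrX")

  xGenes <- geneRanges(annotation)
  xGenes <- xGenes$gene_id[as.character(seqnames(xGenes)) == "chrX"]
  nReact <- round(config@reactivatingGeneFraction * length(xGenes))
  reactGenes <- if (nReact > 0) sample(xGenes, nReact) else character(0)

  traj <- config@xiSilencingTrajectory[timepoints]
  nSnp <- length(exSnps)
  out <- vector("list", length(conditions) * length(replicates) * length(traj))
  i <- 0L
  for (rep_ in replicates) for (cond in conditions) for (tp in names(traj)) {
    i <- i + 1L
    f <- traj[[tp]]
    p <- rep(f, nSnp)
    if (cond != "Nons" && tp == "day5" && length(reactGenes)) {
      lift <- exSnps$gene_id %in% reactGenes
      p[lift] <- (config@reactivationEffect * f) /
        (config@reactivationEffect * f + (1 - f))
    }
    total <- rnbinom(nSnp, mu = config@meanCoverageRna, size = 1 / config@dispersion)
    xi <- rbinom(nSnp, total, p)
    out[[i]] <- data.frame(
      chrom = "chrX", pos = start(exSnps), gene_id = exSnps$gene_id,
      exonic = TRUE,
      sample_id = sprintf("%s_%s_r%d", cond, tp, rep_),
      condition = cond, timepoint = tp, replicate = rep_,
      xi_count = xi, xa_count = total - xi,
      stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, out),
       truth = GroundTruth(reactivatingGenes = sort(reactGenes)))
}

# ---------------------------------------------------------------------------
# ChIP read-start tables
# ---------------------------------------------------------------------------

#' Simulate ChIP-seq read-start positions with banded enrichment
#'
#' Background read starts are Poisson at `meanCoverageChip` per bp; within a
#' mark's region class (its gene-dense or gene-poor blocks) the rate is
#' multiplied by the configured fold for female samples. The H3 control and
#' input carry no planted enrichment. Allele-informative coverage is summarised
#' per SNP: reads covering a SNP are tagged Xi or Xa with Xi:Xa odds
#' `xiChipFold` inside enriched regions of female samples and 1 elsewhere
#' (males are balanced everywhere).
#'
#' @param annotation a [GenomeAnnotation-class]
#' @param config a [SimConfig-class]
#' @param sex "female" (enrichment + Xi skew) or "male" (neither)
#' @param readLength read length in bp for SNP-informative coverage
#' @return list with `reads` (named list of data.frames chrom/pos per sample:
#'   one per mark plus "H3" and "input"), `allelic` (per mark: data.frame
#'   chrom, pos, xi_count, xa_count), and `truth` (enriched regions per mark)
#' @export
simulateChip <- function(annotation, config, sex = c("female", "male"),
                         readLength = 100L) {
  sex <- match.arg(sex)
  stopifnot(is(annotation, "GenomeAnnotation"), is(config, "SimConfig"))
  set.seed(.subSeed(config@seed, 3L))
  lens <- chromLengths(annotation)
  dense <- geneDenseBlocks(annotation)
  marks <- config@marks

  regionFor <- function(cls) {
    if (cls == "gene_dense") return(reduce(dense))
    gaps <- GRanges(names(lens), IRanges(1L, lens))
    GenomicRanges::setdiff(gaps, reduce(dense))
  }

  drawReads <- function(rate, enriched, fold) {
    res <- vector("list", length(lens))
    for (ci in seq_along(lens)) {
      chrom <- names(lens)[ci]; L <- lens[[ci]]
      e <- enriched[as.character(seqnames(enriched)) == chrom]
      # piecewise-constant rate: background everywhere, fold inside e
      nBg <- rpois(1L, rate * L)
      pos <- sample.int(L, nBg, replace = TRUE)
      if (fold > 1 && length(e)) {
        extra <- rpois(1L, rate * (fold - 1) * sum(width(e)))
        if (extra > 0) {
          offs <- sample.int(sum(width(e)), extra, replace = TRUE)
          cw <- cumsum(width(e))
          ei <- findInterval(offs - 1L, c(0L, cw[-length(cw)]))
          ei <- pmin(ei, length(cw))
          pos <- c(pos, start(e)[ei] + (offs - c(0L, cw)[ei] - 1L))
        }
      }
      res[[ci]] <- data.frame(chrom = chrom, pos = sort(pos))
    }
    do.call(rbind, res)
  }

  enrichedL <- list()
  reads <- list()
  for (i in seq_len(nrow(marks))) {
    reg <- regionFor(marks$regionClass[i])
    fold <- if (sex == "female") marks$fold[i] else 1
    enrichedL[[marks$mark[i]]] <- reg
    reads[[marks$mark[i]]] <- drawReads(config@meanCoverageChip, reg, fold)
  }
  reads[["H3"]] <- drawReads(config@meanCoverageChip, GRanges(), 1)
  reads[["input"]] <- drawReads(config@meanCoverageChip, GRanges(), 1)

  # allele-informative coverage per SNP, per mark
  snps <- snpRanges(annotation)
  allelic <- list()
  for (i in seq_len(nrow(marks))) {
    reg <- enrichedL[[marks$mark[i]]]
    fold <- if (sex == "female") marks$fold[i] else 1
    inReg <- overlapsAny(snps, reg)
    rate <- config@meanCoverageChip * readLength * ifelse(inReg, fold, 1)
    depth <- rpois(length(snps), rate)
    odds <- if (sex == "female") ifelse(inReg, config@xiChipFold, 1) else 1
    xi <- rbinom(length(snps), depth, odds / (1 + odds))
    allelic[[marks$mark[i]]] <- data.frame(
      chrom = as.character(seqnames(snps)), pos = start(snps),
      xi_count = xi, xa_count = depth - xi)
  }
  list(reads = reads, allelic = allelic,
       truth = GroundTruth(enrichedRegions =
         GRangesList(lapply(enrichedL, function(g) if (sex == "female") g
                            else GRanges()))))
}

# ---------------------------------------------------------------------------
# eRRBS CpG tables
# ---------------------------------------------------------------------------

#' Simulate bisulphite CpG methylation calls concentrated in CGIs
#'
#' CpGs are laid every ~25 bp inside CGIs. Per CpG, allele, condition and
#' replicate, coverage is negative binomial around `meanCoverageCpg` and the
#' methylated count binomial at the allele mean (`cgiXiMethLevel` /
#' `cgiXaMethLevel` %). For a planted fraction of X CGIs, the knockdown
#' condition's Xi methylation is reduced by `methLossDelta` points uniformly
#' across the CGI.
#'
#' @param annotation a [GenomeAnnotation-class] with CGIs
#' @param config a [SimConfig-class]
#' @param conditions condition labels: first is control, second knockdown
#' @param nReps replicates per condition (control, knockdown)
#' @param chrom restrict to one chromosome (default chrX, where the contrast
#'   lives); `NULL` for all
#' @return list with `sites` (data.frame: chrom, pos, allele, condition,
#'   replicate, meth_count, unmeth_count) and `truth` (demethylated CGIs)
#' @export
simulateErrbs <- function(annotation, config,
                          conditions = c("Nons", "shSetdb1"),
                          nReps = c(3L, 2L), chrom = "chrX") {
  stopifnot(is(annotation, "GenomeAnnotation"), is(config, "SimConfig"))
  set.seed(.subSeed(config@seed, 4L))
  cgis <- cgiRanges(annotation)
  if (!is.null(chrom)) cgis <- cgis[as.character(seqnames(cgis)) %in% chrom]
  if (length(cgis) == 0L) stop("annotation has no CGIs on the requested chromosome")

  nLoss <- round(config@methLossCgiFraction * length(cgis))
  lossIdx <- if (nLoss > 0) sort(sample.int(length(cgis), nLoss)) else integer(0)

  cpgPos <- lapply(seq_along(cgis), function(i) {
    seq(start(cgis)[i], end(cgis)[i], by = 25L)
  })
  cgiOf <- rep(seq_along(cgis), lengths(cpgPos))
  pos <- unlist(cpgPos)
  chromV <- as.character(seqnames(cgis))[cgiOf]
  n <- length(pos)

  out <- list(); k <- 0L
  for (ci in seq_along(conditions)) for (r in seq_len(nReps[ci])) {
    for (allele in c("Xi", "Xa")) {
      base <- if (allele == "Xi") config@cgiXiMethLevel else config@cgiXaMethLevel
      p <- rep(base / 100, n)
      if (ci == 2L && allele == "Xi" && length(lossIdx)) {
        hit <- cgiOf %in% lossIdx
        p[hit] <- pmax(0, p[hit] - config@methLossDelta / 100)
      }
      cov <- rnbinom(n, mu = config@meanCoverageCpg, size = 1 / config@dispersion)
      meth <- rbinom(n, cov, p)
      k <- k + 1L
      out[[k]] <- data.frame(chrom = chromV, pos = pos, allele = allele,
                             condition = conditions[ci], replicate = r,
                             meth_count = meth, unmeth_count = cov - meth,
                             stringsAsFactors = FALSE)
    }
  }
  list(sites = do.call(rbind, out),
       truth = GroundTruth(demethylatedCgis = cgis[lossIdx]))
}

# ---------------------------------------------------------------------------
# pooled shRNA screen
# ---------------------------------------------------------------------------

#' Simulate a pooled shRNA screen count matrix
#'
#' Baseline hairpin abundances are log-normal; planted hit hairpins are
#' multiplied by `screenHitFold` in the GFP+ population only. Per-sample
#' counts are multinomial at `screenDepth` reads.
#'
#' @param config a [SimConfig-class]
#' @param nInitialReps replicates of the initial (pre-sort) timepoint
#' @return list with `counts` (data.frame: hairpin_id then one column per
#'   sample: initial_1..., gfp_pos, gfp_neg) and `truth` (hit hairpin ids)
#' @export
simulateScreen <- function(config, nInitialReps = 2L) {
  stopifnot(is(config, "SimConfig"))
  set.seed(.subSeed(config@seed, 5L))
  n <- config@screenNHairpins
  ids <- sprintf("hp%04d", seq_len(n))
  base <- rlnorm(n, meanlog = 0, sdlog = 1)
  nHit <- round(config@screenHitFraction * n)
  hits <- if (nHit > 0) sort(sample.int(n, nHit)) else integer(0)
  wPos <- base
  wPos[hits] <- wPos[hits] * config@screenHitFold
  draw <- function(w) as.vector(stats::rmultinom(1, config@screenDepth, w / sum(w)))
  counts <- data.frame(hairpin_id = ids)
  for (r in seq_len(nInitialReps)) counts[[paste0("initial_", r)]] <- draw(base)
  counts$gfp_pos <- draw(wPos)
  counts$gfp_neg <- draw(base)
  list(counts = counts, truth = GroundTruth(screenHits = ids[hits]))
}

# ---------------------------------------------------------------------------
# immunofluorescence cross-sections
# ---------------------------------------------------------------------------

#' Simulate two-channel fluorescence cross-section profiles
#'
#' Each cell's profile is a smooth low-frequency baseline plus Gaussian bumps
#' at planted apex positions plus white noise. Channel B peaks co-locate with
#' channel A peaks with probability `ifColocProb`, otherwise they are placed
#' independently.
#'
#' @param config a [SimConfig-class]
#' @param noiseSd override the configured noise sd (e.g. 0 for exact tests)
#' @return list with `profiles` (data.frame: cell_id, channel, index,
#'   intensity) and `truth` (`ifPeakPositions`: per cell, list(A=, B=) planted
#'   apex indices)
#' @export
simulateIfProfiles <- function(config, noiseSd = config@ifNoiseSd) {
  stopifnot(is(config, "SimConfig"))
  set.seed(.subSeed(config@seed, 6L))
  L <- config@ifProfileLength
  nC <- config@ifNCells
  k <- config@ifPeaksPerCell
  idx <- seq_len(L)
  out <- list(); truth <- vector("list", nC)
  for (cell in seq_len(nC)) {
    phase <- runif(1, 0, 2 * pi)
    # gentle low-frequency baseline: its crest stays well below the channel
    # mean once bumps are added, so the mean threshold suppresses noise peaks
    baseline <- 1 + 0.02 * sin(2 * pi * idx / L + phase)
    posA <- sort(sample(seq(15L, L - 15L), k))
    while (k > 1 && min(diff(posA)) < 30L) posA <- sort(sample(seq(15L, L - 15L), k))
    coloc <- runif(k) < config@ifColocProb
    posB <- posA
    for (j in which(!coloc)) {
      cand <- NULL
      for (try_ in 1:200) {
        x <- sample(seq(15L, L - 15L), 1L)
        if (all(abs(x - posA) > 25L) && all(abs(x - posB[-j]) > 25L)) {
          cand <- x; break
        }
      }
      if (is.null(cand)) {  # crowded profile: fall back to the widest gap
        occ <- sort(c(1L, posA, posB[-j], L))
        g <- which.max(diff(occ))
        cand <- as.integer((occ[g] + occ[g + 1L]) / 2)
      }
      posB[j] <- cand
    }
    posB <- sort(posB)
    bump <- function(pos) {
      v <- numeric(L)
      for (p in pos) v <- v + runif(1, 2, 4) * exp(-(idx - p)^2 / (2 * 3^2))
      v
    }
    for (ch in c("A", "B")) {
      pos <- if (ch == "A") posA else posB
      y <- baseline + bump(pos) + rnorm(L, 0, noiseSd)
      out[[length(out) + 1L]] <- data.frame(cell_id = cell, channel = ch,
                                            index = idx, intensity = y)
    }
    truth[[cell]] <- list(A = posA, B = posB)
  }
  list(profiles = do.call(rbind, out),
       truth = GroundTruth(ifPeakPositions = truth))
}
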