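# configuration-driven pipeline: chains simulation and the analysis stages
# for one experiment type and writes per-stage TSV outputs plus a run log.

.writeTsv <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run an end-to-end analysis from a configuration
#'
#' The configuration (a YAML file path or an equivalent nested list) names an
#' experiment type and either input paths or a `simulation` block of
#' [simConfig()] overrides. Results are written as TSV files under `out`,
#' together with `groundtruth.json` (simulated runs) and `run.log` recording
#' the package version, seed and all thresholds in effect. Runs are
#' deterministic given the configuration (including its seed).
#'
#' Experiment types:
#' \describe{
#'   \item{es_timecourse}{allelic RNA-seq: SNP filter, Xi/Xa ratios,
#'     reactivation calls, consensus gene list.}
#'   \item{mef_chip}{ChIP: broad peaks per mark, peak density, 50-kb bin
#'     coverage and correlations, allelic peak enrichment.}
#'   \item{errbs}{methylation: CpG filter, per-CpG differential calls, CGI
#'     calls, CGI meta-profile.}
#'   \item{screen}{hairpin filter + conditional exact test.}
#'   \item{if}{profile smoothing, peak calls, channel overlap.}
#' }
#'
#' @param config YAML path or list; required fields: `experiment`, `out`,
#'   and `simulation` (with `seed`) until external inputs are wired in.
#' @param overwrite allow writing into an existing directory
#' @return invisibly, a named list of written file paths
#' @export
runPipeline <- function(config, overwrite = TRUE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  for (field in c("experiment", "out")) {
    if (is.null(config[[field]])) {
      stop("configuration error: missing required field '", field, "'")
    }
  }
  types <- c("es_timecourse", "mef_chip", "errbs", "screen", "if")
  if (!config$experiment %in% types) {
    stop("unknown experiment type '", config$experiment, "'; expected one of: ",
         paste(types, collapse = ", "))
  }
  if (is.null(config$simulation) || is.null(config$simulation$seed)) {
    stop("configuration error: missing required field 'simulation.seed'")
  }
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(config$out, "run.log")
  unlink(logPath)
  old <- xiLogTo(logPath)
  on.exit(xiLogTo(old))
  xiLog("xiseq %s | experiment=%s | seed=%d",
        as.character(utils::packageVersion("xiseq")), config$experiment,
        as.integer(config$simulation$seed))

  sim <- config$simulation
  sc <- do.call(simConfig, sim[names(sim) %in% methods::slotNames("SimConfig")])
  pars <- config$params %||% list()
  paths <- list()
  truth <- NULL

  if (config$experiment == "es_timecourse") {
    ann <- simulateAnnotation(sc)
    rna <- simulateAllelicRnaseq(ann, sc)
    truth <- rna$truth
    minTotal <- pars$min_total %||% 10
    xiLog("thresholds: min_total=%g, timepoint=%s", minTotal,
          pars$timepoint %||% "day5")
    filt <- filterSnps(rna$counts, minTotal = minTotal)
    ratios <- xiXaRatio(filt)
    cls <- classifyReactivating(ratios, timepoint = pars$timepoint %||% "day5")
    genes <- reactivatingGenes(cls$calls, snpGenes = unique(filt$gene_id))
    paths$ratios <- .writeTsv(ratios, config$out, "xi_xa_ratios")
    paths$calls <- .writeTsv(cls$calls, config$out, "reactivation_calls")
    paths$consensus <- .writeTsv(cls$consensus, config$out, "consensus_snps")
    paths$genes <- .writeTsv(
      data.frame(gene_id = genes$intersection), config$out, "reactivating_genes")
  } else if (config$experiment == "mef_chip") {
    ann <- simulateAnnotation(sc)
    chip <- simulateChip(ann, sc)
    truth <- chip$truth
    win <- pars$window %||% 10000
    pThr <- pars$p_threshold %||% 1e-5
    xiLog("thresholds: window=%g, p_threshold=%g", win, pThr)
    bins <- tileBins(chromLengths(ann), pars$bin_width %||% 50000)
    corRows <- list(); densRows <- list()
    for (mk in sc@marks$mark) {
      ps <- callBroadPeaks(chip$reads[[mk]], chip$reads$H3, chromLengths(ann),
                           window = win, pThreshold = pThr, mark = mk)
      pk <- peakRanges(ps)
      pk$name <- sprintf("%s_peak%d", mk, seq_along(pk))
      paths[[paste0("peaks_", mk)]] <- file.path(config$out,
                                                 paste0("peaks_", mk, ".bed"))
      writeBed(pk, paths[[paste0("peaks_", mk)]])
      dens <- peaksPerMb(ps, chromLengths(ann))
      densRows[[mk]] <- cbind(mark = mk, dens$grouped)
      cov <- binCoverage(peakRanges(ps), bins)
      gcov <- binCoverage(geneRanges(ann), bins)
      ct <- correlateBins(cov, gcov)
      corRows[[mk]] <- data.frame(mark = mk, against = "genes",
                                  r = ct$r, n = ct$n)
      enr <- allelicPeakEnrichment(chip$allelic[[mk]], ps)
      paths[[paste0("allelic_", mk)]] <- .writeTsv(enr$peaks, config$out,
                                                   paste0("allelic_", mk))
    }
    paths$density <- .writeTsv(do.call(rbind, densRows), config$out,
                               "peaks_per_mb")
    paths$correlation <- .writeTsv(do.call(rbind, corRows), config$out,
                                   "bin_correlations")
  } else if (config$experiment == "errbs") {
    ann <- simulateAnnotation(sc)
    err <- simulateErrbs(ann, sc)
    truth <- err$truth
    minCov <- pars$min_coverage %||% 20
    alpha <- pars$alpha %||% 0.05
    xiLog("thresholds: min_coverage>%g, alpha=%g", minCov, alpha)
    filt <- filterCpgs(err$sites, minCoverageExclusive = minCov)
    xi <- filt[filt$allele == "Xi", ]
    diff <- differentialCpgs(xi, "Nons", "shSetdb1", alpha = alpha)
    cgis <- cgiRanges(ann)
    cgis <- cgis[as.character(seqnames(cgis)) == "chrX"]
    cgi <- cgiCalls(xi, cgis, "Nons", "shSetdb1", alpha = alpha)
    prof <- cgiMetaProfile(xi, cgis, nPositions = pars$profile_bins %||% 100)
    paths$cpgs <- .writeTsv(diff, config$out, "differential_cpgs")
    paths$cgis <- .writeTsv(cgi, config$out, "cgi_calls")
    paths$profile <- .writeTsv(prof, config$out, "cgi_profile")
  } else if (config$experiment == "screen") {
    scr <- simulateScreen(sc)
    truth <- scr$truth
    minInitial <- pars$min_initial %||% 1000
    alpha <- pars$alpha %||% 0.1
    xiLog("thresholds: min_initial=%g, alpha=%g", minInitial, alpha)
    filt <- filterHairpins(scr$counts, c("initial_1", "initial_2"),
                           minInitial = minInitial)
    res <- screenExactTest(filt, "gfp_pos", "gfp_neg",
                           dispersion = pars$dispersion %||% 0, alpha = alpha)
    paths$counts <- .writeTsv(scr$counts, config$out, "hairpin_counts")
    paths$results <- .writeTsv(res, config$out, "screen_results")
  } else if (config$experiment == "if") {
    ifd <- simulateIfProfiles(sc)
    truth <- ifd$truth
    win <- pars$window %||% 5
    xiLog("thresholds: smoothing window=%g", win)
    calls <- callProfilePeaks(ifd$profiles, window = win)
    ov <- countPeakOverlaps(calls[calls$channel == "A", ],
                            calls[calls$channel == "B", ])
    paths$calls <- .writeTsv(calls, config$out, "peak_calls")
    paths$overlap <- .writeTsv(ov$perCell, config$out, "peak_overlap")
    xiLog("pooled overlap fraction: %.4f", ov$fraction)
  }

  if (!is.null(truth)) {
    gt <- list(
      reactivating_genes = truth@reactivatingGenes,
      screen_hits = truth@screenHits,
      demethylated_cgis = if (length(truth@demethylatedCgis))
        data.frame(chrom = as.character(seqnames(truth@demethylatedCgis)),
                   start = start(truth@demethylatedCgis),
                   end = end(truth@demethylatedCgis)) else NULL,
      enriched_regions = lapply(as.list(truth@enrichedRegions), function(g)
        data.frame(chrom = as.character(seqnames(g)), start = start(g),
                   end = end(g))))
    gtPath <- file.path(config$out, "groundtruth.json")
    jsonlite::write_json(gt[!vapply(gt, is.null, TRUE)], gtPath,
                         auto_unbox = TRUE, digits = NA)
    paths$groundtruth <- gtPath
  }
  paths$log <- logPath
  invisible(paths)
}
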