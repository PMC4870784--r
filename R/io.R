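# readers/writers for the plain-text formats the pipeline consumes.
# Coordinate conventions are centralized here: BED/bedGraph are 0-based
# half-open on disk and converted to the 1-based closed GRanges convention in
# memory; SNP and CpG positions are 1-based throughout (VCF convention).

#' Read a BED file of intervals
#'
#' Parses at least chrom/start/end (tab-separated), with optional name,
#' score and strand columns. BED's 0-based half-open coordinates become
#' 1-based closed `GRanges`; [writeBed()] inverts the conversion, so a
#' round-trip is bit-exact.
#'
#' @param path file path
#' @return `GRanges` in file order; the 4th column (if any) is kept as
#'   `mcols(x)$name`, the 5th as `score`.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L || all(!nzchar(lines))) return(GRanges())
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 bad[1L]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | !nzchar(chrom))
  if (length(bad)) stop(sprintf("malformed BED line %d: non-numeric coordinates",
                                bad[1L]))
  bad <- which(s < 0 | s >= e)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: requires 0 <= start < end", bad[1L]))
  }
  strand <- rep("*", length(chrom))
  if (any(nf >= 6L)) {
    st <- vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*", "")
    st[!st %in% c("+", "-", ".", "*")] <- "*"
    st[st == "."] <- "*"
    strand <- st
  }
  gr <- GRanges(chrom, IRanges(s + 1L, e), strand = strand)
  if (any(nf >= 4L)) {
    gr$name <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  }
  if (any(nf >= 5L)) {
    gr$score <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")))
  }
  gr
}

#' Write intervals as BED
#'
#' @param gr `GRanges`; `name` and `score` metadata columns are written as
#'   BED columns 4-5 when present.
#' @param path output path
#' @return invisibly, `path`
#' @export
writeBed <- function(gr, path) {
  n <- length(gr)
  cols <- list(as.character(seqnames(gr)),
               format(start(gr) - 1L, scientific = FALSE, trim = TRUE),
               format(end(gr), scientific = FALSE, trim = TRUE))
  if (!is.null(gr$name)) {
    cols <- c(cols, list(gr$name))
    if (!is.null(gr$score)) {
      cols <- c(cols, list(sprintf("%.17g", gr$score)))
      st <- as.character(strand(gr)); st[st == "*"] <- "."
      if (any(st != ".")) cols <- c(cols, list(st))
    }
  }
  lines <- if (n) do.call(paste, c(cols, sep = "\t")) else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write a binned track as bedGraph
#'
#' Sliding windows (step < width) are flattened to step-width records carrying
#' the value of the window that starts at each step, so records never overlap.
#' Values are written with 17 significant digits: re-reading reproduces them
#' to full double precision.
#'
#' @param track a [BinnedTrack-class]
#' @param path output path
#' @return invisibly, `path`
#' @export
writeBedGraph <- function(track, path) {
  stopifnot(is(track, "BinnedTrack"))
  bins <- trackBins(track)
  if (length(bins) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  o <- order(as.character(seqnames(bins)), start(bins))
  if (any(o != seq_along(bins))) bins <- bins[o]
  chrom <- as.character(seqnames(bins))
  s <- start(bins) - 1L
  e <- if (stepWidth(track) < windowWidth(track)) s + stepWidth(track) else end(bins)
  byc <- split(seq_along(bins), chrom)
  for (ii in byc) {
    if (length(ii) > 1L && any(s[ii][-1L] < e[ii][-length(ii)])) {
      stop("bins overlap after flattening; track is not on a sorted step grid")
    }
  }
  writeLines(sprintf("%s\t%s\t%s\t%.17g", chrom,
                     format(s, scientific = FALSE, trim = TRUE),
                     format(e, scientific = FALSE, trim = TRUE),
                     bins$score), path)
  invisible(path)
}

#' Read a bedGraph file into a BinnedTrack
#'
#' @param path file path
#' @param windowWidth,stepWidth window geometry the records represent; by
#'   default each record is its own window (`NULL` infers record width).
#' @return a [BinnedTrack-class]
#' @export
readBedGraph <- function(path, windowWidth = NULL, stepWidth = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(BinnedTrack(GRanges(), windowWidth = windowWidth %||% 1,
                       stepWidth = stepWidth %||% windowWidth %||% 1))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) stop(sprintf("malformed bedGraph line %d", bad[1L]))
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- as.numeric(vapply(fields, `[[`, "", 2L))
  e <- as.numeric(vapply(fields, `[[`, "", 3L))
  v <- as.numeric(vapply(fields, `[[`, "", 4L))
  w <- windowWidth %||% (e[1L] - s[1L])
  st <- stepWidth %||% w
  gr <- GRanges(chrom, IRanges(s + 1L, s + w))
  gr$score <- v
  BinnedTrack(gr, windowWidth = w, stepWidth = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a VCF-lite allelic count table
#'
#' Tab-separated with header: `chrom`, `pos` (1-based), `ref`, `alt`, then for
#' each sample a pair of columns `<sample>.ref` and `<sample>.alt` holding
#' reference/alternate read counts.
#'
#' @param path file path
#' @return long data.frame: chrom, pos, ref, alt, sample_id, ref_count,
#'   alt_count
#' @export
readAllelicCounts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  .assertCols(df, c("chrom", "pos", "ref", "alt"), "allelic count table")
  sampleCols <- grep("\\.(ref|alt)$", names(df), value = TRUE)
  samples <- unique(sub("\\.(ref|alt)$", "", sampleCols))
  out <- lapply(samples, function(s) {
    data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
               sample_id = s,
               ref_count = df[[paste0(s, ".ref")]],
               alt_count = df[[paste0(s, ".alt")]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a long allelic count table in VCF-lite layout
#' @param counts long data.frame as returned by [readAllelicCounts()]
#' @param path output path
#' @return invisibly, `path`
#' @export
writeAllelicCounts <- function(counts, path) {
  .assertCols(counts, c("chrom", "pos", "ref", "alt", "sample_id",
                        "ref_count", "alt_count"))
  key <- paste(counts$chrom, counts$pos)
  sites <- counts[!duplicated(key), c("chrom", "pos", "ref", "alt")]
  skey <- paste(sites$chrom, sites$pos)
  wide <- sites
  for (s in unique(counts$sample_id)) {
    sub <- counts[counts$sample_id == s, ]
    m <- match(skey, paste(sub$chrom, sub$pos))
    wide[[paste0(s, ".ref")]] <- sub$ref_count[m]
    wide[[paste0(s, ".alt")]] <- sub$alt_count[m]
  }
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert a BED-convention (0-based half-open) interval to GRanges
#' @param chrom,start,end vectors; start is 0-based, end exclusive
#' @return `GRanges`
#' @export
bedToGRanges <- function(chrom, start, end) {
  stopifnot(all(start >= 0), all(start < end))
  GRanges(chrom, IRanges(start + 1, end))
}

#' 1-based positions (SNPs, CpGs) to width-1 GRanges
#' @param chrom,pos vectors, `pos` 1-based
#' @return `GRanges`
#' @export
positionsToGRanges <- function(chrom, pos) {
  stopifnot(all(pos >= 1))
  GRanges(chrom, IRanges(pos, pos))
}
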