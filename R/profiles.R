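# 1-D immunofluorescence cross-section analysis: moving-average smoothing,
# rule-based peak calling, and two-channel overlap counting.

#' Moving-average smoothing of an intensity profile
#'
#' Centered moving average of width `window` (odd). At the edges the window
#' shrinks symmetrically to what fits, so the first and last values average
#' fewer observations.
#'
#' @param y numeric intensity values along the cross-section
#' @param window window size in observations, default 5
#' @return smoothed numeric vector of the same length
#' @export
smoothProfile <- function(y, window = 5L) {
  n <- length(y)
  if (n < window) stop("profile shorter than the smoothing window")
  if (window %% 2L == 0L) stop("window must be odd")
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(y))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  # symmetric shrink: use the smaller one-sided reach at the edges
  reach <- pmin(seq_len(n) - lo, hi - seq_len(n))
  lo <- seq_len(n) - reach
  hi <- seq_len(n) + reach
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Rule-based peak calling on a smoothed profile
#'
#' An apex is an index into which the (smoothed) profile strictly increased
#' for at least two successive observations, after which it strictly
#' decreases for the next two, and whose value exceeds the channel-specific
#' mean for the cell. The extent of a peak is the maximal strictly monotone
#' run around its apex; when successive extents share their valley point the
#' later one is trimmed (left-to-right), so extents never overlap.
#'
#' @param y smoothed intensity values (see [smoothProfile()])
#' @param channelMean threshold; defaults to `mean(y)` (the smoothed channel
#'   mean; pass the raw-profile mean to threshold on raw values instead)
#' @return data.frame: apex, start, end (1-based indices, extents inclusive)
#' @export
findProfilePeaks <- function(y, channelMean = mean(y)) {
  m <- .cppFindPeaks(as.numeric(y), channelMean)
  as.data.frame(m)
}

#' Count overlapping peaks between two channels
#'
#' A channel-A peak overlaps iff its extent intersects at least one
#' channel-B extent (as index ranges). Reports per-cell overlap counts and
#' the pooled overlap fraction.
#'
#' @param callsA,callsB data.frames of peak calls with columns `cell_id`,
#'   `start`, `end` (e.g. [findProfilePeaks()] output plus a cell id)
#' @return list: `perCell` (data.frame cell_id, n_peaks_a, n_overlapping),
#'   `fraction` (pooled overlapping / total A peaks)
#' @export
countPeakOverlaps <- function(callsA, callsB) {
  .assertCols(callsA, c("cell_id", "start", "end"))
  .assertCols(callsB, c("cell_id", "start", "end"))
  cells <- sort(unique(callsA$cell_id))
  perCell <- lapply(cells, function(cell) {
    a <- callsA[callsA$cell_id == cell, ]
    b <- callsB[callsB$cell_id == cell, ]
    nOv <- if (nrow(a) == 0L) 0L else if (nrow(b) == 0L) 0L else {
      sum(countOverlaps(IRanges(a$start, a$end), IRanges(b$start, b$end)) > 0L)
    }
    data.frame(cell_id = cell, n_peaks_a = nrow(a), n_overlapping = nOv)
  })
  perCell <- do.call(rbind, perCell)
  list(perCell = perCell,
       fraction = sum(perCell$n_overlapping) / max(1L, sum(perCell$n_peaks_a)))
}

#' Smooth and call peaks for a table of cell profiles
#'
#' Convenience wrapper running [smoothProfile()] and [findProfilePeaks()]
#' per cell and channel.
#'
#' @param profiles data.frame: cell_id, channel, index, intensity (index
#'   ordered within cell/channel)
#' @param window smoothing window
#' @param thresholdOn "smoothed" (default) or "raw": which values define the
#'   channel mean threshold
#' @return data.frame of calls: cell_id, channel, apex, start, end
#' @export
callProfilePeaks <- function(profiles, window = 5L,
                             thresholdOn = c("smoothed", "raw")) {
  thresholdOn <- match.arg(thresholdOn)
  .assertCols(profiles, c("cell_id", "channel", "index", "intensity"))
  sp <- split(profiles, list(profiles$cell_id, profiles$channel), drop = TRUE)
  out <- lapply(sp, function(d) {
    d <- d[order(d$index), ]
    s <- smoothProfile(d$intensity, window)
    thr <- if (thresholdOn == "smoothed") mean(s) else mean(d$intensity)
    pk <- findProfilePeaks(s, thr)
    if (nrow(pk) == 0L) return(NULL)
    data.frame(cell_id = d$cell_id[1L], channel = d$channel[1L],
               apex = d$index[pk$apex], start = d$index[pk$start],
               end = d$index[pk$end])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), channel = character(0),
                      apex = integer(0), start = integer(0), end = integer(0))
  }
  out
}
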