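#' Peak-calling parameters
#'
#' Relaxed defaults are deliberate: every candidate local maximum is kept so
#' that the replicate-reproducibility filter — not the caller — decides what
#' is signal. `min_height = 0` keeps all peaks, `min_distance = 1` imposes
#' no spacing, `trim_fraction = 0.10` trims peak ends whose per-position
#' coverage falls below 10% of the peak's total coverage.
#'
#' @param min_height Minimum apex height to report a peak.
#' @param min_distance Minimum spacing in bases between reported apexes;
#'   when two apexes are closer, the lower one is dropped.
#' @param trim_fraction Fraction of total peak coverage used as the
#'   per-position trimming threshold, in `[0, 1]`.
#' @return A `peak_params` list.
#' @export
peak_params <- function(min_height = 0, min_distance = 1L,
                        trim_fraction = 0.10) {
  stopifnot(min_height >= 0, min_distance >= 1,
            trim_fraction >= 0, trim_fraction <= 1)
  structure(list(min_height = min_height,
                 min_distance = as.integer(min_distance),
                 trim_fraction = trim_fraction),
            class = "peak_params")
}

# Local maxima of a dense non-negative vector. A plateau (run of equal
# values strictly above both neighbours, track ends counting as -Inf)
# yields one peak whose apex is the plateau's first position; ties at the
# summit level are re-broken strand-aware later by peak_summit().
local_maxima <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  left <- c(-Inf, r$values[-k])
  right <- c(r$values[-1], -Inf)
  apex_runs <- which(r$values > left & r$values > right)
  starts[apex_runs]
}

#' Call raw coverage peaks in one replicate
#'
#' Identifies every local maximum in a dense coverage track (subject to
#' `params`) and reports one peak per maximum. The raw span of a peak is
#' the maximal contiguous run of non-zero signal containing the apex;
#' trimming ([trim_peak()]) subsequently narrows it to the region of the
#' most probable 3' end, making results insensitive to the raw-span
#' convention for well-formed peaks. Prominence is the apex height minus
#' the higher of the two flanking minima (walking outward from the apex
#' until a strictly higher point or the track end is met); it is the score
#' later fed to the IDR model.
#'
#' @param track A [coverage_track()].
#' @param params A [peak_params()].
#' @return A data.frame with one row per peak: `contig`, `strand`, `start`,
#'   `end` (1-based, inclusive), `apex`, `height`, `prominence`,
#'   `replicate`. Zero rows for a flat track.
#' @export
call_raw_peaks <- function(track, params = peak_params()) {
  stopifnot(inherits(track, "CoverageTrack"))
  v <- track$values
  apexes <- local_maxima(v)
  apexes <- apexes[v[apexes] >= params$min_height & v[apexes] > 0]
  empty <- data.frame(contig = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      apex = integer(0), height = numeric(0),
                      prominence = numeric(0), replicate = character(0),
                      stringsAsFactors = FALSE)
  if (length(apexes) == 0L) return(empty)
  prom <- vapply(apexes, function(a) prominence_at(v, a), numeric(1))
  if (params$min_distance > 1L && length(apexes) > 1L) {
    keep <- enforce_min_distance(apexes, v[apexes], params$min_distance)
    apexes <- apexes[keep]
    prom <- prom[keep]
  }
  spans <- t(vapply(apexes, function(a) nonzero_span(v, a), integer(2)))
  data.frame(contig = track$contig, strand = track$strand,
             start = spans[, 1], end = spans[, 2],
             apex = as.integer(apexes), height = v[apexes],
             prominence = prom, replicate = track$label,
             stringsAsFactors = FALSE)
}

prominence_at <- function(v, a) {
  h <- v[a]
  lmin <- h
  i <- a - 1L
  while (i >= 1L && v[i] <= h) {
    if (v[i] < lmin) lmin <- v[i]
    i <- i - 1L
  }
  if (i < 1L) lmin <- min(lmin, 0)  # track edge: base level 0
  rmin <- h
  i <- a + 1L
  while (i <= length(v) && v[i] <= h) {
    if (v[i] < rmin) rmin <- v[i]
    i <- i + 1L
  }
  if (i > length(v)) rmin <- min(rmin, 0)
  h - max(lmin, rmin)
}

nonzero_span <- function(v, a) {
  s <- a
  while (s > 1L && v[s - 1L] > 0) s <- s - 1L
  e <- a
  while (e < length(v) && v[e + 1L] > 0) e <- e + 1L
  c(s, e)
}

# Greedy highest-first selection, scipy-style: drop any apex within
# min_distance of an already-kept higher apex.
enforce_min_distance <- function(apexes, heights, min_distance) {
  ord <- order(-heights, apexes)
  keep <- logical(length(apexes))
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(apexes[i] - taken) >= min_distance)) {
      keep[i] <- TRUE
      taken <- c(taken, apexes[i])
    }
  }
  keep
}

#' Trim a coverage profile to the most probable 3' end
#'
#' Implements the 10%-of-total rule: with `S = sum(profile)` and threshold
#' `trim_fraction * S`, positions are removed from each end of the profile,
#' moving inward, while the position's signal is strictly below the
#' threshold. Trimming stops at the first retained position and never
#' removes the apex, so the result is always non-empty. Idempotent.
#'
#' @param profile Numeric vector of per-position signal over the peak span.
#' @param apex Index of the peak maximum within `profile`.
#' @param trim_fraction Threshold fraction (default 0.10).
#' @return Integer vector `c(from, to)`: the retained index range within
#'   `profile`.
#' @export
trim_profile <- function(profile, apex, trim_fraction = 0.10) {
  stopifnot(length(profile) >= 1L, apex >= 1L, apex <= length(profile))
  thr <- trim_fraction * sum(profile)
  from <- 1L
  while (from < apex && profile[from] < thr) from <- from + 1L
  to <- length(profile)
  while (to > apex && profile[to] < thr) to <- to - 1L
  c(from, to)
}

#' @rdname trim_profile
#' @param peak One-row peak data.frame from [call_raw_peaks()].
#' @param track The [coverage_track()] the peak was called on.
#' @return For `trim_peak`: the peak row with `start`/`end` narrowed.
#' @export
trim_peak <- function(peak, track, trim_fraction = 0.10) {
  profile <- track$values[peak$start:peak$end]
  kept <- trim_profile(profile, peak$apex - peak$start + 1L, trim_fraction)
  new_start <- peak$start + kept[1] - 1L
  peak$end <- peak$start + kept[2] - 1L
  peak$start <- new_start
  peak
}

#' Call and trim peaks for one replicate track
#'
#' Convenience wrapper: [call_raw_peaks()] followed by [trim_peak()] on
#' every row.
#' @inheritParams call_raw_peaks
#' @return Trimmed peak data.frame.
#' @export
call_peaks <- function(track, params = peak_params()) {
  pk <- call_raw_peaks(track, params)
  if (nrow(pk) == 0L) return(pk)
  for (i in seq_len(nrow(pk))) {
    pk[i, ] <- trim_peak(pk[i, ], track, params$trim_fraction)
  }
  pk
}

#' Summit of a peak region from cross-replicate mean signal
#'
#' The reported position of a stable 3' RNA end is the highest point of the
#' peak across all replicates: the argmax of the per-position mean signal
#' over the region. Ties at the maximum are broken toward the most
#' downstream position in transcription direction — the largest coordinate
#' on `+`, the smallest on `-`.
#'
#' @param means Numeric vector: per-position cross-replicate mean signal
#'   over the region.
#' @param strand `"+"` or `"-"`.
#' @return Index (1-based, within `means`) of the summit.
#' @export
peak_summit <- function(means, strand) {
  stopifnot(length(means) >= 1L, strand %in% c("+", "-"))
  m <- max(means)
  tied <- which(means == m)
  if (strand == "+") tied[length(tied)] else tied[1]
}
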