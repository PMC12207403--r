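#' Termination efficiency at a 3' RNA end
#'
#' Termination efficiency measures the fraction of transcripts that end at
#' a site rather than reading through, estimated from the drop in matched
#' RNA-seq coverage across the summit:
#' \deqn{T = \frac{u - d}{u} \cdot 100\%}
#' Coverage is taken in 13-nt windows upstream and downstream of the
#' summit, excluding the three positions closest to the termination site
#' on each side, so `u` is the mean over the remaining 10 upstream
#' positions (summit-13 .. summit-4 in transcription direction) and `d`
#' the mean over the 10 downstream positions (summit+4 .. summit+13);
#' windows are mirrored on the `-` strand. Means are computed on the
#' replicate-averaged coverage of all supplied RNA-seq tracks. The
#' estimate is reported only where `u` meets the minimum upstream
#' coverage (`u >= threshold`, default 0.25 RPM), excluding regions with
#' locally disturbed RNA-seq signal. `T` may be negative when coverage
#' rises across the site (`readthrough_gain`); such values are reported
#' as-is rather than clamped, since clamping would hide processing
#' artifacts.
#'
#' @param rnaseq_tracks List of [coverage_track()]s, one per replicate,
#'   same contig and strand, depth-normalized.
#' @param summit Summit position (1-based).
#' @param strand `"+"` or `"-"`.
#' @param threshold Minimum mean upstream coverage for an evaluable
#'   estimate (signal units; default 0.25 RPM).
#' @return A list of class `efficiency_result`: `u`, `d`, `T` (percent, or
#'   `NA` when not evaluable), `evaluable`, `readthrough_gain`, `reason`
#'   (`NA`, `"low_upstream_coverage"` or `"window_out_of_bounds"`).
#' @export
#' @examples
#' up <- c(rep(8, 20), rep(2, 20))
#' tr <- coverage_track("c", "+", up)
#' termination_efficiency(list(tr), summit = 20, strand = "+")$T  # 75
termination_efficiency <- function(rnaseq_tracks, summit, strand,
                                   threshold = 0.25) {
  if (inherits(rnaseq_tracks, "CoverageTrack")) {
    rnaseq_tracks <- list(rnaseq_tracks)
  }
  stopifnot(length(rnaseq_tracks) >= 1L, strand %in% c("+", "-"))
  len <- track_length(rnaseq_tracks[[1]])
  res <- function(u = NA_real_, d = NA_real_, T = NA_real_,
                  evaluable = FALSE, reason = NA_character_) {
    structure(list(u = u, d = d, T = T, evaluable = evaluable,
                   readthrough_gain = isTRUE(evaluable) && !is.na(T) &&
                     T < 0,
                   reason = reason, threshold = threshold),
              class = "efficiency_result")
  }
  if (summit - 13L < 1L || summit + 13L > len) {
    return(res(reason = "window_out_of_bounds"))
  }
  if (strand == "+") {
    up_idx <- (summit - 13L):(summit - 4L)
    dn_idx <- (summit + 4L):(summit + 13L)
  } else {
    up_idx <- (summit + 4L):(summit + 13L)
    dn_idx <- (summit - 13L):(summit - 4L)
  }
  avg <- Reduce(`+`, lapply(rnaseq_tracks, `[[`, "values")) /
    length(rnaseq_tracks)
  u <- mean(avg[up_idx])
  d <- mean(avg[dn_idx])
  if (u < threshold) {
    return(res(u = u, d = d, reason = "low_upstream_coverage"))
  }
  res(u = u, d = d, T = (u - d) / u * 100, evaluable = TRUE)
}

#' @export
print.efficiency_result <- function(x, ...) {
  if (x$evaluable) {
    cat(sprintf("T = %.2f%% (u = %.3g, d = %.3g)%s\n", x$T, x$u, x$d,
                if (x$readthrough_gain) " [readthrough_gain]" else ""))
  } else {
    cat(sprintf("not evaluable (%s)\n", x$reason))
  }
  invisible(x)
}
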