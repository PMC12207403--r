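#' Per-strand coverage track
#'
#' A `CoverageTrack` holds the dense, depth-normalized signal of one genomic
#' strand of one contig: for Term-seq input this is the coverage by read 5'
#' ends (marking RNA 3' termini), for matched RNA-seq input the full-read
#' coverage. Values are per-base, non-negative, in signal units such as CPM
#' (counts per million mapped reads). Reverse-strand tracks are stored in
#' genomic (left-to-right) coordinates; transcription direction is resolved
#' where it matters (summit tie-breaks, efficiency windows), never by
#' reversing the array.
#'
#' @param contig Contig (chromosome/replicon) identifier.
#' @param strand `"+"` or `"-"`.
#' @param values Numeric vector of non-negative per-base signal; its length
#'   is the contig length.
#' @param label Replicate or sample label.
#'
#' @return An object of class `CoverageTrack`: a list with elements
#'   `contig`, `strand`, `values`, `label`.
#' @export
#' @examples
#' tr <- coverage_track("chr", "+", c(0, 0, 5, 1, 0))
#' track_length(tr)
coverage_track <- function(contig, strand, values, label = "track") {
  stopifnot(is.character(contig), length(contig) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-', got: ", strand)
  }
  values <- as.numeric(values)
  if (anyNA(values)) stop("coverage values contain NA")
  if (any(values < 0)) {
    stop("coverage values must be non-negative (found ",
         sum(values < 0), " negative values)")
  }
  structure(
    list(contig = contig, strand = strand, values = values,
         label = as.character(label)),
    class = "CoverageTrack"
  )
}

#' @rdname coverage_track
#' @param x A `CoverageTrack`.
#' @export
track_length <- function(x) length(x$values)

#' @export
print.CoverageTrack <- function(x, ...) {
  nz <- sum(x$values > 0)
  cat(sprintf("CoverageTrack %s(%s) [%s]: %d bp, %d non-zero, max %.4g\n",
              x$contig, x$strand, x$label, track_length(x), nz,
              if (nz) max(x$values) else 0))
  invisible(x)
}

track_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bw", "bigwig")) "BigWig"
  else if (ext %in% c("bg", "bedgraph", "bdg")) "bedGraph"
  else stop("unrecognized coverage format (expect .bw/.bigwig or ",
            ".bedgraph/.bg/.bdg): ", path)
}

#' Read strand-specific coverage tracks
#'
#' Reads a bigWig or bedGraph file into dense [coverage_track()] objects,
#' one per contig. bigWig carries no strand field, so strand is encoded by
#' file pairing — one file per strand per replicate — and supplied here as
#' an argument (the pipeline wrappers use configurable `.fwd`/`.rev`
#' suffixes). Positions absent from the file are zero. bedGraph is accepted
#' as a plain-text dialect interchangeable with bigWig.
#'
#' @param path A bigWig (`.bw`/`.bigwig`) or bedGraph
#'   (`.bedgraph`/`.bg`/`.bdg`) file.
#' @param strand Strand the file encodes, `"+"` or `"-"`.
#' @param seqlengths Optional named vector of contig lengths. Required for
#'   bedGraph if tracks must extend past the last covered interval (e.g.
#'   when a genome is supplied); bigWig files carry their own lengths.
#' @param contigs Optional character vector restricting which contigs are
#'   returned.
#' @param label Replicate/sample label attached to each track.
#'
#' @return Named list of `CoverageTrack`, one per contig.
#' @seealso [write_track()], [cpm_normalize()]
#' @export
read_track <- function(path, strand, seqlengths = NULL, contigs = NULL,
                       label = basename(path)) {
  if (!file.exists(path)) stop("cannot read coverage file: ", path)
  fmt <- track_format(path)
  gr <- rtracklayer::import(path, format = fmt)
  if (length(gr) && any(gr$score < 0)) {
    stop("negative coverage values in ", path,
         " (coverage tracks must be non-negative)")
  }
  sl <- GenomeInfoDb::seqlengths(gr)
  if (!is.null(seqlengths)) {
    sl[names(seqlengths)] <- seqlengths
  }
  contig_names <- names(sl)
  if (length(contig_names) == 0L || all(is.na(sl))) {
    contig_names <- unique(as.character(GenomeInfoDb::seqnames(gr)))
  }
  if (!is.null(contigs)) contig_names <- intersect(contig_names, contigs)
  out <- list()
  for (ctg in contig_names) {
    sub <- gr[as.character(GenomeInfoDb::seqnames(gr)) == ctg]
    len <- sl[[ctg]]
    if (is.null(len) || is.na(len)) {
      len <- if (length(sub)) max(BiocGenerics::end(sub)) else 0L
    }
    vals <- numeric(len)
    if (length(sub)) {
      if (max(BiocGenerics::end(sub)) > len) {
        stop("interval beyond contig length for ", ctg, " in ", path)
      }
      for (i in seq_along(sub)) {
        vals[BiocGenerics::start(sub)[i]:BiocGenerics::end(sub)[i]] <-
          sub$score[i]
      }
    }
    out[[ctg]] <- coverage_track(ctg, strand, vals, label)
  }
  out
}

#' Write coverage tracks
#'
#' Writes a set of [coverage_track()] objects (all from the same strand
#' file) to bigWig or bedGraph. Runs of equal value are merged into single
#' intervals and zero runs are omitted, so `read_track(write_track(x))`
#' reproduces the interval representation exactly.
#'
#' @param tracks A single `CoverageTrack` or list of them (one per contig).
#' @param path Output path; format chosen from the extension as in
#'   [read_track()].
#' @return `path`, invisibly.
#' @export
write_track <- function(tracks, path) {
  if (inherits(tracks, "CoverageTrack")) tracks <- list(tracks)
  contigs <- vapply(tracks, `[[`, character(1), "contig")
  if (anyDuplicated(contigs)) {
    stop("duplicate contigs in track set: ",
         paste(unique(contigs[duplicated(contigs)]), collapse = ", "))
  }
  sl <- vapply(tracks, track_length, integer(1))
  names(sl) <- contigs
  pieces <- lapply(tracks, function(tr) {
    r <- rle(tr$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    GenomicRanges::GRanges(
      seqnames = rep(tr$contig, sum(keep)),
      ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
      score = r$values[keep]
    )
  })
  gr <- do.call(c, unname(pieces))
  GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = track_format(path))
  invisible(path)
}

#' Scale coverage to counts per million
#'
#' Utility scaling raw per-base counts to CPM given the library's total
#' mapped-read count. The pipeline accepts pre-normalized input (tracks are
#' expected to be depth-normalized upstream); this helper is for users
#' starting from raw counts.
#'
#' @param tracks A `CoverageTrack` or list of them.
#' @param total_count Total mapped reads in the library (> 0).
#' @return Tracks with each value multiplied by `1e6 / total_count`, same
#'   shape as the input.
#' @export
cpm_normalize <- function(tracks, total_count) {
  if (!is.numeric(total_count) || length(total_count) != 1L ||
      total_count <= 0) {
    stop("total_count must be a single positive number")
  }
  one <- function(tr) {
    tr$values <- tr$values * (1e6 / total_count)
    tr
  }
  if (inherits(tracks, "CoverageTrack")) one(tracks) else lapply(tracks, one)
}
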