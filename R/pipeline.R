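#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase contig sequences; names
#'   are truncated at the first whitespace.
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(dna))
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}

# Replicate-averaged coverage, keyed [[strand]][[contig]].
mean_tracks <- function(track_list) {
  out <- list()
  for (st in c("+", "-")) {
    contigs <- unique(unlist(lapply(track_list, function(tl) {
      names(tl[[st]])
    })))
    out[[st]] <- stats::setNames(lapply(contigs, function(ctg) {
      vals <- Reduce(`+`, lapply(track_list, function(tl) {
        tl[[st]][[ctg]]$values
      })) / length(track_list)
      coverage_track(ctg, st, vals, label = "mean")
    }), contigs)
  }
  out
}

#' Identify stable 3' RNA ends from replicate Term-seq coverage
#'
#' The first pipeline command: per-replicate, per-strand peak calling
#' with relaxed settings and 10% end trimming ([call_peaks()]), followed
#' by the pairwise-replicate IDR reproducibility filter
#' ([filter_reproducible()]); optionally attaches termination efficiency
#' at every summit from matched RNA-seq coverage
#' ([termination_efficiency()]). With `out_dir`, writes the narrowPeak
#' file, a per-comparison IDR table (TSV), a sidecar TSV with the
#' efficiency columns, and a machine-readable run manifest (parameters,
#' package version, seed).
#'
#' @param term_tracks Term-seq 5'-end coverage: list over replicates of
#'   track sets keyed `[[strand]][[contig]]` (at least 2 replicates).
#' @param rnaseq_tracks Optional matched RNA-seq coverage, same layout.
#' @param peak_parms A [peak_params()].
#' @param config A [reproducibility_config()].
#' @param min_upstream Minimum mean upstream RNA-seq coverage for an
#'   evaluable efficiency (RPM).
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in the manifest; the find step itself is
#'   deterministic.
#' @return List: `regions` (stable ends with efficiency columns when
#'   RNA-seq given), `pairs` (per-comparison IDR tables), `mean_term`
#'   (replicate-averaged Term-seq coverage, used by [merge_pots()]).
#' @export
find_stable_rna_ends <- function(term_tracks, rnaseq_tracks = NULL,
                                 peak_parms = peak_params(),
                                 config = reproducibility_config(),
                                 min_upstream = 0.25,
                                 out_dir = NULL, seed = 1L) {
  if (length(term_tracks) < 2L) {
    stop("find_stable_rna_ends requires at least 2 replicates (got ",
         length(term_tracks), ")")
  }
  peak_list <- lapply(term_tracks, function(tl) {
    pieces <- list()
    for (st in c("+", "-")) {
      for (ctg in names(tl[[st]])) {
        pieces[[paste(st, ctg)]] <- call_peaks(tl[[st]][[ctg]],
                                               peak_parms)
      }
    }
    do.call(rbind, pieces)
  })
  res <- filter_reproducible(peak_list, term_tracks, config)
  regions <- res$regions
  if (!is.null(rnaseq_tracks) && nrow(regions) > 0L) {
    eff <- lapply(seq_len(nrow(regions)), function(i) {
      trs <- lapply(rnaseq_tracks, function(tl) {
        tl[[regions$strand[i]]][[regions$contig[i]]]
      })
      trs <- trs[!vapply(trs, is.null, logical(1))]
      if (length(trs) == 0L) {
        return(list(T = NA_real_, u = NA_real_, d = NA_real_,
                    evaluable = FALSE))
      }
      termination_efficiency(trs, regions$summit[i], regions$strand[i],
                             threshold = min_upstream)
    })
    regions$efficiency <- vapply(eff, function(e) e$T, numeric(1))
    regions$eff_u <- vapply(eff, function(e) e$u, numeric(1))
    regions$eff_d <- vapply(eff, function(e) e$d, numeric(1))
    regions$eff_evaluable <- vapply(eff, function(e) isTRUE(e$evaluable),
                                    logical(1))
  }
  out <- list(regions = regions, pairs = res$pairs,
              mean_term = mean_tracks(term_tracks))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_narrowpeak(regions, file.path(out_dir, "stable_ends.narrowPeak"))
    utils::write.table(regions, file.path(out_dir, "stable_ends.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(res$pairs)) {
      pair_tab <- do.call(rbind, lapply(names(res$pairs), function(nm) {
        cbind(comparison = nm, res$pairs[[nm]])
      }))
      utils::write.table(pair_tab, file.path(out_dir, "idr_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- list(
      command = "find_stable_rna_ends",
      package = "termseqr",
      version = as.character(utils::packageVersion("termseqr")),
      n_replicates = length(term_tracks),
      rnaseq = !is.null(rnaseq_tracks),
      idr_threshold = config$idr_threshold,
      min_no_comp = config$min_no_comp,
      threshold_on = config$threshold_on,
      trim_fraction = peak_parms$trim_fraction,
      min_height = peak_parms$min_height,
      min_distance = peak_parms$min_distance,
      min_upstream = min_upstream,
      seed = seed)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Merge, annotate and report POTs across samples
#'
#' The second pipeline command: merges stable 3' RNA ends from one or
#' more [find_stable_rna_ends()] runs into POTs ([merge_pots()]),
#' attaches gene context, BED overlaps, efficiency and the two
#' terminator-calling protocols ([annotate_pots()]), optionally applies
#' the intrinsic-terminator atlas selection ([atlas_filter()]), and
#' writes the annotation TSV.
#'
#' @param find_results List of results from [find_stable_rna_ends()]
#'   (one per sample).
#' @param genome Named contig sequences ([read_genome_fasta()]).
#' @param features Optional feature table ([read_annotation()]).
#' @param bed_paths Optional named BED paths.
#' @param rnaseq_tracks Optional RNA-seq coverage for POT-level
#'   efficiency: either pooled tracks keyed `[[strand]][[contig]]` or a
#'   per-replicate list of such sets (averaged internally).
#' @param protocols Subset of `c("genome", "local")`; terminator calling
#'   is skipped for protocols not listed.
#' @param config A [terminator_config()].
#' @param atlas Apply [atlas_filter()] to the annotated table.
#' @param labels Sample labels.
#' @param out_path Optional TSV output path.
#' @return The annotated POT data.frame (filtered when `atlas = TRUE`).
#' @export
annotate_stable_ends <- function(find_results, genome, features = NULL,
                                 bed_paths = NULL, rnaseq_tracks = NULL,
                                 protocols = c("genome", "local"),
                                 config = terminator_config(),
                                 atlas = FALSE,
                                 labels = paste0("sample",
                                                 seq_along(find_results)),
                                 out_path = NULL) {
  genome_contigs <- names(genome)
  used <- unique(unlist(lapply(find_results, function(fr) {
    fr$regions$contig
  })))
  if (length(setdiff(used, genome_contigs))) {
    stop("contigs in stable-end tables absent from genome: ",
         paste(setdiff(used, genome_contigs), collapse = ", "))
  }
  pots <- merge_pots(lapply(find_results, `[[`, "regions"),
                     lapply(find_results, `[[`, "mean_term"),
                     labels = labels)
  if (!is.null(rnaseq_tracks) &&
      !any(c("+", "-") %in% names(rnaseq_tracks))) {
    rnaseq_tracks <- mean_tracks(rnaseq_tracks)
  }
  ann <- annotate_pots(pots, genome, features = features,
                       bed_paths = bed_paths,
                       rnaseq_tracks = rnaseq_tracks,
                       protocols = protocols, config = config)
  if (atlas) {
    if (is.null(features)) {
      stop("atlas filtering requires a gene annotation")
    }
    cds <- features[features$type == "CDS", , drop = FALSE]
    ann <- atlas_filter(ann, cds)
  }
  if (!is.null(out_path)) write_annotation_table(ann, out_path)
  ann
}

#' Load per-strand replicate coverage files
#'
#' File-pairing convention for strandless formats: each replicate is a
#' pair of files, forward strand and reverse strand, passed as two
#' parallel vectors.
#'
#' @param fwd_paths,rev_paths Equal-length vectors of coverage files
#'   (bigWig or bedGraph), one pair per replicate.
#' @param seqlengths Optional named contig lengths (see [read_track()]).
#' @param labels Replicate labels.
#' @return Track list keyed `[[replicate]][[strand]][[contig]]`, as
#'   consumed by [find_stable_rna_ends()].
#' @export
read_track_set <- function(fwd_paths, rev_paths, seqlengths = NULL,
                           labels = paste0("rep",
                                           seq_along(fwd_paths))) {
  stopifnot(length(fwd_paths) == length(rev_paths))
  sets <- lapply(seq_along(fwd_paths), function(r) {
    list("+" = read_track(fwd_paths[r], "+", seqlengths = seqlengths,
                          label = labels[r]),
         "-" = read_track(rev_paths[r], "-", seqlengths = seqlengths,
                          label = labels[r]))
  })
  # bedGraph carries no contig-length table, so replicates may infer
  # different lengths from their last covered interval; pad every track
  # of a contig to the common maximum so positions stay aligned
  lens <- list()
  for (tl in sets) {
    for (st in c("+", "-")) {
      for (ctg in names(tl[[st]])) {
        lens[[ctg]] <- max(lens[[ctg]] %||% 0L,
                           track_length(tl[[st]][[ctg]]))
      }
    }
  }
  lapply(sets, function(tl) {
    for (st in c("+", "-")) {
      for (ctg in names(tl[[st]])) {
        tr <- tl[[st]][[ctg]]
        pad <- lens[[ctg]] - track_length(tr)
        if (pad > 0L) {
          tr$values <- c(tr$values, numeric(pad))
          tl[[st]][[ctg]] <- tr
        }
      }
    }
    tl
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
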