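#' Read gene annotation from GFF3/GTF
#'
#' Imports a GFF3 or GTF annotation into a plain feature table.
#' For the "gene" universe used in nearest-gene reporting, `gene`
#' features are preferred; when absent (common in bacterial RefSeq
#' dumps), `CDS` features stand in.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or GTF (`.gtf`) file.
#' @return Data.frame: `contig`, `start`, `end` (1-based inclusive),
#'   `strand`, `type`, `id`.
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  fmt <- if (ext == "gtf") "GTF" else "GFF3"
  gr <- rtracklayer::import(path, format = fmt)
  md <- S4Vectors::mcols(gr)
  pick_id <- function(cols) {
    for (cn in cols) {
      if (cn %in% colnames(md)) {
        v <- as.character(md[[cn]])
        if (any(!is.na(v))) return(v)
      }
    }
    rep(NA_character_, length(gr))
  }
  id <- pick_id(c("ID", "gene_id", "Name", "locus_tag"))
  data.frame(contig = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             type = as.character(md$type),
             id = id, stringsAsFactors = FALSE)
}

#' Gene context of one POT
#'
#' Reports all annotation features overlapping the POT position (any
#' type, distance 0) and the nearest genes upstream and downstream with
#' their distances, separately for the sense (same) and antisense
#' (opposite) strand. Upstream/downstream are resolved in the
#' transcription direction of the POT's strand. Distance is the 0-based
#' gap between the POT and the gene's nearest boundary — the number of
#' bases strictly between them — so 0 means overlapping or immediately
#' adjacent.
#'
#' @param contig,strand,summit POT location.
#' @param features Feature table from [read_annotation()].
#' @return One-row data.frame: `overlapping` (comma-joined `type:id`),
#'   `up_gene`, `up_dist`, `dn_gene`, `dn_dist`, and antisense analogues
#'   `as_up_gene`, `as_up_dist`, `as_dn_gene`, `as_dn_dist`.
#' @export
annotate_genes <- function(contig, strand, summit, features) {
  ctg <- features[features$contig == contig, , drop = FALSE]
  if (nrow(ctg) == 0L) {
    warning("contig ", contig, " not present in annotation")
  }
  ov <- ctg[summit >= ctg$start & summit <= ctg$end, , drop = FALSE]
  overlapping <- if (nrow(ov)) {
    paste(paste0(ov$type, ":", ov$id), collapse = ",")
  } else NA_character_
  gene_types <- if (any(ctg$type == "gene")) "gene" else "CDS"
  genes <- ctg[ctg$type %in% gene_types, , drop = FALSE]
  nearest <- function(gset, direction) {
    # direction "up": gene lies upstream of the summit in transcription
    # direction of `strand`; overlap counts for both with distance 0.
    if (nrow(gset) == 0L) return(list(NA_character_, NA_real_))
    # 0-based gap to the nearest boundary: bases strictly between the
    # summit and the gene; 0 when overlapping or immediately adjacent
    if (strand == "+") {
      d <- if (direction == "up") summit - gset$end - 1L else
        gset$start - summit - 1L
    } else {
      d <- if (direction == "up") gset$start - summit - 1L else
        summit - gset$end - 1L
    }
    inside <- summit >= gset$start & summit <= gset$end
    d[inside] <- 0
    ok <- which(d >= 0)
    if (length(ok) == 0L) return(list(NA_character_, NA_real_))
    k <- ok[which.min(d[ok])]
    list(gset$id[k], d[k])
  }
  sense <- genes[genes$strand == strand, , drop = FALSE]
  anti <- genes[genes$strand == setdiff(c("+", "-"), strand), ,
                drop = FALSE]
  up <- nearest(sense, "up"); dn <- nearest(sense, "dn")
  # antisense genes transcribe the other way; up/down still reported
  # relative to the POT's own transcription direction
  aup <- nearest(anti, "up"); adn <- nearest(anti, "dn")
  data.frame(overlapping = overlapping,
             up_gene = up[[1]], up_dist = up[[2]],
             dn_gene = dn[[1]], dn_dist = dn[[2]],
             as_up_gene = aup[[1]], as_up_dist = aup[[2]],
             as_dn_gene = adn[[1]], as_dn_dist = adn[[2]],
             stringsAsFactors = FALSE)
}

#' Overlaps between POTs and custom BED feature sets
#'
#' For each BED file, attaches to each POT the names of overlapping
#' records (comma-joined) and a logical flag. Overlap is evaluated at the
#' POT position under BED half-open semantics (a POT at a record's end
#' coordinate does not overlap).
#'
#' @param pots Data.frame with `contig`, `strand`, `summit`.
#' @param bed_paths Named character vector/list of BED file paths; names
#'   become column prefixes.
#' @param stranded Logical (recycled per set): require matching strand.
#' @return `pots` with `<set>_overlap` (logical) and `<set>_names`
#'   columns appended per set.
#' @export
annotate_bed_overlaps <- function(pots, bed_paths, stranded = TRUE) {
  if (is.null(names(bed_paths)) || any(!nzchar(names(bed_paths)))) {
    names(bed_paths) <- tools::file_path_sans_ext(
      basename(unlist(bed_paths)))
  }
  stranded <- rep_len(stranded, length(bed_paths))
  for (k in seq_along(bed_paths)) {
    gr <- tryCatch(
      rtracklayer::import(bed_paths[[k]], format = "BED"),
      error = function(e) stop("malformed BED file ", bed_paths[[k]],
                               ": ", conditionMessage(e)))
    nm <- names(bed_paths)[k]
    hitnames <- character(nrow(pots))
    flag <- logical(nrow(pots))
    for (i in seq_len(nrow(pots))) {
      sel <- as.character(GenomeInfoDb::seqnames(gr)) == pots$contig[i] &
        pots$summit[i] >= BiocGenerics::start(gr) &
        pots$summit[i] <= BiocGenerics::end(gr)
      if (stranded[k]) {
        sel <- sel & as.character(BiocGenerics::strand(gr)) %in%
          c(pots$strand[i], "*")
      }
      if (any(sel)) {
        flag[i] <- TRUE
        ids <- if (!is.null(gr$name)) gr$name[sel] else
          as.character(which(sel))
        hitnames[i] <- paste(ids, collapse = ",")
      } else hitnames[i] <- NA_character_
    }
    pots[[paste0(nm, "_overlap")]] <- flag
    pots[[paste0(nm, "_names")]] <- hitnames
  }
  pots
}

#' Write stable 3' RNA ends as narrowPeak
#'
#' Serializes stable-end regions in the BED6+4 narrowPeak layout:
#' `score = min(1000, round(-125 * log2(min_idr)))`, `signalValue` = mean
#' coverage at the summit, `pValue = -1` (unused), `qValue =
#' -log10(min_idr)`, `peak` = summit offset from the region start.
#' Coordinates are converted to BED's 0-based half-open convention at
#' write time; rows are ordered by (contig, start, strand).
#'
#' @param regions Data.frame from [filter_reproducible()]`$regions`.
#' @param path Output path.
#' @param name_prefix Prefix for auto-generated IDs.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(regions, path, name_prefix = "pot") {
  r <- regions[order(regions$contig, regions$start, regions$strand), ,
               drop = FALSE]
  idr <- pmax(r$min_idr, 1e-300)
  df <- data.frame(
    chrom = r$contig,
    chromStart = r$start - 1L,
    chromEnd = r$end,
    name = sprintf("%s_%d", name_prefix, seq_len(nrow(r))),
    score = pmin(1000, round(-125 * log2(idr))),
    strand = r$strand,
    signalValue = r$mean_height,
    pValue = -1,
    qValue = -log10(idr),
    peak = r$summit - r$start,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_narrowpeak
#' @return For `read_narrowpeak`: a regions data.frame (1-based
#'   coordinates, `summit` reconstructed from the peak offset).
#' @export
read_narrowpeak <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "chromStart", "chromEnd",
                                        "name", "score", "strand",
                                        "signalValue", "pValue", "qValue",
                                        "peak"))
  data.frame(contig = df$chrom,
             strand = df$strand,
             start = df$chromStart + 1L,
             end = df$chromEnd,
             summit = df$chromStart + df$peak + 1L,
             min_idr = 10^(-df$qValue),
             name = df$name,
             mean_height = df$signalValue,
             stringsAsFactors = FALSE)
}

#' Merge stable 3' RNA ends across samples into POTs
#'
#' Overlapping stable-end regions from multiple samples (same strand)
#' are unioned by single-linkage interval merge; each merged region is
#' summarized by one POT — the position with the highest cross-sample
#' mean coverage, ties broken toward the most downstream position in
#' transcription direction. The merge is associative and independent of
#' sample order.
#'
#' @param regions_list List (one per sample) of regions data.frames
#'   ([filter_reproducible()]`$regions` or [read_narrowpeak()] output).
#' @param mean_tracks_list List (per sample) of replicate-averaged
#'   Term-seq coverage, keyed `[[strand]][[contig]]`.
#' @param labels Sample labels (default `sample1..N`).
#' @return Data.frame: `contig`, `strand`, `start`, `end`, `summit`,
#'   `min_idr`, `n_samples`, `samples` (comma-joined supporting labels),
#'   `mean_height`.
#' @export
merge_pots <- function(regions_list, mean_tracks_list,
                       labels = paste0("sample", seq_along(regions_list))) {
  stopifnot(length(regions_list) >= 1L,
            length(mean_tracks_list) == length(regions_list))
  all_r <- do.call(rbind, lapply(seq_along(regions_list), function(k) {
    r <- regions_list[[k]]
    if (nrow(r) == 0L) return(NULL)
    r$sample <- labels[k]
    r[, c("contig", "strand", "start", "end", "min_idr", "sample")]
  }))
  empty <- data.frame(contig = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      summit = integer(0), min_idr = numeric(0),
                      n_samples = integer(0), samples = character(0),
                      mean_height = numeric(0), stringsAsFactors = FALSE)
  if (is.null(all_r) || nrow(all_r) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(all_r$contig,
                               IRanges::IRanges(all_r$start, all_r$end),
                               strand = all_r$strand)
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  rows <- lapply(seq_along(merged), function(k) {
    ii <- sh[qh == k]
    ctg <- as.character(GenomeInfoDb::seqnames(merged))[k]
    st <- as.character(BiocGenerics::strand(merged))[k]
    s <- BiocGenerics::start(merged)[k]; e <- BiocGenerics::end(merged)[k]
    means <- Reduce(`+`, lapply(mean_tracks_list, function(tl) {
      tr <- tl[[st]][[ctg]]
      if (is.null(tr)) numeric(e - s + 1L) else tr$values[s:e]
    })) / length(mean_tracks_list)
    summit <- s + peak_summit(means, st) - 1L
    supp <- sort(unique(all_r$sample[ii]))
    data.frame(contig = ctg, strand = st, start = s, end = e,
               summit = summit, min_idr = min(all_r$min_idr[ii]),
               n_samples = length(supp),
               samples = paste(supp, collapse = ","),
               mean_height = means[summit - s + 1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Sequence context of a terminator call with the POT base capitalized:
# A tract + hairpin + 15-nt tail, lowercase, the POT position uppercase
# when it falls inside the context.
pot_context <- function(call) {
  ctx <- tolower(paste0(call$a_tract, call$hairpin_seq,
                        call$u_tract))
  # distance 0 = POT at the hairpin's 3'-most paired base
  pos <- nchar(call$a_tract) + nchar(call$hairpin_seq) + call$distance
  if (pos >= 1L && pos <= nchar(ctx)) {
    substr(ctx, pos, pos) <- toupper(substr(ctx, pos, pos))
  }
  ctx
}

ANNOTATION_HEADER <- "# termseqr annotation table v1"

#' Annotate merged POTs
#'
#' Attaches biological context to a merged POT table: optional
#' termination efficiency from pooled RNA-seq coverage, gene context
#' ([annotate_genes()]), custom BED overlaps ([annotate_bed_overlaps()]),
#' and the two intrinsic-terminator protocols ([call_genome_scan()],
#' [call_local_scan()]), each independently switchable. `is_intrinsic`
#' is true when either protocol calls a terminator.
#'
#' @param pots Data.frame from [merge_pots()].
#' @param genome Named list/vector of contig sequences.
#' @param features Optional feature table from [read_annotation()].
#' @param bed_paths Optional named BED paths for
#'   [annotate_bed_overlaps()].
#' @param rnaseq_tracks Optional RNA-seq coverage keyed
#'   `[[strand]][[contig]]` (pooled replicate average) for
#'   [termination_efficiency()].
#' @param protocols Character subset of `c("genome", "local")`.
#' @param config A [terminator_config()].
#' @param min_upstream Efficiency evaluability threshold (RPM).
#' @return The annotated POT data.frame (one row per POT; terminator
#'   columns are `NA` where no call was made).
#' @export
annotate_pots <- function(pots, genome, features = NULL,
                          bed_paths = NULL, rnaseq_tracks = NULL,
                          protocols = c("genome", "local"),
                          config = terminator_config(),
                          min_upstream = 0.25) {
  n <- nrow(pots)
  ann <- pots
  if (!is.null(rnaseq_tracks)) {
    eff <- lapply(seq_len(n), function(i) {
      tr <- rnaseq_tracks[[pots$strand[i]]][[pots$contig[i]]]
      if (is.null(tr)) {
        return(list(T = NA_real_, u = NA_real_, d = NA_real_,
                    evaluable = FALSE))
      }
      termination_efficiency(list(tr), pots$summit[i], pots$strand[i],
                             threshold = min_upstream)
    })
    ann$efficiency <- vapply(eff, function(e) e$T, numeric(1))
    ann$eff_u <- vapply(eff, function(e) e$u, numeric(1))
    ann$eff_d <- vapply(eff, function(e) e$d, numeric(1))
    ann$eff_evaluable <- vapply(eff, function(e) isTRUE(e$evaluable),
                                logical(1))
  } else {
    ann$efficiency <- NA_real_
    ann$eff_u <- NA_real_
    ann$eff_d <- NA_real_
    ann$eff_evaluable <- FALSE
  }
  if (!is.null(features)) {
    gc <- do.call(rbind, lapply(seq_len(n), function(i) {
      annotate_genes(pots$contig[i], pots$strand[i], pots$summit[i],
                     features)
    }))
    ann <- cbind(ann, gc)
  } else {
    ann$overlapping <- NA_character_
    ann$up_gene <- NA_character_; ann$up_dist <- NA_real_
    ann$dn_gene <- NA_character_; ann$dn_dist <- NA_real_
    ann$as_up_gene <- NA_character_; ann$as_up_dist <- NA_real_
    ann$as_dn_gene <- NA_character_; ann$as_dn_dist <- NA_real_
  }
  term_cols <- function(prefix) {
    ann[[paste0(prefix, "_scan")]] <<- rep(FALSE, n)
    for (cn in c("distance", "dg", "score", "ts", "confidence")) {
      ann[[paste0(prefix, "_", cn)]] <<- rep(NA_real_, n)
    }
    for (cn in c("hairpin", "structure")) {
      ann[[paste0(prefix, "_", cn)]] <<- rep(NA_character_, n)
    }
  }
  term_cols("genome"); term_cols("local")
  ann$seq_context <- rep(NA_character_, n)
  fill <- function(i, prefix, call) {
    if (nrow(call) == 0L) return()
    ann[i, paste0(prefix, "_scan")] <<- TRUE
    ann[i, paste0(prefix, "_distance")] <<- call$distance
    ann[i, paste0(prefix, "_dg")] <<- call$free_energy
    ann[i, paste0(prefix, "_score")] <<- call$hairpin_score
    ann[i, paste0(prefix, "_ts")] <<- call$tail_score
    ann[i, paste0(prefix, "_confidence")] <<- call$confidence
    ann[i, paste0(prefix, "_hairpin")] <<- call$hairpin_seq
    ann[i, paste0(prefix, "_structure")] <<- call$structure
    if (is.na(ann$seq_context[i])) {
      ann$seq_context[i] <<- pot_context(call)
    }
  }
  for (i in seq_len(n)) {
    if ("genome" %in% protocols) {
      fill(i, "genome",
           call_genome_scan(pots$contig[i], pots$strand[i],
                            pots$summit[i], genome, config))
    }
    if ("local" %in% protocols) {
      fill(i, "local",
           call_local_scan(pots$contig[i], pots$strand[i],
                           pots$summit[i], genome, config))
    }
  }
  ann$is_intrinsic <- ann$genome_scan | ann$local_scan
  if (!is.null(bed_paths)) {
    ann <- annotate_bed_overlaps(ann, bed_paths)
  }
  ann
}

#' Write the annotation table
#'
#' Tab-separated, one row per POT, constant column set, versioned header
#' comment. `NA` is written literally.
#'
#' @param ann Data.frame from [annotate_pots()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(ANNOTATION_HEADER, con)
  suppressWarnings(utils::write.table(ann, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE,
                                      na = "NA"))
  invisible(path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = "NA")
}
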