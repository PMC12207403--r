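#' Simulation configuration
#'
#' Defines the synthetic study conditions: a random-background bacterial
#' genome with CDS genes, intrinsic terminators planted downstream of a
#' subset of genes, replicate Term-seq 5'-end coverage concentrated at
#' each planted termination position (with small positional jitter),
#' per-replicate irreproducible noise peaks, and RNA-seq coverage that
#' steps down by each terminator's planted efficiency.
#'
#' @param genome_length Genome size in bp.
#' @param n_genes Number of CDS genes (placed in equal slots, alternating
#'   strands).
#' @param n_terminators Number of planted terminators (one per gene,
#'   first `n_terminators` genes).
#' @param replicates Number of biological replicates R (>= 2).
#' @param noise_peaks Irreproducible noise peaks per replicate
#'   (positions drawn independently per replicate).
#' @param depth_scale Expected Term-seq read count at a planted
#'   terminator of unit expression; also the RNA-seq per-base coverage
#'   scale.
#' @param frac_weak_utract Fraction of terminators planted with a weak
#'   (3-U, dispersed) U tract, detectable by the local scan only.
#' @param frac_reproducible Fraction of terminators present in all
#'   replicates; the rest appear in a single replicate.
#' @param seed Integer seed fixing all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 60000L, n_genes = 55L,
                       n_terminators = 50L, replicates = 3L,
                       noise_peaks = 100L, depth_scale = 50,
                       frac_weak_utract = 0.1, frac_reproducible = 1,
                       seed = 42L) {
  stopifnot(replicates >= 2L, n_terminators <= n_genes,
            genome_length >= n_genes * 1000L)
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes),
                 n_terminators = as.integer(n_terminators),
                 replicates = as.integer(replicates),
                 noise_peaks = as.integer(noise_peaks),
                 depth_scale = depth_scale,
                 frac_weak_utract = frac_weak_utract,
                 frac_reproducible = frac_reproducible,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Build one terminator cassette in transcription orientation:
# 5 A's + C spacer | GC-rich stem | A-rich loop | revcomp stem | U tract.
# The C spacer and the T following the stem make the planted stem
# outward-inextensible, so hairpin enumeration recovers it exactly.
make_cassette <- function(stem_len, loop_len, gc, u_count, u_offset) {
  stem5 <- paste(sample(c("G", "C", "A", "T"), stem_len, replace = TRUE,
                        prob = c(gc / 2, gc / 2, (1 - gc) / 2,
                                 (1 - gc) / 2)), collapse = "")
  stem3 <- revcomp(stem5)
  loop <- paste0("G", strrep("A", loop_len - 1L))
  utract <- rep("C", 10L)
  if (u_count >= 4L) {
    utract[seq_len(min(u_count, 10L))] <- "T"
  } else {
    utract[c(1L, 5L, 9L)[seq_len(u_count)]] <- "T"
  }
  utract <- paste(utract, collapse = "")
  cassette <- paste0("AAAAAC", stem5, loop, stem3, utract)
  hlen <- 2L * stem_len + loop_len
  list(seq = cassette,
       hairpin_lo = 7L,                 # tx index of hairpin start
       hairpin_hi = 6L + hlen,          # tx index of hairpin end
       term_idx = 6L + hlen + u_offset, # tx index of the planted 3' end
       hlen = hlen)
}

#' Simulate a genome with planted terminators
#'
#' Generates a random-background genome, places CDS genes in equal slots
#' with alternating strands, and inserts a terminator cassette
#' (GC-rich hairpin + U tract) 20-60 nt downstream of the CDS for the
#' first `n_terminators` genes. Each terminator gets an expression factor
#' (log2-uniform in `[-1, 1.5]`, shared across replicates so replicate
#' prominence ranks correlate) and a planted termination efficiency
#' (uniform 20-95%). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector, one contig
#'   `"synth1"`), `features` (CDS table as in [read_annotation()]),
#'   `truth` (one row per planted terminator: positions, strand, U
#'   count, expression factor, efficiency, reproducibility flag), and
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$genome_length
  contig <- "synth1"
  gseq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                collapse = "")
  slot <- n %/% config$n_genes
  features <- data.frame(contig = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         type = character(0), id = character(0),
                         stringsAsFactors = FALSE)
  truth_rows <- list()
  for (g in seq_len(config$n_genes)) {
    slot_start <- (g - 1L) * slot + 1L
    glen <- sample(300:700, 1L)
    strand <- if (g %% 2L == 1L) "+" else "-"
    has_term <- g <= config$n_terminators
    # leave room downstream (tx direction) for cassette + readthrough
    if (strand == "+") {
      gs <- slot_start + 60L
      ge <- gs + glen - 1L
    } else {
      ge <- slot_start + slot - 60L
      gs <- ge - glen + 1L
    }
    features <- rbind(features, data.frame(
      contig = contig, start = gs, end = ge, strand = strand,
      type = "CDS", id = sprintf("gene%03d", g),
      stringsAsFactors = FALSE))
    if (!has_term) next
    stem_len <- sample(6:10, 1L)
    loop_len <- sample(4:6, 1L)
    weak <- stats::runif(1) < config$frac_weak_utract
    u_count <- if (weak) 3L else sample(6:9, 1L)
    u_offset <- sample(5:8, 1L)
    offset <- sample(20:60, 1L)
    cas <- make_cassette(stem_len, loop_len, gc = 0.8, u_count, u_offset)
    clen <- nchar(cas$seq)
    if (strand == "+") {
      cstart <- ge + offset  # genomic pos of tx index 1
      substr(gseq, cstart, cstart + clen - 1L) <- cas$seq
      hp_lo <- cstart + cas$hairpin_lo - 1L
      hp_hi <- cstart + cas$hairpin_hi - 1L
      term_pos <- cstart + cas$term_idx - 1L
    } else {
      cend <- gs - offset    # genomic pos of tx index 1
      cstart <- cend - clen + 1L
      substr(gseq, cstart, cend) <- revcomp(cas$seq)
      hp_lo <- cend - cas$hairpin_hi + 1L
      hp_hi <- cend - cas$hairpin_lo + 1L
      term_pos <- cend - cas$term_idx + 1L
    }
    reproducible <- stats::runif(1) < config$frac_reproducible
    truth_rows[[g]] <- data.frame(
      id = sprintf("term%03d", g), contig = contig, strand = strand,
      gene_id = sprintf("gene%03d", g),
      hairpin_start = hp_lo, hairpin_end = hp_hi,
      term_pos = term_pos, stem = stem_len, loop = loop_len,
      u_count = u_count, weak_utract = weak,
      expr = 2^stats::runif(1, -1, 1.5),
      efficiency = round(stats::runif(1, 20, 95), 1),
      reproducible = reproducible, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  genome <- stats::setNames(gseq, contig)
  list(genome = genome, features = features, truth = truth,
       config = config)
}

# Term-seq 5'-end count weights over term_pos +/- 2 nt.
JITTER_W <- c(0.05, 0.15, 0.60, 0.15, 0.05)

#' Simulate replicate Term-seq and RNA-seq coverage
#'
#' For each replicate (with its own depth factor, uniform 0.8-1.2x, to
#' exercise depth normalization): Term-seq 5'-end counts at each
#' reproducible terminator are Poisson with mean
#' `depth_scale * expr * weight` spread over the termination position
#' +/- 2 nt; irreproducible noise peaks (Poisson counts of low,
#' replicate-varying mean) are placed at independent random positions
#' per replicate, kept clear of planted sites; RNA-seq coverage is
#' piecewise constant at `depth_scale * expr` from the gene start to the
#' termination position, dropping by the planted efficiency for 300 nt
#' of readthrough, with per-base Poisson noise. All tracks are
#' CPM-normalized per replicate and assay. Deterministic given the
#' config seed.
#'
#' @param sim Output of [simulate_genome()].
#' @return List with `term` and `rnaseq`: each a list over replicates of
#'   track sets keyed `[[strand]][[contig]]` ([coverage_track()]s), plus
#'   `totals` (raw read totals per replicate).
#' @export
simulate_coverage <- function(sim) {
  config <- sim$config
  set.seed(config$seed + 1000L)
  n <- config$genome_length
  contig <- names(sim$genome)[1]
  truth <- sim$truth
  feats <- sim$features
  reps <- config$replicates
  depth_factor <- stats::runif(reps, 0.8, 1.2)
  single_rep <- ifelse(truth$reproducible, NA_integer_,
                       sample.int(reps, nrow(truth), replace = TRUE))
  term_tracks <- vector("list", reps)
  rna_tracks <- vector("list", reps)
  totals <- list(term = numeric(reps), rnaseq = numeric(reps))
  for (r in seq_len(reps)) {
    tv <- list("+" = numeric(n), "-" = numeric(n))
    rv <- list("+" = numeric(n), "-" = numeric(n))
    for (i in seq_len(nrow(truth))) {
      if (!truth$reproducible[i] && single_rep[i] != r) next
      st <- truth$strand[i]
      lambda <- config$depth_scale * truth$expr[i] * depth_factor[r]
      pos <- truth$term_pos[i] + (-2:2)
      cnt <- stats::rpois(5L, lambda * JITTER_W)
      ok <- pos >= 1L & pos <= n
      tv[[st]][pos[ok]] <- tv[[st]][pos[ok]] + cnt[ok]
    }
    # noise peaks: independent positions per replicate, low varying depth
    for (st in c("+", "-")) {
      zones <- truth$term_pos[truth$strand == st]
      placed <- 0L
      while (placed < config$noise_peaks %/% 2L) {
        p <- sample.int(n - 20L, 1L) + 10L
        if (length(zones) && any(abs(p - zones) <= 40L)) next
        cnt <- stats::rpois(1L, stats::runif(1, 1, 6) * depth_factor[r])
        tv[[st]][p] <- tv[[st]][p] + cnt + 1L
        placed <- placed + 1L
      }
    }
    # RNA-seq: transcript coverage with a step down at each terminator
    for (g in seq_len(nrow(feats))) {
      st <- feats$strand[g]
      ti <- which(truth$gene_id == feats$id[g])
      level <- config$depth_scale * depth_factor[r] *
        if (length(ti)) truth$expr[ti] else 2^stats::runif(1, -1, 1.5)
      if (length(ti)) {
        tp <- truth$term_pos[ti]
        t_eff <- truth$efficiency[ti] / 100
      } else {
        tp <- if (st == "+") feats$end[g] + 40L else feats$start[g] - 40L
        t_eff <- 1
      }
      if (st == "+") {
        body <- feats$start[g]:min(tp, n)
        rt <- if (tp < n) (tp + 1L):min(tp + 300L, n) else integer(0)
      } else {
        body <- max(tp, 1L):feats$end[g]
        rt <- if (tp > 1L) max(tp - 300L, 1L):(tp - 1L) else integer(0)
      }
      rv[[st]][body] <- rv[[st]][body] + stats::rpois(length(body), level)
      if (length(rt)) {
        rv[[st]][rt] <- rv[[st]][rt] +
          stats::rpois(length(rt), level * (1 - t_eff))
      }
    }
    totals$term[r] <- sum(tv[["+"]]) + sum(tv[["-"]])
    totals$rnaseq[r] <- sum(rv[["+"]]) + sum(rv[["-"]])
    lab <- sprintf("rep%d", r)
    term_tracks[[r]] <- lapply(stats::setNames(c("+", "-"), c("+", "-")),
      function(st) {
        tr <- coverage_track(contig, st, tv[[st]], label = lab)
        stats::setNames(list(cpm_normalize(tr, totals$term[r])), contig)
      })
    rna_tracks[[r]] <- lapply(stats::setNames(c("+", "-"), c("+", "-")),
      function(st) {
        tr <- coverage_track(contig, st, rv[[st]], label = lab)
        stats::setNames(list(cpm_normalize(tr, totals$rnaseq[r])), contig)
      })
  }
  list(term = term_tracks, rnaseq = rna_tracks, totals = totals)
}

#' Write simulation inputs to files
#'
#' Emits the same file formats the pipeline consumes: genome FASTA, CDS
#' GFF3, per-replicate per-strand bedGraph coverage (Term-seq and
#' RNA-seq), and the truth table as TSV.
#'
#' @param sim Output of [simulate_genome()].
#' @param cov Output of [simulate_coverage()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, cov, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  fasta <- file.path(dir, "genome.fa")
  dna <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(dna, fasta)
  paths$genome <- fasta
  gff <- file.path(dir, "annotation.gff3")
  gr <- GenomicRanges::GRanges(
    sim$features$contig,
    IRanges::IRanges(sim$features$start, sim$features$end),
    strand = sim$features$strand, type = sim$features$type,
    ID = sim$features$id,
    phase = ifelse(sim$features$type == "CDS", 0L, NA_integer_))
  rtracklayer::export(gr, gff, format = "GFF3")
  paths$annotation <- gff
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth <- truth_path
  sfx <- c("+" = "fwd", "-" = "rev")
  for (assay in c("term", "rnaseq")) {
    for (r in seq_along(cov[[assay]])) {
      for (st in c("+", "-")) {
        p <- file.path(dir, sprintf("%s_rep%d.%s.bedgraph", assay, r,
                                    sfx[[st]]))
        write_track(cov[[assay]][[r]][[st]], p)
        paths[[sprintf("%s_rep%d_%s", assay, r, sfx[[st]])]] <- p
      }
    }
  }
  invisible(paths)
}
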