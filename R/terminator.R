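#' Terminator-calling configuration
#'
#' @param distance_range Allowed distance (bases, transcription direction)
#'   from the hairpin's 3'-most paired base to the POT for an intrinsic
#'   call, default `c(0, 10)`.
#' @param dg_local Free-energy ceiling (kcal/mol) a local-scan call must
#'   satisfy (default -3).
#' @param dg_genome Free-energy ceiling for genome-scan calls (default 0:
#'   the canonical scan relies on its structural criteria, the energy
#'   check only rejects stem-loops not predicted to form at all).
#' @param upstream_nt,downstream_nt Local-scan window around the POT
#'   (default 80 nt upstream to 30 nt downstream, transcription
#'   direction), chosen to cover the expected span and position of an
#'   intrinsic terminator relative to its POT.
#' @param backend Folding backend for [hairpin_free_energy()].
#' @param genome_params,local_params Hairpin presets for the two
#'   protocols.
#' @return A `terminator_config` list.
#' @export
terminator_config <- function(distance_range = c(0L, 10L),
                              dg_local = -3,
                              dg_genome = 0,
                              upstream_nt = 80L, downstream_nt = 30L,
                              backend = c("internal", "rnafold"),
                              genome_params = canonical_hairpin_params(),
                              local_params = permissive_hairpin_params()) {
  stopifnot(length(distance_range) == 2L,
            distance_range[1] <= distance_range[2])
  structure(list(distance_range = as.integer(distance_range),
                 dg_local = dg_local, dg_genome = dg_genome,
                 upstream_nt = as.integer(upstream_nt),
                 downstream_nt = as.integer(downstream_nt),
                 backend = match.arg(backend),
                 genome_params = genome_params,
                 local_params = local_params),
            class = "terminator_config")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    chartr("Uu", "Tt", s))))
}

# Extract the sequence around a summit in transcription direction:
# `up` bases upstream through `down` bases downstream. Returns the
# sequence (5'->3' of the transcribed strand), the genomic span actually
# used, the summit's 1-based position within the sequence, and whether
# the window was truncated at a contig edge.
tx_window <- function(genome, contig, strand, summit, up, down) {
  seq_full <- genome[[contig]]
  len <- nchar(seq_full)
  if (strand == "+") {
    gs <- summit - up; ge <- summit + down
  } else {
    gs <- summit - down; ge <- summit + up
  }
  truncated <- gs < 1L || ge > len
  gs <- max(1L, gs); ge <- min(len, ge)
  s <- substr(seq_full, gs, ge)
  if (strand == "-") s <- revcomp(s)
  pot_local <- if (strand == "+") summit - gs + 1L else ge - summit + 1L
  list(seq = s, gstart = gs, gend = ge, pot_local = pot_local,
       truncated = truncated)
}

# Map local (transcription-direction) coordinates within a tx_window back
# to genomic coordinates.
local_to_genomic <- function(win, strand, lpos) {
  if (strand == "+") win$gstart + lpos - 1L else win$gend - lpos + 1L
}

empty_terminator_call <- function() {
  data.frame(protocol = character(0), contig = character(0),
             strand = character(0), summit = integer(0),
             hairpin_gstart = integer(0), hairpin_gend = integer(0),
             stem = integer(0), loop = integer(0),
             hairpin_seq = character(0), structure = character(0),
             hairpin_score = numeric(0), tail_score = numeric(0),
             confidence = numeric(0), free_energy = numeric(0),
             distance = integer(0), a_tract = character(0),
             u_tract = character(0), truncated = logical(0),
             stringsAsFactors = FALSE)
}

# Annotate enumerated candidates with distance to POT, U-window status,
# tail score and confidence, all in local coordinates of `win`.
candidate_features <- function(cands, win, params) {
  if (nrow(cands) == 0L) {
    cands$distance <- integer(0); cands$uwin <- logical(0)
    cands$ts <- numeric(0); cands$confidence <- numeric(0)
    return(cands)
  }
  n <- nchar(win$seq)
  cands$distance <- win$pot_local - cands$end
  cands$uwin <- vapply(cands$end, function(e) {
    u_window_ok(substr(win$seq, e + 1L, min(n, e + params$uwin_size)),
                params)
  }, logical(1))
  cands$ts <- vapply(cands$end, function(e) {
    as.numeric(tail_score(substr(win$seq, e + 1L, min(n, e + 15L))))
  }, numeric(1))
  cands$confidence <- hairpin_confidence(cands$score, cands$ts)
  cands
}

build_call <- function(protocol, cand, win, contig, strand, summit, dg) {
  n <- nchar(win$seq)
  a_tract <- substr(win$seq, max(1L, cand$start - 10L), cand$start - 1L)
  u_tract <- substr(win$seq, cand$end + 1L, min(n, cand$end + 10L))
  g1 <- local_to_genomic(win, strand, cand$start)
  g2 <- local_to_genomic(win, strand, cand$end)
  data.frame(protocol = protocol, contig = contig, strand = strand,
             summit = as.integer(summit),
             hairpin_gstart = min(g1, g2), hairpin_gend = max(g1, g2),
             stem = cand$stem, loop = cand$loop,
             hairpin_seq = cand$sequence, structure = cand$structure,
             hairpin_score = cand$score, tail_score = cand$ts,
             confidence = cand$confidence, free_energy = dg,
             distance = as.integer(cand$distance),
             a_tract = a_tract, u_tract = u_tract,
             truncated = win$truncated, stringsAsFactors = FALSE)
}

#' Genome-scan intrinsic terminator protocol
#'
#' Assigns the nearest canonical-criteria terminator hairpin upstream of a
#' POT: stem >= 4 contiguous pairs, loop 3-13 nt, stem-loop <= 59 nt, and
#' a U-rich window immediately after the stem ([canonical_hairpin_params()]).
#' The hairpin's 3'-most paired base must lie within `distance_range`
#' upstream of the POT (default 0-10 nt); among qualifying hairpins the
#' nearest wins, ties going to the lower (stronger) hairpin score. The
#' call reports hairpin sequence/structure, A tract (10 nt upstream of
#' the stem), U tract (10 nt downstream), tail score and free energy.
#' Externally produced terminator predictions can be substituted via
#' `terminators` (see [read_terminator_bed()]), in which case only
#' predictions whose hairpin 3' base satisfies the distance rule are
#' assigned.
#'
#' @param contig,strand,summit POT location.
#' @param genome Named list/vector of contig sequences (DNA).
#' @param config A [terminator_config()].
#' @param terminators Optional data.frame of precomputed terminator spans
#'   (columns `contig`, `strand`, `start`, `end`, genomic 1-based).
#' @return One-row data.frame describing the call, or a zero-row frame
#'   when no terminator qualifies.
#' @export
call_genome_scan <- function(contig, strand, summit, genome,
                             config = terminator_config(),
                             terminators = NULL) {
  dmin <- config$distance_range[1]; dmax <- config$distance_range[2]
  params <- config$genome_params
  if (!is.null(terminators)) {
    tt <- terminators[terminators$contig == contig &
                        terminators$strand == strand, , drop = FALSE]
    if (nrow(tt) == 0L) return(empty_terminator_call())
    end3 <- if (strand == "+") tt$end else tt$start
    dist <- if (strand == "+") summit - end3 else end3 - summit
    ok <- dist >= dmin & dist <= dmax
    if (!any(ok)) return(empty_terminator_call())
    tt <- tt[ok, , drop = FALSE]; dist <- dist[ok]
    pick <- which.min(dist)
    span <- abs(tt$end[pick] - tt$start[pick]) + 1L
    win <- tx_window(genome, contig, strand, summit,
                     up = dmax + span + 15L, down = 5L)
    cands <- enumerate_hairpins(win$seq, params)
    cands <- candidate_features(cands, win, params)
    want_end <- win$pot_local - dist[pick]
    cands <- cands[cands$end == want_end, , drop = FALSE]
    if (nrow(cands) == 0L) return(empty_terminator_call())
    cand <- cands[which.min(cands$score), , drop = FALSE]
    dg <- hairpin_free_energy(cand, backend = config$backend)
    return(build_call("genome_scan", cand, win, contig, strand, summit,
                      dg))
  }
  win <- tx_window(genome, contig, strand, summit,
                   up = dmax + params$max_len, down = max(0L, -dmin))
  cands <- enumerate_hairpins(win$seq, params)
  cands <- candidate_features(cands, win, params)
  cands <- cands[cands$distance >= dmin & cands$distance <= dmax &
                   cands$uwin, , drop = FALSE]
  if (nrow(cands) == 0L) return(empty_terminator_call())
  # a canonical-criteria terminator must at least be predicted to form:
  # stem-loops failing the energy check are not candidates at all
  cands$dg <- vapply(seq_len(nrow(cands)), function(k) {
    hairpin_free_energy(cands[k, ], backend = config$backend)
  }, numeric(1))
  cands <- cands[cands$dg <= config$dg_genome, , drop = FALSE]
  if (nrow(cands) == 0L) return(empty_terminator_call())
  cands <- cands[order(cands$distance, cands$score), , drop = FALSE]
  cand <- cands[1, , drop = FALSE]
  build_call("genome_scan", cand, win, contig, strand, summit, cand$dg)
}

#' Local-scan intrinsic terminator protocol
#'
#' Scans the sequence from `upstream_nt` (80) upstream to `downstream_nt`
#' (30) downstream of the POT with permissive hairpin parameters
#' ([permissive_hairpin_params()]: min stem 4, loop 4-20, stem-loop <= 40,
#' >= 1 U in the 6 nt after the stem), to catch real terminators with
#' weak or absent U tracts that the canonical genome scan misses.
#' Candidates within the allowed POT distance are ranked by confidence,
#' then hairpin score, then tail score (evaluated in that order); the
#' best candidate's free energy must be at or below `dg_local`
#' (-3 kcal/mol) for a call. Windows truncated at a contig edge are
#' scanned as-is and flagged.
#'
#' @inheritParams call_genome_scan
#' @return One-row call data.frame, or a zero-row frame.
#' @export
call_local_scan <- function(contig, strand, summit, genome,
                            config = terminator_config()) {
  dmin <- config$distance_range[1]; dmax <- config$distance_range[2]
  params <- config$local_params
  win <- tx_window(genome, contig, strand, summit,
                   up = config$upstream_nt, down = config$downstream_nt)
  cands <- enumerate_hairpins(win$seq, params)
  cands <- candidate_features(cands, win, params)
  cands <- cands[cands$distance >= dmin & cands$distance <= dmax &
                   cands$uwin, , drop = FALSE]
  if (nrow(cands) == 0L) return(empty_terminator_call())
  cands <- cands[order(-cands$confidence, cands$score, cands$ts), ,
                 drop = FALSE]
  cand <- cands[1, , drop = FALSE]
  dg <- hairpin_free_energy(cand, backend = config$backend)
  if (dg > config$dg_local) return(empty_terminator_call())
  build_call("local_scan", cand, win, contig, strand, summit, dg)
}

#' Read externally produced terminator predictions
#'
#' Adapter for substituting an external genome-wide terminator
#' prediction (e.g. from a dedicated scanner) for the internal canonical
#' scan: a BED file of hairpin spans, strand in column 6.
#'
#' @param path BED file path.
#' @return Data.frame with `contig`, `start`, `end` (1-based, inclusive),
#'   `strand`, `name`.
#' @export
read_terminator_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(contig = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             name = if (!is.null(gr$name)) gr$name else
               rep(NA_character_, length(gr)),
             stringsAsFactors = FALSE)
}

# Gap (bases, >= 0) from a summit to the 3' boundary of the nearest
# same-strand CDS lying upstream of it; 0 if the summit is inside a CDS;
# Inf when the contig/strand has no CDS upstream.
cds_downstream_distance <- function(contig, strand, summit, cds) {
  cc <- cds[cds$contig == contig & cds$strand == strand, , drop = FALSE]
  if (nrow(cc) == 0L) return(Inf)
  inside <- summit >= cc$start & summit <= cc$end
  if (any(inside)) return(0L)
  gap <- if (strand == "+") summit - cc$end else cc$start - summit
  gap <- gap[gap >= 0]
  if (length(gap) == 0L) Inf else min(gap)
}

#' Select high-confidence intrinsic terminators
#'
#' Applies the atlas-level selection rules to an annotated POT table:
#' a POT is retained iff (i) it lies within `max_cds_distance` (200 nt)
#' downstream of the nearest same-strand CDS, (ii) it carries an
#' intrinsic call from either protocol, and (iii) when the call comes
#' solely from the local scan, the hairpin free energy is at or below
#' `dg_local_only` (-8 kcal/mol) — the permissive protocol must clear a
#' stricter thermodynamic bar when unconfirmed by the canonical scan.
#'
#' @param ann Data.frame with columns `contig`, `strand`, `summit`,
#'   `genome_scan`, `local_scan` (logicals) and `local_dg` (free energy
#'   of the local-scan call, NA when absent); typically from
#'   [annotate_pots()].
#' @param cds Data.frame of CDS features (`contig`, `start`, `end`,
#'   `strand`), e.g. from [read_annotation()].
#' @param max_cds_distance Maximum distance downstream of a CDS (nt).
#' @param dg_local_only Free-energy ceiling for local-scan-only calls.
#' @return The retained rows of `ann`, with a `cds_distance` column added.
#' @export
atlas_filter <- function(ann, cds, max_cds_distance = 200,
                         dg_local_only = -8) {
  if (nrow(ann) == 0L) {
    ann$cds_distance <- numeric(0)
    return(ann)
  }
  ann$cds_distance <- vapply(seq_len(nrow(ann)), function(i) {
    cds_downstream_distance(ann$contig[i], ann$strand[i], ann$summit[i],
                            cds)
  }, numeric(1))
  called <- ann$genome_scan | ann$local_scan
  dg_ok <- ann$genome_scan |
    (ann$local_scan & !is.na(ann$local_dg) & ann$local_dg <= dg_local_only)
  keep <- ann$cds_distance <= max_cds_distance & called & dg_ok
  out <- ann[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
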