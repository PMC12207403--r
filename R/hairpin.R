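NT_LEVELS <- c("A", "C", "G", "U", "N")

# DNA/RNA-agnostic: T is mapped to U on entry everywhere.
nt_codes <- function(sequence) {
  x <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  bad <- !x %in% NT_LEVELS
  if (any(bad)) {
    stop("non-nucleotide characters in sequence: ",
         paste(unique(x[bad]), collapse = ", "))
  }
  x
}

# Watson-Crick plus G.U wobble.
PAIR_OK <- local({
  m <- matrix(FALSE, 5, 5, dimnames = list(NT_LEVELS, NT_LEVELS))
  for (p in list(c("A", "U"), c("G", "C"), c("G", "U"))) {
    m[p[1], p[2]] <- TRUE
    m[p[2], p[1]] <- TRUE
  }
  m
})

can_pair <- function(a, b) PAIR_OK[a, b]

#' Tail score of the 15 nt downstream of a terminator hairpin
#'
#' Summarizes the U-richness of the tail immediately downstream of a
#' hairpin, weighting U residues closer to the hairpin more heavily. With
#' `x_0 = 1` and `x_n = 0.9 x_{n-1}` when the n-th nucleotide is U (or T),
#' `x_n = 0.6 x_{n-1}` otherwise, the score is `ts = -sum(x_n, n = 1..15)`.
#' Lower scores mean stronger, more hairpin-proximal U tracts; the score
#' is bounded by the all-U and all-non-U geometric sums,
#' `-9 (1 - 0.9^15) <= ts <= -1.5 (1 - 0.6^15)`.
#'
#' @param tail A 15-nt sequence (RNA or DNA alphabet). Shorter tails (at a
#'   contig edge) are padded with `N`, which scores as non-U; the return
#'   value then carries attribute `padded = TRUE`.
#' @return The tail score (negative real).
#' @export
#' @examples
#' tail_score(strrep("U", 15))  # -9 * (1 - 0.9^15)
tail_score <- function(tail) {
  x <- nt_codes(tail)
  padded <- FALSE
  if (length(x) < 15L) {
    x <- c(x, rep("N", 15L - length(x)))
    padded <- TRUE
  }
  if (length(x) > 15L) x <- x[1:15]
  xn <- 1
  total <- 0
  for (n in 1:15) {
    xn <- xn * if (x[n] == "U") 0.9 else 0.6
    total <- total + xn
  }
  ts <- -total
  if (padded) attr(ts, "padded") <- TRUE
  ts
}

#' Hairpin enumeration presets
#'
#' `canonical` mirrors genome-wide intrinsic-terminator search limits:
#' stem of at least 4 paired positions, loop of 3-13 nt, whole stem-loop
#' at most 59 nt, and at least 3 U residues in the 6 nt following the
#' stem. `permissive` mirrors the deliberately relaxed local-scan
#' parameters (min stem 4, loop 4-20, stem-loop at most 40 nt, at least
#' 1 U in the 6 nt after the stem) used when a POT already pins down the
#' search region.
#'
#' @param min_stem Minimum number of contiguous base pairs in the stem.
#' @param min_loop,max_loop Loop length bounds (nt).
#' @param max_len Maximum total stem-loop length (nt).
#' @param uwin_size,uwin_require U-window: require at least `uwin_require`
#'   U residues in the `uwin_size` nt immediately downstream of the stem.
#' @return A `hairpin_params` list.
#' @export
hairpin_params <- function(min_stem = 4L, min_loop = 3L, max_loop = 13L,
                           max_len = 59L, uwin_size = 6L,
                           uwin_require = 3L) {
  stopifnot(min_stem >= 1, min_loop >= 1, max_loop >= min_loop,
            max_len >= 2 * min_stem + min_loop)
  structure(list(min_stem = as.integer(min_stem),
                 min_loop = as.integer(min_loop),
                 max_loop = as.integer(max_loop),
                 max_len = as.integer(max_len),
                 uwin_size = as.integer(uwin_size),
                 uwin_require = as.integer(uwin_require)),
            class = "hairpin_params")
}

#' @rdname hairpin_params
#' @export
canonical_hairpin_params <- function() hairpin_params()

#' @rdname hairpin_params
#' @export
permissive_hairpin_params <- function() {
  hairpin_params(min_stem = 4L, min_loop = 4L, max_loop = 20L,
                 max_len = 40L, uwin_size = 6L, uwin_require = 1L)
}

#' Enumerate maximal stem-loop candidates in a sequence
#'
#' Finds every maximal contiguous stem-loop (Watson-Crick and G.U pairs,
#' no bulges or internal loops) satisfying the preset's stem, loop and
#' length constraints. For each outer pairing the stem is extended inward
#' as far as pairing allows while keeping the loop at or above
#' `min_loop`; a candidate is reported only if its stem cannot also be
#' extended outward within `max_len` (outward-extensible stem-loops are
#' subsumed by their extension). The U-window condition is not applied
#' here — it depends on downstream context and is checked by the calling
#' protocols.
#'
#' @param sequence Nucleotide string (A/C/G/U/T/N).
#' @param params A [hairpin_params()].
#' @return Data.frame with one row per candidate: `start`, `end` (1-based
#'   within `sequence`), `stem`, `loop`, `sequence`, `structure`
#'   (dot-bracket), `score` (from [score_hairpin()]).
#' @export
enumerate_hairpins <- function(sequence, params = hairpin_params()) {
  x <- nt_codes(sequence)
  n <- length(x)
  min_span <- 2L * params$min_stem + params$min_loop
  out_start <- integer(0); out_end <- integer(0)
  out_stem <- integer(0); out_loop <- integer(0)
  if (n >= min_span) {
    for (i in seq_len(n - min_span + 1L)) {
      jlo <- i + min_span - 1L
      jhi <- min(n, i + params$max_len - 1L)
      if (jlo > jhi) next
      for (j in jlo:jhi) {
        if (!PAIR_OK[x[i], x[j]]) next
        s <- 1L
        while (j - i + 1L - 2L * (s + 1L) >= params$min_loop &&
               PAIR_OK[x[i + s], x[j - s]]) {
          s <- s + 1L
        }
        loop <- j - i + 1L - 2L * s
        if (s < params$min_stem || loop > params$max_loop) next
        if (i > 1L && j < n && PAIR_OK[x[i - 1L], x[j + 1L]] &&
            j - i + 3L <= params$max_len) next
        out_start <- c(out_start, i); out_end <- c(out_end, j)
        out_stem <- c(out_stem, s); out_loop <- c(out_loop, loop)
      }
    }
  }
  if (length(out_start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      stem = integer(0), loop = integer(0),
                      sequence = character(0), structure = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  seqs <- vapply(seq_along(out_start), function(k) {
    paste(x[out_start[k]:out_end[k]], collapse = "")
  }, character(1))
  structs <- vapply(seq_along(out_start), function(k) {
    paste0(strrep("(", out_stem[k]), strrep(".", out_loop[k]),
           strrep(")", out_stem[k]))
  }, character(1))
  scores <- vapply(seq_along(out_start), function(k) {
    score_hairpin_at(x, out_start[k], out_end[k], out_stem[k], out_loop[k])
  }, numeric(1))
  data.frame(start = out_start, end = out_end, stem = out_stem,
             loop = out_loop, sequence = seqs, structure = structs,
             score = scores, stringsAsFactors = FALSE)
}

# Pair classes of a contiguous stem, outermost first: "GC", "AU" or "GU".
stem_pair_classes <- function(x, start, end, stem) {
  vapply(seq_len(stem) - 1L, function(k) {
    p <- sort(c(x[start + k], x[end - k]))
    paste(p, collapse = "")
  }, character(1))
}

HAIRPIN_SCORE_CONSTANTS <- c(GC = -2.3, AU = -0.9, GU = 1.3,
                             loop_base = 0.1)

score_hairpin_at <- function(x, start, end, stem, loop,
                             constants = HAIRPIN_SCORE_CONSTANTS) {
  cls <- stem_pair_classes(x, start, end, stem)  # sorted: CG, AU or GU
  per_pair <- constants[c(CG = "GC", AU = "AU", GU = "GU")[cls]]
  sum(per_pair) + loop * constants[["loop_base"]]
}

#' Heuristic hairpin score
#'
#' Additive per-pair approximation of hairpin stability (lower is
#' stronger): each G-C pair contributes `-2.3`, each A-U pair `-0.9`,
#' each G.U wobble `+1.3`, and each loop base `+0.1`. The constants are
#' package defaults, exposed for configuration; the score ranks
#' candidates and is not a free energy.
#'
#' @param candidate One row of the data.frame from [enumerate_hairpins()]
#'   (or a list with `sequence`, `stem`, `loop`).
#' @param constants Named vector with elements `GC`, `AU`, `GU`,
#'   `loop_base`.
#' @return The hairpin score (real; lower = stronger).
#' @export
score_hairpin <- function(candidate, constants = HAIRPIN_SCORE_CONSTANTS) {
  x <- nt_codes(candidate$sequence)
  score_hairpin_at(x, 1L, length(x), candidate$stem, candidate$loop,
                   constants)
}

# Simplified Turner-style dG37 stack energies (kcal/mol). Entry [p, q]:
# outer pair p over inner pair q, pairs written 5'-base first on the
# ascending strand. Watson-Crick values follow the published
# nearest-neighbor set; G.U-containing stacks use representative values.
STACK_DG <- local({
  p <- c("AU", "UA", "CG", "GC", "GU", "UG")
  m <- matrix(NA_real_, 6, 6, dimnames = list(p, p))
  m["AU", ] <- c(-0.93, -1.10, -2.24, -2.08, -0.55, -1.36)
  m["UA", ] <- c(-1.33, -0.93, -2.35, -2.11, -1.00, -1.27)
  m["CG", ] <- c(-2.11, -2.08, -3.26, -2.36, -1.41, -2.11)
  m["GC", ] <- c(-2.35, -2.24, -3.42, -3.26, -1.53, -2.51)
  m["GU", ] <- c(-1.27, -1.36, -2.51, -2.11, -0.50, 1.29)
  m["UG", ] <- c(-1.00, -0.55, -1.53, -1.41, 0.30, -0.50)
  m
})

# Hairpin-loop initiation dG37 by loop size; Jacobson-Stockmayer
# extrapolation beyond 9.
hairpin_loop_dg <- function(loop) {
  init <- c(NA, NA, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)
  if (loop <= 9) init[loop] else 6.4 + 1.75 * 0.6163 * log(loop / 9)
}

#' Hairpin free energy
#'
#' Minimum free energy (kcal/mol, 37 degrees C) of a stem-loop candidate.
#' Two backends: `"internal"` (default) evaluates the candidate's own
#' pairing with a simplified nearest-neighbor model — summed stack
#' energies, hairpin-loop initiation by loop size, and a +0.45 terminal
#' penalty when the outer closing pair is A-U or G.U — and is fully
#' deterministic with no external processes. `"rnafold"` shells out to
#' ViennaRNA's `RNAfold` and returns the MFE of the candidate
#' subsequence under the full Turner model (the subsequence may then fold
#' differently from the candidate's pairing).
#'
#' @param candidate One row from [enumerate_hairpins()].
#' @param backend `"internal"` or `"rnafold"`.
#' @return Free energy in kcal/mol (non-positive for any stable
#'   candidate; positive values mean the stem-loop is not predicted to
#'   form).
#' @export
hairpin_free_energy <- function(candidate,
                                backend = c("internal", "rnafold")) {
  backend <- match.arg(backend)
  if (backend == "rnafold") {
    return(rnafold_mfe(chartr("T", "U", toupper(candidate$sequence))))
  }
  x <- nt_codes(candidate$sequence)
  n <- length(x)
  stem <- candidate$stem
  loop <- candidate$loop
  pair_at <- function(k) paste0(x[k + 1L], x[n - k])  # k = 0-based depth
  dg <- hairpin_loop_dg(loop)
  if (stem >= 2L) {
    for (k in seq_len(stem - 1L) - 1L) {
      dg <- dg + STACK_DG[pair_at(k), pair_at(k + 1L)]
    }
  }
  outer <- pair_at(0L)
  if (outer %in% c("AU", "UA", "GU", "UG")) dg <- dg + 0.45
  dg
}

rnafold_mfe <- function(sequence) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stop("RNAfold binary not found on PATH; use backend = 'internal'")
  }
  out <- system2(exe, args = c("--noPS"), input = sequence,
                 stdout = TRUE, stderr = TRUE)
  line <- out[length(out)]
  m <- regmatches(line, regexpr("\\(\\s*-?[0-9.]+\\)$", line))
  if (length(m) == 0L) {
    stop("could not parse RNAfold output for candidate: ",
         paste(out, collapse = " | "))
  }
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

# U count in the uwin_size nt immediately downstream of the stem.
u_window_ok <- function(downstream_seq, params) {
  if (!nzchar(downstream_seq)) return(params$uwin_require == 0L)
  x <- nt_codes(downstream_seq)
  x <- x[seq_len(min(length(x), params$uwin_size))]
  sum(x == "U") >= params$uwin_require
}

#' Hairpin confidence score
#'
#' Combines the hairpin score and tail score into a single 0-100 scale
#' used to rank local-scan candidates (higher = more terminator-like):
#' `100 * plogis(-(hairpin_score + tail_score + 8) / 4)`. The logistic
#' form and the offset/scale constants are package choices, documented
#' here and configurable; a strong hairpin with a proximal U tract scores
#' above 90, a weak hairpin with no tract below 35.
#'
#' @param hairpin_score From [score_hairpin()].
#' @param ts From [tail_score()].
#' @param offset,scale Logistic calibration constants.
#' @return Confidence in `[0, 100]`.
#' @export
hairpin_confidence <- function(hairpin_score, ts, offset = 8, scale = 4) {
  100 * stats::plogis(-(hairpin_score + ts + offset) / scale)
}
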