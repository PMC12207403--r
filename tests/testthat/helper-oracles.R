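# Independent reference implementations used to check the package's
# algorithms. These deliberately use different code paths (closed forms,
# exhaustive scans) from the implementations they verify.

# Exhaustive local-maximum scan with flank-minima prominence: for every
# position, check it tops a plateau strictly above both neighbours, then
# walk outward for the two flanking minima (track ends count as base
# level 0).
oracle_peaks <- function(v) {
  n <- length(v)
  out <- list()
  for (p in seq_len(n)) {
    if (v[p] <= 0) next
    # plateau start check
    if (p > 1 && v[p - 1] == v[p]) next
    q <- p
    while (q < n && v[q + 1] == v[p]) q <- q + 1
    left_higher <- p > 1 && v[p - 1] > v[p]
    right_higher <- q < n && v[q + 1] > v[p]
    if (left_higher || right_higher) next
    if ((p == 1 || v[p - 1] < v[p]) && (q == n || v[q + 1] < v[p])) {
      flank_min <- function(idx_seq) {
        m <- Inf
        for (i in idx_seq) {
          if (v[i] > v[p]) return(m)   # stopped at higher ground
          m <- min(m, v[i])
        }
        min(m, 0)                      # ran off the track edge
      }
      lmin <- flank_min(rev(seq_len(p - 1)))
      rmin <- flank_min(seq(q + 1, length.out = n - q))
      out[[length(out) + 1]] <- c(apex = p, height = v[p],
                                  prominence = v[p] - max(lmin, rmin))
    }
  }
  if (length(out) == 0) {
    return(data.frame(apex = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  as.data.frame(do.call(rbind, out))
}

# Closed-form statement of the end-inward trimming rule: the retained
# span runs from the leftmost to the rightmost position at or above the
# threshold, clamped to include the apex.
oracle_trim <- function(profile, apex, frac = 0.10) {
  thr <- frac * sum(profile)
  ok <- which(profile >= thr)
  if (length(ok) == 0) return(c(apex, apex))
  c(min(ok, apex), max(ok, apex))
}

# Exhaustive (i, j, s) stem-loop enumeration with explicit maximality
# checks, for sequences up to ~60 nt. Pairing is precomputed as an
# n x n logical matrix so the triple loop stays fast enough for the
# randomized panels.
oracle_hairpins <- function(sequence, params) {
  x <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  n <- length(x)
  pair_set <- c("AU", "UA", "GC", "CG", "GU", "UG")
  P <- matrix(outer(x, x, paste0) %in% pair_set, n, n)
  res <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (j - i + 1 > params$max_len) next
      max_s <- (j - i + 1 - params$min_loop) %/% 2
      if (max_s < 1) next
      for (s in seq_len(max_s)) {
        loop <- j - i + 1 - 2 * s
        if (s < params$min_stem) next
        if (loop < params$min_loop || loop > params$max_loop) next
        paired <- TRUE
        for (k in seq_len(s) - 1L) {
          if (!P[i + k, j - k]) { paired <- FALSE; break }
        }
        if (!paired) next
        # inward maximality
        if (loop - 2 >= params$min_loop && P[i + s, j - s]) next
        # outward maximality
        if (i > 1 && j < n && P[i - 1, j + 1] &&
            j - i + 3 <= params$max_len) next
        res[[length(res) + 1]] <- c(i, j, s, loop)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      stem = integer(0), loop = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, res))
  names(df) <- c("start", "end", "stem", "loop")
  df[order(df$start, df$end), , drop = FALSE]
}

# Direct evaluation of the tail-score recurrence, written as an explicit
# geometric accumulation rather than a loop over a running state.
oracle_tail_score <- function(tail) {
  nts <- strsplit(chartr("Tt", "Uu", toupper(tail)), "")[[1]][1:15]
  mult <- ifelse(nts == "U", 0.9, 0.6)
  -sum(cumprod(mult))
}

# Step tracks with known termination efficiency for efficiency tests.
make_step_track <- function(u_level, d_level, len = 60, summit = 30,
                            strand = "+", contig = "c") {
  v <- numeric(len)
  if (strand == "+") {
    v[1:summit] <- u_level
    v[(summit + 1):len] <- d_level
  } else {
    v[summit:len] <- u_level
    v[1:(summit - 1)] <- d_level
  }
  coverage_track(contig, strand, v)
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
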