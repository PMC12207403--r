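#' Reproducibility-filter configuration
#'
#' @param idr_threshold Peaks must attain an IDR below this value in a
#'   pairwise replicate comparison to count as reproducible there
#'   (default 0.05).
#' @param min_no_comp `M`: minimum number of pairwise comparisons in which
#'   a peak region must be reproducible to be reported (default 1).
#' @param threshold_on Which IDR flavour the threshold applies to:
#'   `"global"` (expected irreproducibility rate at the pair's rank; the
#'   convention of the IDR method this filter follows) or `"local"` (the
#'   pair's own posterior noise probability).
#' @param min_pairs Minimum number of matched peak pairs needed to fit the
#'   copula mixture model for one replicate pair and strand.
#' @return A `reproducibility_config` list.
#' @export
reproducibility_config <- function(idr_threshold = 0.05, min_no_comp = 1L,
                                   threshold_on = c("global", "local"),
                                   min_pairs = 20L) {
  stopifnot(idr_threshold > 0, idr_threshold < 1, min_no_comp >= 1)
  structure(list(idr_threshold = idr_threshold,
                 min_no_comp = as.integer(min_no_comp),
                 threshold_on = match.arg(threshold_on),
                 min_pairs = as.integer(min_pairs)),
            class = "reproducibility_config")
}

#' Match peaks one-to-one across two replicates
#'
#' Pairs overlapping peaks from two replicates on the same contig and
#' strand. Each peak joins at most one pair; competing overlaps are
#' resolved by maximum base overlap, ties by higher joint (summed)
#' prominence, then by leftmost start. Unmatched peaks take no part in the
#' IDR fit.
#'
#' @param peaks_a,peaks_b Peak data.frames from [call_peaks()] for two
#'   replicates (same contig and strand).
#' @return A data.frame with one row per pair: spans and prominence scores
#'   of both members (`start_a`, `end_a`, `score_a`, `idx_a`, and the `_b`
#'   analogues), plus `contig`, `strand`, `overlap`.
#' @export
match_peak_pairs <- function(peaks_a, peaks_b) {
  empty <- data.frame(contig = character(0), strand = character(0),
                      idx_a = integer(0), start_a = integer(0),
                      end_a = integer(0), score_a = numeric(0),
                      idx_b = integer(0), start_b = integer(0),
                      end_b = integer(0), score_b = numeric(0),
                      overlap = integer(0), stringsAsFactors = FALSE)
  if (nrow(peaks_a) == 0L || nrow(peaks_b) == 0L) return(empty)
  ra <- IRanges::IRanges(peaks_a$start, peaks_a$end)
  rb <- IRanges::IRanges(peaks_b$start, peaks_b$end)
  hits <- IRanges::findOverlaps(ra, rb)
  if (length(hits) == 0L) return(empty)
  qa <- S4Vectors::queryHits(hits)
  qb <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(ra[qa], rb[qb]))
  joint <- peaks_a$prominence[qa] + peaks_b$prominence[qb]
  ord <- order(-ov, -joint, pmin(peaks_a$start[qa], peaks_b$start[qb]))
  used_a <- logical(nrow(peaks_a))
  used_b <- logical(nrow(peaks_b))
  keep <- integer(0)
  for (k in ord) {
    if (!used_a[qa[k]] && !used_b[qb[k]]) {
      used_a[qa[k]] <- TRUE
      used_b[qb[k]] <- TRUE
      keep <- c(keep, k)
    }
  }
  keep <- keep[order(peaks_a$start[qa[keep]])]
  data.frame(contig = peaks_a$contig[qa[keep]],
             strand = peaks_a$strand[qa[keep]],
             idx_a = qa[keep], start_a = peaks_a$start[qa[keep]],
             end_a = peaks_a$end[qa[keep]],
             score_a = peaks_a$prominence[qa[keep]],
             idx_b = qb[keep], start_b = peaks_b$start[qb[keep]],
             end_b = peaks_b$end[qb[keep]],
             score_b = peaks_b$prominence[qb[keep]],
             overlap = ov[keep], stringsAsFactors = FALSE)
}

# Marginal CDF of the copula mixture and its numeric pseudo-inverse on a
# monotone grid; the grid spans both components generously.
mixture_quantile <- function(u, pi1, mu, sigma2, n_grid = 4096L) {
  s <- sqrt(sigma2)
  lo <- min(-6, mu - 6 * s)
  hi <- max(6, mu + 6 * s)
  zg <- seq(lo, hi, length.out = n_grid)
  Gg <- pi1 * stats::pnorm(zg, mean = mu, sd = s) +
    (1 - pi1) * stats::pnorm(zg)
  stats::approx(Gg, zg, xout = u, rule = 2, ties = "ordered")$y
}

bvn_log_density <- function(z1, z2, mu, sigma2, rho) {
  s <- sqrt(sigma2)
  a <- (z1 - mu) / s
  b <- (z2 - mu) / s
  -log(2 * pi) - log(sigma2) - 0.5 * log(1 - rho^2) -
    (a^2 - 2 * rho * a * b + b^2) / (2 * (1 - rho^2))
}

#' Fit the IDR copula mixture model on paired prominence scores
#'
#' Models the paired ranks of peak prominences in two replicates as a
#' two-component Gaussian copula mixture: a reproducible component
#' (mixing weight `pi1`, mean shift `mu`, variance `sigma2`, correlation
#' `rho`) and a noise component fixed at the standard bivariate normal
#' with zero correlation. Scores are rank-transformed to empirical
#' quantiles, mapped through the mixture marginal's pseudo-inverse
#' (the copula construction), and the parameters are estimated by EM,
#' recomputing the pseudo-data from the current parameters at every
#' iteration. Convergence: successive log pseudo-likelihood change below
#' `tol` (1e-6) or 500 iterations, whichever first. The procedure is
#' deterministic; ties in scores are broken by average rank.
#'
#' @param pairs Data.frame from [match_peak_pairs()] (columns `score_a`,
#'   `score_b`), or any data.frame with those columns.
#' @param seed Accepted for interface stability; the fit involves no
#'   randomness and the value is unused.
#' @param min_pairs Minimum pair count required to fit (default 20).
#' @param tol,max_iter Convergence tolerance and iteration cap.
#' @return An `idr_model` list: `pi1`, `mu`, `sigma2`, `rho`, `loglik`,
#'   `n_iter`, `converged`.
#' @references The copula mixture follows the irreproducible discovery
#'   rate framework of Li, Brown, Huang & Bickel (2011), Ann. Appl. Stat.
#' @export
fit_idr_model <- function(pairs, seed = 1L, min_pairs = 20L,
                          tol = 1e-6, max_iter = 500L) {
  x <- pairs$score_a
  y <- pairs$score_b
  n <- length(x)
  if (n < min_pairs) {
    stop("too few peak pairs to fit the IDR model (", n, " < ",
         min_pairs, ")")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite prominence scores in IDR input")
  }
  u <- rank(x, ties.method = "average") / (n + 1)
  v <- rank(y, ties.method = "average") / (n + 1)

  pi1 <- 0.5; mu <- 1; sigma2 <- 1; rho <- 0.5
  converged <- FALSE
  iter <- 0L
  ll <- -Inf
  ll_old <- -Inf
  # Each iteration refreshes the copula pseudo-data from the current
  # parameters and takes one EM step; convergence when the log
  # pseudo-likelihood change drops below tol or the parameters
  # stabilize (the pseudo-likelihood is not exactly monotone under the
  # pseudo-data refresh, so parameter stability is checked as well).
  repeat {
    iter <- iter + 1L
    theta_old <- c(pi1, mu, sigma2, rho)
    z1 <- mixture_quantile(u, pi1, mu, sigma2)
    z2 <- mixture_quantile(v, pi1, mu, sigma2)
    l1 <- bvn_log_density(z1, z2, mu, sigma2, rho)
    l0 <- bvn_log_density(z1, z2, 0, 1, 0)
    m <- pmax(l1 + log(pi1), l0 + log(1 - pi1))
    ll <- sum(m + log(exp(l1 + log(pi1) - m) +
                        exp(l0 + log(1 - pi1) - m)))
    post1 <- 1 / (1 + exp(l0 + log(1 - pi1) - l1 - log(pi1)))

    sp <- sum(post1)
    pi1 <- min(max(sp / n, 1e-4), 1 - 1e-4)
    mu <- sum(post1 * (z1 + z2)) / (2 * sp)
    sigma2 <- max(sum(post1 * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * sp),
                  1e-6)
    rho <- sum(post1 * (z1 - mu) * (z2 - mu)) / (sigma2 * sp)
    rho <- min(max(rho, -0.998), 0.998)

    param_delta <- max(abs(c(pi1, mu, sigma2, rho) - theta_old))
    if ((is.finite(ll) && abs(ll - ll_old) < tol) ||
        param_delta < 1e-4) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
  }
  if (!converged) {
    warning("IDR EM did not converge in ", max_iter,
            " iterations (last log-likelihood change ",
            signif(abs(ll - ll_old), 3), "); using last iterate")
  }
  structure(list(pi1 = pi1, mu = mu, sigma2 = sigma2, rho = rho,
                 loglik = ll, n_iter = iter, converged = converged),
            class = "idr_model")
}

#' @export
print.idr_model <- function(x, ...) {
  cat(sprintf(paste0("IDR copula mixture: pi1=%.3f mu=%.3f sigma2=%.3f ",
                     "rho=%.3f (%d iter%s)\n"),
              x$pi1, x$mu, x$sigma2, x$rho, x$n_iter,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Assign local and global IDR values to peak pairs
#'
#' The local IDR of a pair is its posterior probability of belonging to
#' the noise component under the fitted model. The global IDR at rank `k`
#' (pairs sorted ascending by local IDR) is the mean of the `k` smallest
#' local values — the expected irreproducibility rate among the top-`k`
#' pairs — and is non-decreasing along the sort by construction.
#'
#' @param pairs Data.frame from [match_peak_pairs()].
#' @param model An `idr_model` from [fit_idr_model()].
#' @return `pairs` with `idr_local` and `idr_global` columns added (in the
#'   original row order).
#' @export
assign_idr <- function(pairs, model) {
  n <- nrow(pairs)
  if (n == 0L) {
    pairs$idr_local <- numeric(0)
    pairs$idr_global <- numeric(0)
    return(pairs)
  }
  u <- rank(pairs$score_a, ties.method = "average") / (n + 1)
  v <- rank(pairs$score_b, ties.method = "average") / (n + 1)
  z1 <- mixture_quantile(u, model$pi1, model$mu, model$sigma2)
  z2 <- mixture_quantile(v, model$pi1, model$mu, model$sigma2)
  l1 <- bvn_log_density(z1, z2, model$mu, model$sigma2, model$rho)
  l0 <- bvn_log_density(z1, z2, 0, 1, 0)
  local <- 1 / (1 + exp(l1 + log(model$pi1) - l0 - log(1 - model$pi1)))
  ord <- order(local)
  global <- numeric(n)
  global[ord] <- cumsum(local[ord]) / seq_len(n)
  pairs$idr_local <- local
  pairs$idr_global <- pmin(global, 1)
  pairs
}

#' Filter peaks to reproducible stable 3' RNA ends
#'
#' Runs the full replicate-reproducibility filter: for every unordered
#' pair of replicates and each strand, peaks are matched genome-wide
#' ([match_peak_pairs()], pooled across contigs so the EM sees enough
#' pairs), the copula mixture is fitted on prominences and IDR values
#' assigned. A peak region is retained iff it attains an IDR below
#' `config$idr_threshold` in at least `config$min_no_comp` pairwise
#' comparisons. Passing regions are unioned across replicates
#' (single-linkage interval merge per contig and strand); each merged
#' region carries the minimum IDR over its supporting comparisons, the
#' support count, and a summit set by [peak_summit()] on the
#' cross-replicate mean coverage.
#'
#' @param peak_list List (one element per replicate) of trimmed peak
#'   data.frames from [call_peaks()], covering all contigs and strands.
#' @param track_list List (per replicate) of lists keyed by strand then
#'   contig of [coverage_track()] objects, e.g.
#'   `track_list[[rep]][["+"]][["chr"]]`.
#' @param config A [reproducibility_config()].
#' @return A list with `regions` — data.frame of stable ends (`contig`,
#'   `strand`, `start`, `end`, `summit`, `min_idr`, `support`,
#'   `mean_height`) — and `pairs`, the per-comparison IDR tables (for
#'   debugging/TSV export).
#' @export
filter_reproducible <- function(peak_list, track_list, config =
                                  reproducibility_config()) {
  r <- length(peak_list)
  if (r < 2L) stop("at least 2 replicates are required (got ", r, ")")
  stopifnot(length(track_list) == r)
  idr_col <- if (config$threshold_on == "global") "idr_global" else
    "idr_local"
  pair_tables <- list()
  passing <- list()
  for (i in seq_len(r - 1L)) {
    for (j in seq(i + 1L, r)) {
      for (st in c("+", "-")) {
        pa <- peak_list[[i]]
        pb <- peak_list[[j]]
        pa <- pa[pa$strand == st, , drop = FALSE]
        pb <- pb[pb$strand == st, , drop = FALSE]
        pieces <- lapply(union(unique(pa$contig), unique(pb$contig)),
                         function(ctg) {
          match_peak_pairs(pa[pa$contig == ctg, , drop = FALSE],
                           pb[pb$contig == ctg, , drop = FALSE])
        })
        pairs <- do.call(rbind, pieces)
        if (is.null(pairs) || nrow(pairs) == 0L) next
        model <- fit_idr_model(pairs, min_pairs = config$min_pairs)
        pairs <- assign_idr(pairs, model)
        cmp_id <- sprintf("rep%d_vs_rep%d_%s", i, j, st)
        pair_tables[[cmp_id]] <- pairs
        ok <- pairs[[idr_col]] < config$idr_threshold
        if (any(ok)) {
          p <- pairs[ok, , drop = FALSE]
          passing[[cmp_id]] <- data.frame(
            contig = p$contig, strand = p$strand,
            start = pmin(p$start_a, p$start_b),
            end = pmax(p$end_a, p$end_b),
            idr = p[[idr_col]], comparison = cmp_id,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  inst <- do.call(rbind, passing)
  if (is.null(inst) || nrow(inst) == 0L) {
    return(list(regions = data.frame(
      contig = character(0), strand = character(0), start = integer(0),
      end = integer(0), summit = integer(0), min_idr = numeric(0),
      support = integer(0), mean_height = numeric(0),
      stringsAsFactors = FALSE), pairs = pair_tables))
  }
  gr <- GenomicRanges::GRanges(inst$contig,
                               IRanges::IRanges(inst$start, inst$end),
                               strand = inst$strand)
  merged <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  rows <- lapply(seq_along(merged), function(k) {
    ii <- sh[qh == k]
    support <- length(unique(inst$comparison[ii]))
    if (support < config$min_no_comp) return(NULL)
    ctg <- as.character(GenomeInfoDb::seqnames(merged))[k]
    st <- as.character(BiocGenerics::strand(merged))[k]
    s <- BiocGenerics::start(merged)[k]
    e <- BiocGenerics::end(merged)[k]
    means <- cross_replicate_mean(track_list, st, ctg, s, e)
    summit <- s + peak_summit(means, st) - 1L
    data.frame(contig = ctg, strand = st, start = s, end = e,
               summit = summit, min_idr = min(inst$idr[ii]),
               support = support,
               mean_height = means[summit - s + 1L],
               stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows)
  if (is.null(regions)) {
    regions <- data.frame(contig = character(0), strand = character(0),
                          start = integer(0), end = integer(0),
                          summit = integer(0), min_idr = numeric(0),
                          support = integer(0), mean_height = numeric(0),
                          stringsAsFactors = FALSE)
  }
  regions <- regions[order(regions$contig, regions$start, regions$strand), ]
  rownames(regions) <- NULL
  list(regions = regions, pairs = pair_tables)
}

cross_replicate_mean <- function(track_list, strand, contig, start, end) {
  mats <- lapply(track_list, function(tl) {
    tr <- tl[[strand]][[contig]]
    if (is.null(tr)) return(numeric(end - start + 1L))
    tr$values[start:end]
  })
  Reduce(`+`, mats) / length(mats)
}
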