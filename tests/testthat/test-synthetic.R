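small_cfg <- function(seed = 5L) {
  sim_config(seed = seed, n_genes = 12L, n_terminators = 10L,
             noise_peaks = 20L, genome_length = 12000L)
}

test_that("the truth table matches the requested design", {
  sim <- simulate_genome(small_cfg())
  expect_equal(nrow(sim$truth), 10)
  expect_equal(nrow(sim$features), 12)
  expect_setequal(unique(sim$truth$strand), c("+", "-"))
  expect_true(all(sim$truth$efficiency >= 20 & sim$truth$efficiency <= 95))
  expect_equal(nchar(sim$genome[[1]]), 12000)
})

test_that("planted hairpins are recoverable by enumeration in place", {
  sim <- simulate_genome(small_cfg())
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    lo <- min(tr$hairpin_start, tr$hairpin_end) - 3
    hi <- max(tr$hairpin_start, tr$hairpin_end) + 3
    s <- substr(sim$genome[[1]], lo, hi)
    if (tr$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
    h <- enumerate_hairpins(s, permissive_hairpin_params())
    expect_true(any(h$stem >= tr$stem - 1), info = tr$id)
  }
})

test_that("simulation output is deterministic under a fixed seed", {
  s1 <- simulate_genome(small_cfg())
  s2 <- simulate_genome(small_cfg())
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  c1 <- simulate_coverage(s1)
  c2 <- simulate_coverage(s2)
  expect_identical(c1$term[[1]][["+"]][["synth1"]]$values,
                   c2$term[[1]][["+"]][["synth1"]]$values)
  s3 <- simulate_genome(small_cfg(seed = 6L))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("reproducible peaks recur across replicates, noise does not", {
  sim <- simulate_genome(small_cfg())
  cov <- simulate_coverage(sim)
  reps <- length(cov$term)
  # planted signal within +-2 nt in every replicate
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    for (r in seq_len(reps)) {
      v <- cov$term[[r]][[tr$strand]][["synth1"]]$values
      win <- v[(tr$term_pos - 2):(tr$term_pos + 2)]
      expect_gt(sum(win), 0)
    }
  }
  # noise positions differ between replicates (sparse-rate check):
  # few positions carry signal in both replicates away from planted sites
  v1 <- cov$term[[1]][["+"]][["synth1"]]$values
  v2 <- cov$term[[2]][["+"]][["synth1"]]$values
  planted <- unlist(lapply(sim$truth$term_pos[sim$truth$strand == "+"],
                           function(p) (p - 5):(p + 5)))
  both <- which(v1 > 0 & v2 > 0)
  both <- setdiff(both, planted)
  expect_lte(length(both), 3)
})

test_that("complete termination leaves no downstream RNA-seq signal", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  sim$truth$efficiency <- 100
  cov <- simulate_coverage(sim)
  tr <- sim$truth[1, ]
  v <- Reduce(`+`, lapply(cov$rnaseq, function(tl) {
    tl[[tr$strand]][["synth1"]]$values
  }))
  dn <- if (tr$strand == "+") (tr$term_pos + 4):(tr$term_pos + 13) else
    (tr$term_pos - 13):(tr$term_pos - 4)
  up <- if (tr$strand == "+") (tr$term_pos - 13):(tr$term_pos - 4) else
    (tr$term_pos + 4):(tr$term_pos + 13)
  expect_gt(mean(v[up]), 0)
  expect_equal(mean(v[dn]), 0)
})

test_that("simulation files round-trip through the standard formats", {
  sim <- simulate_genome(small_cfg())
  cov <- simulate_coverage(sim)
  dir <- tempfile("simout")
  paths <- write_simulation(sim, cov, dir)
  g <- read_genome_fasta(paths$genome)
  expect_identical(g[["synth1"]], sim$genome[["synth1"]])
  feats <- read_annotation(paths$annotation)
  cds <- feats[feats$type == "CDS", ]
  expect_equal(nrow(cds), nrow(sim$features))
  expect_equal(sort(cds$start), sort(sim$features$start))
  tr <- read_track(paths$term_rep1_fwd, "+",
                   seqlengths = c(synth1 = nchar(sim$genome[[1]])))
  expect_equal(tr[["synth1"]]$values,
               cov$term[[1]][["+"]][["synth1"]]$values)
})
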