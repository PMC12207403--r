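test_that("tail score matches its geometric closed forms", {
  expect_equal(as.numeric(tail_score(strrep("U", 15))),
               -9 * (1 - 0.9^15), tolerance = 1e-12)
  expect_equal(as.numeric(tail_score(strrep("A", 15))),
               -1.5 * (1 - 0.6^15), tolerance = 1e-12)
  expect_equal(as.numeric(tail_score("UUUAAAAAAAAAAAA")),
               oracle_tail_score("UUUAAAAAAAAAAAA"), tolerance = 1e-12)
  # DNA alphabet equivalent
  expect_equal(tail_score(strrep("T", 15)), tail_score(strrep("U", 15)))
  # padding at contig edges scores as non-U and is flagged
  short <- tail_score("UUU")
  expect_true(attr(short, "padded"))
  expect_equal(as.numeric(short), oracle_tail_score("UUUNNNNNNNNNNNN"))
  expect_error(tail_score("UUUXAAAAAAAAAAA"), "non-nucleotide")
})

test_that("any non-U to U substitution strictly decreases the tail score", {
  set.seed(41)
  for (k in 1:200) {
    tail <- strsplit(rand_seq(15), "")[[1]]
    pos <- which(tail != "U")
    if (length(pos) == 0) next
    p <- sample(pos, 1)
    mut <- tail
    mut[p] <- "U"
    expect_lt(tail_score(paste(mut, collapse = "")),
              tail_score(paste(tail, collapse = "")))
  }
  # bounds
  lo <- -9 * (1 - 0.9^15)
  hi <- -1.5 * (1 - 0.6^15)
  for (k in 1:50) {
    ts <- as.numeric(tail_score(rand_seq(15)))
    expect_gte(ts, lo)
    expect_lte(ts, hi)
  }
})

test_that("hairpin enumeration finds planted stems and nothing in poly-A", {
  h <- enumerate_hairpins("GCCGCCGAAAGGCGGC")
  expect_true(any(h$stem == 6 & h$loop == 4))
  expect_equal(nrow(enumerate_hairpins(strrep("A", 16))), 0)
})

test_that("hairpin enumeration agrees with exhaustive search", {
  set.seed(43)
  presets <- list(canonical_hairpin_params(), permissive_hairpin_params())
  for (k in 1:40) {
    s <- rand_seq(60)
    for (p in presets) {
      got <- enumerate_hairpins(s, p)
      got <- got[order(got$start, got$end), , drop = FALSE]
      or <- oracle_hairpins(s, p)
      expect_equal(got$start, or$start, info = s)
      expect_equal(got$end, or$end, info = s)
      expect_equal(got$stem, or$stem, info = s)
      expect_equal(got$loop, or$loop, info = s)
    }
  }
})

test_that("hairpin scores follow the additive per-pair scheme", {
  # 6 G-C pairs, loop 4: -2.3*6 + 0.4
  h <- enumerate_hairpins("GGGGGGAAAACCCCCC",
                          hairpin_params(min_stem = 4, min_loop = 3,
                                         max_loop = 13, max_len = 59))
  six <- h[h$stem == 6, ]
  expect_equal(six$score, -2.3 * 6 + 0.4)
  # 4 A-U pairs, loop 4: -0.9*4 + 0.4
  h2 <- enumerate_hairpins("AAAAGGGGUUUU",
                           hairpin_params(min_stem = 4, min_loop = 4,
                                          max_loop = 13, max_len = 59))
  expect_equal(h2$score[h2$stem == 4], -0.9 * 4 + 0.4)
  # adding a G-C pair always strengthens
  expect_lt(-2.3 * 7 + 0.4, -2.3 * 6 + 0.4)
})

test_that("internal free energies track the reference folding engine", {
  skip_if(Sys.which("RNAfold") == "", "RNAfold not on PATH")
  panel <- c("GCCGCCGAAAGGCGGC",
             "GGGGCCCCGAAAGGGGCCCC",
             "GCGCGCUUCGGCGCGC",
             "AUGGCGUCGAAAACGGCGCCAU",
             "GGCGGGGCAAAAGCCCCGCC")
  for (s in panel) {
    h <- enumerate_hairpins(s, permissive_hairpin_params())
    h <- h[which.min(h$score), ]
    internal <- hairpin_free_energy(h, backend = "internal")
    full <- hairpin_free_energy(h, backend = "rnafold")
    expect_true(abs(internal - full) <= max(2, 0.3 * abs(full)),
                info = sprintf("%s: internal %.2f vs RNAfold %.2f",
                               s, internal, full))
  }
  # strong GC hairpin is comfortably below -3 kcal/mol
  h <- enumerate_hairpins("GCCGCCGAAAGGCGGC")
  expect_lte(hairpin_free_energy(h[which.min(h$score), ]), -3)
})

test_that("unstructured sequences yield no stable candidate", {
  expect_equal(nrow(enumerate_hairpins("AAAAAAAAAAAA",
                                       permissive_hairpin_params())), 0)
  # an all-wobble stem is assigned a non-favourable energy
  h <- data.frame(start = 1, end = 12, stem = 4, loop = 4,
                  sequence = "GGGGAAAAUUUU", structure = "((((....))))",
                  score = 0, stringsAsFactors = FALSE)
  expect_gt(hairpin_free_energy(h), -3)
})

# A compact genome with one strong terminator planted downstream of a
# CDS on each strand, used by the protocol tests.
planted_genome <- function() {
  sim <- simulate_genome(sim_config(seed = 3L, n_genes = 10L,
                                    n_terminators = 10L,
                                    noise_peaks = 10L,
                                    genome_length = 10000L,
                                    frac_weak_utract = 0))
  sim
}

test_that("genome-scan calls planted terminators within range", {
  sim <- planted_genome()
  for (i in seq_len(nrow(sim$truth))) {
    tp <- sim$truth$term_pos[i]
    call <- call_genome_scan(sim$truth$contig[i], sim$truth$strand[i],
                             tp, sim$genome)
    expect_equal(nrow(call), 1, info = sim$truth$id[i])
    expect_gte(call$distance, 0)
    expect_lte(call$distance, 10)
    expect_lte(call$free_energy, 0)
  }
})

test_that("genome-scan respects the distance window", {
  sim <- planted_genome()
  tr <- sim$truth[sim$truth$strand == "+", ][1, ]
  # a POT 14 nt past the hairpin base is out of the default [0, 10]
  far <- call_genome_scan(tr$contig, "+", tr$hairpin_end + 14,
                          sim$genome)
  expect_equal(nrow(far), 0)
  # POT inside the hairpin (negative distance) is out of range too
  inside <- call_genome_scan(tr$contig, "+", tr$hairpin_end - 3,
                             sim$genome)
  if (nrow(inside) > 0) expect_gte(inside$distance, 0)
})

test_that("local scan calls weak-U-tract terminators that the
           canonical scan rejects", {
  sim <- simulate_genome(sim_config(seed = 11L, n_genes = 12L,
                                    n_terminators = 12L,
                                    noise_peaks = 10L,
                                    genome_length = 12000L,
                                    frac_weak_utract = 1))
  weak <- sim$truth
  n_genome <- 0; n_local <- 0
  for (i in seq_len(nrow(weak))) {
    g <- call_genome_scan(weak$contig[i], weak$strand[i],
                          weak$term_pos[i], sim$genome)
    l <- call_local_scan(weak$contig[i], weak$strand[i],
                         weak$term_pos[i], sim$genome)
    n_genome <- n_genome + nrow(g)
    n_local <- n_local + nrow(l)
    if (nrow(l)) {
      expect_lte(l$free_energy, -3)
      expect_gte(l$distance, 0)
      expect_lte(l$distance, 10)
    }
  }
  expect_equal(n_genome, 0)         # < 3 U in the 6-nt window
  expect_gte(n_local, nrow(weak) - 1)
})

test_that("local-scan candidates failing the energy bar are rejected", {
  sim <- planted_genome()
  tr <- sim$truth[1, ]
  strict <- terminator_config(dg_local = -60)  # nothing can pass
  call <- call_local_scan(tr$contig, tr$strand, tr$term_pos, sim$genome,
                          strict)
  expect_equal(nrow(call), 0)
})

test_that("terminator calls are strand-symmetric", {
  # mirror a plus-strand cassette onto the minus strand of a synthetic
  # contig and expect the identical call
  set.seed(51)
  stem5 <- "GGCGCCGG"
  cassette <- paste0("AAAAAC", stem5, "GAAAA",
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(stem5))), "TTTTTTTCCC")
  pad <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  pad2 <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  g_plus <- c(chr = paste0(pad, cassette, pad2))
  pot_plus <- nchar(pad) + 6 + nchar(stem5) * 2 + 5 + 6
  call_p <- call_genome_scan("chr", "+", pot_plus, g_plus)

  g_minus <- c(chr = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g_plus[["chr"]]))))
  pot_minus <- nchar(g_plus[["chr"]]) - pot_plus + 1
  call_m <- call_genome_scan("chr", "-", pot_minus, g_minus)

  expect_equal(nrow(call_p), 1)
  expect_equal(nrow(call_m), 1)
  expect_equal(call_m$hairpin_seq, call_p$hairpin_seq)
  expect_equal(call_m$distance, call_p$distance)
  expect_equal(call_m$free_energy, call_p$free_energy)
  expect_equal(call_m$tail_score, call_p$tail_score)
})

test_that("external terminator predictions can drive the genome scan", {
  sim <- planted_genome()
  tr <- sim$truth[sim$truth$strand == "+", ][1, ]
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("%s\t%d\t%d\tt1\t0\t+", tr$contig,
                     tr$hairpin_start - 1, tr$hairpin_end), bed)
  ext <- read_terminator_bed(bed)
  call <- call_genome_scan(tr$contig, "+", tr$term_pos, sim$genome,
                           terminators = ext)
  expect_equal(nrow(call), 1)
  expect_equal(call$hairpin_gend, tr$hairpin_end)
})

test_that("atlas selection matches the stated decision rules", {
  cds <- data.frame(contig = "c", start = 100, end = 400, strand = "+",
                    type = "CDS", id = "g1", stringsAsFactors = FALSE)
  row <- function(summit, genome_scan, local_scan, local_dg) {
    data.frame(contig = "c", strand = "+", summit = summit,
               genome_scan = genome_scan, local_scan = local_scan,
               local_dg = local_dg, stringsAsFactors = FALSE)
  }
  tab <- rbind(
    row(550, TRUE, FALSE, NA),    # genome call, 150 nt:        keep
    row(550, FALSE, TRUE, -7),    # local-only, dG -7, 150 nt:  drop
    row(550, FALSE, TRUE, -9),    # local-only, dG -9, 150 nt:  keep
    row(650, TRUE, FALSE, NA),    # genome call, 250 nt:        drop
    row(650, FALSE, TRUE, -9),    # local-only, 250 nt:         drop
    row(550, FALSE, FALSE, NA),   # no call:                    drop
    row(600, TRUE, TRUE, -4),     # both calls, exactly 200 nt: keep
    row(300, FALSE, TRUE, -9)     # inside CDS (distance 0):    keep
  )
  kept <- atlas_filter(tab, cds)
  expect_equal(kept$summit, c(550, 550, 600, 300))
  expect_equal(kept$genome_scan, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(kept$cds_distance[1:3], c(150, 150, 200))
})
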