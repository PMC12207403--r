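mk_regions <- function(spans, summits, strand = "+", idr = 0.01,
                       contig = "c") {
  data.frame(contig = contig, strand = strand,
             start = vapply(spans, `[`, numeric(1), 1),
             end = vapply(spans, `[`, numeric(1), 2),
             summit = summits, min_idr = idr,
             support = 1L, mean_height = 1,
             stringsAsFactors = FALSE)
}

mk_mean_tracks <- function(values, contig = "c", strand = "+") {
  tl <- list()
  tl[[strand]] <- setNames(list(coverage_track(contig, strand, values)),
                           contig)
  tl
}

test_that("overlapping sample regions merge into a single POT", {
  v <- numeric(120)
  v[100:108] <- c(1, 2, 3, 9, 3, 2, 9, 2, 1)
  a <- mk_regions(list(c(100, 105)), 103)
  b <- mk_regions(list(c(103, 108)), 106)
  pots <- merge_pots(list(a, b), list(mk_mean_tracks(v),
                                      mk_mean_tracks(v)),
                     labels = c("s1", "s2"))
  expect_equal(nrow(pots), 1)
  expect_equal(pots$start, 100)
  expect_equal(pots$end, 108)
  expect_equal(pots$n_samples, 2)
  expect_equal(pots$samples, "s1,s2")
  # ties at 103 and 106 resolve downstream on +
  expect_equal(pots$summit, 106)
})

test_that("disjoint regions stay separate and merging is order-invariant", {
  v <- numeric(200)
  v[c(50, 150)] <- 5
  a <- mk_regions(list(c(48, 52)), 50)
  b <- mk_regions(list(c(148, 152)), 150)
  p1 <- merge_pots(list(a, b), list(mk_mean_tracks(v), mk_mean_tracks(v)))
  expect_equal(nrow(p1), 2)
  p2 <- merge_pots(list(b, a), list(mk_mean_tracks(v), mk_mean_tracks(v)))
  expect_equal(p1$summit, p2$summit)
  expect_equal(p1$start, p2$start)
})

test_that("minus-strand tie-break picks the most downstream (leftmost)", {
  v <- numeric(120)
  v[100:106] <- c(1, 7, 2, 2, 2, 7, 1)
  a <- mk_regions(list(c(100, 106)), 101, strand = "-")
  pots <- merge_pots(list(a), list(mk_mean_tracks(v, strand = "-")))
  expect_equal(pots$summit, 101)
})

test_that("gene context reports nearest genes with gap distances", {
  feats <- data.frame(contig = "c",
                      start = c(800, 1100, 700),
                      end = c(949, 1300, 1500),
                      strand = c("+", "+", "-"),
                      type = c("gene", "gene", "gene"),
                      id = c("gA", "gB", "gC"),
                      stringsAsFactors = FALSE)
  gc <- annotate_genes("c", "+", 1000, feats)
  expect_equal(gc$up_gene, "gA")
  expect_equal(gc$up_dist, 50)    # 0-based gap: bases 950..999
  expect_equal(gc$dn_gene, "gB")
  expect_equal(gc$dn_dist, 99)    # bases 1001..1099
  # antisense gene overlaps the POT
  expect_equal(gc$as_up_dist, 0)
  # POT inside a feature lists it with distance 0
  gc2 <- annotate_genes("c", "+", 1200, feats)
  expect_match(gc2$overlapping, "gB")
  expect_warning(annotate_genes("nope", "+", 10, feats), "not present")
})

test_that("minus-strand gene context mirrors plus-strand arithmetic", {
  feats <- data.frame(contig = "c", start = 1100, end = 1300,
                      strand = "-", type = "gene", id = "gM",
                      stringsAsFactors = FALSE)
  gc <- annotate_genes("c", "-", 1000, feats)
  # on -, upstream means larger coordinates
  expect_equal(gc$up_gene, "gM")
  expect_equal(gc$up_dist, 99)
})

test_that("BED overlaps follow half-open boundary semantics", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("c\t100\t110\tknownA\t0\t+",
               "c\t300\t310\tknownB\t0\t+"), bed)
  pots <- data.frame(contig = "c", strand = "+",
                     summit = c(105, 110, 111, 200),
                     stringsAsFactors = FALSE)
  out <- annotate_bed_overlaps(pots, c(known = bed))
  expect_equal(out$known_overlap, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$known_names[1], "knownA")
  # empty BED: all flags false
  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  out2 <- annotate_bed_overlaps(pots, c(none = empty))
  expect_false(any(out2$none_overlap))
})

test_that("narrowPeak output encodes IDR and summit offset and
           round-trips", {
  reg <- mk_regions(list(c(100, 110), c(200, 204)), c(104, 202),
                    idr = c(0.05, 0.001))
  p <- tempfile(fileext = ".narrowPeak")
  write_narrowpeak(reg, p)
  lines <- read.table(p, sep = "\t")
  expect_equal(ncol(lines), 10)
  expect_equal(lines$V9[1], -log10(0.05), tolerance = 1e-9)
  expect_equal(lines$V5[1], round(-125 * log2(0.05)))
  expect_equal(lines$V5[2], min(1000, round(-125 * log2(0.001))))
  # summit offset within the span
  expect_true(all(lines$V10 >= 0 & lines$V10 < lines$V3 - lines$V2))
  back <- read_narrowpeak(p)
  expect_equal(back$start, reg$start)
  expect_equal(back$end, reg$end)
  expect_equal(back$summit, reg$summit)
  expect_equal(back$min_idr, reg$min_idr, tolerance = 1e-12)
})

test_that("annotation tables have a constant schema and explicit NAs", {
  sim <- simulate_genome(sim_config(seed = 3L, n_genes = 10L,
                                    n_terminators = 5L,
                                    noise_peaks = 10L,
                                    genome_length = 10000L))
  # two POTs: one at a planted terminator, one in open background
  tr <- sim$truth[1, ]
  v <- numeric(nchar(sim$genome[[1]]))
  v[tr$term_pos] <- 5; v[5000] <- 5
  pots <- merge_pots(
    list(mk_regions(list(c(tr$term_pos - 2, tr$term_pos + 2),
                         c(4998, 5002)),
                    c(tr$term_pos, 5000), strand = tr$strand,
                    contig = "synth1")),
    list(mk_mean_tracks(v, contig = "synth1", strand = tr$strand)))
  ann <- annotate_pots(pots, sim$genome, features = sim$features)
  expect_equal(nrow(ann), 2)
  # constant column count; terminator columns NA where no call
  expect_true(ann$is_intrinsic[ann$summit == tr$term_pos])
  no_call <- ann[ann$summit == 5000, ]
  if (!no_call$is_intrinsic) {
    expect_true(is.na(no_call$genome_hairpin))
  }
  path <- tempfile(fileext = ".tsv")
  write_annotation_table(ann, path)
  expect_equal(readLines(path, n = 1), "# termseqr annotation table v1")
  back <- read_annotation_table(path)
  expect_equal(nrow(back), 2)
  expect_equal(ncol(back), ncol(ann))
  # POT base capitalized exactly once in the sequence context
  ctx <- ann$seq_context[!is.na(ann$seq_context)]
  for (s in ctx) {
    expect_equal(sum(strsplit(s, "")[[1]] %in% LETTERS), 1)
  }
})
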