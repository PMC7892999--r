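# two genes with identical exon spans on opposite strands, plus an
# isolated second same-strand gene for the ambiguity case
counting_fixture <- function() {
  ann_of(tx_rows("sense.t", "chr1", "+", 1000, 2000, gene = "sense"),
         tx_rows("anti.t", "chr1", "-", 1000, 2000, gene = "anti"),
         tx_rows("g2a.t", "chr1", "+", 5000, 5400, gene = "g2a"),
         tx_rows("g2b.t", "chr1", "+", 5300, 5700, gene = "g2b"),
         chrom_lengths = c(chr1 = 10000))
}

two_samples <- function() {
  sample_sheet(c("s1", "s2"), c("purple", "orange"),
               c("phloem", "phloem"), c(1L, 1L))
}

test_that("fragments count to the same-strand gene only", {
  ann <- counting_fixture()
  fr <- list(
    s1 = data.frame(chrom = "chr1", start = c(1100, 1100, 5600),
                    end = c(1180, 1180, 5680),
                    fragment_id = c("f1", "f2", "f3"),
                    strand = c("+", "-", "+")),
    s2 = data.frame(chrom = "chr1", start = 5350, end = 5390,
                    fragment_id = "f4", strand = "+"))
  cm <- count_fragments(fr, two_samples(), ann)
  expect_equal(cm$counts["sense", "s1"], 1L)
  expect_equal(cm$counts["anti", "s1"], 1L)
  expect_equal(cm$counts["g2b", "s1"], 1L)
  # f4 overlaps exons of both same-strand genes: ambiguous, counted to none
  expect_equal(sum(cm$counts[, "s2"]), 0L)
  expect_equal(cm$summary$ambiguous[cm$summary$sample_id == "s2"], 1L)
  # conservation: assigned + ambiguous + unassigned = total
  expect_equal(cm$summary$assigned + cm$summary$ambiguous +
                 cm$summary$unassigned, cm$summary$total)

  expect_error(count_fragments(list(
    s1 = data.frame(chrom = "chrZ", start = 1, end = 10,
                    fragment_id = "f", strand = "+"),
    s2 = fr$s2), two_samples(), ann), "unknown chromosome")
  expect_error(count_fragments(fr["s1"], two_samples(), ann),
               "sample sheet")
})

test_that("flipping every fragment strand swaps sense/antisense counts", {
  ann <- counting_fixture()
  set.seed(12)
  n <- 50
  st <- sample(c("+", "-"), n, replace = TRUE)
  s0 <- sample(1000:1900, n, replace = TRUE)
  fr <- data.frame(chrom = "chr1", start = s0, end = s0 + 60,
                   fragment_id = paste0("f", 1:n), strand = st)
  fr_flip <- fr
  fr_flip$strand <- ifelse(fr$strand == "+", "-", "+")
  cm1 <- count_fragments(list(s1 = fr, s2 = fr), two_samples(), ann)
  cm2 <- count_fragments(list(s1 = fr_flip, s2 = fr_flip), two_samples(),
                         ann)
  expect_equal(cm1$counts["sense", "s1"], cm2$counts["anti", "s1"])
  expect_equal(cm1$counts["anti", "s1"], cm2$counts["sense", "s1"])
  expect_equal(cm1$counts["sense", "s1"] + cm1$counts["anti", "s1"],
               cm2$counts["sense", "s1"] + cm2$counts["anti", "s1"])
})

test_that("BED6 write/read round trip preserves fragments", {
  fr <- data.frame(chrom = "chr1", start = c(0, 150), end = c(80, 230),
                   fragment_id = c("a", "b"), strand = c("+", "-"),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_fragments_bed6(fr, f)
  back <- read_fragments_bed6(f)
  expect_equal(back$start, fr$start)
  expect_equal(back$end, fr$end)
  expect_identical(back$strand, fr$strand)
})

test_that("the minimal SAM reader resolves fragment strand by protocol", {
  f <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:10000",
    # read1 of a pair, forward alignment, 60M
    "r1\t99\tchr1\t101\t60\t60M\t=\t300\t260\t*\t*",
    # its mate (read2): must be ignored
    "r1\t147\tchr1\t301\t60\t60M\t=\t101\t-260\t*\t*",
    # unpaired reverse read with an intron-spanning CIGAR
    "r2\t16\tchr1\t501\t60\t20M100N30M\t*\t0\t0\t*\t*",
    # unmapped: ignored
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  ), f)
  rev <- read_fragments_sam(f, protocol = "reverse")
  expect_equal(nrow(rev), 2)
  expect_equal(rev$start, c(100, 500))
  expect_equal(rev$end, c(160, 650))       # 20M 100N 30M spans 150 bp
  expect_identical(rev$strand, c("-", "+"))  # reverse protocol flips
  fwd <- read_fragments_sam(f, protocol = "forward")
  expect_identical(fwd$strand, c("+", "-"))
})

test_that("median-of-ratios size factors match the hand-derived values", {
  m <- matrix(c(10L, 20L, 40L, 10L, 20L, 40L), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- cbind(a = c(10L, 20L, 40L), b = c(20L, 40L, 80L))
  rownames(m2) <- paste0("g", 1:3)
  s <- estimate_size_factors(m2)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-9)

  m3 <- cbind(a = c(0L, 0L), b = c(3L, 0L))
  rownames(m3) <- c("g1", "g2")
  expect_error(estimate_size_factors(m3), "filter")
})

test_that("size factors scale with a per-sample count multiplier", {
  set.seed(13)
  m <- matrix(rpois(500 * 4, 60), 500, 4,
              dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:4)))
  s1 <- estimate_size_factors(m)
  m2 <- m
  m2[, 2] <- m[, 2] * 3L
  s2 <- estimate_size_factors(m2)
  # after removing the geometric-mean anchoring, sample 2's factor triples
  ratio <- (s2 / s1) / exp(mean(log(s2 / s1)))
  expect_equal(unname(ratio[2] / ratio[1]), 3, tolerance = 1e-9)
})

test_that("size factors recover simulated depth multipliers", {
  cfg <- simulation_config(seed = 14, n_coding_genes = 2000, n_lncNATs = 0,
                           n_lincRNAs = 0, n_intronic = 0, n_proximal = 0,
                           n_novel_coding = 0, anthocyanin_module_size = 0,
                           depth_multipliers = c(0.5, 1, 2, 4))
  sc <- simulate_counts(simulate_expression_design(cfg))
  s <- estimate_size_factors(sc$counts)
  expect_lt(max(abs(s / sc$truth$true_size_factors - 1)), 0.05)
})

test_that("normalization divides by factors and recentres ratio medians", {
  m <- cbind(a = c(10L, 30L), b = c(20L, 60L))
  rownames(m) <- c("g1", "g2")
  expect_equal(normalize_counts(m, c(a = 1, b = 1)), m + 0)
  expect_equal(normalize_counts(m, c(a = 2, b = 1))["g1", "a"], 5)

  cfg <- simulation_config(seed = 15, n_coding_genes = 1000, n_lncNATs = 0,
                           n_lincRNAs = 0, n_intronic = 0, n_proximal = 0,
                           n_novel_coding = 0, anthocyanin_module_size = 0,
                           depth_multipliers = c(0.5, 1, 2, 4))
  sc <- simulate_counts(simulate_expression_design(cfg))
  s <- estimate_size_factors(sc$counts)
  norm <- normalize_counts(sc$counts, s)
  allpos <- rowSums(sc$counts$counts > 0) == ncol(norm)
  ref <- exp(rowMeans(log(norm[allpos, ])))
  med <- apply(norm[allpos, ] / ref, 2, median)
  expect_true(all(abs(med - 1) < 0.05))
  expect_equal(log2_normalized(sc$counts, s), log2(norm + 1))
})

test_that("size factors agree with an independent median-of-ratios fit", {
  cfg <- simulation_config(seed = 16, n_coding_genes = 400, n_lncNATs = 0,
                           n_lincRNAs = 0, n_intronic = 0, n_proximal = 0,
                           n_novel_coding = 0, anthocyanin_module_size = 0,
                           depth_multipliers = c(1, 1, 2, 3))
  sc <- simulate_counts(simulate_expression_design(cfg))
  ours <- estimate_size_factors(sc$counts)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(sc$counts$counts)
  theirs <- theirs / exp(mean(log(theirs)))   # same anchoring
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("counting the simulated read set reproduces the count matrix", {
  cfg <- simulation_config(seed = 17, n_coding_genes = 25, n_lncNATs = 5,
                           n_lincRNAs = 6, n_intronic = 2, n_proximal = 2,
                           n_novel_coding = 3, anthocyanin_module_size = 6,
                           genotype_log2FC_range = c(4, 6))
  sim <- simulate_genome(cfg)
  sc <- simulate_counts(sim)
  ann <- merge_annotations(sim$reference, sim$novel)
  fr <- simulate_reads(sc$counts, ann, cfg)
  cm <- count_fragments(fr, sc$counts$samples, ann)
  expect_identical(cm$counts[rownames(sc$counts$counts), ],
                   sc$counts$counts)
  expect_true(all(cm$summary$ambiguous == 0))
  expect_true(all(cm$summary$unassigned == 0))
})
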