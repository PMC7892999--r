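test_that("sample PCA separates constructed groups and conserves variance", {
  set.seed(91)
  base <- rnorm(200)
  # two triplicate groups of duplicated samples with a mean offset:
  # all between-sample variance lies on one axis
  x <- cbind(base, base, base, base + 5, base + 5, base + 5)
  colnames(x) <- paste0("s", 1:6)
  p <- pca_samples(x)
  expect_equal(sum(p$variance_explained), 100, tolerance = 1e-6)
  expect_true(all(sign(p$scores[1:3, 1]) != sign(p$scores[4:6, 1])))
  expect_gt(p$variance_explained[1], 99.9)
  expect_lt(p$variance_explained[2], 0.1)

  # gene order does not change the scores
  perm <- sample.int(nrow(x))
  p2 <- pca_samples(x[perm, ])
  expect_equal(p2$scores, p$scores, tolerance = 1e-8)
  expect_error(pca_samples(x[, 1:2]), "3 samples")
})

test_that("genotype effect dominates PC1 on simulated data", {
  ok <- 0
  for (s in 1:20) {
    cfg <- simulation_config(seed = 900 + s, n_coding_genes = 400,
                             n_lncNATs = 0, n_lincRNAs = 0, n_intronic = 0,
                             n_proximal = 0, n_novel_coding = 0)
    sc <- simulate_counts(simulate_expression_design(cfg))
    p <- pca_samples(log2_normalized(sc$counts))
    sgn <- sign(p$scores[, 1])
    gt <- sc$counts$samples$genotype
    sep <- length(unique(sgn[gt == "purple"])) == 1 &&
      length(unique(sgn[gt == "orange"])) == 1 &&
      sgn[gt == "purple"][1] != sgn[gt == "orange"][1]
    ok <- ok + (sep && p$variance_explained[1] > p$variance_explained[2])
  }
  expect_gte(ok / 20, 0.95)
})

test_that("transcript summaries bin lengths and normalise per chromosome", {
  ann <- ann_of(tx_rows("t1", "chr1", "+", 0, 250),
                tx_rows("t2", "chr2", "+", 0, 650),
                chrom_lengths = c(chr1 = 1000, chr2 = 1000))
  bio <- data.frame(transcript_id = c("t1", "t2"),
                    biotype = c("noncoding", "coding"))
  s <- summarize_transcripts(ann, bio)
  expect_equal(s$length_hist$count[s$length_hist$biotype == "noncoding" &
                                     s$length_hist$length_class ==
                                       "200-400"], 1)
  agg <- stats::aggregate(proportion ~ biotype, s$chrom_proportions, sum)
  expect_true(all(abs(agg$proportion - 1) < 1e-12))

  # coding simulated above noncoding expression: Welch test is significant
  set.seed(92)
  genes <- c(sprintf("c%02d", 1:40), sprintf("n%02d", 1:40))
  expr <- rbind(matrix(rnorm(40 * 6, 8, 0.5), 40, 6),
                matrix(rnorm(40 * 6, 6, 0.5), 40, 6))
  rownames(expr) <- genes
  parts <- c(lapply(1:40, function(i) tx_rows(sprintf("c%02d", i), "chr1",
                                              "+", i * 100, i * 100 + 50)),
             lapply(1:40, function(i) tx_rows(sprintf("n%02d", i), "chr2",
                                              "+", i * 100, i * 100 + 50)))
  ann2 <- do.call(ann_of, c(parts, list(chrom_lengths = c(chr1 = 10000,
                                                          chr2 = 10000))))
  bio2 <- data.frame(transcript_id = genes,
                     biotype = rep(c("coding", "noncoding"), each = 40))
  s2 <- summarize_transcripts(ann2, bio2, log_norm = expr)
  expect_lt(s2$expression_test$p_value, 0.01)
  expect_gt(s2$expression_test$mean_coding,
            s2$expression_test$mean_noncoding)
})

test_that("delta-delta-Ct identities hold exactly", {
  cts <- data.frame(
    sample_id = rep(c("purple_phloem", "purple_xylem"), each = 2),
    gene_id = rep(c("actin7", "myb"), 2),
    ct_mean = c(20, 26, 20, 24))
  rq <- ddct_relative_expression(cts, "actin7", "purple_phloem")
  expect_equal(rq$RQ[rq$sample_id == "purple_phloem"], 1)
  # ddCt = (24-20) - (26-20) = -2 so RQ = 4
  expect_equal(rq$RQ[rq$sample_id == "purple_xylem"], 4)

  # one cycle earlier than the reference sample doubles RQ
  cts2 <- data.frame(sample_id = rep(c("ref", "s"), each = 2),
                     gene_id = rep(c("actin7", "g"), 2),
                     ct_mean = c(20, 25, 20, 24))
  rq2 <- ddct_relative_expression(cts2, "actin7", "ref")
  expect_equal(rq2$RQ[rq2$sample_id == "s"], 2)

  # a uniform template shift (same offset on target and reference gene)
  # leaves RQ unchanged
  cts3 <- cts2
  cts3$ct_mean[cts3$sample_id == "s"] <- cts3$ct_mean[cts3$sample_id ==
                                                        "s"] - 3
  rq3 <- ddct_relative_expression(cts3, "actin7", "ref")
  expect_equal(rq3$RQ, rq2$RQ)

  # missing target in a sample is flagged, missing reference gene errors
  cts4 <- cts2[-4, ]
  rq4 <- ddct_relative_expression(cts4, "actin7", "ref")
  expect_true(rq4$not_detected[rq4$sample_id == "s"])
  expect_error(ddct_relative_expression(cts2[-3, ], "actin7", "ref"),
               "reference gene")
})

test_that("the pipeline runs end to end, deterministically, evidence-free", {
  cfgl <- list(seed = 93, n_coding_genes = 15, n_lncNATs = 3,
               n_lincRNAs = 4, n_intronic = 1, n_proximal = 1,
               n_novel_coding = 1, anthocyanin_module_size = 6)
  out1 <- run_pipeline(cfgl, outdir = withr::local_tempdir())
  expect_true(all(c("classify", "count", "normalize", "de", "nats",
                    "report") %in% out1$manifest$stages_completed))
  expect_true(file.exists(file.path(out1$outdir, "manifest.json")))
  expect_true(file.exists(file.path(out1$outdir, "run.log")))
  expect_equal(out1$manifest$n_novel, 10)

  out2 <- run_pipeline(cfgl, outdir = withr::local_tempdir())
  d1 <- out1$manifest$outputs
  d2 <- out2$manifest$outputs
  expect_identical(unname(unlist(d1)), unname(unlist(d2)))
})

test_that("the pipeline also runs from files on disk", {
  # build the inputs with the generator, write them out, then run the
  # file-based path
  cfg <- simulation_config(seed = 94, n_coding_genes = 12, n_lncNATs = 3,
                           n_lincRNAs = 3, n_intronic = 1, n_proximal = 1,
                           n_novel_coding = 1, anthocyanin_module_size = 4)
  sim <- simulate_genome(cfg)
  sc <- simulate_counts(sim)
  ann <- merge_annotations(sim$reference, sim$novel)
  fr <- simulate_reads(sc$counts, ann, cfg)
  dir <- withr::local_tempdir()
  write_annotation(sim$reference, file.path(dir, "ref.gff3"))
  write_annotation(sim$novel, file.path(dir, "novel.gff3"))
  write_sequences(sim$sequences, file.path(dir, "genome.fa"))
  paths <- vapply(names(fr), function(s) {
    p <- file.path(dir, paste0(s, ".bed"))
    write_fragments_bed6(fr[[s]], p)
    p
  }, character(1))
  ss <- sc$counts$samples
  ss$path <- unname(paths)
  utils::write.table(ss, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  out <- run_pipeline(list(
    simulate = FALSE, seed = 94,
    reference_gff = file.path(dir, "ref.gff3"),
    novel_gff = file.path(dir, "novel.gff3"),
    genome_fasta = file.path(dir, "genome.fa"),
    sample_sheet = file.path(dir, "samples.tsv")),
    outdir = withr::local_tempdir())
  expect_equal(out$manifest$stages_completed,
               c("classify", "count", "normalize", "de", "nats", "report"))
  # the counts recovered from disk match the simulated matrix
  expect_identical(out$counts$counts[rownames(sc$counts$counts), ],
                   sc$counts$counts)
})

test_that("flat key:value configuration files parse into typed lists", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# a comment", "seed: 7", "n_coding_genes = 30",
               "depth_multipliers: 0.5, 1, 2, 4", "simulate: true",
               "reference_gff: /tmp/x.gff3"), f)
  cfg <- read_pipeline_config(f)
  expect_identical(cfg$seed, 7)
  expect_identical(cfg$depth_multipliers, c(0.5, 1, 2, 4))
  expect_true(cfg$simulate)
  expect_identical(cfg$reference_gff, "/tmp/x.gff3")
  writeLines("no separator here", f)
  expect_error(read_pipeline_config(f), "malformed config line")
})
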