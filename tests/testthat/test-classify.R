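# reference: one 2-exon coding gene on chr1 plus one far gene, used by the
# class-code and subclass examples below
ref_fixture <- function() {
  ann_of(tx_rows("ref1", "chr1", "+", c(1000, 2000), c(1500, 2600)),
         tx_rows("ref2", "chr1", "+", 20000, 21000),
         chrom_lengths = c(chr1 = 50000), biotype = "coding")
}

test_that("class codes follow the positional definitions and precedence", {
  ref <- ref_fixture()
  nov <- ann_of(
    tx_rows("nx", "chr1", "-", 1470, 1900),     # 30 bp antisense overlap
    tx_rows("nu", "chr1", "+", 31000, 31500),   # 10 kb from everything
    tx_rows("ni", "chr1", "-", 1600, 1900),     # inside the intron
    tx_rows("neq", "chr1", "+", c(1000, 2000), c(1500, 2600)),  # identical
    tx_rows("ns", "chr1", "+", 1400, 1800),     # sense overlap
    chrom_lengths = c(chr1 = 50000))
  codes <- assign_class_code(nov, ref)
  got <- stats::setNames(codes$code, codes$transcript_id)
  expect_equal(unname(got["nx"]), "x")
  expect_equal(unname(got["nu"]), "u")
  expect_equal(unname(got["ni"]), "i")
  expect_equal(unname(got["neq"]), "equal")
  expect_equal(unname(got["ns"]), "sense_overlap")
  # the equal call names its reference transcript
  expect_equal(codes$evidence[codes$transcript_id == "neq"], "ref1")

  bad <- ann_of(tx_rows("n1", "chrX", "+", 0, 300),
                chrom_lengths = c(chrX = 1000))
  expect_error(assign_class_code(bad, ref), "absent from the reference")
})

test_that("class codes match the brute-force oracle on random annotations", {
  ref <- random_annotation(n_tx = 30, seed = 31)
  nov <- random_annotation(n_tx = 40, seed = 32)
  codes <- assign_class_code(nov, ref)
  for (i in seq_len(nrow(codes))) {
    expect_equal(codes$code[i],
                 oracle_class_code(nov, ref, codes$transcript_id[i]),
                 label = codes$transcript_id[i])
  }
})

test_that("the long-RNA filter keeps u/x/i transcripts longer than 200 nt", {
  ref <- ref_fixture()
  nov <- ann_of(
    tx_rows("len200", "chr1", "+", 30000, 30200),  # exactly 200: dropped
    tx_rows("len201", "chr1", "+", 33000, 33201),  # 201: kept
    tx_rows("sense", "chr1", "+", 1000, 2600),     # sense overlap: dropped
    chrom_lengths = c(chr1 = 50000))
  flt <- filter_novel_transcripts(nov, ref)
  expect_identical(flt$retained$transcripts$transcript_id, "len201")
  expect_false(flt$decisions$kept[flt$decisions$transcript_id == "len200"])

  # brute-force check over a random novel set, plus length monotonicity
  ref2 <- random_annotation(n_tx = 25, seed = 41)
  nov2 <- random_annotation(n_tx = 50, seed = 42)
  codes <- assign_class_code(nov2, ref2)
  for (cutoff in c(200, 400, 700)) {
    cfg <- thresholds_config(min_tx_len_nt = cutoff)
    flt2 <- filter_novel_transcripts(nov2, ref2, cfg, codes = codes)
    manual <- codes$transcript_id[
      codes$code %in% c("u", "x", "i") &
        transcript_length(nov2)[codes$transcript_id] > cutoff]
    expect_setequal(flt2$decisions$transcript_id[flt2$decisions$kept],
                    manual)
  }
  kept_by_cut <- lapply(c(200, 400, 700), function(cutoff) {
    cfg <- thresholds_config(min_tx_len_nt = cutoff)
    f <- filter_novel_transcripts(nov2, ref2, cfg, codes = codes)
    f$decisions$transcript_id[f$decisions$kept]
  })
  expect_true(all(kept_by_cut[[2]] %in% kept_by_cut[[1]]))
  expect_true(all(kept_by_cut[[3]] %in% kept_by_cut[[2]]))
})

test_that("ORF finder handles the documented edge cases", {
  expect_null(longest_forward_orf("ATGAAATAA", min_aa = 70))
  o <- longest_forward_orf("ATGAAATAA", min_aa = 1)
  expect_equal(o$length_aa, 2)
  expect_true(o$has_stop)

  # 150-codon ORF embedded at nucleotide offset 7
  set.seed(8)
  body <- paste(sample(setdiff(lncnat:::NONSTOP_CODONS, "ATG"), 149,
                       replace = TRUE), collapse = "")
  s <- paste0("CCCCCCC", "ATG", body, "TAA", "CCCCC")
  o <- longest_forward_orf(s, min_aa = 70)
  expect_equal(o$start_nt, 7)
  expect_equal(o$length_aa, 150)
  expect_true(o$has_stop)

  # an ORF of exactly 70 aa is returned at min_aa 70
  body70 <- paste(sample(setdiff(lncnat:::NONSTOP_CODONS, "ATG"), 69,
                         replace = TRUE), collapse = "")
  s70 <- paste0(strrep("C", 230), "ATG", body70, "TGA")
  o <- longest_forward_orf(s70, min_aa = 70)
  expect_equal(o$length_aa, 70)

  # codons containing N neither start nor stop an ORF
  expect_null(longest_forward_orf(paste0("ANG", strrep("AAA", 80), "TAA"),
                                  min_aa = 70))
  oN <- longest_forward_orf(paste0("ATG", strrep("AAA", 40), "TNA",
                                   strrep("AAA", 40), "TAA"),
                            min_aa = 70)
  expect_equal(oN$length_aa, 82)
})

test_that("ORF finder matches the exhaustive-scan oracle", {
  set.seed(9)
  for (i in 1:200) {
    L <- sample(60:400, 1)
    s <- rand_seq(L)
    if (i %% 5 == 0) {  # sprinkle Ns into some sequences
      p <- sample.int(L, max(1, L %/% 30))
      s <- paste0(substring(s, 1, p[1] - 1), "N",
                  substring(s, p[1] + 1, L))
    }
    min_aa <- sample(c(5, 10, 20), 1)
    got <- longest_forward_orf(s, min_aa)
    want <- oracle_orf(s, min_aa)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$length_aa, want$length_aa, label = s)
      # equal-length ties resolve to the smallest start
      expect_lte(got$start_nt, want$start_nt)
    }
  }
})

test_that("biotype rules fire in order: coding, structural, noncoding", {
  ev <- data.frame(
    transcript_id = c("t_cpc_nc", "t_struct", "t_cpc_cod", "t_nc_hom"),
    evidence_type = c("coding_potential", "structural_homology",
                      "coding_potential", "known_ncRNA_homology"),
    value = c("noncoding", "rRNA", "coding", "lncRNA"),
    stringsAsFactors = FALSE)
  orf121 <- list(start_nt = 0, length_aa = 121, has_stop = TRUE)
  orf120 <- list(start_nt = 0, length_aa = 120, has_stop = TRUE)
  orf40 <- list(start_nt = 0, length_aa = 40, has_stop = TRUE)

  expect_equal(classify_biotype("t_plain", orf121, ev)$biotype, "coding")
  expect_equal(classify_biotype("t_plain", orf120, ev)$biotype, "noncoding")
  expect_equal(classify_biotype("t_cpc_nc", orf120, ev)$biotype, "noncoding")
  expect_equal(classify_biotype("t_cpc_nc", orf120, ev)$rule_fired,
               "cpc_noncoding")
  expect_equal(classify_biotype("t_struct", orf40, ev)$biotype, "structural")
  expect_equal(classify_biotype("t_cpc_cod", NULL, ev)$biotype, "coding")
  expect_equal(classify_biotype("t_nc_hom", NULL, ev)$biotype, "noncoding")
  # precedence: a long ORF beats structural homology
  expect_equal(classify_biotype("t_struct", orf121, ev)$biotype, "coding")
  # fallback with no evidence at all
  expect_equal(classify_biotype("t_plain", NULL, ev)$rule_fired,
               "no_evidence_default")
})

test_that("evidence tables validate vocabulary and contradictions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tevidence_type\tvalue",
               "t1\tcoding_potential\tcoding",
               "t1\tcoding_potential\tnoncoding"), f)
  expect_error(read_evidence_table(f), "contradictory")
  writeLines(c("transcript_id\tevidence_type\tvalue",
               "t1\tcoding_potential\tmaybe"), f)
  expect_error(read_evidence_table(f), "unknown value")
  writeLines(c("transcript_id\tevidence_type\tvalue",
               "t1\tstructural_homology\ttRNA"), f)
  ev <- read_evidence_table(f)
  expect_equal(nrow(ev), 1)
})

test_that("positional subclasses follow the lncNAT/intronic/lincRNA rules", {
  ref <- ref_fixture()
  ann <- ann_of(
    tx_rows("as1", "chr1", "-", 1499, 1900),   # 1 bp exonic overlap
    tx_rows("in1", "chr1", "-", 1600, 1900),   # inside the intron
    tx_rows("li1", "chr1", "+", 3601, 4200),   # distance 1001
    tx_rows("pr1", "chr1", "+", 3600, 4200),   # distance 1000
    chrom_lengths = c(chr1 = 50000))
  expect_equal(subclassify_noncoding(ann, "as1", ref), "lncNAT")
  expect_equal(subclassify_noncoding(ann, "in1", ref), "intronic")
  expect_equal(subclassify_noncoding(ann, "li1", ref), "lincRNA")
  expect_equal(subclassify_noncoding(ann, "pr1", ref), "proximal")
})

test_that("subclassification matches a brute-force classifier on random data", {
  ref <- random_annotation(n_tx = 30, seed = 51)
  qry <- random_annotation(n_tx = 100, seed = 52)
  for (id in qry$transcripts$transcript_id) {
    expect_equal(subclassify_noncoding(qry, id, ref),
                 oracle_subclass(qry, id, ref), label = id)
  }
})

test_that("classification partitions transcripts and recovers planted truth", {
  sim <- simulate_genome(simulation_config(
    seed = 61, n_coding_genes = 30, n_lncNATs = 6, n_lincRNAs = 8,
    n_intronic = 3, n_proximal = 3, n_novel_coding = 5))
  cls <- classify_transcripts(sim$novel, sim$reference, sim$sequences)
  calls <- cls$calls
  # partition: one biotype each; subclass present iff noncoding
  expect_equal(nrow(calls), n_transcripts(sim$novel))
  expect_true(all(calls$biotype %in% c("coding", "structural", "noncoding")))
  expect_identical(is.na(calls$subclass), calls$biotype != "noncoding")

  m <- merge(calls, sim$truth$transcripts, by = "transcript_id")
  # embedded >= 121 aa ORFs are all called coding
  expect_true(all(m$biotype[m$true_biotype == "coding"] == "coding"))
  # screened transcripts (max ORF < 70 aa, no evidence) are all noncoding
  expect_true(all(m$biotype[m$true_biotype == "noncoding"] == "noncoding"))
  expect_identical(m$subclass[m$biotype == "noncoding"],
                   m$true_subclass[m$biotype == "noncoding"])
})
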