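## Dataset summaries, sample PCA and delta-delta-Ct relative
## quantification.

#' Principal-component analysis of samples
#'
#' PCA of the samples on gene-centred log2 expression: each gene's values
#' are centred to mean zero across samples (no unit-variance scaling),
#' scores come from the singular value decomposition on the sample
#' dimension, and each component is oriented so that the sample with the
#' largest absolute score on it is positive.
#'
#' @param log_norm genes x samples matrix, conventionally
#'   [log2_normalized] counts.
#' @return list of class `lncnat_pca` with `scores` (samples x PCs),
#'   `variance_explained` (percent per PC, summing to 100) and `sdev`.
#' @export
pca_samples <- function(log_norm) {
  if (ncol(log_norm) < 3L) stop("PCA needs at least 3 samples")
  x <- log_norm - rowMeans(log_norm)
  sv <- svd(t(x))
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- colnames(log_norm)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  ## sign convention: largest-|score| sample positive on each PC
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  ve <- 100 * sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores,
                 variance_explained = stats::setNames(ve,
                                                      colnames(scores)),
                 sdev = sv$d / sqrt(max(1, ncol(log_norm) - 1))),
            class = "lncnat_pca")
}

#' @export
print.lncnat_pca <- function(x, ...) {
  ve <- x$variance_explained
  cat("sample PCA:", nrow(x$scores), "samples;",
      sprintf("PC1 %.1f%%, PC2 %.1f%%", ve[1], ve[2]), "\n")
  invisible(x)
}

#' Summary tables of an annotated transcript set
#'
#' Produces the descriptive views used to characterise a transcriptome:
#' spliced-length histograms in 200-bp bins, exon-count histograms,
#' per-chromosome biotype proportions, and a Welch two-sided t test
#' comparing mean log2 normalized expression of coding vs noncoding
#' genes.
#'
#' @param ann a [genome_annotation] (reference + novel).
#' @param biotypes data.frame (`transcript_id`, `biotype`) covering the
#'   transcripts to summarise; declared biotypes fill the rest.
#' @param log_norm optional genes x samples [log2_normalized] matrix for
#'   the expression comparison.
#' @return list with `length_hist`, `exon_hist`, `chrom_proportions`, and
#'   (when expression is given) `expression_test` (`t`, `df`, `p_value`,
#'   group means).
#' @export
summarize_transcripts <- function(ann, biotypes = NULL, log_norm = NULL) {
  tx <- ann$transcripts
  bio <- ifelse(is.na(tx$declared_biotype), "coding", tx$declared_biotype)
  if (!is.null(biotypes)) {
    i <- match(tx$transcript_id, biotypes$transcript_id)
    bio[!is.na(i)] <- biotypes$biotype[i[!is.na(i)]]
  }
  bin <- 200 * floor(tx$length / 200)
  length_hist <- as.data.frame(table(
    biotype = bio,
    length_class = paste0(bin, "-", bin + 200)), stringsAsFactors = FALSE)
  length_hist <- length_hist[length_hist$Freq > 0, ]
  names(length_hist)[3] <- "count"

  exon_hist <- as.data.frame(table(biotype = bio, n_exons = tx$n_exons),
                             stringsAsFactors = FALSE)
  exon_hist <- exon_hist[exon_hist$Freq > 0, ]
  names(exon_hist)[3] <- "count"

  ct <- table(bio, tx$chrom)
  chrom_proportions <- as.data.frame(sweep(ct, 1, rowSums(ct), "/"),
                                     stringsAsFactors = FALSE)
  names(chrom_proportions) <- c("biotype", "chrom", "proportion")

  out <- list(length_hist = length_hist, exon_hist = exon_hist,
              chrom_proportions = chrom_proportions)
  if (!is.null(log_norm)) {
    gene_bio <- stats::setNames(bio, tx$gene_id)
    common <- intersect(rownames(log_norm), names(gene_bio))
    gmean <- rowMeans(log_norm[common, , drop = FALSE])
    grp <- gene_bio[common]
    if (length(unique(grp[grp %in% c("coding", "noncoding")])) == 2) {
      tt <- stats::t.test(gmean[grp == "coding"],
                          gmean[grp == "noncoding"])
      out$expression_test <- list(
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value,
        mean_coding = mean(gmean[grp == "coding"]),
        mean_noncoding = mean(gmean[grp == "noncoding"]))
    }
  }
  out
}

#' Read a Ct table for relative quantification
#' @param path TSV with columns sample_id, gene_id, ct_mean and optionally
#'   ct_sd.
#' @return validated data.frame.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "ct_mean")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.na(df$ct_mean) & df$ct_mean <= 0)) {
    stop("Ct values must be positive")
  }
  df
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each sample and target gene: `dCt = Ct_target - Ct_reference_gene`
#' within the sample, `ddCt = dCt_sample - dCt_reference_sample`, and the
#' relative quantity `RQ = 2^-ddCt`.  The reference sample therefore has
#' RQ exactly 1 for every gene, and one cycle less template doubles RQ.
#' Targets without a Ct in a sample are flagged not detected.
#'
#' @param cts data.frame with columns `sample_id`, `gene_id`, `ct_mean`
#'   (mean of technical replicates); `NA` Ct means not detected.
#' @param reference_gene housekeeping gene id (e.g. an actin); must be
#'   measured in every sample.
#' @param reference_sample sample id used as the calibrator.
#' @return data.frame `sample_id`, `gene_id`, `RQ`, `not_detected`.
#' @export
ddct_relative_expression <- function(cts, reference_gene,
                                     reference_sample) {
  samples <- unique(cts$sample_id)
  if (!reference_sample %in% samples) {
    stop("reference sample ", reference_sample, " not in the Ct table")
  }
  ref_ct <- stats::setNames(rep(NA_real_, length(samples)), samples)
  for (s in samples) {
    v <- cts$ct_mean[cts$sample_id == s & cts$gene_id == reference_gene]
    if (length(v) == 0L || is.na(v[1])) {
      stop("reference gene ", reference_gene, " has no Ct in sample ", s)
    }
    ref_ct[s] <- v[1]
  }
  targets <- setdiff(unique(cts$gene_id), reference_gene)
  rows <- list()
  for (g in targets) {
    v0 <- cts$ct_mean[cts$sample_id == reference_sample & cts$gene_id == g]
    dct0 <- if (length(v0) && !is.na(v0[1])) {
      v0[1] - ref_ct[reference_sample]
    } else {
      NA_real_
    }
    for (s in samples) {
      v <- cts$ct_mean[cts$sample_id == s & cts$gene_id == g]
      detected <- length(v) > 0L && !is.na(v[1])
      rq <- if (detected && !is.na(dct0)) {
        2^-((v[1] - ref_ct[s]) - dct0)
      } else {
        NA_real_
      }
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = s, gene_id = g, RQ = rq, not_detected = !detected,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
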