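## Strand-specific fragment counting over gene exons and median-of-ratios
## normalization.

GENOTYPES <- c("purple", "orange")
TISSUES <- c("phloem", "xylem")

#' Sample sheet constructor / validator
#'
#' @param sample_id character sample ids (unique).
#' @param genotype `"purple"` or `"orange"` per sample.
#' @param tissue `"phloem"` or `"xylem"` per sample.
#' @param replicate integer replicate index per sample.
#' @param path optional fragment-file path per sample.
#' @return validated data.frame of class `lncnat_samples`.
#' @export
sample_sheet <- function(sample_id, genotype, tissue, replicate,
                         path = NA_character_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   genotype = as.character(genotype),
                   tissue = as.character(tissue),
                   replicate = as.integer(replicate),
                   path = path,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id")
  if (!all(df$genotype %in% GENOTYPES)) {
    stop("genotype must be one of: ", paste(GENOTYPES, collapse = ", "))
  }
  if (!all(df$tissue %in% TISSUES)) {
    stop("tissue must be one of: ", paste(TISSUES, collapse = ", "))
  }
  if (anyDuplicated(df[, c("genotype", "tissue", "replicate")])) {
    stop("duplicated (genotype, tissue, replicate) combination")
  }
  class(df) <- c("lncnat_samples", "data.frame")
  df
}

#' Read a sample sheet TSV
#' @param path TSV with columns sample_id, genotype, tissue, replicate and
#'   optionally path.
#' @return validated sample sheet.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "tissue", "replicate")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  sample_sheet(df$sample_id, df$genotype, df$tissue, df$replicate,
               path = if ("path" %in% names(df)) df$path else NA_character_)
}

#' Read strand-resolved fragments from BED6
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged.  The strand column is taken as the
#' already-resolved originating-transcript strand.
#'
#' @param path BED6 file.
#' @return data.frame `chrom`, `start`, `end`, `fragment_id`, `strand`.
#' @export
read_fragments_bed6 <- function(path) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("BED6 file ", path, " has fewer than 6 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]),
                    fragment_id = as.character(df[[4]]),
                    strand = as.character(df[[6]]),
                    stringsAsFactors = FALSE)
  if (!all(out$strand %in% STRANDS)) {
    stop("BED6 file ", path, " contains fragments without +/- strand")
  }
  if (any(out$end <= out$start)) {
    stop("BED6 file ", path, " contains an empty or inverted interval")
  }
  out
}

cigar_reference_span <- function(cigar) {
  ops <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)
  vapply(seq_along(cigar), function(i) {
    m <- regmatches(cigar[i], ops[i])[[1]]
    if (!length(m)) return(0)
    len <- as.numeric(sub("[MIDNSHP=X]$", "", m))
    op <- sub("^\\d+", "", m)
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1))
}

#' Minimal SAM fragment reader
#'
#' Reads primary mapped alignments and reduces them to fragment intervals:
#' the reference span of read 1 (or of an unpaired read).  The fragment
#' strand is resolved from the alignment strand and the library protocol:
#' the default `"reverse"` (dUTP/TruSeq-style stranded chemistry) flips the
#' read-1 strand; `"forward"` keeps it.
#'
#' @param path SAM file.
#' @param protocol `"reverse"` (default) or `"forward"`.
#' @return data.frame as from [read_fragments_bed6].
#' @export
read_fragments_sam <- function(path, protocol = c("reverse", "forward")) {
  protocol <- match.arg(protocol)
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), fragment_id = character(0),
                      strand = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  keep <- bitwAnd(flag, 4L) == 0L &           # mapped
    bitwAnd(flag, 256L) == 0L &               # primary
    bitwAnd(flag, 2048L) == 0L &              # not supplementary
    (bitwAnd(flag, 1L) == 0L | bitwAnd(flag, 64L) != 0L)  # read1/unpaired
  f <- f[keep]; flag <- flag[keep]
  pos <- vapply(f, function(x) as.numeric(x[4]), numeric(1))
  span <- cigar_reference_span(vapply(f, `[`, character(1), 6))
  read_strand <- ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")
  frag_strand <- if (protocol == "reverse") {
    ifelse(read_strand == "+", "-", "+")
  } else {
    read_strand
  }
  data.frame(chrom = vapply(f, `[`, character(1), 3),
             start = pos - 1,
             end = pos - 1 + span,
             fragment_id = vapply(f, `[`, character(1), 1),
             strand = frag_strand,
             stringsAsFactors = FALSE)
}

#' Strand-specific fragment counting over gene exons
#'
#' A fragment is assigned to a gene when it overlaps at least
#' `min_overlap` bp of the gene's exonic sequence on the same strand.
#' Fragments matching two or more genes on that strand are dropped as
#' ambiguous; fragments matching none stay unassigned.  Per-sample totals
#' always satisfy assigned + ambiguous + unassigned = fragments.
#'
#' @param fragments named list (one entry per sample id) of fragment
#'   data.frames (see [read_fragments_bed6]), or `NULL` to read the files
#'   named in the sample sheet's `path` column.
#' @param samples a [sample_sheet].
#' @param ann the [genome_annotation] (genes = union of exons per
#'   `gene_id`).
#' @param min_overlap minimum exonic overlap in bp (default 1).
#' @return a `count_matrix` object: list with `counts` (genes x samples
#'   integer matrix), `samples`, `size_factors` (`NULL` until estimated)
#'   and `summary` (per-sample assignment accounting).
#' @export
count_fragments <- function(fragments = NULL, samples, ann,
                            min_overlap = 1L) {
  if (is.null(fragments)) {
    if (all(is.na(samples$path))) {
      stop("no fragments given and sample sheet has no path column")
    }
    fragments <- lapply(stats::setNames(samples$path, samples$sample_id),
                        read_fragments_bed6)
  }
  if (!setequal(names(fragments), samples$sample_id)) {
    stop("fragment list names do not match the sample sheet sample ids")
  }

  gene_ids <- sort(unique(ann$transcripts$gene_id))
  ## union of exons per gene (per strand/chrom, genes are single-stranded)
  gr <- ann$exon_gr
  gene_ex <- GenomicRanges::reduce(
    S4Vectors::split(gr, S4Vectors::mcols(gr)$gene_id))
  gene_ex <- gene_ex[gene_ids]
  flat <- unlist(gene_ex, use.names = FALSE)
  flat_gene <- rep(names(gene_ex), lengths(gene_ex))

  counts <- matrix(0L, nrow = length(gene_ids), ncol = nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  summ <- data.frame(sample_id = samples$sample_id, total = 0L,
                     assigned = 0L, ambiguous = 0L, unassigned = 0L)
  for (si in seq_len(nrow(samples))) {
    sid <- samples$sample_id[si]
    fr <- fragments[[sid]]
    nf <- nrow(fr)
    summ$total[si] <- nf
    if (nf == 0L) next
    bad <- setdiff(unique(fr$chrom), names(ann$chrom_lengths))
    if (length(bad)) {
      stop("fragment on unknown chromosome ", bad[1], " in sample ", sid)
    }
    fgr <- GenomicRanges::GRanges(
      seqnames = fr$chrom,
      ranges = IRanges::IRanges(start = fr$start + 1L, end = fr$end),
      strand = fr$strand)
    hits <- GenomicRanges::findOverlaps(fgr, flat,
                                        minoverlap = as.integer(min_overlap))
    if (length(hits)) {
      hg <- unique(data.frame(q = S4Vectors::queryHits(hits),
                              g = flat_gene[S4Vectors::subjectHits(hits)]))
      ngenes <- table(hg$q)
      uniq_q <- as.integer(names(ngenes)[ngenes == 1L])
      amb_q <- as.integer(names(ngenes)[ngenes > 1L])
      assigned_genes <- hg$g[hg$q %in% uniq_q]
      tab <- table(assigned_genes)
      counts[names(tab), si] <- as.integer(tab)
      summ$assigned[si] <- length(uniq_q)
      summ$ambiguous[si] <- length(amb_q)
      summ$unassigned[si] <- nf - length(uniq_q) - length(amb_q)
    } else {
      summ$unassigned[si] <- nf
    }
  }
  count_matrix(counts, samples, summary = summ)
}

#' Bundle counts and sample metadata into a count matrix
#' @param counts genes x samples non-negative integer matrix with
#'   dimnames.
#' @param samples a [sample_sheet] matching the columns.
#' @param size_factors optional per-sample positive size factors.
#' @param summary optional assignment summary.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, size_factors = NULL,
                         summary = NULL) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (ncol(counts) != nrow(samples) ||
      !identical(colnames(counts), samples$sample_id)) {
    stop("count matrix columns must match the sample sheet sample ids")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!is.null(size_factors)) {
    if (length(size_factors) != ncol(counts) || any(size_factors <= 0) ||
        any(!is.finite(size_factors))) {
      stop("size factors must be finite positives, one per sample")
    }
  }
  structure(list(counts = counts, samples = samples,
                 size_factors = size_factors, summary = summary),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' The per-sample scaling constant of the median-of-ratios scheme: each
#' gene with strictly positive counts in every sample defines a reference
#' (its geometric mean across samples); a sample's factor is the median of
#' its count/reference ratios over those genes.  The factors are then
#' rescaled to geometric mean 1 so that the normalized scale is anchored.
#'
#' @param cm a `count_matrix` (or a plain counts matrix).
#' @return named numeric vector of size factors (geometric mean 1).
#' @examples
#' m <- matrix(c(10, 20, 40, 20, 40, 80), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' # sample b is a doubled copy of a: factors (1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(cm) {
  k <- if (is(cm, "count_matrix")) cm$counts else cm
  if (ncol(k) < 2L) stop("size-factor estimation needs at least 2 samples")
  allpos <- rowSums(k > 0) == ncol(k)
  if (!any(allpos)) {
    stop("no gene has positive counts in every sample; ",
         "filter low-count genes before normalization")
  }
  kk <- k[allpos, , drop = FALSE]
  ref <- exp(rowMeans(log(kk)))
  s <- apply(kk / ref, 2, stats::median)
  s <- s / exp(mean(log(s)))   # anchor: geometric mean 1
  stats::setNames(s, colnames(k))
}

#' Normalize counts by size factors
#'
#' @param cm a `count_matrix` or plain counts matrix.
#' @param size_factors per-sample factors; defaults to the ones stored in
#'   `cm`, estimating them if absent.
#' @return real-valued matrix `counts[g, j] / s_j`.
#' @export
normalize_counts <- function(cm, size_factors = NULL) {
  k <- if (is(cm, "count_matrix")) cm$counts else cm
  if (is.null(size_factors) && is(cm, "count_matrix")) {
    size_factors <- cm$size_factors
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(cm)
  sweep(k, 2, size_factors, "/")
}

#' log2(normalized + 1) expression view
#'
#' The transform used for PCA and for sense/antisense correlation.
#'
#' @inheritParams normalize_counts
#' @return matrix of log2(normalized count + 1).
#' @export
log2_normalized <- function(cm, size_factors = NULL) {
  log2(normalize_counts(cm, size_factors) + 1)
}

#' Write a counts (or normalized) matrix as TSV
#' @param m matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts matrix TSV (gene_id column + one column per sample)
#' @param path TSV path.
#' @param samples a [sample_sheet] naming the expected columns.
#' @return a `count_matrix`.
#' @export
read_count_matrix <- function(path, samples) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  if (!all(samples$sample_id %in% colnames(m))) {
    stop("count matrix is missing sample columns from the sample sheet")
  }
  count_matrix(m[, samples$sample_id, drop = FALSE], samples)
}
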