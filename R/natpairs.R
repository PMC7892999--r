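## Sense/antisense pair detection and the three-criterion co-expression
## screen: (1) both members differentially expressed, (2) antisense exonic
## overlap, (3) joint Pearson + Spearman correlation with |r| >= 0.70 and
## p < 0.01.

#' Find all sense/antisense transcript pairs
#'
#' Enumerates every (coding, noncoding) transcript pair on opposite
#' strands with at least 1 bp of exon-vs-exon overlap.  The coding side is
#' taken from declared biotypes in the annotation; the noncoding side from
#' the supplied biotype calls (or declared noncoding biotypes).
#'
#' @param ann a [genome_annotation] holding both reference and novel
#'   transcripts.
#' @param biotypes optional data.frame (`transcript_id`, `biotype`) from
#'   [classify_transcripts]; merged over declared biotypes.
#' @return data.frame `sense_id`, `antisense_id`, `overlap_bp`,
#'   `exons_overlapped` (sense exons touched), `fully_overlapping` (one
#'   span contained in the other), sorted by (`sense_id`, `antisense_id`).
#' @export
find_antisense_pairs <- function(ann, biotypes = NULL) {
  tx <- ann$transcripts
  bio <- ifelse(is.na(tx$declared_biotype), "coding", tx$declared_biotype)
  if (!is.null(biotypes)) {
    i <- match(tx$transcript_id, biotypes$transcript_id)
    bio[!is.na(i)] <- biotypes$biotype[i[!is.na(i)]]
  }
  coding_ids <- tx$transcript_id[bio == "coding"]
  nonc_ids <- tx$transcript_id[bio == "noncoding"]
  empty <- data.frame(sense_id = character(0), antisense_id = character(0),
                      overlap_bp = numeric(0), exons_overlapped = integer(0),
                      fully_overlapping = logical(0))
  if (!length(coding_ids) || !length(nonc_ids)) return(empty)

  gr <- ann$exon_gr
  m <- S4Vectors::mcols(gr)$transcript_id
  cod_gr <- gr[m %in% coding_ids]
  non_gr <- gr[m %in% nonc_ids]
  ## flip the noncoding strand so a same-strand overlap query finds
  ## opposite-strand partners
  flipped <- non_gr
  GenomicRanges::strand(flipped) <- ifelse(
    as.character(GenomicRanges::strand(non_gr)) == "+", "-", "+")
  hits <- GenomicRanges::findOverlaps(flipped, cod_gr)
  if (!length(hits)) return(empty)
  pairs <- unique(data.frame(
    sense_id = S4Vectors::mcols(cod_gr)$transcript_id[
      S4Vectors::subjectHits(hits)],
    antisense_id = S4Vectors::mcols(non_gr)$transcript_id[
      S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE))

  out <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- pairs$sense_id[i]; a <- pairs$antisense_id[i]
    ov <- exonic_antisense_overlap(ann, a, s)
    ts <- ann$transcripts[s, ]; ta <- ann$transcripts[a, ]
    data.frame(sense_id = s, antisense_id = a,
               overlap_bp = ov$overlap_bp,
               exons_overlapped = ov$exons_overlapped,
               fully_overlapping =
                 (ta$start >= ts$start && ta$end <= ts$end) ||
                 (ts$start >= ta$start && ts$end <= ta$end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$overlap_bp >= 1, , drop = FALSE]
  out <- out[order(out$sense_id, out$antisense_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## average ranks with ties shared, as used for Spearman
avg_rank <- function(x) rank(x, ties.method = "average")

pearson_with_p <- function(x, y) {
  n <- length(x)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    return(list(r = NA_real_, p = NA_real_, defined = FALSE))
  }
  r <- stats::cor(x, y)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) {
    return(list(r = r, p = 0, defined = TRUE))
  }
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2), defined = TRUE)
}

#' Pearson and Spearman correlation with p values
#'
#' Pearson r with the two-sided p from `t = r sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom; Spearman rho as Pearson on average ranks
#' (ties shared) with the same t approximation.  Degenerate (zero
#' variance) input yields an undefined result, excluded downstream.  An
#' optional seeded Monte-Carlo permutation p value is available for
#' verifying the t approximation.
#'
#' @param x,y numeric expression vectors of equal length `n >= 4`;
#'   conventionally log2(normalized + 1) values across the samples.
#' @param n_perm if > 0, also compute permutation p values from this many
#'   seeded permutations.
#' @param perm_seed seed for the permutation draw.
#' @return list with `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `n`, `defined`, and (when `n_perm > 0`)
#'   `pearson_p_perm`, `spearman_p_perm`.
#' @export
correlation_with_p <- function(x, y, n_perm = 0, perm_seed = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("correlation needs at least 4 samples")
  pe <- pearson_with_p(x, y)
  sp <- pearson_with_p(avg_rank(x), avg_rank(y))
  out <- list(pearson_r = pe$r, pearson_p = pe$p,
              spearman_rho = sp$r, spearman_p = sp$p,
              n = n, defined = pe$defined && sp$defined)
  if (n_perm > 0 && out$defined) {
    rx <- avg_rank(x); ry <- avg_rank(y)
    set.seed(perm_seed)
    hits_p <- 0L; hits_s <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      if (abs(stats::cor(x, y[perm])) >= abs(pe$r) - 1e-12) {
        hits_p <- hits_p + 1L
      }
      if (abs(stats::cor(rx, ry[perm])) >= abs(sp$r) - 1e-12) {
        hits_s <- hits_s + 1L
      }
    }
    out$pearson_p_perm <- (hits_p + 1) / (n_perm + 1)
    out$spearman_p_perm <- (hits_s + 1) / (n_perm + 1)
  }
  out
}

#' Select candidate regulatory lncNAT pairs
#'
#' Applies the three selection criteria to all antisense pairs: both
#' members must be significantly differentially expressed (Bonferroni
#' adjusted p strictly below `cfg$de_adj_p_max`), the pair must overlap
#' antisense (already true of the input), and both correlation families
#' must jointly pass `|r| >= cfg$corr_abs_min` with `p < cfg$corr_p_max`.
#' Concordance is the sign of the Pearson correlation: concordant pairs
#' co-vary, discordant pairs move in opposite directions.
#'
#' @param pairs result of [find_antisense_pairs].
#' @param de differential-expression table from [wald_de_test] for the
#'   overall genotype contrast (gene-level; transcript ids are looked up
#'   via the annotation's gene ids when `ann` is given, else used as-is).
#' @param expr expression matrix for correlation, conventionally
#'   [log2_normalized] counts over all samples; rownames are gene ids.
#' @param ann optional [genome_annotation] to map transcript ids to gene
#'   ids for the DE and expression lookups.
#' @param cfg a [thresholds_config].
#' @return data.frame of selected pairs sorted by |pearson_r| descending:
#'   sense/antisense ids, overlap fields, both correlation families,
#'   member log2 fold changes and `concordance`.
#' @export
select_candidate_nats <- function(pairs, de, expr, ann = NULL,
                                  cfg = thresholds_config()) {
  gene_of <- function(id) {
    if (is.null(ann)) return(id)
    i <- match(id, ann$transcripts$transcript_id)
    ifelse(is.na(i), id, ann$transcripts$gene_id[i])
  }
  empty <- data.frame(
    sense_id = character(0), antisense_id = character(0),
    overlap_bp = numeric(0), fully_overlapping = logical(0),
    pearson_r = numeric(0), pearson_p = numeric(0),
    spearman_rho = numeric(0), spearman_p = numeric(0),
    sense_log2FC = numeric(0), antisense_log2FC = numeric(0),
    concordance = character(0))
  if (nrow(pairs) == 0L) return(empty)

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sg <- gene_of(pairs$sense_id[i]); ag <- gene_of(pairs$antisense_id[i])
    for (g in c(sg, ag)) {
      if (!g %in% rownames(expr)) {
        stop("gene ", g, " is missing from the expression matrix")
      }
    }
    ds <- de[de$gene_id == sg, ]; da <- de[de$gene_id == ag, ]
    if (nrow(ds) == 0L || nrow(da) == 0L) {
      stop("gene ", if (nrow(ds) == 0L) sg else ag,
           " is missing from the differential-expression table")
    }
    if (!isTRUE(ds$significant[1]) || !isTRUE(da$significant[1])) {
      return(NULL)
    }
    co <- correlation_with_p(expr[sg, ], expr[ag, ])
    if (!co$defined) return(NULL)
    pass <- abs(co$pearson_r) >= cfg$corr_abs_min &&
      abs(co$spearman_rho) >= cfg$corr_abs_min &&
      co$pearson_p < cfg$corr_p_max && co$spearman_p < cfg$corr_p_max
    if (!pass) return(NULL)
    data.frame(
      sense_id = pairs$sense_id[i], antisense_id = pairs$antisense_id[i],
      overlap_bp = pairs$overlap_bp[i],
      fully_overlapping = pairs$fully_overlapping[i],
      pearson_r = co$pearson_r, pearson_p = co$pearson_p,
      spearman_rho = co$spearman_rho, spearman_p = co$spearman_p,
      sense_log2FC = ds$log2FC[1], antisense_log2FC = da$log2FC[1],
      concordance = if (co$pearson_r >= 0) "concordant" else "discordant",
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$pearson_r), out$sense_id, out$antisense_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write candidate NAT pairs as TSV
#' @param nats result of [select_candidate_nats].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nat_candidates <- function(nats, path) {
  utils::write.table(nats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
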