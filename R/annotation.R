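#' @importFrom methods is
#' @importFrom stats median complete.cases
NULL

STRANDS <- c("+", "-")

## Internal convention: all coordinates in a `genome_annotation` are 0-based
## half-open [start, end).  GFF3/GTF I/O and GRanges construction convert at
## the boundary, so interval arithmetic inside the package never carries
## +/-1 corrections.

#' Build a genome annotation from exon and transcript tables
#'
#' The central container of the package: a set of stranded, multi-exon
#' transcript models plus chromosome lengths and an interval index used for
#' overlap queries.
#'
#' @param exons data.frame with columns `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`; coordinates 0-based half-open.
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   and optionally `origin` (`"known"` or `"novel"`) and `declared_biotype`
#'   (`"coding"`, `"noncoding"`, `"structural"` or `NA`).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#'   If `NULL`, lengths are taken as the maximum exon end per chromosome.
#' @return An object of class `genome_annotation` with elements
#'   `chrom_lengths`, `transcripts` (one row per transcript, with span
#'   `start`/`end`, `n_exons` and spliced `length`), `exons` (sorted), and
#'   a GRanges exon index.
#' @export
genome_annotation <- function(exons, transcripts, chrom_lengths = NULL) {
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(exons))) {
    stop("exons must have columns: ", paste(need, collapse = ", "))
  }
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  if (nrow(exons) == 0L) {
    if (nrow(as.data.frame(transcripts)) > 0L) {
      stop("transcript without exon rows: ",
           as.data.frame(transcripts)$transcript_id[1])
    }
    tx0 <- data.frame(transcript_id = character(0), chrom = character(0),
                      strand = character(0), start = numeric(0),
                      end = numeric(0), n_exons = integer(0),
                      length = numeric(0), gene_id = character(0),
                      origin = character(0),
                      declared_biotype = character(0))
    return(structure(
      list(chrom_lengths = stats::setNames(as.numeric(chrom_lengths),
                                           names(chrom_lengths)),
           transcripts = tx0, exons = exons,
           exon_gr = GenomicRanges::GRanges(
             transcript_id = character(0), gene_id = character(0))),
      class = "genome_annotation"))
  }
  bad <- !(exons$strand %in% STRANDS)
  if (any(bad)) {
    stop("unknown strand symbol '", exons$strand[which(bad)[1]],
         "' (transcript ", exons$transcript_id[which(bad)[1]],
         "); strands must be '+' or '-'")
  }
  if (any(exons$start < 0)) stop("negative exon start coordinate")
  if (any(exons$end <= exons$start)) {
    i <- which(exons$end <= exons$start)[1]
    stop("exon with end <= start for transcript ", exons$transcript_id[i])
  }

  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% names(transcripts))) {
    stop("transcripts must have columns transcript_id and gene_id")
  }
  transcripts$transcript_id <- as.character(transcripts$transcript_id)
  transcripts$gene_id <- as.character(transcripts$gene_id)
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicated transcript_id in transcript table")
  }
  if (is.null(transcripts$origin)) transcripts$origin <- "known"
  if (is.null(transcripts$declared_biotype)) {
    transcripts$declared_biotype <- NA_character_
  }
  known_bio <- c("coding", "noncoding", "structural")
  badb <- !is.na(transcripts$declared_biotype) &
    !(transcripts$declared_biotype %in% known_bio)
  if (any(badb)) {
    stop("unknown declared_biotype '",
         transcripts$declared_biotype[which(badb)[1]], "'")
  }

  missing_tx <- setdiff(transcripts$transcript_id, exons$transcript_id)
  if (length(missing_tx)) {
    stop("transcript without exon rows: ", missing_tx[1])
  }
  orphan <- setdiff(exons$transcript_id, transcripts$transcript_id)
  if (length(orphan)) {
    stop("exon rows for unknown transcript: ", orphan[1])
  }

  ## per-transcript consistency: one chrom, one strand, no exon overlap
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (tid in names(sp)) {
    idx <- sp[[tid]]
    if (length(unique(exons$chrom[idx])) != 1L) {
      stop("transcript ", tid, " has exons on multiple chromosomes")
    }
    if (length(unique(exons$strand[idx])) != 1L) {
      stop("transcript ", tid, " has exons on both strands")
    }
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1] < e[-length(e)])) {
        stop("transcript ", tid, " has overlapping exons")
      }
    }
  }
  first <- vapply(sp, `[`, integer(1), 1L)
  ord_tx <- names(sp)
  tx <- data.frame(
    transcript_id = ord_tx,
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    start = vapply(sp, function(i) min(exons$start[i]), numeric(1)),
    end = vapply(sp, function(i) max(exons$end[i]), numeric(1)),
    n_exons = lengths(sp),
    length = vapply(sp, function(i) sum(exons$end[i] - exons$start[i]),
                    numeric(1)),
    stringsAsFactors = FALSE
  )
  meta <- transcripts[match(ord_tx, transcripts$transcript_id),
                      c("transcript_id", "gene_id", "origin",
                        "declared_biotype")]
  tx <- cbind(tx, meta[, c("gene_id", "origin", "declared_biotype"),
                       drop = FALSE])
  rownames(tx) <- NULL

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(exons$end, exons$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  } else {
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
    absent <- setdiff(unique(exons$chrom), names(chrom_lengths))
    if (length(absent)) {
      stop("exons on chromosome absent from chrom_lengths: ", absent[1])
    }
    lim <- chrom_lengths[exons$chrom]
    if (any(exons$end > lim)) {
      i <- which(exons$end > lim)[1]
      stop("exon of transcript ", exons$transcript_id[i],
           " extends past the end of ", exons$chrom[i])
    }
  }

  ## deterministic ordering: (chrom, start, transcript_id)
  tx <- tx[order(tx$chrom, tx$start, tx$transcript_id), , drop = FALSE]
  rownames(tx) <- tx$transcript_id
  exons <- exons[order(exons$chrom, exons$start, exons$transcript_id), ,
                 drop = FALSE]
  rownames(exons) <- NULL

  gidx <- match(exons$transcript_id, tx$transcript_id)
  exon_gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand,
    transcript_id = exons$transcript_id,
    gene_id = tx$gene_id[gidx]
  )

  structure(
    list(chrom_lengths = chrom_lengths,
         transcripts = tx,
         exons = exons,
         exon_gr = exon_gr),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$transcripts), "transcripts /",
      length(unique(x$transcripts$gene_id)), "genes on",
      length(x$chrom_lengths), "chromosomes\n")
  org <- table(x$transcripts$origin)
  cat("  origin:", paste(names(org), org, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of transcripts in an annotation
#' @param ann a `genome_annotation`.
#' @return integer count.
#' @export
n_transcripts <- function(ann) nrow(ann$transcripts)

#' Extract a subset of transcripts as a new annotation
#' @param ann a `genome_annotation`.
#' @param transcript_ids character vector of transcript ids to keep.
#' @return a `genome_annotation` restricted to those transcripts.
#' @export
subset_annotation <- function(ann, transcript_ids) {
  keep_tx <- ann$transcripts[ann$transcripts$transcript_id %in%
                               transcript_ids, , drop = FALSE]
  keep_ex <- ann$exons[ann$exons$transcript_id %in% transcript_ids, ,
                       drop = FALSE]
  genome_annotation(keep_ex, keep_tx, ann$chrom_lengths)
}

#' Merge two annotations into one
#' @param a,b `genome_annotation` objects with compatible chromosomes.
#' @return a combined `genome_annotation`.
#' @export
merge_annotations <- function(a, b) {
  cl <- a$chrom_lengths
  for (nm in names(b$chrom_lengths)) {
    cl[nm] <- max(cl[nm], b$chrom_lengths[nm], na.rm = TRUE)
  }
  genome_annotation(
    rbind(a$exons, b$exons),
    rbind(a$transcripts[, c("transcript_id", "gene_id", "origin",
                            "declared_biotype")],
          b$transcripts[, c("transcript_id", "gene_id", "origin",
                            "declared_biotype")]),
    cl
  )
}

#' Spliced transcript length
#'
#' Length of the mature (spliced) transcript: the sum of its exon lengths,
#' not the genomic span.  This is the quantity the "> 200 nt" long-RNA
#' filter is applied to.
#'
#' @param ann a `genome_annotation`.
#' @param transcript_id one or more transcript ids; default all.
#' @return named numeric vector of spliced lengths (nt).
#' @examples
#' ann <- genome_annotation(
#'   exons = data.frame(transcript_id = "t1", chrom = "chr1",
#'                      start = c(0, 300), end = c(120, 380), strand = "+"),
#'   transcripts = data.frame(transcript_id = "t1", gene_id = "g1"))
#' transcript_length(ann, "t1")  # 200
#' @export
transcript_length <- function(ann, transcript_id = NULL) {
  if (is.null(transcript_id)) {
    stats::setNames(ann$transcripts$length, ann$transcripts$transcript_id)
  } else {
    i <- match(transcript_id, ann$transcripts$transcript_id)
    if (anyNA(i)) stop("unknown transcript: ", transcript_id[is.na(i)][1])
    stats::setNames(ann$transcripts$length[i], transcript_id)
  }
}

## exon table for one transcript, sorted by start
tx_exons <- function(ann, transcript_id) {
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop("unknown transcript: ", transcript_id)
  ex[order(ex$start), , drop = FALSE]
}

## total bp of pairwise interval intersection between two exon sets
## (exons within each set are disjoint, so the sum is the true overlap)
interval_overlap_bp <- function(s1, e1, s2, e2) {
  tot <- 0
  for (i in seq_along(s1)) {
    ov <- pmin(e1[i], e2) - pmax(s1[i], s2)
    tot <- tot + sum(ov[ov > 0])
  }
  tot
}

#' Exon-level antisense overlap between two transcripts
#'
#' Measures how much exonic sequence two transcripts on opposite strands
#' share: the quantity behind the natural-antisense-transcript definition
#' ("antisense of a coding gene, overlapping at least one of its exons").
#'
#' @param ann a `genome_annotation`.
#' @param a,b transcript ids; must lie on the same chromosome and on
#'   opposite strands, otherwise an error is raised.
#' @return list with `overlap_bp` (total exon-vs-exon intersection, bp) and
#'   `exons_overlapped` (number of `b`'s exons with >= 1 bp intersection).
#' @export
exonic_antisense_overlap <- function(ann, a, b) {
  ea <- tx_exons(ann, a)
  eb <- tx_exons(ann, b)
  if (ea$chrom[1] != eb$chrom[1]) {
    stop("transcripts ", a, " and ", b, " are on different chromosomes")
  }
  if (ea$strand[1] == eb$strand[1]) {
    stop("transcripts ", a, " and ", b,
         " are on the same strand; antisense overlap is undefined")
  }
  bp <- interval_overlap_bp(ea$start, ea$end, eb$start, eb$end)
  touched <- vapply(seq_len(nrow(eb)), function(j) {
    any(pmin(ea$end, eb$end[j]) - pmax(ea$start, eb$start[j]) > 0)
  }, logical(1))
  list(overlap_bp = bp, exons_overlapped = sum(touched))
}

#' Distance from a transcript to the nearest protein-coding gene
#'
#' Span-to-span, strand-agnostic gap length; any overlap (either strand)
#' gives distance 0.  Transcripts in the reference whose declared biotype
#' is missing are treated as coding (the usual case for a reference mRNA
#' annotation).
#'
#' @param ann annotation holding the transcript (and usually the reference).
#' @param transcript_id the query transcript.
#' @param ref annotation providing the coding genes; defaults to `ann`.
#' @return distance in bp, or `Inf` when the chromosome carries no coding
#'   gene other than the query's own gene.
#' @export
distance_to_nearest_coding_gene <- function(ann, transcript_id, ref = ann) {
  i <- match(transcript_id, ann$transcripts$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  q <- ann$transcripts[i, ]
  cod <- coding_transcripts(ref)
  cod <- cod[cod$chrom == q$chrom &
               cod$transcript_id != transcript_id, , drop = FALSE]
  if (nrow(cod) == 0L) return(Inf)
  gap <- pmax(cod$start - q$end, q$start - cod$end)
  min(pmax(gap, 0))
}

## reference transcripts considered protein-coding
coding_transcripts <- function(ann) {
  tx <- ann$transcripts
  tx[is.na(tx$declared_biotype) | tx$declared_biotype == "coding", ,
     drop = FALSE]
}

#' Transcripts whose exons overlap a query interval
#'
#' Indexed overlap lookup used by the classification rules; guaranteed (and
#' property-tested) to agree with a brute-force scan over all exons.
#'
#' @param ann a `genome_annotation`.
#' @param chrom chromosome name.
#' @param start,end query interval, 0-based half-open.
#' @param strand `"+"`, `"-"`, or `NULL` for both strands.
#' @return character vector of transcript ids, sorted.
#' @export
query_overlapping_transcripts <- function(ann, chrom, start, end,
                                          strand = NULL) {
  q <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = if (is.null(strand)) "*" else strand
  )
  hits <- GenomicRanges::findOverlaps(q, ann$exon_gr,
                                      ignore.strand = is.null(strand))
  ids <- S4Vectors::mcols(ann$exon_gr)$transcript_id[
    S4Vectors::subjectHits(hits)]
  sort(unique(ids))
}

## intron intervals (0-based half-open) of one transcript; empty for
## single-exon models
tx_introns <- function(ann, transcript_id) {
  ex <- tx_exons(ann, transcript_id)
  k <- nrow(ex)
  if (k < 2L) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  data.frame(start = ex$end[-k], end = ex$start[-1])
}
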