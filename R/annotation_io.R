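## GFF3 / GTF / FASTA input and output.
##
## External files use the 1-based inclusive convention of GFF; everything
## internal is 0-based half-open.  The conversion happens here and nowhere
## else.

TRANSCRIPT_TYPES <- c("transcript", "mRNA", "lnc_RNA", "lincRNA", "ncRNA",
                      "antisense_RNA", "pseudogenic_transcript")

## cheap structural scan so parse failures can name the offending line
prescan_gff <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      stop("malformed annotation line ", i, " in ", path,
           ": expected 9 tab-separated fields, found ", length(f))
    }
    s <- suppressWarnings(as.numeric(f[4]))
    e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e)) {
      stop("malformed annotation line ", i, " in ", path,
           ": non-numeric coordinates")
    }
    if (e < s) {
      stop("annotation line ", i, " in ", path,
           ": end (", e, ") is smaller than start (", s, ")")
    }
  }
  lines
}

## ##sequence-region pragmas, if present
gff_sequence_regions <- function(lines) {
  sr <- grep("^##sequence-region", lines, value = TRUE)
  if (!length(sr)) return(NULL)
  parts <- strsplit(trimws(sr), "\\s+")
  stats::setNames(
    vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
    vapply(parts, function(p) p[2], character(1))
  )
}

#' Read a GFF3 or GTF annotation
#'
#' Imports transcript models from a GFF3 (or GTF) file into the internal
#' 0-based half-open representation.  Exons are grouped per transcript via
#' `Parent` (GFF3) or `transcript_id` (GTF); a `biotype` attribute on the
#' transcript record, when present, populates the declared biotype.
#' Chromosome lengths are taken from `##sequence-region` pragmas when
#' available, otherwise from the right-most exon per chromosome.
#'
#' @param path path to a `.gff3`/`.gff` or `.gtf` file.
#' @return a [genome_annotation].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- prescan_gff(path)
  gr <- rtracklayer::import(path)
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)

  is_gtf <- grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE) ||
    (!is.null(m$transcript_id) && is.null(m$Parent))

  ex <- gr[type == "exon"]
  if (length(ex) == 0L) stop("no exon records in ", path)
  me <- S4Vectors::mcols(ex)
  if (is_gtf) {
    ex_tx <- as.character(me$transcript_id)
  } else {
    par <- me$Parent
    ex_tx <- vapply(seq_along(par), function(i) {
      p <- par[[i]]
      if (length(p) == 0L) NA_character_ else as.character(p[1])
    }, character(1))
  }
  if (anyNA(ex_tx)) stop("exon record without a transcript parent in ", path)

  exons <- data.frame(
    transcript_id = ex_tx,
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE
  )

  ## transcript-level metadata
  tx_ids <- unique(ex_tx)
  gene_id <- stats::setNames(tx_ids, tx_ids)  # fallback: own id
  biotype <- stats::setNames(rep(NA_character_, length(tx_ids)), tx_ids)
  origin <- stats::setNames(rep("known", length(tx_ids)), tx_ids)
  trow <- gr[type %in% TRANSCRIPT_TYPES]
  if (length(trow)) {
    mt <- S4Vectors::mcols(trow)
    tid <- if (!is.null(mt$transcript_id) && is_gtf) {
      as.character(mt$transcript_id)
    } else {
      as.character(mt$ID)
    }
    orphan <- setdiff(tid, tx_ids)
    if (length(orphan)) {
      stop("transcript ", orphan[1], " has no exon records in ", path)
    }
    for (i in seq_along(tid)) {
      id <- tid[i]
      if (!(id %in% tx_ids)) next
      g <- NULL
      if (!is.null(mt$gene_id)) g <- as.character(mt$gene_id[i])
      if ((is.null(g) || is.na(g)) && !is.null(mt$Parent)) {
        p <- mt$Parent[[i]]
        if (length(p)) g <- as.character(p[1])
      }
      if (!is.null(g) && !is.na(g)) gene_id[id] <- g
      if (!is.null(mt$biotype) && !is.na(mt$biotype[i])) {
        biotype[id] <- as.character(mt$biotype[i])
      }
      if (!is.null(mt$origin) && !is.na(mt$origin[i])) {
        origin[id] <- as.character(mt$origin[i])
      }
    }
  } else if (is_gtf && !is.null(me$gene_id)) {
    g <- as.character(me$gene_id)
    gene_id[ex_tx] <- g
  }

  transcripts <- data.frame(
    transcript_id = tx_ids,
    gene_id = unname(gene_id[tx_ids]),
    origin = unname(origin[tx_ids]),
    declared_biotype = unname(biotype[tx_ids]),
    stringsAsFactors = FALSE
  )

  genome_annotation(exons, transcripts,
                    chrom_lengths = gff_sequence_regions(lines))
}

## one GFF3 attribute string from a named character vector, NAs dropped
gff_attrs <- function(x) {
  x <- x[!is.na(x)]
  paste(paste0(names(x), "=", x), collapse = ";")
}

#' Write an annotation as GFF3
#'
#' Deterministic output: records are ordered by (chromosome, start,
#' transcript id), one `##sequence-region` pragma is emitted per
#' chromosome, and coordinates are converted back to the 1-based inclusive
#' GFF convention.  Two calls on the same annotation produce byte-identical
#' files.
#'
#' @param ann a [genome_annotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  out <- c("##gff-version 3")
  for (ch in sort(names(ann$chrom_lengths))) {
    out <- c(out, sprintf("##sequence-region %s 1 %d", ch,
                          as.integer(ann$chrom_lengths[ch])))
  }
  tx <- ann$transcripts
  tx <- tx[order(tx$chrom, tx$start, tx$transcript_id), , drop = FALSE]
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    at <- c(ID = t$transcript_id, gene_id = t$gene_id, origin = t$origin,
            biotype = t$declared_biotype)
    out <- c(out, paste(t$chrom, "lncnat", "transcript",
                        format(t$start + 1, scientific = FALSE),
                        format(t$end, scientific = FALSE),
                        ".", t$strand, ".", gff_attrs(at), sep = "\t"))
    ex <- tx_exons(ann, t$transcript_id)
    for (j in seq_len(nrow(ex))) {
      at <- c(ID = sprintf("%s.exon%d", t$transcript_id, j),
              Parent = t$transcript_id)
      out <- c(out, paste(ex$chrom[j], "lncnat", "exon",
                          format(ex$start[j] + 1, scientific = FALSE),
                          format(ex$end[j], scientific = FALSE),
                          ".", ex$strand[j], ".", gff_attrs(at), sep = "\t"))
    }
  }
  writeLines(out, con)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences; names are the
#'   header token before the first whitespace.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1])
  }
  stats::setNames(toupper(as.character(ss)), nm)
}

#' Write genome sequences as FASTA
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(sequences, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Spliced cDNA sequence of a transcript
#'
#' Concatenates the exon sequences in transcript order; minus-strand
#' transcripts are reverse-complemented so the result reads 5' to 3'.
#'
#' @param ann a [genome_annotation].
#' @param sequences named character vector of chromosome sequences.
#' @param transcript_id the transcript.
#' @return character scalar cDNA sequence.
#' @export
spliced_sequence <- function(ann, sequences, transcript_id) {
  ex <- tx_exons(ann, transcript_id)
  chrom <- ex$chrom[1]
  if (!chrom %in% names(sequences)) {
    stop("no sequence for chromosome ", chrom)
  }
  parts <- substring(sequences[[chrom]], ex$start + 1, ex$end)
  s <- paste(parts, collapse = "")
  if (ex$strand[1] == "-") revcomp(s) else s
}

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N (case-insensitive).
#' @return reverse complement, upper case.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
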