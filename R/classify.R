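## Class-code assignment, the long-RNA filter, biotype rules and
## positional subclassification of noncoding transcripts.

CLASS_CODES <- c("equal", "sense_overlap", "x", "i", "u")
BIOTYPES <- c("coding", "structural", "noncoding")
SUBCLASSES <- c("lncNAT", "lincRNA", "intronic", "proximal")

## exon chain signature used for the "equal" code
exon_chain_key <- function(ann, transcript_id) {
  ex <- tx_exons(ann, transcript_id)
  paste(ex$chrom[1], ex$strand[1],
        paste(ex$start, ex$end, sep = "-", collapse = ","), sep = "|")
}

#' Assign a class code to novel transcripts against a reference
#'
#' Categorises each novel transcript by its positional relationship to the
#' reference annotation, with fixed precedence
#' `equal > sense_overlap > x > i > u`:
#' \describe{
#'   \item{equal}{identical exon chain to a reference transcript}
#'   \item{sense_overlap}{>= 1 bp exonic overlap on the same strand}
#'   \item{x}{>= 1 bp exonic overlap on the opposite strand only}
#'   \item{i}{fully contained in an intron of a reference transcript
#'     (either strand), with no exonic overlap}
#'   \item{u}{intergenic}
#' }
#'
#' @param novel a [genome_annotation] of novel transcripts.
#' @param ref the reference [genome_annotation].
#' @param transcript_id optionally restrict to these novel transcripts.
#' @return data.frame with columns `transcript_id`, `code`, `evidence`
#'   (the reference transcript triggering the call; `NA` for `u`).
#' @export
assign_class_code <- function(novel, ref, transcript_id = NULL) {
  ids <- transcript_id %||% novel$transcripts$transcript_id
  absent <- setdiff(unique(novel$transcripts[ids, "chrom"]),
                    names(ref$chrom_lengths))
  if (length(absent)) {
    stop("novel transcript on chromosome absent from the reference: ",
         absent[1])
  }
  ref_keys <- vapply(ref$transcripts$transcript_id,
                     function(t) exon_chain_key(ref, t), character(1))

  res <- lapply(ids, function(id) {
    q <- novel$transcripts[id, ]
    qex <- tx_exons(novel, id)

    key <- exon_chain_key(novel, id)
    hit <- which(ref_keys == key)
    if (length(hit)) {
      return(list(code = "equal",
                  evidence = ref$transcripts$transcript_id[hit[1]]))
    }

    ## exonic overlaps by strand, via the exon index of the reference
    same <- character(0); anti <- character(0)
    for (j in seq_len(nrow(qex))) {
      same <- c(same, query_overlapping_transcripts(
        ref, qex$chrom[j], qex$start[j], qex$end[j], strand = q$strand))
      anti <- c(anti, query_overlapping_transcripts(
        ref, qex$chrom[j], qex$start[j], qex$end[j],
        strand = setdiff(STRANDS, q$strand)))
    }
    same <- sort(unique(same)); anti <- sort(unique(anti))
    if (length(same)) return(list(code = "sense_overlap", evidence = same[1]))
    if (length(anti)) return(list(code = "x", evidence = anti[1]))

    ## intron containment (either strand, no exonic overlap)
    cand <- ref$transcripts
    cand <- cand[cand$chrom == q$chrom & cand$start <= q$start &
                   cand$end >= q$end & cand$n_exons > 1, , drop = FALSE]
    for (t in cand$transcript_id) {
      intr <- tx_introns(ref, t)
      if (any(intr$start <= q$start & intr$end >= q$end)) {
        return(list(code = "i", evidence = t))
      }
    }
    list(code = "u", evidence = NA_character_)
  })
  data.frame(
    transcript_id = ids,
    code = vapply(res, `[[`, character(1), "code"),
    evidence = vapply(res, `[[`, character(1), "evidence"),
    stringsAsFactors = FALSE
  )
}

#' Filter novel transcripts to candidate new loci
#'
#' Keeps transcripts that represent genuinely new loci (class code `u`,
#' `x` or `i`) and pass the long-RNA length filter (spliced length
#' strictly greater than `cfg$min_tx_len_nt`).  Transcripts matching or
#' sense-overlapping annotated loci are dropped.
#'
#' @param novel a [genome_annotation] of novel transcripts.
#' @param ref the reference [genome_annotation].
#' @param cfg a [thresholds_config].
#' @param codes optional precomputed result of [assign_class_code].
#' @return list with `retained` (a [genome_annotation], possibly empty ids),
#'   and `decisions` (per-transcript data.frame of code, length, kept).
#' @export
filter_novel_transcripts <- function(novel, ref, cfg = thresholds_config(),
                                     codes = NULL) {
  if (is.null(codes)) codes <- assign_class_code(novel, ref)
  len <- transcript_length(novel)[codes$transcript_id]
  keep <- codes$code %in% c("u", "x", "i") & len > cfg$min_tx_len_nt
  decisions <- data.frame(
    transcript_id = codes$transcript_id,
    code = codes$code,
    evidence = codes$evidence,
    length_nt = as.numeric(len),
    kept = keep,
    stringsAsFactors = FALSE
  )
  retained_ids <- codes$transcript_id[keep]
  retained <- if (length(retained_ids)) {
    subset_annotation(novel, retained_ids)
  } else {
    NULL
  }
  list(retained = retained, decisions = decisions)
}

EVIDENCE_VOCAB <- list(
  coding_potential = c("coding", "noncoding"),
  structural_homology = c("tRNA", "rRNA", "snRNA", "snoRNA"),
  known_ncRNA_homology = c("miRNA_precursor", "lncRNA")
)

#' Read an external-evidence table
#'
#' Evidence produced by external tools enters the pipeline as a TSV with
#' columns `transcript_id`, `evidence_type`, `value`.  Recognised types and
#' values: `coding_potential` (coding/noncoding), `structural_homology`
#' (tRNA/rRNA/snRNA/snoRNA), `known_ncRNA_homology`
#' (miRNA_precursor/lncRNA).  Contradictory rows for one transcript raise
#' an error.
#'
#' @param path TSV path, or `NULL` for an empty table.
#' @return data.frame evidence table (possibly zero rows).
#' @export
read_evidence_table <- function(path = NULL) {
  if (is.null(path)) {
    return(data.frame(transcript_id = character(0),
                      evidence_type = character(0),
                      value = character(0), stringsAsFactors = FALSE))
  }
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "evidence_type", "value")
  if (!all(need %in% names(ev))) {
    stop("evidence table must have columns: ", paste(need, collapse = ", "))
  }
  ev <- ev[, need]
  for (i in seq_len(nrow(ev))) {
    ty <- ev$evidence_type[i]
    if (!ty %in% names(EVIDENCE_VOCAB)) {
      stop("unknown evidence_type '", ty, "'")
    }
    if (!ev$value[i] %in% EVIDENCE_VOCAB[[ty]]) {
      stop("unknown value '", ev$value[i], "' for evidence_type ", ty)
    }
  }
  dup <- ev[, c("transcript_id", "evidence_type")]
  d <- duplicated(dup) | duplicated(dup, fromLast = TRUE)
  if (any(d)) {
    conf <- unique(ev[d, ])
    bad <- stats::aggregate(value ~ transcript_id + evidence_type, conf,
                            function(v) length(unique(v)))
    if (any(bad$value > 1)) {
      stop("contradictory evidence rows for transcript ",
           bad$transcript_id[bad$value > 1][1])
    }
    ev <- ev[!duplicated(dup), ]
  }
  ev
}

evidence_for <- function(evidence, transcript_id, type) {
  v <- evidence$value[evidence$transcript_id == transcript_id &
                        evidence$evidence_type == type]
  if (length(v)) v[1] else NA_character_
}

#' Coding / structural / noncoding verdict for one transcript
#'
#' Applies the ordered decision rules; the first match wins:
#' (1) coding when the longest forward ORF is strictly longer than 120 aa
#' or an external coding-potential verdict says coding; (2) structural
#' when a structural-RNA homology (tRNA/rRNA/snRNA/snoRNA) is recorded;
#' (3) noncoding otherwise — on an explicit noncoding verdict, a known
#' ncRNA homology, or by default when no evidence exists (a transcript
#' with no long ORF and no evidence is noncoding).
#'
#' @param transcript_id transcript being classified.
#' @param orf result of [longest_forward_orf] for its cDNA (or `NULL`).
#' @param evidence an evidence table from [read_evidence_table].
#' @param cfg a [thresholds_config].
#' @return list with `transcript_id`, `biotype`, `rule_fired`, `orf`.
#' @export
classify_biotype <- function(transcript_id, orf,
                             evidence = read_evidence_table(),
                             cfg = thresholds_config()) {
  cp <- evidence_for(evidence, transcript_id, "coding_potential")
  sh <- evidence_for(evidence, transcript_id, "structural_homology")
  nc <- evidence_for(evidence, transcript_id, "known_ncRNA_homology")

  if (!is.null(orf) && orf$length_aa >= cfg$coding_orf_min_aa) {
    verdict <- list(biotype = "coding", rule_fired = "orf_gt_120aa")
  } else if (!is.na(cp) && cp == "coding") {
    verdict <- list(biotype = "coding", rule_fired = "cpc_coding")
  } else if (!is.na(sh)) {
    verdict <- list(biotype = "structural",
                    rule_fired = paste0("structural_homology_", sh))
  } else if (!is.na(cp) && cp == "noncoding") {
    verdict <- list(biotype = "noncoding", rule_fired = "cpc_noncoding")
  } else if (!is.na(nc)) {
    verdict <- list(biotype = "noncoding",
                    rule_fired = paste0("ncrna_homology_", nc))
  } else {
    verdict <- list(biotype = "noncoding", rule_fired = "no_evidence_default")
  }
  c(list(transcript_id = transcript_id), verdict, list(orf = orf))
}

#' Positional subclass of a noncoding transcript
#'
#' Orders the positional definitions by specificity: lncNAT (>= 1 bp
#' exonic overlap antisense to a protein-coding transcript), else intronic
#' (fully inside an intron of a coding transcript), else lincRNA (farther
#' than `cfg$linc_min_distance_bp` from any coding gene), else proximal
#' (intergenic but within 1 kb — a class kept distinct rather than folded
#' into the lincRNAs).
#'
#' @param ann annotation holding the transcript.
#' @param transcript_id the noncoding transcript.
#' @param ref reference annotation providing the protein-coding genes.
#' @param cfg a [thresholds_config].
#' @return one of `"lncNAT"`, `"lincRNA"`, `"intronic"`, `"proximal"`.
#' @export
subclassify_noncoding <- function(ann, transcript_id, ref,
                                  cfg = thresholds_config()) {
  i <- match(transcript_id, ann$transcripts$transcript_id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id)
  q <- ann$transcripts[i, ]
  qex <- tx_exons(ann, transcript_id)
  cod <- coding_transcripts(ref)
  cod <- cod[cod$chrom == q$chrom, , drop = FALSE]

  ## antisense exonic overlap with any coding transcript?
  anti_strand <- setdiff(STRANDS, q$strand)
  hits <- character(0)
  for (j in seq_len(nrow(qex))) {
    hits <- c(hits, query_overlapping_transcripts(
      ref, qex$chrom[j], qex$start[j], qex$end[j], strand = anti_strand))
  }
  if (any(hits %in% cod$transcript_id)) return("lncNAT")

  ## fully inside an intron of a coding transcript?
  cand <- cod[cod$start <= q$start & cod$end >= q$end & cod$n_exons > 1, ,
              drop = FALSE]
  for (t in cand$transcript_id) {
    intr <- tx_introns(ref, t)
    if (any(intr$start <= q$start & intr$end >= q$end)) return("intronic")
  }

  d <- distance_to_nearest_coding_gene(ann, transcript_id, ref = ref)
  if (d > cfg$linc_min_distance_bp) "lincRNA" else "proximal"
}

#' Classify a set of novel transcripts end to end
#'
#' Runs class-code assignment, the long-RNA filter, ORF prediction on the
#' spliced sequences, the biotype rules and the positional
#' subclassification, producing one biotype call per retained transcript.
#'
#' @param novel a [genome_annotation] of novel transcripts.
#' @param ref the reference [genome_annotation].
#' @param sequences named character vector of chromosome sequences.
#' @param evidence optional evidence table (see [read_evidence_table]).
#' @param cfg a [thresholds_config].
#' @return list with `calls` — data.frame (`transcript_id`, `code`,
#'   `biotype`, `subclass` (`NA` unless noncoding), `rule_fired`,
#'   `orf_len_aa`) for retained transcripts — and `decisions`, the filter
#'   audit trail for all novel transcripts.
#' @export
classify_transcripts <- function(novel, ref, sequences,
                                 evidence = read_evidence_table(),
                                 cfg = thresholds_config()) {
  codes <- assign_class_code(novel, ref)
  flt <- filter_novel_transcripts(novel, ref, cfg, codes = codes)
  ids <- flt$decisions$transcript_id[flt$decisions$kept]
  calls <- lapply(ids, function(id) {
    orf <- longest_forward_orf(spliced_sequence(novel, sequences, id),
                               min_aa = cfg$orf_search_min_aa)
    bio <- classify_biotype(id, orf, evidence, cfg)
    sub <- if (bio$biotype == "noncoding") {
      subclassify_noncoding(novel, id, ref, cfg)
    } else {
      NA_character_
    }
    data.frame(
      transcript_id = id,
      code = codes$code[codes$transcript_id == id],
      biotype = bio$biotype,
      subclass = sub,
      rule_fired = bio$rule_fired,
      orf_len_aa = if (is.null(orf)) NA_real_ else orf$length_aa,
      stringsAsFactors = FALSE
    )
  })
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(transcript_id = character(0), code = character(0),
               biotype = character(0), subclass = character(0),
               rule_fired = character(0), orf_len_aa = numeric(0))
  list(calls = calls, decisions = flt$decisions)
}

#' Write biotype calls as TSV
#' @param calls the `calls` data.frame from [classify_transcripts].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biotype_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
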