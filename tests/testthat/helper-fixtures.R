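# Small builders for hand-made annotations -----------------------------

# one single- or multi-exon transcript; starts/ends are 0-based half-open
tx_rows <- function(id, chrom, strand, starts, ends, gene = id) {
  list(
    exons = data.frame(transcript_id = id, chrom = chrom, start = starts,
                       end = ends, strand = strand,
                       stringsAsFactors = FALSE),
    tx = data.frame(transcript_id = id, gene_id = gene,
                    stringsAsFactors = FALSE)
  )
}

ann_of <- function(..., chrom_lengths = NULL, origin = NULL,
                   biotype = NULL) {
  parts <- list(...)
  ex <- do.call(rbind, lapply(parts, `[[`, "exons"))
  tx <- do.call(rbind, lapply(parts, `[[`, "tx"))
  if (!is.null(origin)) tx$origin <- origin
  if (!is.null(biotype)) tx$declared_biotype <- biotype
  genome_annotation(ex, tx, chrom_lengths)
}

# random multi-exon annotation on a few chromosomes, used for the
# index-vs-scan property tests
random_annotation <- function(n_tx = 40, n_chrom = 3, L = 50000,
                              seed = 1) {
  set.seed(seed)
  parts <- list()
  for (i in seq_len(n_tx)) {
    ch <- paste0("chr", sample.int(n_chrom, 1))
    k <- sample(1:4, 1)
    pos <- sample.int(L - 6000, 1)
    es <- ee <- numeric(k)
    for (j in seq_len(k)) {
      w <- sample(50:400, 1)
      es[j] <- pos; ee[j] <- pos + w
      pos <- ee[j] + sample(100:800, 1)
    }
    parts[[i]] <- tx_rows(sprintf("t%03d", i), ch,
                          sample(c("+", "-"), 1), es, ee)
  }
  c_len <- stats::setNames(rep(L, n_chrom), paste0("chr", seq_len(n_chrom)))
  do.call(ann_of, c(parts, list(chrom_lengths = c_len)))
}

# Independent brute-force oracles ---------------------------------------

# exhaustive ORF scan: walk codons from every ATG position
oracle_orf <- function(seq, min_aa) {
  s <- toupper(seq)
  L <- nchar(s)
  if (L < 3 * (min_aa + 1)) return(NULL)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (p in seq_len(L - 2)) {
    if (substr(s, p, p + 2) != "ATG") next
    q <- p
    len <- 0
    has_stop <- FALSE
    while (q + 2 <= L) {
      cod <- substr(s, q, q + 2)
      if (q > p && cod %in% stops) {
        has_stop <- TRUE
        break
      }
      len <- len + 1
      q <- q + 3
    }
    if (len >= min_aa) {
      if (is.null(best) || len > best$length_aa) {
        best <- list(start_nt = p - 1, length_aa = len,
                     has_stop = has_stop)
      }
    }
  }
  best
}

# per-base exonic positions of a transcript
oracle_exonic_positions <- function(ann, id) {
  ex <- ann$exons[ann$exons$transcript_id == id, ]
  unlist(lapply(seq_len(nrow(ex)), function(j) {
    seq(ex$start[j], ex$end[j] - 1)
  }))
}

# brute-force overlap scan over every exon row
oracle_overlap_scan <- function(ann, chrom, start, end, strand = NULL) {
  ex <- ann$exons
  hit <- ex$chrom == chrom & ex$start < end & ex$end > start
  if (!is.null(strand)) hit <- hit & ex$strand == strand
  sort(unique(ex$transcript_id[hit]))
}

# brute-force span distance to coding genes
oracle_distance <- function(ann, id, ref) {
  q <- ann$transcripts[id, ]
  tx <- ref$transcripts
  tx <- tx[(is.na(tx$declared_biotype) | tx$declared_biotype == "coding") &
             tx$chrom == q$chrom & tx$transcript_id != id, ]
  if (nrow(tx) == 0) return(Inf)
  min(vapply(seq_len(nrow(tx)), function(i) {
    if (tx$end[i] > q$start && tx$start[i] < q$end) 0
    else max(tx$start[i] - q$end, q$start - tx$end[i])
  }, numeric(1)))
}

# brute-force class code straight from the definitions
oracle_class_code <- function(novel, ref, id) {
  q <- novel$transcripts[id, ]
  qpos <- oracle_exonic_positions(novel, id)
  for (r in ref$transcripts$transcript_id) {
    ex_q <- novel$exons[novel$exons$transcript_id == id, ]
    ex_r <- ref$exons[ref$exons$transcript_id == r, ]
    if (identical(unname(as.matrix(ex_q[order(ex_q$start),
                                        c("start", "end")])),
                  unname(as.matrix(ex_r[order(ex_r$start),
                                        c("start", "end")]))) &&
        ex_q$chrom[1] == ex_r$chrom[1] && ex_q$strand[1] == ex_r$strand[1]) {
      return("equal")
    }
  }
  same <- FALSE
  anti <- FALSE
  for (r in ref$transcripts$transcript_id) {
    rr <- ref$transcripts[r, ]
    if (rr$chrom != q$chrom) next
    rpos <- oracle_exonic_positions(ref, r)
    if (length(intersect(qpos, rpos)) > 0) {
      if (rr$strand == q$strand) same <- TRUE else anti <- TRUE
    }
  }
  if (same) return("sense_overlap")
  if (anti) return("x")
  for (r in ref$transcripts$transcript_id) {
    rr <- ref$transcripts[r, ]
    if (rr$chrom != q$chrom || rr$n_exons < 2) next
    ex <- ref$exons[ref$exons$transcript_id == r, ]
    ex <- ex[order(ex$start), ]
    for (j in seq_len(nrow(ex) - 1)) {
      if (ex$end[j] <= q$start && ex$start[j + 1] >= q$end) return("i")
    }
  }
  "u"
}

# brute-force positional subclass for a noncoding transcript
oracle_subclass <- function(ann, id, ref, linc_dist = 1000) {
  q <- ann$transcripts[id, ]
  qpos <- oracle_exonic_positions(ann, id)
  cod <- ref$transcripts[is.na(ref$transcripts$declared_biotype) |
                           ref$transcripts$declared_biotype == "coding", ]
  for (r in cod$transcript_id) {
    rr <- ref$transcripts[r, ]
    if (rr$chrom != q$chrom || rr$strand == q$strand) next
    if (length(intersect(qpos, oracle_exonic_positions(ref, r))) > 0) {
      return("lncNAT")
    }
  }
  for (r in cod$transcript_id) {
    rr <- ref$transcripts[r, ]
    if (rr$chrom != q$chrom || rr$n_exons < 2) next
    ex <- ref$exons[ref$exons$transcript_id == r, ]
    ex <- ex[order(ex$start), ]
    for (j in seq_len(nrow(ex) - 1)) {
      if (ex$end[j] <= q$start && ex$start[j + 1] >= q$end) {
        return("intronic")
      }
    }
  }
  if (oracle_distance(ann, id, ref) > linc_dist) "lincRNA" else "proximal"
}

# direct-formula correlation oracle (explicit arithmetic, no cor())
oracle_correlation <- function(x, y) {
  n <- length(x)
  r_of <- function(a, b) {
    ma <- sum(a) / n; mb <- sum(b) / n
    sum((a - ma) * (b - mb)) /
      sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  }
  p_of <- function(r) {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  r <- r_of(x, y)
  rho <- r_of(rank(x), rank(y))
  list(r = r, p = p_of(r), rho = rho, p_rho = p_of(rho))
}

# random DNA string
rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
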