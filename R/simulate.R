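## Seeded synthetic data with the statistical structure the analysis
## assumes: a reference annotation of protein-coding genes, planted novel
## transcripts of every positional subclass, genome sequence with embedded
## (or screened-out) ORFs, NB counts with genotype/tissue effects and a
## latent-Gaussian sense/antisense coupling, and strand-tagged fragments.

NONSTOP_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"), paste0)),
                  c("A", "C", "G", "T"), paste0)),
  STOP_CODONS)
## codons whose reverse complement is a stop; over-weighting them makes
## spurious antisense ORFs die quickly during screening
REV_STOP_CODONS <- c("TTA", "CTA", "TCA")

#' Configuration of the synthetic study
#'
#' Defaults emulate the study design the pipeline targets: two genotypes
#' (purple / orange) by two tissues (phloem / xylem) by three replicates;
#' a reference of protein-coding genes spread over nine chromosomes;
#' planted antisense, intergenic, intronic and gene-proximal noncoding
#' transcripts; an "anthocyanin module" of coding genes with very large
#' genotype effects (log2 fold changes drawn from [6, 12], the magnitude
#' regime of strongly genotype-specific pigment genes) whose antisense
#' partners are coupled through a latent Gaussian with correlation
#' `sense_antisense_latent_correlation`.
#'
#' @param seed integer seed; every stochastic call derives from it.
#' @param n_chromosomes number of chromosomes (default 9).
#' @param chrom_length chromosome length in bp.
#' @param n_coding_genes reference protein-coding genes.
#' @param n_lncNATs,n_lincRNAs,n_intronic,n_proximal planted novel
#'   noncoding transcripts per positional subclass.
#' @param n_novel_coding planted novel transcripts carrying an ORF of at
#'   least 121 aa (true biotype coding).
#' @param anthocyanin_module_size coding genes with a genotype effect.
#' @param pair_de_fraction fraction of sense/antisense pairs whose members
#'   carry genotype effects (the rest stay null).
#' @param discordant_fraction fraction of effect-carrying pairs with
#'   opposite-direction regulation.
#' @param fully_overlapping_fraction fraction of lncNATs whose span is
#'   contained in the host span.
#' @param genotype_log2FC_range,tissue_log2FC_range effect-size ranges
#'   (log2) for genotype and tissue effects.
#' @param tissue_effect_fraction fraction of genes with a tissue effect.
#' @param sense_antisense_latent_correlation rho of the latent Gaussian
#'   shared by pair members across samples (in [-1, 1]).
#' @param pair_latent_sd standard deviation (log2 units) of that latent
#'   per-sample biological variation of pair members.
#' @param nb_dispersion NB dispersion alpha of simulated counts
#'   (variance = mu + alpha mu^2).
#' @param base_log2_mean_range log2 baseline mean range for unmodulated
#'   genes.
#' @param module_base_mean baseline (orange) mean count of module genes
#'   and their partners.
#' @param depth_multipliers per-sample sequencing-depth multipliers
#'   (length 1 or one per sample).
#' @param fragment_length fragment length for read simulation (bp).
#' @param noncoding_length_range length range (nt) of planted noncoding
#'   transcripts, centred on the most frequent lncRNA length class.
#' @param orf_retry_cap retries allowed when screening noncoding sequence
#'   for absence of long ORFs.
#' @param n_replicates biological replicates per genotype/tissue cell.
#' @return validated list of class `lncnat_simconfig`.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 9,
                              chrom_length = 300000,
                              n_coding_genes = 50,
                              n_lncNATs = 10,
                              n_lincRNAs = 20,
                              n_intronic = 5,
                              n_proximal = 5,
                              n_novel_coding = 10,
                              anthocyanin_module_size = 15,
                              pair_de_fraction = 0.7,
                              discordant_fraction = 0.25,
                              fully_overlapping_fraction = 0.7,
                              genotype_log2FC_range = c(6, 12),
                              tissue_log2FC_range = c(1, 3),
                              tissue_effect_fraction = 0.1,
                              sense_antisense_latent_correlation = 0.9,
                              pair_latent_sd = 1.0,
                              nb_dispersion = 0.05,
                              base_log2_mean_range = c(3, 9),
                              module_base_mean = 50,
                              depth_multipliers = 1,
                              fragment_length = 80,
                              noncoding_length_range = c(400, 800),
                              orf_retry_cap = 50,
                              n_replicates = 3) {
  cfg <- as.list(environment())
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  cfg$seed <- as.integer(seed)
  counts <- c("n_chromosomes", "n_coding_genes", "n_lncNATs", "n_lincRNAs",
              "n_intronic", "n_proximal", "n_novel_coding",
              "anthocyanin_module_size", "n_replicates")
  for (nm in counts) {
    if (cfg[[nm]] < 0) stop(nm, " must be non-negative")
  }
  rho <- cfg$sense_antisense_latent_correlation
  if (rho < -1 || rho > 1) {
    stop("sense_antisense_latent_correlation must lie in [-1, 1]")
  }
  if (cfg$n_lncNATs > cfg$n_coding_genes) {
    stop("cannot plant more lncNATs than coding genes")
  }
  structure(cfg, class = "lncnat_simconfig")
}

random_dna <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

## spliced cDNA of a coding model: UTR5 + ATG..stop + UTR3, with
## reverse-stop-rich codon usage
make_coding_cdna <- function(n_codons, utr5, utr3) {
  w <- ifelse(NONSTOP_CODONS %in% REV_STOP_CODONS, 8, 1)
  body <- sample(NONSTOP_CODONS, n_codons - 1, replace = TRUE, prob = w)
  paste0(paste(random_dna(utr5), collapse = ""),
         "ATG", paste(body, collapse = ""),
         sample(STOP_CODONS, 1),
         paste(random_dna(utr3), collapse = ""))
}

## split a spliced length into k exon lengths (each >= 100)
split_exon_lengths <- function(total, k) {
  if (k == 1L) return(total)
  extra <- total - 100 * k
  as.vector(100 + stats::rmultinom(1, extra, rep(1, k)))
}

## write a cDNA into the genome char vectors at the exon coordinates
write_cdna <- function(genome, chrom, starts, ends, strand, cdna) {
  genomic <- if (strand == "-") revcomp(cdna) else toupper(cdna)
  gchars <- strsplit(genomic, "", fixed = TRUE)[[1]]
  off <- 0
  for (j in seq_along(starts)) {
    w <- ends[j] - starts[j]
    genome[[chrom]][(starts[j] + 1):ends[j]] <- gchars[(off + 1):(off + w)]
    off <- off + w
  }
  stopifnot(off == length(gchars))
  invisible(NULL)
}

read_genomic <- function(genome, chrom, starts, ends, strand) {
  s <- paste(unlist(lapply(seq_along(starts), function(j) {
    genome[[chrom]][(starts[j] + 1):ends[j]]
  })), collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Simulate a genome: annotation, sequences and planted truth
#'
#' Places non-overlapping protein-coding genes per chromosome, then plants
#' novel transcripts with known ground truth: antisense lncNATs
#' overlapping at least one host exon (a configurable fraction fully
#' contained in the host span), lincRNAs more than 1 kb from any coding
#' span, proximal transcripts within 1 kb, intronic transcripts inside
#' introns, and novel coding transcripts with embedded ORFs of at least
#' 121 aa.  Noncoding sequence is rejection-screened so its longest
#' forward ORF stays below 70 aa; coding sequence carries an embedded
#' ATG...stop ORF and a codon usage that denies long ORFs to the antisense
#' strand.  Identical configurations produce byte-identical output.
#'
#' @param cfg a [simulation_config].
#' @return list of class `lncnat_simulation`: `reference` and `novel`
#'   [genome_annotation]s, `sequences` (named character vector), `truth`
#'   (list with `transcripts` — true biotype/subclass per novel transcript
#'   — and `pairs`), and `cfg`.
#' @export
simulate_genome <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  L <- cfg$chrom_length
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_lengths <- stats::setNames(rep(L, length(chroms)), chroms)

  ## ---- place reference coding genes ----
  genes <- list()
  gaps <- list()
  cursor <- stats::setNames(rep(3000, length(chroms)), chroms)
  prev_end <- stats::setNames(rep(0, length(chroms)), chroms)
  prev_gene <- stats::setNames(rep(NA_character_, length(chroms)), chroms)
  for (i in seq_len(cfg$n_coding_genes)) {
    ch <- chroms[((i - 1) %% length(chroms)) + 1]
    n_ex <- sample(1:4, 1, prob = c(0.3, 0.3, 0.2, 0.2))
    n_cod <- sample(130:300, 1)
    utr5 <- sample(30:120, 1)
    utr3 <- sample(50:250, 1)
    spliced <- utr5 + 3 * (n_cod + 1) + utr3
    exl <- split_exon_lengths(spliced, n_ex)
    intr <- if (n_ex > 1) sample(800:2000, n_ex - 1, replace = TRUE) else
      numeric(0)
    strand <- sample(STRANDS, 1)
    start <- cursor[ch]
    es <- numeric(n_ex); ee <- numeric(n_ex)
    pos <- start
    for (j in seq_len(n_ex)) {
      es[j] <- pos; ee[j] <- pos + exl[j]
      pos <- ee[j] + if (j < n_ex) intr[j] else 0
    }
    end <- ee[n_ex]
    if (end > L - 3000) {
      stop("chromosome ", ch, " too short for the requested gene count")
    }
    gid <- sprintf("gene%04d", i)
    genes[[gid]] <- list(gene_id = gid,
                         transcript_id = paste0(gid, ".t1"),
                         chrom = ch, strand = strand,
                         es = es, ee = ee, start = start, end = end,
                         n_cod = n_cod, utr5 = utr5, utr3 = utr3,
                         exl = exl)
    gaps[[length(gaps) + 1]] <- list(chrom = ch, gs = prev_end[ch],
                                     ge = start,
                                     left_gene = prev_gene[ch],
                                     right_gene = gid)
    prev_end[ch] <- end
    prev_gene[ch] <- gid
    cursor[ch] <- end + sample(4000:8000, 1)
  }
  for (ch in chroms) {
    gaps[[length(gaps) + 1]] <- list(chrom = ch, gs = prev_end[ch],
                                     ge = L - 100,
                                     left_gene = prev_gene[ch],
                                     right_gene = NA_character_)
  }
  gap_used <- rep(FALSE, length(gaps))
  gene_tab <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id, transcript_id = g$transcript_id,
               chrom = g$chrom, strand = g$strand, start = g$start,
               end = g$end, n_exons = length(g$es),
               stringsAsFactors = FALSE)
  }))

  novel <- list()   # each: list(id, chrom, strand, es, ee, subclass, host)
  add_novel <- function(id, chrom, strand, es, ee, subclass, host = NA,
                        code = NA) {
    novel[[id]] <<- list(id = id, chrom = chrom, strand = strand,
                         es = es, ee = ee, subclass = subclass,
                         host = host, code = code)
  }
  flip <- function(s) if (s == "+") "-" else "+"
  nco <- 0  # novel counter
  nid <- function() { nco <<- nco + 1; sprintf("novel%04d", nco) }

  ## ---- lncNATs: antisense single-exon transcripts over host genes ----
  nat_hosts <- character(0)
  pairs <- NULL
  if (cfg$n_lncNATs > 0) {
    nat_hosts <- sample(names(genes), cfg$n_lncNATs)
    full <- stats::runif(cfg$n_lncNATs) < cfg$fully_overlapping_fraction
    for (k in seq_len(cfg$n_lncNATs)) {
      g <- genes[[nat_hosts[k]]]
      len <- sample(cfg$noncoding_length_range[1]:
                      cfg$noncoding_length_range[2], 1)
      if (full[k]) {
        len <- min(len, g$end - g$start - 20)
        s0 <- g$end - len
        e0 <- g$end
      } else {
        ext <- sample(100:300, 1)   # len - ext >= 100 bp of exonic overlap
        s0 <- g$start - ext
        e0 <- min(s0 + len, g$end - 10)
        ## reserve the upstream gap so nothing else lands in it
        for (q in seq_along(gaps)) {
          if (identical(gaps[[q]]$right_gene, g$gene_id)) gap_used[q] <- TRUE
        }
      }
      id <- nid()
      add_novel(id, g$chrom, flip(g$strand), s0, e0, "lncNAT",
                host = g$transcript_id, code = "x")
      pairs <- rbind(pairs, data.frame(
        sense_id = g$transcript_id, antisense_id = id,
        fully_overlapping = full[k], stringsAsFactors = FALSE))
    }
  }

  ## ---- intronic transcripts inside introns of unused multi-exon hosts ----
  if (cfg$n_intronic > 0) {
    elig <- setdiff(gene_tab$gene_id[gene_tab$n_exons > 1], nat_hosts)
    if (length(elig) < cfg$n_intronic) {
      stop("not enough multi-exon genes to host intronic transcripts")
    }
    hosts <- sample(elig, cfg$n_intronic)
    for (h in hosts) {
      g <- genes[[h]]
      ilen <- g$es[-1] - g$ee[-length(g$ee)]
      j <- which.max(ilen)
      len <- min(sample(cfg$noncoding_length_range[1]:
                          cfg$noncoding_length_range[2], 1),
                 ilen[j] - 200)
      off <- sample(50:(ilen[j] - len - 50), 1)
      s0 <- g$ee[j] + off
      add_novel(nid(), g$chrom, sample(STRANDS, 1), s0, s0 + len,
                "intronic", host = g$transcript_id, code = "i")
    }
  }

  ## ---- gap-hosted elements: lincRNAs, proximal, novel coding ----
  avail <- which(!gap_used)
  avail <- avail[sample.int(length(avail))]
  take_gap <- function(pred) {
    for (ii in seq_along(avail)) {
      q <- avail[ii]
      if (pred(gaps[[q]])) {
        avail <<- avail[-ii]
        return(gaps[[q]])
      }
    }
    stop("not enough intergenic space for the requested transcripts")
  }
  novel_coding_meta <- list()
  for (k in seq_len(cfg$n_lincRNAs)) {
    len <- sample(cfg$noncoding_length_range[1]:
                    cfg$noncoding_length_range[2], 1)
    gp <- take_gap(function(gp) {
      lo <- gp$gs + if (is.na(gp$left_gene)) 0 else 1001
      hi <- gp$ge - if (is.na(gp$right_gene)) 0 else 1001
      hi - lo >= len + 10
    })
    lo <- gp$gs + if (is.na(gp$left_gene)) 0 else 1001
    hi <- gp$ge - if (is.na(gp$right_gene)) 0 else 1001
    s0 <- lo + sample(0:(hi - lo - len), 1)
    add_novel(nid(), gp$chrom, sample(STRANDS, 1), s0, s0 + len,
              "lincRNA", code = "u")
  }
  for (k in seq_len(cfg$n_proximal)) {
    len <- sample(cfg$noncoding_length_range[1]:
                    cfg$noncoding_length_range[2], 1)
    gp <- take_gap(function(gp) {
      !is.na(gp$left_gene) &&
        (gp$ge - if (is.na(gp$right_gene)) 10 else 1100) -
          (gp$gs + 100) >= len
    })
    d <- sample(100:900, 1)
    s0 <- gp$gs + min(d, (gp$ge - if (is.na(gp$right_gene)) 10 else 1100) -
                        len - gp$gs)
    add_novel(nid(), gp$chrom, sample(STRANDS, 1), s0, s0 + len,
              "proximal", code = "u")
  }
  for (k in seq_len(cfg$n_novel_coding)) {
    n_ex <- sample(1:2, 1)
    n_cod <- sample(130:250, 1)
    utr5 <- sample(30:120, 1)
    utr3 <- sample(50:250, 1)
    spliced <- utr5 + 3 * (n_cod + 1) + utr3
    exl <- split_exon_lengths(spliced, n_ex)
    intr <- if (n_ex > 1) sample(800:1500, n_ex - 1, replace = TRUE) else
      numeric(0)
    span <- spliced + sum(intr)
    gp <- take_gap(function(gp) gp$ge - gp$gs >= span + 500)
    s0 <- gp$gs + 200 + sample(0:(gp$ge - gp$gs - span - 450), 1)
    es <- numeric(n_ex); ee <- numeric(n_ex); pos <- s0
    for (j in seq_len(n_ex)) {
      es[j] <- pos; ee[j] <- pos + exl[j]
      pos <- ee[j] + if (j < n_ex) intr[j] else 0
    }
    id <- nid()
    add_novel(id, gp$chrom, sample(STRANDS, 1), es, ee, NA_character_,
              code = "u")
    novel_coding_meta[[id]] <- list(n_cod = n_cod, utr5 = utr5, utr3 = utr3)
  }

  ## ---- sequences ----
  genome <- new.env()
  for (ch in chroms) genome[[ch]] <- random_dna(L)
  for (g in genes) {
    write_cdna(genome, g$chrom, g$es, g$ee, g$strand,
               make_coding_cdna(g$n_cod, g$utr5, g$utr3))
  }
  for (id in names(novel_coding_meta)) {
    nv <- novel[[id]]
    m <- novel_coding_meta[[id]]
    write_cdna(genome, nv$chrom, nv$es, nv$ee, nv$strand,
               make_coding_cdna(m$n_cod, m$utr5, m$utr3))
  }
  min_aa <- 70
  for (id in names(novel)) {
    nv <- novel[[id]]
    if (is.na(nv$subclass)) next      # novel coding already written
    screened <- FALSE
    if (nv$subclass != "lncNAT") {
      for (try in seq_len(cfg$orf_retry_cap)) {
        cd <- read_genomic(genome, nv$chrom, nv$es, nv$ee, nv$strand)
        if (is.null(longest_forward_orf(cd, min_aa))) {
          screened <- TRUE
          break
        }
        for (j in seq_along(nv$es)) {
          genome[[nv$chrom]][(nv$es[j] + 1):nv$ee[j]] <-
            random_dna(nv$ee[j] - nv$es[j])
        }
      }
    } else {
      host <- genes[[sub("\\.t1$", "", nv$host)]]
      host_cov <- unlist(lapply(seq_along(host$es), function(j) {
        (host$es[j] + 1):host$ee[j]
      }))
      free <- setdiff((nv$es[1] + 1):nv$ee[1], host_cov)
      for (try in seq_len(cfg$orf_retry_cap)) {
        cd <- read_genomic(genome, nv$chrom, nv$es, nv$ee, nv$strand)
        if (is.null(longest_forward_orf(cd, min_aa))) {
          screened <- TRUE
          break
        }
        if (length(free)) {
          genome[[nv$chrom]][free] <- random_dna(length(free))
        }
        ## redraw the host coding sequence (same geometry); antisense ORFs
        ## survive a free-position resample whenever they sit in the
        ## host-derived part of the transcript
        write_cdna(genome, host$chrom, host$es, host$ee, host$strand,
                   make_coding_cdna(host$n_cod, host$utr5, host$utr3))
      }
    }
    if (!screened) {
      cd <- read_genomic(genome, nv$chrom, nv$es, nv$ee, nv$strand)
      if (!is.null(longest_forward_orf(cd, min_aa))) {
        stop("could not screen out long ORFs for ", id,
             " within the retry cap")
      }
    }
  }
  sequences <- stats::setNames(vapply(chroms, function(ch) {
    paste(genome[[ch]], collapse = "")
  }, character(1)), chroms)

  ## ---- assemble annotations and truth ----
  ref_ex <- do.call(rbind, lapply(genes, function(g) {
    data.frame(transcript_id = g$transcript_id, chrom = g$chrom,
               start = g$es, end = g$ee, strand = g$strand,
               stringsAsFactors = FALSE)
  }))
  ref_tx <- do.call(rbind, lapply(genes, function(g) {
    data.frame(transcript_id = g$transcript_id, gene_id = g$gene_id,
               origin = "known", declared_biotype = "coding",
               stringsAsFactors = FALSE)
  }))
  reference <- genome_annotation(ref_ex, ref_tx, chrom_lengths)

  empty_ex <- data.frame(transcript_id = character(0), chrom = character(0),
                         start = numeric(0), end = numeric(0),
                         strand = character(0))
  nov_ex <- if (!length(novel)) empty_ex else
    do.call(rbind, lapply(novel, function(nv) {
    data.frame(transcript_id = paste0(nv$id, ".t1"), chrom = nv$chrom,
               start = nv$es, end = nv$ee, strand = nv$strand,
               stringsAsFactors = FALSE)
  }))
  nov_tx <- if (!length(novel)) {
    data.frame(transcript_id = character(0), gene_id = character(0),
               origin = character(0), declared_biotype = character(0))
  } else {
    do.call(rbind, lapply(novel, function(nv) {
      data.frame(transcript_id = paste0(nv$id, ".t1"), gene_id = nv$id,
                 origin = "novel", declared_biotype = NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  novel_ann <- genome_annotation(nov_ex, nov_tx, chrom_lengths)

  truth_tx <- if (!length(novel)) {
    data.frame(transcript_id = character(0), gene_id = character(0),
               true_biotype = character(0), true_subclass = character(0),
               true_code = character(0), host = character(0))
  } else {
    do.call(rbind, lapply(novel, function(nv) {
      data.frame(
        transcript_id = paste0(nv$id, ".t1"),
        gene_id = nv$id,
        true_biotype = if (is.na(nv$subclass)) "coding" else "noncoding",
        true_subclass = nv$subclass,
        true_code = nv$code,
        host = nv$host %||% NA_character_,
        stringsAsFactors = FALSE)
    }))
  }
  rownames(truth_tx) <- NULL
  if (!is.null(pairs)) {
    pairs$antisense_id <- paste0(pairs$antisense_id, ".t1")
  } else {
    pairs <- data.frame(sense_id = character(0),
                        antisense_id = character(0),
                        fully_overlapping = logical(0))
  }

  structure(list(reference = reference, novel = novel_ann,
                 sequences = sequences,
                 truth = list(transcripts = truth_tx, pairs = pairs),
                 cfg = cfg),
            class = "lncnat_simulation")
}

#' Expression design without a genome
#'
#' Builds the gene-level structure of a simulated dataset (gene ids,
#' biotypes, sense/antisense pairing) without placing anything on a
#' genome, for count-level studies at sizes where sequence simulation is
#' unnecessary.
#'
#' @param cfg a [simulation_config].
#' @return list shaped like the `truth` of [simulate_genome] plus `cfg`.
#' @export
simulate_expression_design <- function(cfg = simulation_config()) {
  ngene <- cfg$n_coding_genes
  coding <- sprintf("gene%04d", seq_len(ngene))
  nonc_n <- cfg$n_lncNATs + cfg$n_lincRNAs + cfg$n_intronic +
    cfg$n_proximal
  nonc <- if (nonc_n) sprintf("novel%04d", seq_len(nonc_n)) else character(0)
  sub <- rep(c("lncNAT", "lincRNA", "intronic", "proximal"),
             c(cfg$n_lncNATs, cfg$n_lincRNAs, cfg$n_intronic,
               cfg$n_proximal))
  ncod <- if (cfg$n_novel_coding) {
    sprintf("novel%04d", nonc_n + seq_len(cfg$n_novel_coding))
  } else character(0)
  tx <- data.frame(
    transcript_id = paste0(c(coding, nonc, ncod), ".t1"),
    gene_id = c(coding, nonc, ncod),
    true_biotype = c(rep("coding", length(coding)),
                     rep("noncoding", length(nonc)),
                     rep("coding", length(ncod))),
    true_subclass = c(rep(NA_character_, length(coding)), sub,
                      rep(NA_character_, length(ncod))),
    true_code = NA_character_,
    host = NA_character_,
    stringsAsFactors = FALSE)
  pairs <- if (cfg$n_lncNATs > 0) {
    data.frame(sense_id = paste0(coding[seq_len(cfg$n_lncNATs)], ".t1"),
               antisense_id = tx$transcript_id[tx$true_subclass %in%
                                                 "lncNAT"],
               fully_overlapping = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(sense_id = character(0), antisense_id = character(0),
               fully_overlapping = logical(0))
  }
  tx$host[match(pairs$antisense_id, tx$transcript_id)] <- pairs$sense_id
  list(truth = list(transcripts = tx, pairs = pairs), cfg = cfg)
}

#' Simulate the count matrix of the study design
#'
#' Per gene, the log2 mean is baseline + genotype effect (module genes and
#' their antisense partners only) + tissue effect; members of a
#' sense/antisense pair additionally share a per-sample latent Gaussian
#' with correlation `rho` (negated for discordant pairs).  Counts are
#' drawn NB(mean x depth multiplier, alpha).  All draws are seeded from
#' `cfg$seed`, independently of the genome draw.
#'
#' @param sim result of [simulate_genome] or
#'   [simulate_expression_design].
#' @param cfg a [simulation_config]; defaults to the one inside `sim`.
#' @return list with `counts` (a `count_matrix`) and `truth` — the input
#'   truth augmented with the per-gene expression table `genes`
#'   (baseline, true log2 fold changes, module membership, concordance)
#'   and `true_size_factors`.
#' @export
simulate_counts <- function(sim, cfg = sim$cfg) {
  set.seed(cfg$seed + 1L)
  tx <- sim$truth$transcripts
  pairs <- sim$truth$pairs
  ## genome simulations carry the reference separately
  if (!is.null(sim$reference)) {
    ref <- sim$reference$transcripts
    tx <- rbind(
      data.frame(transcript_id = ref$transcript_id,
                 gene_id = ref$gene_id, true_biotype = "coding",
                 true_subclass = NA_character_, true_code = NA_character_,
                 host = NA_character_, stringsAsFactors = FALSE),
      tx)
  }
  genes <- data.frame(
    gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    biotype = tx$true_biotype, subclass = tx$true_subclass,
    base_log2 = stats::runif(nrow(tx), cfg$base_log2_mean_range[1],
                             cfg$base_log2_mean_range[2]),
    lfc_genotype = 0, lfc_tissue = 0, is_module = FALSE,
    pair_id = NA_integer_, concordant = NA,
    stringsAsFactors = FALSE)

  ## module: effect-carrying pair hosts first, then other coding genes
  n_pairs_de <- if (nrow(pairs)) {
    min(nrow(pairs), ceiling(cfg$pair_de_fraction * nrow(pairs)))
  } else 0
  de_pairs <- if (n_pairs_de) seq_len(n_pairs_de) else integer(0)
  host_rows <- match(pairs$sense_id, genes$transcript_id)
  anti_rows <- match(pairs$antisense_id, genes$transcript_id)
  if (nrow(pairs)) {
    genes$pair_id[host_rows] <- seq_len(nrow(pairs))
    genes$pair_id[anti_rows] <- seq_len(nrow(pairs))
  }
  module <- host_rows[de_pairs]
  other_cod <- setdiff(which(genes$biotype == "coding" &
                               is.na(genes$pair_id)),
                       module)
  extra <- max(0, cfg$anthocyanin_module_size - length(module))
  if (extra > 0 && length(other_cod)) {
    module <- c(module, sample(other_cod, min(extra, length(other_cod))))
  }
  genes$is_module[module] <- TRUE
  genes$base_log2[module] <- log2(cfg$module_base_mean)
  genes$lfc_genotype[module] <- stats::runif(
    length(module), cfg$genotype_log2FC_range[1],
    cfg$genotype_log2FC_range[2])
  ## antisense partners of effect-carrying pairs
  if (n_pairs_de) {
    conc <- stats::runif(n_pairs_de) >= cfg$discordant_fraction
    genes$concordant[host_rows[de_pairs]] <- conc
    genes$concordant[anti_rows[de_pairs]] <- conc
    ar <- anti_rows[de_pairs]
    genes$is_module[ar] <- TRUE
    genes$base_log2[ar] <- log2(cfg$module_base_mean)
    genes$lfc_genotype[ar] <- ifelse(conc, 1, -1) *
      stats::runif(n_pairs_de, cfg$genotype_log2FC_range[1],
                   cfg$genotype_log2FC_range[2])
  }
  ## tissue effects on a random subset
  tset <- which(stats::runif(nrow(genes)) < cfg$tissue_effect_fraction)
  genes$lfc_tissue[tset] <- sample(c(-1, 1), length(tset), replace = TRUE) *
    stats::runif(length(tset), cfg$tissue_log2FC_range[1],
                 cfg$tissue_log2FC_range[2])

  ## samples
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      tissue = TISSUES, genotype = GENOTYPES,
                      stringsAsFactors = FALSE)
  samples <- sample_sheet(
    sample_id = paste(grid$genotype, grid$tissue, grid$replicate,
                      sep = "_"),
    genotype = grid$genotype, tissue = grid$tissue,
    replicate = grid$replicate)
  ns <- nrow(samples)
  depth <- rep(cfg$depth_multipliers, length.out = ns)

  is_purple <- as.numeric(samples$genotype == "purple")
  is_xylem <- as.numeric(samples$tissue == "xylem")
  log2mu <- outer(genes$base_log2, rep(1, ns)) +
    outer(genes$lfc_genotype, is_purple) +
    outer(genes$lfc_tissue, is_xylem)

  ## latent sample-level coupling of pair members
  if (nrow(pairs)) {
    rho <- cfg$sense_antisense_latent_correlation
    for (p in seq_len(nrow(pairs))) {
      z1 <- stats::rnorm(ns)
      rr <- if (isTRUE(genes$concordant[host_rows[p]]) ||
                is.na(genes$concordant[host_rows[p]])) rho else -rho
      z2 <- rr * z1 + sqrt(max(0, 1 - rr^2)) * stats::rnorm(ns)
      log2mu[host_rows[p], ] <- log2mu[host_rows[p], ] +
        cfg$pair_latent_sd * z1
      log2mu[anti_rows[p], ] <- log2mu[anti_rows[p], ] +
        cfg$pair_latent_sd * z2
    }
  }

  mu <- sweep(2^log2mu, 2, depth, "*")
  a <- cfg$nb_dispersion
  k <- if (a > 0) {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / a), nrow(mu))
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow(mu))
  }
  dimnames(k) <- list(genes$gene_id, samples$sample_id)
  if (max(k) < .Machine$integer.max) storage.mode(k) <- "integer"
  cm <- count_matrix(k, samples)
  truth <- sim$truth
  truth$genes <- genes
  truth$true_size_factors <- stats::setNames(
    depth / exp(mean(log(depth))), samples$sample_id)
  truth$true_counts <- k
  list(counts = cm, truth = truth)
}

#' Simulate strand-tagged fragments realising a count matrix
#'
#' Emits exactly `counts[g, j]` fragments for gene `g` in sample `j`, each
#' placed uniformly within a single exon of the gene (exon chosen with
#' probability proportional to its length) on the gene's strand, with
#' fragment length `cfg$fragment_length` clipped to the exon.
#'
#' @param cm a `count_matrix` (e.g. from [simulate_counts]).
#' @param ann annotation containing every counted gene, e.g.
#'   `merge_annotations(sim$reference, sim$novel)`.
#' @param cfg a [simulation_config].
#' @return named list (per sample) of fragment data.frames with columns
#'   `chrom`, `start`, `end`, `fragment_id`, `strand`.
#' @export
simulate_reads <- function(cm, ann, cfg) {
  set.seed(cfg$seed + 2L)
  k <- cm$counts
  gene_ids <- rownames(k)
  tx <- ann$transcripts
  ex_by_gene <- split(ann$exons, tx$gene_id[match(ann$exons$transcript_id,
                                                  tx$transcript_id)])
  missing <- setdiff(gene_ids, names(ex_by_gene))
  if (length(missing)) {
    stop("count matrix gene absent from the annotation: ", missing[1])
  }
  out <- list()
  for (j in seq_len(ncol(k))) {
    sid <- colnames(k)[j]
    per_gene <- lapply(gene_ids, function(g) {
      n <- k[g, j]
      if (n == 0L) return(NULL)
      ex <- ex_by_gene[[g]]
      w <- ex$end - ex$start
      ei <- if (nrow(ex) == 1L) rep(1L, n) else
        sample.int(nrow(ex), n, replace = TRUE, prob = w)
      fl <- pmin(cfg$fragment_length, w[ei])
      u <- stats::runif(n)
      s0 <- ex$start[ei] + floor(u * (w[ei] - fl + 1))
      data.frame(chrom = ex$chrom[ei], start = s0, end = s0 + fl,
                 gene = g, strand = ex$strand[ei],
                 stringsAsFactors = FALSE)
    })
    fr <- do.call(rbind, per_gene)
    if (is.null(fr)) {
      fr <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), gene = character(0),
                       strand = character(0))
    }
    fr$fragment_id <- sprintf("%s_frag%06d", sid, seq_len(nrow(fr)))
    out[[sid]] <- fr[, c("chrom", "start", "end", "fragment_id", "strand")]
  }
  out
}

#' Write fragments as BED6
#' @param fragments data.frame from [simulate_reads] (one sample).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed6 <- function(fragments, path) {
  df <- data.frame(fragments$chrom,
                   format(fragments$start, scientific = FALSE,
                          trim = TRUE),
                   format(fragments$end, scientific = FALSE, trim = TRUE),
                   fragments$fragment_id, 0L, fragments$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
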