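## End-to-end orchestration: classify -> count -> normalize -> DE -> NAT
## selection -> reports, with a machine-readable run manifest and a log.

#' Read a flat key:value pipeline configuration file
#'
#' One `key: value` (or `key=value`) pair per line; `#` starts a comment.
#' Values are parsed as numbers when possible, comma-separated values
#' become vectors, `true`/`false` become logicals.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    key <- m[2]
    val <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!anyNA(num)) {
      num
    } else if (all(tolower(val) %in% c("true", "false"))) {
      tolower(val) == "true"
    } else {
      val
    }
    out[[key]] <- parsed
  }
  out
}

pipeline_log <- function(con, msg) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg)
  writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Either simulates a dataset (`config$simulate = TRUE`, the default) or
#' loads the annotation, sequences and fragment files named in the
#' configuration, then runs classification, strand-specific counting,
#' normalization, the three genotype contrasts, NAT selection and the
#' summary reports, writing TSV tables, an annotated GFF3, a JSON run
#' manifest (stages, seeds, thresholds, input digests) and a plain-text
#' log into `outdir`.
#'
#' @param config named list (see [read_pipeline_config]); recognised keys
#'   include `simulate`, `seed`, simulation sizes (`n_coding_genes`, ...),
#'   thresholds (`min_tx_len_nt`, ...), and input paths
#'   (`reference_gff`, `novel_gff`, `genome_fasta`, `sample_sheet`,
#'   `evidence_tsv`).
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the main in-memory results
#'   (`classification`, `counts`, `size_factors`, `de`, `nats`,
#'   `summaries`, `manifest`).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("lncnat_run_")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logcon))
  stages <- character(0)
  seed <- as.integer(config$seed %||% 1L)

  thr_args <- intersect(names(config), names(formals(thresholds_config)))
  cfg <- do.call(thresholds_config,
                 lapply(config[thr_args], as.numeric) %||% list())

  inputs <- list()
  stage <- function(name, expr) {
    pipeline_log(logcon, paste("stage", name, "started"))
    res <- tryCatch(expr, error = function(e) {
      pipeline_log(logcon, paste("stage", name, "FAILED:",
                                 conditionMessage(e)))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    pipeline_log(logcon, paste("stage", name, "completed"))
    res
  }

  simulate <- isTRUE(config$simulate %||% TRUE)
  if (simulate) {
    sim_args <- intersect(names(config), names(formals(simulation_config)))
    scfg <- do.call(simulation_config,
                    c(list(seed = seed), config[setdiff(sim_args, "seed")]))
    sim <- stage("simulate", {
      s <- simulate_genome(scfg)
      write_annotation(s$reference, file.path(outdir, "reference.gff3"))
      write_annotation(s$novel, file.path(outdir, "novel.gff3"))
      write_sequences(s$sequences, file.path(outdir, "genome.fa"))
      s
    })
    reference <- sim$reference
    novel <- sim$novel
    sequences <- sim$sequences
    simc <- simulate_counts(sim)
    frags <- simulate_reads(simc$counts, merge_annotations(reference, novel),
                            scfg)
    samples <- simc$counts$samples
    evidence <- read_evidence_table(NULL)
  } else {
    reference <- read_annotation(config$reference_gff)
    novel <- read_annotation(config$novel_gff)
    sequences <- read_sequences(config$genome_fasta)
    samples <- read_sample_sheet(config$sample_sheet)
    frags <- NULL
    evidence <- read_evidence_table(config$evidence_tsv %||% NULL)
    inputs <- config[intersect(names(config),
                               c("reference_gff", "novel_gff",
                                 "genome_fasta", "sample_sheet",
                                 "evidence_tsv"))]
  }

  cls <- stage("classify", {
    r <- classify_transcripts(novel, reference, sequences, evidence, cfg)
    write_biotype_calls(r$calls, file.path(outdir, "biotype_calls.tsv"))
    r
  })

  combined <- merge_annotations(reference,
                                if (is.null(cls$calls) ||
                                    nrow(cls$calls) == 0L) novel else
                                  subset_annotation(
                                    novel, cls$calls$transcript_id))

  cm <- stage("count", {
    x <- count_fragments(frags, samples, combined)
    write_matrix_tsv(x$counts, file.path(outdir, "counts.tsv"))
    x
  })

  norm <- stage("normalize", {
    sf <- estimate_size_factors(cm)
    cm$size_factors <- sf
    n <- normalize_counts(cm, sf)
    write_matrix_tsv(round(n, 4), file.path(outdir, "normalized.tsv"))
    list(sf = sf, norm = n, log2 = log2(n + 1))
  })

  de <- stage("de", {
    out <- lapply(default_contrasts(cm), function(ct) {
      d <- wald_de_test(cm, norm$sf, ct, cfg = cfg)
      write_de_table(d, file.path(outdir, paste0("de_", ct$name, ".tsv")))
      d
    })
    out
  })

  nats <- stage("nats", {
    pairs <- find_antisense_pairs(combined, cls$calls)
    sel <- select_candidate_nats(pairs, de$purple_vs_orange_all,
                                 norm$log2, ann = combined, cfg = cfg)
    write_nat_candidates(sel, file.path(outdir, "nat_candidates.tsv"))
    sel
  })

  summaries <- stage("report", {
    pca <- pca_samples(norm$log2)
    summ <- summarize_transcripts(combined, cls$calls, norm$log2)
    utils::write.table(
      data.frame(sample_id = rownames(pca$scores),
                 round(pca$scores[, 1:min(4, ncol(pca$scores))], 4)),
      file.path(outdir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(pca = pca, tables = summ)
  })

  manifest <- list(
    package = "lncnat",
    version = as.character(utils::packageVersion("lncnat")),
    seed = seed,
    thresholds = unclass(cfg),
    stages_completed = stages,
    n_reference = n_transcripts(reference),
    n_novel = n_transcripts(novel),
    n_retained = nrow(cls$calls),
    n_nat_candidates = nrow(nats),
    input_digests = if (length(inputs)) {
      as.list(tools::md5sum(unlist(inputs)))
    } else {
      list()
    },
    outputs = as.list(tools::md5sum(
      list.files(outdir, pattern = "\\.(tsv|gff3)$", full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log(logcon, "pipeline finished")

  invisible(list(classification = cls, counts = cm,
                 size_factors = norm$sf, de = de, nats = nats,
                 summaries = summaries, manifest = manifest,
                 outdir = outdir))
}
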