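STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Longest open reading frame on the forward strand
#'
#' Scans all three forward frames of a spliced cDNA sequence for ATG...stop
#' spans under the standard codon table and returns the longest ORF with at
#' least `min_aa` amino acids.  The reverse strand is never searched: the
#' input is the oriented transcript sequence, so only forward ORFs are
#' biologically meaningful for the coding call.
#'
#' Rules: ties are broken towards the smallest start offset; codons
#' containing `N` match neither ATG nor a stop; an ORF running off the 3'
#' end without a stop still counts, with its length measured to the last
#' complete codon (`has_stop = FALSE`).  The amino-acid length includes the
#' initial Met and excludes the stop codon.
#'
#' @param cdna character scalar over A/C/G/T/N (case-insensitive).
#' @param min_aa minimum ORF length in amino acids (default 70).
#' @return `NULL` when no qualifying ORF exists, otherwise a list with
#'   `start_nt` (0-based offset of the A of ATG in `cdna`), `length_aa`,
#'   and `has_stop`.
#' @examples
#' longest_forward_orf("ATGAAATAA", min_aa = 1)  # 2 aa, has_stop
#' @export
longest_forward_orf <- function(cdna, min_aa = 70) {
  s <- toupper(cdna)
  L <- nchar(s)
  if (L < 3 * (min_aa + 1)) return(NULL)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  best <- NULL
  for (frame in 0:2) {
    n_cod <- (L - frame) %/% 3
    if (n_cod < min_aa) next
    idx <- frame + seq(1, by = 3, length.out = n_cod)
    codons <- paste0(chars[idx], chars[idx + 1], chars[idx + 2])
    starts <- which(codons == "ATG")
    if (!length(starts)) next
    stops <- which(codons %in% STOP_CODONS)
    ## index of first stop at or after each codon position
    nxt <- rep(NA_integer_, n_cod)
    if (length(stops)) {
      below <- findInterval(seq_len(n_cod) - 0.5, stops)  # stops before k
      has_next <- below < length(stops)
      nxt[has_next] <- stops[below[has_next] + 1L]
    }
    for (k in starts) {
      if (!is.na(nxt[k])) {
        len <- nxt[k] - k
        hs <- TRUE
      } else {
        len <- n_cod - k + 1
        hs <- FALSE
      }
      if (len < min_aa) next
      start_nt <- frame + 3 * (k - 1)
      if (is.null(best) || len > best$length_aa ||
          (len == best$length_aa && start_nt < best$start_nt)) {
        best <- list(start_nt = start_nt, length_aa = len, has_stop = hs)
      }
    }
  }
  best
}
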