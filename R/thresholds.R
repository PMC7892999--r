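#' Numeric thresholds used throughout the pipeline
#'
#' Bundles every tunable cutoff of the analysis in one validated list.
#' Defaults reflect the usual working definitions in plant lncRNA studies:
#' a transcript must be longer than 200 nt to count as "long"; an open
#' reading frame strictly longer than 120 aa marks a transcript as coding;
#' ORFs are searched down to 70 aa; long intergenic ncRNAs must lie more
#' than 1 kb from any protein-coding gene; sense/antisense co-expression
#' requires both |Pearson r| and |Spearman rho| at or above 0.70 with
#' p < 0.01; differential expression requires a Bonferroni-adjusted
#' p < 0.01.
#'
#' @param min_tx_len_nt minimum spliced transcript length (strictly
#'   greater-than), in nucleotides.
#' @param coding_orf_min_aa minimum ORF length (in amino acids, inclusive)
#'   for the coding call; 121 encodes "strictly greater than 120 aa".
#' @param orf_search_min_aa shortest ORF reported by the ORF finder (aa).
#' @param linc_min_distance_bp minimum distance (strictly greater-than,
#'   bp) from any protein-coding gene for the lincRNA subclass.
#' @param corr_abs_min minimum absolute correlation, applied to Pearson r
#'   and Spearman rho jointly.
#' @param corr_p_max strict upper bound on both correlation p values.
#' @param de_adj_p_max strict upper bound on the Bonferroni-adjusted p for
#'   a gene to be called differentially expressed.
#' @param pseudocount added to group means when forming log2 fold changes.
#' @param dispersion_floor lower bound for the per-gene NB dispersion.
#' @return A list of class `lncnat_thresholds`.
#' @examples
#' cfg <- thresholds_config()
#' cfg$min_tx_len_nt
#' @export
thresholds_config <- function(min_tx_len_nt = 200,
                              coding_orf_min_aa = 121,
                              orf_search_min_aa = 70,
                              linc_min_distance_bp = 1000,
                              corr_abs_min = 0.70,
                              corr_p_max = 0.01,
                              de_adj_p_max = 0.01,
                              pseudocount = 0.5,
                              dispersion_floor = 1e-8) {
  cfg <- list(
    min_tx_len_nt = min_tx_len_nt,
    coding_orf_min_aa = coding_orf_min_aa,
    orf_search_min_aa = orf_search_min_aa,
    linc_min_distance_bp = linc_min_distance_bp,
    corr_abs_min = corr_abs_min,
    corr_p_max = corr_p_max,
    de_adj_p_max = de_adj_p_max,
    pseudocount = pseudocount,
    dispersion_floor = dispersion_floor
  )
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("threshold '", nm, "' must be a single positive finite number")
    }
  }
  if (cfg$corr_abs_min > 1) {
    stop("corr_abs_min must lie in (0, 1]")
  }
  structure(cfg, class = "lncnat_thresholds")
}
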