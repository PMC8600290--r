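# Convenience wrapper running the full detection pipeline:
# preprocess -> fit parental models -> polymorphism test -> marker scan ->
# permutation calibration -> eQTL calls.

#' Run the eQTL detection pipeline end to end
#'
#' @param counts integer matrix genes x samples.
#' @param meta sample metadata (sample_id, line_id, transplant_set,
#'   sowing_date, sampling_time).
#' @param panel \linkS4class{GenotypePanel}.
#' @param meteo \linkS4class{MeteoSeries} (interpolated to minutes if not
#'   already minute-resolution).
#' @param genePositions optional data.frame(gene_id, chrom, pos_bp).
#' @param nPermPoly permutations for the polymorphism test.
#' @param nPermScan permutations for the marker scan.
#' @param qThreshold FDR level for both steps.
#' @param scanAll scan every gene instead of only polymorphism-flagged ones
#'   (used for null calibration runs).
#' @param seed RNG seed controlling both permutation steps.
#' @return list(fe, msetP1, msetP2, poly, scan, pvals, calls).
#' @export
runEqtlPipeline <- function(counts, meta, panel, meteo, genePositions = NULL,
                            nPermPoly = 500, nPermScan = 200,
                            qThreshold = 0.05, scanAll = FALSE, seed = 1) {
  step <- diff(as.numeric(timestamps(meteo)[1:2]))
  if (abs(step - 60) > 1e-6) meteo <- interpolateMeteo(meteo)
  fe <- FieldExpression(counts, meta)
  fe <- preprocessExpression(fe, headingDays(panel))
  msetP1 <- fitGeneModels(fe, panel, "P1", meteo)
  msetP2 <- fitGeneModels(fe, panel, "P2", meteo)
  poly <- polymorphismTest(fe, panel, msetP1, msetP2, meteo,
                           nPerm = nPermPoly, seed = .childSeed(seed, 11))
  scanSet <- if (scanAll) poly$gene_id else poly$gene_id[poly$polymorphic]
  if (!length(scanSet)) {
    return(list(fe = fe, msetP1 = msetP1, msetP2 = msetP2, poly = poly,
                scan = NULL, pvals = NULL,
                calls = callEqtlsEmpty()))
  }
  scan <- scanGenes(fe, panel, msetP1, msetP2, meteo, genes = scanSet)
  pvals <- permutationPvalues(scan, panel, nPerm = nPermScan,
                              seed = .childSeed(seed, 12))
  calls <- callEqtls(scan, pvals, panel, genePositions, qThreshold)
  list(fe = fe, msetP1 = msetP1, msetP2 = msetP2, poly = poly,
       scan = scan, pvals = pvals, calls = calls)
}

# Empty call table with the full schema.
callEqtlsEmpty <- function() {
  data.frame(gene = character(0), marker_block = character(0),
             representative_marker = character(0), chrom = character(0),
             pos_start = numeric(0), pos_end = numeric(0),
             rep_pos = numeric(0), statistic = numeric(0), p = numeric(0),
             q = numeric(0), n_markers_in_block = integer(0),
             selected = logical(0), combined_rss = numeric(0),
             pos_span = character(0), cis_trans = character(0),
             stringsAsFactors = FALSE)
}
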