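# Validation of called eQTLs: prediction under a new environment with
# per-gene improvement accounting, the BIL marker-permutation test, and
# Fisher + BH term enrichment.

#' Predict expression in a new environment under eQTL and background models
#'
#' For every eQTL-influenced gene, the eQTL-model prediction picks each
#' sample's parental model from the gene's selected marker blocks (majority
#' vote, ties toward the donor allele); the background (BG) model prediction
#' always uses the line's background parent. Both use the SAME fitted
#' parental models; nothing is refitted.
#'
#' @param msetP1,msetP2 fitted parental \linkS4class{GeneModelSet}s.
#' @param calls eQTL call table from \code{\link{callEqtls}}.
#' @param panel \linkS4class{GenotypePanel} containing the predicted lines.
#' @param meteoNew minute-resolution \linkS4class{MeteoSeries} of the new
#'   environment (must cover the feature windows).
#' @param metaNew sample metadata of the new samples (line_id,
#'   transplant_set, sowing_date, sampling_time).
#' @param genes genes to predict (default: all called genes). Genes without
#'   a call fall back to the BG assignment with a warning.
#' @return list(predEqtl, predBg) of genes x samples matrices, plus
#'   assignEqtl / assignBg (genes x lines model-choice matrices).
#' @export
predictNewEnvironment <- function(msetP1, msetP2, calls, panel, meteoNew,
                                  metaNew, genes = unique(calls$gene)) {
  missingLines <- setdiff(unique(metaNew$line_id), lineIds(panel))
  if (length(missingLines))
    stop("line(s) absent from panel: ", paste(missingLines, collapse = ", "))
  noCall <- setdiff(genes, unique(calls$gene))
  if (length(noCall))
    warning(length(noCall), " gene(s) without an eQTL call fall back to the ",
            "background assignment")
  sage <- scaledAge(metaNew, headingDays(panel))
  sf <- data.frame(sample_id = metaNew$sample_id,
                   sampling_time = metaNew$sampling_time,
                   scaled_age = unname(sage), stringsAsFactors = FALSE)
  sub <- function(ms) new("GeneModelSet", parent = ms@parent,
                          models = ms@models[genes], grid = ms@grid,
                          sampleIds = ms@sampleIds)
  yhat1 <- predictExpression(sub(msetP1), meteoNew, sf)
  yhat2 <- predictExpression(sub(msetP2), meteoNew, sf)
  lines <- lineIds(panel)
  bg <- background(panel)
  assignBg <- matrix(rep(bg[lines], each = length(genes)),
                     nrow = length(genes), dimnames = list(genes, lines))
  assignEqtl <- assignBg
  for (g in intersect(genes, unique(calls$gene))) {
    sel <- calls$representative_marker[calls$gene == g & calls$selected]
    if (!length(sel)) sel <- calls$representative_marker[calls$gene == g][1]
    assignEqtl[g, ] <- .combinedAssignment(panel, lines, sel)
  }
  lineOf <- as.character(metaNew$line_id)
  build <- function(assign) {
    out <- yhat1
    for (g in genes) {
      useP2 <- assign[g, lineOf] == "P2"
      out[g, useP2] <- yhat2[g, useP2]
    }
    out
  }
  list(predEqtl = build(assignEqtl), predBg = build(assignBg),
       assignEqtl = assignEqtl, assignBg = assignBg)
}

#' Per-gene prediction improvement of the eQTL model over the BG model
#'
#' Weighted squared prediction errors on held-out samples under both
#' assignments; a gene counts as improved iff its error under the eQTL
#' model is strictly smaller. Genes whose two predictions are identical
#' (assignments agree for every sample) are excluded from the fraction.
#'
#' @param predEqtl,predBg genes x samples prediction matrices.
#' @param observed genes x samples observed log2rpm for the same samples.
#' @param weights named per-gene precision weights.
#' @return list(perGene = data.frame(gene_id, error_eqtl, error_bg,
#'   eligible, improved), fraction, nEligible).
#' @export
improvementFraction <- function(predEqtl, predBg, observed, weights) {
  genes <- rownames(observed)
  w <- weights[genes]
  errE <- w * rowSums((observed - predEqtl[genes, , drop = FALSE])^2)
  errB <- w * rowSums((observed - predBg[genes, , drop = FALSE])^2)
  eligible <- rowSums(predEqtl[genes, , drop = FALSE] !=
                        predBg[genes, , drop = FALSE]) > 0
  if (!any(eligible))
    stop("no gene with differing eQTL and background assignments; ",
         "nothing to compare")
  improved <- errE < errB
  list(perGene = data.frame(gene_id = genes, error_eqtl = unname(errE),
                            error_bg = unname(errB),
                            eligible = unname(eligible),
                            improved = unname(improved), row.names = NULL),
       fraction = mean(improved[eligible]), nEligible = sum(eligible))
}

# Enumerate all permutations of 1..n (n <= 7 kept small deliberately).
.allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPerms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Marker permutation test of eQTL-based prediction in a BIL
#'
#' Observed statistic: the sum over eQTL-influenced genes of the weighted
#' squared prediction error for the BIL's samples when each gene's parental
#' model is chosen by the BIL's alleles at the gene's selected eQTL markers.
#' Null: permute the BIL's allele vector across markers (preserving allele
#' counts), reassign models, recompute the total. Empirical
#' p = (1 + #\{null <= observed\}) / (nPerm + 1); with
#' \code{exhaustive = TRUE} (<= 7 markers) all marker permutations are
#' enumerated and p = #\{null <= observed\} / N. Reference totals under the
#' pure-P1 and pure-P2 models are also returned.
#'
#' @param genes eQTL-influenced genes to sum over.
#' @param msetP1,msetP2 fitted parental model sets.
#' @param calls eQTL call table.
#' @param panel \linkS4class{GenotypePanel} containing the BIL.
#' @param bilLine line id of the BIL.
#' @param fe preprocessed \linkS4class{FieldExpression} holding the BIL's
#'   observed samples.
#' @param meteo minute-resolution weather covering those samples.
#' @param nPerm permutations (default 10000).
#' @param percentile percentile of the null reported as threshold
#'   (default 0.001, i.e. the 0.1\% percentile).
#' @param seed RNG seed.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return list(observed, p, threshold, null, refP1, refP2, nPerm).
#' @export
bilPermutationTest <- function(genes, msetP1, msetP2, calls, panel, bilLine,
                               fe, meteo, nPerm = 10000, percentile = 0.001,
                               seed = NULL, exhaustive = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  cd <- SummarizedExperiment::colData(fe)
  sIdx <- which(as.character(cd$line_id) == bilLine)
  if (!length(sIdx)) stop("no samples of line ", bilLine, " in the data")
  sf <- .sampleFrame(fe, sIdx)
  Y <- log2rpm(fe)[genes, sIdx, drop = FALSE]
  w <- geneWeights(fe)[genes]
  sub <- function(ms) new("GeneModelSet", parent = ms@parent,
                          models = ms@models[genes], grid = ms@grid,
                          sampleIds = ms@sampleIds)
  yhat1 <- predictExpression(sub(msetP1), meteo, sf)
  yhat2 <- predictExpression(sub(msetP2), meteo, sf)
  err1 <- w * rowSums((Y - yhat1)^2)
  err2 <- w * rowSums((Y - yhat2)^2)
  av <- alleles(panel)[bilLine, ]
  Mk <- length(av)
  if (length(unique(av)) == 1L) {
    warning("all BIL alleles identical: every permutation is identical; p = 1")
    obs <- sum(ifelse(av[1] == "P1", err1, err2))
    return(list(observed = obs, p = 1, threshold = obs, null = obs,
                refP1 = sum(err1), refP2 = sum(err2), nPerm = 0L))
  }
  donor <- if (background(panel)[bilLine] == "P1") "P2" else "P1"
  markerIdxOf <- lapply(genes, function(g) {
    sel <- calls$representative_marker[calls$gene == g & calls$selected]
    if (!length(sel)) sel <- calls$representative_marker[calls$gene == g][1]
    match(sel, markerIds(panel))
  })
  totalFor <- function(vec) {
    assignP2 <- vapply(markerIdxOf, function(ix) {
      a <- vec[ix]
      n2 <- sum(a == "P2"); n1 <- length(a) - n2
      if (n2 > n1) TRUE else if (n1 > n2) FALSE else donor == "P2"
    }, logical(1))
    sum(ifelse(assignP2, err2, err1))
  }
  obs <- totalFor(av)
  if (exhaustive) {
    if (Mk > 7) stop("exhaustive enumeration supported for <= 7 markers only")
    pm <- .allPerms(Mk)
    null <- apply(pm, 1, function(ix) totalFor(av[ix]))
    p <- sum(null <= obs + 1e-12) / length(null)
    nPerm <- nrow(pm)
  } else {
    null <- vapply(seq_len(nPerm), function(b) totalFor(av[sample.int(Mk)]),
                   numeric(1))
    p <- .permP(sum(null <= obs + 1e-12), nPerm)
  }
  thr <- sort(null)[max(1L, ceiling(percentile * length(null)))]
  list(observed = obs, p = p, threshold = thr, null = null,
       refP1 = sum(err1), refP2 = sum(err2), nPerm = nPerm)
}

#' Term enrichment of a gene set (Fisher exact + BH)
#'
#' For every annotation term, a two-sided 2x2 Fisher exact test of term
#' membership against set membership within the universe, followed by
#' Benjamini-Hochberg adjustment across terms.
#'
#' @param geneSet character vector, subset of \code{universe}.
#' @param universe all analyzed genes.
#' @param annotation data.frame(gene_id, term).
#' @param alpha adjusted-p cutoff for the \code{significant} flag.
#' @return data.frame(term, set_in_term, set_size, universe_in_term,
#'   odds_ratio, p, p_adj, significant), ordered by p.
#' @export
enrichmentTest <- function(geneSet, universe, annotation, alpha = 0.05) {
  if (!length(geneSet) || !length(universe))
    stop("geneSet and universe must be non-empty")
  if (!all(geneSet %in% universe))
    stop("geneSet must be a subset of universe")
  annotation <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  terms <- unique(annotation$term)
  rows <- lapply(terms, function(tm) {
    inTerm <- unique(annotation$gene_id[annotation$term == tm])
    a <- sum(geneSet %in% inTerm)
    b <- length(geneSet) - a
    cc <- sum(!(inTerm %in% geneSet))
    dd <- length(universe) - length(geneSet) - cc
    if ((b == 0 && dd == 0) || (a == 0 && cc == 0)) {
      # term annotates every gene (or none): enrichment is neutral
      orEst <- 1; pv <- 1
    } else {
      ft <- fisher.test(matrix(c(a, b, cc, dd), nrow = 2))
      orEst <- unname(ft$estimate); pv <- ft$p.value
    }
    data.frame(term = tm, set_in_term = a, set_size = length(geneSet),
               universe_in_term = length(inTerm),
               odds_ratio = orEst, p = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
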