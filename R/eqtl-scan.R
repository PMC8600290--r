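# Marker scan for eQTLs: per polymorphic gene, find the marker whose
# genotype assignment (which parental model predicts which sample)
# minimises the weighted prediction residual error; calibrate by line-level
# allele permutation; call eQTLs at FDR 0.05 (BH across genes on max-T
# permutation p-values); group linked markers into assignment-signature
# blocks; classify cis/trans; forward-select multiple eQTLs.

#' Assignment of parental models implied by one marker
#'
#' Every line uses the parental model matching its allele at the marker;
#' samples follow their line.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param marker marker id.
#' @return named character vector line -> "P1"/"P2".
#' @export
assignmentFromMarker <- function(panel, marker) {
  if (!marker %in% markerIds(panel))
    stop("unknown marker id: ", marker)
  setNames(alleles(panel)[, marker], lineIds(panel))
}

#' Scan markers for residual-error reductions
#'
#' For every gene and marker m, computes the weighted residual error sum
#' RSS_m = sum_s w_g (y_gs - yhat_s^(assignment_m))^2 where the assignment
#' picks each sample's parental model by its line's allele at m, and the
#' reduction T_m = RSS_BG - RSS_m relative to the background assignment.
#' The background assignment is always retained as an explicit candidate
#' (its RSS is the baseline), so the minimum over candidates never exceeds
#' RSS_BG. Parental predictions are computed once per parent and reused.
#' BIL samples are excluded from the scan.
#'
#' @param fe preprocessed \linkS4class{FieldExpression}.
#' @param panel \linkS4class{GenotypePanel}.
#' @param msetP1,msetP2 fitted parental \linkS4class{GeneModelSet}s.
#' @param meteo minute-resolution \linkS4class{MeteoSeries}.
#' @param genes genes to scan (default: all rows of \code{fe}); normally the
#'   polymorphic genes from \code{\link{polymorphismTest}}.
#' @return an \linkS4class{EqtlScan}.
#' @export
scanGenes <- function(fe, panel, msetP1, msetP2, meteo, genes = rownames(fe)) {
  cd <- SummarizedExperiment::colData(fe)
  type <- lineType(panel)
  keep <- type[as.character(cd$line_id)] != "bil"
  sf <- .sampleFrame(fe, keep)
  Y <- log2rpm(fe)[genes, keep, drop = FALSE]
  w <- geneWeights(fe)[genes]
  sub1 <- new("GeneModelSet", parent = "P1", models = msetP1@models[genes],
              grid = msetP1@grid, sampleIds = msetP1@sampleIds)
  sub2 <- new("GeneModelSet", parent = "P2", models = msetP2@models[genes],
              grid = msetP2@grid, sampleIds = msetP2@sampleIds)
  yhat1 <- predictExpression(sub1, meteo, sf)
  yhat2 <- predictExpression(sub2, meteo, sf)
  lines <- unique(sf$line_id)
  M <- outer(sf$line_id, lines, "==") + 0
  E1 <- ((Y - yhat1)^2) %*% M * w
  E2 <- ((Y - yhat2)^2) %*% M * w
  colnames(E1) <- colnames(E2) <- lines
  bg <- background(panel)[lines]
  A2 <- (alleles(panel)[lines, , drop = FALSE] == "P2") + 0
  d <- E2 - E1
  # same arithmetic path as the marker columns so that a marker whose
  # assignment equals the background gives T = 0 exactly
  rssBg <- drop(rowSums(E1) + d %*% ((bg == "P2") + 0))
  rssMarker <- rowSums(E1) + d %*% A2
  Tmat <- rssBg - rssMarker
  dimnames(Tmat) <- dimnames(rssMarker) <- list(genes, markerIds(panel))
  new("EqtlScan", geneIds = genes, markerIds = markerIds(panel),
      statistic = Tmat, rssMarker = rssMarker, rssBg = setNames(rssBg, genes),
      lineErrors = list(P1 = E1, P2 = E2), lines = lines,
      background = bg)
}

#' Permutation calibration of the marker scan
#'
#' Null: permute the allele column across lines (samples follow their line)
#' and recompute T. The permutation is stratified by line background —
#' alleles are shuffled among P1-background lines and among P2-background
#' lines separately, preserving each stratum's substitution count — because
#' each parental model is fitted on its own background's samples, so only
#' lines within a background are exchangeable under the null. Returns
#' per-marker p-values p_m = (1 + #\{T_null >= T_m\}) / (nPerm + 1), and
#' per-gene max-T p-values (the maximum of T over markers per permutation)
#' that account for the marker multiplicity within a gene; BH across genes
#' on the max-T p-values gives the gene-level q. A marker carrying the same
#' allele in every line has a constant null and p = 1.
#'
#' @param scan an \linkS4class{EqtlScan}.
#' @param panel the \linkS4class{GenotypePanel} the scan was run on.
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param withinGeneAlpha familywise level used to flag individual markers
#'   within a called gene (threshold = (1 - alpha) quantile of the max-T
#'   null); default 0.05.
#' @return list(pMarker, pGene, qGene, maxT, thresholdT, nPerm).
#' @export
permutationPvalues <- function(scan, panel, nPerm = 200, seed = NULL,
                               withinGeneAlpha = 0.05) {
  if (nPerm < 100) stop("nPerm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  E1 <- scan@lineErrors$P1
  E2 <- scan@lineErrors$P2
  d <- E2 - E1
  base <- rowSums(E1)
  G <- length(scan@geneIds)
  L <- length(scan@lines)
  Mk <- length(scan@markerIds)
  A2 <- (alleles(panel)[scan@lines, , drop = FALSE] == "P2") + 0
  strata <- split(seq_len(L), scan@background)
  perms <- matrix(0L, nPerm, L)
  for (b in seq_len(nPerm)) {
    pv <- integer(L)
    for (s in strata) pv[s] <- if (length(s) > 1) sample(s) else s
    perms[b, ] <- pv
  }
  pMarker <- matrix(NA_real_, G, Mk,
                    dimnames = list(scan@geneIds, scan@markerIds))
  pGene <- numeric(G)
  thrT <- numeric(G)
  maxT <- apply(scan@statistic, 1, max)
  for (g in seq_len(G)) {
    dg <- d[g, ]
    Dp <- matrix(dg[perms], nPerm, L)
    rssNull <- base[g] + Dp %*% A2
    Tnull <- scan@rssBg[g] - rssNull            # nPerm x markers
    Tg <- scan@statistic[g, ]
    cnt <- colSums(Tnull >= matrix(Tg, nPerm, Mk, byrow = TRUE) - 1e-12)
    pMarker[g, ] <- .permP(cnt, nPerm)
    mx <- apply(Tnull, 1, max)
    pGene[g] <- .permP(sum(mx >= maxT[g] - 1e-12), nPerm)
    thrT[g] <- quantile(mx, 1 - withinGeneAlpha, names = FALSE)
  }
  qGene <- p.adjust(pGene, method = "BH")
  list(pMarker = pMarker,
       pGene = setNames(pGene, scan@geneIds),
       qGene = setNames(qGene, scan@geneIds),
       maxT = setNames(maxT, scan@geneIds),
       thresholdT = setNames(thrT, scan@geneIds), nPerm = nPerm)
}

# Combined assignment over several marker blocks: per line, majority vote of
# the alleles at the representative markers; a tie is resolved toward the
# line's non-background (donor) allele, so that with two blocks a line
# deviates from its background if either block carries the donor allele.
.combinedAssignment <- function(panel, lines, markers) {
  al <- alleles(panel)[lines, markers, drop = FALSE]
  v2 <- rowSums(al == "P2")
  v1 <- rowSums(al == "P1")
  bg <- background(panel)[lines]
  donor <- ifelse(bg == "P1", "P2", "P1")
  setNames(ifelse(v1 > v2, "P1", ifelse(v2 > v1, "P2", donor)), lines)
}

# Weighted residual error of one gene under a per-line assignment.
.assignmentRss <- function(scan, gene, assign) {
  e1 <- scan@lineErrors$P1[gene, ]
  e2 <- scan@lineErrors$P2[gene, ]
  sum(e1[assign[scan@lines] == "P1"]) + sum(e2[assign[scan@lines] == "P2"])
}

#' Forward selection of multiple eQTLs for one gene
#'
#' Starting from the block with the largest T, candidate additional blocks
#' (in decreasing T order) are accepted when the combined assignment
#' (majority vote across selected blocks, ties toward the donor allele)
#' strictly lowers the weighted residual error.
#'
#' @param scan an \linkS4class{EqtlScan}.
#' @param panel the \linkS4class{GenotypePanel}.
#' @param gene gene id.
#' @param repMarkers representative markers of the gene's significant
#'   blocks, with their T statistics.
#' @param Tvals numeric vector of the blocks' T statistics.
#' @return list(selected = representative markers of the final set,
#'   combinedRss, assignment = line -> model).
#' @export
multiEqtlSelection <- function(scan, panel, gene, repMarkers, Tvals) {
  stopifnot(length(repMarkers) == length(Tvals), length(repMarkers) >= 1)
  ord <- order(-Tvals)
  repMarkers <- repMarkers[ord]
  sel <- repMarkers[1]
  assign <- .combinedAssignment(panel, scan@lines, sel)
  rss <- .assignmentRss(scan, gene, assign)
  for (m in repMarkers[-1]) {
    cand <- c(sel, m)
    a2 <- .combinedAssignment(panel, scan@lines, cand)
    r2 <- .assignmentRss(scan, gene, a2)
    if (r2 < rss) { sel <- cand; assign <- a2; rss <- r2 }
  }
  list(selected = sel, combinedRss = rss, assignment = assign)
}

#' Call eQTLs from a scan and its permutation calibration
#'
#' Genes with BH-adjusted max-T permutation p below \code{qThreshold} are
#' called. Within a called gene, markers whose T exceeds the gene's
#' familywise null threshold (plus the argmax marker) are grouped into
#' blocks of contiguous markers sharing an identical assignment signature
#' (identical allele columns across the scanned lines); linked markers
#' inside one substituted segment are mathematically indistinguishable, so
#' one call is emitted per block, represented by the member with maximal T
#' (ties to the smallest position). Multiple blocks per gene go through
#' \code{\link{multiEqtlSelection}}; members of the final set are flagged
#' \code{selected}.
#'
#' @param scan an \linkS4class{EqtlScan}.
#' @param pvals result of \code{\link{permutationPvalues}}.
#' @param panel the \linkS4class{GenotypePanel}.
#' @param genePositions optional data.frame(gene_id, chrom, pos_bp) for
#'   cis/trans labels.
#' @param qThreshold FDR level (default 0.05).
#' @param cisWindowBp cis window around the gene (default 2 Mb).
#' @return data.frame, one row per (gene, block): gene, marker_block,
#'   representative_marker, chrom, pos_start, pos_end, pos_span, statistic,
#'   p, q, cis_trans, n_markers_in_block, selected, combined_rss.
#' @export
callEqtls <- function(scan, pvals, panel, genePositions = NULL,
                      qThreshold = 0.05, cisWindowBp = 2e6) {
  mm <- markerMap(panel)
  al <- alleles(panel)[scan@lines, , drop = FALSE]
  sig <- character(0)
  rows <- list()
  for (g in scan@geneIds) {
    if (pvals$qGene[g] >= qThreshold) next
    Tg <- scan@statistic[g, ]
    sigIdx <- which(Tg >= pvals$thresholdT[g] & Tg > 0)
    sigIdx <- sort(union(sigIdx, which.max(Tg)))
    # group into contiguous identical-signature blocks
    blocks <- list()
    cur <- sigIdx[1]
    if (length(sigIdx) > 1) {
      for (i in sigIdx[-1]) {
        lastIdx <- cur[length(cur)]
        contig <- (i == lastIdx + 1) &&
          mm$chrom[i] == mm$chrom[lastIdx] &&
          identical(unname(al[, i]), unname(al[, lastIdx]))
        if (contig) cur <- c(cur, i)
        else { blocks[[length(blocks) + 1]] <- cur; cur <- i }
      }
    }
    blocks[[length(blocks) + 1]] <- cur
    reps <- vapply(blocks, function(b) b[which.max(Tg[b])], integer(1))
    Tb <- Tg[reps]
    ms <- multiEqtlSelection(scan, panel, g, mm$marker[reps], Tb)
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      rows[[length(rows) + 1]] <- data.frame(
        gene = g,
        marker_block = paste(mm$marker[b], collapse = ","),
        representative_marker = mm$marker[reps[bi]],
        chrom = mm$chrom[reps[bi]],
        pos_start = min(mm$pos_bp[b]), pos_end = max(mm$pos_bp[b]),
        rep_pos = mm$pos_bp[reps[bi]],
        statistic = unname(Tb[bi]),
        p = unname(pvals$pGene[g]), q = unname(pvals$qGene[g]),
        n_markers_in_block = length(b),
        selected = mm$marker[reps[bi]] %in% ms$selected,
        combined_rss = ms$combinedRss,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(gene = character(0), marker_block = character(0),
                      representative_marker = character(0),
                      chrom = character(0), pos_start = numeric(0),
                      pos_end = numeric(0), rep_pos = numeric(0),
                      statistic = numeric(0), p = numeric(0), q = numeric(0),
                      n_markers_in_block = integer(0), selected = logical(0),
                      combined_rss = numeric(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  out$pos_span <- if (nrow(out)) paste0(out$pos_start, "-", out$pos_end)
                  else character(0)
  out$cis_trans <- classifyCisTrans(out, genePositions, cisWindowBp)
  out <- out[order(out$gene, out$chrom, out$pos_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify calls as cis or trans
#'
#' A call is cis iff its representative marker lies on the gene's chromosome
#' within \code{cisWindowBp} of the gene position; otherwise trans. Missing
#' gene positions yield "unknown".
#'
#' @param calls data.frame with columns gene, chrom, rep_pos (as produced by
#'   \code{\link{callEqtls}}).
#' @param genePositions data.frame(gene_id, chrom, pos_bp) or NULL.
#' @param cisWindowBp cis distance bound (default 2 Mb).
#' @return character vector of labels "cis"/"trans"/"unknown".
#' @export
classifyCisTrans <- function(calls, genePositions, cisWindowBp = 2e6) {
  if (nrow(calls) == 0) return(character(0))
  if (is.null(genePositions)) return(rep("unknown", nrow(calls)))
  idx <- match(calls$gene, genePositions$gene_id)
  out <- rep("unknown", nrow(calls))
  known <- !is.na(idx)
  sameChrom <- known & genePositions$chrom[idx] == calls$chrom
  dist <- abs(genePositions$pos_bp[idx] - calls$rep_pos)
  out[known] <- ifelse(sameChrom[known] & dist[known] <= cisWindowBp,
                       "cis", "trans")
  out
}
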