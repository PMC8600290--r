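# Sample/gene quality filters, log2rpm normalisation, gene-level precision
# weights, scaled age, weather interpolation, dark periods and the
# sample-sample Pearson correlation matrix.

#' Filter samples by total read count
#'
#' Keeps samples whose total read count is strictly greater than
#' \code{minTotal} (default 1e5 reads).
#'
#' @param counts integer matrix genes x samples.
#' @param minTotal minimum total count (exclusive bound).
#' @return character vector of kept sample ids (possibly empty).
#' @export
filterSamples <- function(counts, minTotal = 1e5) {
  if (ncol(counts) == 0) return(character(0))
  totals <- colSums(counts)
  colnames(counts)[totals > minTotal]
}

#' Filter rarely detected genes
#'
#' Removes genes detected (count > 0) in at most \code{maxDetectFrac} of the
#' samples; a gene detected in exactly 20\% of samples is removed under the
#' default.
#'
#' @param counts integer matrix genes x samples (sample filter already applied).
#' @param maxDetectFrac detection fraction at or below which a gene is dropped.
#' @return character vector of kept gene ids.
#' @export
filterGenes <- function(counts, maxDetectFrac = 0.20) {
  if (nrow(counts) == 0) return(character(0))
  detect <- rowMeans(counts > 0)
  rownames(counts)[detect > maxDetectFrac]
}

#' Convert counts to log2 reads-per-million
#'
#' rpm = count * 1e6 / sample total (totals over the genes present in the
#' matrix, i.e. recomputed after gene filtering); log2rpm = log2(rpm + 1).
#' The +1 pseudo-count keeps the transform defined at zero counts.
#'
#' @param counts filtered integer matrix genes x samples.
#' @return numeric matrix of the same shape.
#' @export
toLog2rpm <- function(counts) {
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("zero total count for sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  rpm <- sweep(counts, 2, totals, "/") * 1e6
  log2(rpm + 1)
}

#' Gene-level precision weights from the mean-variance trend
#'
#' Computes per-gene means and mean squared residuals, fits a smooth trend
#' v(mean) by a running median over equal-size mean-rank bins, and returns
#' one weight per gene, w_g = 1 / max(v(mean_g), eps). Weights are constant
#' within a gene.
#'
#' @param log2rpm numeric matrix genes x samples.
#' @param binSize genes per rank bin of the running median (default 50, at
#'   least 5 bins are used when possible).
#' @param eps variance floor (default 1e-6).
#' @return named numeric vector of weights, one per gene.
#' @export
precisionWeights <- function(log2rpm, binSize = 50, eps = 1e-6) {
  G <- nrow(log2rpm)
  if (G < 10) {
    warning("fewer than 10 genes: using uniform precision weights")
    return(setNames(rep(1, G), rownames(log2rpm)))
  }
  m <- rowMeans(log2rpm)
  s2 <- rowMeans((log2rpm - m)^2)
  ord <- order(m)
  nBins <- max(5L, min(G %/% 5L, ceiling(G / binSize)))
  bin <- ceiling(seq_along(ord) / (G / nBins))
  v <- numeric(G)
  binMed <- tapply(s2[ord], bin, median)
  v[ord] <- binMed[bin]
  w <- 1 / pmax(v, eps)
  setNames(w, rownames(log2rpm))
}

#' Scaled age of each sample
#'
#' Days from sowing to sampling (fractional, minutes since midnight / 1440)
#' divided by the line's days from sowing to heading in its transplant set;
#' a sample taken at heading has scaled age exactly 1.
#'
#' @param meta sample metadata data.frame with line_id, transplant_set,
#'   sowing_date, sampling_time.
#' @param headingDays data.frame(line_id, transplant_set, heading_days).
#' @return named numeric vector of scaled ages (by sample_id).
#' @export
scaledAge <- function(meta, headingDays) {
  key <- paste(meta$line_id, meta$transplant_set)
  hkey <- paste(headingDays$line_id, headingDays$transplant_set)
  idx <- match(key, hkey)
  if (anyNA(idx))
    stop("no heading day for (line, transplant_set): ",
         paste(unique(key[is.na(idx)])[1:min(3, sum(is.na(idx)))], collapse = "; "))
  hd <- headingDays$heading_days[idx]
  if (any(hd <= 0)) stop("heading_days must be positive")
  ageDays <- as.numeric(difftime(meta$sampling_time, meta$sowing_date,
                                 units = "mins")) / 1440
  setNames(ageDays / hd, meta$sample_id)
}

#' Interpolate a weather series to minute resolution
#'
#' Linear interpolation of each variable onto a regular per-minute grid
#' spanning the input range; original points that fall on the grid are
#' preserved exactly.
#'
#' @param meteo a \linkS4class{MeteoSeries} (e.g. 10-min resolution).
#' @return a minute-resolution \linkS4class{MeteoSeries}.
#' @export
interpolateMeteo <- function(meteo) {
  tIn <- as.numeric(timestamps(meteo))
  if (length(tIn) < 2) stop("need at least two time points to interpolate")
  grid <- seq(tIn[1], tIn[length(tIn)], by = 60)
  tempOut <- approx(tIn, temperature(meteo), xout = grid)$y
  radOut <- approx(tIn, radiation(meteo), xout = grid)$y
  MeteoSeries(as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
              tempOut, radOut)
}

#' Dark periods of a weather series
#'
#' Maximal half-open intervals [start, end) during which global solar
#' radiation is strictly below \code{threshold} (default 0.3 kJ m-2 min-1).
#' The final interval is closed by one grid step past the last dark minute.
#'
#' @param meteo minute-resolution \linkS4class{MeteoSeries}.
#' @param threshold radiation threshold, strict.
#' @return data.frame(start, end) of POSIXct interval bounds (0 rows if none).
#' @export
darkPeriods <- function(meteo, threshold = 0.3) {
  dark <- radiation(meteo) < threshold
  tm <- timestamps(meteo)
  if (!any(dark))
    return(data.frame(start = tm[0], end = tm[0]))
  r <- rle(dark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  step <- if (length(tm) > 1) diff(as.numeric(tm[1:2])) else 60
  data.frame(start = tm[starts[keep]],
             end = as.POSIXct(as.numeric(tm[ends[keep]]) + step,
                              origin = "1970-01-01", tz = "UTC"))
}

#' Sample-sample Pearson correlation matrix
#'
#' Pearson correlation between every pair of samples over genes, centering
#' each sample by its own mean across genes. Zero-variance samples yield NA
#' entries and a warning.
#'
#' @param log2rpm numeric matrix genes x samples (>= 2 genes).
#' @return symmetric samples x samples correlation matrix, unit diagonal.
#' @export
sampleCorrelationMatrix <- function(log2rpm) {
  if (nrow(log2rpm) < 2) stop("need at least two genes")
  sds <- apply(log2rpm, 2, sd)
  if (any(sds == 0))
    warning("zero-variance sample(s): ",
            paste(colnames(log2rpm)[sds == 0], collapse = ", "),
            "; correlation undefined (NA)")
  rho <- suppressWarnings(cor(log2rpm))
  diag(rho)[!is.na(diag(rho))] <- 1
  rho
}

#' Construct a FieldExpression object from counts and metadata
#'
#' @param counts integer matrix genes x samples.
#' @param meta sample metadata (one row per sample; matched by sample_id).
#' @return a \linkS4class{FieldExpression} with a counts assay.
#' @export
FieldExpression <- function(counts, meta) {
  idx <- match(colnames(counts), meta$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(colnames(counts)[is.na(idx)][1:min(3, sum(is.na(idx)))],
               collapse = ", "))
  cd <- S4Vectors::DataFrame(meta[idx, , drop = FALSE])
  rownames(cd) <- colnames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("FieldExpression", se)
}

#' Preprocess a FieldExpression object
#'
#' Applies the sample filter (total reads > minTotal) and gene detection
#' filter (detected in > maxDetectFrac of kept samples), recomputes totals on
#' the kept genes, adds the log2rpm assay, gene-level precision weights and
#' per-sample scaled age.
#'
#' @param fe a \linkS4class{FieldExpression} with a counts assay.
#' @param headingDays data.frame(line_id, transplant_set, heading_days), e.g.
#'   \code{headingDays(panel)}.
#' @param minTotal sample filter bound (strict).
#' @param maxDetectFrac gene detection fraction at or below which genes drop.
#' @return the filtered \linkS4class{FieldExpression} with assays counts and
#'   log2rpm, rowData()$weight and colData()$scaled_age.
#' @export
preprocessExpression <- function(fe, headingDays, minTotal = 1e5,
                                 maxDetectFrac = 0.20) {
  counts <- SummarizedExperiment::assay(fe, "counts")
  keepS <- filterSamples(counts, minTotal)
  counts <- counts[, keepS, drop = FALSE]
  keepG <- filterGenes(counts, maxDetectFrac)
  counts <- counts[keepG, , drop = FALSE]
  if (nrow(counts) == 0 || ncol(counts) == 0)
    stop("no genes or samples survive filtering")
  lrpm <- toLog2rpm(counts)
  w <- precisionWeights(lrpm)
  out <- fe[keepG, keepS]
  SummarizedExperiment::assay(out, "counts") <- counts
  SummarizedExperiment::assay(out, "log2rpm") <- lrpm
  SummarizedExperiment::rowData(out)$weight <- unname(w)
  cd <- SummarizedExperiment::colData(out)
  meta <- data.frame(sample_id = rownames(cd), line_id = cd$line_id,
                     transplant_set = cd$transplant_set,
                     sowing_date = cd$sowing_date,
                     sampling_time = cd$sampling_time)
  SummarizedExperiment::colData(out)$scaled_age <-
    unname(scaledAge(meta, headingDays))
  out
}
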