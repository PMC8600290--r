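# Shared fixtures, memoised across test files (test_dir runs all files in
# one session; expensive simulations are built once on first use).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Small desk-scale dataset for unit tests.
smallCfg <- function(...) {
  args <- list(nChrom = 6, markersPerChrom = 8, nCsslPerBackground = 12,
               nGenes = 40, nFillerGenes = 80, nSamplingDays = 5,
               seasonSpanDays = 110, seed = 2015)
  do.call(simConfig, utils::modifyList(args, list(...)))
}

smallSim <- function() memo("smallSim", function() simulateDataset(smallCfg()))

smallFe <- function() memo("smallFe", function() {
  sim <- smallSim()
  fe <- FieldExpression(sim$counts, sim$schedule)
  preprocessExpression(fe, headingDays(sim$panel))
})

smallModels <- function() memo("smallModels", function() {
  sim <- smallSim()
  list(P1 = fitGeneModels(smallFe(), sim$panel, "P1", sim$meteo),
       P2 = fitGeneModels(smallFe(), sim$panel, "P2", sim$meteo))
})

# Default-scale dataset + full pipeline under the study conditions
# (80 CSSLs + 2 parents, 144 markers, 300 focal genes, 20% polymorphic,
# 8 bihourly sampling days, scan permutations 200). Shared by the
# planted-recovery, cross-environment and BIL acceptance checks.
accSim <- function() memo("accSim", function() simulateDataset(simConfig(seed = 42)))

accRun <- function() memo("accRun", function() {
  sim <- accSim()
  runEqtlPipeline(sim$counts, sim$schedule, sim$panel, sim$meteo,
                  genePositions = sim$genePositions,
                  nPermPoly = 500, nPermScan = 200, seed = 3)
})

# FieldExpression carrying a latent log2rpm matrix directly (bypasses the
# count path; used for exact/noiseless checks), uniform weights.
latentFe <- function(sim) {
  lat <- sim$truth$latent
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2rpm = lat),
    colData = S4Vectors::DataFrame(sim$schedule,
                                   row.names = sim$schedule$sample_id))
  fe <- new("FieldExpression", se)
  SummarizedExperiment::rowData(fe)$weight <- rep(1, nrow(lat))
  SummarizedExperiment::colData(fe)$scaled_age <-
    unname(scaledAge(sim$schedule, headingDays(sim$panel)))
  fe
}

# Planted term set of one gene as a sorted character vector.
plantedTerms <- function(par) {
  out <- character(0)
  if (!is.na(par$a)) out <- c(out, "clock")
  if (!is.na(par$c)) out <- c(out, "age")
  if (!is.na(par$d)) out <- c(out, "env")
  sort(out)
}

# Did a call table recover the controlling marker of gene g (block contains
# or is adjacent to it)?
recoveredMarker <- function(calls, panel, g, trueMarker) {
  cb <- calls[calls$gene == g, , drop = FALSE]
  if (!nrow(cb)) return(FALSE)
  ti <- match(trueMarker, markerIds(panel))
  any(vapply(strsplit(cb$marker_block, ","), function(mb)
    any(abs(match(mb, markerIds(panel)) - ti) <= 1), logical(1)))
}

## ---- independent brute-force oracles ----

# Benjamini-Hochberg by the textbook formula.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Pearson correlation matrix by a double loop.
corOracle <- function(m) {
  n <- ncol(m)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- m[, i] - mean(m[, i]); y <- m[, j] - mean(m[, j])
    out[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  out
}

# Weighted RSS by a per-sample loop.
rssOracle <- function(y, yhat, w) {
  s <- 0
  for (i in seq_along(y)) s <- s + w[i] * (y[i] - yhat[i])^2
  s
}

# Two-sided Fisher exact p by hypergeometric tail sums.
fisherOracle <- function(a, b, cc, dd) {
  m <- a + cc; n <- b + dd; k <- a + b
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  dobs <- dhyper(a, m, n, k)
  sum(dens[dens <= dobs * (1 + 1e-7)])
}

# Dark periods by a linear scan.
darkOracle <- function(times, rad, threshold) {
  out <- list()
  inDark <- FALSE
  step <- if (length(times) > 1) diff(as.numeric(times[1:2])) else 60
  for (i in seq_along(rad)) {
    if (rad[i] < threshold && !inDark) { start <- times[i]; inDark <- TRUE }
    if (rad[i] >= threshold && inDark) {
      out[[length(out) + 1]] <- c(start, times[i]); inDark <- FALSE
    }
  }
  if (inDark)
    out[[length(out) + 1]] <-
      c(start, as.POSIXct(as.numeric(times[length(times)]) + step,
                          origin = "1970-01-01", tz = "UTC"))
  out
}
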