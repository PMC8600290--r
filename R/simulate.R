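# Synthetic-data generator. Emulates the experimental design the analysis
# assumes: two parental lines, reciprocal CSSL panels tiling the genome, a
# couple of mosaic BILs, staggered transplant sets, bihourly sampling days
# across one growing season, diurnal + seasonal weather, and counts generated
# from planted per-parent expression models with planted cis/trans eQTLs.
# Emits the ground truth needed for parameter/eQTL-recovery tests.

#' Simulation configuration
#'
#' Returns a validated configuration list with the default desk-scale design:
#' 12 chromosomes x 12 markers, 40 CSSLs per background + 2 parents + 2 BILs,
#' 300 genes (20\% polymorphic, 25\% of those trans-controlled), 8 bihourly
#' sampling days (12 time points each) and 2 transplant sets sown 14 days
#' apart. Planted parental mean differences are at least
#' \code{effectMuRange[1]} times \code{noiseSd}.
#'
#' @param nChrom,markersPerChrom,chromLengthBp genome layout.
#' @param nCsslPerBackground,nBil,bilSubstitutionFrac panel composition; the
#'   BIL donor-allele fraction is targeted within +-5 percentage points.
#' @param nGenes,fracPolymorphic,fracTransAmongEqtl transcriptome layout:
#'   \code{nGenes} focal genes, a fraction of them with planted eQTLs.
#' @param nFillerGenes additional genes that are always non-polymorphic.
#'   Real libraries are normalised over tens of thousands of genes, so
#'   allele-dependent changes in a few genes barely move per-sample totals;
#'   with only a few hundred simulated genes the totals would become
#'   genotype-dependent and leak a spurious background-correlated shift into
#'   every gene's log2rpm. The filler genes restore total-count stability
#'   and pass through the analysis as ordinary null genes.
#' @param noiseSd residual SD on the log2rpm scale.
#' @param baseMuRange range of baseline log2rpm intercepts of the focal
#'   genes (kept low-to-moderate so planted fold changes cannot perturb
#'   library totals).
#' @param fillerMuRange intercept range of the filler genes, extending into
#'   the high-expression housekeeping tail that carries the library mass.
#' @param effectMuRange parental intercept difference for polymorphic genes,
#'   in units of noiseSd (magnitude drawn uniformly, sign random).
#' @param clockProb,clockAmpRange,ageProb,ageCoefRange,envProb,envSnrRange
#'   per-term inclusion probabilities and effect scales (env effect scaled to
#'   a target signal-to-noise ratio). Environmental and scaled-age terms act
#'   on covariates centred at their training-schedule means, so the
#'   intercept is the gene's baseline log2rpm.
#' @param fillerClockAmpRange,fillerAgeCoefRange,fillerEnvSnrRange effect
#'   scales of the filler genes; kept modest (housekeeping-like) so the
#'   library mass they carry stays stable across samples.
#' @param librarySizeRange per-sample library sizes (reads), drawn uniformly.
#' @param nSamplingDays,samplesPerDay,linesPerTimepoint sampling design
#'   (bihourly sampling implies samplesPerDay = 12).
#' @param nTransplantSets,transplantStaggerDays staggered sowing design.
#' @param seasonSpanDays,seasonStart season covered by the weather series.
#' @param headingDayMeanP1,headingDayMeanP2,headingDaySd days from sowing to
#'   heading; the ~10-day parental difference exercises the scaled-age
#'   adjustment.
#' @param countModel "lognormal" (round the latent rpm) or "nbinom"
#'   (negative-binomial resampling of the latent mean).
#' @param nbDispersion NB dispersion when countModel = "nbinom".
#' @param dropoutProb probability that a scheduled sample in the last third
#'   of the season is lost (withered plants); 0 disables dropout.
#' @param seed base RNG seed; a fixed seed gives byte-identical outputs.
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(nChrom = 12, markersPerChrom = 12, chromLengthBp = 3e7,
                      nCsslPerBackground = 40, nBil = 2,
                      bilSubstitutionFrac = 0.18,
                      nGenes = 300, nFillerGenes = 700,
                      fracPolymorphic = 0.20,
                      fracTransAmongEqtl = 0.25,
                      noiseSd = 0.5, baseMuRange = c(6, 10),
                      fillerMuRange = c(6, 14),
                      effectMuRange = c(3, 5),
                      clockProb = 0.6, clockAmpRange = c(0.5, 2),
                      ageProb = 0.5, ageCoefRange = c(0.5, 2),
                      envProb = 0.4, envSnrRange = c(1, 3),
                      fillerClockAmpRange = c(0.05, 0.5),
                      fillerAgeCoefRange = c(0.05, 0.5),
                      fillerEnvSnrRange = c(0.2, 0.8),
                      librarySizeRange = c(5e5, 3e6),
                      nSamplingDays = 8, samplesPerDay = 12,
                      linesPerTimepoint = 2,
                      nTransplantSets = 2, transplantStaggerDays = 14,
                      seasonSpanDays = 150, seasonStart = "2015-05-01",
                      headingDayMeanP1 = 100, headingDayMeanP2 = 90,
                      headingDaySd = 3,
                      countModel = c("lognormal", "nbinom"),
                      nbDispersion = 0.05, dropoutProb = 0, seed = 1) {
  cfg <- list(nChrom = nChrom, markersPerChrom = markersPerChrom,
              chromLengthBp = chromLengthBp,
              nCsslPerBackground = nCsslPerBackground, nBil = nBil,
              bilSubstitutionFrac = bilSubstitutionFrac, nGenes = nGenes,
              nFillerGenes = nFillerGenes,
              fracPolymorphic = fracPolymorphic,
              fracTransAmongEqtl = fracTransAmongEqtl, noiseSd = noiseSd,
              baseMuRange = baseMuRange, fillerMuRange = fillerMuRange,
              effectMuRange = effectMuRange,
              clockProb = clockProb, clockAmpRange = clockAmpRange,
              ageProb = ageProb, ageCoefRange = ageCoefRange,
              envProb = envProb, envSnrRange = envSnrRange,
              fillerClockAmpRange = fillerClockAmpRange,
              fillerAgeCoefRange = fillerAgeCoefRange,
              fillerEnvSnrRange = fillerEnvSnrRange,
              librarySizeRange = librarySizeRange,
              nSamplingDays = nSamplingDays, samplesPerDay = samplesPerDay,
              linesPerTimepoint = linesPerTimepoint,
              nTransplantSets = nTransplantSets,
              transplantStaggerDays = transplantStaggerDays,
              seasonSpanDays = seasonSpanDays, seasonStart = seasonStart,
              headingDayMeanP1 = headingDayMeanP1,
              headingDayMeanP2 = headingDayMeanP2,
              headingDaySd = headingDaySd,
              countModel = match.arg(countModel),
              nbDispersion = nbDispersion, dropoutProb = dropoutProb,
              seed = seed)
  counts <- c("nChrom", "markersPerChrom", "nCsslPerBackground", "nGenes",
              "nSamplingDays", "samplesPerDay", "linesPerTimepoint",
              "nTransplantSets", "seasonSpanDays")
  for (f in counts)
    if (cfg[[f]] < 1) stop("config field '", f, "' must be positive")
  for (f in c("fracPolymorphic", "fracTransAmongEqtl", "bilSubstitutionFrac",
              "dropoutProb"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("config field '", f, "' must be in [0, 1]")
  if (cfg$noiseSd < 0) stop("noiseSd must be >= 0")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a CSSL + BIL genotype panel
#'
#' Two parents (uniform P1 / uniform P2 alleles); per background,
#' \code{nCsslPerBackground} CSSLs each carrying exactly one contiguous donor
#' segment, the segments tiling every marker; \code{nBil} Takanari-background
#' style BILs whose donor-allele fraction hits
#' \code{bilSubstitutionFrac} within +-5 percentage points via a two-state
#' Markov chain along the markers. Heading days are drawn per (line,
#' transplant set) around the background parent's mean.
#'
#' @param cfg a \code{\link{simConfig}} list.
#' @param seed RNG seed (default derived from cfg$seed).
#' @return list(panel = \linkS4class{GenotypePanel}, truth = list(segments)).
#' @export
simulateGenotypes <- function(cfg, seed = .childSeed(cfg$seed, 1)) {
  if (!is.null(seed)) set.seed(seed)
  nM <- cfg$nChrom * cfg$markersPerChrom
  chroms <- sprintf("chr%02d", seq_len(cfg$nChrom))
  mm <- data.frame(
    marker = sprintf("M%03d", seq_len(nM)),
    chrom = rep(chroms, each = cfg$markersPerChrom),
    pos_bp = rep(round(seq(1e6, cfg$chromLengthBp, length.out =
                             cfg$markersPerChrom)), cfg$nChrom))
  nCssl <- cfg$nCsslPerBackground
  if (nCssl < cfg$nChrom)
    stop("need at least one CSSL per chromosome to tile the genome")
  segPerChrom <- rep(nCssl %/% cfg$nChrom, cfg$nChrom)
  extra <- nCssl %% cfg$nChrom
  if (extra > 0) segPerChrom[seq_len(extra)] <- segPerChrom[seq_len(extra)] + 1L
  if (max(segPerChrom) > cfg$markersPerChrom)
    stop("markersPerChrom too small to tile the requested CSSL count")
  # overlapping donor segments, as in real reciprocal CSSL panels where
  # adjacent lines share boundary regions: segment length ~ 2m/s so each
  # marker is covered by about two lines per background
  segments <- list()
  for (ci in seq_len(cfg$nChrom)) {
    s <- segPerChrom[ci]
    m <- cfg$markersPerChrom
    L <- max(1L, min(m, round(2 * m / s)))
    starts <- if (s == 1) 1L else round(seq(1, m - L + 1, length.out = s))
    off <- (ci - 1) * m
    for (si in seq_len(s))
      segments[[length(segments) + 1]] <- off + (starts[si]:(starts[si] + L - 1))
  }
  lines <- c("P1", "P2",
             sprintf("SL_K%02d", seq_len(nCssl)),
             sprintf("SL_T%02d", seq_len(nCssl)),
             if (cfg$nBil > 0) sprintf("BIL%02d", seq_len(cfg$nBil)))
  al <- matrix("P1", nrow = length(lines), ncol = nM,
               dimnames = list(lines, mm$marker))
  al["P2", ] <- "P2"
  segTruth <- list()
  for (i in seq_len(nCssl)) {        # Koshihikari-role (P1) background
    al[sprintf("SL_K%02d", i), ] <- "P1"
    al[sprintf("SL_K%02d", i), segments[[i]]] <- "P2"
    segTruth[[sprintf("SL_K%02d", i)]] <- segments[[i]]
  }
  for (i in seq_len(nCssl)) {        # Takanari-role (P2) background
    al[sprintf("SL_T%02d", i), ] <- "P2"
    al[sprintf("SL_T%02d", i), segments[[i]]] <- "P1"
    segTruth[[sprintf("SL_T%02d", i)]] <- segments[[i]]
  }
  # BILs: P2 background, P1 donor blocks from a two-state Markov chain,
  # redrawn until the realised donor fraction is within +-5pp of target.
  tgt <- cfg$bilSubstitutionFrac
  for (b in seq_len(cfg$nBil)) {
    for (try in seq_len(2000)) {
      state <- runif(1) < tgt
      v <- logical(nM)
      pStay <- 0.85
      for (j in seq_len(nM)) {
        v[j] <- state
        pNext <- if (state) pStay else 1 - (tgt / (1 - tgt)) * (1 - pStay)
        state <- if (runif(1) < pNext) state else !state
      }
      frac <- mean(v)
      if (abs(frac - tgt) <= 0.05 && any(v) && !all(v)) break
    }
    al[sprintf("BIL%02d", b), ] <- ifelse(v, "P1", "P2")
  }
  # line types and backgrounds are known from construction; record them
  # rather than re-inferring from the allele patterns
  bg <- setNames(c("P1", "P2", rep("P1", nCssl), rep("P2", nCssl),
                   rep("P2", cfg$nBil)), lines)
  type <- setNames(c("parent", "parent", rep("cssl", 2 * nCssl),
                     rep("bil", cfg$nBil)), lines)
  hd <- expand.grid(line_id = lines, transplant_set = seq_len(cfg$nTransplantSets),
                    stringsAsFactors = FALSE)
  mu <- ifelse(bg[hd$line_id] == "P1",
               cfg$headingDayMeanP1, cfg$headingDayMeanP2)
  hd$heading_days <- pmax(30, rnorm(nrow(hd), mu, cfg$headingDaySd))
  panel <- GenotypePanel(al, mm, headingDays = hd)
  panel@background <- bg
  panel@lineType <- type
  validObject(panel)
  list(panel = panel, truth = list(segments = segTruth))
}

#' Simulate a season of minute-resolution weather
#'
#' Temperature is a seasonal trend plus a diurnal sinusoid (peak 14:00) plus
#' AR(1) noise; radiation is a daylight half-sinusoid scaled by a daily cloud
#' factor, exactly zero at night.
#'
#' @param cfg a \code{\link{simConfig}} list.
#' @param seed RNG seed.
#' @param tempBase,tempSeasonalAmp,tempDiurnalAmp,radPeak climate parameters
#'   (degC, degC, degC, kJ m-2 min-1); override to emulate another season.
#' @param startDate first day (ISO date); defaults to cfg$seasonStart.
#' @return a minute-resolution \linkS4class{MeteoSeries}.
#' @export
simulateMeteo <- function(cfg, seed = .childSeed(cfg$seed, 2),
                          tempBase = 18, tempSeasonalAmp = 8,
                          tempDiurnalAmp = 4, radPeak = 1.2,
                          startDate = cfg$seasonStart) {
  if (!is.null(seed)) set.seed(seed)
  nDays <- cfg$seasonSpanDays
  N <- nDays * 1440L
  minuteIdx <- 0:(N - 1)
  h <- (minuteIdx %% 1440) / 60
  day <- minuteIdx %/% 1440
  trend <- tempBase + tempSeasonalAmp * sin(pi * (day + h / 24) / nDays)
  diurnal <- tempDiurnalAmp * cos(2 * pi * (h - 14) / 24)
  noise <- as.numeric(stats::filter(rnorm(N, 0, 0.03), 0.995,
                                    method = "recursive"))
  temp <- trend + diurnal + noise
  rise <- 5.5; sunset <- 18.75
  cloud <- runif(nDays, 0.25, 1)
  rad <- ifelse(h >= rise & h <= sunset,
                radPeak * cloud[day + 1] * sin(pi * (h - rise) / (sunset - rise)),
                0)
  rad <- pmax(rad, 0)
  t0 <- .parseTime(startDate)
  MeteoSeries(t0 + minuteIdx * 60, temp, rad)
}

#' Simulate the bihourly stratified sampling schedule
#'
#' Each sampling day runs 12 bihourly time points from 16:00 to 14:00 the
#' next day. Lines are drawn with a stratified (lowest-count-first)
#' randomisation so per-line totals across the season differ by at most one;
#' no (line, transplant set) is sampled twice on a day.
#'
#' @param cfg a \code{\link{simConfig}} list.
#' @param panel a \linkS4class{GenotypePanel}.
#' @param seed RNG seed.
#' @return sample metadata data.frame (sample_id, line_id, transplant_set,
#'   sowing_date, sampling_time, site_id).
#' @export
simulateSchedule <- function(cfg, panel, seed = .childSeed(cfg$seed, 3)) {
  if (!is.null(seed)) set.seed(seed)
  lines <- lineIds(panel)
  nNeed <- cfg$samplesPerDay * cfg$linesPerTimepoint
  if (nNeed > length(lines))
    stop("more requested samples per day (", nNeed,
         ") than lines available (", length(lines), ")")
  t0 <- .parseTime(cfg$seasonStart)
  firstDay <- max(35, (cfg$nTransplantSets - 1) * cfg$transplantStaggerDays + 21)
  lastDay <- cfg$seasonSpanDays - 20
  if (lastDay <= firstDay) stop("seasonSpanDays too short for the schedule")
  days <- unique(round(seq(firstDay, lastDay,
                           length.out = cfg$nSamplingDays)))
  hours <- 16 + 2 * (0:(cfg$samplesPerDay - 1))
  counts <- matrix(0L, nrow = length(lines), ncol = cfg$nTransplantSets,
                   dimnames = list(lines, NULL))
  rows <- list()
  for (d in days) {
    for (st in seq_len(cfg$nTransplantSets)) {
      ord <- order(counts[, st], runif(length(lines)))
      chosen <- lines[ord[seq_len(nNeed)]]
      chosen <- sample(chosen)
      counts[chosen, st] <- counts[chosen, st] + 1L
      tp <- rep(hours, each = cfg$linesPerTimepoint)
      for (i in seq_along(chosen)) {
        rows[[length(rows) + 1]] <- data.frame(
          line_id = chosen[i], transplant_set = st,
          sowing_date = t0 + (st - 1) * cfg$transplantStaggerDays * 86400,
          sampling_time = t0 + d * 86400 + tp[i] * 3600,
          stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, rows)
  if (cfg$dropoutProb > 0) {
    late <- as.numeric(difftime(meta$sampling_time, t0, units = "days")) >
      2 / 3 * cfg$seasonSpanDays
    drop <- late & runif(nrow(meta)) < cfg$dropoutProb
    meta <- meta[!drop, , drop = FALSE]
  }
  meta <- meta[order(meta$sampling_time, meta$transplant_set, meta$line_id), ]
  meta$sample_id <- sprintf("S%05d", seq_len(nrow(meta)))
  meta$site_id <- "simfield"
  rownames(meta) <- NULL
  meta[, c("sample_id", "line_id", "transplant_set", "sowing_date",
           "sampling_time", "site_id")]
}

# Evaluate a planted parental model (one parameter row) for given samples.
# sage and E are centred at the training-schedule means (stored with the
# truth), so par$mu is the gene's baseline log2rpm.
.evalPlanted <- function(par, hours, sage, E, centers) {
  y <- rep(par$mu, length(hours))
  if (!is.na(par$a)) y <- y + par$a * cos(2 * pi * hours / 24) +
      par$b * sin(2 * pi * hours / 24)
  if (!is.na(par$c)) y <- y + par$c * (sage - centers$sage)
  if (!is.na(par$d)) y <- y + par$d * (E - centers$E[par$specIdx])
  y
}

#' Simulate expression counts from planted parental models
#'
#' Each gene has a parental model per parent (intercept, optional clock,
#' scaled-age and gated-window environment terms). For a polymorphic gene the
#' model used for a sample is chosen by the line's allele at the planted
#' controlling marker; otherwise by the line's background. Latent log2rpm
#' gets Gaussian noise (sd = noiseSd); counts are
#' \code{round(max(2^y - 1, 0) * librarySize / 1e6)} (or a negative-binomial
#' draw around that mean when cfg$countModel = "nbinom").
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param meteo a minute-resolution \linkS4class{MeteoSeries} covering the
#'   schedule (including the longest feature window before each sample).
#' @param schedule sample metadata from \code{\link{simulateSchedule}}.
#' @param cfg a \code{\link{simConfig}} list.
#' @param seed RNG seed.
#' @param truth optional SimTruth from a previous call: reuse the planted
#'   parameters (e.g. to generate a validation season for the same genomes).
#' @return list(counts, truth, genePositions); \code{truth} holds the planted
#'   parameters, polymorphism flags, controlling markers, cis/trans labels
#'   and the latent expression matrix.
#' @export
simulateExpression <- function(panel, meteo, schedule, cfg,
                               seed = .childSeed(cfg$seed, 4), truth = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hours <- .hourOfDay(schedule$sampling_time)
  sage <- scaledAge(schedule, headingDays(panel))
  # when re-generating under a new season, the planted models keep their
  # original feature definitions (grid) and covariate centres
  grid <- if (!is.null(truth)) truth$grid else envFeatureGrid(meteo)
  Emat <- sapply(seq_len(nrow(grid)), function(i)
    envFeature(meteo, schedule$sampling_time, grid$variable[i],
               grid$window_hours[i], grid$threshold[i]))
  Emat <- matrix(Emat, nrow = nrow(schedule))
  if (is.null(truth)) {
    G <- cfg$nGenes + cfg$nFillerGenes
    geneIds <- c(sprintf("g%04d", seq_len(cfg$nGenes)),
                 if (cfg$nFillerGenes > 0)
                   sprintf("h%04d", seq_len(cfg$nFillerGenes)))
    chroms <- unique(markerMap(panel)$chrom)
    gChrom <- sample(chroms, G, replace = TRUE)
    gPos <- round(runif(G, 1e6, cfg$chromLengthBp))
    nPoly <- round(cfg$nGenes * cfg$fracPolymorphic)
    polyIdx <- sort(sample(cfg$nGenes, nPoly))
    nTrans <- round(nPoly * cfg$fracTransAmongEqtl)
    transIdx <- if (nTrans > 0) sort(sample(polyIdx, nTrans)) else integer(0)
    mm <- markerMap(panel)
    ctrl <- rep(NA_character_, G)
    cistrans <- rep(NA_character_, G)
    for (g in polyIdx) {
      if (g %in% transIdx) {
        cand <- which(mm$chrom != gChrom[g])
        ctrl[g] <- mm$marker[sample(cand, 1)]
        cistrans[g] <- "trans"
      } else {
        cand <- which(mm$chrom == gChrom[g])
        ctrl[g] <- mm$marker[cand[which.min(abs(mm$pos_bp[cand] - gPos[g]))]]
        cistrans[g] <- "cis"
      }
    }
    isFiller <- seq_len(G) > cfg$nGenes
    lo <- function(focal, fill) ifelse(isFiller, fill[1], focal[1])
    hi <- function(focal, fill) ifelse(isFiller, fill[2], focal[2])
    drawParams <- function() {
      mu <- c(runif(cfg$nGenes, cfg$baseMuRange[1], cfg$baseMuRange[2]),
              if (cfg$nFillerGenes > 0)
                runif(cfg$nFillerGenes, cfg$fillerMuRange[1],
                      cfg$fillerMuRange[2]))
      hasClock <- runif(G) < cfg$clockProb
      amp <- runif(G, lo(cfg$clockAmpRange, cfg$fillerClockAmpRange),
                   hi(cfg$clockAmpRange, cfg$fillerClockAmpRange))
      ph <- runif(G, 0, 2 * pi)
      a <- ifelse(hasClock, amp * cos(ph), NA)
      b <- ifelse(hasClock, amp * sin(ph), NA)
      hasAge <- runif(G) < cfg$ageProb
      cc <- ifelse(hasAge,
                   sample(c(-1, 1), G, TRUE) *
                     runif(G, lo(cfg$ageCoefRange, cfg$fillerAgeCoefRange),
                           hi(cfg$ageCoefRange, cfg$fillerAgeCoefRange)), NA)
      hasEnv <- runif(G) < cfg$envProb
      spec <- sample(nrow(grid), G, replace = TRUE)
      sdE <- apply(Emat, 2, sd)[spec]
      snr <- runif(G, lo(cfg$envSnrRange, cfg$fillerEnvSnrRange),
                   hi(cfg$envSnrRange, cfg$fillerEnvSnrRange))
      d <- ifelse(hasEnv & sdE > 1e-8,
                  sample(c(-1, 1), G, TRUE) * snr * max(cfg$noiseSd, 0.25) / sdE,
                  NA)
      data.frame(mu = mu, a = a, b = b, c = cc, d = d,
                 envVariable = ifelse(is.na(d), NA, grid$variable[spec]),
                 envWindow = ifelse(is.na(d), NA, grid$window_hours[spec]),
                 envThreshold = ifelse(is.na(d), NA, grid$threshold[spec]),
                 specIdx = ifelse(is.na(d), NA, spec),
                 stringsAsFactors = FALSE)
    }
    p1 <- drawParams()
    p2 <- p1
    if (nPoly > 0) {
      dmu <- sample(c(-1, 1), nPoly, TRUE) *
        runif(nPoly, cfg$effectMuRange[1], cfg$effectMuRange[2]) *
        max(cfg$noiseSd, 0.25)
      p2$mu[polyIdx] <- p1$mu[polyIdx] + dmu
      reClock <- polyIdx[runif(nPoly) < 0.5]
      if (length(reClock)) {
        amp <- runif(length(reClock), cfg$clockAmpRange[1], cfg$clockAmpRange[2])
        ph <- runif(length(reClock), 0, 2 * pi)
        p2$a[reClock] <- amp * cos(ph)
        p2$b[reClock] <- amp * sin(ph)
      }
    }
    truth <- list(
      genes = data.frame(gene_id = geneIds, chrom = gChrom, pos_bp = gPos,
                         polymorphic = seq_len(G) %in% polyIdx,
                         filler = seq_len(G) > cfg$nGenes,
                         controlling_marker = ctrl, cis_trans = cistrans,
                         stringsAsFactors = FALSE),
      params = list(P1 = p1, P2 = p2),
      centers = list(sage = mean(sage), E = colMeans(Emat)),
      grid = grid,
      noiseSd = cfg$noiseSd)
  }
  G <- nrow(truth$genes)
  geneIds <- truth$genes$gene_id
  n <- nrow(schedule)
  al <- alleles(panel)
  bg <- background(panel)
  lineOf <- schedule$line_id
  latent <- matrix(0, G, n, dimnames = list(geneIds, schedule$sample_id))
  for (g in seq_len(G)) {
    if (truth$genes$polymorphic[g]) {
      parent <- al[lineOf, truth$genes$controlling_marker[g]]
    } else {
      parent <- bg[lineOf]
    }
    for (pp in c("P1", "P2")) {
      idx <- which(parent == pp)
      if (!length(idx)) next
      par <- truth$params[[pp]][g, ]
      E <- if (!is.na(par$specIdx)) Emat[idx, par$specIdx] else 0
      latent[g, idx] <- .evalPlanted(par, hours[idx], sage[idx], E,
                                     truth$centers)
    }
  }
  noisy <- latent + matrix(rnorm(G * n, 0, cfg$noiseSd), G, n)
  lib <- runif(n, cfg$librarySizeRange[1], cfg$librarySizeRange[2])
  mean_counts <- sweep(pmax(2^noisy - 1, 0), 2, lib / 1e6, "*")
  counts <- if (cfg$countModel == "nbinom") {
    matrix(stats::rnbinom(G * n, mu = mean_counts, size = 1 / cfg$nbDispersion),
           G, n)
  } else {
    round(mean_counts)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- dimnames(latent)
  truth$latent <- latent
  truth$librarySizes <- setNames(lib, schedule$sample_id)
  list(counts = counts, truth = truth,
       genePositions = truth$genes[, c("gene_id", "chrom", "pos_bp")])
}

#' Simulate a complete input bundle
#'
#' Runs \code{\link{simulateGenotypes}}, \code{\link{simulateMeteo}},
#' \code{\link{simulateSchedule}} and \code{\link{simulateExpression}} with
#' seeds derived from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{simConfig}} list.
#' @param truth optional SimTruth to reuse (validation-season generation).
#' @param ... passed to \code{\link{simulateMeteo}} (e.g. a different
#'   \code{tempBase} or \code{seed} for a different season).
#' @return list(panel, meteo, schedule, counts, genePositions, truth).
#' @export
simulateDataset <- function(cfg, truth = NULL, ...) {
  gen <- simulateGenotypes(cfg)
  meteo <- simulateMeteo(cfg, ...)
  schedule <- simulateSchedule(cfg, gen$panel)
  expr <- simulateExpression(gen$panel, meteo, schedule, cfg, truth = truth)
  expr$truth$segments <- gen$truth$segments
  list(panel = gen$panel, meteo = meteo, schedule = schedule,
       counts = expr$counts, genePositions = expr$genePositions,
       truth = expr$truth)
}
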