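# A hand-built 4-line panel used by several tests below.
toyPanel <- function() {
  al <- rbind(P1 = c("P1", "P1", "P1"),
              P2 = c("P2", "P2", "P2"),
              LA = c("P2", "P1", "P1"),   # P1 background, donor at M1
              LB = c("P1", "P2", "P2"))   # P2 background, donor at M1
  colnames(al) <- c("M1", "M2", "M3")
  GenotypePanel(al, data.frame(marker = c("M1", "M2", "M3"),
                               chrom = "chr01", pos_bp = c(1e6, 2e6, 3e6)))
}

test_that("marker assignments follow alleles, background markers change nothing", {
  panel <- toyPanel()
  a1 <- assignmentFromMarker(panel, "M1")
  expect_identical(unname(a1), c("P1", "P2", "P2", "P1"))
  a3 <- assignmentFromMarker(panel, "M3")
  # M3 equals every line's background: assignment == background assignment
  expect_identical(unname(a3), unname(background(panel)))
  expect_error(assignmentFromMarker(panel, "M99"), "unknown marker")
})

test_that("scan statistics equal the brute-force weighted residual sums", {
  sim <- smallSim()
  fe <- smallFe()
  mods <- smallModels()
  genes <- rownames(fe)[1:5]
  scan <- scanGenes(fe, sim$panel, mods$P1, mods$P2, sim$meteo, genes = genes)
  # brute force for one gene and three markers
  cd <- SummarizedExperiment::colData(fe)
  keep <- lineType(sim$panel)[as.character(cd$line_id)] != "bil"
  sf <- data.frame(sample_id = rownames(cd)[keep],
                   sampling_time = cd$sampling_time[keep],
                   scaled_age = cd$scaled_age[keep],
                   line_id = as.character(cd$line_id)[keep])
  y <- log2rpm(fe)[genes[1], keep]
  w <- geneWeights(fe)[genes[1]]
  sub <- function(ms) new("GeneModelSet", parent = ms@parent,
                          models = ms@models[genes[1]], grid = ms@grid,
                          sampleIds = ms@sampleIds)
  p1 <- predictExpression(sub(mods$P1), sim$meteo, sf)[1, ]
  p2 <- predictExpression(sub(mods$P2), sim$meteo, sf)[1, ]
  for (mk in markerIds(sim$panel)[c(1, 10, 25)]) {
    assign <- assignmentFromMarker(sim$panel, mk)[sf$line_id]
    rss <- 0
    for (i in seq_along(y))
      rss <- rss + w * (y[i] - if (assign[i] == "P1") p1[i] else p2[i])^2
    expect_equal(unname(scan@rssMarker[genes[1], mk]), unname(rss),
                 tolerance = 1e-10)
  }
  # background-identical assignment -> T exactly 0
  bgAssign <- background(sim$panel)[sf$line_id]
  for (mk in markerIds(sim$panel)) {
    if (identical(unname(assignmentFromMarker(sim$panel, mk)[sf$line_id]),
                  unname(bgAssign)))
      expect_identical(unname(scan@statistic[genes[1], mk]), 0)
  }
  # the background assignment is an explicit candidate: statistics are
  # reductions relative to it, and the candidate-set minimum (markers plus
  # background) never exceeds RSS_BG
  expect_equal(scan@statistic, scan@rssBg - scan@rssMarker, tolerance = 1e-12)
  candMin <- pmin(apply(scan@rssMarker, 1, min), scan@rssBg)
  expect_true(all(candMin <= scan@rssBg))
})

test_that("scan results are invariant to sample order", {
  sim <- smallSim()
  fe <- smallFe()
  mods <- smallModels()
  genes <- rownames(fe)[1:3]
  s1 <- scanGenes(fe, sim$panel, mods$P1, mods$P2, sim$meteo, genes = genes)
  perm <- sample(ncol(fe))
  s2 <- scanGenes(fe[, perm], sim$panel, mods$P1, mods$P2, sim$meteo,
                  genes = genes)
  expect_equal(s1@statistic, s2@statistic, tolerance = 1e-10)
})

test_that("permutation p-values respect their formula bounds and degeneracies", {
  sim <- smallSim()
  fe <- smallFe()
  mods <- smallModels()
  tg <- sim$truth$genes
  genes <- intersect(tg$gene_id[tg$polymorphic], rownames(fe))
  scan <- scanGenes(fe, sim$panel, mods$P1, mods$P2, sim$meteo, genes = genes)
  pv <- permutationPvalues(scan, sim$panel, nPerm = 100, seed = 4)
  expect_true(all(pv$pMarker >= 1 / 101 - 1e-12))
  expect_true(all(pv$pMarker <= 1))
  expect_true(all(pv$pGene >= 1 / 101 - 1e-12))
  expect_error(permutationPvalues(scan, sim$panel, nPerm = 10), "at least 100")
  # markers identical to the background assignment have constant nulls: p = 1
  cd <- SummarizedExperiment::colData(fe)
  keep <- lineType(sim$panel)[as.character(cd$line_id)] != "bil"
  lines <- unique(as.character(cd$line_id)[keep])
  bgAssign <- background(sim$panel)[lines]
  for (mk in markerIds(sim$panel)) {
    if (identical(unname(alleles(sim$panel)[lines, mk]), unname(bgAssign)))
      expect_equal(unname(pv$pMarker[, mk]), rep(1, length(genes)))
  }
})

test_that("scan permutation p-values are roughly uniform under the null", {
  cfg0 <- smallCfg(fracPolymorphic = 0, nGenes = 100, nFillerGenes = 100,
                   seed = 77)
  sim0 <- simulateDataset(cfg0)
  fe0 <- FieldExpression(sim0$counts, sim0$schedule)
  fe0 <- preprocessExpression(fe0, headingDays(sim0$panel))
  m1 <- fitGeneModels(fe0, sim0$panel, "P1", sim0$meteo)
  m2 <- fitGeneModels(fe0, sim0$panel, "P2", sim0$meteo)
  focal <- intersect(sprintf("g%04d", 1:100), rownames(fe0))
  scan0 <- scanGenes(fe0, sim0$panel, m1, m2, sim0$meteo, genes = focal)
  pv0 <- permutationPvalues(scan0, sim0$panel, nPerm = 200, seed = 5)
  # Kolmogorov distance of the gene-level p-values from uniform
  pg <- sort(pv0$pGene)
  ks <- max(abs(pg - seq_along(pg) / length(pg)))
  expect_lt(ks, 0.163)   # 1% critical value at n = 100
  expect_identical(nrow(callEqtls(scan0, pv0, sim0$panel)), 0L)
})

test_that("BH adjustment matches the hand formula", {
  expect_equal(p.adjust(c(0.001, 0.002, 0.5), "BH"), c(0.003, 0.003, 0.5))
  set.seed(12)
  p <- runif(200)^2
  expect_equal(p.adjust(p, "BH"), bhOracle(p), tolerance = 1e-12)
})

test_that("calls group contiguous identical-signature markers into single blocks", {
  run <- accRun()
  sim <- accSim()
  calls <- run$calls
  expect_gt(nrow(calls), 0)
  al <- alleles(sim$panel)[run$scan@lines, ]
  mm <- markerMap(sim$panel)
  for (r in seq_len(nrow(calls))) {
    blk <- strsplit(calls$marker_block[r], ",")[[1]]
    idx <- match(blk, mm$marker)
    expect_true(all(diff(idx) == 1))                        # contiguous
    expect_identical(length(unique(mm$chrom[idx])), 1L)     # one chromosome
    for (j in idx[-1])
      expect_identical(unname(al[, j]), unname(al[, idx[1]]))  # same signature
    expect_true(calls$representative_marker[r] %in% blk)
    expect_identical(calls$n_markers_in_block[r], length(blk))
  }
  # q >= p for every call
  expect_true(all(calls$q >= calls$p - 1e-12))
})

test_that("cis/trans classification follows the 2 Mb same-chromosome rule", {
  calls <- data.frame(gene = c("gA", "gB", "gC", "gD"),
                      chrom = c("chr09", "chr02", "chr09", "chr01"),
                      rep_pos = c(10.4e6, 5e6, 5.0e6, 1e6),
                      stringsAsFactors = FALSE)
  gp <- data.frame(gene_id = c("gA", "gB", "gC"),
                   chrom = c("chr09", "chr05", "chr09"),
                   pos_bp = c(10.6e6, 5e6, 10.0e6))
  lab <- classifyCisTrans(calls, gp)
  expect_identical(lab, c("cis", "trans", "trans", "unknown"))
  expect_identical(classifyCisTrans(calls[0, ], gp), character(0))
  expect_identical(classifyCisTrans(calls, NULL), rep("unknown", 4))
})

test_that("planted eQTLs are localised to the controlling marker's block", {
  run <- accRun()
  sim <- accSim()
  tg <- sim$truth$genes
  planted <- tg[tg$polymorphic, ]
  hit <- vapply(seq_len(nrow(planted)), function(i)
    recoveredMarker(run$calls, sim$panel, planted$gene_id[i],
                    planted$controlling_marker[i]), logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("forward selection adds a second block only when it lowers the error", {
  # hand-built scan: 4 lines, gene errors designed so that an OR-combination
  # of two markers is strictly better than either alone
  al <- rbind(P1 = c("P1", "P1"), P2 = c("P2", "P2"),
              LA = c("P2", "P1"), LB = c("P1", "P2"))
  colnames(al) <- c("M1", "M2")
  panel <- GenotypePanel(al, data.frame(marker = c("M1", "M2"),
                                        chrom = c("chr01", "chr02"),
                                        pos_bp = c(1e6, 1e6)))
  panel@background <- setNames(c("P1", "P2", "P1", "P1"), rownames(al))
  panel@lineType <- setNames(c("parent", "parent", "cssl", "cssl"),
                             rownames(al))
  # errors: LA and LB both truly expressed like P2 (donor) although their
  # background is P1; LA carries donor at M1, LB at M2
  e1 <- matrix(c(0, 5, 5, 5), nrow = 1,
               dimnames = list("g", c("P1", "P2", "LA", "LB")))
  e2 <- matrix(c(5, 0, 0, 0), nrow = 1,
               dimnames = list("g", c("P1", "P2", "LA", "LB")))
  scan <- new("EqtlScan", geneIds = "g", markerIds = c("M1", "M2"),
              statistic = matrix(c(10, 10), 1,
                                 dimnames = list("g", c("M1", "M2"))),
              rssMarker = matrix(0, 1, 2), rssBg = c(g = 20),
              lineErrors = list(P1 = e1, P2 = e2),
              lines = rownames(al),
              background = panel@background)
  sel <- multiEqtlSelection(scan, panel, "g", c("M1", "M2"), c(10, 9))
  expect_setequal(sel$selected, c("M1", "M2"))
  # combined OR assignment predicts P2 for LA and LB: total error 0+0+0+0
  expect_equal(sel$combinedRss, 0)
  # a second block that changes nothing is rejected
  sel1 <- multiEqtlSelection(scan, panel, "g", c("M1", "M1"), c(10, 9))
  expect_identical(sel1$selected, "M1")
  # single-block call: set of one, RSS of that assignment
  selOne <- multiEqtlSelection(scan, panel, "g", "M1", 10)
  expect_identical(selOne$selected, "M1")
  a <- dyneQTL:::.combinedAssignment(panel, rownames(al), "M1")
  expect_equal(selOne$combinedRss,
               dyneQTL:::.assignmentRss(scan, "g", a))
})
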