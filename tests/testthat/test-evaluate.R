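# Minimal hand-built scenario: intercept-only parental models, a panel with
# one BIL, and observed expression for the BIL's samples.
tinyEvalScenario <- function(bilAlleles = c("P1", "P2", "P2"),
                             obsShift = 0) {
  al <- rbind(P1 = c("P1", "P1", "P1"),
              P2 = c("P2", "P2", "P2"),
              BIL = bilAlleles)
  colnames(al) <- c("M1", "M2", "M3")
  panel <- GenotypePanel(al, data.frame(marker = c("M1", "M2", "M3"),
                                        chrom = "chr01",
                                        pos_bp = c(1e6, 2e6, 3e6)),
                         headingDays = data.frame(
                           line_id = rep(c("P1", "P2", "BIL"), 2),
                           transplant_set = rep(1:2, each = 3),
                           heading_days = 100))
  panel@background <- setNames(c("P1", "P2", "P2"), rownames(al))
  panel@lineType <- setNames(c("parent", "parent", "bil"), rownames(al))
  mkModel <- function(g, mu) list(gene_id = g, terms = character(0),
                                  coef = c(mu = unname(mu)), env = NULL,
                                  rssw = 0, n = 10, k = 1, aic = 0, weight = 1)
  genes <- c("gX", "gY", "gZ")
  muP1 <- c(gX = 2, gY = 5, gZ = 8)
  muP2 <- c(gX = 4, gY = 3, gZ = 6)
  msetP1 <- new("GeneModelSet", parent = "P1",
                models = setNames(lapply(genes, function(g)
                  mkModel(g, muP1[g])), genes),
                grid = data.frame(), sampleIds = "s0")
  msetP2 <- new("GeneModelSet", parent = "P2",
                models = setNames(lapply(genes, function(g)
                  mkModel(g, muP2[g])), genes),
                grid = data.frame(), sampleIds = "s0")
  calls <- data.frame(gene = genes,
                      representative_marker = c("M1", "M2", "M3"),
                      selected = TRUE, stringsAsFactors = FALSE)
  t0 <- as.POSIXct("2015-07-01 00:00:00", tz = "UTC")
  meta <- data.frame(sample_id = c("b1", "b2"), line_id = "BIL",
                     transplant_set = 1L, sowing_date = t0 - 50 * 86400,
                     sampling_time = c(t0, t0 + 7200))
  # observed = model implied by the BIL's true alleles, plus a shift
  obs <- rbind(gX = rep(muP1["gX"], 2), gY = rep(muP2["gY"], 2),
               gZ = rep(muP2["gZ"], 2)) + obsShift
  for (g in genes) {
    a <- al["BIL", calls$representative_marker[calls$gene == g]]
    obs[g, ] <- (if (a == "P1") muP1[g] else muP2[g]) + obsShift
  }
  colnames(obs) <- meta$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2rpm = obs),
    colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id))
  fe <- new("FieldExpression", se)
  SummarizedExperiment::rowData(fe)$weight <- rep(1, 3)
  SummarizedExperiment::colData(fe)$scaled_age <- c(0.5, 0.5)
  tgrid <- seq(t0 - 4 * 86400, t0 + 86400, by = 60)
  met <- MeteoSeries(tgrid, rep(25, length(tgrid)), rep(0, length(tgrid)))
  list(panel = panel, msetP1 = msetP1, msetP2 = msetP2, calls = calls,
       fe = fe, meteo = met, meta = meta, genes = genes)
}

test_that("new-environment predictions switch models by eQTL but not by background", {
  sc <- tinyEvalScenario()
  pred <- predictNewEnvironment(sc$msetP1, sc$msetP2, sc$calls, sc$panel,
                                sc$meteo, sc$meta)
  # BIL background is P2 -> BG prediction uses P2 model everywhere
  expect_equal(unname(pred$predBg[, 1]), c(4, 3, 6))
  # eQTL assignment: gX follows M1 (P1 allele) -> P1 model; gY, gZ stay P2
  expect_equal(unname(pred$predEqtl[, 1]), c(2, 3, 6))
  # a line with no substituted alleles gets identical predictions
  metaP2 <- sc$meta; metaP2$line_id <- "P2"; metaP2$sample_id <- c("p1", "p2")
  predP2 <- predictNewEnvironment(sc$msetP1, sc$msetP2, sc$calls, sc$panel,
                                  sc$meteo, metaP2)
  expect_identical(predP2$predEqtl, predP2$predBg)
  # a gene without a call falls back to the background assignment
  expect_warning(
    predNC <- predictNewEnvironment(sc$msetP1, sc$msetP2,
                                    sc$calls[sc$calls$gene != "gX", ],
                                    sc$panel, sc$meteo, sc$meta,
                                    genes = sc$genes),
    "without an eQTL call")
  expect_equal(predNC$predEqtl["gX", ], predNC$predBg["gX", ])
  expect_error(predictNewEnvironment(sc$msetP1, sc$msetP2, sc$calls,
                                     sc$panel, sc$meteo,
                                     transform(sc$meta, line_id = "NOPE")),
               "absent from panel")
})

test_that("improvement accounting is strict, excludes ties, and is antisymmetric", {
  sc <- tinyEvalScenario()
  pred <- predictNewEnvironment(sc$msetP1, sc$msetP2, sc$calls, sc$panel,
                                sc$meteo, sc$meta)
  obs <- log2rpm(sc$fe)
  w <- geneWeights(sc$fe)
  imp <- improvementFraction(pred$predEqtl, pred$predBg, obs, w)
  # only gX differs between assignments; it is predicted exactly
  expect_identical(imp$nEligible, 1L)
  expect_identical(imp$perGene$eligible, c(TRUE, FALSE, FALSE))
  expect_equal(imp$fraction, 1)
  # hand arithmetic on a 3-sample case
  pe <- matrix(c(1, 1, 1), 1, dimnames = list("g", NULL))
  pb <- matrix(c(2, 2, 2), 1, dimnames = list("g", NULL))
  ob <- matrix(c(1.2, 0.9, 1.1), 1, dimnames = list("g", NULL))
  impH <- improvementFraction(pe, pb, ob, c(g = 2))
  expect_equal(impH$perGene$error_eqtl, 2 * (0.2^2 + 0.1^2 + 0.1^2))
  expect_equal(impH$perGene$error_bg, 2 * (0.8^2 + 1.1^2 + 0.9^2))
  expect_true(impH$perGene$improved)
  # antisymmetry: swapping prediction sets flips the fraction
  impSwap <- improvementFraction(pb, pe, ob, c(g = 2))
  expect_equal(impSwap$fraction, 1 - impH$fraction)
  # identical assignments for every gene -> error
  expect_error(improvementFraction(pb, pb, ob, c(g = 2)), "nothing to compare")
})

test_that("BIL permutation test matches exhaustive enumeration on 3 markers", {
  sc <- tinyEvalScenario()
  bt <- bilPermutationTest(sc$genes, sc$msetP1, sc$msetP2, sc$calls,
                           sc$panel, "BIL", sc$fe, sc$meteo,
                           exhaustive = TRUE)
  # independent enumeration over all 3! = 6 index permutations
  al <- alleles(sc$panel)["BIL", ]
  muP1 <- c(gX = 2, gY = 5, gZ = 8); muP2 <- c(gX = 4, gY = 3, gZ = 6)
  obs <- log2rpm(sc$fe)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  totals <- apply(perms, 1, function(ix) {
    av <- al[ix]
    s <- 0
    for (gi in 1:3) {
      g <- sc$genes[gi]
      mu <- if (av[gi] == "P1") muP1[g] else muP2[g]
      s <- s + sum((obs[g, ] - mu)^2)
    }
    s
  })
  expect_equal(sort(bt$null), sort(unname(totals)), tolerance = 1e-12)
  expect_equal(bt$observed, totals[1], tolerance = 1e-12)
  expect_equal(bt$p, mean(totals <= totals[1] + 1e-12))
  # sampling-based p is close to the exhaustive one
  btMC <- bilPermutationTest(sc$genes, sc$msetP1, sc$msetP2, sc$calls,
                             sc$panel, "BIL", sc$fe, sc$meteo,
                             nPerm = 2000, seed = 2)
  expect_lt(abs(btMC$p - bt$p), 0.05)
  # two seeds agree within Monte-Carlo error at nPerm = 2000
  btMC2 <- bilPermutationTest(sc$genes, sc$msetP1, sc$msetP2, sc$calls,
                              sc$panel, "BIL", sc$fe, sc$meteo,
                              nPerm = 2000, seed = 3)
  mcSd <- sqrt(bt$p * (1 - bt$p) / 2000)
  expect_lt(abs(btMC$p - btMC2$p), 4 * mcSd + 1e-12)
  # reference totals are the all-P1 / all-P2 errors
  refP1 <- sum(vapply(sc$genes, function(g) sum((obs[g, ] - muP1[g])^2),
                      numeric(1)))
  expect_equal(bt$refP1, refP1, tolerance = 1e-12)
})

test_that("a BIL with a uniform allele vector degenerates to p = 1", {
  sc <- tinyEvalScenario(bilAlleles = c("P2", "P2", "P2"))
  expect_warning(
    bt <- bilPermutationTest(sc$genes, sc$msetP1, sc$msetP2, sc$calls,
                             sc$panel, "BIL", sc$fe, sc$meteo, nPerm = 200),
    "identical")
  expect_identical(bt$p, 1)
})

test_that("enrichment tests match a hypergeometric tail-sum oracle", {
  universe <- sprintf("g%03d", 1:100)
  geneSet <- universe[1:10]
  ann <- rbind(
    data.frame(gene_id = universe[c(1:8, 11:12)], term = "T_enriched"),
    data.frame(gene_id = universe, term = "T_all"),
    data.frame(gene_id = universe[51:60], term = "T_null"))
  res <- enrichmentTest(geneSet, universe, ann)
  # (8, 2, 2, 88) table for T_enriched
  row <- res[res$term == "T_enriched", ]
  expect_equal(row$p, fisherOracle(8, 2, 2, 88), tolerance = 1e-10)
  # spec example table (8, 2, 10, 80)
  ft <- fisher.test(matrix(c(8, 2, 10, 80), 2))
  expect_equal(ft$p.value, fisherOracle(8, 2, 10, 80), tolerance = 1e-10)
  # a term annotating every gene is neutral
  rowAll <- res[res$term == "T_all", ]
  expect_identical(rowAll$odds_ratio, 1)
  expect_identical(rowAll$p, 1)
  # BH across terms, significance flags
  expect_equal(res$p_adj, bhOracle(res$p), tolerance = 1e-12)
  expect_true(row$significant)
  expect_false(res$significant[res$term == "T_null"])
  # random 2x2 tables against the oracle
  set.seed(6)
  for (i in 1:20) {
    a <- rpois(1, 5); b <- rpois(1, 5); cc <- rpois(1, 8); dd <- rpois(1, 40)
    ft <- fisher.test(matrix(c(a, b, cc, dd), 2))
    expect_equal(ft$p.value, fisherOracle(a, b, cc, dd), tolerance = 1e-10)
  }
  expect_error(enrichmentTest(character(0), universe, ann), "non-empty")
  expect_error(enrichmentTest("zzz", universe, ann), "subset")
})
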