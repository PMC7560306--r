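# Trait extraction, calibration, summaries, merging and the comparison
# report.

pathPoly <- matrix(c(1L, 1L, 1L, 2L), 2, 2, byrow = TRUE)

lineGraph <- function(rows, cols, lens) {
  n <- length(rows)
  nodes <- data.frame(id = seq_len(n), row = rows, col = cols,
                      kind = c("terminal", rep("branching", max(0, n - 2)),
                               "terminal"),
                      stringsAsFactors = FALSE)
  edges <- lapply(seq_len(n - 1), function(i)
    list(a = i, b = i + 1, lengthPx = lens[i], polyline = pathPoly))
  new("PlantGraph", nodes = nodes, edges = edges, sourceRegionId = 1L)
}

test_that("anchor nodes are the bottom-most and top-most, ties to smaller column", {
  g <- lineGraph(c(900, 500, 100), c(10, 12, 14), c(400, 400))
  a <- anchorNodes(g)
  expect_equal(graphNodes(g)$row[a$lowest], 900)
  expect_equal(graphNodes(g)$row[a$highest], 100)
  # tie on the lowest row: smaller column wins
  nodes <- data.frame(id = 1:3, row = c(50, 50, 10), col = c(60, 40, 50),
                      kind = c("terminal", "terminal", "terminal"),
                      stringsAsFactors = FALSE)
  edges <- list(list(a = 1, b = 3, lengthPx = 40, polyline = pathPoly),
                list(a = 2, b = 3, lengthPx = 40, polyline = pathPoly))
  g2 <- new("PlantGraph", nodes = nodes, edges = edges, sourceRegionId = 1L)
  expect_equal(anchorNodes(g2)$lowest, 2)
})

test_that("pixel-to-mm conversion is linear and guards against negatives", {
  bar <- scaleBar(200, 20)
  expect_equal(pxToMM(400, bar), 40)
  expect_equal(pxToMM(0, bar), 0)
  a <- 123.4; b <- 77.1
  expect_equal(pxToMM(a + b, bar), pxToMM(a, bar) + pxToMM(b, bar))
  expect_error(pxToMM(-1, bar), "negative")
})

test_that("a branchless vertical plant reports total = internode and no leaves", {
  g <- lineGraph(c(500, 100), c(50, 50), 400)
  bar <- scaleBar(200, 20)
  expect_warning(rec <- measureSeedling(g, bar), "branchless")
  expect_equal(rec$totalShootMM, 40)
  expect_equal(rec$internodeMM, 40)
  expect_length(rec$leafMM, 0)
})

test_that("a constructed two-leaf graph measures shoot, internode and ordered leaves", {
  # base(1) -- junction(2) with hanging leaf(3) and terminal blade(4)
  nodes <- data.frame(id = 1:4,
                      row = c(600, 300, 160, 80),
                      col = c(100, 100, 180, 100),
                      kind = c("terminal", "branching", "terminal", "terminal"),
                      stringsAsFactors = FALSE)
  edges <- list(list(a = 1, b = 2, lengthPx = 300, polyline = pathPoly),
                list(a = 2, b = 3, lengthPx = 170, polyline = pathPoly),
                list(a = 2, b = 4, lengthPx = 230, polyline = pathPoly))
  g <- new("PlantGraph", nodes = nodes, edges = edges, sourceRegionId = 1L)
  rec <- measureSeedling(g, scaleBar(200, 20))
  expect_equal(rec$totalShootMM, (300 + 230) / 10)
  expect_equal(rec$internodeMM, 30)
  # two leaves, longest first at the shared junction
  expect_equal(rec$leafMM, c(23, 17))
  expect_gte(rec$totalShootMM, rec$internodeMM)
})

test_that("generated seedlings recover ground truth within the stated envelope", {
  out <- cachedScene("seedling2", function()
    randomSeedlingScene(1, 2, sceneSpec(seed = 5)))
  cfg <- analysisConfig(cornerWindowFrac = out$cornerWindowFrac)
  res <- suppressWarnings(analyzeImage(out$image, cfg))
  tr <- out$truth@plants[[1]]
  rec <- res$records[[1]]
  mmpp <- out$truth@barLengthMM / out$truth@barWidthPx
  expect_length(rec$leafMM, tr$leafCount)
  expect_lt(abs(rec$totalShootPx - tr$shootPx), 0.02 * tr$shootPx)
  expect_lt(abs(rec$internodePx - tr$internodePx),
            max(0.02 * tr$internodePx, 3))
  for (i in seq_len(tr$leafCount))
    expect_lt(abs(rec$leafMM[i] - tr$leafMM[i]), 0.3)
})

test_that("coleoptiles measure as the farthest geodesic without pruning", {
  # straight 250 px coleoptile
  g <- lineGraph(c(400, 150), c(80, 80), 250)
  expect_equal(measureColeoptile(g, scaleBar(200, 20))$coleoptileMM, 25)
  # a short fork near the tip: the longer branch defines the length
  nodes <- data.frame(id = 1:4,
                      row = c(400, 160, 150, 152),
                      col = c(80, 80, 80, 86),
                      kind = c("terminal", "branching", "terminal", "terminal"),
                      stringsAsFactors = FALSE)
  edges <- list(list(a = 1, b = 2, lengthPx = 240, polyline = pathPoly),
                list(a = 2, b = 3, lengthPx = 10, polyline = pathPoly),
                list(a = 2, b = 4, lengthPx = 7, polyline = pathPoly))
  g2 <- new("PlantGraph", nodes = nodes, edges = edges, sourceRegionId = 1L)
  expect_equal(measureColeoptile(g2, scaleBar(200, 20))$coleoptileMM, 25)
})

test_that("generated coleoptile scenes recover arc length within 2%", {
  out <- randomColeoptileScene(1, sceneSpec(seed = 4))
  cfg <- analysisConfig("coleoptile", cornerWindowFrac = out$cornerWindowFrac)
  res <- analyzeImage(out$image, cfg)
  tr <- out$truth@plants[[1]]
  expect_lt(abs(res$records[[1]]$coleoptilePx - tr$coleoptilePx),
            max(0.02 * tr$coleoptilePx, 3))
})

test_that("summaries use the sample sd and se = sd/sqrt(n)", {
  s <- summarizeValues(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$se, 1 / sqrt(3))
  s2 <- summarizeValues(c(5, 5, 5, 5))
  expect_equal(s2$sd, 0); expect_equal(s2$se, 0)
  expect_error(summarizeValues(7), "insufficient-sample")
  # se * sqrt(n) = sd, always
  set.seed(8)
  for (i in 1:5) {
    v <- rnorm(sample(2:30, 1))
    s3 <- summarizeValues(v)
    expect_equal(s3$se * sqrt(s3$n), s3$sd)
    expect_lte(s3$se, s3$sd)
  }
})

mockRecord <- function(id, shoot, group = NULL) {
  rec <- list(regionId = id, totalShootMM = shoot, internodeMM = shoot / 2,
              leafMM = numeric(0), coleoptileMM = NA_real_,
              areaPx = 100L, group = if (is.null(group)) NA_character_ else group,
              leafPolylines = list())
  class(rec) <- "traitRecord"
  rec
}

test_that("grouped summaries split by label and default to 'ungrouped'", {
  recs <- lapply(1:7, function(i) mockRecord(i, 10 + i))
  labels <- setNames(c("a", "a", "a", "b", "b", "b", "b"), 1:7)
  sm <- groupAndSummarize(recs, labels)
  shootA <- sm[sm$group == "a" & sm$parameter == "total_shoot_mm", ]
  shootB <- sm[sm$group == "b" & sm$parameter == "total_shoot_mm", ]
  expect_equal(shootA$n, 3); expect_equal(shootB$n, 4)
  expect_equal(shootA$mean, mean(11:13))
  # single group over everything equals plain summarize
  smAll <- groupAndSummarize(recs, setNames(rep("g", 7), 1:7))
  ref <- summarizeValues(10 + 1:7)
  expect_equal(smAll[smAll$parameter == "total_shoot_mm", "mean"], ref$mean)
  expect_equal(smAll[smAll$parameter == "total_shoot_mm", "sd"], ref$sd)
  # unlabeled records are "ungrouped"
  smU <- groupAndSummarize(recs, NULL)
  expect_true(all(smU$group == "ungrouped"))
  expect_error(groupAndSummarize(recs, setNames("x", 99)), "unknown-region")
})

test_that("merging regions unions pixels and bridges disconnected parts", {
  mk <- function(id, r0, c0, h, w) {
    px <- as.matrix(expand.grid(row = r0:(r0 + h - 1), col = c0:(c0 + w - 1)))
    new("PlantRegion", id = id,
        pixels = matrix(as.integer(px), ncol = 2,
                        dimnames = list(NULL, c("row", "col"))),
        contour = matrix(integer(0), 0, 2), areaPx = nrow(px),
        bbox = as.integer(c(r0, c0, r0 + h - 1, c0 + w - 1)))
  }
  r1 <- mk(1L, 10, 10, 20, 30)   # 600 px
  r2 <- mk(2L, 60, 50, 20, 35)   # 700 px
  m <- mergeRegions(list(r1, r2), c(1, 2))
  expect_equal(m@id, 1L)
  expect_gte(m@areaPx, 1300)               # union plus bridge pixels
  expect_lte(m@areaPx, 1300 + 60)
  sub <- matrix(0L, m@bbox[3], m@bbox[4])
  sub[m@pixels] <- 1L
  expect_equal(max(labelMask8(sub)), 1)    # merged region is connected
  expect_error(mergeRegions(list(r1, r2), 1), "at least 2")
  expect_error(mergeRegions(list(r1, r2), c(1, 9)), "unknown id")
})

test_that("re-attaching a cut-off stem fragment restores shoot length", {
  out <- cachedScene("seedling2", function()
    randomSeedlingScene(1, 2, sceneSpec(seed = 5)))
  cfg <- analysisConfig(cornerWindowFrac = out$cornerWindowFrac)
  mask <- segmentColor(preprocessImage(out$image, cfg), cfg)
  # sever the stem ~35 px above the base to create two regions
  tr <- out$truth@plants[[1]]
  cutRow <- tr$base[1] - 35
  mask[(cutRow - 2):(cutRow + 2), ] <- 0L
  cfgCut <- analysisConfig(minDetectionAreaPx = 50,
                           cornerWindowFrac = out$cornerWindowFrac)
  regs <- extractRegions(mask, cfgCut)
  expect_gte(length(regs), 2)
  bar <- detectScaleBar(out$image, cfg)
  measure <- function(reg) {
    suppressWarnings(measureSeedling(
      pruneGraph(buildPlantGraph(skeletonize(reg)), cfgCut), bar,
      regionId = reg@id))
  }
  mainReg <- regs[[which.max(vapply(regs, function(r) r@areaPx, 0L))]]
  unmerged <- measure(mainReg)$totalShootMM
  merged <- measure(mergeRegions(regs, vapply(regs, function(r) r@id, 0L)))
  expect_gt(merged$totalShootMM, unmerged)
})

test_that("the comparison report reproduces the pooled t closed form", {
  a <- c(1, 2, 3); b <- c(1, 2, 4)
  rep_ <- compareMeasurements(a, b)
  # hand-computed pooled-variance t: sp2 = (2*1 + 2*7/3)/4 = 5/3
  tHand <- (2 - 7 / 3) / sqrt((5 / 3) * (2 / 3))
  expect_equal(rep_$tStat, tHand)
  expect_equal(rep_$tStat, -1 / sqrt(10))
  expect_equal(rep_$n, 3)
  expect_true(all(c(rep_$shapiroPA, rep_$shapiroPB, rep_$fTestP,
                    rep_$tTestP) >= 0))
  expect_true(all(c(rep_$fTestP, rep_$tTestP) <= 1))
})

test_that("identical lists give t p-value 1; a large shift gives p < 0.001", {
  x <- c(10.2, 11.5, 9.8, 10.9, 10.4)
  same <- compareMeasurements(x, x)
  expect_equal(same$meanA, same$meanB)
  expect_equal(same$tTestP, 1)
  far <- compareMeasurements(x, x + 100)
  expect_lt(far$tTestP, 0.001)
  expect_error(compareMeasurements(c(1, 2), c(3, 4)), "insufficient-sample")
  expect_error(compareMeasurements(1:4, 1:5), "insufficient-sample")
})
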