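# Graph construction, simplification, pruning and geodesics.

skeletonFromPixels <- function(px) {
  new("Skeleton", pixels = matrix(as.integer(px), ncol = 2L,
                                  dimnames = list(NULL, c("row", "col"))),
      sourceRegionId = 1L)
}

test_that("a straight line becomes two terminals joined by one edge", {
  px <- cbind(50, 11:110)
  g <- buildPlantGraph(skeletonFromPixels(px))
  expect_equal(nrow(graphNodes(g)), 2)
  expect_equal(sort(graphNodes(g)$kind), c("terminal", "terminal"))
  expect_length(graphEdges(g), 1)
  expect_equal(graphEdges(g)[[1]]$lengthPx, 99)
})

test_that("a perfect diagonal measures 99 * sqrt(2)", {
  px <- cbind(1:100, 1:100)
  g <- buildPlantGraph(skeletonFromPixels(px))
  expect_equal(graphEdges(g)[[1]]$lengthPx, 99 * sqrt(2))
})

test_that("a Y-shaped skeleton yields 3 terminals, 1 branching node, 3 edges", {
  fx <- makeSkeletonFixture(list(
    nodes = data.frame(id = 1:4,
                       row = c(100, 40, 40, 160),
                       col = c(100, 40, 160, 100),
                       kind = c("branching", "terminal", "terminal", "terminal")),
    edges = list(list(a = 1, b = 2), list(a = 1, b = 3), list(a = 1, b = 4))))
  g <- fx$graph
  expect_equal(sum(graphNodes(g)$kind == "terminal"), 3)
  expect_equal(sum(graphNodes(g)$kind == "branching"), 1)
  expect_length(graphEdges(g), 3)
})

test_that("degree-2 nodes dissolve with length conserved", {
  nodes <- data.frame(id = 1:3, row = c(10, 10, 10), col = c(1, 31, 71),
                      kind = c("terminal", "branching", "terminal"),
                      stringsAsFactors = FALSE)
  mkpoly <- function(c0, c1) cbind(10L, c0:c1)
  edges <- list(list(a = 1, b = 2, lengthPx = 30, polyline = mkpoly(1, 31)),
                list(a = 2, b = 3, lengthPx = 40, polyline = mkpoly(31, 71)))
  g <- new("PlantGraph", nodes = nodes, edges = edges, sourceRegionId = 1L)
  s <- simplifyGraph(g)
  expect_equal(nrow(graphNodes(s)), 2)
  expect_length(graphEdges(s), 1)
  expect_equal(graphEdges(s)[[1]]$lengthPx, 70)
  expect_equal(nrow(graphEdges(s)[[1]]$polyline), 71)
  # graphs with no degree-2 nodes are untouched
  y <- buildPlantGraph(skeletonFromPixels(rbind(
    cbind(10:30, 50), cbind(9 - 0:15, 49 - 0:15), cbind(9 - 0:15, 51 + 0:15))))
  expect_equal(sum(vapply(graphEdges(simplifyGraph(y)), `[[`, 0, "lengthPx")),
               sum(vapply(graphEdges(y), `[[`, 0, "lengthPx")))
})

test_that("pruning removes a 49.2 px spur and keeps the degree-4 junction", {
  p <- pruneGraph(spurGraph(49.2), analysisConfig())
  expect_equal(nrow(graphNodes(p)), 4)
  nd <- graphNodes(p)
  deg <- nodeDegrees(p)
  expect_equal(unname(deg[as.character(nd$id[nd$kind == "branching"])]), 3L)
})

test_that("a terminal edge of exactly 50.0 px is kept: 'shorter than' is strict", {
  p <- pruneGraph(spurGraph(50.0), analysisConfig())
  expect_equal(nrow(graphNodes(p)), 5)
})

test_that("the basal edge below the lowest node is exempt regardless of length", {
  nodes <- data.frame(id = 1:4,
                      row = c(100, 110, 20, 99),
                      col = c(100, 100, 100, 140),
                      kind = c("branching", "terminal", "terminal", "terminal"),
                      stringsAsFactors = FALSE)
  g <- mkGraph(nodes, list(c(1, 2, 10), c(1, 3, 80), c(1, 4, 60)))
  p <- pruneGraph(g, analysisConfig())
  expect_true(2 %in% graphNodes(p)$id)       # 10 px basal edge survives
  expect_equal(nrow(graphNodes(p)), 4)
})

test_that("a spur at a degree-3 junction removes two nodes (junction dissolves)", {
  nodes <- data.frame(id = 1:4,
                      row = c(100, 180, 20, 99),
                      col = c(100, 100, 100, 140),
                      kind = c("branching", "terminal", "terminal", "terminal"),
                      stringsAsFactors = FALSE)
  g <- mkGraph(nodes, list(c(1, 2, 80), c(1, 3, 80), c(1, 4, 30)))
  p <- pruneGraph(g, analysisConfig())
  expect_equal(nrow(graphNodes(p)), 2)
  expect_length(graphEdges(p), 1)
  expect_equal(graphEdges(p)[[1]]$lengthPx, 160)
})

test_that("coleoptile mode skips pruning entirely", {
  g <- spurGraph(8)
  p <- pruneGraph(g, analysisConfig("coleoptile"))
  expect_equal(nrow(graphNodes(p)), nrow(graphNodes(g)))
})

test_that("pruning that would empty the graph is an error", {
  nodes <- data.frame(id = 1:2, row = c(10, 20), col = c(5, 5),
                      kind = "terminal", stringsAsFactors = FALSE)
  g <- mkGraph(nodes, list(c(1, 2, 5)))
  # single edge: its bottom endpoint is the basal terminal, so it survives
  expect_equal(nrow(graphNodes(pruneGraph(g, analysisConfig()))), 2)
})

test_that("pruning the nine-node fixture leaves seven nodes", {
  fx <- makeSkeletonFixture(nineNodeTreeSpec())
  expect_equal(nrow(graphNodes(fx$graph)), 9)
  deg <- nodeDegrees(fx$graph)
  junctions <- graphNodes(fx$graph)$id[graphNodes(fx$graph)$kind == "branching"]
  expect_true(sum(deg[as.character(junctions)] >= 4) >= 2)
  p <- pruneGraph(fx$graph, analysisConfig())
  expect_equal(nrow(graphNodes(p)), 7)
})

test_that("after pruning no short terminal edge remains except the basal one", {
  set.seed(21)
  cfg <- analysisConfig()
  for (rep in 1:5) {
    out <- randomSeedlingScene(1, sample(2:4, 1),
                               sceneSpec(seed = 300 + rep))
    cfgS <- analysisConfig(cornerWindowFrac = out$cornerWindowFrac)
    mask <- segmentColor(preprocessImage(out$image, cfgS), cfgS)
    reg <- extractRegions(mask, cfgS)[[1]]
    g <- pruneGraph(buildPlantGraph(skeletonize(reg)), cfg)
    deg <- nodeDegrees(g)
    nd <- graphNodes(g)
    termIds <- nd$id[deg[as.character(nd$id)] == 1]
    basal <- nd$id[order(-nd$row, nd$col)][1]
    for (e in graphEdges(g)) {
      isTerm <- e$a %in% termIds || e$b %in% termIds
      touchesBasal <- basal %in% c(e$a, e$b)
      if (isTerm && !touchesBasal) expect_gte(e$lengthPx, cfg@pruneThresholdPx)
    }
  }
})

test_that("geodesics match hand-computed path sums on a path graph", {
  nodes <- data.frame(id = 1:3, row = c(1, 1, 1), col = c(1, 2, 3),
                      kind = c("terminal", "branching", "terminal"),
                      stringsAsFactors = FALSE)
  poly <- matrix(c(1L, 1L, 1L, 2L), 2, 2, byrow = TRUE)
  edges <- list(list(a = 1, b = 2, lengthPx = 3, polyline = poly),
                list(a = 2, b = 3, lengthPx = 4, polyline = poly))
  g <- new("PlantGraph", nodes = nodes, edges = edges, sourceRegionId = 1L)
  geo <- geodesicDistances(g, 1)
  expect_equal(unname(geo$dist[c("1", "2", "3")]), c(0, 3, 7))
  expect_equal(unname(geo$parent["3"]), 2L)
})

test_that("on trees, distance equals the unique path sum", {
  fx <- makeSkeletonFixture(nineNodeTreeSpec())
  g <- fx$graph
  geo <- geodesicDistances(g, anchorNodes(g)$lowest)
  # walk each parent chain and re-sum edge lengths
  lens <- new.env()
  for (e in graphEdges(g)) {
    assign(paste(sort(c(e$a, e$b)), collapse = "-"), e$lengthPx, envir = lens)
  }
  for (v in graphNodes(g)$id) {
    d <- 0; u <- v
    while (!is.na(geo$parent[as.character(u)])) {
      p <- geo$parent[as.character(u)]
      d <- d + get(paste(sort(c(u, p)), collapse = "-"), envir = lens)
      u <- p
    }
    expect_equal(unname(geo$dist[as.character(v)]), d)
  }
})

test_that("Dijkstra equals brute-force simple-path enumeration", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    g <- randomWeightedGraph(n, extra = sample(0:3, 1))
    src <- sample.int(n, 1)
    geo <- geodesicDistances(g, src)
    brute <- bruteGeodesics(n, graphEdges(g), src)
    expect_equal(unname(geo$dist[as.character(1:n)]), brute, tolerance = 1e-12)
  }
})

test_that("disconnected graphs are reported", {
  nodes <- data.frame(id = 1:4, row = 1:4, col = 1:4,
                      kind = "terminal", stringsAsFactors = FALSE)
  poly <- matrix(c(1L, 1L, 1L, 2L), 2, 2, byrow = TRUE)
  edges <- list(list(a = 1, b = 2, lengthPx = 1, polyline = poly),
                list(a = 3, b = 4, lengthPx = 1, polyline = poly))
  g <- new("PlantGraph", nodes = nodes, edges = edges, sourceRegionId = 1L)
  expect_error(geodesicDistances(g, 1), "unreachable-node")
})

test_that("plant graphs round-trip through JSON", {
  fx <- makeSkeletonFixture(nineNodeTreeSpec())
  js <- plantGraphToJSON(fx$graph)
  g2 <- plantGraphFromJSON(js)
  expect_equal(graphNodes(g2), graphNodes(fx$graph))
  expect_equal(length(graphEdges(g2)), length(graphEdges(fx$graph)))
  e1 <- graphEdges(fx$graph)[[3]]; e2 <- graphEdges(g2)[[3]]
  expect_equal(e2$lengthPx, e1$lengthPx)
  expect_equal(unname(e2$polyline), unname(e1$polyline))
})
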