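# Independent oracles and small fixture builders shared across tests.

# Naive Otsu: scan all 256 candidate thresholds, computing the
# between-class variance directly from the split pixel vectors.
otsuOracle <- function(gray) {
  v <- as.numeric(gray)
  best <- -Inf; bt <- NA_integer_
  for (t in 1:255) {
    lo <- v[v < t]; hi <- v[v >= t]
    s <- if (!length(lo) || !length(hi)) 0 else {
      w0 <- length(lo) / length(v)
      w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    }
    if (s > best) { best <- s; bt <- t }
  }
  bt
}

# Brute-force single-source shortest paths by exhaustive simple-path
# enumeration (depth-first), for graphs of up to ~10 nodes.
bruteGeodesics <- function(n, edges, src) {
  adj <- vector("list", n)
  for (e in edges) {
    adj[[e$a]] <- c(adj[[e$a]], list(c(e$b, e$lengthPx)))
    adj[[e$b]] <- c(adj[[e$b]], list(c(e$a, e$lengthPx)))
  }
  best <- rep(Inf, n)
  dfs <- function(v, visited, d) {
    if (d < best[v]) best[v] <<- d
    for (nb in adj[[v]]) {
      u <- nb[1L]
      if (!visited[u]) {
        visited[u] <- TRUE
        dfs(u, visited, d + nb[2L])
        visited[u] <- FALSE
      }
    }
  }
  vis <- rep(FALSE, n); vis[src] <- TRUE
  dfs(src, vis, 0)
  best
}

# Random connected weighted graph wrapped as a PlantGraph (spanning tree
# plus a few extra edges; geometry is irrelevant, only weights matter).
randomWeightedGraph <- function(n, extra = 2L) {
  edges <- list()
  addE <- function(a, b) {
    w <- round(stats::runif(1, 0.5, 9.5), 2)
    edges[[length(edges) + 1L]] <<- list(
      a = a, b = b, lengthPx = w,
      polyline = matrix(c(1L, 1L, 1L, 2L), 2L, 2L, byrow = TRUE))
  }
  for (v in 2:n) addE(sample.int(v - 1L, 1L), v)
  have <- vapply(edges, function(e) paste(sort(c(e$a, e$b)), collapse = "-"), "")
  tries <- 0L
  while (extra > 0L && tries < 50L) {
    ab <- sort(sample.int(n, 2L))
    key <- paste(ab, collapse = "-")
    tries <- tries + 1L
    if (!key %in% have) {
      addE(ab[1L], ab[2L]); have <- c(have, key); extra <- extra - 1L
    }
  }
  nodes <- data.frame(id = seq_len(n), row = sample.int(500, n),
                      col = sample.int(500, n), kind = "branching",
                      stringsAsFactors = FALSE)
  new("PlantGraph", nodes = nodes, edges = edges, sourceRegionId = 1L)
}

# Tree spec used by several pruning tests: nine nodes, two short spurs,
# one at a degree-4 and one at a degree-5 junction, so pruning removes
# exactly the two spur terminals (nine -> seven nodes).
nineNodeTreeSpec <- function() {
  nodes <- data.frame(
    id = 1:9,
    row = c(400, 320, 320, 305, 240, 228, 240, 130, 120),
    col = c(200, 200, 120, 232, 200, 170, 280, 150, 260),
    kind = c("terminal", "branching", "terminal", "terminal", "branching",
             "terminal", "terminal", "terminal", "terminal"),
    stringsAsFactors = FALSE)
  edges <- list(
    list(a = 1, b = 2),            # basal stem, 80 px
    list(a = 2, b = 3),            # long arm at junction 2 (80 px)
    list(a = 2, b = 4),            # spur at degree-4 junction 2 (< 50 px)
    list(a = 2, b = 5),            # stem up
    list(a = 5, b = 6),            # spur at degree-5 junction 5 (< 50 px)
    list(a = 5, b = 7),            # long arm (80 px)
    list(a = 5, b = 8),            # leaf
    list(a = 5, b = 9))            # leaf
  list(nodes = nodes, edges = edges)
}

# Naive per-pixel two-subiteration thinning (the textbook formulation),
# as an independent oracle for the vectorized implementation.
thinOracle <- function(img) {
  img <- rbind(0L, cbind(0L, img, 0L), 0L)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      del <- NULL
      for (r in 2:(nrow(img) - 1)) for (c_ in 2:(ncol(img) - 1)) {
        if (img[r, c_] != 1L) next
        p <- c(img[r - 1, c_], img[r - 1, c_ + 1], img[r, c_ + 1],
               img[r + 1, c_ + 1], img[r + 1, c_], img[r + 1, c_ - 1],
               img[r, c_ - 1], img[r - 1, c_ - 1])
        B <- sum(p)
        if (B < 2 || B > 6) next
        seq_ <- c(p, p[1])
        A <- sum(seq_[-9] == 0 & seq_[-1] == 1)
        if (A != 1) next
        ok <- if (step == 1)
          p[1] * p[3] * p[5] == 0 && p[3] * p[5] * p[7] == 0
        else
          p[1] * p[3] * p[7] == 0 && p[1] * p[5] * p[7] == 0
        if (ok) del <- rbind(del, c(r, c_))
      }
      if (!is.null(del)) {
        changed <- TRUE
        img[del] <- 0L
      }
    }
    if (!changed) break
  }
  img[2:(nrow(img) - 1), 2:(ncol(img) - 1)]
}

# Minimal PlantGraph builder with dummy polylines (lengths carry the
# semantics under test).
mkGraph <- function(nodes, edgeList) {
  poly <- matrix(c(1L, 1L, 1L, 2L), 2, 2, byrow = TRUE)
  edges <- lapply(edgeList, function(e)
    list(a = e[1], b = e[2], lengthPx = e[3], polyline = poly))
  new("PlantGraph", nodes = nodes, edges = edges, sourceRegionId = 1L)
}

# degree-4 junction (node 1) with basal stem, upper stem, long arm and a
# variable-length terminal spur (node 5)
spurGraph <- function(spurLen) {
  nodes <- data.frame(id = 1:5,
                      row = c(100, 180, 20, 100, 99),
                      col = c(100, 100, 100, 30, 140),
                      kind = c("branching", "terminal", "terminal",
                               "terminal", "terminal"),
                      stringsAsFactors = FALSE)
  mkGraph(nodes, list(c(1, 2, 80), c(1, 3, 80), c(1, 4, 70),
                      c(1, 5, spurLen)))
}

# One small cached seedling scene so pipeline tests do not re-render.
.sceneCache <- new.env(parent = emptyenv())
cachedScene <- function(key, maker) {
  if (is.null(.sceneCache[[key]])) .sceneCache[[key]] <- maker()
  .sceneCache[[key]]
}
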