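# Skeleton-to-graph conversion, spur pruning, simplification, geodesics.

#' Convert a skeleton to a plant graph
#'
#' Terminal pixels (one 8-neighbour) become terminal nodes. Maximal
#' 8-connected clusters of branching pixels (more than two neighbours)
#' collapse into a single branching node placed at the cluster member
#' nearest the cluster centroid. Maximal runs of edge points between nodes
#' become edges, stored with their pixel polylines and geodesic lengths
#' (1 per orthogonal, sqrt(2) per diagonal step).
#'
#' @param skel a [Skeleton-class].
#' @return a [PlantGraph-class].
#' @export
buildPlantGraph <- function(skel) {
  px <- skel@pixels
  adj <- .skeletonAdjacency(px)
  deg <- lengths(adj)
  if (any(deg == 0L))
    stop("too-small-object: isolated skeleton pixel")
  kind <- ifelse(deg == 1L, "terminal", ifelse(deg == 2L, "edge", "branching"))
  n <- nrow(px)

  # node id per pixel (0 = edge point)
  nodeOf <- integer(n)
  nodeCoord <- list(); nodeKind <- character(0)
  repPixel <- integer(0)  # representative pixel index per node
  # branching clusters
  brIdx <- which(kind == "branching")
  if (length(brIdx)) {
    sub <- match(seq_len(n), brIdx)  # pixel -> position in brIdx (NA if not branching)
    edges <- do.call(rbind, lapply(brIdx, function(i) {
      nb <- adj[[i]]
      nb <- nb[kind[nb] == "branching"]
      if (length(nb)) cbind(sub[i], sub[nb]) else NULL
    }))
    g <- igraph::make_empty_graph(n = length(brIdx), directed = FALSE)
    if (!is.null(edges)) {
      keep <- edges[, 1L] < edges[, 2L]
      if (any(keep))
        g <- igraph::add_edges(g, t(edges[keep, , drop = FALSE]))
    }
    comp <- igraph::components(g)$membership
    for (cl in sort(unique(comp))) {
      members <- brIdx[comp == cl]
      pts <- px[members, , drop = FALSE]
      cen <- colMeans(pts)
      d2 <- (pts[, 1L] - cen[1L])^2 + (pts[, 2L] - cen[2L])^2
      rep_ <- members[order(d2, pts[, 1L], pts[, 2L])[1L]]
      nodeKind <- c(nodeKind, "branching")
      nodeCoord[[length(nodeKind)]] <- px[rep_, ]
      repPixel[length(nodeKind)] <- rep_
      nodeOf[members] <- length(nodeKind)
    }
  }
  for (i in which(kind == "terminal")) {
    nodeKind <- c(nodeKind, "terminal")
    nodeCoord[[length(nodeKind)]] <- px[i, ]
    repPixel[length(nodeKind)] <- i
    nodeOf[i] <- length(nodeKind)
  }
  if (!any(nodeOf > 0L))
    stop("skeleton is a closed loop: no terminal or branching pixel found")

  # deterministic node ids: sort by (row, col) of the node coordinate
  coords <- do.call(rbind, nodeCoord)
  ord <- order(coords[, 1L], coords[, 2L])
  newId <- match(seq_along(nodeKind), ord)
  nodeOf[nodeOf > 0L] <- newId[nodeOf[nodeOf > 0L]]
  repPixel <- repPixel[ord]  # reindex representatives to the new node ids
  nodes <- data.frame(id = seq_along(nodeKind),
                      row = as.integer(coords[ord, 1L]),
                      col = as.integer(coords[ord, 2L]),
                      kind = nodeKind[ord],
                      stringsAsFactors = FALSE)

  # shortest pixel path from a node's representative pixel to a member
  # pixel, inside the cluster (keeps intra-cluster steps on the polylines,
  # so path lengths through multi-pixel junction clusters are conserved)
  clusterPath <- function(member) {
    node <- nodeOf[member]
    rep_ <- repPixel[node]
    if (rep_ == member) return(member)
    # BFS within the cluster
    frontier <- rep_; parent <- setNames(0L, as.character(rep_))
    while (length(frontier)) {
      nxtFront <- integer(0)
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (nodeOf[v] != node || as.character(v) %in% names(parent)) next
          parent[as.character(v)] <- u
          if (v == member) {
            path <- v
            while (path[1L] != rep_) path <- c(parent[as.character(path[1L])], path)
            return(as.integer(path))
          }
          nxtFront <- c(nxtFront, v)
        }
      }
      frontier <- nxtFront
    }
    c(rep_, member)  # fallback (members are connected by construction)
  }
  edgesOut <- list()
  visited <- logical(n)           # edge points consumed by a traced chain
  directSeen <- character(0)      # node-pixel adjacency pairs already emitted
  addEdge <- function(iStart, iEnd, midIdx) {
    polyIdx <- c(clusterPath(iStart), midIdx, rev(clusterPath(iEnd)))
    poly <- px[polyIdx, , drop = FALSE]
    poly <- .dedupePath(poly)
    edgesOut[[length(edgesOut) + 1L]] <<- list(
      a = nodeOf[iStart], b = nodeOf[iEnd],
      lengthPx = chamferLength(poly),
      polyline = matrix(as.integer(poly), ncol = 2L,
                        dimnames = list(NULL, c("row", "col"))))
  }
  nodePixels <- which(nodeOf > 0L)
  for (i in nodePixels) {
    for (q in adj[[i]]) {
      if (nodeOf[q] > 0L) {
        if (nodeOf[q] == nodeOf[i]) next  # internal to a branching cluster
        key <- paste(sort(c(i, q)), collapse = "-")
        if (key %in% directSeen) next
        directSeen <- c(directSeen, key)
        addEdge(i, q, integer(0))
      } else if (!visited[q]) {
        chain <- q; visited[q] <- TRUE
        prev <- i; cur <- q
        repeat {
          nxt <- adj[[cur]]
          nxt <- nxt[nxt != prev]
          if (length(nxt) != 1L)
            stop("skeleton tracing error: edge point without unique continuation")
          if (nodeOf[nxt] > 0L) {
            addEdge(i, nxt, chain)
            break
          }
          visited[nxt] <- TRUE
          chain <- c(chain, nxt)
          prev <- cur; cur <- nxt
        }
      }
    }
  }
  out <- new("PlantGraph", nodes = nodes, edges = edgesOut,
             sourceRegionId = skel@sourceRegionId)
  # thinning occasionally leaves junction clusters that collapse to
  # degree-2 nodes; dissolve them so nodes are terminal or branching
  simplifyGraph(out)
}

#' @noRd
.refreshKinds <- function(graph) {
  deg <- nodeDegrees(graph)
  graph@nodes$kind <- ifelse(deg[as.character(graph@nodes$id)] <= 1L,
                             "terminal", ifelse(deg[as.character(graph@nodes$id)] == 2L,
                                                "edge", "branching"))
  graph
}

#' Dissolve degree-2 nodes
#'
#' Every node of degree 2 is removed and its two incident edges merged into
#' one whose length is their sum and whose polyline is their concatenation;
#' total summed edge length is conserved. Needed after pruning, when former
#' junctions drop to degree 2.
#'
#' @param graph a [PlantGraph-class].
#' @return the simplified [PlantGraph-class].
#' @export
simplifyGraph <- function(graph) {
  nodes <- graph@nodes
  edges <- graph@edges
  orientTo <- function(e, id) {
    # return polyline oriented so that it ENDS at node id's side
    if (e$b == id) e$polyline else e$polyline[rev(seq_len(nrow(e$polyline))), , drop = FALSE]
  }
  repeat {
    deg <- setNames(integer(nrow(nodes)), nodes$id)
    for (e in edges) {
      deg[as.character(e$a)] <- deg[as.character(e$a)] + 1L
      deg[as.character(e$b)] <- deg[as.character(e$b)] + 1L
    }
    cand <- nodes$id[deg[as.character(nodes$id)] == 2L]
    merged <- FALSE
    for (v in cand) {
      inc <- which(vapply(edges, function(e) e$a == v || e$b == v, TRUE))
      if (length(inc) != 2L) next  # self-loop at v: leave as is
      e1 <- edges[[inc[1L]]]; e2 <- edges[[inc[2L]]]
      a <- if (e1$a == v) e1$b else e1$a
      b <- if (e2$a == v) e2$b else e2$a
      if (a == v || b == v) next   # self-loop, skip
      p1 <- orientTo(e1, v)                         # a ... v
      p2 <- orientTo(e2, v)                         # b ... v
      p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]  # v ... b
      poly <- rbind(p1, p2[-1L, , drop = FALSE])
      newEdge <- list(a = a, b = b, lengthPx = e1$lengthPx + e2$lengthPx,
                      polyline = poly)
      edges <- c(edges[-inc], list(newEdge))
      nodes <- nodes[nodes$id != v, , drop = FALSE]
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  out <- new("PlantGraph", nodes = nodes, edges = edges,
             sourceRegionId = graph@sourceRegionId)
  .refreshKinds(out)
}

#' Prune short terminal spurs
#'
#' A single pass over the edges that are terminal in the input graph:
#' every terminal edge strictly shorter than `pruneThresholdPx` is removed
#' together with its terminal node, except the basal edge, i.e. the
#' terminal edge whose terminal endpoint has the greatest row coordinate
#' (lowest in the image; ties broken towards the smallest column). Former
#' junctions that drop to degree 2 are then dissolved with
#' [simplifyGraph()]. In coleoptile mode the graph is returned unchanged:
#' coleoptiles may be shorter than the threshold and are never pruned.
#'
#' @param graph a [PlantGraph-class].
#' @param cfg an [AnalysisConfig-class].
#' @return the pruned, simplified [PlantGraph-class].
#' @export
pruneGraph <- function(graph, cfg = analysisConfig()) {
  if (cfg@plantType == "coleoptile") return(graph)
  nodes <- graph@nodes
  edges <- graph@edges
  deg <- nodeDegrees(graph)
  termIds <- nodes$id[deg[as.character(nodes$id)] == 1L]
  if (!length(termIds)) return(simplifyGraph(graph))
  # protected basal terminal: greatest row, ties by smallest column
  tnodes <- nodes[nodes$id %in% termIds, , drop = FALSE]
  basal <- tnodes$id[order(-tnodes$row, tnodes$col)][1L]
  dropEdges <- integer(0); dropNodes <- integer(0)
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    ta <- e$a %in% termIds; tb <- e$b %in% termIds
    if (!ta && !tb) next
    endpts <- c(e$a, e$b)[c(ta, tb)]
    if (basal %in% endpts) next
    if (e$lengthPx < cfg@pruneThresholdPx) {
      dropEdges <- c(dropEdges, i)
      dropNodes <- c(dropNodes, endpts)
    }
  }
  if (length(dropEdges)) {
    edges <- edges[-dropEdges]
    nodes <- nodes[!nodes$id %in% dropNodes, , drop = FALSE]
  }
  if (nrow(nodes) < 2L)
    stop("all-pruned: pruning would leave fewer than 2 nodes")
  out <- new("PlantGraph", nodes = nodes, edges = edges,
             sourceRegionId = graph@sourceRegionId)
  simplifyGraph(out)
}

#' @noRd
.asIgraph <- function(graph) {
  el <- do.call(rbind, lapply(graph@edges, function(e) c(e$a, e$b)))
  g <- igraph::make_empty_graph(n = nrow(graph@nodes), directed = FALSE)
  ids <- graph@nodes$id
  if (!is.null(el)) {
    g <- igraph::add_edges(g, t(matrix(match(el, ids), ncol = 2L)))
    igraph::E(g)$weight <- vapply(graph@edges, `[[`, 0, "lengthPx")
  }
  igraph::V(g)$name <- as.character(ids)
  g
}

#' Geodesic distances from a source node
#'
#' Shortest paths from `sourceId` to every node, with edge weights equal to
#' the geodesic pixel lengths (Dijkstra, via igraph). Used to measure the
#' shoot as the path from the lowest to the highest node and the coleoptile
#' as the farthest geodesic from the lowest node.
#'
#' @param graph a [PlantGraph-class].
#' @param sourceId a node id of `graph`.
#' @return list with `source`, `dist` (named numeric by node id) and
#'   `parent` (named integer; `NA` for the source), encoding one shortest
#'   path per node.
#' @export
geodesicDistances <- function(graph, sourceId) {
  ids <- graph@nodes$id
  if (!sourceId %in% ids) stop("source node not in graph")
  g <- .asIgraph(graph)
  src <- as.character(sourceId)
  d <- igraph::distances(g, v = src, algorithm = "dijkstra")[1L, ]
  if (any(!is.finite(d)))
    stop("unreachable-node: graph is disconnected")
  paths <- igraph::shortest_paths(g, from = src, to = igraph::V(g),
                                  output = "vpath")$vpath
  parent <- setNames(rep(NA_integer_, length(ids)), as.character(ids))
  for (p in paths) {
    nm <- names(p)
    if (length(nm) >= 2L)
      parent[nm[length(nm)]] <- as.integer(nm[length(nm) - 1L])
  }
  list(source = sourceId,
       dist = setNames(as.numeric(d[as.character(ids)]), as.character(ids)),
       parent = parent)
}

#' Serialize a plant graph to JSON
#'
#' @param graph a [PlantGraph-class].
#' @param path optional file to write to.
#' @return JSON string (invisibly if written to `path`).
#' @export
plantGraphToJSON <- function(graph, path = NULL) {
  obj <- list(
    sourceRegionId = graph@sourceRegionId,
    nodes = graph@nodes,
    edges = lapply(graph@edges, function(e)
      list(a = e$a, b = e$b, lengthPx = e$lengthPx,
           polyline = unname(apply(e$polyline, 1L, as.integer, simplify = FALSE))))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname plantGraphToJSON
#' @param json JSON string or file path produced by [plantGraphToJSON()].
#' @export
plantGraphFromJSON <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE,
                            simplifyMatrix = TRUE)
  edges <- lapply(seq_len(nrow(obj$edges)), function(i) {
    poly <- obj$edges$polyline[[i]]
    list(a = obj$edges$a[i], b = obj$edges$b[i],
         lengthPx = obj$edges$lengthPx[i],
         polyline = matrix(as.integer(poly), ncol = 2L,
                           dimnames = list(NULL, c("row", "col"))))
  })
  new("PlantGraph", nodes = obj$nodes, edges = edges,
      sourceRegionId = as.integer(obj$sourceRegionId))
}
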