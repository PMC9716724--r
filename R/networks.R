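## Indirect-association social network and relatedness-based genetic
## network, plus the node/graph metrics reported for them.

.newAttributedNetwork <- function(adj, individuals, kind) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  idx <- match(igraph::V(g)$name, individuals$individual_id)
  g <- igraph::set_vertex_attr(g, "sex", value = individuals$sex[idx])
  g <- igraph::set_vertex_attr(g, "ageClass",
                               value = individuals$ageClass[idx])
  new("AttributedNetwork", graph = g, kind = kind)
}

#' Build the indirect-association social network
#'
#' Gambit of the group over survey occasions: all individuals detected on
#' the same occasion are taken to associate. Every pair co-detected on an
#' occasion gains one co-occurrence; an edge exists iff the pair was
#' co-detected at least once and its weight is the number of occasions
#' co-detected (raw counts; set `index = "sri"` for the simple-ratio
#' association index instead). Individuals never detected remain isolated
#' nodes.
#'
#' @param detections data.frame with columns `survey_id`, `individual_id`
#'   (one row per detection of an individual on an occasion).
#' @param individuals data.frame with columns `individual_id`, `sex`,
#'   `ageClass`; defines the node set. Detections of individuals absent
#'   from this table are an error.
#' @param index "count" (default) or "sri" (simple-ratio index,
#'   co-detections / occasions where at least one of the pair was
#'   detected).
#' @return an [AttributedNetwork-class] of kind "social".
#' @export
buildSocialNetwork <- function(detections, individuals, index = c("count", "sri")) {
  index <- match.arg(index)
  stopifnot(all(c("survey_id", "individual_id") %in% names(detections)),
            all(c("individual_id", "sex", "ageClass") %in% names(individuals)))
  surveys <- unique(detections$survey_id)
  if (length(surveys) < 1L) stop("at least one survey occasion is required")
  unknown <- setdiff(unique(detections$individual_id),
                     individuals$individual_id)
  if (length(unknown)) {
    stop("detections reference unknown individuals: ",
         paste(unknown, collapse = ", "))
  }
  ids <- sort(individuals$individual_id)
  M <- table(factor(detections$individual_id, levels = ids),
             factor(detections$survey_id, levels = surveys))
  M <- (unclass(M) > 0) * 1
  co <- tcrossprod(M)
  diag(co) <- 0
  if (index == "sri") {
    det <- rowSums(M)
    either <- outer(det, det, "+") - co
    sri <- ifelse(either > 0, co / either, 0)
    diag(sri) <- 0
    co <- sri
  }
  .newAttributedNetwork(co, individuals, "social")
}

#' Build the relatedness-based genetic network
#'
#' An edge joins two individuals iff their pairwise relatedness reaches the
#' unrelated cutoff (default R >= 0.125); the edge weight is R itself (or,
#' with `weight = "classRank"`, the kin-class rank 3/2/1 for
#' first/second/third-class relatives). The kin class is stored as an edge
#' attribute. Masked pairs contribute no edge and are counted in a message.
#'
#' @param rmat a [RelatednessMatrix-class].
#' @param individuals data.frame with `individual_id`, `sex`, `ageClass`
#'   covering the matrix ids.
#' @param threshold minimum R for an edge.
#' @param weight "relatedness" (default) or "classRank".
#' @param edges kin-class cut points, see [classifyKin()].
#' @return an [AttributedNetwork-class] of kind "genetic".
#' @export
buildGeneticNetwork <- function(rmat, individuals, threshold = 0.125,
                                weight = c("relatedness", "classRank"),
                                edges = c(0.125, 0.1875, 0.375)) {
  weight <- match.arg(weight)
  stopifnot(is(rmat, "RelatednessMatrix"))
  ids <- individualIds(rmat)
  if (length(ids) < 2L) stop("genetic network requires at least 2 individuals")
  v <- rmat@values
  nMasked <- sum(is.na(v[lower.tri(v)]))
  if (nMasked > 0L) message(nMasked, " masked pair(s) contribute no edge")
  adj <- v
  adj[is.na(adj) | adj < threshold] <- 0
  if (weight == "classRank") {
    kc <- classifyKin(v, edges = edges)
    dim(kc) <- dim(v)
    rk <- matrix(0, nrow(v), ncol(v), dimnames = dimnames(v))
    rk[kc == "first"] <- 3
    rk[kc == "second"] <- 2
    rk[kc == "third"] <- 1
    rk[adj == 0] <- 0
    adj <- rk
  }
  net <- .newAttributedNetwork(adj, individuals, "genetic")
  g <- net@graph
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g)
    rv <- v[cbind(el[, 1L], el[, 2L])]
    g <- igraph::set_edge_attr(g, "kinClass", value = classifyKin(rv, edges))
    g <- igraph::set_edge_attr(g, "R", value = rv)
  }
  new("AttributedNetwork", graph = g, kind = "genetic")
}

#' Node and graph metrics of an attributed network
#'
#' Degree (incident edge count; the degree-centrality measure), strength
#' (weighted degree: sum of incident edge weights), plus graph-level edge
#' count, connectance (edges / all possible pairs), and mean and SD of the
#' degree distribution.
#'
#' @param net an [AttributedNetwork-class].
#' @return list: `nodes` (data.frame id, sex, ageClass, degree, strength,
#'   degreeCentrality = degree / (n - 1)) and `graph` (list nNodes, nEdges,
#'   connectance, meanDegree, sdDegree, meanStrength).
#' @export
networkMetrics <- function(net) {
  stopifnot(is(net, "AttributedNetwork"))
  g <- net@graph
  n <- igraph::vcount(g)
  if (n < 2L) stop("metrics require at least 2 nodes")
  deg <- igraph::degree(g)
  str <- igraph::strength(g)
  e <- igraph::ecount(g)
  nodes <- data.frame(
    id = igraph::V(g)$name,
    sex = igraph::V(g)$sex,
    ageClass = igraph::V(g)$ageClass,
    degree = as.integer(deg),
    strength = as.numeric(str),
    degreeCentrality = deg / (n - 1),
    stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  list(nodes = nodes,
       graph = list(nNodes = n,
                    nEdges = e,
                    connectance = connectanceFromCounts(n, e),
                    meanDegree = meanDegreeFromCounts(n, e),
                    sdDegree = stats::sd(deg),
                    meanStrength = mean(str)))
}

#' Connectance from node and edge counts
#'
#' Realized fraction of possible undirected edges: edges / (n (n - 1) / 2).
#'
#' @param n number of nodes (>= 2).
#' @param edges number of undirected edges.
#' @return connectance in [0, 1].
#' @export
#' @examples
#' connectanceFromCounts(33, 336)
connectanceFromCounts <- function(n, edges) {
  stopifnot(n >= 2, edges >= 0)
  edges / (n * (n - 1) / 2)
}

#' Mean degree from node and edge counts
#'
#' @inheritParams connectanceFromCounts
#' @return 2 * edges / n.
#' @export
meanDegreeFromCounts <- function(n, edges) {
  stopifnot(n >= 1, edges >= 0)
  2 * edges / n
}

#' Check reported network summaries against their reported counts
#'
#' Recomputes connectance and mean degree from reported node and edge
#' counts and compares them with independently reported values; useful for
#' auditing published network summaries.
#'
#' @param nNodes,nEdges reported counts.
#' @param connectance,meanDegree reported derived values.
#' @param tol absolute tolerance of the comparison.
#' @return list: recomputed `connectance` and `meanDegree`, and logical
#'   `consistent`.
#' @export
checkNetworkSummary <- function(nNodes, nEdges, connectance, meanDegree,
                                tol = 0.001) {
  cRe <- connectanceFromCounts(nNodes, nEdges)
  dRe <- meanDegreeFromCounts(nNodes, nEdges)
  list(connectance = cRe, meanDegree = dRe,
       consistent = abs(cRe - connectance) <= tol &&
         abs(dRe - meanDegree) <= tol)
}

#' Weighted adjacency matrix of an attributed network
#'
#' @param net an [AttributedNetwork-class].
#' @return symmetric numeric matrix of edge weights (0 = no edge), nodes
#'   sorted as in the graph.
#' @export
networkAdjacency <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net@graph, attr = "weight",
                                        sparse = FALSE))
}

#' Write a network edge list as CSV
#'
#' Columns: source, target, weight, and kinClass for genetic networks.
#' Nodes within an edge and rows are ordered by id for byte-stable output.
#'
#' @param net an [AttributedNetwork-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeEdgeList <- function(net, path) {
  g <- net@graph
  el <- igraph::as_edgelist(g)
  if (nrow(el) > 0L) {
    swap <- el[, 1L] > el[, 2L]
    el[swap, ] <- el[swap, 2:1]
  }
  df <- data.frame(source = el[, 1L], target = el[, 2L],
                   weight = if (igraph::ecount(g)) igraph::E(g)$weight else numeric(),
                   stringsAsFactors = FALSE)
  if ("kinClass" %in% igraph::edge_attr_names(g)) {
    df$kinClass <- igraph::E(g)$kinClass
  }
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML (node attributes included)
#'
#' @param net an [AttributedNetwork-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(net@graph, path, format = "graphml")
  invisible(path)
}
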