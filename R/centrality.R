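#' Normalized betweenness centrality
#'
#' For node i, the sum over unordered node pairs \{j, k\} (both distinct from
#' i) of g_jk(i) / g_jk, where g_jk is the number of geodesics (shortest
#' paths by edge count) between j and k and g_jk(i) the number of those
#' passing through i.  Pairs in different components contribute nothing.  The
#' raw sum is divided by (n-1)(n-2)/2 -- the number of pairs a node could
#' possibly mediate in an undirected network -- so values lie in [0, 1]: 0
#' for a node on no geodesic (isolates included), 1 for the centre of a star.
#'
#' Geodesics are computed on the unweighted skeleton.  Projection weights
#' encode similarity (shared-partner counts), not distances; treating them as
#' path costs would invert their meaning.
#'
#' Uses Brandes' single-source dependency-accumulation algorithm; see
#' \code{\link{betweenness_bruteforce}} for the exhaustive oracle with the
#' identical contract.
#'
#' @param pn a \code{projected_network} with at least one node.
#' @return A named numeric vector over all nodes, in node order, values in
#'   [0, 1].  All zeros when the network has fewer than 3 nodes.
#' @examples
#' star <- projected_network("drug", c("hub", "a", "b", "c"),
#'                           from = c("hub", "hub", "hub"),
#'                           to = c("a", "b", "c"), weight = c(1, 1, 1))
#' betweenness(star) # hub 1, leaves 0
#' @export
betweenness <- function(pn) {
  stopifnot(inherits(pn, "projected_network"))
  n <- length(pn$nodes)
  if (n == 0L) stop("empty network: no nodes", call. = FALSE)
  bc <- stats::setNames(numeric(n), pn$nodes)
  if (n <= 2L || nrow(pn$edges) == 0L) return(bc)
  adj <- .adjacency(pn)
  raw <- numeric(n)
  queue <- integer(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep.int(-1L, n)
    dist[s] <- 0L
    preds <- vector("list", n)
    queue[1L] <- s
    qhead <- 1L
    qtail <- 1L
    while (qhead <= qtail) {
      v <- queue[qhead]
      qhead <- qhead + 1L
      dv1 <- dist[v] + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          qtail <- qtail + 1L
          queue[qtail] <- w
          dist[w] <- dv1
        }
        if (dist[w] == dv1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (idx in rev(seq_len(qtail))) {
      w <- queue[idx]
      coeff <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coeff
      if (w != s) raw[w] <- raw[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  bc[] <- (raw / 2) / ((n - 1) * (n - 2) / 2)
  bc
}

#' Exhaustive betweenness oracle
#'
#' Enumerates every geodesic of every node pair by breadth-first layered path
#' expansion, counts interior occurrences directly, and applies the same
#' (n-1)(n-2)/2 normalization as \code{\link{betweenness}}.  Intended as an
#' independent correctness authority for small networks; refuses networks
#' with more than 64 nodes to guard against combinatorial blow-up.
#'
#' @param pn a \code{projected_network} with at most 64 nodes.
#' @return A named numeric vector, same contract as \code{\link{betweenness}}.
#' @export
betweenness_bruteforce <- function(pn) {
  stopifnot(inherits(pn, "projected_network"))
  n <- length(pn$nodes)
  if (n == 0L) stop("empty network: no nodes", call. = FALSE)
  if (n > 64L) stop("oracle size limit: more than 64 nodes", call. = FALSE)
  bc <- stats::setNames(numeric(n), pn$nodes)
  if (n <= 2L || nrow(pn$edges) == 0L) return(bc)
  adj <- .adjacency(pn)
  raw <- numeric(n)
  for (j in seq_len(n - 1L)) {
    # plain BFS from j: distances and shortest-path predecessors
    dist <- rep.int(-1L, n)
    dist[j] <- 0L
    preds <- vector("list", n)
    frontier <- j
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) preds[[w]] <- c(preds[[w]], v)
        }
      }
      frontier <- unique(nxt)
    }
    for (k in seq.int(j + 1L, n)) {
      if (dist[k] < 0L) next # disconnected pair: g_jk = 0, skip
      paths <- .enumerate_geodesics(k, j, preds)
      interior <- unlist(lapply(paths, function(p) {
        p[p != j & p != k]
      }))
      if (length(interior) > 0L) {
        counts <- tabulate(interior, nbins = n)
        raw <- raw + counts / length(paths)
      }
    }
  }
  bc[] <- raw / ((n - 1) * (n - 2) / 2)
  bc
}

# all geodesics from source to v, expanded through the predecessor DAG
.enumerate_geodesics <- function(v, source, preds) {
  if (v == source) return(list(source))
  out <- list()
  for (p in preds[[v]]) {
    sub <- .enumerate_geodesics(p, source, preds)
    out <- c(out, lapply(sub, function(path) c(path, v)))
  }
  out
}

#' Per-node centrality table for a projected network
#'
#' One row per node (isolates included) with normalized betweenness and
#' degree, in network node order.
#'
#' @param pn a \code{projected_network}.
#' @return A \code{data.frame} of class \code{centrality_table} with columns
#'   \code{node_id}, \code{betweenness}, \code{degree} and a \code{mode}
#'   attribute.
#' @export
centrality_table <- function(pn) {
  stopifnot(inherits(pn, "projected_network"))
  bc <- betweenness(pn)
  deg <- degrees(pn)
  structure(
    data.frame(
      node_id = pn$nodes,
      betweenness = unname(bc),
      degree = unname(deg),
      stringsAsFactors = FALSE
    ),
    mode = pn$mode,
    class = c("centrality_table", "data.frame")
  )
}

#' Rank nodes by betweenness centrality
#'
#' Rows sorted by betweenness descending; ties broken by node id ascending
#' (bytewise lexicographic) so output is deterministic.  Tied values receive
#' distinct consecutive ranks.
#'
#' @param ct a \code{\link{centrality_table}} (or data.frame with
#'   \code{node_id} and \code{betweenness} columns).
#' @param k number of top rows to return; truncated to the node count.
#' @return A \code{data.frame} with columns \code{rank}, \code{node_id},
#'   \code{betweenness}, and \code{degree} when present in \code{ct}.
#' @export
rank_nodes <- function(ct, k = 20L) {
  stopifnot(is.data.frame(ct),
            all(c("node_id", "betweenness") %in% names(ct)))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  o <- order(-ct$betweenness, ct$node_id, method = "radix")
  o <- o[seq_len(min(k, nrow(ct)))]
  out <- data.frame(
    rank = seq_along(o),
    node_id = ct$node_id[o],
    betweenness = ct$betweenness[o],
    stringsAsFactors = FALSE
  )
  if ("degree" %in% names(ct)) out$degree <- ct$degree[o]
  out
}
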