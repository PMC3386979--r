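#' Construct a one-mode projected network
#'
#' Low-level constructor used by \code{\link{project}}, the file readers and
#' the test suite.  Edges are undirected and stored once with endpoints
#' ordered by node position; self-edges, zero weights and duplicate pairs are
#' rejected.
#'
#' @param mode \code{"drug"} or \code{"target"}.
#' @param nodes character vector of all node ids (isolates included), in a
#'   fixed deterministic order.
#' @param from,to character vectors of edge endpoints (same length).
#' @param weight positive integer vector of shared-partner counts.
#' @return An object of class \code{projected_network}: list with
#'   \code{mode}, \code{nodes}, and \code{edges} (data.frame \code{from},
#'   \code{to}, \code{weight}, endpoints ordered so that \code{from} precedes
#'   \code{to} in \code{nodes}).
#' @export
projected_network <- function(mode = c("drug", "target"), nodes,
                              from = character(), to = character(),
                              weight = integer()) {
  mode <- match.arg(mode)
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids", call. = FALSE)
  fi <- match(as.character(from), nodes)
  ti <- match(as.character(to), nodes)
  if (anyNA(fi) || anyNA(ti)) {
    stop("edge endpoint not in node set", call. = FALSE)
  }
  if (any(fi == ti)) stop("self-edges are not allowed", call. = FALSE)
  w <- as.numeric(weight)
  if (length(w) != length(fi) || anyNA(w) || any(w < 1) || any(w != floor(w))) {
    stop("edge weights must be positive integers", call. = FALSE)
  }
  # normalize: smaller node index first, edges sorted by (from, to) index
  lo <- pmin(fi, ti)
  hi <- pmax(fi, ti)
  if (anyDuplicated(paste(lo, hi))) {
    stop("duplicate edges for the same node pair", call. = FALSE)
  }
  o <- order(lo, hi)
  structure(
    list(
      mode = mode,
      nodes = nodes,
      edges = data.frame(
        from = nodes[lo[o]],
        to = nodes[hi[o]],
        weight = as.integer(w[o]),
        stringsAsFactors = FALSE
      )
    ),
    class = "projected_network"
  )
}

#' Project the two-mode drug-target network into a one-mode network
#'
#' Converts the bipartite network into a drug-drug or target-target network
#' based on the network neighbourhood: two drugs are tied by the number of
#' targets they simultaneously address; two targets by the number of drugs
#' that address both.  Shared partners are counted as distinct nodes --
#' interaction multiplicity is ignored.  Every node of the chosen mode is
#' retained in the node list even when it shares no partner with any other
#' node (such isolates draw no edges and get degree and betweenness 0
#' downstream).
#'
#' @param net a \code{bipartite_network}.
#' @param mode which one-mode network to build: \code{"drug"} or
#'   \code{"target"}.
#' @return A \code{\link{projected_network}}.
#' @examples
#' net <- build_bipartite(drug_target_pairs(c("A", "A", "B", "B"),
#'                                          c("t1", "t2", "t1", "t2")))
#' project(net, "drug")    # edge A-B with weight 2
#' project(net, "target")  # edge t1-t2 with weight 2
#' @export
project <- function(net, mode = c("drug", "target")) {
  stopifnot(inherits(net, "bipartite_network"))
  mode <- match.arg(mode)
  di <- match(net$edges$drug, net$drugs)
  ti <- match(net$edges$target, net$targets)
  inc <- matrix(0L, nrow = length(net$drugs), ncol = length(net$targets))
  inc[cbind(di, ti)] <- 1L
  if (mode == "drug") {
    shared <- tcrossprod(inc)
    nodes <- net$drugs
  } else {
    shared <- crossprod(inc)
    nodes <- net$targets
  }
  idx <- which(upper.tri(shared) & shared > 0, arr.ind = TRUE)
  projected_network(
    mode = mode, nodes = nodes,
    from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
    weight = as.integer(shared[idx])
  )
}

#' Nodal degree in a projected network
#'
#' The number of distinct neighbours of each node; edge weights are ignored.
#' Isolates map to 0.
#'
#' @param pn a \code{projected_network}.
#' @return A named integer vector over all nodes, in node order.
#' @export
degrees <- function(pn) {
  stopifnot(inherits(pn, "projected_network"))
  deg <- integer(length(pn$nodes))
  names(deg) <- pn$nodes
  if (nrow(pn$edges) > 0L) {
    tab <- table(factor(c(pn$edges$from, pn$edges$to), levels = pn$nodes))
    deg[] <- as.integer(tab)
  }
  deg
}

#' @export
print.projected_network <- function(x, ...) {
  deg <- degrees(x)
  cat(sprintf("one-mode %s-%s network: %d nodes (%d isolates), %d edges\n",
              x$mode, x$mode, length(x$nodes), sum(deg == 0L),
              nrow(x$edges)))
  invisible(x)
}

# internal: adjacency list of node indices (weight-blind skeleton)
.adjacency <- function(pn) {
  n <- length(pn$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(pn$edges) > 0L) {
    fi <- match(pn$edges$from, pn$nodes)
    ti <- match(pn$edges$to, pn$nodes)
    nb <- split(c(ti, fi), c(fi, ti))
    for (k in names(nb)) adj[[as.integer(k)]] <- sort(nb[[k]])
  }
  adj
}
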