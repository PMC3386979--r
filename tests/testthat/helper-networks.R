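# Fixture builders and independent oracles shared across the suite.
# All randomness is seeded by the caller so every test is reproducible.

# Erdos-Renyi one-mode network on n labelled nodes, edge probability p,
# random small integer weights (weights never matter for geodesics).
rand_projected <- function(n, p, seed, mode = "drug") {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < p
  projected_network(mode, nodes,
                    from = nodes[idx[keep, 1L]], to = nodes[idx[keep, 2L]],
                    weight = sample(1:3, sum(keep), replace = TRUE))
}

# random bipartite pair list: each drug-target link present with prob p;
# guaranteed non-empty
rand_bipartite_pairs <- function(n_drugs, n_targets, p, seed) {
  set.seed(seed)
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  targets <- sprintf("t%02d", seq_len(n_targets))
  grid <- expand.grid(d = drugs, t = targets, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < p
  if (!any(keep)) keep[sample.int(length(keep), 1L)] <- TRUE
  drug_target_pairs(grid$d[keep], grid$t[keep])
}

# independent projection oracle: exhaustive pairwise set intersections
# computed straight from the raw pair list
oracle_projection_weights <- function(pairs, mode) {
  if (mode == "drug") {
    sets <- split(pairs$target_id, pairs$drug_id)
  } else {
    sets <- split(pairs$drug_id, pairs$target_id)
  }
  ids <- names(sets)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      w <- length(intersect(unique(sets[[i]]), unique(sets[[j]])))
      if (w > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          a = min(ids[i], ids[j]), b = max(ids[i], ids[j]), w = w,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(a = character(), b = character(), w = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$a, res$b), , drop = FALSE]
}

# normalize a projected network's edges to a sorted (a, b, w) frame for
# comparison with the oracle
edges_sorted <- function(pn) {
  e <- pn$edges
  a <- pmin(e$from, e$to)
  b <- pmax(e$from, e$to)
  res <- data.frame(a = a, b = b, w = e$weight, stringsAsFactors = FALSE)
  res <- res[order(res$a, res$b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# simple named graphs
path_graph <- function(n) {
  nodes <- sprintf("p%02d", seq_len(n))
  projected_network("drug", nodes, nodes[-n], nodes[-1L],
                    weight = rep(1L, n - 1L))
}

cycle_graph <- function(n) {
  nodes <- sprintf("c%02d", seq_len(n))
  projected_network("drug", nodes, nodes, c(nodes[-1L], nodes[1L]),
                    weight = rep(1L, n))
}

star_graph <- function(n_leaves) {
  nodes <- c("hub", sprintf("leaf%02d", seq_len(n_leaves)))
  projected_network("drug", nodes, rep("hub", n_leaves), nodes[-1L],
                    weight = rep(1L, n_leaves))
}

complete_graph <- function(n) {
  nodes <- sprintf("k%02d", seq_len(n))
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  projected_network("drug", nodes, nodes[idx[, 1L]], nodes[idx[, 2L]],
                    weight = rep(1L, nrow(idx)))
}
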