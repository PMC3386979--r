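#' Build the two-mode drug-target network from interaction pair records
#'
#' Node sets are the distinct drug and target identifiers in order of first
#' appearance.  Duplicate (drug, target) records are merged into a single
#' cross-edge whose weight is the summed multiplicity -- the edge weight
#' carries interaction frequency for two-mode export, but all downstream
#' projections and degree statistics use distinct edges only.  Drug and target
#' identifier namespaces must be disjoint: an identifier appearing in both
#' roles is a hard error, since it would corrupt the one-mode projections.
#'
#' @param pairs a \code{\link{drug_target_pairs}} table (or a data.frame with
#'   columns \code{drug_id}, \code{target_id} and optionally
#'   \code{multiplicity}).
#' @return An object of class \code{bipartite_network}: a list with
#'   \code{drugs}, \code{targets} (character vectors in first-appearance
#'   order) and \code{edges} (data.frame \code{drug}, \code{target},
#'   \code{weight}).
#' @examples
#' p <- drug_target_pairs(c("A", "A", "B"), c("t1", "t2", "t2"))
#' build_bipartite(p)
#' @export
build_bipartite <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("empty input: no drug-target pairs", call. = FALSE)
  }
  if (!all(c("drug_id", "target_id") %in% names(pairs))) {
    stop("pairs must have drug_id and target_id columns", call. = FALSE)
  }
  if (is.null(pairs$multiplicity)) pairs$multiplicity <- 1L
  if (!inherits(pairs, "drug_target_pairs")) {
    pairs <- drug_target_pairs(pairs$drug_id, pairs$target_id,
                               pairs$multiplicity)
  }
  drugs <- unique(pairs$drug_id)
  targets <- unique(pairs$target_id)
  both <- intersect(drugs, targets)
  if (length(both) > 0L) {
    stop(sprintf("bipartite violation: id(s) appear as both drug and target: %s",
                 paste(both, collapse = ", ")), call. = FALSE)
  }
  # merge duplicate records, keeping first-appearance edge order
  key <- paste(pairs$drug_id, pairs$target_id, sep = "\t")
  first <- !duplicated(key)
  wsum <- rowsum(pairs$multiplicity, key)
  w <- as.integer(wsum[match(key[first], rownames(wsum)), 1L])
  structure(
    list(
      drugs = drugs,
      targets = targets,
      edges = data.frame(
        drug = pairs$drug_id[first],
        target = pairs$target_id[first],
        weight = w,
        stringsAsFactors = FALSE
      )
    ),
    class = "bipartite_network"
  )
}

#' Average number of distinct targets per drug
#'
#' The distinct drug-target edge count divided by the number of drugs.
#' Interaction multiplicity never inflates this statistic: a drug recorded
#' twice against the same target still contributes one target.
#'
#' @param net a \code{bipartite_network}.
#' @return A single non-negative number.
#' @examples
#' net <- build_bipartite(drug_target_pairs(c("A", "A", "B"),
#'                                          c("t1", "t2", "t3")))
#' avg_targets_per_drug(net) # 1.5
#' @export
avg_targets_per_drug <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  if (length(net$drugs) == 0L) stop("empty network: no drugs", call. = FALSE)
  nrow(net$edges) / length(net$drugs)
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite drug-target network: %d drugs, %d targets, %d edges\n",
              length(x$drugs), length(x$targets), nrow(x$edges)))
  cat(sprintf("  avg targets per drug: %.4f\n", avg_targets_per_drug(x)))
  invisible(x)
}
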