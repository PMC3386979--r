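#' Run the full drug-target network analysis and write a report bundle
#'
#' Orchestrates the pipeline: read (or accept) the pair table, build the
#' two-mode network, project both one-mode networks, compute centralities,
#' rank the top nodes, optionally test the centrality-sales association, and
#' export everything.  The bundle written to \code{out_dir} contains:
#' \itemize{
#'   \item \code{summary.txt} / \code{summary.json}: cohort statistics
#'     (drug, target, pair counts, average targets per drug).
#'   \item \code{top_targets.tsv} / \code{top_drugs.tsv} (+ \code{.json}
#'     twins): top-k betweenness tables for each one-mode network.
#'   \item \code{degrees_targets.tsv} / \code{degrees_drugs.tsv}: full
#'     ranked centrality/degree tables.
#'   \item \code{drug_drug.net}, \code{target_target.net},
#'     \code{drug_drug.graphml}, \code{target_target.graphml}: exports.
#'   \item \code{association.txt} / \code{association.json} when a sales
#'     table is supplied.
#' }
#' All outputs are a pure function of the inputs and flags, so repeated runs
#' are byte-identical.
#'
#' @param pairs a \code{\link{drug_target_pairs}} table, or a path to a
#'   pairs TSV.
#' @param sales optional \code{\link{sales_table}} or path to a sales TSV.
#' @param out_dir output directory, created if missing.
#' @param top_k rows in the top-betweenness tables.
#' @param drop_isolates drop degree-0 nodes from the Pajek/GraphML exports
#'   (they are always kept in centrality tables, with betweenness 0).
#' @param log_sales correlate log sales instead of raw sales.
#' @param n_perm permutations for the permutation p-value (0 skips it).
#' @param seed seed for the permutation test.
#' @return Invisibly, a list with the networks, centrality tables, summary
#'   and association result.
#' @export
run_report <- function(pairs, sales = NULL, out_dir, top_k = 20L,
                       drop_isolates = FALSE, log_sales = FALSE,
                       n_perm = 999L, seed = 1L) {
  if (is.character(pairs)) pairs <- read_pairs(pairs)
  if (is.character(sales)) sales <- read_sales(sales)
  if (top_k < 1L) stop("top_k must be a positive integer", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  net <- build_bipartite(pairs)
  pn_drug <- project(net, "drug")
  pn_target <- project(net, "target")
  ct_drug <- centrality_table(pn_drug)
  ct_target <- centrality_table(pn_target)

  summary_stats <- list(
    n_drugs = length(net$drugs),
    n_targets = length(net$targets),
    n_pairs = nrow(net$edges),
    avg_targets_per_drug = avg_targets_per_drug(net),
    n_isolated_drugs = sum(ct_drug$degree == 0L),
    n_isolated_targets = sum(ct_target$degree == 0L)
  )
  .write_kv(summary_stats, file.path(out_dir, "summary.txt"))
  .write_json(summary_stats, file.path(out_dir, "summary.json"))

  for (side in list(list(ct = ct_target, pn = pn_target, tag = "targets",
                         net_tag = "target_target"),
                    list(ct = ct_drug, pn = pn_drug, tag = "drugs",
                         net_tag = "drug_drug"))) {
    top <- rank_nodes(side$ct, k = top_k)
    write_centrality(top, file.path(out_dir, paste0("top_", side$tag,
                                                    ".tsv")))
    .write_json(top, file.path(out_dir, paste0("top_", side$tag, ".json")))
    full <- rank_nodes(side$ct, k = nrow(side$ct))
    write_centrality(full, file.path(out_dir, paste0("degrees_", side$tag,
                                                     ".tsv")))
    .write_json(full, file.path(out_dir, paste0("degrees_", side$tag,
                                                ".json")))
    pn_out <- if (drop_isolates) .drop_isolates(side$pn) else side$pn
    write_pajek(pn_out, file.path(out_dir, paste0(side$net_tag, ".net")))
    write_graphml(pn_out, file.path(out_dir, paste0(side$net_tag,
                                                    ".graphml")))
  }

  assoc <- NULL
  if (!is.null(sales)) {
    assoc <- associate(ct_drug, sales, log_sales = log_sales,
                       n_perm = n_perm, seed = seed)
    out <- list(
      n = assoc$n, r = assoc$r, p_t = assoc$p_t, p_perm = assoc$p_perm,
      log_sales = assoc$log_sales,
      n_dropped_from_centrality = length(
        assoc$join_report$dropped_from_centrality),
      n_dropped_from_sales = length(assoc$join_report$dropped_from_sales)
    )
    .write_kv(out, file.path(out_dir, "association.txt"))
    .write_json(out, file.path(out_dir, "association.json"))
  }

  invisible(list(net = net, pn_drug = pn_drug, pn_target = pn_target,
                 ct_drug = ct_drug, ct_target = ct_target,
                 summary = summary_stats, association = assoc))
}

.drop_isolates <- function(pn) {
  deg <- degrees(pn)
  projected_network(mode = pn$mode, nodes = pn$nodes[deg > 0L],
                    from = pn$edges$from, to = pn$edges$to,
                    weight = pn$edges$weight)
}

# small "key: value" text block; reals printed with 7 decimals
.write_kv <- function(x, path) {
  fmt1 <- function(v) {
    if (is.numeric(v) && length(v) == 1L) {
      if (is.na(v)) "NA"
      else if (v == floor(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
      else sprintf("%.7f", v)
    } else {
      as.character(v)
    }
  }
  writeLines(sprintf("%s: %s", names(x), vapply(x, fmt1, character(1))),
             path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.write_json <- function(x, path) {
  writeLines(jsonlite::toJSON(x, pretty = TRUE, auto_unbox = TRUE,
                              digits = NA, na = "null", dataframe = "rows"),
             path, sep = "\n", useBytes = TRUE)
  invisible(path)
}
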