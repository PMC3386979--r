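#' Construct a validated per-drug sales table
#'
#' @param drug_id character vector of unique drug identifiers.
#' @param sales non-negative finite sales values (uniform but arbitrary
#'   currency units).
#' @param class_code optional short therapeutic-class codes (ATC level-1
#'   style, e.g. "N", "C", "L").
#' @return A \code{data.frame} of class \code{sales_table}.
#' @export
sales_table <- function(drug_id, sales, class_code = NULL) {
  drug_id <- trimws(as.character(drug_id))
  .check_ids(drug_id, "drug_id")
  if (anyDuplicated(drug_id)) {
    stop("duplicate drug_id in sales table", call. = FALSE)
  }
  sales <- as.numeric(sales)
  if (length(sales) != length(drug_id) || anyNA(sales) ||
      any(!is.finite(sales)) || any(sales < 0)) {
    stop("sales must be non-negative finite numbers, one per drug",
         call. = FALSE)
  }
  out <- data.frame(drug_id = drug_id, sales = sales,
                    stringsAsFactors = FALSE)
  if (!is.null(class_code)) {
    class_code <- as.character(class_code)
    if (length(class_code) != length(drug_id)) {
      stop("class_code must match drug_id in length", call. = FALSE)
    }
    out$class_code <- class_code
  }
  structure(out, class = c("sales_table", "data.frame"))
}

#' Join a drug centrality table with a sales table
#'
#' Inner join on drug id, preserving the centrality-table row order.  Drugs
#' missing from either side are dropped (never imputed) and listed in the
#' join report.
#'
#' @param ct a drug-mode \code{\link{centrality_table}}.
#' @param st a \code{\link{sales_table}}.
#' @return A list with \code{x} (betweenness), \code{y} (sales),
#'   \code{drug_id}, and \code{report} (a list naming drugs dropped from
#'   either side).
#' @export
join_centrality_sales <- function(ct, st) {
  stopifnot(is.data.frame(ct), is.data.frame(st))
  if (!is.null(attr(ct, "mode")) && attr(ct, "mode") != "drug") {
    stop("centrality table must be for the drug-drug network", call. = FALSE)
  }
  keep <- ct$node_id %in% st$drug_id
  if (!any(keep)) stop("no joinable drugs between centrality and sales tables",
                       call. = FALSE)
  ids <- ct$node_id[keep]
  m <- match(ids, st$drug_id)
  list(
    drug_id = ids,
    x = ct$betweenness[keep],
    y = st$sales[m],
    report = list(
      n_joined = length(ids),
      dropped_from_centrality = ct$node_id[!keep],
      dropped_from_sales = setdiff(st$drug_id, ct$node_id)
    )
  )
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2));
#' the p-value comes from t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of
#' freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length n >= 3, each with nonzero
#'   variance.
#' @return A list with \code{n}, \code{r}, \code{p_t}.
#' @examples
#' pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)) # r = 0.8
#' @export
pearson <- function(x, y) {
  .check_xy(x, y)
  ht <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(n = length(x), r = unname(ht$estimate), p_t = ht$p.value)
}

.check_xy <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in input", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate vector: zero variance", call. = FALSE)
  }
  invisible(NULL)
}

#' Permutation p-value for a Pearson correlation
#'
#' Robustness companion to the parametric t-test (sales distributions are
#' heavy-tailed).  y is permuted \code{n_perm} times; the two-sided p-value
#' uses the add-one estimator (1 + #\{|r_perm| >= |r_obs|\}) / (n_perm + 1),
#' so the smallest attainable value is 1 / (n_perm + 1).
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @param n_perm number of permutations, at least 99.
#' @param seed integer seed; results are reproducible given the seed.
#' @return The permutation p-value in (0, 1].
#' @export
permutation_pvalue <- function(x, y, n_perm = 999L, seed = 1L) {
  .check_xy(x, y)
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 99L) {
    stop("n_perm must be at least 99", call. = FALSE)
  }
  r_obs <- abs(stats::cor(x, y))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (abs(stats::cor(x, sample(y))) >= r_obs) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Centrality-sales association for a drug cohort
#'
#' Joins the drug centrality table with the sales table, then correlates
#' betweenness centrality with sales (optionally log-transformed, the latent
#' scale on which the synthetic generator plants its correlation).  The
#' Pearson r with its t-test p-value is the headline statistic; a
#' permutation p-value is added as a distribution-free check.
#'
#' @param ct drug-mode \code{\link{centrality_table}}.
#' @param st \code{\link{sales_table}}.
#' @param log_sales correlate \code{log(sales)} instead of raw sales
#'   (requires strictly positive sales).
#' @param n_perm permutations for the permutation p-value; \code{0} skips it.
#' @param seed seed for the permutation test.
#' @return A list of class \code{association_result}: \code{n}, \code{r},
#'   \code{p_t}, \code{p_perm} (NA when skipped), \code{log_sales},
#'   \code{join_report}.
#' @export
associate <- function(ct, st, log_sales = FALSE, n_perm = 999L, seed = 1L) {
  j <- join_centrality_sales(ct, st)
  y <- j$y
  if (log_sales) {
    if (any(y <= 0)) {
      stop("log_sales requires strictly positive sales values", call. = FALSE)
    }
    y <- log(y)
  }
  pe <- pearson(j$x, y)
  p_perm <- if (n_perm >= 99L) {
    permutation_pvalue(j$x, y, n_perm = n_perm, seed = seed)
  } else {
    NA_real_
  }
  structure(
    list(n = pe$n, r = pe$r, p_t = pe$p_t, p_perm = p_perm,
         log_sales = log_sales, join_report = j$report),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("centrality-sales association (n = %d%s)\n", x$n,
              if (x$log_sales) ", log sales" else ""))
  cat(sprintf("  Pearson r = %.4f, t-test P = %.3g\n", x$r, x$p_t))
  if (!is.na(x$p_perm)) cat(sprintf("  permutation P = %.3g\n", x$p_perm))
  invisible(x)
}

# preserve caller RNG state around seeded operations
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
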