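# Shared TSV dialect: UTF-8, tab-delimited, "#" comment lines, optional
# header auto-detected by its canonical column names, LF line endings.

.read_tsv_lines <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !grepl("^#", lines)
  list(lines = lines[keep], lineno = which(keep))
}

.bad_line <- function(path, lineno, line, why) {
  stop(sprintf("%s: line %d (%s): %s", path, lineno, why, line),
       call. = FALSE)
}

#' Read a drug-target pair table (TSV)
#'
#' Two or three tab-separated columns: drug id, target id, optional positive
#' integer multiplicity (default 1).  Blank lines and lines starting with
#' \code{#} are skipped; a header line whose first two fields are
#' \code{drug_id} and \code{target_id} is recognized and dropped.  Malformed
#' lines are reported with their line number and content.
#'
#' @param path file path.
#' @return A \code{\link{drug_target_pairs}} table.
#' @export
read_pairs <- function(path) {
  tl <- .read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    stop(sprintf("%s: no data lines", path), call. = FALSE)
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  start <- 1L
  f1 <- fields[[1L]]
  if (length(f1) >= 2L && f1[1L] == "drug_id" && f1[2L] == "target_id") {
    start <- 2L
  }
  idx <- seq.int(start, length.out = length(fields) - start + 1L)
  if (length(idx) == 0L) stop(sprintf("%s: no data lines", path), call. = FALSE)
  d <- character(length(idx)); t <- character(length(idx))
  m <- integer(length(idx))
  for (i in seq_along(idx)) {
    f <- trimws(fields[[idx[i]]])
    ln <- tl$lineno[idx[i]]; raw <- tl$lines[idx[i]]
    if (length(f) < 2L || length(f) > 3L) {
      .bad_line(path, ln, raw, "expected 2 or 3 tab-separated fields")
    }
    if (!nzchar(f[1L]) || !nzchar(f[2L])) {
      .bad_line(path, ln, raw, "empty identifier")
    }
    if (length(f) == 3L) {
      if (!grepl("^[0-9]+$", f[3L]) || as.numeric(f[3L]) < 1) {
        .bad_line(path, ln, raw, "multiplicity is not a positive integer")
      }
      m[i] <- as.integer(f[3L])
    } else {
      m[i] <- 1L
    }
    d[i] <- f[1L]; t[i] <- f[2L]
  }
  drug_target_pairs(d, t, m)
}

#' Write a drug-target pair table (TSV)
#'
#' Canonical form: header \code{drug_id<TAB>target_id<TAB>multiplicity},
#' one record per line, LF endings.  \code{write_pairs(read_pairs(f), f)} is
#' byte-stable.
#'
#' @param pairs a \code{\link{drug_target_pairs}} table.
#' @param path file path.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(is.data.frame(pairs),
            all(c("drug_id", "target_id") %in% names(pairs)))
  mult <- if (is.null(pairs$multiplicity)) rep(1L, nrow(pairs)) else
    pairs$multiplicity
  lines <- c("drug_id\ttarget_id\tmultiplicity",
             sprintf("%s\t%s\t%d", pairs$drug_id, pairs$target_id,
                     as.integer(mult)))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a per-drug sales table (TSV)
#'
#' Columns: drug id, non-negative sales value, optional therapeutic class
#' code.  Same dialect as \code{\link{read_pairs}}; the recognized header is
#' \code{drug_id<TAB>sales[<TAB>class_code]}.
#'
#' @param path file path.
#' @return A \code{\link{sales_table}}.
#' @export
read_sales <- function(path) {
  tl <- .read_tsv_lines(path)
  if (length(tl$lines) == 0L) {
    stop(sprintf("%s: no data lines", path), call. = FALSE)
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  start <- 1L
  f1 <- fields[[1L]]
  if (length(f1) >= 2L && f1[1L] == "drug_id" && f1[2L] == "sales") start <- 2L
  idx <- seq.int(start, length.out = length(fields) - start + 1L)
  if (length(idx) == 0L) stop(sprintf("%s: no data lines", path), call. = FALSE)
  d <- character(length(idx)); s <- numeric(length(idx))
  cc <- character(length(idx)); has_cc <- FALSE
  for (i in seq_along(idx)) {
    f <- trimws(fields[[idx[i]]])
    ln <- tl$lineno[idx[i]]; raw <- tl$lines[idx[i]]
    if (length(f) < 2L || length(f) > 3L) {
      .bad_line(path, ln, raw, "expected 2 or 3 tab-separated fields")
    }
    val <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(val) || !is.finite(val) || val < 0) {
      .bad_line(path, ln, raw, "sales is not a non-negative number")
    }
    d[i] <- f[1L]; s[i] <- val
    if (length(f) == 3L) { cc[i] <- f[3L]; has_cc <- TRUE }
  }
  sales_table(d, s, class_code = if (has_cc) cc else NULL)
}

#' Write a per-drug sales table (TSV)
#'
#' Sales values are printed with \code{\%.17g} so the read-back value is
#' bit-identical.
#'
#' @param st a \code{\link{sales_table}}.
#' @param path file path.
#' @export
write_sales <- function(st, path) {
  stopifnot(is.data.frame(st), all(c("drug_id", "sales") %in% names(st)))
  if (is.null(st$class_code)) {
    lines <- c("drug_id\tsales",
               sprintf("%s\t%.17g", st$drug_id, st$sales))
  } else {
    lines <- c("drug_id\tsales\tclass_code",
               sprintf("%s\t%.17g\t%s", st$drug_id, st$sales, st$class_code))
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a ranked centrality table (TSV)
#'
#' Columns \code{rank}, \code{node_id}, \code{betweenness}, \code{degree};
#' betweenness is printed with 7 decimal places.
#'
#' @param ct a \code{\link{centrality_table}} (all nodes are ranked) or the
#'   output of \code{\link{rank_nodes}}.
#' @param path file path.
#' @export
write_centrality <- function(ct, path) {
  rk <- if ("rank" %in% names(ct)) ct else rank_nodes(ct, k = nrow(ct))
  deg <- if ("degree" %in% names(rk)) rk$degree else NA_integer_
  lines <- c("rank\tnode_id\tbetweenness\tdegree",
             sprintf("%d\t%s\t%.7f\t%d", rk$rank, rk$node_id,
                     rk$betweenness, deg))
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}
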