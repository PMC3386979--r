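# Pajek NET dialect: the undirected *Vertices/*Edges subset only.  Labels
# are double-quoted with internal quotes escaped by doubling; vertex ids are
# 1-based and contiguous in node order; edge lines are "i j w" with i < j.

.pajek_quote <- function(x) {
  sprintf("\"%s\"", gsub("\"", "\"\"", x, fixed = TRUE))
}

#' Write a projected network in Pajek NET format
#'
#' Emits \code{*Vertices n} with quoted labels in node order, then
#' \code{*Edges} lines \code{i j w} with integer shared-partner weights.
#' Isolates appear in the vertex block only.  Output is byte-stable for a
#' given network (LF endings).
#'
#' @param pn a \code{projected_network}.
#' @param path file path.
#' @export
write_pajek <- function(pn, path) {
  stopifnot(inherits(pn, "projected_network"))
  n <- length(pn$nodes)
  lines <- c(
    sprintf("*Vertices %d", n),
    sprintf("%d %s", seq_len(n), .pajek_quote(pn$nodes)),
    "*Edges"
  )
  if (nrow(pn$edges) > 0L) {
    fi <- match(pn$edges$from, pn$nodes)
    ti <- match(pn$edges$to, pn$nodes)
    lines <- c(lines, sprintf("%d %d %d", pmin(fi, ti), pmax(fi, ti),
                              pn$edges$weight))
  }
  writeLines(lines, path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a projected network from Pajek NET format
#'
#' Inverse of \code{\link{write_pajek}} on its own output.  Only the
#' undirected subset is supported: a \code{*Arcs} section is rejected.
#' Pajek files carry no drug/target mode, so the mode of the returned
#' network is supplied by the caller.
#'
#' @param path file path.
#' @param mode mode to stamp on the returned network.
#' @return A \code{\link{projected_network}}.
#' @export
read_pajek <- function(path, mode = c("drug", "target")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (any(grepl("^\\*Arcs", lines, ignore.case = TRUE))) {
    stop("directed networks unsupported (*Arcs section present)",
         call. = FALSE)
  }
  vhead <- grep("^\\*Vertices", lines, ignore.case = TRUE)
  ehead <- grep("^\\*Edges", lines, ignore.case = TRUE)
  if (length(vhead) != 1L || length(ehead) != 1L || ehead < vhead) {
    stop(sprintf("%s: expected one *Vertices and one *Edges section", path),
         call. = FALSE)
  }
  n <- as.integer(sub("^\\*Vertices\\s+", "", lines[vhead],
                      ignore.case = TRUE))
  if (is.na(n)) stop(sprintf("%s: bad *Vertices count", path), call. = FALSE)
  vlines <- lines[seq.int(vhead + 1L, length.out = ehead - vhead - 1L)]
  vlines <- vlines[nzchar(trimws(vlines))]
  if (length(vlines) != n) {
    stop(sprintf("%s: vertex count %d does not match *Vertices %d", path,
                 length(vlines), n), call. = FALSE)
  }
  vm <- regmatches(vlines, regexec('^\\s*(\\d+)\\s+"(.*)"\\s*$', vlines))
  nodes <- character(n)
  for (i in seq_len(n)) {
    if (length(vm[[i]]) != 3L) {
      stop(sprintf("%s: malformed vertex line: %s", path, vlines[i]),
           call. = FALSE)
    }
    id <- as.integer(vm[[i]][2L])
    if (id != i) {
      stop(sprintf("%s: vertex ids must be contiguous 1..n (got %d at row %d)",
                   path, id, i), call. = FALSE)
    }
    nodes[i] <- gsub("\"\"", "\"", vm[[i]][3L], fixed = TRUE)
  }
  elines <- if (ehead < length(lines)) lines[seq.int(ehead + 1L,
                                                     length(lines))] else
    character(0)
  elines <- elines[nzchar(trimws(elines))]
  fi <- ti <- integer(length(elines)); w <- integer(length(elines))
  for (i in seq_along(elines)) {
    f <- strsplit(trimws(elines[i]), "\\s+")[[1L]]
    if (length(f) < 2L || length(f) > 3L || anyNA(suppressWarnings(
      as.integer(f)))) {
      stop(sprintf("%s: malformed edge line: %s", path, elines[i]),
           call. = FALSE)
    }
    fi[i] <- as.integer(f[1L]); ti[i] <- as.integer(f[2L])
    w[i] <- if (length(f) == 3L) as.integer(f[3L]) else 1L
    if (fi[i] < 1L || fi[i] > n || ti[i] < 1L || ti[i] > n) {
      stop(sprintf("%s: edge endpoint out of range: %s", path, elines[i]),
           call. = FALSE)
    }
  }
  projected_network(mode = mode, nodes = nodes,
                    from = nodes[fi], to = nodes[ti], weight = w)
}
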