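#' Construct a validated table of drug-target interaction pairs
#'
#' One row per observed drug-target interaction.  Identifiers are taken
#' verbatim (case-sensitive) after trimming surrounding whitespace; they must
#' be non-empty and may not contain tab characters, which delimit the on-disk
#' format.  \code{multiplicity} records the interaction frequency carried by
#' the two-mode network's edge weights; it never influences one-mode
#' projections or per-drug target counts, which use distinct edges only.
#'
#' @param drug_id character vector of drug identifiers.
#' @param target_id character vector of target identifiers, same length.
#' @param multiplicity positive integer vector (recycled if length 1).
#' @return A \code{data.frame} of class \code{drug_target_pairs} with columns
#'   \code{drug_id}, \code{target_id}, \code{multiplicity}.
#' @examples
#' drug_target_pairs(c("GLEEVEC", "GLEEVEC"), c("POTPKABL1", "BPDGFR"))
#' @export
drug_target_pairs <- function(drug_id, target_id, multiplicity = 1L) {
  drug_id <- trimws(as.character(drug_id))
  target_id <- trimws(as.character(target_id))
  if (length(drug_id) != length(target_id)) {
    stop("drug_id and target_id must have the same length", call. = FALSE)
  }
  if (length(multiplicity) == 1L) {
    multiplicity <- rep(multiplicity, length(drug_id))
  }
  if (length(multiplicity) != length(drug_id)) {
    stop("multiplicity must have length 1 or length(drug_id)", call. = FALSE)
  }
  .check_ids(drug_id, "drug_id")
  .check_ids(target_id, "target_id")
  m <- suppressWarnings(as.numeric(multiplicity))
  if (anyNA(m) || any(m < 1) || any(m != floor(m))) {
    stop("multiplicity must be a positive integer (>= 1)", call. = FALSE)
  }
  structure(
    data.frame(
      drug_id = drug_id,
      target_id = target_id,
      multiplicity = as.integer(m),
      stringsAsFactors = FALSE
    ),
    class = c("drug_target_pairs", "data.frame")
  )
}

.check_ids <- function(ids, what) {
  if (any(is.na(ids)) || any(!nzchar(ids))) {
    stop(sprintf("%s contains empty or missing identifiers", what),
         call. = FALSE)
  }
  if (any(grepl("\t", ids, fixed = TRUE))) {
    stop(sprintf("%s contains tab characters (the field delimiter)", what),
         call. = FALSE)
  }
  invisible(ids)
}

#' @export
print.drug_target_pairs <- function(x, ...) {
  cat(sprintf("drug-target pairs: %d records, %d drugs, %d targets\n",
              nrow(x), length(unique(x$drug_id)),
              length(unique(x$target_id))))
  NextMethod()
}
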