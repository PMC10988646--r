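# Expression matrix container: miRNA x subject counts with presence semantics.
# A zero count means the miRNA was not detected in that subject; there is no
# separate missingness channel.

#' Construct an expression matrix
#'
#' @param counts numeric matrix, miRNAs in rows, subjects in columns;
#'   dimnames required and unique; all cells finite and non-negative.
#' @param normalized logical; TRUE when each subject column has been
#'   divided by its total (columns then sum to 1 within 1e-9).
#' @return An \code{expression_matrix} object.
#' @export
expression_matrix <- function(counts, normalized = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    validation_error("counts must be a numeric matrix")
  }
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts)))) {
    validation_error("counts must carry miRNA rownames and subject colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    validation_error("duplicate miRNA ids in counts matrix")
  }
  if (anyDuplicated(colnames(counts))) {
    validation_error("duplicate subject ids in counts matrix")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    validation_error("counts must be finite and non-negative")
  }
  if (normalized) {
    # a freshly normalized matrix has unit column sums; a row subset of
    # one (e.g. after the presence filter) keeps fractions but sums < 1
    if (any(counts > 1 + 1e-9) || any(colSums(counts) > 1 + 1e-9)) {
      validation_error("normalized matrix cells must be fractions of the subject total")
    }
  }
  structure(list(counts = counts, normalized = normalized),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d miRNAs x %d subjects (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' miRNA ids of an expression matrix
#' @param m an \code{\link{expression_matrix}}
#' @return Character vector of miRNA ids.
#' @export
mirna_ids <- function(m) rownames(m$counts)

#' Subject ids of an expression matrix
#' @param m an \code{\link{expression_matrix}}
#' @return Character vector of subject ids.
#' @export
subject_ids <- function(m) colnames(m$counts)

#' Presence indicator matrix
#'
#' A miRNA is "present" in a subject when its count is strictly positive.
#'
#' @param m an \code{\link{expression_matrix}}
#' @return Logical matrix of the same shape as the counts.
#' @export
presence <- function(m) m$counts > 0

#' Per-subject total-count normalization
#'
#' Divides every subject column by its total so that columns sum to 1,
#' removing library-size differences before ranking.
#'
#' @param m raw \code{\link{expression_matrix}}
#' @return Normalized \code{expression_matrix}.
#' @export
normalize_per_subject <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$normalized) usage_error("matrix is already normalized")
  totals <- colSums(m$counts)
  if (any(totals <= 0)) {
    validation_error(paste0("subject column(s) with zero total counts: ",
                            paste(colnames(m$counts)[totals <= 0],
                                  collapse = ", ")))
  }
  out <- expression_matrix(sweep(m$counts, 2L, totals, "/"), normalized = TRUE)
  stopifnot(all(abs(colSums(out$counts) - 1) < 1e-9))
  out
}

#' Minimum-presence filter
#'
#' Retains exactly the miRNAs detected (nonzero count) in at least
#' \code{min_present} subjects; row order is preserved. The boundary is
#' inclusive: presence in exactly \code{min_present} subjects keeps the
#' miRNA.
#'
#' @param m an \code{\link{expression_matrix}}
#' @param min_present minimum number of subjects with a nonzero count
#'   (default 11)
#' @return Filtered \code{expression_matrix} (possibly with zero rows).
#' @export
presence_filter <- function(m, min_present = 11L) {
  stopifnot(inherits(m, "expression_matrix"))
  if (min_present < 1L) usage_error("min_present must be >= 1")
  keep <- rowSums(m$counts > 0) >= min_present
  expression_matrix(m$counts[keep, , drop = FALSE], normalized = m$normalized)
}
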