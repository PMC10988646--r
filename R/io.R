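# Readers and writers for every tabular format the pipeline touches.
# Counts travel as tab-separated miRNA x subject tables (StringTie-style
# gene-by-sample layout); phenotypes as CSV/TSV with documented column
# names; association records and edge matrices as CSV. All numeric text
# uses 6 significant digits so outputs are byte-deterministic.

#' Read a miRNA count table
#'
#' First column = miRNA ids, remaining columns = subject ids; cells must
#' be numeric and non-negative. Duplicate miRNA ids are rejected.
#'
#' @param path path to a tab-separated counts file
#' @return A raw \code{\link{expression_matrix}}.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) schema_error("counts file needs an id column plus >= 1 subject")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    validation_error(paste0("duplicate miRNA id(s) in counts file: ",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
                dimnames = list(ids, names(df)[-1]))
  for (j in seq_len(ncol(mat))) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      parse_error(sprintf(
        "invalid count '%s' at row '%s', column '%s' (must be numeric and >= 0)",
        df[[j + 1L]][bad[1]], ids[bad[1]], colnames(mat)[j]))
    }
    mat[, j] <- v
  }
  expression_matrix(mat, normalized = FALSE)
}

#' Write a miRNA count table
#'
#' @param m an \code{\link{expression_matrix}}
#' @param path output path (tab-separated)
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(mirna = rownames(m$counts),
                   apply(m$counts, 2L, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-subject phenotype table
#'
#' Accepts comma- or tab-separated files (sniffed from the header line)
#' and validates through \code{\link{cohort_table}}: ordinal columns must
#' use their enumerated levels and the Braak-derived group column is
#' recomputed, never read.
#'
#' @param path path to the phenotype file
#' @param domain_map named list of test names per domain
#' @return A validated \code{\link{cohort_table}}.
#' @export
read_phenotypes <- function(path, domain_map = default_domain_map()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  cohort_table(df, domain_map = domain_map)
}

#' Write a per-subject phenotype table
#'
#' @param cohort a \code{\link{cohort_table}}
#' @param path output path
#' @param sep field separator (default comma)
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(cohort, path, sep = ",") {
  df <- as.data.frame(cohort)
  df$group <- NULL  # derived; recomputed on read
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write association records as CSV
#'
#' @param records output of \code{\link{screen_associations}}
#' @param path output path
#' @return \code{path}, invisibly.
#' @export
write_associations <- function(records, path) {
  df <- as.data.frame(records)
  for (col in c("rho", "p_value", "q_value")) df[[col]] <- fmt_num(df[[col]])
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association records written by \code{write_associations}
#' @param path path to the CSV
#' @return An \code{association_records} data.frame.
#' @export
read_associations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$q_value <- suppressWarnings(as.numeric(df$q_value))
  class(df) <- c("association_records", "data.frame")
  df
}

#' Write the network edge matrix
#'
#' One row per edge: mirna, hub, sign, rho, p, weight (= 100 |rho|), in
#' deterministic order (hub, then miRNA, lexicographic). An empty network
#' yields a header-only file.
#'
#' @param net a \code{\link{build_network}} result
#' @param path output path (CSV)
#' @return \code{path}, invisibly.
#' @export
write_edge_matrix <- function(net, path) {
  stopifnot(inherits(net, "phenotype_network"))
  e <- net$edges
  e <- e[order(e$hub, e$mirna), , drop = FALSE]
  out <- data.frame(mirna = e$mirna, hub = e$hub, sign = e$sign,
                    rho = fmt_num(e$rho), p = fmt_num(e$p),
                    weight = fmt_num(e$weight), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge matrix back into edge records
#' @param path path to a CSV written by \code{\link{write_edge_matrix}}
#' @return data.frame with columns mirna, hub, sign, rho, p, weight.
#' @export
read_edge_matrix <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

INTERACTION_CATEGORIES <- c("Amyloid associated", "Tau associated",
                            "Cytokine", "Transcription factor")
INTERACTION_SOURCES <- c("starmir-like", "tarbase-like")

#' Read a miRNA-mRNA interaction-prediction table
#'
#' Tab-separated with columns mirna, gene, accession, site, logit_prob,
#' category, source, source_score. Categories and sources must come from
#' their enumerated vocabularies; when a gene panel is supplied, genes
#' outside the panel are rejected.
#'
#' @param path path to the TSV
#' @param panel optional \code{\link{default_gene_panel}}-shaped
#'   data.frame used to validate gene symbols
#' @return An \code{interaction_table} data.frame.
#' @export
read_interactions <- function(path, panel = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("mirna", "gene", "accession", "site", "logit_prob",
                "category", "source", "source_score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    schema_error(paste0("interaction table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  interaction_table(df, panel = panel)
}

#' Construct and validate an interaction table
#'
#' @param df data.frame with the interaction columns (see
#'   \code{\link{read_interactions}})
#' @param panel optional gene panel for symbol validation
#' @return An \code{interaction_table} data.frame.
#' @export
interaction_table <- function(df, panel = NULL) {
  if (nrow(df)) {
    bad_cat <- setdiff(unique(df$category), INTERACTION_CATEGORIES)
    if (length(bad_cat)) {
      validation_error(paste0("unknown interaction category: ",
                              paste(bad_cat, collapse = ", ")))
    }
    bad_src <- setdiff(unique(df$source), INTERACTION_SOURCES)
    if (length(bad_src)) {
      validation_error(paste0("unknown interaction source: ",
                              paste(bad_src, collapse = ", ")))
    }
    df$logit_prob <- as.numeric(df$logit_prob)
    if (any(!is.finite(df$logit_prob))) {
      validation_error("logit_prob must be finite")
    }
    df$source_score <- suppressWarnings(as.numeric(df$source_score))
    if (!is.null(panel)) {
      bad_gene <- setdiff(unique(df$gene), panel$gene)
      if (length(bad_gene)) {
        validation_error(paste0("gene(s) outside the configured panel: ",
                                paste(bad_gene, collapse = ", ")))
      }
    }
  }
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Write an interaction table
#' @param t an \code{interaction_table}
#' @param path output path (TSV)
#' @return \code{path}, invisibly.
#' @export
write_interactions <- function(t, path) {
  df <- as.data.frame(t)
  if (nrow(df)) {
    df$logit_prob <- fmt_num(df$logit_prob)
    df$source_score <- ifelse(is.na(df$source_score), "",
                              fmt_num(df$source_score))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
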