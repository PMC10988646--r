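# small in-code fixtures shared across test files

tiny_counts <- function() {
  m <- matrix(c(2, 3, 5,
                1, 0, 4,
                0, 7, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("miR-a", "miR-b", "miR-c"),
                              c("S1", "S2", "S3")))
  expression_matrix(m)
}

tiny_cohort <- function(seed = 1L, n_mirna = 30L, ...) {
  simulate_cohort(simulation_spec(seed = seed, n_mirna = n_mirna, ...))
}

# hand-built association records for network tests
make_records <- function(df) {
  n <- nrow(df)
  rec <- data.frame(
    mirna = as.character(df[["mirna"]]),
    phenotype = as.character(df[["phenotype"]]),
    statistic = rep("spearman_rho", n), rho = as.numeric(df[["rho"]]),
    p_value = if (is.null(df[["p"]])) rep(0.01, n) else df[["p"]],
    n_used = rep(26L, n), q_value = rep(NA_real_, n),
    sign = ifelse(df[["rho"]] > 0, "positive", "negative"),
    highlight = rep(FALSE, n), significant = rep(TRUE, n),
    stringsAsFactors = FALSE)
  class(rec) <- c("association_records", "data.frame")
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

interaction_row <- function(mirna, gene, logit = 1, n_sites = 1,
                            source = "starmir-like", score = NA_real_) {
  panel <- default_gene_panel()
  i <- match(gene, panel$gene)
  data.frame(mirna = mirna, gene = gene, accession = panel$accession[i],
             site = sprintf("site_%d", seq_len(n_sites)),
             logit_prob = logit, category = panel$category[i],
             source = source, source_score = score,
             stringsAsFactors = FALSE)
}

make_interactions <- function(...) {
  interaction_table(do.call(rbind, list(...)))
}
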