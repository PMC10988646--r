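# Target-prediction post-processing: validated-interaction filtering,
# site-to-hit deduplication, logit-probability screening, gene-count
# adjusted connectivity scores and the bipartite miRNA-gene network.

#' Default AD-related gene panel
#'
#' The 16-gene panel probed against the resilience-related miRNAs:
#' amyloid-processing genes, tau kinases and tau itself, the REST
#' transcription factor and inflammatory cytokines, with RefSeq
#' accessions.
#'
#' @return data.frame (\code{gene_panel}) with columns gene, accession,
#'   category.
#' @export
default_gene_panel <- function() {
  df <- data.frame(
    gene = c("ADAM10", "ADAM17", "APP", "BACE1", "CDK5", "GSK3A", "GSK3B",
             "MAPT", "MME", "PSEN1", "PSEN2", "REST", "MAPK13", "IL1A",
             "IL1B", "IL6"),
    accession = c("NM_001110.4", "NM_003183.6", "NM_000484.4", "NM_012104.6",
                  "NM_004935.4", "NM_019884.3", "NM_002093.4",
                  "NM_001377265.1", "NM_007288.3", "NM_000021.4",
                  "NM_000447.3", "NM_001363453.2", "NM_002754.5",
                  "NM_000575.5", "NM_000576.3", "NM_000600.5"),
    category = c("Amyloid associated", "Amyloid associated",
                 "Amyloid associated", "Amyloid associated",
                 "Tau associated", "Tau associated", "Tau associated",
                 "Tau associated", "Amyloid associated",
                 "Amyloid associated", "Amyloid associated",
                 "Transcription factor", "Tau associated", "Cytokine",
                 "Cytokine", "Cytokine"),
    stringsAsFactors = FALSE)
  class(df) <- c("gene_panel", "data.frame")
  df
}

#' Resilience-related miRNA list
#'
#' The 12 miRNA entries differentially expressed between low (I/II) and
#' high (III/IV) Braak-stage groups in the cohort this package emulates:
#' 8 upregulated and 4 down-regulated (each named cluster counts as one
#' entry). Packaged as demo input for connectivity analyses.
#'
#' @return data.frame with columns mirna, direction ("up"/"down").
#' @export
resilience_mirnas <- function() {
  data.frame(
    mirna = c("miR-12121", "miR-134", "miR-3137", "miR-4528",
              "miR-4639-3p/548a-3p", "miR-4705", "miR-5692b", "miR-617",
              "miR-12118", "miR-1320/8061", "miR-4521", "miR-548aj-5p"),
    direction = c(rep("up", 8L), rep("down", 4L)),
    stringsAsFactors = FALSE)
}

#' Filter validated interactions by prediction score
#'
#' Keeps tarbase-like records whose prediction score reaches
#' \code{min_score} (inclusive boundary); starmir-like records pass
#' through unchanged (they are screened later by logit probability).
#'
#' @param t an \code{interaction_table}
#' @param min_score minimum prediction score for validated-interaction
#'   sources (default 0.8)
#' @return Filtered \code{interaction_table}.
#' @export
filter_validated <- function(t, min_score = 0.8) {
  stopifnot(inherits(t, "interaction_table"))
  if (nrow(t) == 0L) return(t)
  tarb <- t$source == "tarbase-like"
  if (any(tarb & is.na(t$source_score))) {
    validation_error("tarbase-like record(s) missing source_score")
  }
  keep <- !tarb | t$source_score >= min_score
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deduplicate predicted sites into hits
#'
#' Multiple predicted sites of one miRNA on one mRNA count as a single
#' hit: the result has one row per distinct (miRNA, gene) pair.
#'
#' @param t an \code{interaction_table}
#' @return data.frame with columns mirna, gene.
#' @export
dedup_hits <- function(t) {
  if (nrow(t) == 0L) {
    return(data.frame(mirna = character(), gene = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(as.data.frame(t)[, c("mirna", "gene")])
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-count-adjusted connectivity scores
#'
#' Drops predicted sites below the minimum logit probability, collapses
#' the survivors into distinct (miRNA, gene) hits, counts hits per gene,
#' and scores each panel category as total hits over the category's
#' genes divided by the number of panel genes in that category (genes
#' with zero hits stay in the denominator).
#'
#' @param t an \code{interaction_table} restricted to panel genes
#' @param panel a \code{\link{default_gene_panel}}-shaped data.frame
#' @param logit_min minimum logit probability for a site to survive
#' @return List (\code{connectivity_result}) with \code{gene_hits}
#'   (gene, category, hits), \code{category_scores} (category, n_genes,
#'   total_hits, score), \code{surviving} (the deduplicated hit pairs)
#'   and \code{logit_min}.
#' @export
connectivity_scores <- function(t, panel = default_gene_panel(), logit_min) {
  stopifnot(inherits(t, "interaction_table"))
  if (missing(logit_min)) usage_error("logit_min must be supplied")
  if (any(table(panel$category) == 0)) {
    validation_error("empty gene panel category")
  }
  bad <- setdiff(unique(t$gene), panel$gene)
  if (length(bad)) {
    validation_error(paste0("interaction gene(s) outside panel: ",
                            paste(bad, collapse = ", ")))
  }
  surv <- t[t$logit_prob >= logit_min, , drop = FALSE]
  hits <- dedup_hits(surv)
  gene_hits <- data.frame(
    gene = panel$gene, category = panel$category,
    hits = as.integer(table(factor(hits$gene, levels = panel$gene))),
    stringsAsFactors = FALSE)
  cats <- sort(unique(panel$category))
  category_scores <- data.frame(
    category = cats,
    n_genes = as.integer(table(factor(panel$category, levels = cats))),
    total_hits = vapply(cats, function(cc) {
      sum(gene_hits$hits[gene_hits$category == cc])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  category_scores$score <- category_scores$total_hits / category_scores$n_genes
  rownames(category_scores) <- NULL
  structure(list(gene_hits = gene_hits, category_scores = category_scores,
                 surviving = hits, logit_min = logit_min),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("connectivity_result: %d surviving hits (logit_min %s)\n",
              nrow(x$surviving), fmt_num(x$logit_min)))
  print(x$category_scores)
  invisible(x)
}

#' Bipartite miRNA-gene target network
#'
#' Gene nodes (attribute: category as sign surrogate, hit count as
#' degree) linked to the miRNA nodes predicted to regulate them, shaped
#' like a phenotype network so it exports through
#' \code{\link{write_graph_file}}. Panel genes without surviving hits
#' appear as isolated nodes.
#'
#' @param res a \code{\link{connectivity_scores}} result
#' @param panel the gene panel used
#' @return A \code{phenotype_network}-classed bipartite graph with gene
#'   hubs and miRNA leaves; edge weight 1 per hit.
#' @export
bipartite_target_network <- function(res, panel = default_gene_panel()) {
  stopifnot(inherits(res, "connectivity_result"))
  hits <- res$surviving
  gene_nodes <- data.frame(id = panel$gene, kind = "gene",
                           sign = panel$category, stringsAsFactors = FALSE)
  mir_ids <- sort(unique(hits$mirna))
  mir_nodes <- data.frame(id = mir_ids,
                          kind = rep("mirna", length(mir_ids)),
                          sign = rep("none", length(mir_ids)),
                          stringsAsFactors = FALSE)
  nodes <- rbind(gene_nodes, mir_nodes)
  deg <- table(c(hits$gene, hits$mirna))
  nodes$degree <- as.integer(deg[nodes$id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  nh <- nrow(hits)
  edges <- data.frame(mirna = hits$mirna, hub = hits$gene,
                      sign = rep("none", nh), rho = rep(NA_real_, nh),
                      p = rep(NA_real_, nh), weight = rep(1, nh),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, coordinates = NULL),
            class = "phenotype_network")
}

#' Simulate a StarMir-style interaction-prediction table (synthetic)
#'
#' Generates a synthetic prediction table for demonstration and testing:
#' each (miRNA, gene) pair receives 0-3 predicted sites with logit
#' probabilities drawn uniformly, so that after screening each gene is
#' typically regulated by several miRNA species. This stands in for an
#' exported prediction-tool table; it carries no biological information.
#'
#' @param mirnas character vector of miRNA ids
#'   (default \code{resilience_mirnas()$mirna})
#' @param panel gene panel (default \code{\link{default_gene_panel}})
#' @param seed integer seed
#' @param site_lambda mean number of predicted sites per (miRNA, gene)
#'   pair (Poisson; default 1.2)
#' @param logit_range range of the uniform logit probabilities
#' @return An \code{interaction_table}.
#' @export
simulate_interactions <- function(mirnas = resilience_mirnas()$mirna,
                                  panel = default_gene_panel(), seed = 1L,
                                  site_lambda = 1.2,
                                  logit_range = c(-0.5, 1.5)) {
  set.seed(seed)
  rows <- list()
  for (m in mirnas) {
    for (gi in seq_len(nrow(panel))) {
      n_sites <- stats::rpois(1L, site_lambda)
      if (n_sites == 0L) next
      pos <- sort(sample.int(2000L, n_sites))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = m, gene = panel$gene[gi], accession = panel$accession[gi],
        site = sprintf("site_%d-%d", pos, pos + 21L),
        logit_prob = round(stats::runif(n_sites, logit_range[1],
                                        logit_range[2]), 4),
        category = panel$category[gi], source = "starmir-like",
        source_score = NA_real_, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), gene = character(),
               accession = character(), site = character(),
               logit_prob = numeric(), category = character(),
               source = character(), source_score = numeric(),
               stringsAsFactors = FALSE)
  rownames(df) <- NULL
  interaction_table(df, panel = panel)
}
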