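# End-to-end orchestration. Each run_* stage writes its outputs under
# out_dir, appends to a JSON run manifest (config snapshot, seed, file
# digests, row counts, timestamps) and is deterministic given config +
# seed; reruns differ only in manifest timestamps.

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

load_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = FALSE)
  else list(tool = "mirphenet",
            version = as.character(utils::packageVersion("mirphenet")),
            stages = list())
}

record_stage <- function(out_dir, stage, config, seed, files) {
  man <- load_manifest(out_dir)
  entries <- lapply(files, function(f) {
    list(path = basename(f$path),
         md5 = unname(tools::md5sum(f$path)),
         rows = f$rows)
  })
  man$stages[[stage]] <- list(
    config = config, seed = seed, outputs = entries,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, manifest_path(out_dir), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(man)
}

count_lines <- function(path) max(0L, length(readLines(path)) - 1L)

#' Simulate a study and write its input files
#'
#' Writes the phenotype CSV, counts TSV and planted ground-truth CSV for
#' a simulated study, plus a manifest entry. Bit-identical on rerun with
#' the same spec.
#'
#' @param spec a \code{\link{simulation_spec}}
#' @param out_dir output directory (created if needed)
#' @return List with the cohort, the count matrix and the written paths.
#' @export
run_simulate <- function(spec = simulation_spec(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(spec)
  counts <- simulate_counts(spec, cohort)
  truth <- ground_truth(spec)
  p_pheno <- file.path(out_dir, "phenotypes.csv")
  p_counts <- file.path(out_dir, "counts.tsv")
  p_truth <- file.path(out_dir, "ground_truth.csv")
  write_phenotypes(cohort, p_pheno)
  write_counts(counts, p_counts)
  utils::write.table(truth, p_truth, sep = ",", quote = FALSE,
                     row.names = FALSE)
  record_stage(out_dir, "simulate", unclass(spec), spec$seed,
               list(list(path = p_pheno, rows = nrow(cohort)),
                    list(path = p_counts, rows = nrow(counts$counts)),
                    list(path = p_truth, rows = nrow(truth))))
  list(cohort = cohort, counts = counts,
       paths = c(phenotypes = p_pheno, counts = p_counts,
                 ground_truth = p_truth))
}

#' Run the association screen stage
#'
#' Normalization, presence filter, rank-correlation screen and summary
#' tables; writes records and summaries as CSV and logs stage counts.
#'
#' @param counts raw \code{\link{expression_matrix}} (or path to a
#'   counts TSV)
#' @param cohort \code{\link{cohort_table}} (or path to a phenotype file)
#' @param cfg an \code{\link{analysis_config}}
#' @param out_dir output directory
#' @return List with the records, the summary table and written paths.
#' @export
run_associate <- function(counts, cohort, cfg = analysis_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(cohort)) cohort <- read_phenotypes(cohort)
  norm <- normalize_per_subject(counts)
  filtered <- presence_filter(norm, cfg$min_present)
  if (nrow(filtered$counts) == 0L) {
    warning("no miRNA passes the presence filter; record file is empty",
            call. = FALSE)
  }
  message(sprintf("associate: %d miRNAs in, %d pass presence filter (>= %d subjects)",
                  nrow(counts$counts), nrow(filtered$counts), cfg$min_present))
  records <- if (nrow(filtered$counts)) {
    screen_associations(filtered, cohort, cfg)
  } else {
    screen_empty()
  }
  message(sprintf("associate: %d significant records at p < %s",
                  nrow(records), fmt_num(cfg$alpha)))
  summaries <- association_summary_table(records)
  p_rec <- file.path(out_dir, "associations.csv")
  p_sum <- file.path(out_dir, "association_summaries.csv")
  write_associations(records, p_rec)
  utils::write.table(
    data.frame(summaries[, c("phenotype", "sign", "count")],
               median_rho = fmt_num(summaries$median_rho),
               rho_min = fmt_num(summaries$rho_min),
               rho_max = fmt_num(summaries$rho_max),
               n_highlighted = summaries$n_highlighted),
    p_sum, sep = ",", quote = FALSE, row.names = FALSE)
  record_stage(out_dir, "associate",
               unclass(cfg), cfg$seed,
               list(list(path = p_rec, rows = nrow(records)),
                    list(path = p_sum, rows = nrow(summaries))))
  list(records = records, summaries = summaries,
       paths = c(associations = p_rec, summaries = p_sum))
}

screen_empty <- function() {
  rec <- data.frame(mirna = character(), phenotype = character(),
                    statistic = character(), rho = numeric(),
                    p_value = numeric(), n_used = integer(),
                    q_value = numeric(), sign = character(),
                    highlight = logical(), significant = logical(),
                    stringsAsFactors = FALSE)
  class(rec) <- c("association_records", "data.frame")
  rec
}

#' Run the network stage
#'
#' Builds the signed phenotype-hub network from association records,
#' computes the gravity layout, and writes the edge matrix, degree table
#' and graph exports.
#'
#' @param records \code{\link{screen_associations}} output (or path to a
#'   records CSV)
#' @param out_dir output directory
#' @param format graph export format(s), subset of
#'   \code{c("gexf", "graphml")}
#' @param seed layout seed
#' @param layout_iter layout iteration cap
#' @return List with the network, the layout and written paths.
#' @export
run_network <- function(records, out_dir, format = c("gexf", "graphml"),
                        seed = 1L, layout_iter = 100L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(records)) records <- read_associations(records)
  net <- build_network(records)
  if (nrow(net$nodes)) {
    lay <- two_step_gravity_layout(net, seed = seed, max_iter = layout_iter)
    net <- set_layout(net, lay)
  } else lay <- NULL
  p_edge <- file.path(out_dir, "edge_matrix.csv")
  p_deg <- file.path(out_dir, "degree_table.csv")
  write_edge_matrix(net, p_edge)
  utils::write.table(degree_table(net), p_deg, sep = ",", quote = FALSE,
                     row.names = FALSE)
  files <- list(list(path = p_edge, rows = nrow(net$edges)),
                list(path = p_deg, rows = nrow(net$nodes)))
  for (f in format) {
    p_g <- file.path(out_dir, paste0("network.", f))
    write_graph_file(net, p_g, format = f)
    files[[length(files) + 1L]] <- list(path = p_g, rows = nrow(net$nodes))
  }
  record_stage(out_dir, "network", list(format = format, seed = seed),
               seed, files)
  list(network = net, layout = lay,
       paths = c(edge_matrix = p_edge, degree_table = p_deg))
}

#' Run the group-statistics stage
#'
#' Writes the subject-characteristics summary with its chi-square /
#' Kruskal-Wallis test column and the Dunn post hoc table for age.
#'
#' @param cohort a \code{\link{cohort_table}} (or path)
#' @param out_dir output directory
#' @return List with the summary table and written paths.
#' @export
run_groupstats <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(cohort)) cohort <- read_phenotypes(cohort)
  summ <- cohort_summary(cohort)
  p_sum <- file.path(out_dir, "group_summary.csv")
  out <- summ
  out$statistic <- fmt_num(out$statistic)
  out$p_value <- fmt_num(out$p_value)
  utils::write.table(out, p_sum, sep = ",", quote = FALSE, row.names = FALSE)
  dunn <- dunn_posthoc(split(cohort$age_at_death, cohort$group),
                       adjust = "bonferroni")
  p_dunn <- file.path(out_dir, "dunn_age.csv")
  dunn$dunn_z <- fmt_num(dunn$dunn_z)
  dunn$p_value <- fmt_num(dunn$p_value)
  dunn$p_adjusted <- fmt_num(dunn$p_adjusted)
  utils::write.table(dunn, p_dunn, sep = ",", quote = FALSE, row.names = FALSE)
  record_stage(out_dir, "groupstats", list(), NA,
               list(list(path = p_sum, rows = nrow(summ)),
                    list(path = p_dunn, rows = nrow(dunn))))
  list(summary = summ, paths = c(summary = p_sum, dunn = p_dunn))
}

#' Run the target-connectivity stage
#'
#' Validated-interaction filtering, logit screening, connectivity
#' scoring and the bipartite gene-miRNA graph export.
#'
#' @param interactions an \code{interaction_table} (or path to a TSV)
#' @param panel gene panel
#' @param cfg an \code{\link{analysis_config}} (supplies
#'   \code{logit_min} and \code{tarbase_min_score})
#' @param out_dir output directory
#' @param format graph export format
#' @return List with the connectivity result and written paths.
#' @export
run_connectivity <- function(interactions, panel = default_gene_panel(),
                             cfg = analysis_config(), out_dir,
                             format = "gexf") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(interactions)) {
    interactions <- read_interactions(interactions, panel = panel)
  }
  kept <- filter_validated(interactions, cfg$tarbase_min_score)
  res <- connectivity_scores(kept, panel, logit_min = cfg$logit_min)
  p_scores <- file.path(out_dir, "connectivity_scores.csv")
  sc <- res$category_scores
  sc$score <- fmt_num(sc$score)
  utils::write.table(sc, p_scores, sep = ",", quote = FALSE, row.names = FALSE)
  p_hits <- file.path(out_dir, "gene_hits.csv")
  utils::write.table(res$gene_hits, p_hits, sep = ",", quote = FALSE,
                     row.names = FALSE)
  net <- bipartite_target_network(res, panel)
  p_g <- file.path(out_dir, paste0("target_network.", format))
  write_graph_file(net, p_g, format = format)
  record_stage(out_dir, "connectivity",
               list(logit_min = cfg$logit_min,
                    tarbase_min_score = cfg$tarbase_min_score),
               cfg$seed,
               list(list(path = p_scores, rows = nrow(sc)),
                    list(path = p_hits, rows = nrow(res$gene_hits)),
                    list(path = p_g, rows = nrow(net$nodes))))
  list(result = res, network = net,
       paths = c(scores = p_scores, gene_hits = p_hits, graph = p_g))
}

#' Run the full pipeline
#'
#' Chains simulate -> associate -> network -> group stats (and a
#' connectivity demo on the packaged resilience miRNA list) and stamps
#' one manifest. Deterministic given the simulation and config seeds: two runs
#' with the same seed produce identical files, and manifests identical
#' except for timestamps.
#'
#' @param spec a \code{\link{simulation_spec}}
#' @param cfg an \code{\link{analysis_config}}
#' @param out_dir output directory
#' @param layout_iter layout iteration cap for the network stage
#' @return List with every stage's result and the manifest.
#' @export
run_all <- function(spec = simulation_spec(), cfg = analysis_config(),
                    out_dir, layout_iter = 100L) {
  sim <- run_simulate(spec, out_dir)
  assoc <- run_associate(sim$counts, sim$cohort, cfg, out_dir)
  net <- run_network(assoc$records, out_dir, seed = cfg$seed,
                     layout_iter = layout_iter)
  gs <- run_groupstats(sim$cohort, out_dir)
  inter <- simulate_interactions(seed = cfg$seed)
  conn <- run_connectivity(inter, cfg = cfg, out_dir = out_dir)
  list(simulate = sim, associate = assoc, network = net, groupstats = gs,
       connectivity = conn,
       manifest = load_manifest(out_dir))
}
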