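# The rank-correlation screen: tie-corrected ranking, Spearman and
# point-biserial statistics with t-approximation p-values, the significance
# and presence cut-offs, and per-phenotype summaries.

#' Analysis configuration
#'
#' Bundles the screen's tunable parameters. Defaults reproduce the
#' headline analysis: uncorrected p < 0.05 cut-off, miRNAs present in
#' fewer than 11 subjects removed, highlighting at p < 0.0005, BH false
#' discovery control off (when enabled the conventional boundary is
#' q = 0.1).
#'
#' @param alpha significance cut-off on the uncorrected p-value
#' @param min_present minimum subjects with a nonzero count
#' @param highlight_alpha p-value threshold for the highlight flag
#' @param fdr_q optional Benjamini-Hochberg boundary; NULL disables FDR
#' @param zero_policy how zero counts enter each correlation:
#'   \code{"rank_bottom"} (default) keeps every subject, with undetected
#'   miRNAs tied at the bottom of the expression ranking so ranks span
#'   the whole cohort; \code{"drop"} treats zeros as missing and uses
#'   pairwise-complete subjects. Missing phenotype values are always
#'   dropped pairwise, with \code{n_used} recording the pairs kept.
#' @param logit_min minimum logit probability for target-connectivity
#'   screening
#' @param tarbase_min_score prediction-score filter for validated
#'   interactions
#' @param seed integer seed used by pipeline stages
#' @return An \code{analysis_config} list.
#' @export
analysis_config <- function(alpha = 0.05, min_present = 11L,
                            highlight_alpha = 5e-4, fdr_q = NULL,
                            zero_policy = c("rank_bottom", "drop"),
                            logit_min = 0.5, tarbase_min_score = 0.8,
                            seed = 1L) {
  if (!(alpha > 0 && alpha < 1)) usage_error("alpha must lie in (0, 1)")
  if (min_present < 1L) usage_error("min_present must be >= 1")
  if (!is.null(fdr_q) && !(fdr_q > 0 && fdr_q < 1)) {
    usage_error("fdr_q must lie in (0, 1) or be NULL")
  }
  zero_policy <- match.arg(zero_policy)
  structure(list(alpha = alpha, min_present = as.integer(min_present),
                 highlight_alpha = highlight_alpha, fdr_q = fdr_q,
                 zero_policy = zero_policy,
                 logit_min = logit_min,
                 tarbase_min_score = tarbase_min_score,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Rank a vector with mean-rank tie correction
#'
#' Ascending ranks (1 = lowest value); tied values all receive the mean
#' of the ranks they span, so the rank sum n(n+1)/2 is conserved.
#'
#' @param x numeric vector, length >= 2, all values finite
#' @return List with \code{values} (the ranks), \code{n}, and
#'   \code{tie_groups} (sizes of groups of tied values, ties only).
#' @examples
#' rank_with_ties(c(5, 5, 2))$values  # 2.5 2.5 1
#' @export
rank_with_ties <- function(x) {
  if (length(x) < 2L) usage_error("need at least 2 values to rank")
  if (any(!is.finite(x))) validation_error("non-finite value in vector to rank")
  r <- rank(x, ties.method = "average")
  tab <- table(x)
  structure(list(values = r, n = length(x),
                 tie_groups = as.integer(tab[tab > 1L])),
            class = "ranked_vector")
}

t_approx_p <- function(r, n) {
  # two-sided p from t = r * sqrt((n-2)/(1-r^2)) on n-2 df;
  # |r| = 1 is reported at the machine floor, never exactly 0
  if (abs(r) >= 1) return(.Machine$double.xmin)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  max(2 * stats::pt(-abs(tval), df = n - 2), .Machine$double.xmin)
}

#' Tie-corrected Spearman correlation
#'
#' Pearson correlation of mean-rank-assigned ranks, with a two-sided
#' p-value from the t approximation on n - 2 degrees of freedom. Pairs
#' with a missing value in either vector are dropped; \code{n_used}
#' reports the pairs retained.
#'
#' @param x,y numeric vectors of equal length
#' @return List with \code{rho}, \code{p_value}, \code{n_used}.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) usage_error("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) usage_error("need at least 4 complete pairs")
  rx <- rank_with_ties(x)$values
  ry <- rank_with_ties(y)$values
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    validation_error("undefined correlation: a ranked vector has zero variance")
  }
  rho <- stats::cor(rx, ry)
  list(rho = rho, p_value = t_approx_p(rho, n), n_used = n)
}

#' Point-biserial correlation
#'
#' Pearson correlation between a 0/1-coded binary variable and a numeric
#' variable, with the same t-approximation p-value as the Spearman screen.
#'
#' @param b binary vector (two levels, coded or coercible to 0/1)
#' @param y numeric vector of equal length
#' @return List with \code{r}, \code{p_value}, \code{n_used}.
#' @export
point_biserial <- function(b, y) {
  if (length(b) != length(y)) usage_error("b and y must have equal length")
  keep <- is.finite(as.numeric(b)) & is.finite(y)
  b <- as.numeric(b)[keep]; y <- y[keep]
  n <- length(b)
  if (n < 4L) usage_error("need at least 4 complete pairs")
  if (length(unique(b)) != 2L) {
    validation_error("binary variable must contain exactly two levels")
  }
  if (stats::sd(y) == 0) {
    validation_error("undefined correlation: y has zero variance")
  }
  r <- stats::cor(b, y)
  list(r = r, p_value = t_approx_p(r, n), n_used = n)
}

#' Critical correlation for a given sample size and level
#'
#' The smallest |rho| whose two-sided t-approximation p-value reaches
#' \code{alpha}: rho_crit = t_c / sqrt(n - 2 + t_c^2) with t_c the
#' alpha/2 upper quantile on n - 2 df. Monotone decreasing in n. At the
#' cohort size 26 and alpha 0.05 this evaluates to 0.3882, the screening
#' bound conventionally quoted as rho > 0.38.
#'
#' @param n number of subjects (>= 4)
#' @param alpha two-sided significance level
#' @return The critical |rho| in (0, 1).
#' @export
critical_rho <- function(n, alpha = 0.05) {
  if (n < 4L) usage_error("n must be >= 4")
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Screen every miRNA against every phenotype
#'
#' For each (miRNA, phenotype) pair: binary sex uses the point-biserial
#' coefficient on the normalized expression values; every other
#' phenotype uses the tie-corrected Spearman correlation of expression
#' ranks against phenotype ranks (zero counts rank tied at the bottom;
#' higher pathology and age rank higher). Records with p < alpha are
#' retained, the highlight flag marks p < highlight_alpha, and when
#' \code{cfg$fdr_q} is set BH q-values are computed across the full
#' pre-filter record set. Phenotypes with zero variance are skipped with
#' a warning.
#'
#' @param m normalized, presence-filtered \code{\link{expression_matrix}}
#' @param cohort a \code{\link{cohort_table}} whose subjects match the
#'   matrix columns
#' @param cfg an \code{\link{analysis_config}}
#' @param domain_map named list of test names per domain
#' @param keep_all if TRUE, return every record regardless of alpha
#'   (the \code{significant} column then marks the cut-off)
#' @return data.frame of class \code{association_records} with columns
#'   mirna, phenotype, statistic, rho, p_value, q_value, n_used, sign,
#'   highlight.
#' @export
screen_associations <- function(m, cohort, cfg = analysis_config(),
                                domain_map = attr(cohort, "domain_map") %||%
                                  default_domain_map(),
                                keep_all = FALSE) {
  stopifnot(inherits(m, "expression_matrix"), inherits(cohort, "cohort_table"))
  if (!identical(subject_ids(m), cohort$subject_id)) {
    if (!setequal(subject_ids(m), cohort$subject_id)) {
      validation_error("expression matrix and cohort cover different subjects")
    }
    cohort <- cohort[match(subject_ids(m), cohort$subject_id), , drop = FALSE]
  }
  ph <- phenotype_values(cohort, domain_map)
  binary <- attr(ph, "binary")
  out <- vector("list", length(ph))
  names(out) <- names(ph)
  for (p_id in names(ph)) {
    v <- ph[[p_id]]
    ok <- is.finite(v)
    if (stats::sd(v[ok]) == 0 || sum(ok) < 4L) {
      warning(sprintf("phenotype '%s' skipped (zero variance or too few values)",
                      p_id), call. = FALSE)
      next
    }
    nmir <- nrow(m$counts)
    rho <- pval <- numeric(nmir); nuse <- integer(nmir)
    kind <- if (p_id %in% binary) "point_biserial_r" else "spearman_rho"
    for (i in seq_len(nmir)) {
      expr <- m$counts[i, ]
      if (cfg$zero_policy == "drop") expr[expr == 0] <- NA_real_
      res <- if (kind == "point_biserial_r") {
        pb <- point_biserial(v, expr)
        list(rho = pb$r, p_value = pb$p_value, n_used = pb$n_used)
      } else {
        spearman_cor(expr, v)
      }
      rho[i] <- res$rho; pval[i] <- res$p_value; nuse[i] <- res$n_used
    }
    out[[p_id]] <- data.frame(
      mirna = rownames(m$counts), phenotype = p_id, statistic = kind,
      rho = rho, p_value = pval, n_used = nuse,
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(rec)) rec <- data.frame(mirna = character(), phenotype = character(),
                                      statistic = character(), rho = numeric(),
                                      p_value = numeric(), n_used = integer())
  rownames(rec) <- NULL
  rec$q_value <- if (!is.null(cfg$fdr_q)) stats::p.adjust(rec$p_value, "BH") else NA_real_
  rec$sign <- ifelse(rec$rho > 0, "positive", "negative")
  rec$highlight <- rec$p_value < cfg$highlight_alpha
  rec$significant <- rec$p_value < cfg$alpha
  if (!is.null(cfg$fdr_q)) {
    rec$significant <- rec$significant & rec$q_value <= cfg$fdr_q
  }
  if (!keep_all) rec <- rec[rec$significant, , drop = FALSE]
  rec <- rec[order(rec$phenotype, rec$mirna), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("association_records", "data.frame")
  rec
}

#' Summarize associations for one phenotype and sign
#'
#' Count, median rho, rho range and the highlighted miRNA list for the
#' records of the given phenotype and correlation sign, mirroring how
#' results are conventionally quoted (e.g. "50 miRNAs, median rho 0.47,
#' range 0.39-0.72").
#'
#' @param records output of \code{\link{screen_associations}}
#' @param phenotype_id phenotype to summarize
#' @param sign \code{"positive"} or \code{"negative"}
#' @return List with \code{phenotype}, \code{sign}, \code{count},
#'   \code{median_rho}, \code{rho_range}, \code{highlighted}.
#' @export
summarize_associations <- function(records, phenotype_id, sign) {
  sub <- records[records$phenotype == phenotype_id & records$sign == sign, ,
                 drop = FALSE]
  if (nrow(sub) == 0L) {
    return(list(phenotype = phenotype_id, sign = sign, count = 0L,
                median_rho = NA_real_, rho_range = c(NA_real_, NA_real_),
                highlighted = character()))
  }
  list(phenotype = phenotype_id, sign = sign, count = nrow(sub),
       median_rho = stats::median(sub$rho),
       rho_range = range(sub$rho),
       highlighted = sub$mirna[sub$highlight])
}

#' Summary table over all phenotype/sign strata
#'
#' @param records output of \code{\link{screen_associations}}
#' @return data.frame with one row per (phenotype, sign) stratum that has
#'   at least one record: count, median rho, min/max rho, number
#'   highlighted.
#' @export
association_summary_table <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(phenotype = character(), sign = character(),
                      count = integer(), median_rho = numeric(),
                      rho_min = numeric(), rho_max = numeric(),
                      n_highlighted = integer()))
  }
  strata <- unique(records[, c("phenotype", "sign")])
  strata <- strata[order(strata$phenotype, strata$sign), , drop = FALSE]
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    s <- summarize_associations(records, strata$phenotype[i], strata$sign[i])
    data.frame(phenotype = s$phenotype, sign = s$sign, count = s$count,
               median_rho = s$median_rho, rho_min = s$rho_range[1],
               rho_max = s$rho_range[2],
               n_highlighted = length(s$highlighted),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
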