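# Cohort-level group comparisons: Pearson chi-square for categorical
# variables (no continuity correction; the compared tables are larger
# than 2x2), Kruskal-Wallis with tie correction for numeric/ordinal
# variables, and Dunn's post hoc z-test for pairwise follow-up.

#' Pearson chi-square test on a contingency table
#'
#' Classic Pearson statistic sum (O - E)^2 / E with expected counts from
#' the row/column marginals, df = (r-1)(c-1), no continuity correction.
#' A warning is attached (not an error) when any expected count is below
#' 5, as is routine for small autopsy cohorts.
#'
#' @param tab matrix of non-negative counts, at least 2x2, with positive
#'   marginals
#' @return List (\code{group_test_result}) with \code{variable},
#'   \code{test}, \code{statistic}, \code{df}, \code{p_value},
#'   \code{low_expected}.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) validation_error("contingency counts must be non-negative")
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    usage_error("contingency table must be at least 2x2")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    validation_error("degenerate contingency table: all-zero row or column")
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(variable = NA_character_, test = "chi_square",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value),
                 low_expected = any(res$expected < 5)),
            class = "group_test_result")
}

#' Kruskal-Wallis test across groups
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom.
#'
#' @param groups list of numeric vectors, one per group; at least 2
#'   groups of at least 2 observations each (missing values dropped)
#' @return List (\code{group_test_result}) with \code{statistic} (H),
#'   \code{df}, \code{p_value}.
#' @export
kruskal_wallis_test <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2L) usage_error("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    validation_error("every group needs at least 2 observations")
  }
  x <- unlist(groups)
  if (length(unique(x)) == 1L) {
    # every observation identical: no evidence against equality
    return(structure(list(variable = NA_character_, test = "kruskal_wallis",
                          statistic = 0, df = length(groups) - 1L,
                          p_value = 1), class = "group_test_result"))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  res <- stats::kruskal.test(x, g)
  structure(list(variable = NA_character_, test = "kruskal_wallis",
                 statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value)),
            class = "group_test_result")
}

#' Dunn's post hoc z-test for all group pairs
#'
#' After a Kruskal-Wallis test, compares every pair of groups on the
#' pooled ranks: z = (Rbar_i - Rbar_j) / SE with the tie-corrected pooled
#' variance SE = sqrt[(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j)],
#' two-sided p-values, optionally Bonferroni-adjusted over the
#' k(k-1)/2 pairs.
#'
#' @param groups list of numeric vectors, one per group
#' @param adjust \code{"none"} or \code{"bonferroni"}
#' @return data.frame with columns group_i, group_j, dunn_z, p_value,
#'   p_adjusted.
#' @export
dunn_posthoc <- function(groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2L) usage_error("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    validation_error("every group needs at least 2 observations")
  }
  if (is.null(names(groups))) names(groups) <- as.character(seq_along(groups))
  x <- unlist(groups)
  n_i <- vapply(groups, length, integer(1))
  g <- rep(names(groups), n_i)
  N <- length(x)
  r <- rank(x, ties.method = "average")
  rbar <- tapply(r, g, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_pooled <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2L)
  k <- ncol(pairs)
  out <- data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                    dunn_z = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_len(k)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(var_pooled * (1 / n_i[[i]] + 1 / n_i[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    out$dunn_z[p] <- z
    out$p_value[p] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_adjusted <- if (adjust == "bonferroni") pmin(1, k * out$p_value)
                    else out$p_value
  out
}

#' Reference contingency tables and group summaries of the emulated cohort
#'
#' The published subject-characteristics table of the 26-subject cohort
#' this package emulates, packaged so group-level statistics can be
#' recomputed offline: per-group sex, ApoE, CERAD and NIA-Reagan level
#' counts (columns = Braak groups I-II, III, IV) plus the per-group
#' pathology-load means and group sizes.
#'
#' @return List with contingency matrices \code{sex}, \code{apoe},
#'   \code{cerad}, \code{nia_reagan}, numeric vectors
#'   \code{amyloid_6e10_mean}, \code{tangle_at8_mean} and
#'   \code{group_sizes}.
#' @export
cohort_reference_tables <- function() {
  grp <- c("I-II", "III", "IV")
  list(
    sex = matrix(c(4, 3, 5, 4, 5, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("male", "female"), grp)),
    apoe = matrix(c(1, 0, 3, 4, 7, 5, 3, 1, 2), nrow = 3, byrow = TRUE,
                  dimnames = list(c("e2/e3", "e3/e3", "e3/e4"), grp)),
    cerad = matrix(c(1, 0, 2, 1, 2, 6, 2, 1, 0, 4, 5, 2), nrow = 4,
                   byrow = TRUE,
                   dimnames = list(c("Definite", "Probable", "Possible",
                                     "No AD"), grp)),
    nia_reagan = matrix(c(1, 2, 8, 7, 6, 2), nrow = 2, byrow = TRUE,
                        dimnames = list(c("Intermediate", "Low"), grp)),
    amyloid_6e10_mean = stats::setNames(c(2.6, 2.8, 4.6), grp),
    tangle_at8_mean = stats::setNames(c(0.6, 0.7, 2.2), grp),
    group_sizes = stats::setNames(c(8L, 8L, 10L), grp)
  )
}

#' Subject-characteristics summary with group tests
#'
#' Per-Braak-group summary of a cohort in the layout of a subject
#' characteristics table: n (male, female); min-max (median) for age,
#' education, MMSE and the global composite; level counts for ApoE,
#' CERAD and NIA-Reagan; mean pathology loads. Each numeric/ordinal row
#' is paired with a Kruskal-Wallis p-value and each categorical row with
#' a Pearson chi-square p-value (single-group cohorts get summaries
#' without tests).
#'
#' @param cohort a \code{\link{cohort_table}}
#' @return data.frame with one row per variable: per-group summary
#'   strings, test name, statistic and p-value.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  grps <- levels(droplevels(cohort$group))
  split_by <- function(v) split(v, droplevels(cohort$group))
  one_test <- length(grps) < 2L
  rng_med <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return("-")
    sprintf("%s-%s (%s)", fmt_num(min(v)), fmt_num(max(v)),
            fmt_num(stats::median(v)))
  }
  lvl_counts <- function(f) {
    vapply(split(f, droplevels(cohort$group)), function(x) {
      paste(sprintf("%s n=%d", names(table(x)), as.integer(table(x))),
            collapse = "; ")
    }, character(1))
  }
  kw_row <- function(name, v, summ) {
    res <- if (one_test) NULL else kruskal_wallis_test(split_by(v))
    data.frame(variable = name, t(summ),
               test = if (one_test) NA_character_ else "kruskal_wallis",
               statistic = if (one_test) NA_real_ else res$statistic,
               p_value = if (one_test) NA_real_ else res$p_value,
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  chi_row <- function(name, f) {
    tab <- table(f, droplevels(cohort$group))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    res <- if (one_test || nrow(tab) < 2L) NULL else chi_square_test(tab)
    data.frame(variable = name, t(lvl_counts(f)),
               test = if (is.null(res)) NA_character_ else "chi_square",
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               p_value = if (is.null(res)) NA_real_ else res$p_value,
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  n_row <- {
    summ <- vapply(grps, function(g) {
      sub <- cohort[cohort$group == g, ]
      sprintf("n=%d (%d, %d)", nrow(sub), sum(sub$sex == "male"),
              sum(sub$sex == "female"))
    }, character(1))
    tab <- table(cohort$sex, droplevels(cohort$group))
    res <- if (one_test) NULL else chi_square_test(tab)
    data.frame(variable = "n (male, female)", t(summ),
               test = if (one_test) NA_character_ else "chi_square",
               statistic = if (one_test) NA_real_ else res$statistic,
               p_value = if (one_test) NA_real_ else res$p_value,
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  num_summ <- function(v) vapply(split_by(v), rng_med, character(1))
  mean_summ <- function(v) {
    vapply(split_by(v), function(x) {
      x <- x[is.finite(x)]
      sprintf("%s (n=%d)", fmt_num(mean(x)), length(x))
    }, character(1))
  }
  rows <- list(
    n_row,
    kw_row("Age at death in years (median)", cohort$age_at_death,
           num_summ(cohort$age_at_death)),
    kw_row("Education in years (median)", cohort$education,
           num_summ(cohort$education)),
    kw_row("MMSE score (median)", as.numeric(cohort$mmse),
           num_summ(as.numeric(cohort$mmse))),
    kw_row("GCS (median)", cohort$gcs, num_summ(cohort$gcs)),
    chi_row("ApoE status", droplevels(cohort$apoe)),
    chi_row("CERAD", droplevels(cohort$cerad)),
    chi_row("NIA-Reagan", droplevels(cohort$nia_reagan)),
    kw_row("PCC 6E10 load", as.numeric(cohort$amyloid_6e10),
           mean_summ(as.numeric(cohort$amyloid_6e10))),
    kw_row("PCC AT8 load", as.numeric(cohort$tangle_at8),
           mean_summ(as.numeric(cohort$tangle_at8)))
  )
  out <- do.call(rbind, rows)
  names(out)[2:(1 + length(grps))] <- paste0("Braak ", grps)
  rownames(out) <- NULL
  out
}
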