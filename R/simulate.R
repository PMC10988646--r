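# Seeded cohort and count-matrix simulator. The defaults emulate the study
# conditions the package targets: 26 autopsy subjects split 8/8/10 across
# Braak groups I-II/III/IV with per-group demographics and pathology
# drawn to match the published cohort description; 906 miRNAs with
# per-miRNA presence rates spanning 0.42-1.00 and roughly a quarter of
# miRNAs present in all subjects; negative-binomial count marginals with
# per-subject library-size scaling; and Gaussian-copula-planted Spearman
# correlations between selected miRNAs and phenotypes.

#' Simulation specification
#'
#' @param n_subjects cohort size (default 26)
#' @param group_sizes subjects per Braak group I-II / III / IV
#'   (default 8, 8, 10); must sum to \code{n_subjects}
#' @param n_mirna number of miRNAs probed (default 906)
#' @param presence_rate_range per-miRNA probability that a subject has a
#'   nonzero count, drawn uniformly in this range (default 0.42-1.00)
#' @param all_present_frac fraction of miRNAs given presence rate exactly
#'   1, emulating the subset detected in every subject (default 220/906)
#' @param planted_effects data.frame with columns \code{mirna},
#'   \code{phenotype}, \code{target_rho}: miRNA-phenotype pairs whose
#'   population Spearman correlation is planted via a Gaussian copula
#' @param nb_mean_log_range range of per-miRNA log mean counts
#'   (natural log; default log(5)..log(500))
#' @param nb_dispersion negative-binomial size parameter (default 2)
#' @param library_size_cv coefficient of variation of the per-subject
#'   library-size factor (default 0.3)
#' @param test_noise_sd within-domain noise s.d. of each cognitive test
#'   around its domain latent (default 0.5)
#' @param missing_pathology_n number of Braak III subjects with missing
#'   pathology load scores (default 2, as in the cohort emulated)
#' @param seed integer random seed
#' @return A \code{simulation_spec} list.
#' @export
simulation_spec <- function(n_subjects = 26L, group_sizes = c(8L, 8L, 10L),
                            n_mirna = 906L,
                            presence_rate_range = c(0.42, 1.00),
                            all_present_frac = 220 / 906,
                            planted_effects = NULL,
                            nb_mean_log_range = log(c(5, 500)),
                            nb_dispersion = 2,
                            library_size_cv = 0.3,
                            test_noise_sd = 0.5,
                            missing_pathology_n = 2L,
                            seed = 1L) {
  if (sum(group_sizes) != n_subjects) {
    schema_error("group_sizes must sum to n_subjects")
  }
  if (length(group_sizes) != 3L) schema_error("exactly 3 Braak groups expected")
  if (presence_rate_range[1] <= 0 || presence_rate_range[2] > 1 ||
      presence_rate_range[1] > presence_rate_range[2]) {
    schema_error("presence_rate_range must lie within (0, 1]")
  }
  if (!is.null(planted_effects)) {
    req <- c("mirna", "phenotype", "target_rho")
    if (!all(req %in% names(planted_effects))) {
      schema_error("planted_effects needs columns mirna, phenotype, target_rho")
    }
    if (any(abs(planted_effects$target_rho) >= 1)) {
      schema_error("|target_rho| must be < 1")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 group_sizes = as.integer(group_sizes),
                 n_mirna = as.integer(n_mirna),
                 presence_rate_range = presence_rate_range,
                 all_present_frac = all_present_frac,
                 planted_effects = planted_effects,
                 nb_mean_log_range = nb_mean_log_range,
                 nb_dispersion = nb_dispersion,
                 library_size_cv = library_size_cv,
                 test_noise_sd = test_noise_sd,
                 missing_pathology_n = as.integer(missing_pathology_n),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# per-group generating parameters follow the published cohort description:
# age and education ranges, sex and ApoE and CERAD and NIA-Reagan level
# counts, and mean pathology loads per Braak group
group_params <- function() {
  list(
    age_range  = list(`I-II` = c(76, 92), III = c(82, 96), IV = c(83, 93)),
    educ_range = list(`I-II` = c(12, 21), III = c(14, 21), IV = c(14, 27)),
    sex_counts = list(`I-II` = c(male = 4, female = 4),
                      III   = c(male = 3, female = 5),
                      IV    = c(male = 5, female = 5)),
    apoe_counts = list(`I-II` = c(`e2/e3` = 1, `e3/e3` = 4, `e3/e4` = 3),
                       III   = c(`e2/e3` = 0, `e3/e3` = 7, `e3/e4` = 1),
                       IV    = c(`e2/e3` = 3, `e3/e3` = 5, `e3/e4` = 2)),
    cerad_counts = list(
      `I-II` = c(`No AD` = 4, Possible = 2, Probable = 1, Definite = 1),
      III   = c(`No AD` = 5, Possible = 1, Probable = 2, Definite = 0),
      IV    = c(`No AD` = 2, Possible = 0, Probable = 6, Definite = 2)),
    nia_counts = list(`I-II` = c(Low = 7, Intermediate = 1),
                      III   = c(Low = 6, Intermediate = 2),
                      IV    = c(Low = 2, Intermediate = 8)),
    amyloid_mean = c(`I-II` = 2.6, III = 2.8, IV = 4.6),
    tangle_mean  = c(`I-II` = 0.6, III = 0.7, IV = 2.2)
  )
}

# resize Table-2-style level counts to an arbitrary group size,
# preserving proportions
scale_counts <- function(counts, n) {
  if (sum(counts) == n) return(counts)
  out <- floor(counts / sum(counts) * n)
  rem <- n - sum(out)
  frac <- counts / sum(counts) * n - out
  add <- order(frac, decreasing = TRUE)[seq_len(rem)]
  out[add] <- out[add] + 1L
  out
}

expand_counts <- function(counts) rep(names(counts), times = counts)

#' Simulate a cohort table
#'
#' Subjects receive group labels per \code{group_sizes}; demographics,
#' ApoE, CERAD, NIA-Reagan and pathology loads are drawn within
#' group-specific ranges/level frequencies so that higher Braak groups
#' carry stochastically higher pathology and an age-group association
#' exists. Each of the 19 cognitive tests is its domain latent plus
#' Gaussian noise, mapped onto a test-specific scale; the global
#' composite is the mean of per-test z-scores.
#'
#' @param spec a \code{\link{simulation_spec}}
#' @return A validated \code{\link{cohort_table}}.
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  gp <- group_params()
  groups <- rep(c("I-II", "III", "IV"), times = spec$group_sizes)
  n <- spec$n_subjects
  df <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                   stringsAsFactors = FALSE)
  df$braak <- unlist(lapply(seq_along(groups), function(i) {
    switch(groups[i],
           `I-II` = sample(c("I", "II"), 1L),
           III = "III", IV = "IV")
  }))
  per_group <- function(field, draw) {
    unlist(lapply(c("I-II", "III", "IV"), function(g) {
      draw(g, spec$group_sizes[match(g, c("I-II", "III", "IV"))])
    }))
  }
  df$age_at_death <- per_group("age", function(g, k) {
    r <- gp$age_range[[g]]; round(stats::runif(k, r[1], r[2]), 1)
  })
  df$education <- per_group("educ", function(g, k) {
    r <- gp$educ_range[[g]]; round(stats::runif(k, r[1], r[2]))
  })
  df$sex <- per_group("sex", function(g, k) {
    sample(expand_counts(scale_counts(gp$sex_counts[[g]], k)))
  })
  df$apoe <- per_group("apoe", function(g, k) {
    sample(expand_counts(scale_counts(gp$apoe_counts[[g]], k)))
  })
  df$cerad <- per_group("cerad", function(g, k) {
    sample(expand_counts(scale_counts(gp$cerad_counts[[g]], k)))
  })
  df$nia_reagan <- per_group("nia", function(g, k) {
    sample(expand_counts(scale_counts(gp$nia_counts[[g]], k)))
  })
  df$mmse <- sample(25:30, n, replace = TRUE,
                    prob = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.25))
  clip05 <- function(x) pmin(5, pmax(0, x))
  df$amyloid_6e10 <- per_group("amy", function(g, k) {
    clip05(round(stats::rnorm(k, gp$amyloid_mean[[g]], 0.8)))
  })
  df$tangle_at8 <- per_group("tau", function(g, k) {
    clip05(round(stats::rnorm(k, gp$tangle_mean[[g]], 0.6)))
  })
  if (spec$missing_pathology_n > 0L) {
    iii <- which(groups == "III")
    drop <- iii[seq_len(min(spec$missing_pathology_n, length(iii)))]
    df$amyloid_6e10[drop] <- NA
    df$tangle_at8[drop] <- NA
  }
  dm <- default_domain_map()
  # domain latents are independent standard normals; tests sit on
  # plausible raw scales so that z-invariance is exercised downstream
  latents <- matrix(stats::rnorm(n * length(dm)), nrow = n,
                    dimnames = list(NULL, names(dm)))
  tests <- battery_tests(dm)
  scales <- stats::setNames(5 + 2 * seq_along(tests), tests)
  offsets <- stats::setNames(10 * seq_along(tests), tests)
  for (d in names(dm)) {
    for (t in dm[[d]]) {
      raw <- latents[, d] + spec$test_noise_sd * stats::rnorm(n)
      df[[t]] <- offsets[[t]] + scales[[t]] * raw
    }
  }
  cohort_table(df, domain_map = dm)
}

# Pearson latent correlation giving population Spearman rho under a
# Gaussian copula
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

# normal scores of a (possibly tied) phenotype vector
normal_scores <- function(v) {
  r <- rank(v, ties.method = "average")
  stats::qnorm(r / (length(v) + 1))
}

#' Simulate a count matrix for a cohort
#'
#' Counts are negative-binomial with per-miRNA log means drawn uniformly
#' in \code{nb_mean_log_range} and a per-subject library-size factor.
#' Presence rates are implemented as per-miRNA zero-inflation (a subject's
#' cell is zeroed with probability 1 - presence rate); a fixed fraction
#' of miRNAs is present in every subject. For each planted effect the
#' miRNA's latent normal is coupled to the phenotype's normal scores with
#' Pearson correlation 2 sin(pi rho / 6), the Gaussian-copula calibration
#' that makes the population Spearman correlation equal \code{target_rho};
#' planted miRNAs carry no zero-inflation so the planted correlation is
#' not attenuated by absence.
#'
#' @param spec a \code{\link{simulation_spec}}
#' @param cohort cohort from \code{\link{simulate_cohort}}
#' @return A raw \code{\link{expression_matrix}} (miRNA x subject).
#' @export
simulate_counts <- function(spec, cohort) {
  stopifnot(inherits(spec, "simulation_spec"), inherits(cohort, "cohort_table"))
  set.seed(spec$seed + 1L)
  n <- nrow(cohort)
  nm <- spec$n_mirna
  ids <- sprintf("miR-sim-%04d", seq_len(nm))
  planted <- spec$planted_effects
  if (!is.null(planted)) {
    ph <- phenotype_values(cohort)
    bad <- setdiff(planted$phenotype, names(ph))
    if (length(bad)) {
      schema_error(paste0("planted phenotype(s) not in cohort: ",
                          paste(bad, collapse = ", ")))
    }
    bad_id <- setdiff(planted$mirna, ids)
    if (length(bad_id)) {
      schema_error(paste0("planted miRNA id(s) outside simulated labels: ",
                          paste(bad_id, collapse = ", ")))
    }
  }
  log_mu <- stats::runif(nm, spec$nb_mean_log_range[1], spec$nb_mean_log_range[2])
  pres <- stats::runif(nm, spec$presence_rate_range[1], spec$presence_rate_range[2])
  pres[stats::runif(nm) < spec$all_present_frac] <- 1
  lib <- if (spec$library_size_cv > 0) {
    sdlog <- sqrt(log(1 + spec$library_size_cv^2))
    stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  } else rep(1, n)
  counts <- matrix(0, nrow = nm, ncol = n,
                   dimnames = list(ids, cohort$subject_id))
  planted_idx <- if (is.null(planted)) integer() else match(planted$mirna, ids)
  for (i in seq_len(nm)) {
    k <- match(i, planted_idx)
    z <- if (!is.na(k)) {
      v <- ph[[planted$phenotype[k]]]
      zs <- normal_scores(ifelse(is.finite(v), v, stats::median(v, na.rm = TRUE)))
      r <- spearman_to_pearson(planted$target_rho[k])
      r * zs + sqrt(1 - r^2) * stats::rnorm(n)
    } else stats::rnorm(n)
    mu_i <- exp(log_mu[i]) * lib
    counts[i, ] <- stats::qnbinom(stats::pnorm(z), size = spec$nb_dispersion,
                                  mu = mu_i)
    if (is.na(k) && pres[i] < 1) {
      counts[i, stats::runif(n) > pres[i]] <- 0
    }
  }
  expression_matrix(counts, normalized = FALSE)
}

#' Planted ground truth
#'
#' Echoes the planted (miRNA, phenotype, target rho) triples of a spec,
#' for use by recovery tests.
#'
#' @param spec a \code{\link{simulation_spec}}
#' @return data.frame with columns mirna, phenotype, target_rho (zero
#'   rows when nothing was planted).
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(spec$planted_effects)) {
    return(data.frame(mirna = character(), phenotype = character(),
                      target_rho = numeric()))
  }
  out <- as.data.frame(spec$planted_effects)[, c("mirna", "phenotype",
                                                 "target_rho")]
  rownames(out) <- NULL
  out
}
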