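# the rank-correlation screen: ranking, statistics, thresholds, summaries

test_that("mean-rank tie correction conserves the rank sum", {
  expect_equal(rank_with_ties(c(10, 20, 30))$values, c(1, 2, 3))
  expect_equal(rank_with_ties(c(5, 5, 2))$values, c(2.5, 2.5, 1))
  expect_equal(rank_with_ties(c(0, 0, 0, 7))$values, c(2, 2, 2, 4))
  expect_error(rank_with_ties(c(1, NA)), class = "validation_error")
  set.seed(42)
  for (i in 1:50) {
    x <- sample(0:5, 20, replace = TRUE)
    r <- rank_with_ties(x)
    expect_equal(sum(r$values), 20 * 21 / 2)
    expect_true(all(r$values >= 1 & r$values <= 20))
  }
})

test_that("spearman matches closed form, brute-force rank oracle and cor.test", {
  expect_equal(spearman_cor(1:5, 1:5)$rho, 1)
  # closed form 1 - 6 sum d^2 / (n(n^2-1)) with sum d^2 = 2
  expect_equal(spearman_cor(1:5, c(1, 2, 3, 5, 4))$rho, 0.9)
  # tied example equals Pearson on mean ranks
  x <- c(1, 2, 2, 4); y <- c(3, 1, 1, 2)
  expect_equal(spearman_cor(x, y)$rho,
               cor(rank(x, ties.method = "average"),
                   rank(y, ties.method = "average")))
  # oracle equivalence over random tied/untied vectors, and p-value
  # agreement with cor.test's t approximation
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(5:30, 1)
    x <- sample(0:8, n, replace = TRUE) + stats::rnorm(n, sd = 0.01 * (i %% 2))
    y <- stats::rnorm(n)
    got <- spearman_cor(x, y)
    expect_equal(got$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  x <- rnorm(20); y <- rnorm(20)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  # AS89/exact p differs from the t approximation; compare rho exactly
  expect_equal(spearman_cor(x, y)$rho, unname(ref$estimate))
  tref <- cor.test(rank(x), rank(y), method = "pearson")
  expect_equal(spearman_cor(x, y)$p_value, tref$p.value, tolerance = 1e-12)
})

test_that("spearman symmetry, sign anti-symmetry, and degenerate inputs", {
  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(spearman_cor(x, y)$rho, spearman_cor(y, x)$rho)
    expect_equal(spearman_cor(x, -y)$rho, -spearman_cor(x, y)$rho)
  }
  expect_error(spearman_cor(rep(1, 10), rnorm(10)),
               class = "validation_error")
  expect_gt(spearman_cor(1:10, 1:10)$p_value, 0)  # never exactly 0
  # missing values drop pairwise with n_used logged
  x <- c(1:8, NA, 10); y <- 1:10
  expect_equal(spearman_cor(x, y)$n_used, 9L)
})

test_that("point-biserial equals Pearson on 0/1 coding", {
  got <- point_biserial(c(0, 0, 1, 1), c(1, 2, 3, 4))
  expect_equal(got$r, 0.894, tolerance = 5e-4)
  expect_equal(got$r, cor(c(0, 0, 1, 1), c(1, 2, 3, 4)))
  expect_error(point_biserial(c(0, 0, 0, 0), rnorm(4)),
               class = "validation_error")
  set.seed(3)
  for (i in 1:20) {
    b <- rbinom(12, 1, 0.5); if (length(unique(b)) < 2) next
    y <- rnorm(12)
    expect_equal(point_biserial(b, y)$r, cor(b, y))
  }
})

test_that("critical rho reproduces the n=26 screening bound and is monotone", {
  expect_equal(critical_rho(26, 0.05), 0.38824, tolerance = 1e-4)
  expect_gte(critical_rho(26, 0.05), 0.38)  # the printed bound
  expect_equal(critical_rho(5, 0.05), 0.878, tolerance = 1e-3)
  ns <- 5:60
  expect_true(all(diff(vapply(ns, critical_rho, 1, alpha = 0.05)) < 0))
  # alpha -> 0 pushes the bound toward 1
  expect_gt(critical_rho(26, 1e-10), 0.9)
  expect_gt(critical_rho(26, 1e-14), critical_rho(26, 1e-10))
  # inverting: a correlation at exactly the bound has p = alpha
  r <- critical_rho(26, 0.05)
  expect_equal(mirphenet:::t_approx_p(r, 26), 0.05, tolerance = 1e-10)
})

test_that("per-subject normalization and presence filter behave at boundaries", {
  m <- tiny_counts()
  norm <- normalize_per_subject(m)
  expect_equal(norm$counts[, "S1"], c(`miR-a` = 2, `miR-b` = 1, `miR-c` = 0) / 3)
  expect_true(all(abs(colSums(norm$counts) - 1) < 1e-9))
  expect_true(norm$normalized)
  z <- expression_matrix(matrix(c(1, 2, 0, 0), 2,
                                dimnames = list(c("a", "b"), c("S1", "S2"))))
  expect_error(normalize_per_subject(z), "S2", class = "validation_error")

  counts <- matrix(0, nrow = 3, ncol = 26,
                   dimnames = list(paste0("m", 1:3), paste0("S", 1:26)))
  counts[1, 1:11] <- 5   # present in exactly 11 -> kept
  counts[2, 1:10] <- 5   # present in 10 -> removed
  counts[3, ] <- 1       # present everywhere
  em <- expression_matrix(counts)
  kept <- presence_filter(em, 11)
  expect_identical(rownames(kept$counts), c("m1", "m3"))
  expect_identical(presence_filter(em, 1)$counts, em$counts)
})

test_that("composite domain scores are z-based and shift-invariant", {
  co <- tiny_cohort()
  dm <- default_domain_map()
  s <- composite_domain_score(co, "perc.sp")
  # mean of per-test z-scores
  zs <- sapply(dm$perc.sp, function(t) scale(co[[t]])[, 1])
  expect_equal(s, rowMeans(zs))
  # adding a constant to one test's raw scores changes nothing
  co2 <- co
  co2[[dm$perc.sp[1]]] <- co2[[dm$perc.sp[1]]] + 100
  expect_equal(composite_domain_score(co2, "perc.sp"), s)
  # single-test domain reduces to that test's z-score
  dm1 <- list(solo = dm$perc.sp[1])
  expect_equal(composite_domain_score(co, "solo", dm1),
               scale(co[[dm$perc.sp[1]]])[, 1])
  expect_error(composite_domain_score(co, "nope"), class = "usage_error")
})

test_that("the domain map covers 19 disjoint tests in five domains", {
  dm <- default_domain_map()
  expect_length(dm, 5L)
  tests <- unlist(dm)
  expect_length(tests, 19L)
  expect_false(anyDuplicated(tests) > 0)
})

test_that("screen retains p < alpha records with correct signs and flags", {
  spec <- simulation_spec(n_mirna = 60, seed = 5,
    planted_effects = data.frame(mirna = "miR-sim-0001",
                                 phenotype = "age", target_rho = 0.9))
  co <- simulate_cohort(spec)
  m <- presence_filter(normalize_per_subject(simulate_counts(spec, co)), 11)
  rec <- screen_associations(m, co)
  expect_true(all(rec$p_value < 0.05))
  expect_identical(rec$sign, ifelse(rec$rho > 0, "positive", "negative"))
  expect_identical(rec$highlight, rec$p_value < 5e-4)
  expect_true(all(rec$n_used <= nrow(co)))
  # the strong planted effect is recovered with its sign
  hit <- rec[rec$mirna == "miR-sim-0001" & rec$phenotype == "age", ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$sign, "positive")
  # sex rows use the point-biserial statistic
  all_rec <- screen_associations(m, co, keep_all = TRUE)
  expect_true(all(all_rec$statistic[all_rec$phenotype == "sex"] ==
                    "point_biserial_r"))
  expect_true(all(all_rec$statistic[all_rec$phenotype != "sex"] ==
                    "spearman_rho"))
  # pathology rows use fewer subjects when loads are missing
  expect_true(all(all_rec$n_used[all_rec$phenotype == "amyl.6e10"] == 24L))
})

test_that("screen is monotone in alpha and min_present", {
  spec <- simulation_spec(n_mirna = 80, seed = 9)
  co <- simulate_cohort(spec)
  raw <- simulate_counts(spec, co)
  norm <- normalize_per_subject(raw)
  key <- function(r) paste(r$mirna, r$phenotype)
  r05 <- screen_associations(presence_filter(norm, 11), co,
                             analysis_config(alpha = 0.05))
  r01 <- screen_associations(presence_filter(norm, 11), co,
                             analysis_config(alpha = 0.01))
  expect_true(all(key(r01) %in% key(r05)))
  m11 <- presence_filter(norm, 11)
  m16 <- presence_filter(norm, 16)
  expect_true(all(rownames(m16$counts) %in% rownames(m11$counts)))
  # BH mode never adds records either
  rq <- screen_associations(m11, co, analysis_config(alpha = 0.05, fdr_q = 0.1))
  expect_true(all(key(rq) %in% key(r05)))
  expect_true(all(!is.na(rq$q_value)))
})

test_that("summaries report count, median and range per stratum", {
  rec <- make_records(data.frame(
    mirna = c("a", "b", "c", "d", "e"),
    phenotype = c("age", "age", "age", "age", "age"),
    rho = c(0.39, 0.47, 0.72, -0.4, -0.6)))
  s <- summarize_associations(rec, "age", "positive")
  expect_equal(s$count, 3L)
  expect_equal(s$median_rho, 0.47)
  expect_equal(s$rho_range, c(0.39, 0.72))
  sneg <- summarize_associations(rec, "age", "negative")
  expect_equal(sneg$median_rho, -0.5)  # even count: mean of central pair
  s0 <- summarize_associations(rec, "mmse", "positive")
  expect_equal(s0$count, 0L)
  expect_true(is.na(s0$median_rho))
  tab <- association_summary_table(rec)
  expect_equal(tab$count[tab$sign == "positive"], 3L)
})
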