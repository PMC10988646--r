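# readers/writers and domain-type validation

test_that("counts round-trip through TSV and reject malformed cells", {
  m <- tiny_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(m, path)
  back <- read_counts(path)
  expect_equal(back$counts, m$counts)
  expect_false(back$normalized)
  expect_identical(dim(back), c(3L, 3L))

  # negative cell -> parse error naming the offending cell
  bad <- readLines(path)
  bad[3] <- sub("\t1\t", "\t-4\t", bad[3])
  writeLines(bad, path)
  expect_error(read_counts(path), "miR-b.*S1|S1.*miR-b", class = "parse_error")

  # duplicate miRNA id -> validation error
  lines <- c("mirna\tS1\tS2", "miR-a\t1\t2", "miR-a\t3\t4")
  writeLines(lines, path)
  expect_error(read_counts(path), "duplicate", class = "validation_error")
})

test_that("written counts are byte-deterministic", {
  m <- tiny_counts()
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_counts(m, p1); write_counts(m, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("phenotype reading validates ordinals, ranges and derives group", {
  co <- tiny_cohort()
  expect_identical(as.character(co$group),
                   as.character(mirphenet:::braak_group(as.integer(co$braak))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(co, path)
  back <- read_phenotypes(path)
  expect_equal(back$subject_id, co$subject_id)
  expect_equal(as.character(back$braak), as.character(co$braak))
  expect_equal(as.character(back$group), as.character(co$group))
  expect_equal(back$age_at_death, co$age_at_death)
  expect_equal(back$gcs, co$gcs, tolerance = 1e-5)  # 6-sig-digit text

  df <- as.data.frame(co)
  df$braak <- as.character(df$braak)
  df$braak[1] <- "VII"
  expect_error(cohort_table(df), "braak", class = "validation_error")

  df <- as.data.frame(co)
  df$mmse[2] <- 31
  expect_error(cohort_table(df), "mmse", class = "validation_error")

  df <- as.data.frame(co)
  df$age_at_death <- NULL
  expect_error(cohort_table(df), "age_at_death", class = "schema_error")

  # braak III maps to group III
  expect_equal(as.character(co$group[as.character(co$braak) == "III"][1]), "III")
})

test_that("edge matrix writes weight = 100|rho| in deterministic order", {
  rec <- make_records(data.frame(
    mirna = c("miR-z", "miR-a", "miR-b"),
    phenotype = c("age", "age", "mmse"),
    rho = c(0.5, -0.44, 0.6)))
  net <- build_network(rec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_edge_matrix(net, path)
  em <- read_edge_matrix(path)
  expect_equal(em$weight[em$mirna == "miR-z"], 50)
  expect_equal(em$weight[em$mirna == "miR-a"], 44)
  # sorted by hub then mirna
  expect_equal(order(em$hub, em$mirna), seq_len(nrow(em)))
  # byte-identical on rewrite
  p2 <- withr::local_tempfile()
  write_edge_matrix(net, p2)
  expect_identical(readLines(path), readLines(p2))
  # empty network -> header-only file
  empty <- build_network(make_records(data.frame(
    mirna = character(), phenotype = character(), rho = numeric())))
  p3 <- withr::local_tempfile()
  write_edge_matrix(empty, p3)
  expect_length(readLines(p3), 1L)
})

test_that("graph export produces valid GEXF/GraphML that round-trips", {
  rec <- make_records(data.frame(
    mirna = c("miR-a", "miR-b", "miR-c"),
    phenotype = c("age", "age", "mmse"),
    rho = c(0.5, 0.62, -0.41)))
  net <- build_network(rec)   # 2 hubs + 3 miRNAs
  for (fmt in c("gexf", "graphml")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_graph_file(net, path, format = fmt)
    back <- read_graph_file(path, format = fmt)
    expect_equal(nrow(back$nodes), 5L)
    expect_setequal(back$nodes$id, net$nodes$id)
    expect_equal(back$nodes$degree[match(net$nodes$id, back$nodes$id)],
                 net$nodes$degree)
    expect_equal(back$edges$weight, net$edges$weight, tolerance = 1e-5)
    expect_null(back$coordinates)  # no layout attached
  }
  expect_error(write_graph_file(net, tempfile(), format = "dot"),
               class = "usage_error")
  # with coordinates embedded
  net2 <- set_layout(net, two_step_gravity_layout(net, seed = 1, max_iter = 20))
  path <- withr::local_tempfile(fileext = ".gexf")
  write_graph_file(net2, path, format = "gexf")
  back <- read_graph_file(path, format = "gexf")
  expect_equal(nrow(back$coordinates), 5L)
})

test_that("exported GraphML is readable by igraph with matching weights", {
  skip_if_not_installed("igraph")
  rec <- make_records(data.frame(
    mirna = c("miR-a", "miR-b"), phenotype = c("age", "age"),
    rho = c(0.5, -0.7)))
  net <- build_network(rec)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(net, path, format = "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 4L)
  expect_setequal(igraph::E(g)$weight, c(50, 70))
})

test_that("interaction tables validate categories and round-trip", {
  t <- make_interactions(
    interaction_row("miR-134", "BACE1", logit = 0.9),
    interaction_row("miR-617", "IL6", logit = 0.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(t, path)
  back <- read_interactions(path, panel = default_gene_panel())
  expect_equal(nrow(back), 2L)
  expect_equal(back$logit_prob, t$logit_prob)

  bad <- as.data.frame(t)
  bad$category[1] <- "Kinase"
  expect_error(interaction_table(bad), "Kinase", class = "validation_error")

  # empty file -> empty table
  writeLines(paste(c("mirna", "gene", "accession", "site", "logit_prob",
                     "category", "source", "source_score"), collapse = "\t"),
             path)
  expect_equal(nrow(read_interactions(path)), 0L)
})
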