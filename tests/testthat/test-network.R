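# signed phenotype-hub network construction, degrees and layout

test_that("network construction creates signed hubs with 100|rho| weights", {
  rec <- make_records(data.frame(
    mirna = "miR-X", phenotype = "age", rho = 0.5))
  net <- build_network(rec)
  expect_setequal(net$nodes$id, c("age_pos", "miR-X"))
  expect_equal(net$edges$weight, 50)

  rec2 <- make_records(data.frame(
    mirna = c("miR-X", "miR-Y"), phenotype = "age", rho = c(0.5, -0.44)))
  net2 <- build_network(rec2)
  hubs <- net2$nodes[net2$nodes$kind == "phenotype_hub", ]
  expect_setequal(hubs$id, c("age_pos", "age_neg"))
  expect_setequal(hubs$sign, c("pos", "neg"))
  expect_setequal(net2$edges$weight, c(50, 44))

  rec3 <- make_records(data.frame(
    mirna = "miR-Z", phenotype = c("age", "mmse", "braak"),
    rho = c(0.5, 0.6, -0.5)))
  net3 <- build_network(rec3)
  expect_equal(net3$nodes$degree[net3$nodes$id == "miR-Z"], 3L)
  expect_equal(nrow(build_network(make_records(data.frame(
    mirna = character(), phenotype = character(), rho = numeric())))$nodes), 0L)
})

test_that("networks are bipartite with bounded weights and conserved degrees", {
  spec <- simulation_spec(n_mirna = 120, seed = 13)
  co <- simulate_cohort(spec)
  m <- presence_filter(normalize_per_subject(simulate_counts(spec, co)), 11)
  rec <- screen_associations(m, co)
  net <- build_network(rec)
  hubs <- net$nodes$id[net$nodes$kind == "phenotype_hub"]
  mirs <- net$nodes$id[net$nodes$kind == "mirna"]
  expect_true(all(net$edges$mirna %in% mirs))
  expect_true(all(net$edges$hub %in% hubs))
  # weights live in (100 * critical_rho(n_used), 100], record-wise
  expect_true(all(net$edges$weight <= 100))
  expect_true(all(abs(rec$rho) >
                    vapply(rec$n_used, critical_rho, 1, alpha = 0.05)))
  # handshake: hub degrees sum to the edge count
  expect_equal(sum(net$nodes$degree[net$nodes$kind == "phenotype_hub"]),
               nrow(net$edges))
  expect_equal(sum(net$nodes$degree), 2L * nrow(net$edges))
})

test_that("edge matrix round-trip reconstructs the network", {
  rec <- make_records(data.frame(
    mirna = c("miR-a", "miR-b", "miR-c"),
    phenotype = c("age", "mmse", "age"), rho = c(0.5, -0.61, 0.44)))
  net <- build_network(rec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_edge_matrix(net, path)
  em <- read_edge_matrix(path)
  rec2 <- make_records(data.frame(
    mirna = em$mirna,
    phenotype = sub("_(pos|neg)$", "", em$hub), rho = em$rho))
  net2 <- build_network(rec2)
  expect_equal(net2$edges[, c("mirna", "hub", "weight")],
               net$edges[, c("mirna", "hub", "weight")])
  expect_equal(net2$nodes, net$nodes)
})

test_that("degree table sorts by degree then id", {
  rec <- make_records(data.frame(
    mirna = c("miR-a", "miR-b", "miR-c", "miR-a", "miR-b"),
    phenotype = c("age", "age", "age", "mmse", "mmse"),
    rho = c(0.5, 0.5, 0.5, 0.6, 0.6)))
  dt <- degree_table(build_network(rec))
  expect_equal(dt$node[1], "age_pos")  # degree 3
  expect_equal(dt$degree[1], 3L)
  expect_true(all(diff(dt$degree) <= 0))
  ties <- dt[dt$degree == 2L, "node"]
  expect_equal(ties, sort(ties))
  expect_equal(nrow(degree_table(build_network(make_records(data.frame(
    mirna = character(), phenotype = character(), rho = numeric()))))), 0L)
})

test_that("gravity layout is deterministic, finite and settles symmetric cases", {
  rec <- make_records(data.frame(
    mirna = c("miR-a", "miR-b"), phenotype = "age", rho = c(0.5, 0.5)))
  net <- build_network(rec)
  l1 <- two_step_gravity_layout(net, seed = 3, max_iter = 300)
  l2 <- two_step_gravity_layout(net, seed = 3, max_iter = 300)
  expect_identical(l1$coordinates, l2$coordinates)
  expect_true(all(is.finite(as.matrix(l1$coordinates[, c("x", "y")]))))
  d12 <- function(l, a, b) {
    ca <- l$coordinates[l$coordinates$id == a, c("x", "y")]
    cb <- l$coordinates[l$coordinates$id == b, c("x", "y")]
    sqrt(sum((ca - cb)^2))
  }
  # the two leaves sit at equal distance from their common hub
  expect_equal(d12(l1, "miR-a", "age_pos"), d12(l1, "miR-b", "age_pos"),
               tolerance = 0.05)
  # single node settles at the gravity centre
  one <- build_network(make_records(data.frame(
    mirna = "miR-solo", phenotype = "age", rho = 0.5)))
  one$nodes <- one$nodes[one$nodes$id == "miR-solo", ]
  one$edges <- one$edges[0, ]
  lone <- two_step_gravity_layout(one, seed = 1, max_iter = 200)
  expect_lt(sqrt(sum(lone$coordinates[, c("x", "y")]^2)), 1e-3)
  expect_error(two_step_gravity_layout(net, tol = -1), class = "usage_error")
})

test_that("layout of K4 with equal weights stays near-symmetric", {
  # four mutually linked nodes cannot be pairwise equidistant in the
  # plane (at most three points are); the attainable symmetry is a
  # tightly bounded spread of the six pairwise distances
  nodes <- data.frame(id = paste0("n", 1:4), kind = "mirna", sign = "none",
                      degree = 3L, stringsAsFactors = FALSE)
  pairs <- combn(nodes$id, 2)
  edges <- data.frame(mirna = pairs[1, ], hub = pairs[2, ], sign = "none",
                      rho = NA_real_, p = NA_real_, weight = 50,
                      stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges, coordinates = NULL),
                   class = "phenotype_network")
  lay <- two_step_gravity_layout(net, seed = 2, max_iter = 1000, tol = 1e-8)
  xy <- as.matrix(lay$coordinates[, c("x", "y")])
  d <- as.vector(dist(xy))
  # both symmetric equilibria (centre + triangle, rhombus) keep the
  # distance ratio below 2; a collapsed or stretched layout would not
  expect_lt(max(d) / min(d), 2)
  expect_true(all(is.finite(xy)))
  # deterministic under the same seed
  lay2 <- two_step_gravity_layout(net, seed = 2, max_iter = 1000, tol = 1e-8)
  expect_identical(lay$coordinates, lay2$coordinates)
})
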