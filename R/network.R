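# Signed phenotype-hub network: each phenotype contributes up to two hub
# nodes (<phenotype>_pos, <phenotype>_neg); miRNA nodes link to the hub
# matching the sign of their significant correlation; edge weight is
# 100 * |rho|. Node size in downstream plots is the degree.

#' Build the phenotype-hub association network
#'
#' One hub node per (phenotype, sign) stratum with at least one record,
#' one node per distinct miRNA; every edge joins a miRNA to a hub
#' (bipartite by construction) with weight 100 |rho|.
#'
#' @param records significance-filtered \code{\link{screen_associations}}
#'   output
#' @return A \code{phenotype_network}: list with \code{nodes}
#'   (id, kind, sign, degree) and \code{edges}
#'   (mirna, hub, sign, rho, p, weight) data.frames.
#' @export
build_network <- function(records) {
  if (nrow(records) == 0L) {
    return(structure(list(
      nodes = data.frame(id = character(), kind = character(),
                         sign = character(), degree = integer(),
                         stringsAsFactors = FALSE),
      edges = data.frame(mirna = character(), hub = character(),
                         sign = character(), rho = numeric(), p = numeric(),
                         weight = numeric(), stringsAsFactors = FALSE),
      coordinates = NULL), class = "phenotype_network"))
  }
  hub_id <- paste0(records$phenotype,
                   ifelse(records$sign == "positive", "_pos", "_neg"))
  edges <- data.frame(mirna = records$mirna, hub = hub_id,
                      sign = records$sign, rho = records$rho,
                      p = records$p_value, weight = 100 * abs(records$rho),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$hub, edges$mirna), , drop = FALSE]
  rownames(edges) <- NULL
  hubs <- unique(edges[, c("hub", "sign")])
  hub_nodes <- data.frame(
    id = hubs$hub, kind = "phenotype_hub",
    sign = ifelse(hubs$sign == "positive", "pos", "neg"),
    stringsAsFactors = FALSE)
  mir_nodes <- data.frame(id = sort(unique(edges$mirna)), kind = "mirna",
                          sign = "none", stringsAsFactors = FALSE)
  nodes <- rbind(hub_nodes[order(hub_nodes$id), , drop = FALSE], mir_nodes)
  deg <- table(c(edges$hub, edges$mirna))
  nodes$degree <- as.integer(deg[nodes$id])
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, coordinates = NULL),
            class = "phenotype_network")
}

#' @export
print.phenotype_network <- function(x, ...) {
  cat(sprintf("phenotype_network: %d hubs, %d miRNAs, %d edges\n",
              sum(x$nodes$kind == "phenotype_hub"),
              sum(x$nodes$kind != "phenotype_hub"), nrow(x$edges)))
  invisible(x)
}

#' Node degree table
#'
#' @param net a \code{phenotype_network}
#' @return data.frame (node, kind, sign, degree) sorted by descending
#'   degree, ties broken lexicographically by node id.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "phenotype_network"))
  n <- net$nodes
  out <- data.frame(node = n$id, kind = n$kind, sign = n$sign,
                    degree = n$degree, stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-phase gravity layout
#'
#' A force-directed layout run as two alternating phases per iteration:
#' phase A applies weighted spring attraction along edges plus pairwise
#' repulsion between all nodes; phase B applies radial gravity toward
#' the origin scaled by node degree, pulling high-degree hubs to the
#' centre. Iteration stops at a steady state (maximum displacement below
#' \code{tol}), when a rounded-position digest repeats (limit cycle), or
#' at \code{max_iter}. Initial placement is seeded and the result is
#' deterministic given the seed. Coordinates are presentation-only: no
#' statistic depends on them.
#'
#' @param net a \code{phenotype_network} (or any list with \code{nodes}
#'   and \code{edges} data.frames in the same shape)
#' @param seed integer seed for the initial placement
#' @param max_iter iteration cap
#' @param tol steady-state threshold on the maximum displacement
#' @param k characteristic length of the force system
#' @param gravity gravity strength
#' @return List (\code{layout_state}) with \code{coordinates}
#'   (id, x, y), \code{iterations}, \code{displacement}, and
#'   \code{converged} (\code{"steady_state"}, \code{"limit_cycle"} or
#'   \code{"max_iter"}).
#' @export
two_step_gravity_layout <- function(net, seed = 1L, max_iter = 500L,
                                    tol = 1e-4, k = 1, gravity = 0.05) {
  if (tol <= 0) usage_error("tol must be positive")
  nodes <- net$nodes
  edges <- net$edges
  n <- nrow(nodes)
  if (n == 0L) usage_error("cannot lay out an empty network")
  set.seed(seed)
  pos <- matrix(stats::runif(2 * n, -1, 1), ncol = 2,
                dimnames = list(nodes$id, c("x", "y")))
  if (n == 1L) pos[1, ] <- c(0, 0)
  deg <- nodes$degree
  ei <- match(edges$mirna, nodes$id)
  ej <- match(edges$hub, nodes$id)
  w <- if (nrow(edges)) edges$weight / 100 else numeric()
  seen <- new.env(parent = emptyenv())
  digest_pos <- function(p) paste(signif(as.vector(p), 6), collapse = ",")
  step <- 0.1
  status <- "max_iter"
  it <- 0L
  disp_max <- Inf
  while (it < max_iter) {
    it <- it + 1L
    force <- matrix(0, n, 2)
    # phase A: spring attraction along edges + all-pairs repulsion
    if (length(ei)) {
      d <- pos[ei, , drop = FALSE] - pos[ej, , drop = FALSE]
      fa <- -d * (w / k)  # linear spring toward the hub, scaled by weight
      add <- rowsum(fa, group = ei)
      idx <- as.integer(rownames(add))
      force[idx, ] <- force[idx, ] + add
      sub <- rowsum(fa, group = ej)
      idx <- as.integer(rownames(sub))
      force[idx, ] <- force[idx, ] - sub
    }
    dx <- outer(pos[, 1], pos[, 1], "-")  # dx[i,j]: repulsion on i from j
    dy <- outer(pos[, 2], pos[, 2], "-")
    dist2 <- dx^2 + dy^2 + 1e-12
    diag(dist2) <- Inf
    force[, 1] <- force[, 1] + rowSums(dx * (k^2 / dist2))
    force[, 2] <- force[, 2] + rowSums(dy * (k^2 / dist2))
    pos_a <- pos + step * force
    # phase B: radial gravity toward the origin, scaled by degree
    gpull <- gravity * (1 + deg)
    pos_b <- pos_a - step * pos_a * gpull
    disp <- sqrt(rowSums((pos_b - pos)^2))
    disp_max <- max(disp)
    pos <- pos_b
    if (disp_max < tol) { status <- "steady_state"; break }
    dg <- digest_pos(pos)
    if (!is.null(seen[[dg]])) { status <- "limit_cycle"; break }
    seen[[dg]] <- TRUE
    step <- step * 0.995  # slow cooling keeps the loop contractive
  }
  list(coordinates = data.frame(id = nodes$id, x = pos[, 1], y = pos[, 2],
                                stringsAsFactors = FALSE),
       iterations = it, displacement = disp_max, converged = status)
}

#' Attach layout coordinates to a network
#'
#' @param net a \code{phenotype_network}
#' @param layout result of \code{\link{two_step_gravity_layout}}
#' @return The network with a \code{coordinates} data.frame set.
#' @export
set_layout <- function(net, layout) {
  stopifnot(inherits(net, "phenotype_network"))
  net$coordinates <- layout$coordinates
  net
}
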