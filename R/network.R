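#' All-pairs correlation matrices over fatigue and analytes
#'
#' Pools the unsmoothed subject-centered z-scores of one group across
#' subject-days and computes the symmetric Pearson correlation and p-value
#' matrices over the `fatigue` node (daily mean variant) plus every analyte.
#' Smoothed views are rejected: network mapping is the one analysis that runs
#' on unsmoothed data, and the guard enforces that exemption. Missing values
#' (degenerate fatigue of zero-variance subjects) are dropped pairwise, so
#' each pair carries its own `n`.
#'
#' @param view The unsmoothed `analysis_view`.
#' @param group `"patient"` or `"control"`.
#' @return List of class `pairwise_matrix`: `r`, `p`, `n` (square matrices
#'   with `fatigue` first), `variables`, `group`.
#' @export
pairwise_matrix <- function(view, group) {
  stopifnot(inherits(view, "analysis_view"))
  if (is_smoothed_view(view))
    stop("network mapping requires the unsmoothed view")
  sel <- view[view$group == group, ]
  if (nrow(sel) == 0) stop("no subjects in group: ", group)
  vars <- c("fatigue", attr(view, "analyte_names"))
  x <- as.matrix(sel[, c("fatigue_mean", attr(view, "analyte_names"))])
  colnames(x) <- vars

  r <- stats::cor(x, use = "pairwise.complete.obs")
  n <- crossprod(!is.na(x))
  # Two-sided p from t = r * sqrt((n - 2) / (1 - r^2)); undefined for n < 3.
  tval <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = pmax(n - 2, 1), lower.tail = FALSE)
  p[n < 3] <- NA_real_
  diag(r) <- 1
  diag(p) <- 0
  structure(list(r = r, p = p, n = n, variables = vars, group = group),
            class = "pairwise_matrix")
}

#' Benjamini-Hochberg threshold over a p-value family
#'
#' Controls the false-discovery rate at level `q` over a family of `m` tests:
#' with p-values sorted ascending, the rejection set is all p at or below
#' `p_(k)` for the largest `k` with `p_(k) <= k * q / m`. Returns the realized
#' (data-adaptive) p threshold, which is what a corrected significance cutoff
#' reported alongside an FDR level corresponds to; with no rejections the
#' threshold is `NA`.
#'
#' @param pvals Numeric p-values in `[0, 1]` (NAs are not counted in `m`).
#' @param q Target false-discovery rate in (0, 1).
#' @return List: `threshold` (largest rejected p or `NA`), `rejected`
#'   (logical, same length as `pvals`), `n_rejected`, `m`, `q`.
#' @examples
#' bh_threshold(c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06), q = 0.05)
#' @export
bh_threshold <- function(pvals, q = 0.01) {
  if (length(q) != 1 || q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  rejected <- !is.na(adj) & adj <= q
  list(threshold = if (any(rejected)) max(pvals[rejected]) else NA_real_,
       rejected = rejected,
       n_rejected = sum(rejected),
       m = sum(!is.na(pvals)),
       q = q)
}

#' Build the FDR-thresholded analyte network
#'
#' Thresholds the all-pairs correlation matrices with [bh_threshold()] over
#' the family of all unique off-diagonal pairs (fatigue counts as one node
#' among the analytes) and assembles the undirected network whose edges are
#' the rejected pairs. The highlighted set comprises the fatigue node, the
#' leptin node, and leptin's significant neighbors.
#'
#' @param pm A `pairwise_matrix`.
#' @param q Target false-discovery rate.
#' @return Object of class `analyte_network`: list with `graph` (igraph),
#'   `edges` (tibble: node1, node2, r, p), `nodes`, `threshold` (realized p
#'   cutoff), `q`, `m`, `highlighted`, `leptin_degree`, `fatigue_leptin_edge`,
#'   `group`.
#' @export
build_network <- function(pm, q = 0.01) {
  stopifnot(inherits(pm, "pairwise_matrix"))
  vars <- pm$variables
  ut <- upper.tri(pm$p)
  pairs <- which(ut, arr.ind = TRUE)
  bh <- bh_threshold(pm$p[ut], q = q)
  keep <- which(bh$rejected)
  edges <- tibble::tibble(
    node1 = vars[pairs[keep, 1]],
    node2 = vars[pairs[keep, 2]],
    r = pm$r[ut][keep],
    p = pm$p[ut][keep]
  )
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = vars, stringsAsFactors = FALSE))
  if (nrow(edges) > 0) {
    igraph::E(g)$r <- edges$r
    igraph::E(g)$p <- edges$p
  }
  deg <- igraph::degree(g)
  leptin_neighbors <- if ("leptin" %in% vars && deg[["leptin"]] > 0)
    names(igraph::neighbors(g, "leptin")) else character(0)
  net <- list(
    graph = g,
    nodes = vars,
    edges = edges,
    threshold = bh$threshold,
    q = q,
    m = bh$m,
    highlighted = unique(c("fatigue", "leptin", leptin_neighbors)),
    leptin_degree = if ("leptin" %in% vars) unname(deg[["leptin"]]) else NA,
    fatigue_leptin_edge = any(
      (edges$node1 == "fatigue" & edges$node2 == "leptin") |
      (edges$node1 == "leptin" & edges$node2 == "fatigue")),
    degrees = deg,
    group = pm$group
  )
  class(net) <- "analyte_network"
  net
}

#' @export
print.analyte_network <- function(x, ...) {
  cat("<analyte_network> group: ", x$group, "; ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges",
      " (FDR q = ", x$q, ", realized p <= ",
      signif(x$threshold, 3), ")\n",
      "  leptin degree: ", x$leptin_degree,
      "; fatigue-leptin edge: ", x$fatigue_leptin_edge, "\n", sep = "")
  invisible(x)
}

#' Force-directed layout (Fruchterman-Reingold)
#'
#' Classic spring-embedded layout for the thresholded network: every node
#' pair repels with force `k^2 / d`, every edge attracts with `d^2 / k`
#' (`k` the ideal spring length for the frame area), displacements are capped
#' by a linearly cooling temperature, and coordinates are clamped to the
#' `[-1, 1]^2` frame and recentered on the origin. Deterministic for a fixed
#' seed; a single node lands at the frame center.
#'
#' @param net An `analyte_network`.
#' @param iterations Number of cooling iterations.
#' @param seed Integer seed for the random initial placement.
#' @return Numeric matrix (nodes x 2) of coordinates, row names = node names.
#' @export
fr_layout <- function(net, iterations = 150, seed = 1L) {
  stopifnot(inherits(net, "analyte_network"))
  nodes <- net$nodes
  n <- length(nodes)
  if (n == 1) {
    return(matrix(0, 1, 2, dimnames = list(nodes, c("x", "y"))))
  }
  set.seed(as.integer(seed))
  pos <- matrix(runif(2 * n, -1, 1), ncol = 2)
  k <- sqrt(4 / n)                      # ideal distance for a [-1,1]^2 frame
  ei <- cbind(match(net$edges$node1, nodes), match(net$edges$node2, nodes))
  temp <- 0.25
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2)
    # Repulsion: k^2 / d for every pair.
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- pos[i, ] - pos[j, ]
        dist <- max(sqrt(sum(d^2)), 1e-9)
        f <- (k^2 / dist) * (d / dist)
        disp[i, ] <- disp[i, ] + f
        disp[j, ] <- disp[j, ] - f
      }
    }
    # Attraction along edges: d^2 / k.
    if (nrow(ei) > 0) {
      for (e in seq_len(nrow(ei))) {
        i <- ei[e, 1]; j <- ei[e, 2]
        d <- pos[i, ] - pos[j, ]
        dist <- max(sqrt(sum(d^2)), 1e-9)
        f <- (dist^2 / k) * (d / dist)
        disp[i, ] <- disp[i, ] - f
        disp[j, ] <- disp[j, ] + f
      }
    }
    len <- pmax(sqrt(rowSums(disp^2)), 1e-9)
    step <- pmin(len, temp) / len
    pos <- pos + disp * step
    pos <- pmin(pmax(pos, -1), 1)
    temp <- temp * (1 - it / iterations)
  }
  pos <- sweep(pos, 2, colMeans(pos))
  # Recentring may nudge points past the frame; rescale uniformly if so.
  extent <- max(abs(pos))
  if (extent > 1) pos <- pos / extent
  dimnames(pos) <- list(nodes, c("x", "y"))
  pos
}

#' Export a network and its layout
#'
#' `write_network_graphml()` writes the graph (with r and p edge attributes)
#' as GraphML; `write_edge_list()` writes a TSV edge list
#' (`node1`, `node2`, `r`, `p`); `write_layout_csv()` writes layout
#' coordinates as CSV.
#'
#' @param net An `analyte_network`.
#' @param coords Coordinate matrix from [fr_layout()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_layout_csv <- function(coords, path) {
  df <- data.frame(node = rownames(coords), x = coords[, 1], y = coords[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.analyte_network <- function(x, coords = NULL, seed = 1L, ...) {
  if (is.null(coords)) coords <- fr_layout(x, seed = seed)
  vcol <- ifelse(x$nodes %in% c("fatigue", "leptin"), "red",
                 ifelse(x$nodes %in% x$highlighted, "salmon", "grey70"))
  plot(x$graph, layout = coords, vertex.color = vcol, vertex.size = 6,
       vertex.label.cex = 0.6, ...)
  invisible(x)
}
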