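#' C-score segregation test against a fixed-fixed null model
#'
#' Binarises the count table and computes the mean checkerboard score over
#' taxon pairs, `C = mean (r_i - S_ij)(r_j - S_ij)` with `r` the per-taxon
#' occupancy and `S` the number of shared sites. The null distribution holds
#' both taxon occupancies and site richness fixed (sequential checkerboard
#' swaps with burn-in and thinning); the standardised effect size and a
#' two-sided permutation p-value indicate whether co-occurrence structure is
#' non-random, the screen run before network inference.
#'
#' @param x a `count_table` or presence-absence matrix (taxa x sites).
#' @param n_null number of null matrices (default 999, minimum 99).
#' @param seed integer seed.
#' @param burn_in swap attempts before sampling (default 5000).
#' @param thin swap attempts between samples (default 100).
#' @return list of class `cscore_result`: `observed`, `null_mean`,
#'   `null_sd`, `ses`, `p`, `n_null`, `null` values.
#' @export
cscore_test <- function(x, n_null = 999, seed = 1L, burn_in = 5000,
                        thin = 100) {
  if (n_null < 99) stop("cscore_test: n_null must be >= 99", call. = FALSE)
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  m <- (m > 0) * 1L
  degenerate <- rowSums(m) == 0 | rowSums(m) == ncol(m)
  if (any(degenerate)) {
    warning("cscore_test: excluding ", sum(degenerate),
            " all-present/all-absent taxa", call. = FALSE)
    m <- m[!degenerate, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("cscore_test: fewer than 2 usable taxa", call. = FALSE)
  obs <- cscore(m)
  null <- with_seed(seed, {
    cur <- swap_matrix(m, burn_in)
    vapply(seq_len(n_null), function(b) {
      cur <<- swap_matrix(cur, thin)
      cscore(cur)
    }, numeric(1))
  })
  mu <- mean(null); sdv <- stats::sd(null)
  p_hi <- (sum(null >= obs) + 1) / (n_null + 1)
  p_lo <- (sum(null <= obs) + 1) / (n_null + 1)
  structure(list(observed = obs, null_mean = mu, null_sd = sdv,
                 ses = if (sdv > 0) (obs - mu) / sdv else 0,
                 p = min(1, 2 * min(p_hi, p_lo)), n_null = n_null,
                 null = null),
            class = "cscore_result")
}

#' Mean checkerboard C-score of a presence-absence matrix
#' @param m binary matrix, taxa as rows.
#' @return mean `(r_i - S)(r_j - S)` over taxon pairs.
#' @export
cscore <- function(m) {
  m <- (as.matrix(m) > 0) * 1L
  r <- rowSums(m)
  S <- tcrossprod(m)                    # shared sites per taxon pair
  P <- (matrix(r, nrow(m), nrow(m)) - S) *
    (matrix(r, nrow(m), nrow(m), byrow = TRUE) - S)
  mean(P[upper.tri(P)])
}

# perform `attempts` random checkerboard swap attempts preserving margins
swap_matrix <- function(m, attempts) {
  nr <- nrow(m); nc <- ncol(m)
  i1 <- sample.int(nr, attempts, replace = TRUE)
  i2 <- sample.int(nr, attempts, replace = TRUE)
  j1 <- sample.int(nc, attempts, replace = TRUE)
  j2 <- sample.int(nc, attempts, replace = TRUE)
  for (t in seq_len(attempts)) {
    a <- i1[t]; b <- i2[t]; cc <- j1[t]; dd <- j2[t]
    if (a == b || cc == dd) next
    x11 <- m[a, cc]; x22 <- m[b, dd]
    if (x11 == x22 && m[a, dd] == m[b, cc] && x11 != m[a, dd]) {
      m[a, cc] <- m[a, dd]; m[a, dd] <- x11
      m[b, dd] <- m[b, cc]; m[b, cc] <- x22
    }
  }
  m
}

#' Infer a correlation-threshold co-occurrence network
#'
#' Pearson correlations of per-sample relative abundances between all taxon
#' pairs across the group's samples; an edge is kept when `|r| >=
#' r_threshold` and the t-test p-value (n-2 df, two-sided) is at most
#' `p_max` (study rule: `|r| >= 0.6`, `p <= 0.01`). Taxa without any edge
#' are excluded from the node list. Correlations are computed on read
#' fractions by default; `clr = TRUE` applies a centred log-ratio transform
#' first, and `adjust = "BH"` applies Benjamini-Hochberg correction (both
#' off by default, matching the study rule).
#'
#' @param x a `count_table` (typically family-collapsed).
#' @param samples optional sample selector defining the group.
#' @param r_threshold minimum absolute Pearson correlation (default 0.6).
#' @param p_max maximum p-value (default 0.01).
#' @param min_samples minimum group size (default 10).
#' @param clr use centred log-ratio abundances instead of fractions.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param group_label optional label stored on the network.
#' @return object of class `cooccurrence_network`: `graph` (igraph),
#'   `edges` data.frame (`from`, `to`, `r`, `p`, `sign`), `nodes`
#'   data.frame (`taxon`, `rel_abund`), `params`, `n_samples`.
#' @export
infer_network <- function(x, samples = NULL, r_threshold = 0.6, p_max = 0.01,
                          min_samples = 10, clr = FALSE,
                          adjust = c("none", "BH"), group_label = NULL) {
  stopifnot(inherits(x, "count_table"))
  adjust <- match.arg(adjust)
  xt <- if (is.null(samples)) x else subset_count_table(x, samples = samples)
  n <- ncol(xt$counts)
  if (n < min_samples)
    stop("infer_network: insufficient replication (", n, " < ", min_samples,
         " samples)", call. = FALSE)
  rel <- relative_abundance(xt)
  mat <- if (clr) {
    lg <- log(rel + 1e-6)
    sweep(lg, 2, colMeans(lg), "-")
  } else rel
  keep <- apply(mat, 1, stats::sd) > 0
  mat <- mat[keep, , drop = FALSE]
  r <- stats::cor(t(mat))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(p) <- 1
  if (adjust == "BH") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], "BH")
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  sel <- which(upper.tri(r) & abs(r) >= r_threshold & p <= p_max, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(mat)[sel[, 1]], to = rownames(mat)[sel[, 2]],
    r = r[sel], p = p[sel],
    sign = ifelse(r[sel] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  node_ids <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = node_ids))
  ra <- rowMeans(rel)[node_ids]
  nodes <- data.frame(taxon = node_ids, rel_abund = unname(ra),
                      stringsAsFactors = FALSE)
  structure(list(graph = g, edges = edges, nodes = nodes,
                 params = list(r_threshold = r_threshold, p_max = p_max,
                               clr = clr, adjust = adjust),
                 n_samples = n, group_label = group_label),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network%s: %d nodes, %d edges (%.0f%% positive), n = %d samples\n",
              if (is.null(x$group_label)) "" else paste0(" [", x$group_label, "]"),
              nrow(x$nodes), nrow(x$edges),
              if (nrow(x$edges)) 100 * mean(x$edges$sign == "positive") else NA,
              x$n_samples))
  invisible(x)
}

#' Node connectivity metrics
#'
#' Degree, closeness centrality and betweenness centrality for every node.
#' Closeness uses the Wasserman-Faust formulation for disconnected graphs:
#' `CC = (n_reach - 1) / sum(d)` scaled by `(n_reach - 1)/(n - 1)`, so
#' values are comparable across components; betweenness is Brandes',
#' normalised by `(n-1)(n-2)/2`. Shortest paths are unweighted.
#'
#' @param net a `cooccurrence_network` (or bare igraph graph).
#' @return data.frame: `taxon`, `degree`, `closeness`, `betweenness`.
#' @export
node_metrics <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n < 2) stop("node_metrics: need at least 2 nodes", call. = FALSE)
  deg <- igraph::degree(g)
  D <- igraph::distances(g, weights = NA)
  cc <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) return(0)
    (length(d) / sum(d)) * (length(d) / (n - 1))
  }, numeric(1))
  bc <- igraph::betweenness(g, weights = NA,
                            normalized = n > 2)
  data.frame(taxon = igraph::V(g)$name, degree = unname(deg),
             closeness = unname(cc), betweenness = unname(bc),
             stringsAsFactors = FALSE)
}

#' Community modules by modularity maximisation
#'
#' Partitions the network into modules maximising Newman's modularity
#' `Q = sum_i (e_ii - a_i^2)` by the greedy agglomerative method (default)
#' or Louvain. Modules holding fewer than 2.5% of the nodes are flagged
#' small, the study's display convention.
#'
#' @param net a `cooccurrence_network` or igraph graph.
#' @param method `"greedy-newman"` (default) or `"louvain"`.
#' @param seed integer seed (Louvain is stochastic).
#' @param small_fraction threshold below which a module is "small".
#' @return list: `membership` (named integer), `Q`, `n_modules`,
#'   `small_modules` (module ids), `method`.
#' @export
detect_modules <- function(net, method = c("greedy-newman", "louvain"),
                           seed = 1L, small_fraction = 0.025) {
  method <- match.arg(method)
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(seq_len(n), igraph::V(g)$name)
    return(list(membership = memb, Q = 0, n_modules = n,
                small_modules = unname(memb), method = method))
  }
  cl <- with_seed(seed, switch(method,
    "greedy-newman" = igraph::cluster_fast_greedy(g, weights = NULL),
    "louvain" = igraph::cluster_louvain(g, weights = NULL)))
  memb <- igraph::membership(cl)
  Q <- igraph::modularity(g, memb)
  sizes <- table(memb)
  small <- as.integer(names(sizes)[sizes < small_fraction * n])
  list(membership = stats::setNames(as.integer(memb), igraph::V(g)$name),
       Q = Q, n_modules = length(sizes), small_modules = small,
       method = method)
}

#' Modularity of an arbitrary partition
#'
#' Definitional `Q = sum_i (e_ii - a_i^2)` over modules, where `e_ii` is the
#' fraction of edges inside module `i` and `a_i` the fraction of edge ends
#' attached to it.
#'
#' @param net a `cooccurrence_network` or igraph graph.
#' @param membership integer module id per node (graph vertex order).
#' @return Q (numeric scalar).
#' @export
modularity_q <- function(net, membership) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  ends <- igraph::as_edgelist(g, names = FALSE)
  memb <- as.integer(membership)
  e_in <- tapply(memb[ends[, 1]] == memb[ends[, 2]],
                 factor(memb[ends[, 1]], levels = sort(unique(memb))), sum)
  e_in[is.na(e_in)] <- 0
  # a_i: fraction of edge endpoints in module i
  degs <- igraph::degree(g)
  a <- tapply(degs, factor(memb, levels = sort(unique(memb))), sum) / (2 * m)
  # e_ii must count edges with BOTH ends in i regardless of which end indexed
  within <- memb[ends[, 1]] == memb[ends[, 2]]
  e_ii <- tapply(within, factor(memb[ends[, 1]], levels = sort(unique(memb))),
                 sum)
  e_ii[is.na(e_ii)] <- 0
  sum(e_ii / m - a^2)
}

#' Keystone taxa of a network
#'
#' Nodes whose degree, closeness and betweenness all strictly exceed the
#' network-wide 75th percentile (linear-interpolation quantile) of the
#' respective metric — the hub criterion used to flag taxa with outsized
#' influence on network structure.
#'
#' @param net a `cooccurrence_network`.
#' @param metrics optional precomputed [node_metrics()] output.
#' @return character vector of keystone taxon ids (possibly empty).
#' @export
keystone_taxa <- function(net, metrics = NULL) {
  if (is.null(metrics)) metrics <- node_metrics(net)
  if (nrow(metrics) < 4) {
    warning("keystone_taxa: fewer than 4 nodes; empty set", call. = FALSE)
    return(character(0))
  }
  q <- vapply(metrics[c("degree", "closeness", "betweenness")],
              stats::quantile, numeric(1), probs = 0.75, names = FALSE)
  sel <- metrics$degree > q[1] & metrics$closeness > q[2] &
    metrics$betweenness > q[3]
  metrics$taxon[sel]
}

#' Zone affinity and edge summary of a network
#'
#' Assigns each node a zone affinity (the floodplain zone where its mean
#' relative abundance is higher), then tallies positive/negative edge
#' percentages, same-zone versus cross-zone edge counts by sign, and a
#' keystone-by-zone cross-tab — the ingredients of the per-sub-biome network
#' comparison.
#'
#' @param net a `cooccurrence_network`.
#' @param h a `sample_hierarchy` covering the network's samples.
#' @param x the `count_table` the network was inferred from (same sample
#'   set).
#' @param keystones optional keystone taxon ids (computed if missing).
#' @return list: `affinity` (named character), `pct_positive`,
#'   `pct_negative`, `edge_tab` (sign x same/cross-zone counts),
#'   `keystone_by_zone`.
#' @export
zone_edge_summary <- function(net, h, x, keystones = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"),
            inherits(h, "sample_hierarchy"), inherits(x, "count_table"))
  ids <- colnames(x$counts)
  hz <- h$zone[match(ids, h$sample_id)]
  if (length(unique(hz[!is.na(hz)])) < 2)
    warning("zone_edge_summary: only one zone represented", call. = FALSE)
  rel <- relative_abundance(x)
  aff <- vapply(net$nodes$taxon, function(tx) {
    mm <- tapply(rel[tx, ], hz, mean)
    if (length(mm) < 2 || anyNA(mm)) return("undetermined")
    names(mm)[which.max(mm)]
  }, character(1))
  e <- net$edges
  pct_pos <- if (nrow(e)) 100 * mean(e$sign == "positive") else NA_real_
  same <- aff[e$from] == aff[e$to] &
    aff[e$from] != "undetermined" & aff[e$to] != "undetermined"
  cross <- aff[e$from] != aff[e$to] &
    aff[e$from] != "undetermined" & aff[e$to] != "undetermined"
  edge_tab <- rbind(
    positive = c(same_zone = sum(same & e$sign == "positive"),
                 cross_zone = sum(cross & e$sign == "positive")),
    negative = c(same_zone = sum(same & e$sign == "negative"),
                 cross_zone = sum(cross & e$sign == "negative")))
  if (is.null(keystones)) keystones <- keystone_taxa(net)
  kz <- table(affinity = aff[net$nodes$taxon],
              keystone = net$nodes$taxon %in% keystones)
  list(affinity = aff, pct_positive = pct_pos,
       pct_negative = if (is.na(pct_pos)) NA_real_ else 100 - pct_pos,
       edge_tab = edge_tab, keystone_by_zone = kz)
}

#' Full network characterisation for one sample group
#'
#' Convenience wrapper: [infer_network()], [node_metrics()],
#' [detect_modules()], [keystone_taxa()], and (when hierarchy given)
#' [zone_edge_summary()], returning one row of summary statistics in the
#' layout of the study's network table.
#'
#' @param x family-level `count_table`.
#' @param samples sample selector for the group.
#' @param h optional `sample_hierarchy` for zone summaries.
#' @param group_label label for reporting.
#' @param seed integer seed (module detection).
#' @param ... passed to [infer_network()].
#' @return list: `network`, `metrics`, `modules`, `keystones`, `zones`,
#'   `summary` (one-row data.frame).
#' @export
analyze_network <- function(x, samples = NULL, h = NULL, group_label = NULL,
                            seed = 1L, ...) {
  net <- infer_network(x, samples = samples, group_label = group_label, ...)
  if (nrow(net$nodes) < 2) {
    return(list(network = net, metrics = NULL, modules = NULL,
                keystones = character(0), zones = NULL,
                summary = data.frame(group = group_label %||% NA,
                                     n_samples = net$n_samples,
                                     nodes = nrow(net$nodes),
                                     edges = nrow(net$edges))))
  }
  met <- node_metrics(net)
  mod <- detect_modules(net, seed = seed)
  ks <- suppressWarnings(keystone_taxa(net, met))
  zones <- if (!is.null(h)) {
    xt <- if (is.null(samples)) x else subset_count_table(x, samples = samples)
    zone_edge_summary(net, h, xt, keystones = ks)
  }
  qtl <- function(v) sprintf("%.3g (%.3g, %.3g)", stats::median(v),
                             stats::quantile(v, 0.25), stats::quantile(v, 0.75))
  summary <- data.frame(
    group = group_label %||% NA_character_, n_samples = net$n_samples,
    nodes = nrow(net$nodes), edges = nrow(net$edges),
    degree = qtl(met$degree), closeness = qtl(met$closeness),
    betweenness = qtl(met$betweenness), keystones = length(ks),
    pct_positive = if (is.null(zones)) 100 * mean(net$edges$sign == "positive")
      else zones$pct_positive,
    pct_negative = if (is.null(zones))
      100 * mean(net$edges$sign == "negative") else zones$pct_negative,
    modularity = mod$Q, n_modules = mod$n_modules,
    stringsAsFactors = FALSE)
  list(network = net, metrics = met, modules = mod, keystones = ks,
       zones = zones, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
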