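# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (enumeration, closed forms,
# definitional recomputation) and shares no code with the package internals.

rand_count_table <- function(n_taxa = 8, n_samples = 6, lambda = 30,
                             seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples)
  count_table(m, paste0("t", seq_len(n_taxa)))
}

# random undirected simple graph as adjacency matrix
rand_adjacency <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, p)
  a <- a + t(a)
  dimnames(a) <- list(paste0("v", 1:n), paste0("v", 1:n))
  a
}

adjacency_to_network <- function(a) {
  if (is.null(rownames(a)))
    dimnames(a) <- list(paste0("v", seq_len(nrow(a))),
                        paste0("v", seq_len(nrow(a))))
  idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  edges <- data.frame(from = rownames(a)[idx[, 1]],
                      to = rownames(a)[idx[, 2]],
                      r = rep(1, nrow(idx)), p = rep(0, nrow(idx)),
                      sign = rep("positive", nrow(idx)),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  structure(list(graph = g, edges = edges,
                 nodes = data.frame(taxon = rownames(a),
                                    rel_abund = 1 / nrow(a)),
                 params = list(), n_samples = NA),
            class = "cooccurrence_network")
}

# all-pairs shortest-path distances by Floyd-Warshall
floyd_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# degree / Wasserman-Faust closeness / normalised betweenness from scratch:
# shortest-path counts via powers of the adjacency matrix (walks of minimal
# length are exactly the shortest paths)
graph_metrics_oracle <- function(a) {
  n <- nrow(a)
  d <- floyd_distances(a)
  maxd <- max(d[is.finite(d)])
  pows <- vector("list", max(maxd, 1))
  pows[[1]] <- a
  if (maxd >= 2) for (k in 2:maxd) pows[[k]] <- pows[[k - 1]] %*% a
  npaths <- function(i, j) {
    if (i == j) return(1)
    if (!is.finite(d[i, j])) return(0)
    pows[[d[i, j]]][i, j]
  }
  deg <- rowSums(a)
  cc <- sapply(1:n, function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) return(0)
    (length(di) / sum(di)) * (length(di) / (n - 1))
  })
  bc <- numeric(n)
  for (v in 1:n) {
    tot <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t])) next
      if (d[s, v] + d[v, t] == d[s, t])
        tot <- tot + npaths(s, v) * npaths(v, t) / npaths(s, t)
    }
    bc[v] <- tot
  }
  if (n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  list(degree = unname(deg), closeness = unname(cc), betweenness = bc)
}

# method-of-moments (EMS) estimates for a balanced two-level nested design:
# y[group, subgroup, rep]; returns c(group, subgroup, residual) variances
ems_nested_oracle <- function(y, group, subgroup) {
  a <- length(unique(group))
  cell <- paste(group, subgroup)
  b <- length(unique(cell)) / a
  n <- length(y) / (a * b)
  gm <- mean(y)
  m_g <- tapply(y, group, mean)
  m_c <- tapply(y, cell, mean)
  ss_a <- b * n * sum((m_g - gm)^2)
  ss_b <- n * sum((m_c - m_g[sub("^([^ ]+) .*$", "\\1", names(m_c))])^2)
  ss_w <- sum((y - m_c[cell])^2)
  ms_a <- ss_a / (a - 1)
  ms_b <- ss_b / (a * (b - 1))
  ms_w <- ss_w / (a * b * (n - 1))
  c(group = (ms_a - ms_b) / (b * n), subgroup = (ms_b - ms_w) / n,
    residual = ms_w)
}

# multi-site Baselga statistics recomputed with explicit set operations
multi_site_oracle <- function(m, mode) {
  n <- ncol(m)
  if (mode == "incidence") {
    sets <- lapply(seq_len(n), function(j) which(m[, j] > 0))
    Si <- lengths(sets)
    ST <- length(Reduce(union, sets))
    smin <- smax <- 0
    for (j in 1:(n - 1)) for (k in (j + 1):n) {
      b <- length(setdiff(sets[[j]], sets[[k]]))
      cc <- length(setdiff(sets[[k]], sets[[j]]))
      smin <- smin + min(b, cc); smax <- smax + max(b, cc)
    }
    denom <- sum(Si) - ST
    tot <- (smin + smax) / (2 * denom + smin + smax)
    trn <- smin / (denom + smin)
    c(tot, trn, tot - trn)
  } else {
    smin <- smax <- sA <- 0
    for (j in 1:(n - 1)) for (k in (j + 1):n) {
      B <- sum(pmax(m[, j] - m[, k], 0))
      C <- sum(pmax(m[, k] - m[, j], 0))
      sA <- sA + sum(pmin(m[, j], m[, k]))
      smin <- smin + min(B, C); smax <- smax + max(B, C)
    }
    tot <- (smin + smax) / (2 * sA + smin + smax)
    trn <- smin / (sA + smin)
    c(tot, trn, tot - trn)
  }
}

# adjusted Rand index from the pair-counting contingency formula
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# tiny balanced nested dataset wrapped in a sample_hierarchy for vca tests
balanced_nested_data <- function(a = 4, b = 3, n = 4, sA = 2, sB = 1.2,
                                 sW = 0.8, seed = 1) {
  set.seed(seed)
  fp <- rep(paste0("FP", 1:a), each = b * n)
  hab <- rep(rep(c("riffle", "run", "pool")[1:b], each = n), a)
  eff_a <- rnorm(a, 0, sA)
  eff_b <- matrix(rnorm(a * b, 0, sB), a, b)
  y <- eff_a[rep(1:a, each = b * n)] +
    eff_b[cbind(rep(1:a, each = b * n), rep(rep(1:b, each = n), a))] +
    rnorm(a * b * n, 0, sW)
  ids <- sprintf("s%03d", seq_along(y))
  h <- sample_hierarchy(ids, "montane", fp, "main-channel", hab)
  list(env = data.frame(sample_id = ids, y = y), h = h,
       group = fp, subgroup = hab)
}
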