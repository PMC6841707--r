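#' Principal component analysis by NIPALS
#'
#' Iterative extraction of principal components tolerant of missing cells:
#' each axis is fitted by alternating least squares on the observed entries,
#' the fitted rank-1 layer is deflated, and the next axis extracted.
#' Variables are expected log-transformed and standardised upstream (the
#' pipeline's environmental tables are). Sign convention: the largest
#' absolute loading on each axis is made positive.
#'
#' @param env numeric matrix or data.frame, samples x variables; `NA`
#'   allowed.
#' @param n_axes number of components to extract.
#' @param center,scale. center and/or scale columns first (means/sds over
#'   observed cells).
#' @param tol convergence tolerance on the score vector.
#' @param max_iter maximum iterations per axis.
#' @return list of class `ordination_result`: `scores` (samples x axes),
#'   `loadings` (variables x axes), `explained` (fraction of total variance
#'   per axis), `method = "nipals-pca"`, `iterations`.
#' @export
nipals_pca <- function(env, n_axes = 2, center = TRUE, scale. = TRUE,
                       tol = 1e-9, max_iter = 500) {
  X <- as.matrix(env)
  storage.mode(X) <- "double"
  if (center) X <- sweep(X, 2, colMeans(X, na.rm = TRUE), "-")
  if (scale.) {
    s <- apply(X, 2, stats::sd, na.rm = TRUE)
    s[s == 0] <- 1
    X <- sweep(X, 2, s, "/")
  }
  obs <- !is.na(X)
  total_ss <- sum(X^2, na.rm = TRUE)
  n <- nrow(X); p <- ncol(X)
  scores <- matrix(0, n, n_axes)
  loadings <- matrix(0, p, n_axes)
  explained <- numeric(n_axes)
  iters <- integer(n_axes)
  Xa <- X
  for (a in seq_len(n_axes)) {
    t_vec <- Xa[, which.max(apply(Xa, 2, function(z) sum(z^2, na.rm = TRUE)))]
    t_vec[is.na(t_vec)] <- 0
    for (it in seq_len(max_iter)) {
      # p = X't / t't over observed cells
      pl <- vapply(seq_len(p), function(j) {
        o <- obs[, j]
        denom <- sum(t_vec[o]^2)
        if (denom == 0) 0 else sum(Xa[o, j] * t_vec[o]) / denom
      }, numeric(1))
      pl <- pl / sqrt(sum(pl^2))
      t_new <- vapply(seq_len(n), function(i) {
        o <- obs[i, ]
        denom <- sum(pl[o]^2)
        if (denom == 0) 0 else sum(Xa[i, o] * pl[o]) / denom
      }, numeric(1))
      delta <- sqrt(sum((t_new - t_vec)^2)) / max(sqrt(sum(t_new^2)), 1e-300)
      t_vec <- t_new
      if (delta < tol) break
    }
    if (delta >= tol)
      stop("nipals_pca: axis ", a, " failed to converge after ", max_iter,
           " iterations", call. = FALSE)
    iters[a] <- it
    flip <- sign(pl[which.max(abs(pl))])
    scores[, a] <- t_vec * flip
    loadings[, a] <- pl * flip
    Xa <- Xa - tcrossprod(t_vec, pl)     # deflate (NA cells stay NA)
    explained[a] <- sum(t_vec^2) / total_ss
  }
  rownames(scores) <- rownames(env)
  rownames(loadings) <- colnames(env)
  structure(list(scores = scores, loadings = loadings, explained = explained,
                 method = "nipals-pca", iterations = iters),
            class = "ordination_result")
}

#' Group dispersion in ordination space (environmental heterogeneity)
#'
#' Euclidean distance of each sample's ordination scores to its group
#' centroid, with per-group mean and coefficient of variation — the
#' environmental-heterogeneity measure compared across floodplains.
#'
#' @param ord an `ordination_result` (or a plain score matrix).
#' @param groups factor-like group labels, one per sample.
#' @return list: `distances` (per sample), `centroids`, and `summary`
#'   data.frame with per-group `n`, `mean_dist`, `cv` (`NA` for singletons).
#' @export
group_dispersion <- function(ord, groups) {
  sc <- if (inherits(ord, "ordination_result")) ord$scores else as.matrix(ord)
  groups <- as.factor(groups)
  stopifnot(nrow(sc) == length(groups))
  if (nlevels(groups) >= 2) {
    d2 <- as.matrix(stats::dist(sc))
    bd <- vegan::betadisper(stats::as.dist(d2), groups, type = "centroid")
    dist_to_centroid <- as.numeric(bd$distances)
    centroids <- bd$centroids
  } else {
    cen <- colMeans(sc)
    dist_to_centroid <- sqrt(rowSums(sweep(sc, 2, cen)^2))
    centroids <- matrix(cen, 1, dimnames = list(levels(groups), NULL))
  }
  names(dist_to_centroid) <- rownames(sc)
  agg <- tapply(dist_to_centroid, groups, function(z)
    c(n = length(z), mean_dist = mean(z),
      cv = if (length(z) < 2 || mean(z) == 0) NA_real_ else
        stats::sd(z) / mean(z)))
  summ <- do.call(rbind, agg)
  summ <- data.frame(group = rownames(summ), summ, row.names = NULL)
  list(distances = dist_to_centroid, centroids = centroids,
       summary = summ)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS of a dissimilarity matrix with multiple random
#' starts (best kept), final configuration centred and rotated to principal
#' axes. The optimisation engine is vegan's monoMDS/metaMDS machinery.
#'
#' @param d dissimilarity matrix or `dist`.
#' @param k embedding dimension (default 2).
#' @param n_starts number of random starts (default 20).
#' @param seed integer seed.
#' @return `ordination_result` with `scores`, `stress` (in `[0, 1]`),
#'   `converged`, `method = "nmds"`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1L) {
  dm <- if (inherits(d, "dist")) d else stats::as.dist(as.matrix(d))
  if (any(!is.finite(dm)))
    stop("nmds: non-finite dissimilarities", call. = FALSE)
  fit <- with_seed(seed,
    vegan::metaMDS(dm, k = k, try = n_starts, trymax = n_starts,
                   trace = 0, autotransform = FALSE, wascores = FALSE))
  structure(list(scores = vegan::scores(fit, display = "sites"),
                 stress = fit$stress, converged = fit$converged,
                 method = "nmds", k = k, n_starts = n_starts, seed = seed),
            class = "ordination_result")
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of community differences among groups:
#' `R = (mean between-group rank - mean within-group rank) / (n(n-1)/4)`,
#' with a permutation p-value using the `(b+1)/(m+1)` estimator. `R` is 1
#' under complete separation and near 0 for random labels.
#'
#' @param d dissimilarity matrix or `dist`.
#' @param groups group labels, one per sample; every group needs >= 2
#'   members.
#' @param n_perm number of label permutations (default 999); `"exact"`
#'   enumerates all distinct label permutations (small n only).
#' @param seed integer seed.
#' @return list: `R`, `p`, `n_perm`, `null` (permuted R values).
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1L) {
  dm <- as.matrix(if (inherits(d, "dist")) d else d)
  groups <- as.factor(groups)
  n <- nrow(dm)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2)
    stop("anosim: need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("anosim: every group needs at least 2 members", call. = FALSE)
  lower <- which(lower.tri(dm))
  rk <- rank(dm[lower])
  same <- outer(groups, groups, "==")[lower]
  denom <- n * (n - 1) / 4
  stat <- function(same_vec)
    (mean(rk[!same_vec]) - mean(rk[same_vec])) / denom
  R <- stat(same)
  if (identical(n_perm, "exact")) {
    perms <- all_permutations(n)
    null <- apply(perms, 1, function(pm)
      stat(outer(groups[pm], groups[pm], "==")[lower]))
    p <- mean(null >= R)    # observed included: identity is one permutation
    n_used <- nrow(perms)
  } else {
    null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      pm <- sample.int(n)
      stat(outer(groups[pm], groups[pm], "==")[lower])
    }, numeric(1)))
    p <- (sum(null >= R) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  list(R = R, p = p, n_perm = n_used, null = null)
}

# all n! permutations of seq_len(n) as rows (n <= 8 guard)
all_permutations <- function(n) {
  stopifnot(n <= 8)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Fit environmental vectors onto an ordination
#'
#' For each variable, least-squares regression of the (centred) variable on
#' the site scores gives a direction of maximal correlation; the arrow is
#' the normalised coefficient vector scaled by `sqrt(r2)`, and significance
#' is assessed by permuting the variable across sites.
#'
#' @param ord `ordination_result` or score matrix (2-D or more).
#' @param env data.frame/matrix of environmental variables (samples x vars).
#' @param n_perm permutations for the r2 test (default 999).
#' @param seed integer seed.
#' @return data.frame: variable, one arrow column per axis, `r2`, `p`.
#' @export
envfit_vectors <- function(ord, env, n_perm = 999, seed = 1L) {
  sc <- if (inherits(ord, "ordination_result")) ord$scores else as.matrix(ord)
  E <- as.matrix(env)
  if (is.null(colnames(E))) colnames(E) <- paste0("var", seq_len(ncol(E)))
  stopifnot(nrow(E) == nrow(sc))
  scc <- scale(sc, center = TRUE, scale = FALSE)
  qr_s <- qr(scc)
  r2_of <- function(v) {
    v <- v - mean(v)
    tv <- sum(v^2)
    if (tv == 0) return(0)
    fit <- qr.fitted(qr_s, v)
    sum(fit^2) / tv
  }
  res <- with_seed(seed, lapply(seq_len(ncol(E)), function(j) {
    v <- E[, j]
    r2 <- r2_of(v)
    if (stats::sd(v) == 0) {
      co <- rep(0, ncol(sc)); p <- 1
    } else {
      co <- qr.coef(qr_s, v - mean(v))
      co[is.na(co)] <- 0
      len <- sqrt(sum(co^2))
      co <- if (len > 0) co / len * sqrt(r2) else co
      null <- vapply(seq_len(n_perm), function(b) r2_of(sample(v)), numeric(1))
      p <- (sum(null >= r2) + 1) / (n_perm + 1)
    }
    c(co, r2 = r2, p = p)
  }))
  out <- as.data.frame(do.call(rbind, res))
  names(out)[seq_len(ncol(sc))] <- paste0("axis", seq_len(ncol(sc)))
  data.frame(variable = colnames(E), out, row.names = NULL)
}
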