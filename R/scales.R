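#' Nested variance-component analysis by REML
#'
#' Fits `y = mu + biome + floodplain(biome) + zone(floodplain) +
#' habitat(zone) + residual` with all effects random, by REML (lme4), and
#' returns the variance attributable to each nested spatial scale as a
#' percentage of the total — the decomposition used to ask at which scale a
#' biogeochemical variable varies most. Negative estimates cannot arise
#' under the constrained optimiser; percentages are renormalised to sum to
#' 100. The biome level has very few units in a typical design and is
#' flagged `low_replication` when it has fewer than 3 levels.
#'
#' @param env data.frame with a `sample_id` column and the variable.
#' @param h a `sample_hierarchy` matching `env$sample_id`.
#' @param variable column name in `env` to decompose.
#' @param log_transform log-transform the variable first (default TRUE;
#'   zeros offset by half the smallest positive value).
#' @param levels nesting levels to include, innermost last.
#' @return data.frame of class `variance_components`: `component`,
#'   `variance`, `percent`, plus attributes `variable`, `low_replication`.
#' @export
vca <- function(env, h, variable, log_transform = TRUE,
                levels = c("biome", "floodplain", "zone", "habitat")) {
  stopifnot(inherits(h, "sample_hierarchy"), variable %in% names(env))
  idx <- match(env$sample_id, h$sample_id)
  if (anyNA(idx))
    stop("vca: env rows without hierarchy entry", call. = FALSE)
  hh <- h[idx, , drop = FALSE]
  y <- env[[variable]]
  if (log_transform) {
    pos <- y[y > 0]
    if (!length(pos)) stop("vca: no positive values to log-transform",
                           call. = FALSE)
    y <- log(y + ifelse(y > 0, 0, min(pos) / 2))
  }
  # nested coding: each level's factor is unique within its parents
  dat <- data.frame(y = y)
  parent <- NULL
  for (lv in levels) {
    lab <- if (is.null(parent)) hh[[lv]] else paste(parent, hh[[lv]], sep = "/")
    dat[[lv]] <- factor(lab)
    parent <- lab
  }
  usable <- levels[vapply(levels, function(lv) nlevels(dat[[lv]]) >= 2,
                          logical(1))]
  if (!length(usable))
    stop("vca: no level has >= 2 units", call. = FALSE)
  form <- stats::as.formula(paste(
    "y ~ 1 +", paste(sprintf("(1 | %s)", usable), collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(
    form, data = dat, REML = TRUE,
    control = lme4::lmerControl(
      optimizer = "bobyqa",
      check.nobs.vs.nlev = "ignore", check.nobs.vs.nRE = "ignore",
      optCtrl = list(rhoend = 1e-12))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- stats::setNames(vc$vcov, vc$grp)
  comp <- c(levels, "residual")
  variance <- c(vapply(levels, function(lv)
    if (lv %in% names(v)) unname(v[lv]) else 0, numeric(1)),
    residual = unname(v["Residual"]))
  variance <- pmax(variance, 0)
  out <- data.frame(component = comp, variance = unname(variance),
                    percent = 100 * unname(variance) / sum(variance))
  class(out) <- c("variance_components", "data.frame")
  attr(out, "variable") <- variable
  attr(out, "low_replication") <- levels[vapply(levels, function(lv)
    nlevels(dat[[lv]]) < 3, logical(1))]
  out
}

#' Distance-based Moran eigenvector maps
#'
#' Spatial eigenfunctions from site coordinates: Euclidean distances are
#' truncated at the longest edge of the minimum spanning tree (so the graph
#' stays connected), distances beyond the threshold are replaced by four
#' times it, and the modified distance matrix is double-centred and
#' eigendecomposed (PCoA). Eigenvectors with positive eigenvalues are kept
#' as spatial predictors; leading vectors describe broad-scale gradients,
#' trailing ones fine-scale patterns.
#'
#' @param coords 2-column matrix/data.frame of projected coordinates (m).
#' @param truncation optional explicit truncation distance; default the
#'   longest MST edge.
#' @param tol relative eigenvalue threshold for "positive".
#' @return list of class `spatial_eigenvectors`: `vectors` (sites x MEMs,
#'   centred, unit norm), `values`, `truncation`.
#' @export
build_dbmem <- function(coords, truncation = NULL, tol = 1e-8) {
  xy <- as.matrix(coords)
  if (nrow(unique(xy)) < 3)
    stop("build_dbmem: need at least 3 distinct sites", call. = FALSE)
  D <- as.matrix(stats::dist(xy))
  if (is.null(truncation)) {
    mst <- vegan::spantree(stats::as.dist(D))
    truncation <- max(mst$dist)
  }
  Dmod <- D
  Dmod[Dmod > truncation] <- 4 * truncation
  # PCoA: double-centre -0.5 * D^2
  A <- -0.5 * Dmod^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  eig <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- eig$values > tol * max(abs(eig$values))
  if (!any(keep))
    stop("build_dbmem: no positive eigenvalues (degenerate coordinates)",
         call. = FALSE)
  vec <- eig$vectors[, keep, drop = FALSE]
  vec <- sweep(vec, 2, colMeans(vec), "-")
  vec <- sweep(vec, 2, sqrt(colSums(vec^2)), "/")
  colnames(vec) <- paste0("MEM", seq_len(ncol(vec)))
  structure(list(vectors = vec, values = eig$values[keep],
                 truncation = truncation),
            class = "spatial_eigenvectors")
}

#' Forward selection of RDA predictors with double stopping
#'
#' Greedy forward selection for redundancy analysis: at each step the
#' candidate with the best fit enters only if its conditional permutation
#' p-value is at most `alpha` and the cumulative adjusted R2 does not exceed
#' that of the global model (Blanchet's double stopping rule). If the global
#' model itself is not significant the selection is empty, with a warning.
#'
#' @param Y response matrix (samples x taxa), typically Hellinger-transformed
#'   abundances (see [hellinger()]).
#' @param X candidate predictor matrix/data.frame (samples x predictors).
#' @param alpha entry threshold on the permutation p-value (default 0.05).
#' @param n_perm permutations per test (default 999).
#' @param seed integer seed.
#' @return list: `selected` (names), `adj_r2` (cumulative after each entry),
#'   `global_adj_r2`, `global_p`, `trace` data.frame.
#' @export
forward_select_rda <- function(Y, X, alpha = 0.05, n_perm = 999, seed = 1L) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  stopifnot(nrow(Y) == nrow(X))
  global <- vegan::rda(Y ~ ., data = X)
  global_r2 <- vegan::RsquareAdj(global)$adj.r.squared
  global_p <- with_seed(derive_seed(seed, "global"),
    stats::anova(global, permutations = n_perm)$`Pr(>F)`[1])
  if (is.na(global_p) || global_p > alpha) {
    warning("forward_select_rda: global model not significant (p = ",
            signif(global_p, 3), "); empty selection", call. = FALSE)
    return(list(selected = character(0), adj_r2 = numeric(0),
                global_adj_r2 = global_r2, global_p = global_p,
                trace = data.frame()))
  }
  selected <- character(0)
  adj_r2 <- numeric(0)
  trace <- list()
  candidates <- names(X)
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    fits <- vapply(remaining, function(v) {
      f <- stats::as.formula(paste("Y ~", paste(c(selected, v), collapse = "+")))
      vegan::RsquareAdj(vegan::rda(f, data = X))$adj.r.squared
    }, numeric(1))
    best <- remaining[which.max(fits)]
    # conditional permutation test of the best candidate given the selected
    f_best <- if (length(selected))
      stats::as.formula(paste("Y ~", best, "+ Condition(",
                              paste(selected, collapse = "+"), ")"))
    else stats::as.formula(paste("Y ~", best))
    p_best <- with_seed(derive_seed(seed, paste0("step", step)),
      stats::anova(vegan::rda(f_best, data = X),
                   permutations = n_perm)$`Pr(>F)`[1])
    # the adjusted-R2 ceiling guards against accumulating spurious
    # predictors; at step 1 the global significance gate already did that
    # job, and the ceiling would reject a lone true predictor half the time
    # (its adjusted R2 exceeds the global one by a symmetric noise term)
    enter <- !is.na(p_best) && p_best <= alpha &&
      (step == 1L || max(fits) <= global_r2 + 1e-12)
    trace[[step]] <- data.frame(step = step, candidate = best,
                                adj_r2 = max(fits), p = p_best,
                                entered = enter)
    if (!enter) break
    selected <- c(selected, best)
    adj_r2 <- c(adj_r2, max(fits))
  }
  list(selected = selected, adj_r2 = adj_r2, global_adj_r2 = global_r2,
       global_p = global_p, trace = do.call(rbind, trace))
}

#' Hellinger transformation of a count table
#'
#' Square root of per-sample relative abundances; the standard response
#' transformation before RDA of community data.
#'
#' @param x a `count_table` or taxa-by-samples matrix.
#' @return samples x taxa numeric matrix.
#' @export
hellinger <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  y <- t(m)
  sqrt(y / rowSums(y))
}

#' Environment-versus-space variance partitioning
#'
#' Partitions the variation of a community matrix between an environmental
#' and a spatial predictor set using adjusted R2 from three RDAs (env, space,
#' joint): `[a]` environment unique, `[b]` shared, `[c]` space unique,
#' `[d]` residual, with `a+b = adjR2(env)`, `b+c = adjR2(space)`,
#' `a+b+c+d = 1`. Unique fractions can be slightly negative (reported as
#' computed and flagged).
#'
#' @param Y response matrix (samples x taxa), e.g. [hellinger()] output.
#' @param X_env environmental predictors (samples x vars).
#' @param X_spatial spatial predictors, e.g. selected MEMs.
#' @return list of class `variance_partition`: `fractions` named vector
#'   (a, b, c, d), `adj_r2` (env, space, full), `negative_fractions`.
#' @export
varpart_fractions <- function(Y, X_env, X_spatial) {
  Y <- as.matrix(Y)
  E <- as.matrix(X_env); S <- as.matrix(X_spatial)
  if (!ncol(E) || !ncol(S))
    stop("varpart_fractions: both predictor sets must be non-empty",
         call. = FALSE)
  full_X <- cbind(E, S)
  if (qr(scale(full_X, scale = FALSE))$rank < ncol(full_X)) {
    qd <- qr(scale(full_X, scale = FALSE))
    dropped <- colnames(full_X)[-qd$pivot[seq_len(qd$rank)]]
    stop("varpart_fractions: rank-deficient full model; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  r2_env <- vegan::RsquareAdj(vegan::rda(Y, E))$adj.r.squared
  r2_spa <- vegan::RsquareAdj(vegan::rda(Y, S))$adj.r.squared
  r2_full <- vegan::RsquareAdj(vegan::rda(Y, full_X))$adj.r.squared
  a <- r2_full - r2_spa
  c_ <- r2_full - r2_env
  b <- r2_env - a
  d <- 1 - r2_full
  fr <- c(a = a, b = b, c = c_, d = d)
  structure(list(fractions = fr,
                 adj_r2 = c(env = r2_env, space = r2_spa, full = r2_full),
                 negative_fractions = names(fr)[fr < 0]),
            class = "variance_partition")
}
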