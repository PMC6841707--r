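#' Per-sample Shannon alpha diversity
#'
#' `H = -sum p_i log p_i` (natural log) over taxa with positive counts.
#' Samples with zero total reads are reported as `NA`.
#'
#' @param x a `count_table`.
#' @return named numeric vector, one H per sample.
#' @export
shannon_alpha <- function(x) {
  stopifnot(inherits(x, "count_table"))
  apply(x$counts, 2, function(cj)
    if (sum(cj) == 0) NA_real_ else entropy_nat(cj))
}

#' Bray-Curtis dissimilarity matrix between samples
#'
#' `d(j,k) = sum|x_ij - x_ik| / sum(x_ij + x_ik)` over taxa.
#'
#' @param x a `count_table` or a numeric taxa-by-samples matrix.
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("bray_curtis: need at least 2 samples", call. = FALSE)
  if (any(colSums(m) == 0))
    stop("bray_curtis: sample(s) with zero total", call. = FALSE)
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Pairwise beta-diversity partition into turnover and nestedness
#'
#' Splits pairwise dissimilarity into its replacement (turnover) and
#' richness-difference (nestedness) components after Baselga. In incidence
#' mode the Sorensen dissimilarity decomposes as
#' `beta_sor = beta_sim + beta_sne` with
#' `beta_sim = min(b,c)/(a + min(b,c))`; in abundance mode the Bray-Curtis
#' dissimilarity decomposes into balanced-variation and abundance-gradient
#' components using the sums `A = sum min(x,y)`, `B`, `C` of per-taxon
#' minima and differences.
#'
#' @param x a `count_table`.
#' @param mode `"incidence"` (Sorensen family) or `"abundance"`
#'   (Bray-Curtis family).
#' @return list of class `beta_partition`: matrices `total`, `turnover`,
#'   `nestedness`, plus `mode`.
#' @export
beta_partition <- function(x, mode = c("incidence", "abundance")) {
  mode <- match.arg(mode)
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  n <- ncol(m)
  tot <- trn <- nes <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    p <- beta_pair(m[, j], m[, k], mode)
    tot[j, k] <- tot[k, j] <- p[1]
    trn[j, k] <- trn[k, j] <- p[2]
    nes[j, k] <- nes[k, j] <- p[3]
  }
  structure(list(total = tot, turnover = trn, nestedness = nes, mode = mode),
            class = "beta_partition")
}

# single-pair Baselga partition; returns c(total, turnover, nestedness)
beta_pair <- function(xj, xk, mode) {
  if (mode == "incidence") {
    pj <- xj > 0; pk <- xk > 0
    a <- sum(pj & pk); b <- sum(pj & !pk); cc <- sum(!pj & pk)
    if (a + b + cc == 0) return(c(NA_real_, NA_real_, NA_real_))
    total <- (b + cc) / (2 * a + b + cc)
    turnover <- if (a + min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
    c(total, turnover, total - turnover)
  } else {
    A <- sum(pmin(xj, xk))
    B <- sum(xj - pmin(xj, xk))
    C <- sum(xk - pmin(xj, xk))
    if (A + B + C == 0) return(c(NA_real_, NA_real_, NA_real_))
    total <- (B + C) / (2 * A + B + C)
    turnover <- if (A + min(B, C) == 0) 0 else min(B, C) / (A + min(B, C))
    c(total, turnover, total - turnover)
  }
}

#' Multi-site beta-diversity partition for a group of samples
#'
#' Baselga's multi-site statistics over all samples of a group (typically
#' one floodplain): incidence mode returns Sorensen `beta_SOR` split into
#' Simpson turnover `beta_SIM` and nestedness `beta_SNE`; abundance mode
#' the multi-site Bray-Curtis family (`beta_BC = beta_BC.bal + beta_BC.gra`).
#'
#' @param x a `count_table`.
#' @param group optional logical/integer/character selector of samples.
#' @param mode `"incidence"` or `"abundance"`.
#' @return named numeric vector `c(total, turnover, nestedness)`.
#' @export
multi_site_beta <- function(x, group = NULL, mode = c("incidence", "abundance")) {
  mode <- match.arg(mode)
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (!is.null(group)) m <- m[, group, drop = FALSE]
  n <- ncol(m)
  if (n < 3) stop("multi_site_beta: need at least 3 samples", call. = FALSE)
  if (mode == "incidence") {
    p <- m > 0
    Si <- colSums(p)                     # per-site richness
    ST <- sum(rowSums(p) > 0)            # pooled richness
    sum_bmin <- 0; sum_bmax <- 0
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      b <- sum(p[, j] & !p[, k]); cc <- sum(!p[, j] & p[, k])
      sum_bmin <- sum_bmin + min(b, cc)
      sum_bmax <- sum_bmax + max(b, cc)
    }
    denom_a <- sum(Si) - ST              # sum of a_i matching terms
    total <- (sum_bmin + sum_bmax) / (2 * denom_a + sum_bmin + sum_bmax)
    turnover <- sum_bmin / (denom_a + sum_bmin)
    c(total = total, turnover = turnover, nestedness = total - turnover)
  } else {
    sum_min <- 0; sum_max <- 0
    for (j in seq_len(n - 1)) for (k in (j + 1):n) {
      B <- sum(m[, j] - pmin(m[, j], m[, k]))
      C <- sum(m[, k] - pmin(m[, j], m[, k]))
      sum_min <- sum_min + min(B, C)
      sum_max <- sum_max + max(B, C)
    }
    # multi-site analogue of A: pairwise sum of shared abundance
    sum_A <- 0
    for (j in seq_len(n - 1)) for (k in (j + 1):n)
      sum_A <- sum_A + sum(pmin(m[, j], m[, k]))
    total <- (sum_min + sum_max) / (2 * sum_A + sum_min + sum_max)
    turnover <- sum_min / (sum_A + sum_min)
    c(total = total, turnover = turnover, nestedness = total - turnover)
  }
}

#' Per-taxon and per-sample contributions to beta diversity
#'
#' Legendre-De Caceres decomposition of total community variance: columns of
#' the (by default Hellinger-transformed) abundance matrix are centred, the
#' total sum of squares is split by taxon (species contributions, SCBD) and
#' by sample (local contributions, LCBD); each vector sums to 1.
#'
#' @param x a `count_table`.
#' @param group optional sample selector.
#' @param transform `"hellinger"` (default), `"relative"` or `"none"`.
#' @return list: `scbd` (per taxon), `lcbd` (per sample), `ss_total`.
#' @export
taxon_contributions <- function(x, group = NULL,
                                transform = c("hellinger", "relative", "none")) {
  transform <- match.arg(transform)
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (!is.null(group)) m <- m[, group, drop = FALSE]
  if (ncol(m) < 3)
    stop("taxon_contributions: need at least 3 samples", call. = FALSE)
  y <- t(m)                              # samples x taxa
  y <- switch(transform,
              hellinger = sqrt(y / rowSums(y)),
              relative = y / rowSums(y),
              none = y)
  yc <- scale(y, center = TRUE, scale = FALSE)
  ss <- sum(yc^2)
  if (ss <= 0)
    stop("taxon_contributions: no variation among samples", call. = FALSE)
  list(scbd = colSums(yc^2) / ss, lcbd = rowSums(yc^2) / ss, ss_total = ss)
}

#' Per-sample fraction of reads in a guild
#'
#' @param x a `count_table` with guild tags.
#' @param guild guild label, e.g. `"heterocystous-cyanobacteria"`; several
#'   labels may be given and are pooled (e.g. both cyanobacterial guilds).
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
guild_fractions <- function(x, guild) {
  stopifnot(inherits(x, "count_table"))
  if (is.null(x$guild))
    stop("guild_fractions: count table has no guild tags", call. = FALSE)
  known <- unique(c(x$guild, "heterocystous-cyanobacteria",
                    "other-cyanobacteria", "diatom", "other", "mixed"))
  bad <- setdiff(guild, known)
  if (length(bad))
    stop("guild_fractions: unknown guild label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  sel <- x$guild %in% guild
  tot <- colSums(x$counts)
  ifelse(tot == 0, NA_real_, colSums(x$counts[sel, , drop = FALSE]) / tot)
}
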