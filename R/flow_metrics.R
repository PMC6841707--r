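#' Colwell's predictability, constancy and contingency of river flow
#'
#' Classifies a periodic discharge series into time states (calendar months
#' by default) and flow classes (log2 bins of the mean-scaled monthly mean,
#' Colwell's convention), builds the time-by-class contingency table, and
#' returns the information-theoretic components: constancy
#' `C = 1 - H(Y)/log s`, contingency (seasonality)
#' `M = (H(X) + H(Y) - H(XY))/log s`, and predictability `P = C + M`, where
#' `X` indexes time states, `Y` flow classes, and `s` the number of classes.
#' `P` is maximal when flow magnitude is either constant (`C`) or fully
#' determined by season (`M`); dams typically depress `M`.
#'
#' @param f a [flow_series()].
#' @param time_states `"month"` (default: calendar months of monthly-mean
#'   discharge) or an integer vector assigning each observation to a state.
#' @param flow_classes `"log2"` (default: `floor(log2(q/mean(q)))`, scale
#'   free) or a numeric vector of explicit class breakpoints.
#' @return list of class `colwell_result`: `P`, `C`, `M`, `n_time_states`,
#'   `n_flow_classes`, and the contingency `table`.
#' @export
colwell <- function(f, time_states = "month", flow_classes = "log2") {
  stopifnot(inherits(f, "flow_series"))
  if (identical(time_states, "month")) {
    ym <- format(f$dates, "%Y-%m")
    q <- tapply(f$discharge, ym, mean)
    month <- as.integer(substr(names(q), 6, 7))
    if (length(unique(substr(names(q), 1, 4))) < 2)
      stop("colwell: need at least 2 complete annual cycles", call. = FALSE)
    state <- month
    values <- as.numeric(q)
  } else {
    state <- as.integer(time_states)
    values <- f$discharge
    stopifnot(length(state) == length(values))
  }
  cls <- flow_class(values, flow_classes)
  s <- length(unique(cls))
  if (s < 2 && length(unique(values)) > 1)
    stop("colwell: degenerate class structure (s < 2)", call. = FALSE)
  tab <- table(factor(state), factor(cls))
  colwell_from_table(tab)
}

# class assignment: log2 bins of mean-scaled values (zeros to lowest bin)
flow_class <- function(values, flow_classes) {
  if (identical(flow_classes, "log2")) {
    sc <- values / mean(values)
    cls <- ifelse(sc > 0, floor(log2(sc)), -Inf)
    cls[!is.finite(cls)] <- min(cls[is.finite(cls)], 0) - 1
    cls
  } else {
    findInterval(values, sort(as.numeric(flow_classes)))
  }
}

#' Colwell components from a time-by-class contingency table
#'
#' @param tab matrix of counts, time states as rows, flow classes as columns.
#' @return a `colwell_result` (see [colwell()]).
#' @export
colwell_from_table <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  s <- ncol(tab)
  logs <- log(s)
  HX <- entropy_nat(rowSums(tab))
  HY <- entropy_nat(colSums(tab))
  HXY <- entropy_nat(as.vector(tab))
  if (s == 1) {
    C <- 1; M <- 0
  } else {
    C <- 1 - HY / logs
    M <- (HX + HY - HXY) / logs
  }
  structure(list(P = C + M, C = C, M = M,
                 n_time_states = nrow(tab), n_flow_classes = s,
                 table = tab),
            class = "colwell_result")
}

#' @export
print.colwell_result <- function(x, ...) {
  cat(sprintf("Colwell components (t=%d states, s=%d classes):\n",
              x$n_time_states, x$n_flow_classes))
  cat(sprintf("  P = %.3f  (C = %.3f constancy, M = %.3f contingency)\n",
              x$P, x$C, x$M))
  invisible(x)
}

#' Bootstrap uncertainty for Colwell's seasonality M
#'
#' Resamples whole years with replacement (preserving within-year
#' seasonality), recomputes `M` for each replicate, and returns the point
#' estimate with bootstrap SE and percentile 95% CI — the error bars of the
#' flow-predictability comparison between free-flowing and dammed rivers.
#'
#' @param f a [flow_series()].
#' @param n_boot number of bootstrap replicates (default 999).
#' @param seed integer seed.
#' @param ... passed to [colwell()].
#' @return list: `M`, `se`, `ci` (2.5/97.5 percentiles), `n_years`,
#'   `boot` (replicate values).
#' @export
colwell_bootstrap <- function(f, n_boot = 999, seed = 1L, ...) {
  stopifnot(inherits(f, "flow_series"))
  yr <- format(f$dates, "%Y")
  years <- unique(yr)
  if (length(years) < 3)
    stop("colwell_bootstrap: need at least 3 years", call. = FALSE)
  point <- colwell(f, ...)$M
  idx <- split(seq_along(yr), yr)
  boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    pick <- sample(years, length(years), replace = TRUE)
    take <- unlist(idx[pick], use.names = FALSE)
    # relabel dates so resampled years remain distinct annual cycles
    dts <- seq.Date(as.Date("2001-01-01"), by = "day", length.out = length(take))
    colwell(flow_series(f$river, dts, f$discharge[take]), ...)$M
  }, numeric(1)))
  list(M = point, se = stats::sd(boot),
       ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       n_years = length(years), boot = boot)
}

#' Habitat diversity of a floodplain
#'
#' Shannon diversity (natural log) of the relative frequencies of habitat
#' types sampled in a floodplain; used as the habitat-diversity axis against
#' flow predictability.
#'
#' @param h a `sample_hierarchy`.
#' @param floodplain floodplain name.
#' @return Shannon H (numeric scalar).
#' @export
habitat_diversity <- function(h, floodplain) {
  stopifnot(inherits(h, "sample_hierarchy"))
  sub <- h[h$floodplain == floodplain, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("habitat_diversity: unknown floodplain: ", floodplain, call. = FALSE)
  entropy_nat(table(sub$habitat))
}
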