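#' Remove rare taxa by prevalence and total read count
#'
#' Drops taxa detected in fewer than a given fraction of samples or carrying
#' fewer than a minimum number of reads in total. The defaults reproduce the
#' study rule: taxa present in less than a quarter of samples or with fewer
#' than 20 reads are removed. `rule = "or"` removes on either condition (the
#' stricter reading, default); `rule = "and"` removes only taxa failing both.
#'
#' @param x a `count_table`.
#' @param min_prevalence_fraction minimum fraction of samples with count > 0.
#' @param min_total_reads minimum total reads across samples.
#' @param rule `"or"` (default) or `"and"`: how the two removal conditions
#'   combine.
#' @return filtered `count_table`; samples unchanged.
#' @export
filter_taxa <- function(x, min_prevalence_fraction = 0.25,
                        min_total_reads = 20, rule = c("or", "and")) {
  stopifnot(inherits(x, "count_table"))
  rule <- match.arg(rule)
  prev <- rowMeans(x$counts > 0)
  tot <- rowSums(x$counts)
  low_prev <- prev < min_prevalence_fraction
  low_tot <- tot < min_total_reads
  drop <- if (rule == "or") low_prev | low_tot else low_prev & low_tot
  if (all(drop))
    warning("filter_taxa: no taxa pass the filter", call. = FALSE)
  subset_count_table(x, taxa = !drop)
}

#' Rarefy samples to a common read depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads; samples with fewer reads than `depth` are dropped (and named in a
#' message). A single seeded draw is used, matching common mothur practice.
#'
#' @param x a `count_table`.
#' @param depth target reads per sample (default 10000).
#' @param seed integer seed for the subsampling draw.
#' @return rarefied `count_table` with attribute `"dropped_samples"`.
#' @export
rarefy <- function(x, depth = 10000, seed = 1L) {
  stopifnot(inherits(x, "count_table"))
  tot <- colSums(x$counts)
  keep <- tot >= depth
  if (!any(keep))
    stop("rarefy: all samples below depth ", depth, call. = FALSE)
  dropped <- colnames(x$counts)[!keep]
  if (length(dropped))
    message("rarefy: dropping ", length(dropped), " sample(s) below depth ",
            depth, ": ", paste(dropped, collapse = ", "))
  m <- x$counts[, keep, drop = FALSE]
  # seeded draw without disturbing the caller's RNG state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  res <- vapply(seq_len(ncol(m)), function(j) {
    cj <- m[, j]
    if (sum(cj) == depth) return(cj)
    picked <- sample.int(sum(cj), depth)
    # map read indices back to taxa via cumulative counts
    tabulate(findInterval(picked - 1L, cumsum(cj), left.open = FALSE) + 1L,
             nbins = length(cj))
  }, integer(nrow(m)))
  dimnames(res) <- dimnames(m)
  out <- count_table(res, x$taxon_ids, x$lineage, x$guild)
  attr(out, "dropped_samples") <- dropped
  out
}

#' Collapse taxa to a lineage rank
#'
#' Sums counts over taxa sharing the same label at the requested rank of the
#' semicolon-delimited lineage (the study collapses OTUs to roughly Family
#' for network analysis). Guild tags propagate when unanimous within a group
#' and become `"mixed"` otherwise; taxa lacking the rank are pooled into
#' `"unclassified-<parent>"`.
#'
#' @param x a `count_table` with lineage annotations.
#' @param level 1-based rank index into the lineage path (e.g. 2 for family
#'   in a `phylum;family` lineage), or a rank label resolved against
#'   `attr(x, "ranks")` when present.
#' @return collapsed `count_table`; per-sample totals are conserved exactly.
#' @export
collapse_taxa <- function(x, level = 2L) {
  stopifnot(inherits(x, "count_table"))
  if (is.null(x$lineage))
    stop("collapse_taxa: count table has no lineage annotations", call. = FALSE)
  parts <- strsplit(x$lineage, ";", fixed = TRUE)
  lab <- vapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) >= level && nzchar(p[level])) p[level]
    else {
      parent <- if (level > 1 && length(p) >= level - 1) p[level - 1] else "root"
      paste0("unclassified-", parent)
    }
  }, character(1))
  groups <- split(seq_along(lab), lab)
  counts <- t(vapply(groups, function(i)
    colSums(x$counts[i, , drop = FALSE]), numeric(ncol(x$counts))))
  if (ncol(x$counts) == 1L) counts <- matrix(counts, ncol = 1L,
                                             dimnames = list(names(groups), colnames(x$counts)))
  lineage <- vapply(groups, function(i) {
    p <- trimws(strsplit(x$lineage[i[1]], ";", fixed = TRUE)[[1]])
    paste(p[seq_len(min(level, length(p)))], collapse = ";")
  }, character(1))
  guild <- if (is.null(x$guild)) NULL else vapply(groups, function(i) {
    g <- unique(x$guild[i])
    if (length(g) == 1L) g else "mixed"
  }, character(1))
  count_table(counts, names(groups), lineage = lineage, guild = guild)
}
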