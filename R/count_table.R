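#' Construct a taxon-by-sample count table
#'
#' The central container of the pipeline: an integer matrix of sequence reads
#' with taxa as rows and samples as columns, carrying per-taxon lineage labels
#' (semicolon-delimited rank path) and an optional guild tag used for
#' cyanobacteria/diatom summaries.
#'
#' @param counts non-negative integer matrix, taxa x samples. Row names are
#'   taken as taxon ids if `taxon_ids` is missing.
#' @param taxon_ids character vector of unique taxon identifiers.
#' @param lineage character vector of semicolon-delimited rank paths (e.g.
#'   `"Cyanobacteria;Nostocaceae"`), or `NULL`.
#' @param guild optional per-taxon tag, one of
#'   `"heterocystous-cyanobacteria"`, `"other-cyanobacteria"`, `"diatom"`,
#'   `"other"` (or `"mixed"` after collapsing).
#' @return an object of class `count_table`.
#' @export
count_table <- function(counts, taxon_ids = rownames(counts), lineage = NULL,
                        guild = NULL) {
  counts <- as.matrix(counts)
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon", seq_len(nrow(counts)))
  taxon_ids <- as.character(taxon_ids)
  storage.mode(counts) <- "double"
  validate_counts(counts, taxon_ids)
  storage.mode(counts) <- "integer"
  rownames(counts) <- taxon_ids
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (!is.null(lineage)) {
    lineage <- as.character(lineage)
    stopifnot(length(lineage) == nrow(counts))
  }
  if (!is.null(guild)) {
    guild <- as.character(guild)
    stopifnot(length(guild) == nrow(counts))
  }
  structure(
    list(counts = counts, taxon_ids = taxon_ids, lineage = lineage,
         guild = guild),
    class = "count_table"
  )
}

validate_counts <- function(counts, taxon_ids) {
  if (anyNA(counts))
    stop("count table validation: missing values in counts", call. = FALSE)
  if (any(counts < 0))
    stop("count table validation: negative counts", call. = FALSE)
  if (any(counts != round(counts)))
    stop("count table validation: non-integer counts", call. = FALSE)
  if (anyDuplicated(taxon_ids))
    stop("count table validation: duplicate taxon ids: ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, %s reads total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  if (!is.null(x$guild))
    cat("guilds:", paste(names(table(x$guild)), table(x$guild),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Subset a count table by taxa and/or samples
#'
#' @param x a `count_table`.
#' @param taxa,samples logical, integer or character index into rows/columns.
#' @return a `count_table`.
#' @export
subset_count_table <- function(x, taxa = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_table"))
  counts <- x$counts
  lineage <- x$lineage
  guild <- x$guild
  if (!is.null(taxa)) {
    if (is.character(taxa)) taxa <- match(taxa, rownames(counts))
    counts <- counts[taxa, , drop = FALSE]
    if (!is.null(lineage)) lineage <- lineage[taxa]
    if (!is.null(guild)) guild <- guild[taxa]
  }
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  count_table(counts, rownames(counts), lineage, guild)
}

#' Convert counts to per-sample relative abundances
#'
#' @param x a `count_table`.
#' @return numeric matrix of column-normalised fractions (columns sum to 1).
#' @export
relative_abundance <- function(x) {
  stopifnot(inherits(x, "count_table"))
  tot <- colSums(x$counts)
  if (any(tot == 0))
    stop("relative_abundance: sample(s) with zero total reads: ",
         paste(colnames(x$counts)[tot == 0], collapse = ", "), call. = FALSE)
  sweep(x$counts, 2, tot, "/")
}

#' Sample hierarchy metadata
#'
#' Per-sample labels for the four nested spatial scales of the study design
#' (biome > floodplain > zone > habitat type) plus projected coordinates.
#' Habitat types are constrained to their zone: riffle, run, pool, confluence
#' and shoreline are main-channel habitats; backwater, side-channel,
#' parafluvial-springbrook, orthofluvial-springbrook and pond are off-channel.
#'
#' @param sample_id character vector of unique sample ids.
#' @param biome `"montane"` or `"grassland"`.
#' @param floodplain floodplain (river) name.
#' @param zone `"main-channel"` or `"off-channel"`.
#' @param habitat habitat type (see Details).
#' @param x,y projected coordinates in metres.
#' @return a `data.frame` of class `sample_hierarchy`.
#' @export
sample_hierarchy <- function(sample_id, biome, floodplain, zone, habitat,
                             x = NA_real_, y = NA_real_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("sample_hierarchy: duplicate sample ids", call. = FALSE)
  biome <- match.arg(as.character(biome), c("montane", "grassland"),
                     several.ok = TRUE)
  zone <- match.arg(as.character(zone), c("main-channel", "off-channel"),
                    several.ok = TRUE)
  habitat <- as.character(habitat)
  bad <- !habitat %in% unlist(habitat_types())
  if (any(bad))
    stop("sample_hierarchy: unknown habitat type(s): ",
         paste(unique(habitat[bad]), collapse = ", "), call. = FALSE)
  mismatch <- (habitat %in% habitat_types()$`main-channel`) !=
    (zone == "main-channel")
  if (any(mismatch))
    stop("sample_hierarchy: habitat type inconsistent with zone for sample(s) ",
         paste(sample_id[mismatch], collapse = ", "), call. = FALSE)
  out <- data.frame(
    sample_id = sample_id, biome = biome,
    floodplain = as.character(floodplain), zone = zone, habitat = habitat,
    x = as.numeric(x), y = as.numeric(y), stringsAsFactors = FALSE
  )
  class(out) <- c("sample_hierarchy", "data.frame")
  out
}

#' Habitat types by floodplain zone
#'
#' @return named list with the five main-channel and five off-channel types.
#' @export
habitat_types <- function() {
  list(
    `main-channel` = c("riffle", "run", "pool", "confluence", "shoreline"),
    `off-channel` = c("backwater", "side-channel", "parafluvial-springbrook",
                      "orthofluvial-springbrook", "pond")
  )
}

#' Pair a count table with its sample hierarchy
#'
#' Checks that samples agree and returns both, ordered identically.
#'
#' @param x a `count_table`.
#' @param h a `sample_hierarchy`.
#' @return list with elements `counts` and `hierarchy`.
#' @export
pair_samples <- function(x, h) {
  stopifnot(inherits(x, "count_table"), inherits(h, "sample_hierarchy"))
  miss <- setdiff(colnames(x$counts), h$sample_id)
  if (length(miss))
    stop("pair_samples: samples missing from hierarchy: ",
         paste(miss, collapse = ", "), call. = FALSE)
  h <- h[match(colnames(x$counts), h$sample_id), , drop = FALSE]
  rownames(h) <- NULL
  class(h) <- c("sample_hierarchy", "data.frame")
  list(counts = x, hierarchy = h)
}

#' Daily discharge series for a river
#'
#' @param river river name.
#' @param dates `Date` vector, strictly increasing, daily.
#' @param discharge non-negative discharge in cubic metres per second.
#' @return a `flow_series` object.
#' @export
flow_series <- function(river, dates, discharge) {
  dates <- as.Date(dates)
  discharge <- as.numeric(discharge)
  stopifnot(length(dates) == length(discharge))
  if (any(diff(as.numeric(dates)) <= 0))
    stop("flow_series: dates must be strictly increasing", call. = FALSE)
  if (anyNA(discharge) || any(discharge < 0))
    stop("flow_series: discharge must be non-negative and complete",
         call. = FALSE)
  structure(list(river = as.character(river), dates = dates,
                 discharge = discharge),
            class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("flow_series '%s': %d days (%s to %s), mean %.2f m3/s\n",
              x$river, length(x$dates), min(x$dates), max(x$dates),
              mean(x$discharge)))
  invisible(x)
}
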