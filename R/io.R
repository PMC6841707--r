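#' Read a count table from disk
#'
#' TSV layout: taxa as rows, first column the taxon id, optional `lineage`
#' and `guild` columns, remaining columns one per sample. A comment header
#' line `# orientation: samples-as-rows` flips the orientation on read, so
#' tables exported samples-first are handled transparently. BIOM-JSON files
#' are read through the biomformat package when available.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"biom-json"`.
#' @return a [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("read_count_table: no such file: ", path, call. = FALSE)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("read_count_table: biomformat package required for biom-json",
           call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(count_table(m, rownames(m)))
  }
  first <- readLines(path, n = 1L)
  samples_as_rows <- grepl("orientation:\\s*samples-as-rows", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("read_count_table: malformed file (need id column plus data): ",
         path, call. = FALSE)
  ids <- as.character(df[[1]])
  lineage <- if ("lineage" %in% names(df)) df[["lineage"]] else NULL
  guild <- if ("guild" %in% names(df)) df[["guild"]] else NULL
  keep <- setdiff(names(df)[-1], c("lineage", "guild"))
  m <- as.matrix(df[, keep, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(df[, keep, drop = FALSE], 2,
                       function(z) any(is.na(suppressWarnings(as.numeric(z))))))
    stop("read_count_table: non-numeric counts in column(s) ",
         paste(keep[bad], collapse = ", "), " of ", path, call. = FALSE)
  }
  rownames(m) <- ids
  if (samples_as_rows) {
    m <- t(m)
    if (!is.null(lineage) || !is.null(guild))
      stop("read_count_table: lineage/guild columns not supported with ",
           "samples-as-rows orientation", call. = FALSE)
    return(count_table(m, rownames(m)))
  }
  count_table(m, ids, lineage = lineage, guild = guild)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]: taxa as rows, `taxon_id` first, then
#' `lineage`/`guild` columns when present, then one column per sample.
#'
#' @param x a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(taxon_id = x$taxon_ids, stringsAsFactors = FALSE)
  if (!is.null(x$lineage)) df$lineage <- x$lineage
  if (!is.null(x$guild)) df$guild <- x$guild
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample hierarchy metadata from TSV
#'
#' Expected columns: `sample_id`, `biome`, `floodplain`, `zone`, `habitat`,
#' and optionally `x`, `y` (projected metres).
#'
#' @param path file path.
#' @return a [sample_hierarchy()].
#' @export
read_sample_hierarchy <- function(path) {
  if (!file.exists(path))
    stop("read_sample_hierarchy: no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "biome", "floodplain", "zone", "habitat")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_sample_hierarchy: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sample_hierarchy(df$sample_id, df$biome, df$floodplain, df$zone, df$habitat,
                   x = if ("x" %in% names(df)) df$x else NA_real_,
                   y = if ("y" %in% names(df)) df$y else NA_real_)
}

#' Write sample hierarchy metadata to TSV
#' @param h a `sample_hierarchy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_hierarchy <- function(h, path) {
  utils::write.table(as.data.frame(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a daily discharge series from TSV
#'
#' Columns `date` (ISO) and `discharge` (m3/s).
#'
#' @param path file path.
#' @param river river name; defaults to the file name stem.
#' @return a [flow_series()].
#' @export
read_flow_series <- function(path, river = NULL) {
  if (!file.exists(path))
    stop("read_flow_series: no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("date", "discharge") %in% names(df)))
    stop("read_flow_series: need columns date, discharge", call. = FALSE)
  if (is.null(river)) river <- sub("\\.[^.]*$", "", basename(path))
  flow_series(river, as.Date(df$date), df$discharge)
}

#' Write a flow series to TSV
#' @param f a `flow_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flow_series <- function(f, path) {
  utils::write.table(
    data.frame(date = format(f$dates), discharge = f$discharge),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a water-chemistry table from TSV
#'
#' One row per habitat sample; a `sample_id` column plus numeric
#' biogeochemical variables (DOC, NH4, NO3, DON, TN, SRP, TP, NP, chla, BOM).
#'
#' @param path file path.
#' @return data.frame with `sample_id` and numeric columns.
#' @export
read_env_table <- function(path) {
  if (!file.exists(path))
    stop("read_env_table: no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("read_env_table: need a sample_id column", call. = FALSE)
  num <- setdiff(names(df), "sample_id")
  if (any(vapply(df[num], function(z) any(z < 0, na.rm = TRUE), logical(1))))
    stop("read_env_table: negative concentrations", call. = FALSE)
  df
}
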