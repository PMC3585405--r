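#' Construct a feature table
#'
#' A feature table holds a samples x features intensity matrix from
#' non-targeted LC-MS profiling together with per-feature mass-to-charge and
#' retention-time metadata. Feature identifiers follow the `"<mz>_<rt>"`
#' dialect (e.g. `"1056.528_226.57"`: m/z 1056.528 Da at 226.57 s), so the
#' metadata is recoverable from the column names alone.
#'
#' @param intensities numeric matrix, samples in rows, features in columns;
#'   finite and non-negative. Row names are sample ids, column names are
#'   feature ids.
#' @param mz,rt optional numeric vectors (Da, seconds) overriding values
#'   parsed from the feature ids; `NA` allowed for unparseable ids kept by
#'   a permissive reader.
#' @param channel `"MS"` (low collision energy) or `"MSE"` (high collision
#'   energy).
#' @return An object of class `feature_table` with elements `intensities`,
#'   `mz`, `rt`, `channel`.
#' @export
feature_table <- function(intensities, mz = NULL, rt = NULL, channel = c("MS", "MSE")) {
  channel <- match.arg(channel)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(colnames(intensities)))
    stop("intensities must have feature ids as column names")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("sample", seq_len(nrow(intensities)))
  if (anyDuplicated(colnames(intensities)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(intensities)[duplicated(colnames(intensities))]),
               collapse = ", "))
  if (any(!is.finite(intensities)))
    stop("intensities must be finite (upstream gap filling is assumed)")
  if (any(intensities < 0))
    stop("negative intensities are not valid ion counts")
  if (is.null(mz) || is.null(rt)) {
    parsed <- parse_feature_ids(colnames(intensities), on_error = "error")
    if (is.null(mz)) mz <- parsed$mz
    if (is.null(rt)) rt <- parsed$rt
  }
  stopifnot(length(mz) == ncol(intensities), length(rt) == ncol(intensities))
  if (any(mz <= 0, na.rm = TRUE)) stop("mz must be positive")
  if (any(rt < 0, na.rm = TRUE)) stop("rt must be non-negative")
  structure(
    list(intensities = intensities, mz = as.numeric(mz), rt = as.numeric(rt),
         channel = channel),
    class = "feature_table")
}

#' Parse "<mz>_<rt>" feature identifiers
#'
#' @param ids character vector of feature ids.
#' @param on_error `"error"` rejects unparseable ids; `"na"` keeps them with
#'   `NA` m/z and retention time.
#' @return data.frame with columns `id`, `mz`, `rt`.
#' @examples
#' parse_feature_ids("1056.528_226.57")
#' @export
parse_feature_ids <- function(ids, on_error = c("error", "na")) {
  on_error <- match.arg(on_error)
  m <- regmatches(ids, regexec("^([0-9]+\\.?[0-9]*)_([0-9]+\\.?[0-9]*)$", ids))
  ok <- lengths(m) == 3L
  if (any(!ok) && on_error == "error")
    stop("unparseable feature id(s): ", paste(utils::head(ids[!ok], 5), collapse = ", "))
  mz <- rt <- rep(NA_real_, length(ids))
  mz[ok] <- as.numeric(vapply(m[ok], `[`, "", 2L))
  rt[ok] <- as.numeric(vapply(m[ok], `[`, "", 3L))
  data.frame(id = ids, mz = mz, rt = rt, stringsAsFactors = FALSE)
}

#' Read a feature table from delimited text
#'
#' Expects the layout produced by peak-picking pipelines after export: first
#' column the sample identifier, remaining columns one molecular feature each,
#' named `"<mz>_<rt>"`. The matrix must already be gap-filled: missing or
#' negative cells are rejected.
#'
#' @param path file path (CSV or TSV; the delimiter is sniffed from the
#'   header line).
#' @param channel collision-energy channel label, `"MS"` or `"MSE"`.
#' @param id_errors passed to [parse_feature_ids()]: `"error"` (default)
#'   rejects malformed ids, `"na"` keeps them without metadata.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, channel = c("MS", "MSE"),
                               id_errors = c("error", "na")) {
  channel <- match.arg(channel)
  id_errors <- match.arg(id_errors)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- as.character(df[[1L]])
  parsed <- parse_feature_ids(colnames(mat), on_error = id_errors)
  ft <- feature_table(mat, mz = parsed$mz, rt = parsed$rt, channel = channel)
  message(sprintf("read %d samples x %d features from %s",
                  nrow(mat), ncol(mat), path))
  ft
}

#' Write a feature table to delimited text
#'
#' Inverse of [read_feature_table()]: first column `sample`, then one column
#' per feature id.
#'
#' @param ft a [feature_table()].
#' @param path output path; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(sample = rownames(ft$intensities), ft$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average technical replicates to accession-level rows
#'
#' LC-MS injections are typically replicated (three technical replicates in a
#' randomized injection order is common); network and association analyses
#' operate on one row per biological line, so replicate injections are
#' averaged (arithmetic mean per feature) before scaling.
#'
#' @param ft a [feature_table()] with one row per injection.
#' @param replicate_map named character vector mapping every sample
#'   (injection) id to its biological line id.
#' @return A [feature_table()] with one row per biological id, in first-seen
#'   order of `replicate_map`.
#' @export
average_technical_replicates <- function(ft, replicate_map) {
  stopifnot(inherits(ft, "feature_table"))
  samples <- rownames(ft$intensities)
  unmapped <- setdiff(samples, names(replicate_map))
  if (length(unmapped))
    stop("unmapped sample(s): ", paste(utils::head(unmapped, 5), collapse = ", "))
  bio <- replicate_map[samples]
  groups <- unique(bio)
  out <- rowsum(ft$intensities, group = bio, reorder = FALSE) /
    as.vector(table(bio)[unique(bio)])
  out <- out[groups, , drop = FALSE]
  feature_table(out, mz = ft$mz, rt = ft$rt, channel = ft$channel)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features, channel %s\n",
              nrow(x$intensities), ncol(x$intensities), x$channel))
  cat(sprintf("  mz range [%.3f, %.3f], rt range [%.2f, %.2f] s\n",
              min(x$mz, na.rm = TRUE), max(x$mz, na.rm = TRUE),
              min(x$rt, na.rm = TRUE), max(x$rt, na.rm = TRUE)))
  invisible(x)
}
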