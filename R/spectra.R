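#' Construct a spectrum
#'
#' A peak list with relative intensities scaled so the base peak is exactly
#' 999 (the NIST msp convention). Peaks are stored in ascending m/z order;
#' zero-intensity peaks are dropped.
#'
#' @param mz numeric m/z values (Da).
#' @param intensity matching non-negative intensities (any scale).
#' @param name spectrum name/identifier.
#' @param precursor_mz optional precursor m/z.
#' @param rt optional retention time (s).
#' @param kind `"MS"` (survey) or `"idMSMS"` (reconstructed fragment
#'   spectrum).
#' @param provenance character vector of contributing feature ids.
#' @return An object of class `spectrum`; zero peaks is permitted but the
#'   object carries `empty = TRUE`.
#' @export
spectrum <- function(mz, intensity, name = "spectrum", precursor_mz = NA_real_,
                     rt = NA_real_, kind = c("MS", "idMSMS"),
                     provenance = character()) {
  kind <- match.arg(kind)
  stopifnot(length(mz) == length(intensity))
  mz <- unname(as.numeric(mz)); intensity <- unname(as.numeric(intensity))
  keep <- intensity > 0
  mz <- mz[keep]; intensity <- intensity[keep]
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  provenance_ord <- if (length(provenance) == length(keep))
    provenance[keep][ord] else provenance
  if (length(intensity)) intensity <- intensity / max(intensity) * 999
  structure(list(mz = mz, intensity = intensity, name = name,
                 precursor_mz = precursor_mz, rt = rt, kind = kind,
                 provenance = provenance_ord, empty = length(mz) == 0L),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum '%s' (%s): %d peaks%s%s\n", x$name, x$kind,
              length(x$mz),
              if (!is.na(x$precursor_mz)) sprintf(", precursor %.4f", x$precursor_mz) else "",
              if (!is.na(x$rt)) sprintf(", rt %.2f s", x$rt) else ""))
  invisible(x)
}

#' Retention-time grouping for spectral reconstruction
#'
#' Candidate fragments for an indiscriminant MS/MS spectrum are the features
#' eluting with the feature of interest: all features whose retention time
#' lies within `window` seconds on either side of the target's.
#'
#' @param target_id feature id (`"<mz>_<rt>"`) of the feature of interest.
#' @param ft a [feature_table()] to search (typically the high
#'   collision-energy channel).
#' @param window half-window in seconds (default 2).
#' @return character vector of candidate feature ids (the target itself
#'   included when present in `ft`).
#' @export
rt_window_group <- function(target_id, ft, window = 2) {
  stopifnot(inherits(ft, "feature_table"))
  rt_target <- parse_feature_ids(target_id)$rt
  ids <- colnames(ft$intensities)
  ids[abs(ft$rt - rt_target) <= window]
}

#' Correlational filter for co-eluting features
#'
#' Fragments of one compound rise and fall together across samples, so
#' candidates are kept only when their cross-sample Pearson correlation with
#' the target feature reaches `r_min`. Zero-variance candidates are dropped.
#'
#' @param ft a [feature_table()] containing the candidates.
#' @param candidates candidate feature ids.
#' @param target_profile numeric per-sample intensity vector of the target
#'   feature (same sample order as `ft`).
#' @param r_min minimum Pearson correlation (default 0.5).
#' @return retained candidate ids.
#' @export
correlation_filter <- function(ft, candidates, target_profile, r_min = 0.5) {
  stopifnot(inherits(ft, "feature_table"))
  if (nrow(ft$intensities) < 3L) stop("need at least 3 samples to correlate")
  if (stats::sd(target_profile) == 0) stop("target profile has zero variance")
  keep <- vapply(candidates, function(id) {
    x <- ft$intensities[, id]
    stats::sd(x) > 0 && stats::cor(x, target_profile) >= r_min
  }, NA)
  candidates[keep]
}

#' Reconstruct MS and idMS/MS spectra for a feature of interest
#'
#' Emulates indiscriminant MS/MS: the instrument alternates a low
#' collision-energy (survey, "MS") and a high collision-energy (all-ion
#' fragmentation, "MSE") scan, so no precursor is ever isolated. A fragment
#' spectrum for a target feature is reconstructed by (1) collecting features
#' in either channel within a retention-time window of the target and (2)
#' keeping those whose cross-sample abundance pattern correlates with the
#' target. Peak intensity is the median intensity of the retained feature
#' across samples, renormalized to base peak 999.
#'
#' @param target_id feature id in the low collision-energy table.
#' @param low_ce,high_ce [feature_table()]s for the two channels, same
#'   samples in the same order.
#' @param window retention-time half-window, seconds (default 2).
#' @param r_min correlational-filter threshold (default 0.5).
#' @return list with `ms` and `idmsms` [spectrum()]s (provenance records the
#'   contributing feature ids; an empty spectrum carries `empty = TRUE`).
#' @export
reconstruct_idmsms <- function(target_id, low_ce, high_ce, window = 2,
                               r_min = 0.5) {
  stopifnot(inherits(low_ce, "feature_table"), inherits(high_ce, "feature_table"))
  if (!target_id %in% colnames(low_ce$intensities))
    stop("target feature ", target_id, " absent from the low-CE table")
  if (!identical(rownames(low_ce$intensities), rownames(high_ce$intensities)))
    stop("channels must cover the same samples in the same order")
  target_profile <- low_ce$intensities[, target_id]
  target_mz <- parse_feature_ids(target_id)$mz
  target_rt <- parse_feature_ids(target_id)$rt
  build <- function(ft, kind) {
    cand <- rt_window_group(target_id, ft, window = window)
    kept <- if (length(cand))
      correlation_filter(ft, cand, target_profile, r_min = r_min)
    else character()
    idx <- match(kept, colnames(ft$intensities))
    spectrum(mz = ft$mz[idx],
             intensity = apply(ft$intensities[, idx, drop = FALSE], 2L,
                               stats::median),
             name = paste0(target_id, "_", kind),
             precursor_mz = target_mz, rt = target_rt, kind = kind,
             provenance = kept)
  }
  list(ms = build(low_ce, "MS"), idmsms = build(high_ce, "idMSMS"))
}

#' Write spectra as a NIST-style .msp library
#'
#' One record per spectrum: `Name:`, optional `PrecursorMZ:` and `RT:`,
#' `Num Peaks:`, then one `mz intensity` pair per line, records separated by
#' a blank line — the dialect spectral viewers and library-search tools
#' consume.
#'
#' @param spectra a [spectrum()] or list of them.
#' @param path output path.
#' @export
write_msp <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  lines <- unlist(lapply(spectra, function(s) {
    stopifnot(inherits(s, "spectrum"))
    c(paste0("Name: ", s$name),
      if (!is.na(s$precursor_mz)) paste0("PrecursorMZ: ", sprintf("%.4f", s$precursor_mz)),
      if (!is.na(s$rt)) paste0("RT: ", sprintf("%.2f", s$rt)),
      paste0("Num Peaks: ", length(s$mz)),
      if (length(s$mz)) sprintf("%.4f %.4f", s$mz, s$intensity),
      "")
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a .msp spectral library
#'
#' Inverse of [write_msp()].
#'
#' @param path file path.
#' @return list of [spectrum()]s.
#' @export
read_msp <- function(path) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^Name:", lines)))
  recs <- recs[names(recs) != "0"]
  lapply(unname(recs), function(block) {
    block <- block[block != ""]
    field <- function(key) {
      hit <- grep(paste0("^", key, ":"), block, value = TRUE)
      if (length(hit)) sub(paste0("^", key, ":\\s*"), "", hit[1]) else NA_character_
    }
    n <- as.integer(field("Num Peaks"))
    if (is.na(n)) stop("malformed msp record (missing Num Peaks)")
    peak_lines <- grep("^[0-9]", block, value = TRUE)
    if (length(peak_lines) != n)
      stop("malformed msp record: declared ", n, " peaks, found ",
           length(peak_lines))
    mz <- int <- numeric(n)
    if (n > 0L) {
      parts <- strsplit(peak_lines, "\\s+")
      mz <- as.numeric(vapply(parts, `[`, "", 1L))
      int <- as.numeric(vapply(parts, `[`, "", 2L))
    }
    spectrum(mz, int, name = field("Name"),
             precursor_mz = as.numeric(field("PrecursorMZ")),
             rt = as.numeric(field("RT")),
             kind = "MS")
  })
}

#' Cosine similarity between two spectra
#'
#' Peaks are matched greedily across spectra by smallest m/z difference
#' within the tolerance (each peak used at most once); the score is the
#' normalized dot product of matched intensities, 0 when no peak pairs
#' match and 1 for identical spectra.
#'
#' @param s1,s2 [spectrum()]s (non-empty).
#' @param mz_tol matching tolerance in Da (default 0.01).
#' @return similarity in `[0, 1]`.
#' @export
cosine_match <- function(s1, s2, mz_tol = 0.01) {
  stopifnot(inherits(s1, "spectrum"), inherits(s2, "spectrum"))
  if (s1$empty || s2$empty) stop("cannot match empty spectra")
  pairs <- expand.grid(i = seq_along(s1$mz), j = seq_along(s2$mz))
  pairs$d <- abs(s1$mz[pairs$i] - s2$mz[pairs$j])
  pairs <- pairs[pairs$d <= mz_tol, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used1 <- used2 <- logical(0)
  dot <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (i %in% used1 || j %in% used2) next
    dot <- dot + s1$intensity[i] * s2$intensity[j]
    used1 <- c(used1, i); used2 <- c(used2, j)
  }
  dot / sqrt(sum(s1$intensity^2) * sum(s2$intensity^2))
}
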