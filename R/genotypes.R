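#' Construct a genotype matrix
#'
#' Biallelic SNP dosages for a panel of lines. SNP identifiers follow the
#' `"S<chrom>_<pos>"` dialect (e.g. `"S7_18857356"`: chromosome 7, position
#' 18,857,356 bp), so the map is recoverable from the column names.
#'
#' @param dosage numeric matrix, lines in rows, SNPs in columns; entries in
#'   \{0, 1, 2\} or `NA` for missing calls.
#' @param chrom,pos optional integer vectors overriding values parsed from
#'   the SNP ids.
#' @return An object of class `genotype_matrix` with elements `dosage`,
#'   `chrom`, `pos`.
#' @export
genotype_matrix <- function(dosage, chrom = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(colnames(dosage))) stop("dosage must have SNP ids as column names")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("line", seq_len(nrow(dosage)))
  if (anyDuplicated(colnames(dosage)))
    stop("duplicate SNP ids")
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad))
    stop("dosages must be 0/1/2 or missing; offending value(s): ",
         paste(utils::head(unique(dosage[bad]), 5), collapse = ", "))
  if (is.null(chrom) || is.null(pos)) {
    parsed <- parse_snp_ids(colnames(dosage))
    if (is.null(chrom)) chrom <- parsed$chrom
    if (is.null(pos)) pos <- parsed$pos
  }
  stopifnot(length(chrom) == ncol(dosage), length(pos) == ncol(dosage))
  structure(list(dosage = dosage, chrom = as.integer(chrom), pos = as.numeric(pos)),
            class = "genotype_matrix")
}

#' Parse "S<chrom>_<pos>" SNP identifiers
#'
#' @param ids character vector of SNP ids.
#' @return data.frame with columns `id`, `chrom`, `pos`.
#' @examples
#' parse_snp_ids("S7_18857356")
#' @export
parse_snp_ids <- function(ids) {
  m <- regmatches(ids, regexec("^S([0-9]+)_([0-9]+)$", ids))
  ok <- lengths(m) == 3L
  if (any(!ok))
    stop("malformed SNP id(s): ", paste(utils::head(ids[!ok], 5), collapse = ", "))
  data.frame(id = ids,
             chrom = as.integer(vapply(m, `[`, "", 2L)),
             pos = as.numeric(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Read genotype dosages from text
#'
#' Supports two dialects. Numeric: first column the line id, remaining
#' columns SNP dosages 0/1/2 (`NA` or -9 for missing). HapMap-style: the
#' standard 11 metadata columns (`rs#`, `alleles`, `chrom`, `pos`, ...)
#' followed by one column per line holding single-letter genotype calls;
#' calls are converted to minor-allele dosage, `N` to missing, and
#' non-biallelic markers rejected.
#'
#' @param path file path (delimiter sniffed from the header).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", "-9"),
                          comment.char = "")  # HapMap headers start with rs#
  if (identical(names(df)[1:4], c("rs#", "alleles", "chrom", "pos")))
    return(read_hapmap_df(df))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1L]])
  genotype_matrix(mat)
}

# HapMap-style text -> dosage of the non-reference (alphabetically second)
# allele, per the "alleles" column "A/B".
read_hapmap_df <- function(df) {
  meta_n <- 11L
  alleles <- strsplit(df[["alleles"]], "/", fixed = TRUE)
  if (any(lengths(alleles) != 2L))
    stop("non-biallelic marker(s) in HapMap input")
  calls <- as.matrix(df[, -(seq_len(meta_n)), drop = FALSE])
  # IUPAC heterozygote codes for the 6 unordered base pairs
  het <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  dos <- matrix(NA_real_, nrow = nrow(calls), ncol = ncol(calls))
  for (i in seq_len(nrow(calls))) {
    a <- alleles[[i]][1]; b <- alleles[[i]][2]
    key <- paste0(sort(c(a, b)), collapse = "")
    row <- calls[i, ]
    d <- rep(NA_real_, length(row))
    d[row == a] <- 0; d[row == b] <- 2
    d[row == het[[key]]] <- 1
    bad <- !is.na(row) & row != "N" & is.na(d)
    if (any(bad))
      stop("call(s) inconsistent with declared alleles at ", df[["rs#"]][i])
    dos[i, ] <- d
  }
  mat <- t(dos)
  colnames(mat) <- df[["rs#"]]
  rownames(mat) <- colnames(calls)
  genotype_matrix(mat, chrom = df[["chrom"]], pos = df[["pos"]])
}

#' Write genotype dosages as numeric delimited text
#'
#' @param g a [genotype_matrix()].
#' @param path output path (`.tsv` for tabs, else commas).
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(line = rownames(g$dosage), g$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-SNP minor allele frequency
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector, `min(p, 1 - p)` of the dosage allele frequency,
#'   missing calls excluded.
#' @export
minor_allele_freq <- function(g) {
  p <- colMeans(g$dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}
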