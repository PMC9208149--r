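#' Normalize a gene product (function) name
#'
#' Function names are compared after uppercasing, trimming and collapsing
#' internal whitespace, so that e.g. "mfs  transporter" and "MFS transporter"
#' count as the same function. A strict mode keeps the string verbatim for
#' users who want byte-identical matching.
#'
#' @param x character vector of product strings.
#' @param strict if `TRUE`, return `x` unchanged (case-sensitive matching).
#' @return character vector of normalized names.
#' @export
normalize_function <- function(x, strict = FALSE) {
  if (strict) return(x)
  x <- toupper(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# stable, locale-independent ordering helper
ord <- function(...) order(..., method = "radix")

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# gap between [a_start,a_end) and [b_start,b_end) with a_end <= b_start
interval_gap <- function(a_end, b_start) b_start - a_end

# check mandatory columns
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

#' Build stable occurrence identifiers
#' @noRd
occ_key <- function(replicon_id, start, end) {
  sprintf("%s:%d-%d", replicon_id, as.integer(start), as.integer(end))
}

# deterministic e-value used by the simulator: a monotone function of
# alignment length x identity so that best-hit resolution is reproducible
sim_evalue <- function(alen, pident) {
  expo <- pmin(180, round(alen * pident / 100 / 4))
  10^(-expo)
}

#' Assign half-open distance bins
#'
#' Bins follow the left-closed right-open convention: `[50-100[` includes 50
#' and excludes 100. Distance 0 (an IS overlapping the gene) is kept in a
#' dedicated `overlap` bin; positive distances start at `[1-50[`.
#'
#' @param d non-negative integer distances in bp.
#' @param width bin width in bp.
#' @return character vector of bin labels.
#' @export
dist_bin <- function(d, width = 50) {
  lab <- character(length(d))
  lab[d == 0] <- "overlap"
  pos <- d > 0
  lo <- pmax(1L, (d[pos] %/% width) * width)
  hi <- ((d[pos] %/% width) + 1L) * width
  lab[pos] <- sprintf("[%d-%d[", lo, hi)
  lab
}

#' Assign half-open size bins
#' @param x positive integer sizes in bp.
#' @param width bin width in bp.
#' @return character vector of bin labels such as `[1200-1300[`.
#' @export
size_bin <- function(x, width = 100) {
  lo <- (x %/% width) * width
  sprintf("[%d-%d[", lo, lo + width)
}

# write a TSV deterministically (no quotes unless needed, no row names)
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             quote = "", comment.char = "", check.names = FALSE, ...)
}
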