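tax_ranks <- c("phylum", "class", "order", "family", "genus", "species",
               "strain")

#' Read a taxonomy lineage table
#'
#' TSV with columns `assembly_id` plus the seven ranks phylum..strain.
#' Proteobacterial classes are promoted to phylum rank at load time
#' (e.g. a row with phylum "Proteobacteria" and class "Alphaproteobacteria"
#' is analyzed with phylum = "Alphaproteobacteria"), because those classes
#' are treated as phylum-level clades throughout the analysis.
#'
#' @param path TSV file.
#' @param promote_proteobacteria logical; promote proteobacterial classes.
#' @return data frame keyed by `assembly_id` with the seven ranks.
#' @export
read_taxonomy <- function(path, promote_proteobacteria = TRUE) {
  df <- read_tsv(path)
  need_cols(df, c("assembly_id", tax_ranks), path)
  if (anyDuplicated(df$assembly_id))
    stopf("duplicate assembly_id in taxonomy: %s",
          paste(unique(df$assembly_id[duplicated(df$assembly_id)]),
                collapse = ", "))
  for (r in c("assembly_id", tax_ranks))
    if (any(is.na(df[[r]]) | df[[r]] == ""))
      stopf("taxonomy rank '%s' has empty values", r)
  if (promote_proteobacteria) {
    pro <- df$phylum == "Proteobacteria"
    df$phylum[pro] <- df$class[pro]
  }
  rownames(df) <- NULL
  df[, c("assembly_id", tax_ranks)]
}

#' Check that every assembly has a lineage
#' @param taxonomy taxonomy data frame.
#' @param assembly_ids character vector to check.
#' @return invisibly `TRUE`; errors listing missing IDs otherwise.
#' @export
check_taxonomy_coverage <- function(taxonomy, assembly_ids) {
  miss <- setdiff(unique(assembly_ids), taxonomy$assembly_id)
  if (length(miss))
    stopf("assemblies without taxonomy lineage: %s",
          paste(miss, collapse = ", "))
  invisible(TRUE)
}

motif_types <- c("TFBS", "promoter", "terminator", "riboswitch")

#' Read regulatory motif intervals
#'
#' BED-like TSV (0-based half-open on disk, like BED) with columns
#' `replicon_id`, `start`, `end`, `motif_id`, `strand`, `motif_type`,
#' `provenance`. Types are TFBS, promoter, terminator or riboswitch;
#' provenance is `experimental` or `predicted`.
#'
#' @param path file path.
#' @return data frame of motifs; zero rows for an empty file.
#' @export
read_motifs <- function(path) {
  cols <- c("replicon_id", "start", "end", "motif_id", "strand",
            "motif_type", "provenance")
  if (file.size(path) == 0)
    return(stats::setNames(
      data.frame(character(), integer(), integer(), character(), character(),
                 character(), character(), stringsAsFactors = FALSE), cols))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   quote = "", comment.char = "#")
  if (ncol(df) != length(cols))
    stopf("%s: expected %d tab-separated columns, found %d", path,
          length(cols), ncol(df))
  names(df) <- cols
  bad <- setdiff(unique(df$motif_type), motif_types)
  if (length(bad)) stopf("unknown motif type token(s): %s",
                         paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$provenance), c("experimental", "predicted"))
  if (length(bad)) stopf("unknown provenance token(s): %s",
                         paste(bad, collapse = ", "))
  if (any(df$start >= df$end)) stopf("motif intervals must satisfy start < end")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write regulatory motifs
#' @param motifs motif data frame as returned by [read_motifs()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  write.table(motifs, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

blast6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")

#' Read BLAST tabular (outfmt 6) hits of IS members against replicons
#'
#' Subject coordinates are normalized to 0-based half-open intervals with
#' `start < end` regardless of hit orientation (minus-strand hits have
#' `sstart > send` in BLAST output). Translated (tBLASTn) hit files may be
#' supplied alongside nucleotide ones; their subject coordinates are already
#' in nucleotide space in outfmt 6.
#'
#' @param path outfmt-6 TSV.
#' @param family_map data frame mapping `member_name` to `family` (see
#'   [read_family_map()]); if supplied, a `family` column is attached.
#' @param program `"nucleotide"` or `"translated"` label for the file.
#' @return data frame of normalized alignment hits.
#' @export
read_is_hits <- function(path, family_map = NULL,
                         program = c("nucleotide", "translated")) {
  program <- match.arg(program)
  if (file.size(path) == 0) {
    df <- data.frame(member_name = character(), replicon_id = character(),
                     start = integer(), end = integer(),
                     percent_identity = numeric(), alignment_length = integer(),
                     e_value = numeric(), program = character(),
                     stringsAsFactors = FALSE)
  } else {
    raw <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "#")
    if (ncol(raw) != 12)
      stopf("%s: expected 12 outfmt-6 columns, found %d", path, ncol(raw))
    names(raw) <- blast6_cols
    df <- data.frame(member_name = raw$qseqid,
                     replicon_id = raw$sseqid,
                     start = pmin(raw$sstart, raw$send) - 1L,
                     end = pmax(raw$sstart, raw$send),
                     percent_identity = raw$pident,
                     alignment_length = as.integer(raw$length),
                     e_value = raw$evalue,
                     program = program,
                     stringsAsFactors = FALSE)
  }
  if (!is.null(family_map)) {
    df$family <- family_map$family[match(df$member_name,
                                         family_map$member_name)]
    if (anyNA(df$family))
      stopf("hit member(s) missing from family map: %s",
            paste(unique(df$member_name[is.na(df$family)]), collapse = ", "))
  }
  df
}

#' Read the IS member-to-family map
#' @param path TSV with columns `member_name`, `family` and optionally
#'   `nucleotide_length`, `has_protein`.
#' @return data frame.
#' @export
read_family_map <- function(path) {
  df <- read_tsv(path)
  need_cols(df, c("member_name", "family"), path)
  if (anyDuplicated(df$member_name)) stopf("duplicate member_name in %s", path)
  if (any(df$family == "")) stopf("empty family label in %s", path)
  df
}

#' Read gene-vs-gene homology hits
#'
#' Same outfmt-6 layout as IS hits but query and subject are gene IDs. The
#' relation is made symmetric by keeping, for each unordered gene pair, the
#' best (smallest) E-value over both directions. Self-hits are dropped.
#'
#' @param path outfmt-6 TSV.
#' @return data frame with `gene_a`, `gene_b` (lexicographically ordered)
#'   and `e_value`.
#' @export
read_homology <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      e_value = numeric(), stringsAsFactors = FALSE))
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "#")
  if (ncol(raw) != 12)
    stopf("%s: expected 12 outfmt-6 columns, found %d", path, ncol(raw))
  names(raw) <- blast6_cols
  homology_edges(raw$qseqid, raw$sseqid, raw$evalue)
}

#' Build symmetric homology edges from raw pairs
#' @param gene_x,gene_y character vectors of gene IDs.
#' @param e_value numeric E-values.
#' @return symmetric edge data frame (best E-value per unordered pair).
#' @export
homology_edges <- function(gene_x, gene_y, e_value) {
  keep <- gene_x != gene_y
  a <- pmin(gene_x[keep], gene_y[keep])
  b <- pmax(gene_x[keep], gene_y[keep])
  ev <- e_value[keep]
  key <- paste(a, b, sep = "\r")
  o <- ord(key, ev)
  first <- !duplicated(key[o])
  data.frame(gene_a = a[o][first], gene_b = b[o][first],
             e_value = ev[o][first], stringsAsFactors = FALSE)
}

#' Read / write IS occurrence tables
#'
#' Occurrence TSVs carry `occurrence_id`, `replicon_id`, `start`, `end`
#' (0-based half-open), `family`, `best_member`, `best_e_value`,
#' `merged_hit_count`.
#'
#' @param path TSV file.
#' @return data frame of occurrences.
#' @export
read_occurrences <- function(path) {
  df <- read_tsv(path)
  need_cols(df, c("occurrence_id", "replicon_id", "start", "end", "family",
                  "best_member", "best_e_value", "merged_hit_count"), path)
  df
}

#' @rdname read_occurrences
#' @param occurrences occurrence data frame.
#' @export
write_occurrences <- function(occurrences, path) {
  write_tsv(occurrences, path)
}
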