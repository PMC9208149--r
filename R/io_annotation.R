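#' Construct a genome set
#'
#' The central annotation container: a pair of data frames describing
#' replicons and genes for one or more assemblies ("genomes"). A genome is the
#' set of replicons sharing an `assembly_id`; a replicon is a chromosome or a
#' plasmid. All coordinates are 0-based half-open.
#'
#' @param replicons data frame with columns `assembly_id`, `replicon_id`,
#'   `replicon_type` (`"chromosome"` or `"plasmid"`), `length_bp`.
#' @param genes data frame with columns `replicon_id`, `gene_id`, `start`,
#'   `end`, `strand` (`"+"`/`"-"`), `product`, `is_coding`.
#' @return an object of class `genome_set`.
#' @export
genome_set <- function(replicons, genes) {
  need_cols(replicons, c("assembly_id", "replicon_id", "replicon_type",
                         "length_bp"), "replicons")
  need_cols(genes, c("replicon_id", "gene_id", "start", "end", "strand",
                     "product", "is_coding"), "genes")
  if (anyDuplicated(replicons$replicon_id))
    stopf("replicon_id values are not unique: %s",
          paste(unique(replicons$replicon_id[duplicated(replicons$replicon_id)]),
                collapse = ", "))
  bad_type <- setdiff(unique(replicons$replicon_type),
                      c("chromosome", "plasmid"))
  if (length(bad_type))
    stopf("unknown replicon_type: %s", paste(bad_type, collapse = ", "))
  if (nrow(genes)) {
    if (any(genes$start >= genes$end))
      stopf("gene intervals must satisfy start < end")
    len <- replicons$length_bp[match(genes$replicon_id, replicons$replicon_id)]
    if (anyNA(len))
      stopf("genes reference unknown replicon(s): %s",
            paste(unique(genes$replicon_id[is.na(len)]), collapse = ", "))
    if (any(genes$start < 0 | genes$end > len))
      stopf("gene intervals out of replicon bounds")
    genes <- genes[ord(genes$replicon_id, genes$start, genes$end), ,
                   drop = FALSE]
  }
  rownames(genes) <- NULL
  rownames(replicons) <- NULL
  structure(list(replicons = replicons, genes = genes), class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf("genome_set: %d assemblies, %d replicons, %d genes\n",
              length(unique(x$replicons$assembly_id)),
              nrow(x$replicons), nrow(x$genes)))
  invisible(x)
}

gb_cols <- c("assembly_id", "replicon_id", "replicon_type", "replicon_length",
             "feature_type", "start", "end", "strand", "gene_id", "product")

#' Read replicon annotations
#'
#' Reads genome annotation into a [genome_set()]. Two dialects are supported:
#' GFF3 (1-based inclusive on disk; `region` features carry `assembly_id` and
#' `replicon_type` attributes, CDS features are coding genes, other feature
#' types are kept as non-coding objects) and a GenBank-style flat feature
#' table (TSV, 1-based inclusive). Coordinates are converted to the internal
#' 0-based half-open convention at this boundary.
#'
#' @param path file path.
#' @param dialect `"gff3"` or `"genbank_table"`.
#' @return a [genome_set()].
#' @export
read_annotation <- function(path, dialect = c("gff3", "genbank_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (dialect == "gff3") read_annotation_gff3(path) else
    read_annotation_gbtab(path)
}

read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  is_region <- df$type %in% c("region", "sequence_region")
  reg <- df[is_region, , drop = FALSE]
  if (!nrow(reg)) stopf("%s: no region features describing replicons", path)
  rtype <- if ("replicon_type" %in% names(reg))
    as.character(reg$replicon_type) else rep(NA_character_, nrow(reg))
  unknown <- is.na(rtype) | !(rtype %in% c("chromosome", "plasmid"))
  if (any(unknown)) {
    warnf("replicon type missing/unknown for %s; defaulting to chromosome",
          paste(reg$seqnames[unknown], collapse = ", "))
    rtype[unknown] <- "chromosome"
  }
  asm <- if ("assembly_id" %in% names(reg)) as.character(reg$assembly_id)
         else reg$seqnames
  replicons <- data.frame(assembly_id = asm,
                          replicon_id = reg$seqnames,
                          replicon_type = rtype,
                          length_bp = as.integer(reg$end),
                          stringsAsFactors = FALSE)
  feat <- df[!is_region, , drop = FALSE]
  gid <- if ("ID" %in% names(feat)) as.character(feat$ID)
         else sprintf("%s_g%06d", feat$seqnames, seq_len(nrow(feat)))
  prod <- if ("product" %in% names(feat)) as.character(feat$product)
          else rep("", nrow(feat))
  prod[is.na(prod)] <- ""
  genes <- data.frame(replicon_id = feat$seqnames,
                      gene_id = gid,
                      start = as.integer(feat$start) - 1L,
                      end = as.integer(feat$end),
                      strand = ifelse(feat$strand == "-", "-", "+"),
                      product = prod,
                      is_coding = feat$type == "CDS",
                      stringsAsFactors = FALSE)
  genome_set(replicons, genes)
}

read_annotation_gbtab <- function(path) {
  df <- tryCatch(read_tsv(path), error = function(e)
    stopf("%s: malformed feature table (%s)", path, conditionMessage(e)))
  need_cols(df, gb_cols, path)
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$start > df$end)
  if (length(bad))
    stopf("%s: malformed record at data line %d", path, bad[1])
  src <- !duplicated(df$replicon_id)
  rtype <- df$replicon_type[src]
  unknown <- !(rtype %in% c("chromosome", "plasmid"))
  if (any(unknown)) {
    warnf("unknown replicon type; defaulting to chromosome")
    rtype[unknown] <- "chromosome"
  }
  replicons <- data.frame(assembly_id = df$assembly_id[src],
                          replicon_id = df$replicon_id[src],
                          replicon_type = rtype,
                          length_bp = as.integer(df$replicon_length[src]),
                          stringsAsFactors = FALSE)
  genes <- data.frame(replicon_id = df$replicon_id,
                      gene_id = df$gene_id,
                      start = as.integer(df$start) - 1L,
                      end = as.integer(df$end),
                      strand = df$strand,
                      product = ifelse(is.na(df$product), "", df$product),
                      is_coding = df$feature_type == "CDS",
                      stringsAsFactors = FALSE)
  genome_set(replicons, genes)
}

#' Write replicon annotations
#'
#' Inverse of [read_annotation()]; internal 0-based half-open coordinates are
#' converted back to the on-disk convention of the chosen dialect.
#'
#' @param gs a [genome_set()].
#' @param path output file.
#' @param dialect `"gff3"` or `"genbank_table"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(gs, path, dialect = c("gff3", "genbank_table")) {
  dialect <- match.arg(dialect)
  if (dialect == "genbank_table") {
    g <- gs$genes
    r <- gs$replicons[match(g$replicon_id, gs$replicons$replicon_id), ]
    out <- data.frame(assembly_id = r$assembly_id,
                      replicon_id = g$replicon_id,
                      replicon_type = r$replicon_type,
                      replicon_length = r$length_bp,
                      feature_type = ifelse(g$is_coding, "CDS", "misc_feature"),
                      start = g$start + 1L,
                      end = g$end,
                      strand = g$strand,
                      gene_id = g$gene_id,
                      product = g$product,
                      stringsAsFactors = FALSE)
    return(invisible(write_tsv(out, path)))
  }
  r <- gs$replicons
  g <- gs$genes
  reg <- GenomicRanges::GRanges(r$replicon_id,
                                IRanges::IRanges(1, r$length_bp),
                                strand = "*")
  S4Vectors::mcols(reg) <- S4Vectors::DataFrame(
    type = "region", ID = paste0("region:", r$replicon_id),
    assembly_id = r$assembly_id, replicon_type = r$replicon_type)
  if (nrow(g)) {
    feat <- GenomicRanges::GRanges(g$replicon_id,
                                   IRanges::IRanges(g$start + 1L, g$end),
                                   strand = g$strand)
    S4Vectors::mcols(feat) <- S4Vectors::DataFrame(
      type = ifelse(g$is_coding, "CDS", "ncRNA"), ID = g$gene_id,
      assembly_id = r$assembly_id[match(g$replicon_id, r$replicon_id)],
      replicon_type = NA_character_, product = g$product)
    S4Vectors::mcols(reg)$product <- NA_character_
    all <- c(reg, feat)
  } else {
    S4Vectors::mcols(reg)$product <- NA_character_
    all <- reg
  }
  all <- sort(all)
  S4Vectors::mcols(all)$type <- factor(S4Vectors::mcols(all)$type)
  suppressWarnings(GenomeInfoDb::seqlengths(all) <-
    setNames(r$length_bp, r$replicon_id))
  # CDS phase is not modelled; suppress the exporter's phase notice
  suppressWarnings(rtracklayer::export(all, path, format = "gff3"))
  invisible(path)
}
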