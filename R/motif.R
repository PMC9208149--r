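#' Intersect IS occurrences with regulatory motifs
#'
#' A motif counts for an IS iff their intervals share at least one base
#' pair, strand-agnostically (IS occurrences carry no strand; motifs are
#' counted in both orientations). `contained_only` restricts to motifs fully
#' inside the IS, and `strands` can pre-filter motifs to one orientation for
#' promoter-focused analyses of pre-oriented inputs. Zero-motif ISs are
#' retained with `n_motifs = 0`.
#'
#' @param occurrences occurrence data frame (typically the OD-shaped subset).
#' @param motifs motif data frame ([read_motifs()]).
#' @param contained_only require full containment instead of >= 1 bp overlap.
#' @param strands motif strand symbols to keep before intersecting.
#' @return data frame per occurrence: `occurrence_id`, `family`,
#'   `replicon_id`, `n_motifs`, `motif_ids` (comma-joined),
#'   plus per-type and per-provenance counts.
#' @export
overlap_motifs <- function(occurrences, motifs, contained_only = FALSE,
                           strands = c("+", "-", ".")) {
  occ <- occurrences
  motifs <- motifs[motifs$strand %in% strands, , drop = FALSE]
  out <- data.frame(occurrence_id = occ$occurrence_id, family = occ$family,
                    replicon_id = occ$replicon_id,
                    n_motifs = 0L, motif_ids = "",
                    stringsAsFactors = FALSE)
  for (ty in motif_types) out[[paste0("n_", ty)]] <- 0L
  out$n_experimental <- 0L
  out$n_predicted <- 0L
  if (!nrow(occ) || !nrow(motifs)) return(out)
  common <- intersect(unique(occ$replicon_id), unique(motifs$replicon_id))
  for (rep_id in common) {
    oi <- which(occ$replicon_id == rep_id)
    mi <- which(motifs$replicon_id == rep_id)
    o_r <- IRanges::IRanges(occ$start[oi] + 1L, occ$end[oi])
    m_r <- IRanges::IRanges(motifs$start[mi] + 1L, motifs$end[mi])
    if (contained_only) {
      # "within" is query-within-subject: motif contained in IS
      ov <- IRanges::findOverlaps(m_r, o_r, type = "within")
      qi <- S4Vectors::subjectHits(ov)
      si <- S4Vectors::queryHits(ov)
    } else {
      ov <- IRanges::findOverlaps(o_r, m_r)
      qi <- S4Vectors::queryHits(ov)
      si <- S4Vectors::subjectHits(ov)
    }
    if (!length(qi)) next
    for (k in seq_along(oi)) {
      hits <- si[qi == k]
      if (!length(hits)) next
      i <- oi[k]
      mm <- motifs[mi[hits], , drop = FALSE]
      out$n_motifs[i] <- length(hits)
      out$motif_ids[i] <- paste(mm$motif_id, collapse = ",")
      for (ty in motif_types)
        out[[paste0("n_", ty)]][i] <- sum(mm$motif_type == ty)
      out$n_experimental[i] <- sum(mm$provenance == "experimental")
      out$n_predicted[i] <- sum(mm$provenance == "predicted")
    }
  }
  out
}

#' Motif-per-IS summary statistics
#'
#' Per group (IS family by default, or any per-occurrence grouping such as
#' sIG category): the fraction of ISs containing at least one motif, the
#' mean number of motifs per motif-containing IS, and the per-type /
#' per-provenance motif totals.
#'
#' @param overlaps output of [overlap_motifs()].
#' @param groups optional data frame `occurrence_id`, `group`; defaults to
#'   grouping by `family`.
#' @return data frame, one row per group plus an `ALL` row.
#' @export
motif_stats <- function(overlaps, groups = NULL) {
  grp <- if (is.null(groups)) overlaps$family else {
    g <- setNames(groups$group, groups$occurrence_id)
    as.character(g[overlaps$occurrence_id])
  }
  one <- function(d, label) {
    with_m <- d$n_motifs > 0
    data.frame(group = label,
               n_is = nrow(d),
               n_with_motif = sum(with_m),
               fraction_with_motif = if (nrow(d)) mean(with_m) else NA_real_,
               mean_motifs_per_containing_is =
                 if (any(with_m)) mean(d$n_motifs[with_m]) else NA_real_,
               n_motifs = sum(d$n_motifs),
               n_TFBS = sum(d$n_TFBS), n_promoter = sum(d$n_promoter),
               n_terminator = sum(d$n_terminator),
               n_riboswitch = sum(d$n_riboswitch),
               n_experimental = sum(d$n_experimental),
               n_predicted = sum(d$n_predicted),
               stringsAsFactors = FALSE)
  }
  parts <- lapply(sort(unique(grp)), function(gl)
    one(overlaps[grp == gl, , drop = FALSE], gl))
  rbind(do.call(rbind, parts), one(overlaps, "ALL"))
}
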