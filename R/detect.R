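#' Filter alignment hits by the 80:80 rule
#'
#' Keeps hits with alignment length >= `min_len` and percent identity
#' >= `min_identity` (both boundaries inclusive). Defaults implement the
#' 80:80 acceptance rule used for mobile-element calling.
#'
#' @param hits normalized hit data frame (see [read_is_hits()]).
#' @param min_len minimum alignment length in bp.
#' @param min_identity minimum percent identity (0-100).
#' @return the surviving rows of `hits`.
#' @export
filter_hits <- function(hits, min_len = 80, min_identity = 80) {
  hits[hits$alignment_length >= min_len &
         hits$percent_identity >= min_identity, , drop = FALSE]
}

# rank hits for best-E-value selection; ties broken by longer alignment,
# then higher identity, then member name (deterministic)
hit_rank_order <- function(hits) {
  ord(hits$e_value, -hits$alignment_length, -hits$percent_identity,
      hits$member_name)
}

# label overlap-connected components of intervals already sorted by start
overlap_components <- function(start, end) {
  n <- length(start)
  if (!n) return(integer(0))
  run_max <- cummax(c(-Inf, end[-n]))
  cumsum(start >= run_max)
}

#' Resolve overlapping hits to a single best hit per region
#'
#' Where several IS members align over the same replicon region, only the
#' hit with the best (smallest) E-value is kept. "Same region" is the
#' transitive closure of pairwise interval overlap (>= 1 bp, any family):
#' within each overlap-connected component one hit survives. Ties on
#' E-value are broken by longer alignment, then higher identity, then
#' member name.
#'
#' @param hits filtered hit data frame.
#' @return non-overlapping subset of `hits`.
#' @export
resolve_overlaps <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- ord(hits$replicon_id, hits$start, hits$end)
  h <- hits[o, , drop = FALSE]
  comp <- paste0(h$replicon_id, "\r",
                 ave(seq_len(nrow(h)), h$replicon_id, FUN = function(i)
                   overlap_components(h$start[i], h$end[i])))
  pr <- hit_rank_order(h)
  best <- pr[!duplicated(comp[pr])]
  out <- h[sort(best), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge contiguous same-family hits into IS occurrences
#'
#' Adjacent surviving hits on the same replicon that belong to the same IS
#' family and are separated by a gap strictly smaller than `merge_gap`
#' (default 80 bp; a gap of exactly 80 bp is NOT merged) are unioned into a
#' single occurrence, modelling fragmented or interrupted elements. The
#' occurrence inherits `best_member` and `best_e_value` from its constituent
#' hit with the smallest E-value.
#'
#' @param selected_hits non-overlapping hits (output of [resolve_overlaps()]),
#'   with a `family` column.
#' @param merge_gap merge threshold in bp (strict less-than).
#' @return occurrence data frame (`occurrence_id`, `replicon_id`, `start`,
#'   `end`, `family`, `best_member`, `best_e_value`, `merged_hit_count`).
#' @export
merge_occurrences <- function(selected_hits, merge_gap = 80) {
  h <- selected_hits
  need_cols(h, "family", "selected_hits")
  if (!nrow(h)) {
    return(data.frame(occurrence_id = character(), replicon_id = character(),
                      start = integer(), end = integer(), family = character(),
                      best_member = character(), best_e_value = numeric(),
                      merged_hit_count = integer(), stringsAsFactors = FALSE))
  }
  h <- h[ord(h$replicon_id, h$start, h$end), , drop = FALSE]
  n <- nrow(h)
  same <- c(FALSE, h$replicon_id[-1] == h$replicon_id[-n] &
                    h$family[-1] == h$family[-n] &
                    (h$start[-1] - h$end[-n]) < merge_gap)
  run <- cumsum(!same)
  pr <- hit_rank_order(h)
  best <- pr[!duplicated(run[pr])]
  best <- best[ord(run[best])]
  occ <- data.frame(
    replicon_id = h$replicon_id[best],
    start = as.integer(tapply(h$start, run, min)),
    end = as.integer(tapply(h$end, run, max)),
    family = h$family[best],
    best_member = h$member_name[best],
    best_e_value = h$e_value[best],
    merged_hit_count = as.integer(tapply(h$start, run, length)),
    stringsAsFactors = FALSE)
  occ$occurrence_id <- occ_key(occ$replicon_id, occ$start, occ$end)
  occ <- occ[, c("occurrence_id", "replicon_id", "start", "end", "family",
                 "best_member", "best_e_value", "merged_hit_count")]
  rownames(occ) <- NULL
  occ
}

#' Call IS occurrences from raw alignment hits
#'
#' Composes the three detection steps: 80:80 filtering, best-E-value overlap
#' resolution, and same-family merging. Nucleotide and translated hits should
#' be pooled (row-bound) before calling.
#'
#' @inheritParams filter_hits
#' @inheritParams merge_occurrences
#' @param min_size minimum occurrence length in bp; shorter merged intervals
#'   are dropped.
#' @return occurrence data frame; pairwise non-overlapping per replicon.
#' @export
detect_is <- function(hits, min_len = 80, min_identity = 80, merge_gap = 80,
                      min_size = 80) {
  occ <- merge_occurrences(resolve_overlaps(
    filter_hits(hits, min_len, min_identity)), merge_gap)
  occ[occ$end - occ$start >= min_size, , drop = FALSE]
}

#' Family-by-clade IS distribution and uniformity test
#'
#' For each IS family and taxonomic clade, tabulates the number of genomes
#' of the clade containing at least one occurrence of the family, the clade
#' size and their ratio (the heatmap fraction), plus the genome count
#' expected if family-containing genomes were spread uniformly across
#' clades. Per family, Student's t tests flag non-uniform distributions:
#' for every clade, a Welch two-sample t compares per-genome
#' presence/absence of the family between the clade and all other genomes;
#' the family-level p-value is the smallest clade p after Bonferroni
#' correction over clades, so a family is non-uniform when at least one
#' clade's occupancy departs from the rest at level `alpha`.
#'
#' @param occurrences occurrence data frame.
#' @param gs [genome_set()].
#' @param taxonomy taxonomy data frame ([read_taxonomy()]).
#' @param clade_rank rank treated as the clade (default `"phylum"`).
#' @param min_genomes minimum number of family-containing genomes for the
#'   test to run (families below the gate report `not_tested`).
#' @param alpha significance level.
#' @return list with `table` (family x clade rows) and `tests` (one row per
#'   family with `p_value` and `nonuniform`).
#' @export
clade_family_distribution <- function(occurrences, gs, taxonomy,
                                      clade_rank = "phylum",
                                      min_genomes = 10, alpha = 0.01) {
  check_taxonomy_coverage(taxonomy, gs$replicons$assembly_id)
  asm <- gs$replicons$assembly_id[match(occurrences$replicon_id,
                                        gs$replicons$replicon_id)]
  clade_of <- setNames(taxonomy[[clade_rank]], taxonomy$assembly_id)
  genomes <- unique(gs$replicons$assembly_id)
  clade <- clade_of[genomes]
  clade_sizes <- table(clade)
  n_total <- length(genomes)
  fam_asm <- unique(data.frame(family = occurrences$family, assembly_id = asm,
                               stringsAsFactors = FALSE))
  fam_asm$clade <- clade_of[fam_asm$assembly_id]
  families <- sort(unique(fam_asm$family))
  clades <- names(clade_sizes)
  grid <- expand.grid(family = families, clade = clades,
                      stringsAsFactors = FALSE)
  obs_tab <- table(factor(fam_asm$family, families),
                   factor(fam_asm$clade, clades))
  grid$genomes_with_IS <- as.integer(obs_tab[cbind(grid$family, grid$clade)])
  grid$total_genomes <- as.integer(clade_sizes[grid$clade])
  grid$fraction <- grid$genomes_with_IS / grid$total_genomes
  fam_tot <- tapply(grid$genomes_with_IS, grid$family, sum)
  grid$expected <- as.numeric(fam_tot[grid$family]) *
    grid$total_genomes / n_total
  tests <- do.call(rbind, lapply(families, function(f) {
    g <- grid[grid$family == f, ]
    n_with <- sum(g$genomes_with_IS)
    if (n_with < min_genomes || nrow(g) < 2) {
      return(data.frame(family = f, n_genomes = n_with, statistic = NA_real_,
                        p_value = NA_real_, nonuniform = NA,
                        call = "not_tested", stringsAsFactors = FALSE))
    }
    present <- as.integer(genomes %in%
                            fam_asm$assembly_id[fam_asm$family == f])
    per_clade <- vapply(g$clade, function(cl) {
      x <- present[clade == cl]
      y <- present[clade != cl]
      tt <- tryCatch(t.test(x, y), error = function(e) NULL)
      if (is.null(tt)) c(NA_real_, 1) else
        c(unname(tt$statistic), tt$p.value)
    }, numeric(2))
    p_bonf <- pmin(1, per_clade[2, ] * nrow(g))
    best <- which.min(p_bonf)
    p <- p_bonf[best]
    data.frame(family = f, n_genomes = n_with,
               statistic = per_clade[1, best], p_value = p,
               nonuniform = p < alpha,
               call = if (p < alpha) "nonuniform" else "uniform",
               stringsAsFactors = FALSE)
  }))
  list(table = grid, tests = tests)
}

#' IS density per replicon class
#'
#' Total base pairs of all replicons of a class divided by the number of IS
#' occurrences called on them: "one IS per N bp", reported separately for
#' chromosomes and plasmids. Classes absent from the input are omitted;
#' classes with replicons but no occurrences report `Inf`.
#'
#' @param occurrences occurrence data frame.
#' @param gs [genome_set()].
#' @return named numeric vector (bp per IS) over present replicon classes.
#' @export
is_density <- function(occurrences, gs) {
  r <- gs$replicons
  classes <- sort(unique(r$replicon_type))
  occ_class <- r$replicon_type[match(occurrences$replicon_id, r$replicon_id)]
  vapply(setNames(classes, classes), function(cl) {
    bp <- sum(as.numeric(r$length_bp[r$replicon_type == cl]))
    n <- sum(occ_class == cl)
    if (n == 0) Inf else bp / n
  }, numeric(1))
}
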