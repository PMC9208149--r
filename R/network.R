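#' Build the phylum graph of an IS family
#'
#' Nodes are phyla; for every phylum sIG set of the family, each unordered
#' pair of distinct phyla represented in the set increments that edge's
#' weight by one (a set spanning k phyla contributes to all k(k-1)/2 edges;
#' `pair_semantics = "single"` instead adds one edge only between the two
#' most-represented phyla of the set). Node annotations carry the family's
#' occurrence count, the number of IS-containing genomes, and their ratio.
#'
#' @param sig sIG classification ([classify_sig()]).
#' @param records the IG records used for classification.
#' @param occurrences occurrence data frame.
#' @param gs [genome_set()].
#' @param taxonomy taxonomy data frame.
#' @param family the IS family.
#' @param pair_semantics `"all_pairs"` (default) or `"single"`.
#' @return list with `family`, `nodes` (phylum, is_count,
#'   is_containing_genomes, is_per_genome) and `edges` (phylum_a, phylum_b,
#'   weight).
#' @export
build_graph <- function(sig, records, occurrences, gs, taxonomy, family,
                        pair_semantics = c("all_pairs", "single")) {
  pair_semantics <- match.arg(pair_semantics)
  sets <- sig$sets[sig$sets$family == family &
                     sig$sets$category == "phylum", , drop = FALSE]
  phy_of_rec <- setNames(records$phylum, records$occurrence_id)
  edge_tab <- new.env(parent = emptyenv())
  for (sid in sets$set_id) {
    occ <- sig$members$occurrence_id[sig$members$set_id == sid]
    phyla <- phy_of_rec[occ]
    u <- sort(unique(phyla))
    if (length(u) < 2) next
    pairs <- if (pair_semantics == "all_pairs") utils::combn(u, 2)
      else {
        top <- names(sort(table(phyla), decreasing = TRUE))[1:2]
        matrix(sort(top), nrow = 2)
      }
    for (j in seq_len(ncol(pairs))) {
      key <- paste(pairs[1, j], pairs[2, j], sep = "\r")
      assign(key, (get0(key, edge_tab, ifnotfound = 0L)) + 1L, edge_tab)
    }
  }
  keys <- sort(ls(edge_tab))
  edges <- if (length(keys)) {
    sp <- do.call(rbind, strsplit(keys, "\r"))
    data.frame(phylum_a = sp[, 1], phylum_b = sp[, 2],
               weight = vapply(keys, get0, integer(1), envir = edge_tab),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(phylum_a = character(), phylum_b = character(),
                    weight = integer(), stringsAsFactors = FALSE)
  # node statistics from the full occurrence table
  asm <- gs$replicons$assembly_id[match(occurrences$replicon_id,
                                        gs$replicons$replicon_id)]
  phy <- setNames(taxonomy$phylum, taxonomy$assembly_id)[asm]
  fam_occ <- occurrences$family == family
  is_count <- table(phy[fam_occ])
  genomes_with <- tapply(asm[fam_occ], phy[fam_occ],
                         function(a) length(unique(a)))
  phyla <- sort(unique(c(names(is_count), edges$phylum_a, edges$phylum_b)))
  nodes <- data.frame(
    phylum = phyla,
    is_count = as.integer(ifelse(is.na(is_count[phyla]), 0L,
                                 is_count[phyla])),
    is_containing_genomes = as.integer(ifelse(is.na(genomes_with[phyla]), 0L,
                                              genomes_with[phyla])),
    stringsAsFactors = FALSE)
  nodes$is_per_genome <- ifelse(nodes$is_containing_genomes > 0,
                                nodes$is_count / nodes$is_containing_genomes,
                                NA_real_)
  list(family = family, nodes = nodes, edges = edges)
}

#' Degree and strength of every phylum node
#'
#' Degree is the number of incident edges (distinct partner phyla); strength
#' is the sum of incident edge weights. The handshake identity holds: the
#' strengths sum to twice the total edge weight.
#'
#' @param graph output of [build_graph()].
#' @return data frame `phylum`, `degree`, `strength`.
#' @export
node_metrics <- function(graph) {
  e <- graph$edges
  phyla <- graph$nodes$phylum
  deg <- table(factor(c(e$phylum_a, e$phylum_b), phyla))
  str <- tapply(c(e$weight, e$weight),
                factor(c(e$phylum_a, e$phylum_b), phyla), sum, default = 0L)
  data.frame(phylum = phyla, degree = as.integer(deg),
             strength = as.integer(str), stringsAsFactors = FALSE)
}

#' Rank phyla as IS reservoirs
#'
#' Normalizes each phylum's total IS load by its number of IS-containing
#' genomes and ranks phyla by ISs per IS-containing genome (ties broken
#' alphabetically, stable).
#'
#' @param occurrences occurrence data frame.
#' @param gs [genome_set()].
#' @param taxonomy taxonomy data frame.
#' @return data frame `phylum`, `is_count`, `is_containing_genomes`,
#'   `is_per_genome`, `rank`.
#' @export
reservoir_ranking <- function(occurrences, gs, taxonomy) {
  asm <- gs$replicons$assembly_id[match(occurrences$replicon_id,
                                        gs$replicons$replicon_id)]
  phy <- setNames(taxonomy$phylum, taxonomy$assembly_id)[asm]
  is_count <- table(phy)
  genomes_with <- tapply(asm, phy, function(a) length(unique(a)))
  out <- data.frame(phylum = names(is_count),
                    is_count = as.integer(is_count),
                    is_containing_genomes = as.integer(
                      genomes_with[names(is_count)]),
                    stringsAsFactors = FALSE)
  out$is_per_genome <- out$is_count / out$is_containing_genomes
  out <- out[ord(-out$is_per_genome, out$phylum), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
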