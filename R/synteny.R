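#' Build per-IS records for synteny analysis
#'
#' One record per IS occurrence having both flanking (-1 and +1) coding
#' genes, carrying the flank gene IDs/products, the IS family, its shape and
#' the host genome's lineage.
#'
#' @param couples output of [build_couples()].
#' @param gs [genome_set()].
#' @param taxonomy taxonomy data frame.
#' @return data frame keyed by `occurrence_id`.
#' @export
ig_records <- function(couples, gs, taxonomy) {
  l <- couples[couples$position == -1L, ]
  r <- couples[couples$position == 1L, ]
  m <- match(l$occurrence_id, r$occurrence_id)
  has <- !is.na(m)
  rec <- data.frame(occurrence_id = l$occurrence_id[has],
                    family = l$family[has],
                    replicon_id = l$replicon_id[has],
                    left_gene = l$gene_id[has],
                    left_product = l$gene_product[has],
                    right_gene = r$gene_id[m[has]],
                    right_product = r$gene_product[m[has]],
                    shape = classify_shape(l$gene_strand[has],
                                           r$gene_strand[m[has]]),
                    stringsAsFactors = FALSE)
  rec$assembly_id <- gs$replicons$assembly_id[match(rec$replicon_id,
                                                    gs$replicons$replicon_id)]
  check_taxonomy_coverage(taxonomy, rec$assembly_id)
  tx <- taxonomy[match(rec$assembly_id, taxonomy$assembly_id), ]
  rec$phylum <- tx$phylum
  rec$species <- tx$species
  rec$strain <- tx$strain
  rownames(rec) <- NULL
  rec
}

#' Restrict records to given IG shapes
#'
#' The synteny analysis focuses on divergent `OD` ISs, where the element can
#' serve as a promoter for both neighbors; other shapes can be admitted via
#' `shapes`.
#'
#' @param records output of [ig_records()].
#' @param shapes shape codes to keep.
#' @return subset of `records`.
#' @export
select_shape <- function(records, shapes = "OD") {
  out <- records[records$shape %in% shapes, , drop = FALSE]
  if (!nrow(out)) warnf("no IS records with shape(s) %s",
                        paste(shapes, collapse = ","))
  out
}

# homology lookup environment: key "a\rb" (sorted) -> e_value
homology_env <- function(homology) {
  env <- new.env(parent = emptyenv(), size = max(1L, nrow(homology)))
  if (nrow(homology)) {
    keys <- paste(homology$gene_a, homology$gene_b, sep = "\r")
    for (i in seq_along(keys)) assign(keys[i], homology$e_value[i], env)
  }
  env
}

hom_ok <- function(env, g1, g2, threshold) {
  key <- paste(min(g1, g2), max(g1, g2), sep = "\r")
  ev <- get0(key, env, inherits = FALSE)
  !is.null(ev) && ev <= threshold
}

#' Pre-syntenic IG (presIG) relation between two IS records
#'
#' Two IG records are presIG partners iff (i) their ISs belong to the same
#' family, (ii) at least two of the four flanking genes form homologous
#' cross-genome pairs (each gene used at most once, so the two pairs are
#' either side-preserving or side-crossing), and (iii) the records come from
#' distinct strains (assemblies). Homology is E-value <= `threshold`;
#' missing homology data counts as non-homologous.
#'
#' @param rec_a,rec_b single rows of [ig_records()].
#' @param homology homology edge data frame ([read_homology()]).
#' @param threshold homology E-value threshold.
#' @param strict_sides require side-preserving pairs (-1 with -1, +1 with +1).
#' @return logical.
#' @export
pre_sig <- function(rec_a, rec_b, homology, threshold = 1e-50,
                    strict_sides = FALSE) {
  if (rec_a$family != rec_b$family) return(FALSE)
  if (rec_a$assembly_id == rec_b$assembly_id) return(FALSE)
  env <- if (is.environment(homology)) homology else homology_env(homology)
  straight <- hom_ok(env, rec_a$left_gene, rec_b$left_gene, threshold) &&
    hom_ok(env, rec_a$right_gene, rec_b$right_gene, threshold)
  if (straight) return(TRUE)
  if (strict_sides) return(FALSE)
  hom_ok(env, rec_a$left_gene, rec_b$right_gene, threshold) &&
    hom_ok(env, rec_a$right_gene, rec_b$left_gene, threshold)
}

# candidate record pairs sharing at least one strong homology edge between
# flank genes, then fully evaluated with pre_sig()
presig_edges <- function(records, homology, threshold = 1e-50,
                         strict_sides = FALSE) {
  strong <- homology[homology$e_value <= threshold, , drop = FALSE]
  if (!nrow(strong) || nrow(records) < 2)
    return(data.frame(a = integer(), b = integer()))
  gene2rec <- split(rep(seq_len(nrow(records)), 2),
                    c(records$left_gene, records$right_gene))
  cand <- unique(do.call(rbind, lapply(seq_len(nrow(strong)), function(i) {
    ra <- gene2rec[[strong$gene_a[i]]]
    rb <- gene2rec[[strong$gene_b[i]]]
    if (is.null(ra) || is.null(rb)) return(NULL)
    eg <- expand.grid(a = ra, b = rb)
    eg[eg$a != eg$b, , drop = FALSE]
  })))
  if (is.null(cand) || !nrow(cand)) return(data.frame(a = integer(),
                                                      b = integer()))
  cand <- unique(data.frame(a = pmin(cand$a, cand$b),
                            b = pmax(cand$a, cand$b)))
  env <- homology_env(strong)
  keep <- vapply(seq_len(nrow(cand)), function(i)
    pre_sig(records[cand$a[i], ], records[cand$b[i], ], env, threshold,
            strict_sides), logical(1))
  cand[keep, , drop = FALSE]
}

sig_categories <- c("phylum", "class_to_genus", "species", "unique")

#' Classify syntenic IS-gene (sIG) sets
#'
#' sIG sets are the connected components of the pairwise presIG relation
#' over the selected IG records. A component's category is set by its
#' taxonomic span, in priority order: members in >= 2 phyla -> `phylum`;
#' else >= 2 species (one phylum) -> `class_to_genus`; else >= 2 strains of
#' one species -> `species`. Partner-less records are `unique` IGs.
#'
#' @param records selected IG records ([select_shape()]).
#' @param homology homology edges.
#' @param taxonomy taxonomy data frame (already joined into records;
#'   accepted for interface completeness, may be `NULL`).
#' @param threshold homology E-value threshold (default 1e-50).
#' @param strict_sides see [pre_sig()].
#' @return list with `sets` (one row per sIG set: `set_id`, `family`,
#'   `category`, `n_members`, `n_phyla`, `n_species`, `n_strains`,
#'   `dominant_function`) and `members` (`set_id`, `occurrence_id`).
#' @export
classify_sig <- function(records, homology, taxonomy = NULL,
                         threshold = 1e-50, strict_sides = FALSE) {
  n <- nrow(records)
  if (!n)
    return(list(sets = data.frame(), members = data.frame()))
  ed <- presig_edges(records, homology, threshold, strict_sides)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(ed))
    g <- igraph::add_edges(g, rbind(ed$a, ed$b))
  comp <- igraph::components(g)$membership
  sets <- do.call(rbind, lapply(split(seq_len(n), comp), function(idx) {
    r <- records[idx, , drop = FALSE]
    n_ph <- length(unique(r$phylum))
    n_sp <- length(unique(r$species))
    n_st <- length(unique(r$assembly_id))
    cat <- if (length(idx) == 1) "unique"
      else if (n_ph >= 2) "phylum"
      else if (n_sp >= 2) "class_to_genus"
      else "species"
    fn <- normalize_function(c(r$left_product, r$right_product))
    fn <- fn[fn != ""]
    dom <- if (length(fn)) names(sort(table(fn), decreasing = TRUE))[1]
           else NA_character_
    data.frame(family = r$family[1], category = cat,
               n_members = length(idx), n_phyla = n_ph, n_species = n_sp,
               n_strains = n_st, dominant_function = dom,
               members = paste(r$occurrence_id, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  sets <- sets[ord(sets$family, -sets$n_members, sets$members), , drop = FALSE]
  sets$set_id <- sprintf("sIG_%05d", seq_len(nrow(sets)))
  members <- do.call(rbind, lapply(seq_len(nrow(sets)), function(i)
    data.frame(set_id = sets$set_id[i],
               occurrence_id = strsplit(sets$members[i], ",")[[1]],
               stringsAsFactors = FALSE)))
  sets$members <- NULL
  rownames(sets) <- NULL
  sets <- sets[, c("set_id", "family", "category", "n_members", "n_phyla",
                   "n_species", "n_strains", "dominant_function")]
  list(sets = sets, members = members)
}

#' Category counts as a function of the homology threshold
#'
#' Reclassifies the records at each E-value threshold and reports record and
#' set counts per category; used to pick an operating threshold at the
#' crossing of the phylum/species/unique curves. Relaxing the threshold
#' (larger E-value) can only add presIG edges, so the unique count is
#' monotone non-increasing.
#'
#' @param records selected IG records.
#' @param homology homology edges.
#' @param thresholds numeric vector of E-value thresholds.
#' @inheritParams classify_sig
#' @return data frame `threshold`, `category`, `n_records`, `n_sets`.
#' @export
threshold_sweep <- function(records, homology, thresholds,
                            strict_sides = FALSE) {
  thresholds <- sort(thresholds)
  do.call(rbind, lapply(thresholds, function(th) {
    cl <- classify_sig(records, homology, threshold = th,
                       strict_sides = strict_sides)
    cnt_rec <- tapply(cl$sets$n_members,
                      factor(cl$sets$category, sig_categories), sum,
                      default = 0L)
    cnt_set <- table(factor(cl$sets$category, sig_categories))
    data.frame(threshold = th, category = sig_categories,
               n_records = as.integer(cnt_rec),
               n_sets = as.integer(cnt_set), stringsAsFactors = FALSE)
  }))
}
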