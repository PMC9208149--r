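# Small corpora and hand-built genome fixtures shared across tests.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed,
             n_phyla = 3L, species_per_phylum = 2L, strains_per_species = 2L,
             replicon_length = c(2e5, 4e5), plasmid_prob = 0.3,
             plasmid_length = c(3e4, 6e4),
             is_per_genome = 6, plasmid_is_per_genome = 2,
             n_hotspots = 2L, n_sig = c(phylum = 1L, class_to_genus = 1L,
                                        species = 1L),
             noise_homology_pairs = 10L,
             background_motifs_per_genome = 2L, ...)
}

small_corpus <- function(seed = 1, ...) simulate_corpus(small_cfg(seed, ...))

# one replicon with explicit genes; coordinates 0-based half-open
toy_genome <- function(genes, length_bp = 10000, replicon_id = "chrA",
                       assembly_id = "GCA_T1", replicon_type = "chromosome") {
  genome_set(
    data.frame(assembly_id = assembly_id, replicon_id = replicon_id,
               replicon_type = replicon_type, length_bp = length_bp,
               stringsAsFactors = FALSE),
    genes)
}

toy_genes <- function(starts, ends, strands = "+", products = "protein X",
                      coding = TRUE, replicon_id = "chrA") {
  n <- length(starts)
  data.frame(replicon_id = rep_len(replicon_id, n),
             gene_id = sprintf("g%03d", seq_len(n)),
             start = as.integer(starts), end = as.integer(ends),
             strand = rep_len(strands, n),
             product = rep_len(products, n),
             is_coding = rep_len(coding, n), stringsAsFactors = FALSE)
}

toy_occ <- function(starts, ends, families = "IS1", replicon_id = "chrA",
                    members = NULL) {
  n <- length(starts)
  fam <- rep_len(families, n)
  if (is.null(members)) members <- paste0(fam, "_m01")
  data.frame(occurrence_id = sprintf("%s:%d-%d", replicon_id,
                                     as.integer(starts), as.integer(ends)),
             replicon_id = replicon_id, start = as.integer(starts),
             end = as.integer(ends), family = fam,
             best_member = rep_len(members, n), best_e_value = 1e-100,
             merged_hit_count = 1L, stringsAsFactors = FALSE)
}

toy_taxonomy <- function(assembly_ids, phyla = "PhylumA", species = NULL,
                         strains = NULL) {
  n <- length(assembly_ids)
  if (is.null(species)) species <- rep("GenusA speciesA", n)
  if (is.null(strains)) strains <- sprintf("strain%02d", seq_len(n))
  data.frame(assembly_id = assembly_ids, phylum = rep_len(phyla, n),
             class = "ClassA", order = "OrderA", family = "FamilyA",
             genus = "GenusA", species = rep_len(species, n),
             strain = rep_len(strains, n), stringsAsFactors = FALSE)
}

# minimal sig/records scaffold for graph construction; sets_phyla is a list
# of character vectors, the phyla spanned by each phylum sIG set
graph_fixture <- function(sets_phyla, family = "IS1") {
  records <- list(); members <- list(); sets <- list()
  for (s in seq_along(sets_phyla)) {
    ph <- sets_phyla[[s]]
    ids <- sprintf("r%02d_%02d:1-100", s, seq_along(ph))
    records[[s]] <- data.frame(occurrence_id = ids, family = family,
                               replicon_id = "r", left_gene = "L",
                               left_product = "p", right_gene = "R",
                               right_product = "q", shape = "OD",
                               assembly_id = sprintf("A%02d%02d", s,
                                                     seq_along(ph)),
                               phylum = ph, species = "sp", strain = "st",
                               stringsAsFactors = FALSE)
    sets[[s]] <- data.frame(set_id = sprintf("S%02d", s), family = family,
                            category = "phylum", n_members = length(ph),
                            n_phyla = length(unique(ph)), n_species = 1,
                            n_strains = length(ph), dominant_function = "p",
                            stringsAsFactors = FALSE)
    members[[s]] <- data.frame(set_id = sprintf("S%02d", s),
                               occurrence_id = ids, stringsAsFactors = FALSE)
  }
  list(sig = list(sets = do.call(rbind, sets),
                  members = do.call(rbind, members)),
       records = do.call(rbind, records))
}

empty_gs_tax <- function(records) {
  reps <- data.frame(assembly_id = records$assembly_id,
                     replicon_id = sprintf("rep%03d", seq_len(nrow(records))),
                     replicon_type = "chromosome", length_bp = 100000L,
                     stringsAsFactors = FALSE)
  gs <- genome_set(reps, toy_genes(integer(0), integer(0)))
  tax <- toy_taxonomy(records$assembly_id, phyla = records$phylum)
  list(gs = gs, tax = tax)
}
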