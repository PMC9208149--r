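base_products <- c(
  "hypothetical protein", "MFS transporter", "ABC transporter ATP-binding protein",
  "LysR family transcriptional regulator", "TetR family transcriptional regulator",
  "MerR family DNA binding transcriptional regulator", "transposase",
  "ATP-binding protein", "site specific DNA methyltransferase",
  "pyruvate kinase", "amidase", "amino acid permease", "DNA-binding response regulator",
  "glycosyl transferase", "aminotransferase", "histidine kinase",
  "ribosomal protein L7", "elongation factor Tu", "DNA polymerase III subunit",
  "cold shock protein", "peptidase M23", "acyl-CoA dehydrogenase",
  "outer membrane porin", "two-component sensor kinase")

shape_strand_map <- list(SPS = c("+", "+"), SNS = c("-", "-"),
                         OC = c("+", "-"), OD = c("-", "+"))

#' Simulation configuration
#'
#' Parameters of the synthetic corpus generator. Defaults describe the
#' standard study corpus: a 3-level taxonomy of 4 phyla x 3 species x 3
#' strains (36 genomes) with 1-5 Mb chromosomes, an 8-family toy IS library
#' with member lengths between 300 and 3000 bp (mode near 1200 bp),
#' equiprobable IG shapes, fragmentation gaps straddling the 80 bp merge
#' threshold, decoy hits violating the 80:80 rule, planted hotspots of >= 3
#' ISs, syntenic G-blocks copied at the phylum / class-to-genus / species
#' levels with homology E-values well below 1e-50, and per-family motif
#' rates.
#'
#' @param seed integer seed; identical seed + config give byte-identical
#'   corpora.
#' @param ... overrides of the defaults listed below.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_phyla = 4L, species_per_phylum = 3L, strains_per_species = 3L,
    replicon_length = c(1e6, 5e6),
    plasmid_prob = 0.25, plasmid_length = c(5e4, 3e5),
    mean_gene_length = 900, mean_intergenic = 150,
    noncoding_rate = 0.03,
    n_extra_products = 40,
    n_families = 8L, members_per_family = 4L,
    is_length_range = c(300, 3000),
    is_per_genome = 12, plasmid_is_per_genome = 3,
    overlap_gene_rate = 0.1,
    shape_props = c(SPS = 0.25, SNS = 0.25, OC = 0.25, OD = 0.25),
    fragmentation_rate = 0.15, frag_gap = c(20, 140),
    decoys_per_genome = 1.5,
    extra_hit_rate = 0.3,
    identity_range = c(86, 99.5),
    is_gene_dist = c(1, 300),
    n_hotspots = 3L, hotspot_size = c(3L, 5L), hotspot_gap = c(90L, 450L),
    n_sig = c(phylum = 3L, class_to_genus = 3L, species = 3L),
    sig_members = c(2L, 3L),
    block_homology_log10e = c(-120, -60),
    noise_homology_pairs = 30L,
    noise_homology_log10e = c(-20, -3),
    sig_threshold = 1e-50,
    motif_rate = 0.4,
    motifs_per_is = c(1L, 3L),
    motif_len = c(8L, 40L),
    background_motifs_per_genome = 5L,
    motif_type_probs = c(TFBS = 0.5, promoter = 0.3, terminator = 0.15,
                         riboswitch = 0.05),
    motif_prov_probs = c(experimental = 0.4, predicted = 0.6))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown sim_config field(s): %s",
                         paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

# toy IS reference library, deterministic under the active RNG state
make_is_library <- function(cfg) {
  fams <- paste0("IS", c("1", "3", "5", "21", "30", "256", "481",
                         "607", "91", "110", "200", "982"))[
                           seq_len(cfg$n_families)]
  do.call(rbind, lapply(fams, function(f) {
    len <- round(cfg$is_length_range[1] +
                   diff(cfg$is_length_range) *
                   rbeta(cfg$members_per_family, 2.5, 4.5))
    data.frame(member_name = sprintf("%s_m%02d", f,
                                     seq_len(cfg$members_per_family)),
               family = f, nucleotide_length = as.integer(len),
               has_protein = TRUE, stringsAsFactors = FALSE)
  }))
}

make_taxonomy <- function(cfg) {
  rows <- list()
  for (p in seq_len(cfg$n_phyla))
    for (s in seq_len(cfg$species_per_phylum))
      for (t in seq_len(cfg$strains_per_species)) {
        rows[[length(rows) + 1]] <- data.frame(
          assembly_id = sprintf("GCA_%02d%02d%02d", p, s, t),
          phylum = sprintf("Phylum%02d", p),
          class = sprintf("Class%02d", p),
          order = sprintf("Order%02d%02d", p, s),
          family = sprintf("Family%02d%02d", p, s),
          genus = sprintf("Genus%02d%02d", p, s),
          species = sprintf("Genus%02d%02d species%02d", p, s, s),
          strain = sprintf("strain%02d", t), stringsAsFactors = FALSE)
      }
  do.call(rbind, rows)
}

make_vocab <- function(cfg) {
  vocab <- c(base_products,
             sprintf("DUF%04d family protein", 1000 + seq_len(cfg$n_extra_products)))
  w <- 1 / seq_along(vocab)
  w[1] <- sum(w[-1]) * 0.25 / 0.75  # ~20-25% hypothetical protein
  list(names = vocab, weights = w / sum(w))
}

part_row <- function(kind, len, pre_gap, strand = "+", product = "",
                     coding = TRUE, role = "ord", unit_id = NA_character_,
                     family = NA_character_, member = NA_character_,
                     identity = NA_real_, frag_gap = NA_integer_,
                     shape = NA_character_, gene_id = NA_character_) {
  data.frame(kind = kind, len = as.integer(len), pre_gap = as.integer(pre_gap),
             strand = strand, product = product, coding = coding, role = role,
             unit_id = unit_id, family = family, member = member,
             identity = identity, frag_gap = as.integer(frag_gap),
             shape = shape, gene_id = gene_id, stringsAsFactors = FALSE)
}

rgene_len <- function(n, cfg)
  pmin(4000L, pmax(150L, round(rgamma(n, shape = 9,
                                      scale = cfg$mean_gene_length / 9))))
rgap <- function(n, cfg)
  60L + as.integer(round(rexp(n, 1 / max(1, cfg$mean_intergenic - 60))))

rdist <- function(n, cfg) sample(cfg$is_gene_dist[1]:cfg$is_gene_dist[2], n,
                                 replace = TRUE)

sample_product <- function(n, vocab) sample(vocab$names, n, replace = TRUE,
                                            prob = vocab$weights)

# expand one planted unit into its parts
unit_parts <- function(u, cfg, vocab, lib) {
  g <- function(strand, product = sample_product(1, vocab), role = "flank",
                gene_id = NA_character_, pre_gap = rgap(1, cfg))
    part_row("gene", rgene_len(1, cfg), pre_gap, strand, product, TRUE, role,
             unit_id = u$unit_id, gene_id = gene_id)
  isp <- function(member_row, pre_gap, identity, frag_gap = NA_integer_,
                  shape = NA_character_)
    part_row("is", member_row$nucleotide_length, pre_gap, ".", "", FALSE,
             "is", unit_id = u$unit_id, family = member_row$family,
             member = member_row$member_name, identity = identity,
             frag_gap = frag_gap, shape = shape)
  rid <- function() runif(1, cfg$identity_range[1], cfg$identity_range[2])
  if (u$type == "bg") {
    st <- shape_strand_map[[u$shape]]
    rbind(g(st[1]),
          isp(u$member, rdist(1, cfg), rid(), u$frag_gap, u$shape),
          g(st[2], pre_gap = rdist(1, cfg)))
  } else if (u$type == "overlap") {
    st <- shape_strand_map[[u$shape]]
    mid_len <- rgene_len(1, cfg)
    ov <- sample(10:min(mid_len - 20L, u$member$nucleotide_length - 20L), 1)
    rbind(g(st[1]),
          part_row("gene", mid_len, rgap(1, cfg),
                   sample(c("+", "-"), 1), sample_product(1, vocab), TRUE,
                   "ov_gene", unit_id = u$unit_id),
          isp(u$member, -ov, rid(), shape = u$shape),
          g(st[2], pre_gap = rdist(1, cfg)))
  } else if (u$type == "hotspot") {
    k <- nrow(u$members)
    st <- sample(c("+", "-"), 2, replace = TRUE)
    sh <- classify_shape(st[1], st[2])
    parts <- list(g(st[1], product = u$flank_products[1], role = "hs_flank"))
    for (i in seq_len(k)) {
      pg <- if (i == 1) rdist(1, cfg) else
        sample(cfg$hotspot_gap[1]:cfg$hotspot_gap[2], 1)
      parts[[length(parts) + 1]] <- isp(u$members[i, ], pg, rid(), shape = sh)
    }
    parts[[length(parts) + 1]] <- g(st[2], product = u$flank_products[2],
                                    role = "hs_flank", pre_gap = rdist(1, cfg))
    do.call(rbind, parts)
  } else if (u$type == "syn") {
    rbind(g("-", product = u$left_product, role = "syn_flank",
            gene_id = u$left_gene),
          isp(u$member, rdist(1, cfg), rid(), shape = "OD"),
          g("+", product = u$right_product, role = "syn_flank",
            gene_id = u$right_gene, pre_gap = rdist(1, cfg)))
  } else stopf("unknown unit type %s", u$type)
}

build_replicon <- function(rep_id, target_len, units, cfg, vocab, lib) {
  n_ord <- max(60L, as.integer(round(
    target_len / (cfg$mean_gene_length + cfg$mean_intergenic))))
  slots <- seq(5L, n_ord - 5L, by = 3L)
  if (length(units) > length(slots))
    stopf("infeasible plan: %d planted units exceed capacity of %s",
          length(units), rep_id)
  ordf <- part_row("gene", rgene_len(n_ord, cfg), rgap(n_ord, cfg),
                   sample(c("+", "-"), n_ord, replace = TRUE),
                   sample_product(n_ord, vocab),
                   runif(n_ord) > cfg$noncoding_rate, "ord")
  segs <- list()
  if (length(units)) {
    at <- sort(sample(slots, length(units)))
    prev <- 0L
    for (i in seq_along(units)) {
      segs[[length(segs) + 1]] <- ordf[(prev + 1):at[i], , drop = FALSE]
      segs[[length(segs) + 1]] <- unit_parts(units[[i]], cfg, vocab, lib)
      prev <- at[i]
    }
    segs[[length(segs) + 1]] <- ordf[(prev + 1):n_ord, , drop = FALSE]
  } else segs <- list(ordf)
  parts <- do.call(rbind, segs)
  ends <- cumsum(as.numeric(parts$pre_gap + parts$len))
  parts$start <- as.integer(ends - parts$len)
  parts$end <- as.integer(ends)
  length_bp <- as.integer(ends[length(ends)] + rgap(1, cfg))
  is_gene <- parts$kind == "gene"
  auto <- is.na(parts$gene_id) & is_gene
  parts$gene_id[auto] <- sprintf("%s_g%05d", rep_id, cumsum(auto)[auto])
  genes <- parts[is_gene, c("gene_id", "start", "end", "strand", "product",
                            "coding", "role"), drop = FALSE]
  names(genes)[names(genes) == "coding"] <- "is_coding"
  genes$replicon_id <- rep(rep_id, nrow(genes))
  iss <- parts[parts$kind == "is",
               c("unit_id", "family", "member", "identity", "frag_gap",
                 "shape", "start", "end"), drop = FALSE]
  iss$replicon_id <- rep(rep_id, nrow(iss))
  rownames(genes) <- rownames(iss) <- NULL
  list(genes = genes, is = iss, length_bp = length_bp)
}

#' Emit a fragmented IS as two alignment hits
#'
#' Splits the alignment of one planted IS into two same-member hits
#' separated by `gap_bp` of unaligned sequence. Merging back into a single
#' occurrence is expected iff `gap_bp < 80`.
#'
#' @param member_name,family IS member and family labels.
#' @param replicon_id subject replicon.
#' @param start,length 0-based start and total footprint length in bp.
#' @param gap_bp the unaligned gap (>= 0).
#' @param identity percent identity given to both hits.
#' @return list with `hits` (two normalized hit rows) and `merge_expected`.
#' @export
fragment_is <- function(member_name, family, replicon_id, start, length,
                        gap_bp, identity = 95) {
  stopifnot(gap_bp >= 0, length >= gap_bp + 200)
  l1 <- as.integer((length - gap_bp) %/% 2)
  l2 <- as.integer(length - gap_bp - l1)
  hits <- data.frame(
    member_name = member_name, replicon_id = replicon_id,
    start = as.integer(c(start, start + l1 + gap_bp)),
    end = as.integer(c(start + l1, start + length)),
    percent_identity = identity, alignment_length = c(l1, l2),
    e_value = sim_evalue(c(l1, l2), identity), program = "nucleotide",
    family = family, stringsAsFactors = FALSE)
  list(hits = hits, merge_expected = gap_bp < 80)
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Produces mutually consistent genomes, annotations, taxonomy, IS and
#' gene-homology hit tables, regulatory motifs, and a `truth` record
#' describing what the pipeline is expected to recover: IS occurrence
#' intervals (including merge expectations for fragmented elements and
#' never-called decoys), IG shapes, hotspots, sIG sets with their intended
#' category, per-occurrence motif counts, and per-class IS densities.
#'
#' @param cfg a [sim_config()].
#' @return list with `gs` ([genome_set()]), `taxonomy`, `hits`,
#'   `family_map`, `homology`, `motifs`, `truth`, and `cfg`.
#' @export
simulate_corpus <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  lib <- make_is_library(cfg)
  tax <- make_taxonomy(cfg)
  vocab <- make_vocab(cfg)
  n_gen <- nrow(tax)
  pick_member <- function(fam) lib[lib$family == fam, ][
    sample(sum(lib$family == fam), 1), ]

  # ---- corpus-level plans -------------------------------------------------
  fams <- unique(lib$family)
  unit_counter <- 0L
  next_unit <- function(prefix) {
    unit_counter <<- unit_counter + 1L
    sprintf("%s_%04d", prefix, unit_counter)
  }
  units_by_asm <- setNames(vector("list", n_gen), tax$assembly_id)
  add_unit <- function(asm, u) units_by_asm[[asm]][[
    length(units_by_asm[[asm]]) + 1]] <<- u

  # synteny plan
  sig_truth <- list()
  fam_i <- 0L
  for (catg in names(cfg$n_sig)) {
    for (k in seq_len(cfg$n_sig[[catg]])) {
      fam_i <- fam_i + 1L
      fam <- fams[(fam_i - 1L) %% length(fams) + 1L]
      n_m <- sample(cfg$sig_members[1]:cfg$sig_members[2], 1)
      asms <- switch(catg,
        phylum = {
          ph <- sample(unique(tax$phylum), min(n_m, cfg$n_phyla))
          vapply(ph, function(x) sample(tax$assembly_id[tax$phylum == x], 1),
                 character(1))
        },
        class_to_genus = {
          ph <- sample(unique(tax$phylum), 1)
          sp <- sample(unique(tax$species[tax$phylum == ph]),
                       min(n_m, cfg$species_per_phylum))
          vapply(sp, function(x) sample(tax$assembly_id[tax$species == x], 1),
                 character(1))
        },
        species = {
          sp <- sample(unique(tax$species), 1)
          sample(tax$assembly_id[tax$species == sp],
                 min(n_m, cfg$strains_per_species))
        })
      set_id <- sprintf("SYN_%s_%02d", catg, k)
      prods <- sample_product(2, vocab)
      member_units <- lapply(asms, function(a) {
        list(type = "syn", unit_id = next_unit("syn"),
             member = pick_member(fam), set_id = set_id,
             left_gene = sprintf("%s_L_%s", set_id, a),
             right_gene = sprintf("%s_R_%s", set_id, a),
             left_product = prods[1], right_product = prods[2])
      })
      for (i in seq_along(asms)) add_unit(asms[i], member_units[[i]])
      sig_truth[[set_id]] <- list(set_id = set_id, category = catg,
                                  family = fam, assemblies = unname(asms),
                                  unit_ids = vapply(member_units, `[[`,
                                                    "", "unit_id"))
    }
  }

  # hotspot plan
  hs_truth <- list()
  hs_asms <- sample(tax$assembly_id, cfg$n_hotspots)
  for (i in seq_along(hs_asms)) {
    k <- sample(cfg$hotspot_size[1]:cfg$hotspot_size[2], 1)
    members <- do.call(rbind, lapply(sample(fams, k, replace = TRUE),
                                     pick_member))
    uid <- next_unit("hs")
    add_unit(hs_asms[i], list(type = "hotspot", unit_id = uid,
                              members = members,
                              flank_products = sample_product(2, vocab)))
    hs_truth[[uid]] <- list(unit_id = uid, assembly_id = hs_asms[i], n_is = k)
  }

  # background IS plan (incl. overlap units, fragmentation, shapes)
  for (a in tax$assembly_id) {
    n_bg <- rpois(1, cfg$is_per_genome)
    if (!n_bg) next
    shapes <- sample(names(cfg$shape_props), n_bg, replace = TRUE,
                     prob = cfg$shape_props)
    for (j in seq_len(n_bg)) {
      m <- pick_member(sample(fams, 1))
      if (runif(1) < cfg$overlap_gene_rate) {
        add_unit(a, list(type = "overlap", unit_id = next_unit("ov"),
                         member = m, shape = shapes[j]))
      } else {
        fg <- NA_integer_
        if (runif(1) < cfg$fragmentation_rate &&
            m$nucleotide_length >= cfg$frag_gap[2] + 200)
          fg <- sample(cfg$frag_gap[1]:cfg$frag_gap[2], 1)
        add_unit(a, list(type = "bg", unit_id = next_unit("bg"), member = m,
                         shape = shapes[j], frag_gap = fg))
      }
    }
  }

  # ---- build replicons ----------------------------------------------------
  replicons <- list(); genes <- list(); is_rows <- list()
  for (a in tax$assembly_id) {
    chr_id <- paste0(a, "_chr")
    L <- runif(1, cfg$replicon_length[1], cfg$replicon_length[2])
    rl <- build_replicon(chr_id, L, units_by_asm[[a]], cfg, vocab, lib)
    replicons[[chr_id]] <- data.frame(assembly_id = a, replicon_id = chr_id,
                                      replicon_type = "chromosome",
                                      length_bp = rl$length_bp,
                                      stringsAsFactors = FALSE)
    genes[[chr_id]] <- rl$genes
    is_rows[[chr_id]] <- rl$is
    if (runif(1) < cfg$plasmid_prob) {
      pl_id <- paste0(a, "_pls")
      n_p <- rpois(1, cfg$plasmid_is_per_genome)
      p_units <- list()
      if (n_p) {
        p_sh <- sample(names(cfg$shape_props), n_p, replace = TRUE,
                       prob = cfg$shape_props)
        p_units <- lapply(seq_len(n_p), function(j)
          list(type = "bg", unit_id = next_unit("bg"),
               member = pick_member(sample(fams, 1)), shape = p_sh[j],
               frag_gap = NA_integer_))
      }
      pl <- build_replicon(pl_id, runif(1, cfg$plasmid_length[1],
                                        cfg$plasmid_length[2]),
                           p_units, cfg, vocab, lib)
      replicons[[pl_id]] <- data.frame(assembly_id = a, replicon_id = pl_id,
                                       replicon_type = "plasmid",
                                       length_bp = pl$length_bp,
                                       stringsAsFactors = FALSE)
      genes[[pl_id]] <- pl$genes
      is_rows[[pl_id]] <- pl$is
    }
  }
  replicons <- do.call(rbind, replicons)
  all_genes <- do.call(rbind, genes)
  planted <- do.call(rbind, is_rows)
  if (is.null(planted))
    planted <- data.frame(unit_id = character(), family = character(),
                          member = character(), identity = numeric(),
                          frag_gap = integer(), shape = character(),
                          start = integer(), end = integer(),
                          replicon_id = character(), stringsAsFactors = FALSE)
  rownames(replicons) <- rownames(all_genes) <- rownames(planted) <- NULL

  # ---- hits and expected occurrences -------------------------------------
  hits <- list(); occ_truth <- list()
  for (i in seq_len(nrow(planted))) {
    p <- planted[i, ]
    len <- p$end - p$start
    if (!is.na(p$frag_gap)) {
      fr <- fragment_is(p$member, p$family, p$replicon_id, p$start, len,
                        p$frag_gap, round(p$identity, 1))
      hits[[length(hits) + 1]] <- fr$hits
      occ_truth[[length(occ_truth) + 1]] <- if (fr$merge_expected)
        data.frame(replicon_id = p$replicon_id, start = p$start, end = p$end,
                   family = p$family, best_member = p$member,
                   merged_hit_count = 2L, unit_id = p$unit_id,
                   shape = p$shape, stringsAsFactors = FALSE)
      else
        data.frame(replicon_id = p$replicon_id,
                   start = fr$hits$start, end = fr$hits$end,
                   family = p$family, best_member = p$member,
                   merged_hit_count = 1L, unit_id = p$unit_id,
                   shape = p$shape, stringsAsFactors = FALSE)
    } else {
      pid <- round(p$identity, 1)
      h <- data.frame(member_name = p$member, replicon_id = p$replicon_id,
                      start = p$start, end = p$end, percent_identity = pid,
                      alignment_length = len,
                      e_value = sim_evalue(len, pid),
                      program = "nucleotide", family = p$family,
                      stringsAsFactors = FALSE)
      if (len >= 160 && runif(1) < cfg$extra_hit_rate) {
        others <- lib[lib$family == p$family &
                        lib$member_name != p$member, ]
        om <- others[sample(nrow(others), 1), ]
        pid2 <- max(80.5, pid - 3)
        h <- rbind(h, data.frame(
          member_name = om$member_name, replicon_id = p$replicon_id,
          start = p$start + 20L, end = p$end - 20L,
          percent_identity = pid2, alignment_length = len - 40L,
          e_value = sim_evalue(len - 40L, pid2), program = "nucleotide",
          family = p$family, stringsAsFactors = FALSE))
      }
      hits[[length(hits) + 1]] <- h
      occ_truth[[length(occ_truth) + 1]] <- data.frame(
        replicon_id = p$replicon_id, start = p$start, end = p$end,
        family = p$family, best_member = p$member, merged_hit_count = 1L,
        unit_id = p$unit_id, shape = p$shape, stringsAsFactors = FALSE)
    }
  }
  # decoy hits violating the 80:80 rule, placed inside ordinary genes
  decoys <- list()
  for (a in tax$assembly_id) {
    n_d <- rpois(1, cfg$decoys_per_genome)
    if (!n_d) next
    chr_id <- paste0(a, "_chr")
    cand <- all_genes[all_genes$replicon_id == chr_id &
                        all_genes$role == "ord" &
                        (all_genes$end - all_genes$start) > 300, ]
    cand <- cand[sample(nrow(cand), min(n_d, nrow(cand))), , drop = FALSE]
    for (j in seq_len(nrow(cand))) {
      m <- lib[sample(nrow(lib), 1), ]
      short <- runif(1) < 0.5
      dl <- if (short) sample(30:79, 1) else 200L
      dp <- if (short) round(runif(1, 86, 99), 1) else round(runif(1, 60, 79.4), 1)
      s <- cand$start[j] + 5L
      decoys[[length(decoys) + 1]] <- data.frame(
        member_name = m$member_name, replicon_id = chr_id, start = s,
        end = s + dl, percent_identity = dp, alignment_length = dl,
        e_value = sim_evalue(dl, dp), program = "nucleotide",
        family = m$family, reason = if (short) "short" else "low_identity",
        stringsAsFactors = FALSE)
    }
  }
  decoy_df <- if (length(decoys)) do.call(rbind, decoys) else NULL
  empty_hits <- data.frame(member_name = character(),
                           replicon_id = character(), start = integer(),
                           end = integer(), percent_identity = numeric(),
                           alignment_length = integer(), e_value = numeric(),
                           program = character(), family = character(),
                           stringsAsFactors = FALSE)
  hits <- if (length(hits)) do.call(rbind, hits) else empty_hits
  if (!is.null(decoy_df))
    hits <- rbind(hits, decoy_df[, names(hits)])
  hits$orient <- sample(c("+", "-"), nrow(hits), replace = TRUE)
  rownames(hits) <- NULL
  occ_truth <- if (length(occ_truth)) do.call(rbind, occ_truth) else
    data.frame(replicon_id = character(), start = integer(), end = integer(),
               family = character(), best_member = character(),
               merged_hit_count = integer(), unit_id = character(),
               shape = character(), stringsAsFactors = FALSE)
  occ_truth$occurrence_id <- occ_key(occ_truth$replicon_id, occ_truth$start,
                                     occ_truth$end)
  occ_truth <- occ_truth[ord(occ_truth$replicon_id, occ_truth$start), ]
  rownames(occ_truth) <- NULL

  # ---- homology table -----------------------------------------------------
  hom <- list()
  for (s in sig_truth) {
    for (side in c("L", "R")) {
      ids <- sprintf("%s_%s_%s", s$set_id, side, s$assemblies)
      if (length(ids) >= 2) {
        pr <- utils::combn(ids, 2)
        hom[[length(hom) + 1]] <- data.frame(
          gene_a = pr[1, ], gene_b = pr[2, ],
          e_value = 10^runif(ncol(pr), cfg$block_homology_log10e[1],
                             cfg$block_homology_log10e[2]),
          stringsAsFactors = FALSE)
      }
    }
  }
  ordg <- all_genes$gene_id[all_genes$role == "ord"]
  if (cfg$noise_homology_pairs > 0) {
    ga <- sample(ordg, cfg$noise_homology_pairs)
    gb <- sample(setdiff(ordg, ga), cfg$noise_homology_pairs)
    hom[[length(hom) + 1]] <- data.frame(
      gene_a = ga, gene_b = gb,
      e_value = 10^runif(cfg$noise_homology_pairs,
                         cfg$noise_homology_log10e[1],
                         cfg$noise_homology_log10e[2]),
      stringsAsFactors = FALSE)
  }
  hom <- if (length(hom)) do.call(rbind, hom) else
    data.frame(gene_a = character(), gene_b = character(),
               e_value = numeric(), stringsAsFactors = FALSE)
  hom <- homology_edges(hom$gene_a, hom$gene_b, hom$e_value)

  # ---- motifs -------------------------------------------------------------
  rate <- if (length(cfg$motif_rate) == 1)
    setNames(rep(cfg$motif_rate, length(fams)), fams) else cfg$motif_rate
  od <- occ_truth[!is.na(occ_truth$shape) & occ_truth$shape == "OD", ]
  motif_rows <- list(); motif_truth <- list()
  for (i in seq_len(nrow(od))) {
    o <- od[i, ]
    n_m <- 0L
    if (runif(1) < rate[[o$family]]) {
      n_m <- sample(cfg$motifs_per_is[1]:cfg$motifs_per_is[2], 1)
      for (j in seq_len(n_m)) {
        ml <- sample(cfg$motif_len[1]:cfg$motif_len[2], 1)
        ms <- o$start + sample.int(o$end - o$start - ml, 1)
        motif_rows[[length(motif_rows) + 1]] <- data.frame(
          replicon_id = o$replicon_id, start = ms, end = ms + ml,
          motif_id = sprintf("M%06d", length(motif_rows) + 1L),
          strand = sample(c("+", "-"), 1),
          motif_type = sample(names(cfg$motif_type_probs), 1,
                              prob = cfg$motif_type_probs),
          provenance = sample(names(cfg$motif_prov_probs), 1,
                              prob = cfg$motif_prov_probs),
          stringsAsFactors = FALSE)
      }
    }
    motif_truth[[length(motif_truth) + 1]] <- data.frame(
      occurrence_id = o$occurrence_id, family = o$family, n_motifs = n_m,
      stringsAsFactors = FALSE)
  }
  # background motifs inside ordinary genes (never overlap an IS)
  for (a in tax$assembly_id) {
    chr_id <- paste0(a, "_chr")
    cand <- all_genes[all_genes$replicon_id == chr_id &
                        all_genes$role == "ord" &
                        (all_genes$end - all_genes$start) > 200, ]
    n_b <- min(cfg$background_motifs_per_genome, nrow(cand))
    cand <- cand[sample(nrow(cand), n_b), , drop = FALSE]
    for (j in seq_len(n_b)) {
      ml <- sample(cfg$motif_len[1]:cfg$motif_len[2], 1)
      ms <- cand$start[j] + 10L
      motif_rows[[length(motif_rows) + 1]] <- data.frame(
        replicon_id = chr_id, start = ms, end = ms + ml,
        motif_id = sprintf("M%06d", length(motif_rows) + 1L),
        strand = sample(c("+", "-", "."), 1),
        motif_type = sample(names(cfg$motif_type_probs), 1,
                            prob = cfg$motif_type_probs),
        provenance = sample(names(cfg$motif_prov_probs), 1,
                            prob = cfg$motif_prov_probs),
        stringsAsFactors = FALSE)
    }
  }
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    read_motifs(textConnection_empty())
  motif_truth <- if (length(motif_truth)) do.call(rbind, motif_truth) else
    data.frame(occurrence_id = character(), family = character(),
               n_motifs = integer(), stringsAsFactors = FALSE)

  # ---- assemble truth -----------------------------------------------------
  hs_occ <- occ_truth[grepl("^hs_", occ_truth$unit_id), ]
  hotspot_truth <- do.call(rbind, lapply(split(hs_occ, hs_occ$unit_id),
    function(d) data.frame(unit_id = d$unit_id[1],
                           replicon_id = d$replicon_id[1],
                           span_start = min(d$start), span_end = max(d$end),
                           n_is = nrow(d),
                           member_occurrences = paste(
                             d$occurrence_id[ord(d$start)], collapse = ","),
                           stringsAsFactors = FALSE)))
  sig_sets_truth <- do.call(rbind, lapply(sig_truth, function(s) {
    keys <- occ_truth$occurrence_id[occ_truth$unit_id %in% s$unit_ids]
    data.frame(set_id = s$set_id, category = s$category, family = s$family,
               n_members = length(keys),
               member_occurrences = paste(sort(keys), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  dens <- vapply(split(seq_len(nrow(replicons)), replicons$replicon_type),
                 function(idx) {
    bp <- sum(as.numeric(replicons$length_bp[idx]))
    n <- sum(occ_truth$replicon_id %in% replicons$replicon_id[idx])
    if (n == 0) Inf else bp / n
  }, numeric(1))
  truth <- list(occurrences = occ_truth,
                decoys = decoy_df,
                hotspots = hotspot_truth,
                sig_sets = sig_sets_truth,
                motifs = motif_truth,
                density_bp_per_is = as.list(dens))

  gs <- genome_set(replicons,
                   all_genes[, c("replicon_id", "gene_id", "start", "end",
                                 "strand", "product", "is_coding")])
  fam_map <- lib[, c("member_name", "family", "nucleotide_length",
                     "has_protein")]
  list(gs = gs, taxonomy = tax, hits = hits, family_map = fam_map,
       homology = hom, motifs = motifs, truth = truth, cfg = cfg)
}

textConnection_empty <- function() {
  f <- tempfile()
  file.create(f)
  f
}

#' Write a simulated corpus to standard-format files
#'
#' Emits `genomes.gff3`, `taxonomy.tsv`, `is_hits.tsv` (BLAST outfmt 6),
#' `is_families.tsv`, `gene_homology.tsv` (outfmt 6), `motifs.bed` (BED+2)
#' and `truth.json` under `dir`. Optionally writes random replicon sequences
#' as FASTA (the hit tables are authoritative; sequences only exist so an
#' external aligner adapter can be exercised by hand).
#'
#' @param corpus output of [simulate_corpus()].
#' @param dir output directory (created if missing).
#' @param write_fasta also write `genomes.fasta`.
#' @return named list of written paths.
#' @export
write_corpus <- function(corpus, dir, write_fasta = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    annotation = file.path(dir, "genomes.gff3"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    is_hits = file.path(dir, "is_hits.tsv"),
    family_map = file.path(dir, "is_families.tsv"),
    homology = file.path(dir, "gene_homology.tsv"),
    motifs = file.path(dir, "motifs.bed"),
    truth = file.path(dir, "truth.json"))
  write_annotation(corpus$gs, paths$annotation, "gff3")
  write_tsv(corpus$taxonomy, paths$taxonomy)
  write_blast6(corpus$hits, paths$is_hits)
  write_tsv(corpus$family_map, paths$family_map)
  hom6 <- data.frame(member_name = corpus$homology$gene_a,
                     replicon_id = corpus$homology$gene_b,
                     start = 0L, end = 100L, percent_identity = 90,
                     alignment_length = 100L,
                     e_value = corpus$homology$e_value,
                     program = "nucleotide", orient = "+",
                     stringsAsFactors = FALSE)
  write_blast6(hom6, paths$homology)
  write_motifs(corpus$motifs, paths$motifs)
  jsonlite::write_json(corpus$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  if (write_fasta) {
    paths$fasta <- file.path(dir, "genomes.fasta")
    con <- file(paths$fasta, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus$gs$replicons))) {
      r <- corpus$gs$replicons[i, ]
      writeLines(paste0(">", r$replicon_id), con)
      seq <- paste(sample(c("A", "C", "G", "T"), r$length_bp, replace = TRUE),
                   collapse = "")
      writeLines(substring(seq, seq(1, nchar(seq), 80),
                           pmin(nchar(seq), seq(80, nchar(seq) + 79, 80))),
                 con)
    }
  }
  paths
}

# write normalized hits back to BLAST outfmt 6 (1-based inclusive subject
# coordinates, orientation restored from the `orient` column when present)
write_blast6 <- function(hits, path) {
  orient <- if ("orient" %in% names(hits)) hits$orient else
    rep("+", nrow(hits))
  fwd <- orient != "-"
  out <- data.frame(
    qseqid = hits$member_name, sseqid = hits$replicon_id,
    pident = hits$percent_identity, length = hits$alignment_length,
    mismatch = round(hits$alignment_length *
                       (100 - hits$percent_identity) / 100),
    gapopen = 0L, qstart = 1L, qend = hits$alignment_length,
    sstart = ifelse(fwd, hits$start + 1L, hits$end),
    send = ifelse(fwd, hits$end, hits$start + 1L),
    evalue = format(hits$e_value, scientific = TRUE, digits = 3),
    bitscore = round(hits$alignment_length * 1.8),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
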