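default_params <- list(
  min_len = 80, min_identity = 80, merge_gap = 80, min_size = 80,
  min_is = 10, alpha = 0.01, margin = 0.1, gate_frac = 1e-4,
  min_run = 3, n_mc = 100, require_nonuniform = TRUE,
  sig_threshold = 1e-50, strict_sides = FALSE, exclude_hypothetical = FALSE,
  shapes = "OD", contained_only = FALSE, clade_rank = "phylum")

#' Run the full IS landscape pipeline
#'
#' Orchestrates the stages in dependency order — detect, couples (shapes +
#' IGF), hotspots, synteny, network, motifs, report — reading the standard
#' input formats and writing one TSV per stage plus a JSON run log of all
#' parameters and seeds into `out_dir`. The pipeline is a pure function of
#' (inputs, config, seed): reruns with the same configuration produce
#' byte-identical outputs. A missing `motifs` entry skips the motif stage
#' (logged); a missing `homology` entry skips synteny and network.
#'
#' @param config a list or path to a YAML file with entries `annotation`,
#'   `taxonomy`, `is_hits`, `family_map`, optional `homology`, optional
#'   `motifs`, `out_dir`, `seed`, optional `annotation_dialect`, and any
#'   parameter of the analysis (see Details in the vignette); every
#'   threshold of the method (80 bp / 80% / 80 bp gap / 1e-50 / 0.01% /
#'   p=0.01 / 10% rule / >=10 IS / >=3 hotspot ISs) is overridable.
#' @return invisibly, a list of stage results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- modifyList(default_params, config[intersect(names(config),
                                                   names(default_params))])
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stopf("config must name out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = seed, params = p, stages = list())
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  emit <- function(df, name) {
    paths[[name]] <<- file.path(out_dir, paste0(name, ".tsv"))
    write_tsv(df, paths[[name]])
  }
  excl <- if (p$exclude_hypothetical) "HYPOTHETICAL PROTEIN" else character(0)

  # ---- load inputs --------------------------------------------------------
  res <- list()
  stage("load", {
    dialect <- if (is.null(config$annotation_dialect)) "gff3" else
      config$annotation_dialect
    res$gs <- read_annotation(config$annotation, dialect)
    res$taxonomy <- read_taxonomy(config$taxonomy)
    check_taxonomy_coverage(res$taxonomy, res$gs$replicons$assembly_id)
    fam_map <- read_family_map(config$family_map)
    res$hits <- read_is_hits(config$is_hits, fam_map)
  })

  # ---- detect -------------------------------------------------------------
  stage("detect", {
    res$occurrences <- detect_is(res$hits, p$min_len, p$min_identity,
                                 p$merge_gap, p$min_size)
    emit(res$occurrences, "occurrences")
    res$density <- is_density(res$occurrences, res$gs)
    res$clades <- clade_family_distribution(res$occurrences, res$gs,
                                            res$taxonomy, p$clade_rank,
                                            p$min_is, p$alpha)
    emit(res$clades$table, "clade_distribution")
    emit(res$clades$tests, "clade_tests")
  })
  log$stages$detect <- list(n_occurrences = nrow(res$occurrences))

  # ---- couples ------------------------------------------------------------
  stage("couples", {
    res$couples <- build_couples(res$occurrences, res$gs)
    res$shapes <- ig_shapes(res$couples)
    cp <- res$couples
    cp$shape <- res$shapes$shape[match(cp$occurrence_id,
                                       res$shapes$occurrence_id)]
    emit(cp, "couples")
    res$shape_stats <- shape_representation(res$shapes, p$min_is, p$alpha,
                                            p$margin)
    emit(res$shape_stats, "shape_stats")
    res$bins <- distance_size_bins(res$couples, res$occurrences)
    emit(res$bins, "distance_size_bins")
  })
  log$stages$couples <- list(n_couples = nrow(res$couples))

  # ---- igf ----------------------------------------------------------------
  stage("igf", {
    res$igf <- build_igf(res$couples, res$gs, p$gate_frac,
                         exclude_functions = excl, min_is = p$min_is,
                         alpha = p$alpha, margin = p$margin)
    if (!is.null(res$igf$stats)) emit(res$igf$stats, "igf_stats")
  })
  log$stages$igf <- list(min_function_count = res$igf$min_count)

  # ---- hotspots -----------------------------------------------------------
  stage("hotspots", {
    res$hs_tests <- nonuniformity_tests(res$occurrences, res$gs,
                                        n_mc = p$n_mc, seed = seed,
                                        min_is = p$min_is, alpha = p$alpha)
    emit(res$hs_tests, "hotspot_tests")
    hs <- detect_hotspots(res$occurrences, res$gs, p$min_run)
    if (p$require_nonuniform && nrow(hs)) {
      ok <- res$hs_tests$replicon_id[res$hs_tests$tested &
                                       res$hs_tests$nonuniform]
      hs <- hs[hs$replicon_id %in% ok, , drop = FALSE]
    }
    res$hotspots <- hs
    emit(hs, "hotspots")
    emit(hotspot_functions(hs, exclude_functions = excl),
         "hotspot_functions")
  })
  log$stages$hotspots <- list(n_hotspots = nrow(res$hotspots),
                              require_nonuniform = p$require_nonuniform)

  # ---- synteny ------------------------------------------------------------
  if (!is.null(config$homology)) {
    stage("synteny", {
      res$homology <- read_homology(config$homology)
      res$records <- select_shape(ig_records(res$couples, res$gs,
                                             res$taxonomy), p$shapes)
      res$sig <- classify_sig(res$records, res$homology,
                              threshold = p$sig_threshold,
                              strict_sides = p$strict_sides)
      emit(res$sig$sets, "sig_sets")
      emit(res$sig$members, "sig_members")
    })
    log$stages$synteny <- list(n_sets = nrow(res$sig$sets))

    stage("network", {
      fams <- sort(unique(res$sig$sets$family[res$sig$sets$category ==
                                                "phylum"]))
      edges <- list(); nodes <- list()
      for (f in fams) {
        gph <- build_graph(res$sig, res$records, res$occurrences, res$gs,
                           res$taxonomy, f)
        if (nrow(gph$edges)) {
          e <- gph$edges; e$family <- f
          edges[[f]] <- e
        }
        nm <- node_metrics(gph)
        nm <- merge(gph$nodes, nm, by = "phylum", sort = TRUE)
        nm$family <- f
        nodes[[f]] <- nm
      }
      res$network_edges <- if (length(edges)) do.call(rbind, edges) else
        data.frame(phylum_a = character(), phylum_b = character(),
                   weight = integer(), family = character())
      res$network_nodes <- if (length(nodes)) do.call(rbind, nodes) else
        data.frame()
      emit(res$network_edges, "network_edges")
      emit(res$network_nodes, "network_nodes")
      res$reservoirs <- reservoir_ranking(res$occurrences, res$gs,
                                          res$taxonomy)
      emit(res$reservoirs, "reservoir_ranking")
    })
    log$stages$network <- list(n_edges = nrow(res$network_edges))
  } else {
    log$stages$synteny <- list(skipped = "no homology input")
  }

  # ---- motifs -------------------------------------------------------------
  if (!is.null(config$motifs)) {
    stage("motifs", {
      mot <- read_motifs(config$motifs)
      occ_sel <- res$occurrences[res$occurrences$occurrence_id %in%
        res$shapes$occurrence_id[res$shapes$shape %in% p$shapes], ,
        drop = FALSE]
      res$motif_overlap <- overlap_motifs(occ_sel, mot, p$contained_only)
      emit(res$motif_overlap, "motif_overlap")
      res$motif_summary <- motif_stats(res$motif_overlap)
      emit(res$motif_summary, "motif_summary")
    })
    log$stages$motifs <- list(
      n_is_with_motif = sum(res$motif_overlap$n_motifs > 0))
  } else {
    log$stages$motifs <- list(skipped = "no motif input")
  }

  # ---- report -------------------------------------------------------------
  stage("report", {
    shp <- table(factor(res$shapes$shape, shape_levels))
    rows <- list(
      c("n_occurrences", nrow(res$occurrences)),
      c("n_genomes", length(unique(res$gs$replicons$assembly_id))),
      c("bp_per_is_chromosome",
        round(unname(res$density["chromosome"]), 1)))
    if ("plasmid" %in% names(res$density))
      rows <- c(rows, list(c("bp_per_is_plasmid",
                             round(unname(res$density["plasmid"]), 1))))
    for (s in shape_levels)
      rows <- c(rows, list(c(paste0("shape_frac_", s),
                             round(unname(shp[s]) / max(1, sum(shp)), 4))))
    if (!is.null(res$sig)) {
      for (catg in sig_categories)
        rows <- c(rows, list(c(paste0("n_records_", catg),
          sum(res$sig$sets$n_members[res$sig$sets$category == catg]))))
    }
    rows <- c(rows, list(c("n_hotspots", nrow(res$hotspots))))
    if (!is.null(res$motif_summary)) {
      all_row <- res$motif_summary[res$motif_summary$group == "ALL", ]
      rows <- c(rows, list(
        c("frac_is_with_motif", round(all_row$fraction_with_motif, 4)),
        c("mean_motifs_per_containing_is",
          round(all_row$mean_motifs_per_containing_is, 4))))
    }
    report <- data.frame(metric = vapply(rows, `[`, "", 1),
                         value = vapply(rows, `[`, "", 2),
                         stringsAsFactors = FALSE)
    emit(report, "report")
    res$report <- report
  })
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$run_log <- file.path(out_dir, "run_log.json")
  invisible(c(res, list(paths = paths, log = log)))
}
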