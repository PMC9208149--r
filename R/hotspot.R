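#' Test a replicon for non-uniform IS placement
#'
#' Wilcoxon-Mann-Whitney test of the observed adjacent inter-IS spacings
#' against spacings pooled from `n_mc` uniform random placements of the same
#' number of ISs on the same replicon length. The alternative is one-sided
#' (observed spacings stochastically smaller), because the non-uniformity
#' relevant to hotspot formation is clustering: an excess of short spacings.
#' Perfectly even placement, which a two-sided location test would also
#' reject, is deliberately not flagged. `method = "quantile"` instead
#' compares observed IS start positions with the uniform quantiles of the
#' replicon (two-sided, paired). The test is only applied to replicons
#' carrying at least `min_is` occurrences.
#'
#' @param occurrences occurrences of one replicon (or their start positions).
#' @param replicon_length replicon length in bp.
#' @param n_mc number of Monte-Carlo uniform placements.
#' @param seed integer seed for the Monte-Carlo draw.
#' @param min_is minimum IS count for the test to run.
#' @param alpha significance level.
#' @param method `"mc"` (spacings vs Monte-Carlo pool) or `"quantile"`.
#' @return list `n_is`, `p_value`, `nonuniform`, `tested`.
#' @export
nonuniformity_test <- function(occurrences, replicon_length, n_mc = 100,
                               seed = 1, min_is = 10, alpha = 0.01,
                               method = c("mc", "quantile")) {
  method <- match.arg(method)
  pos <- if (is.data.frame(occurrences)) occurrences$start else occurrences
  n <- length(pos)
  if (n < min_is)
    return(list(n_is = n, p_value = NA_real_, nonuniform = NA, tested = FALSE))
  pos <- sort(as.numeric(pos))
  obs_sp <- diff(pos)
  p <- if (method == "mc") {
    mc_sp <- withr_seed(seed, {
      unlist(lapply(seq_len(n_mc), function(i)
        diff(sort(runif(n, 0, replicon_length)))))
    })
    suppressWarnings(wilcox.test(obs_sp, mc_sp,
                                 alternative = "less")$p.value)
  } else {
    q <- replicon_length * seq_len(n) / (n + 1)
    suppressWarnings(wilcox.test(pos, q, paired = TRUE)$p.value)
  }
  list(n_is = n, p_value = p, nonuniform = p < alpha, tested = TRUE)
}

# evaluate expr with a local RNG state seeded by `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Run the non-uniformity test on every replicon
#'
#' @param occurrences occurrence data frame.
#' @param gs [genome_set()].
#' @inheritParams nonuniformity_test
#' @return data frame per replicon: `replicon_id`, `n_is`, `p_value`,
#'   `nonuniform`, `tested`.
#' @export
nonuniformity_tests <- function(occurrences, gs, n_mc = 100, seed = 1,
                                min_is = 10, alpha = 0.01,
                                method = c("mc", "quantile")) {
  method <- match.arg(method)
  reps <- gs$replicons
  do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    occ <- occurrences[occurrences$replicon_id == reps$replicon_id[i], ]
    res <- nonuniformity_test(occ, reps$length_bp[i], n_mc = n_mc,
                              seed = seed + i, min_is = min_is,
                              alpha = alpha, method = method)
    data.frame(replicon_id = reps$replicon_id[i], n_is = res$n_is,
               p_value = res$p_value, nonuniform = res$nonuniform,
               tested = res$tested, stringsAsFactors = FALSE)
  }))
}

#' Detect IS hotspots
#'
#' A hotspot is a maximal run of at least `min_run` consecutive IS
#' occurrences (in genomic order, any family mix) in which every adjacent
#' pair is separated by a gap smaller than the summed lengths of the two
#' ISs and no coding gene overlaps that inter-IS gap. Genes overlapping the
#' ISs themselves do not break a chain. Replicons are treated as linear.
#'
#' @param occurrences occurrence data frame.
#' @param gs [genome_set()].
#' @param min_run minimum number of member ISs.
#' @return data frame per hotspot: `hotspot_id`, `replicon_id`, `span_start`,
#'   `span_end`, `n_is`, `n_families`, `families` (comma-joined),
#'   `member_occurrences` (comma-joined), `flank_left_gene`,
#'   `flank_left_product`, `flank_right_gene`, `flank_right_product`.
#' @export
detect_hotspots <- function(occurrences, gs, min_run = 3) {
  empty <- data.frame(hotspot_id = character(), replicon_id = character(),
                      span_start = integer(), span_end = integer(),
                      n_is = integer(), n_families = integer(),
                      families = character(), member_occurrences = character(),
                      flank_left_gene = character(),
                      flank_left_product = character(),
                      flank_right_gene = character(),
                      flank_right_product = character(),
                      stringsAsFactors = FALSE)
  out <- list()
  for (rep_id in unique(occurrences$replicon_id)) {
    occ <- occurrences[occurrences$replicon_id == rep_id, , drop = FALSE]
    occ <- occ[ord(occ$start, occ$end), , drop = FALSE]
    n <- nrow(occ)
    if (n < min_run) next
    g <- gs$genes[gs$genes$replicon_id == rep_id & gs$genes$is_coding, ,
                  drop = FALSE]
    gap_lo <- occ$end[-n]
    gap_hi <- occ$start[-1]
    len <- occ$end - occ$start
    close_enough <- (gap_hi - gap_lo) < (len[-n] + len[-1])
    gene_free <- if (nrow(g)) {
      ov <- IRanges::findOverlaps(IRanges::IRanges(gap_lo + 1L, gap_hi),
                                  IRanges::IRanges(g$start + 1L, g$end))
      !(seq_len(n - 1) %in% S4Vectors::queryHits(ov))
    } else rep(TRUE, n - 1)
    linked <- close_enough & gene_free
    r <- rle(linked)
    pos <- cumsum(c(1, r$lengths))
    for (k in which(r$values & r$lengths >= (min_run - 1))) {
      i0 <- pos[k]; i1 <- pos[k + 1]  # members i0 .. i1 of occ
      mem <- occ[i0:i1, , drop = FALSE]
      span <- c(mem$start[1], mem$end[nrow(mem)])
      fl <- g[g$end <= span[1], , drop = FALSE]
      fl <- if (nrow(fl)) fl[which.max(fl$end), ] else NULL
      fr <- g[g$start >= span[2], , drop = FALSE]
      fr <- if (nrow(fr)) fr[which.min(fr$start), ] else NULL
      out[[length(out) + 1]] <- data.frame(
        hotspot_id = sprintf("HS_%s_%d", rep_id, span[1]),
        replicon_id = rep_id, span_start = span[1], span_end = span[2],
        n_is = nrow(mem), n_families = length(unique(mem$family)),
        families = paste(sort(unique(mem$family)), collapse = ","),
        member_occurrences = paste(mem$occurrence_id, collapse = ","),
        flank_left_gene = if (is.null(fl)) NA_character_ else fl$gene_id,
        flank_left_product = if (is.null(fl)) NA_character_ else fl$product,
        flank_right_gene = if (is.null(fr)) NA_character_ else fr$gene_id,
        flank_right_product = if (is.null(fr)) NA_character_ else fr$product,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  hs <- do.call(rbind, out)
  rownames(hs) <- NULL
  hs
}

#' Tally gene functions flanking hotspots
#'
#' Counts, per normalized function name, how many hotspots have a flanking
#' gene (the nearest coding gene outside the span, on either side) with that
#' function. A hotspot with both flanks sharing one function counts once for
#' it. Functions can be excluded (typically `"HYPOTHETICAL PROTEIN"`).
#'
#' @param hotspots output of [detect_hotspots()].
#' @param exclude_functions normalized names to drop.
#' @param strict_names skip name normalization.
#' @return data frame `function_name`, `n_hotspots`, sorted by count.
#' @export
hotspot_functions <- function(hotspots, exclude_functions = character(0),
                              strict_names = FALSE) {
  if (!nrow(hotspots))
    return(data.frame(function_name = character(), n_hotspots = integer(),
                      stringsAsFactors = FALSE))
  per_hs <- lapply(seq_len(nrow(hotspots)), function(i) {
    fn <- c(hotspots$flank_left_product[i], hotspots$flank_right_product[i])
    fn <- fn[!is.na(fn) & fn != ""]
    unique(normalize_function(fn, strict = strict_names))
  })
  tab <- table(unlist(per_hs))
  tab <- tab[!(names(tab) %in% exclude_functions)]
  out <- data.frame(function_name = names(tab), n_hotspots = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[ord(-out$n_hotspots, out$function_name), , drop = FALSE]
}
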