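#' Build IS-gene (IG) couples
#'
#' Pairs every IS occurrence with its neighboring coding genes: the nearest
#' gene lying entirely to its left (relative position -1), the nearest gene
#' entirely to its right (+1), and any overlapping gene (0, distance 0).
#' Non-coding genetic objects are skipped. Distance is the gap between the
#' nearest interval boundaries. An IS at a replicon edge may lack one
#' neighbor; an IS on a replicon without coding genes yields no couples.
#'
#' @param occurrences occurrence data frame ([detect_is()]).
#' @param gs [genome_set()].
#' @return data frame with one row per couple: `occurrence_id`, `family`,
#'   `replicon_id`, `gene_id`, `position` (-1/0/1), `distance_bp`,
#'   `gene_strand`, `gene_product`.
#' @export
build_couples <- function(occurrences, gs) {
  empty <- data.frame(occurrence_id = character(), family = character(),
                      replicon_id = character(), gene_id = character(),
                      position = integer(), distance_bp = integer(),
                      gene_strand = character(), gene_product = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(occurrences)) return(empty)
  out <- list()
  for (rep_id in unique(occurrences$replicon_id)) {
    occ <- occurrences[occurrences$replicon_id == rep_id, , drop = FALSE]
    g <- gs$genes[gs$genes$replicon_id == rep_id & gs$genes$is_coding, ,
                  drop = FALSE]
    if (!nrow(g)) next
    res <- list()
    # -1 neighbor: max end among genes entirely left (end <= IS start)
    ge <- g[ord(g$end, g$start, g$gene_id), , drop = FALSE]
    il <- findInterval(occ$start, ge$end)
    has_l <- il >= 1
    if (any(has_l)) {
      gl <- ge[il[has_l], , drop = FALSE]
      res$left <- data.frame(occurrence_id = occ$occurrence_id[has_l],
                             family = occ$family[has_l],
                             replicon_id = rep_id, gene_id = gl$gene_id,
                             position = -1L,
                             distance_bp = occ$start[has_l] - gl$end,
                             gene_strand = gl$strand,
                             gene_product = gl$product,
                             stringsAsFactors = FALSE)
    }
    # +1 neighbor: min start among genes entirely right (start >= IS end)
    gsrt <- g[ord(g$start, g$end, g$gene_id), , drop = FALSE]
    ir <- findInterval(occ$end - 0.5, gsrt$start) + 1L
    has_r <- ir <= nrow(gsrt)
    if (any(has_r)) {
      gr <- gsrt[ir[has_r], , drop = FALSE]
      res$right <- data.frame(occurrence_id = occ$occurrence_id[has_r],
                              family = occ$family[has_r],
                              replicon_id = rep_id, gene_id = gr$gene_id,
                              position = 1L,
                              distance_bp = gr$start - occ$end[has_r],
                              gene_strand = gr$strand,
                              gene_product = gr$product,
                              stringsAsFactors = FALSE)
    }
    # overlapping genes: position 0, distance 0
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(occ$start + 1L, occ$end),
      IRanges::IRanges(g$start + 1L, g$end))
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      res$over <- data.frame(occurrence_id = occ$occurrence_id[qi],
                             family = occ$family[qi],
                             replicon_id = rep_id, gene_id = g$gene_id[si],
                             position = 0L, distance_bp = 0L,
                             gene_strand = g$strand[si],
                             gene_product = g$product[si],
                             stringsAsFactors = FALSE)
    }
    out[[rep_id]] <- do.call(rbind, res)
  }
  if (!length(out)) return(empty)
  cp <- do.call(rbind, out)
  cp <- cp[ord(cp$replicon_id, cp$occurrence_id, cp$position), , drop = FALSE]
  rownames(cp) <- NULL
  cp
}

#' Classify the IG shape of an IS from its flanking gene strands
#'
#' Shapes, reading the two flanking genes left to right along the replicon:
#' `SPS` (both `+`, same orientation positive strand), `SNS` (both `-`),
#' `OC` (`+`,`-`: opposite convergent), `OD` (`-`,`+`: opposite divergent,
#' the configuration in which the IS can act as a promoter for either
#' neighbor).
#'
#' @param left_strand,right_strand strands of the -1 and +1 genes.
#' @return character vector of shape codes.
#' @export
classify_shape <- function(left_strand, right_strand) {
  ifelse(left_strand == "+",
         ifelse(right_strand == "+", "SPS", "OC"),
         ifelse(right_strand == "+", "OD", "SNS"))
}

#' IS-level shape table from IG couples
#'
#' Shape is defined only for ISs having both a -1 and a +1 neighbor; the
#' overlapped (position 0) gene never contributes.
#'
#' @param couples output of [build_couples()].
#' @return data frame `occurrence_id`, `family`, `shape`.
#' @export
ig_shapes <- function(couples) {
  l <- couples[couples$position == -1L, ]
  r <- couples[couples$position == 1L, ]
  m <- match(l$occurrence_id, r$occurrence_id)
  has <- !is.na(m)
  data.frame(occurrence_id = l$occurrence_id[has],
             family = l$family[has],
             shape = classify_shape(l$gene_strand[has],
                                    r$gene_strand[m[has]]),
             stringsAsFactors = FALSE)
}

shape_levels <- c("SPS", "SNS", "OC", "OD")

#' Shape over/under-representation per IS family
#'
#' For each IS family (and the pooled `ALL` row) compares the four observed
#' shape counts against the uniform expectation (25% each) with a chi-square
#' test (3 df). When p < `alpha`, a shape is called `over` (`under`) if its
#' observed count is more than 10% above (below) expectation; otherwise
#' `normal`. Families with fewer than `min_is` shaped ISs are `not_tested`.
#'
#' @param shapes output of [ig_shapes()].
#' @param min_is minimum number of shaped ISs per tested unit.
#' @param alpha significance level.
#' @param margin the 10% rule margin (0.1).
#' @param overall include the pooled `ALL` unit.
#' @return long data frame: `unit`, `shape`, `observed`, `expected`,
#'   `chi2`, `p_value`, `call`.
#' @export
shape_representation <- function(shapes, min_is = 10, alpha = 0.01,
                                 margin = 0.1, overall = TRUE) {
  units <- split(shapes$shape, shapes$family)
  if (overall) units <- c(units, list(ALL = shapes$shape))
  do.call(rbind, lapply(names(units), function(u) {
    obs <- table(factor(units[[u]], shape_levels))
    n <- sum(obs)
    e <- n / 4
    if (n < min_is) {
      return(data.frame(unit = u, shape = shape_levels,
                        observed = as.integer(obs), expected = e,
                        chi2 = NA_real_, p_value = NA_real_,
                        call = "not_tested", stringsAsFactors = FALSE))
    }
    chi2 <- sum((obs - e)^2 / e)
    p <- pchisq(chi2, df = 3, lower.tail = FALSE)
    call <- rep("normal", 4)
    if (p < alpha) {
      call[obs > (1 + margin) * e] <- "over"
      call[obs < (1 - margin) * e] <- "under"
    }
    data.frame(unit = u, shape = shape_levels, observed = as.integer(obs),
               expected = e, chi2 = chi2, p_value = p, call = call,
               stringsAsFactors = FALSE)
  }))
}

#' IS-family x gene-function (IGF) couples and representation statistics
#'
#' An IGF couple associates an IS family with the normalized function name of
#' one neighboring gene (each IS contributes 2 or 3 couples via its -1/0/+1
#' neighbors). Statistics are restricted to function names whose corpus
#' frequency reaches `gate_frac` of all coding genes (default 0.01%,
#' recomputed from the corpus at hand). For family f and function g, the
#' expected couple count is (number of gated IGF couples of f) x (corpus
#' frequency of g among gated functions); a 1-df chi-square with the 10%
#' rule calls `over`/`under` at p < `alpha`.
#'
#' @param couples output of [build_couples()].
#' @param gs [genome_set()] supplying the gene corpus.
#' @param gate_frac corpus-frequency gate (fraction of all coding genes).
#' @param min_function_count absolute override of the gate count.
#' @param exclude_functions normalized function names to drop (e.g.
#'   `"HYPOTHETICAL PROTEIN"`).
#' @param strict_names if `TRUE`, match product strings byte-for-byte
#'   instead of normalizing case/whitespace.
#' @param min_is minimum gated couples per family for testing.
#' @param alpha,margin significance level and 10% rule margin.
#' @return list with `couples` (IGF table), `stats` (per family x gated
#'   function), and `min_count` (the realized gate).
#' @export
build_igf <- function(couples, gs, gate_frac = 1e-4,
                      min_function_count = NULL,
                      exclude_functions = character(0),
                      strict_names = FALSE, min_is = 10, alpha = 0.01,
                      margin = 0.1) {
  corpus <- gs$genes[gs$genes$is_coding & gs$genes$product != "", ]
  fn_corpus <- normalize_function(corpus$product, strict = strict_names)
  n_genes <- length(fn_corpus)
  min_count <- if (is.null(min_function_count))
    max(1L, as.integer(ceiling(gate_frac * n_genes))) else min_function_count
  counts <- table(fn_corpus)
  eligible <- setdiff(names(counts)[counts >= min_count], exclude_functions)
  igf <- couples[couples$gene_product != "", ]
  igf$function_name <- normalize_function(igf$gene_product,
                                          strict = strict_names)
  igf <- igf[!(igf$function_name %in% exclude_functions), ]
  igf$gated <- igf$function_name %in% eligible
  freq <- counts[eligible] / sum(counts[eligible])
  stats <- do.call(rbind, lapply(split(igf[igf$gated, ], igf$family[igf$gated]),
                                 function(d) {
    f <- d$family[1]
    t_f <- nrow(d)
    obs <- table(factor(d$function_name, eligible))
    e <- t_f * as.numeric(freq)
    res <- data.frame(family = f, function_name = eligible,
                      observed = as.integer(obs), expected = e,
                      chi2 = NA_real_, p_value = NA_real_,
                      call = "not_tested", stringsAsFactors = FALSE)
    ok <- t_f >= min_is & e >= 1 & (t_f - e) >= 1
    chi2 <- (obs - e)^2 / e + (obs - e)^2 / (t_f - e)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    res$chi2[ok] <- chi2[ok]
    res$p_value[ok] <- p[ok]
    call <- rep("normal", length(e))
    call[p < alpha & obs > (1 + margin) * e] <- "over"
    call[p < alpha & obs < (1 - margin) * e] <- "under"
    res$call[ok] <- call[ok]
    res
  }))
  if (!is.null(stats)) {
    stats$p_adjust_bh <- stats::p.adjust(stats$p_value, method = "BH")
    rownames(stats) <- NULL
  }
  list(couples = igf, stats = stats, min_count = min_count)
}

#' Binned IS-gene distance x IS size histogram
#'
#' Counts IG couples in left-closed right-open distance bins (`[50-100[`
#' includes 50, excludes 100; distance 0 is the `overlap` bin) crossed with
#' IS size bins, optionally stratified by a per-occurrence grouping (e.g.
#' sIG category or clade).
#'
#' @param couples output of [build_couples()].
#' @param occurrences occurrence data frame (for IS sizes).
#' @param groups optional data frame `occurrence_id`, `group`.
#' @param bin_dist,bin_size bin widths in bp.
#' @return data frame `group`, `family`, `dist_bin`, `size_bin`, `n`.
#' @export
distance_size_bins <- function(couples, occurrences, groups = NULL,
                               bin_dist = 50, bin_size = 100) {
  sz <- occurrences$end - occurrences$start
  names(sz) <- occurrences$occurrence_id
  d <- data.frame(family = couples$family,
                  dist_bin = dist_bin(couples$distance_bp, bin_dist),
                  size_bin = size_bin(as.integer(sz[couples$occurrence_id]),
                                      bin_size),
                  stringsAsFactors = FALSE)
  d$group <- if (is.null(groups)) "all" else {
    g <- setNames(groups$group, groups$occurrence_id)
    out <- g[couples$occurrence_id]
    ifelse(is.na(out), "ungrouped", out)
  }
  agg <- stats::aggregate(list(n = rep(1L, nrow(d))),
                          d[, c("group", "family", "dist_bin", "size_bin")],
                          FUN = sum)
  agg[ord(agg$group, agg$family, agg$dist_bin, agg$size_bin), , drop = FALSE]
}
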