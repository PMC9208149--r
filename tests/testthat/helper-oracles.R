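# Independent brute-force oracles. These deliberately share no code with the
# package implementation: O(n^2) double loops, explicit graph searches and
# adjacency matrices.

oracle_filter <- function(hits, min_len = 80, min_identity = 80) {
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits)))
    keep[i] <- hits$alignment_length[i] >= min_len &&
      hits$percent_identity[i] >= min_identity
  hits[keep, , drop = FALSE]
}

# overlap-connected components by breadth-first search on the explicit
# pairwise overlap graph; keep the per-component best hit
oracle_resolve <- function(hits) {
  n <- nrow(hits)
  if (n == 0) return(hits)
  adj <- outer(hits$replicon_id, hits$replicon_id, "==") &
    outer(hits$start, hits$end, "<") & t(outer(hits$start, hits$end, "<"))
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n); cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  keep <- integer(0)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    key <- order(hits$e_value[idx], -hits$alignment_length[idx],
                 -hits$percent_identity[idx], hits$member_name[idx],
                 method = "radix")
    keep <- c(keep, idx[key[1]])
  }
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sequential same-family interval union with strict < gap rule
oracle_merge <- function(hits, merge_gap = 80) {
  if (!nrow(hits)) return(NULL)
  h <- hits[order(hits$replicon_id, hits$start, method = "radix"), ,
            drop = FALSE]
  groups <- list(); cur <- h[1, , drop = FALSE]
  for (i in seq_len(nrow(h))[-1]) {
    r <- h[i, , drop = FALSE]
    last <- cur[nrow(cur), ]
    if (r$replicon_id == last$replicon_id && r$family == last$family &&
        (r$start - max(cur$end)) < merge_gap) {
      cur <- rbind(cur, r)
    } else {
      groups[[length(groups) + 1]] <- cur
      cur <- r
    }
  }
  groups[[length(groups) + 1]] <- cur
  do.call(rbind, lapply(groups, function(g) {
    key <- order(g$e_value, -g$alignment_length, -g$percent_identity,
                 g$member_name, method = "radix")[1]
    data.frame(replicon_id = g$replicon_id[1], start = min(g$start),
               end = max(g$end), family = g$family[1],
               best_member = g$member_name[key],
               best_e_value = g$e_value[key], merged_hit_count = nrow(g),
               stringsAsFactors = FALSE)
  }))
}

oracle_detect <- function(hits, min_len = 80, min_identity = 80,
                          merge_gap = 80, min_size = 80) {
  m <- oracle_merge(oracle_resolve(oracle_filter(hits, min_len,
                                                 min_identity)), merge_gap)
  if (is.null(m)) return(NULL)
  m[m$end - m$start >= min_size, , drop = FALSE]
}

# nearest-neighbor linear scan for one IS against one replicon's genes
oracle_neighbors <- function(is_start, is_end, genes) {
  genes <- genes[genes$is_coding, , drop = FALSE]
  left <- NULL; right <- NULL; over <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$end <= is_start) {
      if (is.null(left) || g$end > left$end ||
          (g$end == left$end && g$start > left$start)) left <- g
    }
    if (g$start >= is_end) {
      if (is.null(right) || g$start < right$start ||
          (g$start == right$start && g$end < right$end)) right <- g
    }
    if (g$start < is_end && g$end > is_start) over <- c(over, g$gene_id)
  }
  list(left = left, right = right, overlap = over)
}

# double-loop interval overlap counts (motifs per IS)
oracle_motif_counts <- function(occ, motifs) {
  n <- integer(nrow(occ))
  for (i in seq_len(nrow(occ))) for (j in seq_len(nrow(motifs))) {
    if (occ$replicon_id[i] == motifs$replicon_id[j] &&
        occ$start[i] < motifs$end[j] && motifs$start[j] < occ$end[i])
      n[i] <- n[i] + 1L
  }
  n
}

# adjacency-matrix degree/strength
oracle_node_metrics <- function(edges, phyla) {
  A <- matrix(0, length(phyla), length(phyla), dimnames = list(phyla, phyla))
  for (i in seq_len(nrow(edges))) {
    A[edges$phylum_a[i], edges$phylum_b[i]] <- edges$weight[i]
    A[edges$phylum_b[i], edges$phylum_a[i]] <- edges$weight[i]
  }
  data.frame(phylum = phyla, degree = as.integer(rowSums(A > 0)),
             strength = as.integer(rowSums(A)), stringsAsFactors = FALSE)
}

# random normalized hit tables for property tests
random_hits <- function(n, n_replicons = 2, families = c("IS1", "IS3"),
                        span = 20000) {
  reps <- sprintf("r%02d", seq_len(n_replicons))
  fam <- sample(families, n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(30:2000, n, replace = TRUE)
  data.frame(member_name = paste0(fam, "_m", sample(1:3, n, replace = TRUE)),
             replicon_id = sample(reps, n, replace = TRUE),
             start = start, end = start + len,
             percent_identity = round(runif(n, 60, 100), 1),
             alignment_length = len,
             e_value = signif(10^runif(n, -150, -1), 3),
             program = "nucleotide", family = fam,
             stringsAsFactors = FALSE)
}

canon_occ <- function(df) {
  df <- df[order(df$replicon_id, df$start, df$end, method = "radix"),
           c("replicon_id", "start", "end", "family", "best_member",
             "best_e_value", "merged_hit_count")]
  rownames(df) <- NULL
  df
}
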