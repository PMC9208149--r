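mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(member_name = r$m, replicon_id = ifelse(is.null(r$r), "chrA",
                                                       r$r),
               start = r$s, end = r$e,
               percent_identity = r$id, alignment_length = r$e - r$s,
               e_value = r$ev, program = "nucleotide",
               family = sub("_m.*", "", r$m), stringsAsFactors = FALSE)))
}

test_that("the 80:80 filter is boundary-inclusive", {
  h <- data.frame(member_name = "IS1_m01", replicon_id = "chrA",
                  start = 0L, end = c(81L, 80L, 80L, 79L),
                  percent_identity = c(85, 79.9, 80, 85),
                  alignment_length = c(81L, 80L, 80L, 79L),
                  e_value = 1e-30, program = "nucleotide", family = "IS1",
                  stringsAsFactors = FALSE)
  kept <- filter_hits(h)
  expect_equal(kept$alignment_length, c(81L, 80L))
  expect_equal(kept$percent_identity, c(85, 80))
  expect_equal(nrow(filter_hits(h[0, ])), 0)
})

test_that("filtering equals the brute-force predicate oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    h <- random_hits(100)
    expect_equal(filter_hits(h), oracle_filter(h), ignore_attr = TRUE)
  }
})

test_that("overlap resolution keeps the best E-value per hit region", {
  h <- mk_hits(list(m = "IS1_m01", s = 100, e = 600, id = 95, ev = 1e-30),
               list(m = "IS3_m01", s = 500, e = 900, id = 90, ev = 1e-10),
               list(m = "IS1_m02", s = 2000, e = 2500, id = 92, ev = 1e-20))
  r <- resolve_overlaps(h)
  expect_equal(r$member_name, c("IS1_m01", "IS1_m02"))
  # disjoint hits are all kept
  h2 <- mk_hits(list(m = "IS1_m01", s = 0, e = 100, id = 95, ev = 1e-5),
                list(m = "IS1_m02", s = 200, e = 300, id = 95, ev = 1e-3))
  expect_equal(nrow(resolve_overlaps(h2)), 2)
})

test_that("overlap resolution equals the component-minimum graph oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    h <- random_hits(20, span = 4000)  # dense => many overlaps
    canon <- function(d) {
      d <- d[order(d$replicon_id, d$start, d$end, d$member_name,
                   method = "radix"), ]
      rownames(d) <- NULL
      d
    }
    expect_equal(canon(resolve_overlaps(h)), canon(oracle_resolve(h)))
  }
})

test_that("same-family merging respects the strict 80 bp gap rule", {
  h <- mk_hits(list(m = "IS1_m01", s = 100, e = 400, id = 95, ev = 1e-30),
               list(m = "IS1_m02", s = 450, e = 900, id = 92, ev = 1e-20))
  occ <- merge_occurrences(h)  # gap 50 < 80 -> merged
  expect_equal(nrow(occ), 1)
  expect_equal(c(occ$start, occ$end), c(100L, 900L))
  expect_equal(occ$merged_hit_count, 2L)
  expect_equal(occ$best_member, "IS1_m01")  # smallest E-value wins
  h$start[2] <- 480L  # gap exactly 80 -> NOT merged
  expect_equal(nrow(merge_occurrences(h)), 2)
  h$start[2] <- 450L
  h$family[2] <- "IS3"  # different families never merge
  expect_equal(nrow(merge_occurrences(h)), 2)
})

test_that("detect() equals the composed brute-force oracle on random hits", {
  for (seed in 1:10) {
    set.seed(seed)
    h <- random_hits(sample(20:200, 1))
    got <- detect_is(h)
    want <- oracle_detect(h)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(canon_occ(got), canon_occ(want))
    }
  }
})

test_that("called occurrences never overlap and thresholds act monotonically", {
  set.seed(99)
  h <- random_hits(150)
  occ <- detect_is(h)
  by_rep <- split(occ, occ$replicon_id)
  for (d in by_rep) {
    d <- d[order(d$start), ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  n_strict <- nrow(filter_hits(h, 80, 80))
  expect_gte(nrow(filter_hits(h, 60, 80)), n_strict)
  expect_gte(nrow(filter_hits(h, 80, 70)), n_strict)
})

test_that("planted ISs are recovered exactly and decoys are never called", {
  corpus <- small_corpus(seed = 21)
  occ <- detect_is(corpus$hits)
  tr <- corpus$truth$occurrences
  expect_setequal(occ$occurrence_id, tr$occurrence_id)
  m <- match(occ$occurrence_id, tr$occurrence_id)
  expect_equal(occ$best_member, tr$best_member[m])
  expect_equal(occ$merged_hit_count, tr$merged_hit_count[m])
  expect_equal(occ$family, tr$family[m])
  if (!is.null(corpus$truth$decoys)) {
    dk <- sprintf("%s:%d-%d", corpus$truth$decoys$replicon_id,
                  corpus$truth$decoys$start, corpus$truth$decoys$end)
    expect_length(intersect(dk, occ$occurrence_id), 0)
  }
})

test_that("IS density is total class bp over class occurrence count", {
  gs <- genome_set(
    data.frame(assembly_id = "A", replicon_id = c("c1", "p1"),
               replicon_type = c("chromosome", "plasmid"),
               length_bp = c(1000000L, 50000L), stringsAsFactors = FALSE),
    toy_genes(10, 500, replicon_id = "c1"))
  occ <- toy_occ(1000, 2000, replicon_id = "p1")
  d <- is_density(occ, gs)
  expect_equal(unname(d["plasmid"]), 50000)
  expect_equal(unname(d["chromosome"]), Inf)
  gs2 <- genome_set(gs$replicons[1, ], gs$genes)
  expect_false("plasmid" %in% names(is_density(occ[0, ], gs2)))
  # planted densities recovered from a simulated corpus
  corpus <- small_corpus(seed = 33)
  occ_c <- detect_is(corpus$hits)
  d2 <- is_density(occ_c, corpus$gs)
  expect_equal(as.list(d2), corpus$truth$density_bp_per_is)
})

test_that("family-by-clade distribution reports fractions and flags forced placement", {
  # 3 clades x 20 genomes, one replicon each
  asm <- sprintf("GCA_%02d", 1:60)
  reps <- data.frame(assembly_id = asm, replicon_id = paste0(asm, "_c"),
                     replicon_type = "chromosome", length_bp = 100000L,
                     stringsAsFactors = FALSE)
  gs <- genome_set(reps, toy_genes(integer(0), integer(0)))
  tax <- toy_taxonomy(asm, phyla = rep(c("PhX", "PhY", "PhZ"), each = 20))
  # family present in every genome -> fraction 1, uniform
  occ_all <- toy_occ(rep(100, 60), rep(400, 60), families = "IS1",
                     replicon_id = paste0(asm, "_c"))
  occ_all$replicon_id <- paste0(asm, "_c")
  occ_all$occurrence_id <- sprintf("%s:100-400", occ_all$replicon_id)
  res <- clade_family_distribution(occ_all, gs, tax)
  expect_true(all(res$table$fraction == 1))
  expect_false(res$tests$nonuniform[res$tests$family == "IS1"])
  # family forced into one clade -> flagged nonuniform
  occ_x <- occ_all[1:18, ]  # all in PhX (first 20 assemblies)
  occ_x$family <- "IS9"
  res2 <- clade_family_distribution(rbind(occ_all, occ_x), gs, tax)
  t9 <- res2$tests[res2$tests$family == "IS9", ]
  expect_true(t9$nonuniform)
  g9 <- res2$table[res2$table$family == "IS9", ]
  expect_equal(g9$expected, rep(18 * 20 / 60, 3))  # uniform expectation
  # below the 10-genome gate -> not tested
  occ_s <- occ_all[1:5, ]; occ_s$family <- "IS8"
  res3 <- clade_family_distribution(rbind(occ_all, occ_s), gs, tax)
  expect_equal(res3$tests$call[res3$tests$family == "IS8"], "not_tested")
})
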