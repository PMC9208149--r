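test_that("three close gene-free ISs form one hotspot; a gene breaks it", {
  far_genes <- toy_genes(c(0, 9000), c(500, 9500), products = "MFS transporter")
  occ <- toy_occ(c(1000, 2300, 3600), c(2200, 3500, 4800),
                 families = c("IS1", "IS3", "IS1"))
  gs <- toy_genome(far_genes)
  hs <- detect_hotspots(occ, gs)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$n_is, 3L)
  expect_equal(c(hs$span_start, hs$span_end), c(1000L, 4800L))
  expect_equal(hs$n_families, 2L)
  expect_equal(hs$flank_left_product, "MFS transporter")
  # a coding gene inside an inter-IS gap breaks the chain
  gs2 <- toy_genome(rbind(far_genes,
                          toy_genes(2210, 2290)[, names(far_genes)]))
  expect_equal(nrow(detect_hotspots(occ, gs2)), 0)
  # min_run: two qualifying ISs are not a hotspot
  expect_equal(nrow(detect_hotspots(occ[1:2, ], gs)), 0)
})

test_that("gap condition compares against the summed IS lengths", {
  gs <- toy_genome(toy_genes(0, 100), length_bp = 50000)
  # lengths 400 each; gaps 900 >= 400+400 -> chain never links
  occ <- toy_occ(c(1000, 2300, 3600), c(1400, 2700, 4000))
  expect_equal(nrow(detect_hotspots(occ, gs)), 0)
  # gaps 700 < 800 -> links
  occ2 <- toy_occ(c(1000, 2100, 3200), c(1400, 2500, 3600))
  expect_equal(nrow(detect_hotspots(occ2, gs)), 1)
})

test_that("maximal runs are reported whole, not decomposed", {
  gs <- toy_genome(toy_genes(0, 100), length_bp = 50000)
  occ <- toy_occ(seq(1000, by = 1300, length.out = 5),
                 seq(2200, by = 1300, length.out = 5))
  hs <- detect_hotspots(occ, gs)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$n_is, 5L)
})

test_that("hotspot at the replicon edge counts only its present flank", {
  gs <- toy_genome(toy_genes(9000, 9600, products = "ATP-binding protein"))
  occ <- toy_occ(c(100, 1400, 2700), c(1300, 2600, 3900))
  hs <- detect_hotspots(occ, gs)
  expect_equal(nrow(hs), 1)
  expect_true(is.na(hs$flank_left_gene))
  tab <- hotspot_functions(hs)
  expect_equal(tab$function_name, "ATP-BINDING PROTEIN")
  expect_equal(tab$n_hotspots, 1L)
})

test_that("hotspot function tally counts hotspots per flanking function", {
  gs <- toy_genome(toy_genes(c(0, 6000, 20000, 26000),
                             c(500, 6500, 20500, 26500),
                             products = c("MFS transporter", "amidase",
                                          "MFS transporter", "pyruvate kinase")),
                   length_bp = 40000)
  occ <- toy_occ(c(1000, 2300, 3600, 21000, 22300, 23600),
                 c(2200, 3500, 4800, 22200, 23500, 24800))
  hs <- detect_hotspots(occ, gs)
  expect_equal(nrow(hs), 2)
  tab <- hotspot_functions(hs)
  expect_equal(tab$n_hotspots[tab$function_name == "MFS TRANSPORTER"], 2L)
  tab2 <- hotspot_functions(hs, exclude_functions = "MFS TRANSPORTER")
  expect_false("MFS TRANSPORTER" %in% tab2$function_name)
})

test_that("reported hotspots re-validate their defining conditions", {
  corpus <- small_corpus(seed = 13)
  occ <- detect_is(corpus$hits)
  hs <- detect_hotspots(occ, corpus$gs)
  expect_gt(nrow(hs), 0)
  for (i in seq_len(nrow(hs))) {
    mem <- occ[match(strsplit(hs$member_occurrences[i], ",")[[1]],
                     occ$occurrence_id), ]
    mem <- mem[order(mem$start), ]
    expect_gte(nrow(mem), 3)
    len <- mem$end - mem$start
    gaps <- mem$start[-1] - mem$end[-nrow(mem)]
    expect_true(all(gaps < len[-length(len)] + len[-1]))
    g <- corpus$gs$genes
    g <- g[g$replicon_id == hs$replicon_id[i] & g$is_coding, ]
    for (j in seq_len(nrow(mem) - 1))
      expect_false(any(g$start < mem$start[j + 1] & g$end > mem$end[j]))
  }
})

test_that("equally spaced ISs are not flagged as non-uniform", {
  pos <- seq(10000, 4990000, length.out = 100)
  res <- nonuniformity_test(pos, 5e6, seed = 1)
  expect_true(res$tested)
  expect_false(res$nonuniform)
})

test_that("clustered placements are flagged and few ISs are not tested", {
  set.seed(42)
  centers <- runif(5, 0, 4.5e6)
  pos <- as.integer(rep(centers, each = 20) + runif(100, 0, 3e4))
  res <- nonuniformity_test(pos, 5e6, seed = 7)
  expect_true(res$nonuniform)
  expect_equal(nonuniformity_test(pos[1:5], 5e6)$tested, FALSE)
})

test_that("the uniformity gate controls hotspot reporting in the pipeline", {
  corpus <- small_corpus(seed = 13)
  occ <- detect_is(corpus$hits)
  tests <- nonuniformity_tests(occ, corpus$gs, seed = 3)
  expect_equal(nrow(tests), nrow(corpus$gs$replicons))
  expect_true(all(!tests$tested | !is.na(tests$p_value)))
})
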