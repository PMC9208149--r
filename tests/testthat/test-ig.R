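test_that("couples capture -1/+1 neighbors with boundary-gap distances", {
  gs <- toy_genome(toy_genes(c(0, 2500), c(900, 3100), strands = c("+", "-")))
  occ <- toy_occ(1000, 2200)
  cp <- build_couples(occ, gs)
  expect_equal(nrow(cp), 2)
  left <- cp[cp$position == -1, ]
  right <- cp[cp$position == 1, ]
  expect_equal(left$distance_bp, 100L)
  expect_equal(right$distance_bp, 300L)
  expect_equal(left$gene_id, "g001")
  expect_equal(right$gene_id, "g002")
})

test_that("a gene overlapping the IS adds a position-0 couple at distance 0", {
  gs <- toy_genome(toy_genes(c(0, 950, 2500), c(900, 1001, 3100)))
  occ <- toy_occ(1000, 2200)  # gene 2 overlaps by 1 bp
  cp <- build_couples(occ, gs)
  expect_equal(sort(cp$position), c(-1L, 0L, 1L))
  ov <- cp[cp$position == 0, ]
  expect_equal(ov$gene_id, "g002")
  expect_equal(ov$distance_bp, 0L)
  # the -1 neighbor is the nearest gene entirely to the left
  expect_equal(cp$gene_id[cp$position == -1], "g001")
})

test_that("non-coding features are skipped and edge ISs lack a neighbor", {
  g <- toy_genes(c(0, 2500), c(900, 3100), coding = c(FALSE, TRUE))
  gs <- toy_genome(g)
  cp <- build_couples(toy_occ(1000, 2200), gs)
  expect_equal(cp$position, 1L)  # only the right, coding neighbor
  # replicon without coding genes yields no couples
  gs2 <- toy_genome(toy_genes(0, 900, coding = FALSE))
  expect_equal(nrow(build_couples(toy_occ(1000, 2200), gs2)), 0)
})

test_that("couples equal the nearest-neighbor linear-scan oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n_g <- 30
    starts <- sort(sample.int(50000, n_g))
    genes <- toy_genes(starts, starts + sample(100:800, n_g, replace = TRUE),
                       strands = sample(c("+", "-"), n_g, replace = TRUE),
                       coding = runif(n_g) > 0.2)
    genes <- genes[genes$end <= 60000, ]
    gs <- toy_genome(genes, length_bp = 70000)
    os <- sample.int(55000, 8)
    occ <- toy_occ(os, os + sample(200:2000, 8, replace = TRUE))
    occ <- occ[occ$end <= 70000, ]
    cp <- build_couples(occ, gs)
    for (i in seq_len(nrow(occ))) {
      want <- oracle_neighbors(occ$start[i], occ$end[i], gs$genes)
      mine <- cp[cp$occurrence_id == occ$occurrence_id[i], ]
      expect_equal(mine$gene_id[mine$position == -1],
                   if (is.null(want$left)) character(0) else want$left$gene_id)
      expect_equal(mine$gene_id[mine$position == 1],
                   if (is.null(want$right)) character(0) else
                     want$right$gene_id)
      expect_setequal(mine$gene_id[mine$position == 0], want$overlap)
    }
  }
})

test_that("shape classification enumerates the four strand combinations", {
  expect_equal(classify_shape(c("+", "-", "+", "-"), c("+", "+", "-", "-")),
               c("SPS", "OD", "OC", "SNS"))
  # exhaustive fixture: one IS per combination -> each shape exactly once
  combos <- expand.grid(l = c("+", "-"), r = c("+", "-"),
                        stringsAsFactors = FALSE)
  shapes <- classify_shape(combos$l, combos$r)
  expect_setequal(shapes, c("SPS", "SNS", "OC", "OD"))
})

test_that("shapes are invariant under coordinate translation", {
  g <- toy_genes(c(0, 2500), c(900, 3100), strands = c("-", "+"))
  occ <- toy_occ(1000, 2200)
  s1 <- ig_shapes(build_couples(occ, toy_genome(g)))
  g2 <- g; g2$start <- g2$start + 5000L; g2$end <- g2$end + 5000L
  occ2 <- toy_occ(6000, 7200)
  s2 <- ig_shapes(build_couples(occ2, toy_genome(g2, length_bp = 20000)))
  expect_equal(s1$shape, "OD")
  expect_equal(s2$shape, s1$shape)
})

test_that("shape chi-square applies the 25% expectation and the 10% rule", {
  mk_shapes <- function(counts)
    data.frame(occurrence_id = sprintf("o%03d", seq_len(sum(counts))),
               family = "IS1",
               shape = rep(c("SPS", "SNS", "OC", "OD"), counts),
               stringsAsFactors = FALSE)
  st <- shape_representation(mk_shapes(c(25, 25, 25, 25)), overall = FALSE)
  expect_true(all(st$call == "normal"))
  expect_equal(unique(st$expected), 25)
  st2 <- shape_representation(mk_shapes(c(70, 10, 10, 10)), overall = FALSE)
  expect_equal(unique(st2$chi2), 108)  # hand-computed: (45^2+3*15^2)/25
  expect_lt(unique(st2$p_value), 0.01)
  expect_equal(st2$call[st2$observed == 70], "over")    # 70 > 1.1*25
  expect_equal(st2$call[st2$observed == 10], rep("under", 3))
  st3 <- shape_representation(mk_shapes(c(2, 2, 2, 2)), overall = FALSE)
  expect_true(all(st3$call == "not_tested"))  # below the 10-IS gate
  # per-family shape totals equal the number of shaped ISs
  corpus <- small_corpus(seed = 5)
  occ <- detect_is(corpus$hits)
  sh <- ig_shapes(build_couples(occ, corpus$gs))
  st4 <- shape_representation(sh)
  tot <- tapply(st4$observed[st4$unit != "ALL"], st4$unit[st4$unit != "ALL"],
                sum)
  expect_equal(as.integer(tot[sort(unique(sh$family))]),
               as.integer(table(sh$family)[sort(unique(sh$family))]))
})

test_that("IGF gate arithmetic, expectation formula and calls are correct", {
  # corpus of 10,000 genes -> 0.01% gate = ceiling(1) = 1
  n <- 10000
  prods <- c(rep("FUNCTION A", 500), rep("FUNCTION B", 9499), "RARE ONE")
  genes <- toy_genes(seq(0, by = 10, length.out = n),
                     seq(8, by = 10, length.out = n), products = prods)
  gs <- toy_genome(genes, length_bp = 200000)
  cp <- data.frame(occurrence_id = sprintf("o%03d", 1:200), family = "IS1",
                   replicon_id = "chrA", gene_id = "gX",
                   position = rep(c(-1L, 1L), 100), distance_bp = 10L,
                   gene_strand = "+",
                   gene_product = c(rep("FUNCTION A", 40),
                                    rep("FUNCTION B", 159), "RARE ONE"),
                   stringsAsFactors = FALSE)
  igf <- build_igf(cp, gs)
  expect_equal(igf$min_count, 1L)
  expect_true("RARE ONE" %in% igf$stats$function_name)  # passes min count 1
  # family 200 couples, FUNCTION A at 5% corpus frequency -> expected 10
  stA <- igf$stats[igf$stats$function_name == "FUNCTION A", ]
  expect_equal(stA$expected, 200 * 500 / 10000)
  expect_equal(stA$observed, 40L)
  expect_equal(stA$call, "over")  # 40 > 1.1 * 10, chi2 p << 0.01
  # expected counts sum to the family's gated couple total
  expect_equal(sum(igf$stats$expected), 200)
  expect_equal(sum(igf$stats$observed), 200L)
  # hypothetical-protein-style exclusion by flag
  igf2 <- build_igf(cp, gs, exclude_functions = "FUNCTION B")
  expect_false("FUNCTION B" %in% igf2$stats$function_name)
})

test_that("distance and size bins are left-closed right-open", {
  expect_equal(dist_bin(c(0, 1, 49, 50, 99, 100, 150)),
               c("overlap", "[1-50[", "[1-50[", "[50-100[", "[50-100[",
                 "[100-150[", "[150-200["))
  expect_equal(size_bin(c(1200, 1299, 1300)),
               c("[1200-1300[", "[1200-1300[", "[1300-1400["))
  corpus <- small_corpus(seed = 9)
  occ <- detect_is(corpus$hits)
  cp <- build_couples(occ, corpus$gs)
  bins <- distance_size_bins(cp, occ)
  expect_equal(sum(bins$n), nrow(cp))  # histogram conserves couple count
})
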