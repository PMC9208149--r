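# two-genome fixture: each genome one OD IS with designated flank genes
two_records <- function(fam_a = "IS1", fam_b = "IS1",
                        phy = c("PhA", "PhB"),
                        sp = c("Ga sa", "Gb sb"),
                        asm = c("GCA_A", "GCA_B")) {
  data.frame(occurrence_id = c("rA:100-1300", "rB:100-1300"),
             family = c(fam_a, fam_b), replicon_id = c("rA", "rB"),
             left_gene = c("a_L", "b_L"), left_product = "prod L",
             right_gene = c("a_R", "b_R"), right_product = "prod R",
             shape = "OD", assembly_id = asm, phylum = phy,
             species = sp, strain = c("s1", "s2"), stringsAsFactors = FALSE)
}

hom <- function(...) {
  p <- list(...)
  homology_edges(vapply(p, `[[`, "", 1), vapply(p, `[[`, "", 2),
                 as.numeric(vapply(p, `[[`, "", 3)))
}

test_that("shape selection keeps only the requested shapes", {
  rec <- do.call(rbind, lapply(1:40, function(i) {
    r <- two_records()[1, ]
    r$occurrence_id <- sprintf("r%02d:1-2", i)
    r$shape <- rep(c("SPS", "SNS", "OC", "OD"), 10)[i]
    r
  }))
  expect_equal(nrow(select_shape(rec)), 10)
  expect_true(all(select_shape(rec)$shape == "OD"))
  expect_equal(nrow(select_shape(rec, c("OD", "OC"))), 20)
  expect_warning(out <- select_shape(rec[rec$shape == "SPS", ]), "no IS")
  expect_equal(nrow(out), 0)
  # matches a plain predicate filter
  expect_equal(select_shape(rec)$occurrence_id,
               rec$occurrence_id[rec$shape == "OD"])
})

test_that("presIG needs same family, two homolog pairs, distinct strains", {
  r <- two_records()
  h2 <- hom(c("a_L", "b_L", "1e-80"), c("a_R", "b_R", "1e-80"))
  expect_true(pre_sig(r[1, ], r[2, ], h2))
  # only one homologous pair
  h1 <- hom(c("a_L", "b_L", "1e-80"))
  expect_false(pre_sig(r[1, ], r[2, ], h1))
  # different families
  rd <- two_records(fam_b = "IS3")
  expect_false(pre_sig(rd[1, ], rd[2, ], h2))
  # E-value boundary: <= threshold qualifies
  hb <- hom(c("a_L", "b_L", "1e-50"), c("a_R", "b_R", "1e-50"))
  expect_true(pre_sig(r[1, ], r[2, ], hb, threshold = 1e-50))
  expect_false(pre_sig(r[1, ], r[2, ], hb, threshold = 1e-51))
  # same assembly never links
  rs <- two_records(asm = c("GCA_A", "GCA_A"))
  expect_false(pre_sig(rs[1, ], rs[2, ], h2))
})

test_that("one promiscuous gene cannot satisfy the two-of-four rule", {
  r <- two_records()
  h <- hom(c("a_L", "b_L", "1e-80"), c("a_L", "b_R", "1e-80"))
  expect_false(pre_sig(r[1, ], r[2, ], h))  # both pairs reuse a_L
  # crossed sides are allowed by default but not in strict mode
  hx <- hom(c("a_L", "b_R", "1e-80"), c("a_R", "b_L", "1e-80"))
  expect_true(pre_sig(r[1, ], r[2, ], hx))
  expect_false(pre_sig(r[1, ], r[2, ], hx, strict_sides = TRUE))
})

test_that("component taxonomic span sets the sIG category", {
  h2 <- hom(c("a_L", "b_L", "1e-80"), c("a_R", "b_R", "1e-80"))
  # two phyla -> phylum sIG
  cl <- classify_sig(two_records(), h2)
  expect_equal(cl$sets$category, "phylum")
  expect_equal(cl$sets$n_members, 2L)
  # one phylum, two species -> class_to_genus
  cl2 <- classify_sig(two_records(phy = c("PhA", "PhA")), h2)
  expect_equal(cl2$sets$category, "class_to_genus")
  # one species, distinct strains -> species
  cl3 <- classify_sig(two_records(phy = c("PhA", "PhA"),
                                  sp = c("Ga sa", "Ga sa")), h2)
  expect_equal(cl3$sets$category, "species")
  # no homology -> two unique IGs
  cl4 <- classify_sig(two_records(), hom(c("x", "y", "1e-80")))
  expect_equal(cl4$sets$category, c("unique", "unique"))
  expect_equal(cl4$sets$dominant_function, c("PROD L", "PROD L"))
})

test_that("every OD record lands in exactly one set (partition invariant)", {
  corpus <- small_corpus(seed = 17)
  occ <- detect_is(corpus$hits)
  rec <- select_shape(ig_records(build_couples(occ, corpus$gs), corpus$gs,
                                 corpus$taxonomy))
  cl <- classify_sig(rec, corpus$homology)
  expect_setequal(cl$members$occurrence_id, rec$occurrence_id)
  expect_equal(nrow(cl$members), nrow(rec))
  expect_equal(sum(cl$sets$n_members), nrow(rec))
})

test_that("classification is invariant to record order", {
  corpus <- small_corpus(seed = 17)
  occ <- detect_is(corpus$hits)
  rec <- select_shape(ig_records(build_couples(occ, corpus$gs), corpus$gs,
                                 corpus$taxonomy))
  cl1 <- classify_sig(rec, corpus$homology)
  set.seed(1)
  cl2 <- classify_sig(rec[sample(nrow(rec)), ], corpus$homology)
  cat1 <- cl1$sets$category[match(cl1$members$set_id, cl1$sets$set_id)]
  cat2 <- cl2$sets$category[match(cl2$members$set_id, cl2$sets$set_id)]
  expect_equal(cat1[order(cl1$members$occurrence_id)],
               cat2[order(cl2$members$occurrence_id)])
})

test_that("planted sIG components are recovered with their category", {
  for (seed in c(2, 8)) {
    corpus <- small_corpus(seed = seed)
    occ <- detect_is(corpus$hits)
    rec <- select_shape(ig_records(build_couples(occ, corpus$gs), corpus$gs,
                                   corpus$taxonomy))
    cl <- classify_sig(rec, corpus$homology)
    mem <- vapply(split(cl$members$occurrence_id, cl$members$set_id),
                  function(x) paste(sort(x), collapse = ","), "")
    tru <- corpus$truth$sig_sets
    got_ids <- names(mem)[match(tru$member_occurrences, mem)]
    expect_false(anyNA(got_ids))  # every planted component found intact
    expect_equal(cl$sets$category[match(got_ids, cl$sets$set_id)],
                 tru$category)
    # all non-planted OD records are unique IGs
    planted <- unlist(strsplit(tru$member_occurrences, ","))
    rest <- setdiff(rec$occurrence_id, planted)
    rest_sets <- cl$members$set_id[match(rest, cl$members$occurrence_id)]
    expect_true(all(cl$sets$category[match(rest_sets, cl$sets$set_id)] ==
                      "unique"))
  }
})

test_that("threshold sweep is monotone and hits both extremes", {
  corpus <- small_corpus(seed = 17)
  occ <- detect_is(corpus$hits)
  rec <- select_shape(ig_records(build_couples(occ, corpus$gs), corpus$gs,
                                 corpus$taxonomy))
  th <- 10^c(-300, -150, -100, -50, -20, -1)
  sw <- threshold_sweep(rec, corpus$homology, th)
  uq <- sw$n_records[sw$category == "unique"]
  expect_true(all(diff(uq) <= 0))  # relaxing never increases unique count
  expect_equal(uq[1], nrow(rec))   # below all edges: everything unique
  # per-threshold counts partition the records
  for (t1 in th)
    expect_equal(sum(sw$n_records[sw$threshold == t1]), nrow(rec))
})
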