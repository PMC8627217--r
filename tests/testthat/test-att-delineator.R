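# att-pair search, mono/tripartite delineation, splice conservation

test_that("a planted exact repeat flanking a seeded region is found at full length", {
  set.seed(41)
  cs <- rand_mono_case(core_len = 17L)
  g <- mini_genome(cs$text)
  anchors <- data.frame(anchor_id = "a1", replicon_id = "chr", locus_id = "t",
                        anchor_class = "tRNA-Phe", strand = "+",
                        pos3p = cs$attL_start, stringsAsFactors = FALSE)
  seeds <- cs$attL_start + cs$core_len + c(200, 250, 300)
  pairs <- find_att_pairs(g$replicons$chr, anchors, seeds)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$attL_start, cs$attL_start)
  expect_equal(pairs$attR_start, cs$attR_start)
  expect_equal(pairs$core_len, 17L)
  # without an enclosed seed the pair is rejected
  expect_equal(nrow(find_att_pairs(g$replicons$chr, anchors,
                                   seeds = numeric(0))), 0L)
  # pair calls are invariant to seed order
  p2 <- find_att_pairs(g$replicons$chr, anchors, rev(seeds))
  expect_equal(p2, pairs, ignore_attr = TRUE)
})

test_that("monopartite excision obeys the one-core circle convention", {
  set.seed(42)
  cs <- rand_mono_case(core_len = 20L, inner = 960L)
  g <- mini_genome(cs$text)
  pair <- data.frame(replicon_id = "chr", attL_start = cs$attL_start,
                     attL_end = cs$attL_start + 20L,
                     attR_start = cs$attR_start, attR_end = cs$attR_start + 20L,
                     core_seq = cs$core, core_len = 20L, anchor_id = "a",
                     anchor_class = "tRNA-Phe", n_seeds = 1L,
                     span = cs$attR_start + 20L - cs$attL_start,
                     stringsAsFactors = FALSE)
  el <- delineate_monopartite(pair, g, element_id = "E")
  frag_len <- cs$attR_start + 20L - cs$attL_start
  expect_equal(nchar(el$circular_sequence), frag_len - 20L)
  expect_equal(element_length(el), 980L)
})

test_that("excision and re-integration conserve the replicon byte-for-byte", {
  set.seed(43)
  for (i in 1:10) {
    cs <- rand_mono_case()
    g <- mini_genome(cs$text)
    pair <- data.frame(replicon_id = "chr", attL_start = cs$attL_start,
                       attL_end = cs$attL_start + cs$core_len,
                       attR_start = cs$attR_start,
                       attR_end = cs$attR_start + cs$core_len,
                       core_seq = cs$core, core_len = cs$core_len,
                       anchor_id = "a", anchor_class = "x", n_seeds = 1L,
                       span = 0L, stringsAsFactors = FALSE)
    el <- delineate_monopartite(pair, g, element_id = "E")
    ex <- excise_element(el, g)
    expect_identical(integrate_element(ex$scar, el), cs$text)
    oracle <- oracle_splice(cs$text, cs$core)
    expect_identical(oracle[[1]]$seq, ex$scar)
    expect_true(same_circle(oracle[[2]]$seq, ex$circle))
  }
})

test_that("tripartite resolution joins fragments into the oracle's circle", {
  set.seed(44)
  for (i in 1:6) {
    cs <- rand_tri_case()
    g <- mini_genome(cs$text)
    el <- resolve_multipartite(cs$pairs, g, element_id = "T")
    expect_equal(el$partite_count, 3L)
    expect_setequal(el$fragments$role, c("alpha", "beta", "gamma"))
    oracle <- oracle_splice(cs$text, unlist(cs$cores))
    expect_equal(length(oracle), 2L)
    circ <- oracle[[which(vapply(oracle, `[[`, TRUE, "circ"))]]$seq
    scar <- oracle[[which(!vapply(oracle, `[[`, TRUE, "circ"))]]$seq
    expect_equal(nchar(el$circular_sequence), nchar(circ))
    expect_true(same_circle(el$circular_sequence, circ))
    ex <- excise_element(el, g)
    expect_identical(ex$scar, scar)
    expect_identical(integrate_element(ex$scar, el), cs$text)
  }
})

test_that("a missing att pair leaves the multipartite structure unresolvable", {
  set.seed(45)
  cs <- rand_tri_case()
  g <- mini_genome(cs$text)
  expect_error(resolve_multipartite(cs$pairs[1:2, ], g),
               "unresolvable multipartite structure")
  # one pair degrades gracefully to a monopartite element
  el <- resolve_multipartite(cs$pairs[1, , drop = FALSE], g)
  expect_equal(el$partite_count, 1L)
})

test_that("repABC without att flags an assembly artifact; att evidence wins", {
  set.seed(46)
  cs <- rand_mono_case()
  g <- mini_genome(cs$text)
  pair <- data.frame(replicon_id = "chr", attL_start = cs$attL_start,
                     attL_end = cs$attL_start + cs$core_len,
                     attR_start = cs$attR_start,
                     attR_end = cs$attR_start + cs$core_len,
                     core_seq = cs$core, core_len = cs$core_len,
                     anchor_id = "a", anchor_class = "x", n_seeds = 1L,
                     span = 0L, stringsAsFactors = FALSE)
  el <- delineate_monopartite(pair, g, element_id = "E")
  el$feature_loci <- c("repL")
  rep_hit <- data.frame(query_locus = "repL", exemplar_id = "repA_1",
                        role_label = "repA", percent_identity = 90,
                        query_coverage = 1, subject_coverage = 1, score = 100,
                        raw_score = 0, evalue_proxy = 0,
                        stringsAsFactors = FALSE)
  # resolved att + repABC: kept
  expect_identical(disambiguate_integrated_plasmid(el, rep_hit),
                   "keep_as_element")
  el2 <- el
  el2$att_status <- "att_not_found"
  expect_identical(disambiguate_integrated_plasmid(el2, rep_hit),
                   "flag_assembly_artifact")
  # no repABC, no att: kept (att_not_found element)
  expect_identical(disambiguate_integrated_plasmid(el2, rep_hit[0, ]),
                   "keep_as_element")
})

test_that("delineation mirrors under reverse complementation of the replicon", {
  set.seed(47)
  cs <- rand_mono_case(core_len = 18L)
  g <- mini_genome(cs$text)
  anchors <- data.frame(anchor_id = "a1", replicon_id = "chr", locus_id = "t",
                        anchor_class = "tRNA-Phe", strand = "+",
                        pos3p = cs$attL_start, stringsAsFactors = FALSE)
  seeds <- cs$attL_start + cs$core_len + 300
  el <- delineate_monopartite(
    find_att_pairs(g$replicons$chr, anchors, seeds), g, element_id = "E")
  L <- nchar(cs$text)
  gr <- mini_genome(rc(cs$text))
  anchors_r <- anchors
  anchors_r$strand <- "-"
  anchors_r$pos3p <- L - anchors$pos3p
  pairs_r <- find_att_pairs(gr$replicons$chr, anchors_r, L - seeds)
  expect_equal(nrow(pairs_r), 1L)
  el_r <- delineate_monopartite(pairs_r, gr, element_id = "Er")
  expect_equal(el_r$fragments$start, L - el$fragments$end)
  expect_equal(el_r$fragments$end, L - el$fragments$start)
  # the excised circles are the same circular molecule on opposite strands
  expect_true(same_circle(el_r$circular_sequence, rc(el$circular_sequence)))
})
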