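# classification rules, symbiosis flag, QS profiling, redundancy, motifs

make_el <- function(loci, att_status = "resolved", id = "E1") {
  fragments <- data.frame(replicon_id = "chr", start = 0L, end = 1000L,
                          role = "mono", left_core_family = "S",
                          right_core_family = "S", left_core_len = 17L,
                          right_core_len = 17L, anchor_class = "tRNA-Phe",
                          stringsAsFactors = FALSE)
  el <- mobelem:::new_element(id, "g", fragments, 1L, "ACGT",
                              data.frame(core_seq = "A", family = "S",
                                         length = 17L),
                              "tRNA-Phe", att_status, feature_loci = loci)
  el
}

fake_hit <- function(locus, role, scov = 1, id = 90) {
  data.frame(query_locus = locus, exemplar_id = paste0(role, "_1"),
             role_label = role, percent_identity = id, query_coverage = 1,
             subject_coverage = scov, score = 100, raw_score = 0,
             evalue_proxy = 1e-30, stringsAsFactors = FALSE)
}

test_that("classification rules follow the decision order", {
  rel <- data.frame(query_locus = "r1", family = "MOB_P", subtype = "P1",
                    score = 50, decision_basis = "panel_search",
                    stringsAsFactors = FALSE)
  ints <- data.frame(query_locus = "i1", int_class = "tyrosine",
                     int_family = "intS", score = 80, stringsAsFactors = FALSE)
  trb <- data.frame(cluster_id = "CC1", replicon_id = "chr",
                    cluster_type = "trb_T4SS", member_loci = "t1,t2",
                    roles = paste(trb_core_roles(), collapse = ","),
                    completeness = 1, start = 1, end = 10,
                    rdf_adjacent = FALSE, stringsAsFactors = FALSE)
  traacd <- trb
  traacd$cluster_type <- "traACD"
  traacd$member_loci <- "a1,c1"
  t4cp <- trb
  t4cp$cluster_type <- "T4CP_only"
  t4cp$member_loci <- "v1"
  t4cp$roles <- "virD4"
  hits <- fake_hit("x", "nodA")[0, ]

  # att + integrase + relaxase + trb T4SS -> ICE
  ice <- classify_element(make_el(c("r1", "i1", "t1", "t2")), trb, rel, ints,
                          hits)
  expect_identical(ice$mge_class, "ICE")
  expect_identical(ice$t4ss_type, "trb")
  expect_identical(ice$relaxase_family, "MOB_P")
  # att + integrase + traACD relaxase, no T4SS -> IME
  ime <- classify_element(make_el(c("r1", "i1", "a1", "c1")), traacd, rel,
                          ints, hits)
  expect_identical(ime$mge_class, "IME")
  # plasmid + relaxase + T4SS -> conjugative plasmid
  pc <- classify_element(make_el(c("r1", "t1", "t2"), att_status = "plasmid"),
                         trb, rel, ints, hits)
  expect_identical(pc$mge_class, "conjugative_plasmid")
  # plasmid + virD4 + relaxase, no T4SS -> mobilizable plasmid
  pm <- classify_element(make_el(c("r1", "v1"), att_status = "plasmid"),
                         t4cp, rel, ints, hits)
  expect_identical(pm$mge_class, "mobilizable_plasmid")
  # nothing -> unclassified
  un <- classify_element(make_el("z9"), trb[0, ], rel[0, ], ints[0, ], hits)
  expect_identical(un$mge_class, "unclassified")
})

test_that("the symbiosis flag needs nodABC+nodIJ plus nif and fix roles", {
  full <- do.call(rbind, lapply(
    c("nodA", "nodB", "nodC", "nodI", "nodJ", "nifH", "nifD", "nifK",
      "fixN", "fixO", "fixQ", "fixP"),
    function(r) fake_hit(paste0("L_", r), r)))
  el <- make_el(full$query_locus)
  expect_true(flag_symbiosis(el, full))
  expect_false(flag_symbiosis(make_el("L_nodC"), fake_hit("L_nodC", "nodC")))
  # an IME with traACD machinery and no symbiosis roles is not an ICESym
  ime_hits <- rbind(fake_hit("a1", "traA"), fake_hit("c1", "traC"))
  expect_false(flag_symbiosis(make_el(c("a1", "c1")), ime_hits))
})

test_that("QS profiling calls intact copies, frameshifts and remnants", {
  panel <- default_reference_panel()
  set.seed(51)
  b <- mobelem:::.new_builder()
  mobelem:::.b_spacer(b, 100L)
  mobelem:::.sim_remnant_gene(b, "g", "E", "traR1", panel)
  mobelem:::.b_spacer(b, 40L)
  for (role in c("traI1", "traI2", "traR2")) {
    mobelem:::.sim_gene(b, "g", "E", role, 0.02, panel)
    mobelem:::.b_spacer(b, 60L)
  }
  mobelem:::.sim_frameshift_gene(b, "g", "E", "qseC", 0.02, panel)
  mobelem:::.b_spacer(b, 200L)
  g <- genome_record("g", list(replicon("chr", mobelem:::.b_seq(b))),
                     mobelem:::.b_features(b, "chr"))
  hits <- search_panel(g, panel)
  el <- make_el(g$features$locus_id)
  el$fragments$end <- nchar(g$replicons$chr$sequence)
  qp <- profile_qs_locus(el, hits, g, panel)
  expect_equal(unname(qp$counts[c("traR1", "traR2", "traI1", "traI2")]),
               c(0L, 1L, 1L, 1L))
  expect_identical(qp$profile$status[qp$profile$role == "traR1"], "remnant")
  expect_identical(qp$profile$basis[qp$profile$role == "qseC"], "frameshift")
  expect_true(all(qp$profile$status[qp$profile$role %in%
                                      c("traI1", "traI2", "traR2")] == "intact"))
  expect_identical(qp$pseudogenes$basis, "frameshift")
})

test_that("planting a frameshift flips an intact copy to pseudogene", {
  panel <- default_reference_panel()
  set.seed(52)
  for (role in c("traI1", "qseM", "fseA")) {
    b <- mobelem:::.new_builder()
    mobelem:::.b_spacer(b, 50L)
    mobelem:::.sim_gene(b, "g", "E", role, 0.02, panel)
    mobelem:::.b_spacer(b, 50L)
    g1 <- genome_record("g", list(replicon("chr", mobelem:::.b_seq(b))),
                        mobelem:::.b_features(b, "chr"))
    b2 <- mobelem:::.new_builder()
    mobelem:::.b_spacer(b2, 50L)
    mobelem:::.sim_frameshift_gene(b2, "g", "E", role, 0.02, panel)
    mobelem:::.b_spacer(b2, 50L)
    g2 <- genome_record("g", list(replicon("chr", mobelem:::.b_seq(b2))),
                        mobelem:::.b_features(b2, "chr"))
    el1 <- make_el(g1$features$locus_id)
    el2 <- make_el(g2$features$locus_id)
    s1 <- profile_qs_locus(el1, search_panel(g1, panel), g1, panel)$profile$status
    s2 <- profile_qs_locus(el2, search_panel(g2, panel), g2, panel)$profile$status
    expect_identical(s1, "intact")
    expect_identical(s2, "pseudogene")
  }
})

test_that("redundancy groups by accessory content, ignoring IS clusters", {
  pa <- matrix(0L, nrow = 6, ncol = 4,
               dimnames = list(c("OG1", "OG2", "OG3", "OG4", "OG5", "IS1"),
                               c("e1", "e2", "e3", "e4")))
  pa[c("OG1", "OG2"), "e1"] <- 1L
  pa[c("OG1", "OG2"), "e2"] <- 1L      # identical to e1
  pa["IS1", "e2"] <- 1L                 # except IS content
  pa[c("OG1", "OG3"), "e3"] <- 1L      # one non-IS difference
  pa[c("OG1", "OG2"), "e4"] <- 2L      # SNP-only copy (same cluster set)
  groups <- collapse_redundant(pa, is_clusters = "IS1",
                               element_lengths = c(e1 = 100, e2 = 300,
                                                   e3 = 200, e4 = 50))
  expect_equal(nrow(groups), 2L)
  big <- groups[groups$n_members == 3, ]
  expect_identical(big$member_element_ids, "e1,e2,e4")
  expect_identical(big$representative_element_id, "e2")  # longest member
  # ordering-invariant
  g2 <- collapse_redundant(pa[, c(3, 1, 4, 2)], is_clusters = "IS1",
                           element_lengths = c(e1 = 100, e2 = 300, e3 = 200,
                                               e4 = 50))
  expect_equal(g2, groups)
})

test_that("motif models score training sequences above threshold and find plants", {
  set.seed(53)
  cons <- rand_dna(47)
  training <- vapply(1:6, function(i) mut_nt(cons, 0.06), "")
  m <- build_motif(training, "nodbox")
  for (s in training) {
    expect_gte(mobelem:::.motif_score(m, s), m$threshold)
  }
  text <- paste0(rand_dna(2500), cons, rand_dna(2500))
  h <- scan_motif(m, text)
  expect_true(any(h$start == 2500 & h$end == 2547 & h$strand == "+"))
  # reverse-strand plant
  text_r <- paste0(rand_dna(1000), rc(cons), rand_dna(1000))
  hr <- scan_motif(m, text_r)
  expect_true(any(hr$start == 1000 & hr$strand == "-"))
  expect_error(build_motif(c("ACGT", "ACG")), "unequal length")
})
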