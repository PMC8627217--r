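# panel search, relaxase typing, conjugation clusters, integrases

test_that("panel search reports exact copies at identity 100 and full coverage", {
  panel <- default_reference_panel()
  q <- setNames(panel$seq[panel$role == "trbB"], "q1")
  hits <- search_panel(q, panel, prefilter = "none")
  top <- hits[hits$exemplar_id == "trbB_1", ]
  expect_equal(top$percent_identity, 100)
  expect_equal(top$query_coverage, 1)
  expect_equal(top$subject_coverage, 1)
})

test_that("the pairwise-identity cutoff is a strict floor on reported identity", {
  set.seed(31)
  gene <- rand_dna(900)
  panel <- data.frame(exemplar_id = "trbB_nt", role = "trbB", seq = gene,
                      stringsAsFactors = FALSE)
  # the cutoff is a strict floor on the reported identity: a homolog just
  # below the threshold is dropped, just above it is kept
  hom <- mut_nt(gene, 0.45)
  all_hits <- search_panel(setNames(hom, "h"), panel, min_identity = 0,
                           min_coverage = 0, type = "nucleotide",
                           prefilter = "none")
  id <- all_hits$percent_identity[1]
  expect_equal(nrow(search_panel(setNames(hom, "h"), panel,
                                 min_identity = id + 0.01,
                                 min_coverage = 0, type = "nucleotide",
                                 prefilter = "none")), 0L)
  expect_gte(nrow(search_panel(setNames(hom, "h"), panel,
                               min_identity = id - 0.01,
                               min_coverage = 0, type = "nucleotide",
                               prefilter = "none")), 1L)
  # a 30%-diverged homolog clears the 50% rule
  hom60 <- mut_nt(gene, 0.30)
  expect_equal(nrow(search_panel(setNames(hom60, "h60"), panel,
                                 min_identity = 50, min_coverage = 0.5,
                                 type = "nucleotide", prefilter = "none")), 1L)
})

test_that("simulated homologs at a 70% identity target are reported within 3 points", {
  panel <- default_reference_panel()
  set.seed(33)
  for (role in c("rlxS", "nifD", "traG")) {
    ex <- panel$seq[panel$role == role]
    mutant <- mutate_protein(ex, 0.30)
    hits <- search_panel(setNames(mutant, "m"), panel, prefilter = "none")
    top <- hits[hits$role_label == role, ][1, ]
    expect_lt(abs(top$percent_identity - 70), 3)
    # oracle: realized identity by direct position comparison (no indels)
    realized <- 100 * mean(strsplit(mutant, "")[[1]] == strsplit(ex, "")[[1]])
    expect_lt(abs(top$percent_identity - realized), 3)
  }
})

test_that("local alignment scores equal a dynamic-programming oracle on short proteins", {
  set.seed(34)
  for (i in 1:12) {
    a <- sim_protein(sample(20:60, 1))
    b <- if (i %% 2) sim_protein(sample(20:60, 1)) else mutate_protein(a, 0.3)
    df <- mobelem:::align_local_set(c(q = a), b, "protein")
    expect_equal(df$raw_score, sw_score(a, b))
  }
})

test_that("identity is symmetric", {
  set.seed(35)
  for (i in 1:6) {
    a <- sim_protein(80)
    b <- mutate_protein(a, 0.2)
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("relaxase calls respect the bit threshold and best-e-value tie-break", {
  hits <- data.frame(
    query_locus = c("L1", "L2", "L3", "L3"),
    exemplar_id = c("rlxS_1", "MOB_Q_1", "MOB_P1_1", "MOB_Q_1"),
    role_label = c("rlxS", "MOB_Q", "MOB_P1", "MOB_Q"),
    percent_identity = 80, query_coverage = 1, subject_coverage = 1,
    score = c(50, 32, 60, 70), raw_score = 0,
    evalue_proxy = c(1e-20, 1e-5, 1e-40, 1e-35), stringsAsFactors = FALSE)
  calls <- classify_relaxases(hits, bit_threshold = 33)
  expect_equal(nrow(calls), 2L)  # L2 fails the threshold (32 < 33)
  l1 <- calls[calls$query_locus == "L1", ]
  expect_identical(l1$family, "MOB_P")
  expect_identical(l1$subtype, "P1")
  # ambiguous L3: best full-sequence e-value wins despite the lower score
  l3 <- calls[calls$query_locus == "L3", ]
  expect_identical(l3$family, "MOB_P")
  # output invariant to hit order; one family per locus
  calls2 <- classify_relaxases(hits[rev(seq_len(nrow(hits))), ],
                               bit_threshold = 33)
  expect_equal(calls2[order(calls2$query_locus), ],
               calls[order(calls$query_locus), ], ignore_attr = TRUE)
  expect_false(anyDuplicated(calls$query_locus) > 0)
})

test_that("relaxases can be classified from an hmmscan domain table", {
  dir <- withr::local_tempdir()
  tbl <- file.path(dir, "dom.tbl")
  writeLines(c(
    "# hmmscan domtblout",
    "MOB_P1 - 210 locA - 300 1e-45 58.2 - 1 1 0 0 0 0 0 0 - -",
    "MOB_Q  - 185 locA - 300 1e-30 41.0 - 1 1 0 0 0 0 0 0 - -",
    "MOB_F  - 190 locB - 250 1e-10 20.0 - 1 1 0 0 0 0 0 0 - -",
    "badrow only three"), tbl)
  expect_warning(calls <- classify_relaxases(hmm_table = tbl), "malformed")
  expect_equal(nrow(calls), 1L)   # locB fails -T 33
  expect_identical(calls$family, "MOB_P")
  expect_identical(calls$subtype, "P1")
  expect_identical(calls$decision_basis, "hmm_table")
})

test_that("conjugation clusters are typed from colocated roles", {
  panel <- default_reference_panel()
  set.seed(36)
  b <- mobelem:::.new_builder()
  # full trb operon
  for (role in trb_cluster_roles()) {
    mobelem:::.sim_gene(b, "g", "e", role, 0.03, panel)
    mobelem:::.b_spacer(b, 80L)
  }
  mobelem:::.b_spacer(b, 15000L)
  # divergent traA/traC with traD and adjacent RDF
  mobelem:::.sim_gene(b, "g", "e", "rdfS", 0.03, panel)
  mobelem:::.b_spacer(b, 80L)
  mobelem:::.sim_gene(b, "g", "e", "traA", 0.03, panel, strand = "+")
  mobelem:::.b_spacer(b, 90L)
  mobelem:::.sim_gene(b, "g", "e", "traC", 0.03, panel, strand = "-")
  mobelem:::.b_spacer(b, 80L)
  mobelem:::.sim_gene(b, "g", "e", "traD", 0.03, panel)
  mobelem:::.b_spacer(b, 15000L)
  # lone virD4
  mobelem:::.sim_gene(b, "g", "e", "virD4", 0.03, panel)
  mobelem:::.b_spacer(b, 500L)
  g <- genome_record("g", list(replicon("chr", mobelem:::.b_seq(b))),
                     mobelem:::.b_features(b, "chr"))
  hits <- search_panel(g, panel)
  cc <- detect_conjugation_clusters(g, hits)
  expect_equal(cc$cluster_type, c("trb_T4SS", "traACD", "T4CP_only"))
  expect_equal(cc$completeness[1], 1.0)
  expect_true(cc$rdf_adjacent[2])
  expect_equal(cc$completeness[2], 1.0)
})

test_that("integrases are classed tyrosine/serine with tripartite families", {
  panel <- default_reference_panel()
  set.seed(37)
  qs <- c(i1 = panel$seq[panel$role == "intS"],
          i2 = mutate_protein(panel$seq[panel$role == "intM"], 0.20),
          i3 = panel$seq[panel$role == "srtI"])
  hits <- search_panel(qs, panel, prefilter = "none")
  calls <- detect_integrases(hits)
  calls <- calls[order(calls$query_locus), ]
  expect_identical(calls$int_class, c("tyrosine", "tyrosine", "serine"))
  expect_identical(calls$int_family, c("intS", "intM", "other"))
})
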