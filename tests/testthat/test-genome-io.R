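# genome model, coordinate conventions, readers/writers, anchors

test_that("GFF3 coordinates convert to 0-based half-open and round-trip", {
  set.seed(11)
  prot <- sim_protein(40L)
  nt <- mobelem:::back_translate(prot)
  text <- paste0(rand_dna(100), nt, rand_dna(100))
  feats <- data.frame(
    locus_id = c("cds1", "trna1"), replicon_id = "chr",
    start = c(100L, 400L), end = c(100L + nchar(nt), 476L),
    strand = c("+", "-"), kind = c("CDS", "tRNA"),
    product = c("thing", "tRNA-Phe"), protein = c(prot, NA),
    trna_isotype = c(NA, "Phe"), stringsAsFactors = FALSE)
  g <- genome_record("gx", list(replicon("chr", paste0(text, rand_dna(200)))),
                     feats)
  dir <- withr::local_tempdir()
  paths <- write_genome(g, file.path(dir, "gx"))
  gff <- readLines(paths[["gff3"]])
  cds_row <- strsplit(grep("\tCDS\t", gff, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(cds_row[4]), 101L)  # 1-based inclusive start
  expect_equal(as.integer(cds_row[5]), 100L + nchar(nt))
  g2 <- read_genome(paths[["fna"]], paths[["gff3"]], paths[["faa"]],
                    genome_id = "gx")
  expect_identical(g2$replicons$chr$sequence, g$replicons$chr$sequence)
  f1 <- g$features[order(g$features$locus_id), ]
  f2 <- g2$features[order(g2$features$locus_id), ]
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f2[, c("locus_id", "start", "end", "strand", "kind")],
               f1[, c("locus_id", "start", "end", "strand", "kind")])
  expect_identical(f2$protein[f2$kind == "CDS"], prot)
  expect_identical(f2$trna_isotype[f2$kind == "tRNA"], "Phe")
})

test_that("simulated genomes survive a write/read round trip with truth features", {
  cfg <- list(seed = 21, core_families = 6, accessory_per_genome = 1,
              genomes = list(list(
                genome_id = "s1", chromosome_length = 6e4,
                elements = list(list(id = "IMEt", class = "IME", partite = 1L,
                                     anchor = "tRNA-Asn", circle_length = 8000L,
                                     core_len = 16L, divergence = 0.05,
                                     n_filler = 3L)))))
  sim <- simulate_mobilome(cfg)
  dir <- withr::local_tempdir()
  paths <- write_genome(sim$genomes$s1, file.path(dir, "s1"))
  g2 <- read_genome(paths[["fna"]], paths[["gff3"]], paths[["faa"]],
                    genome_id = "s1")
  f1 <- sim$genomes$s1$features
  f2 <- g2$features
  f1 <- f1[order(f1$locus_id), ]
  f2 <- f2[order(f2$locus_id), ]
  expect_equal(nrow(f1), nrow(f2))
  expect_equal(f2$start, f1$start)
  expect_equal(f2$end, f1$end)
  expect_identical(f2$protein[f2$kind == "CDS"], f1$protein[f1$kind == "CDS"])
  # write -> read -> write is byte-stable
  paths2 <- write_genome(g2, file.path(dir, "s1b"))
  expect_identical(readLines(paths2[["gff3"]]), readLines(paths[["gff3"]]))
})

test_that("the minimal GenBank reader loads CDS and tRNA features", {
  gb <- c(
    "LOCUS       chrZ                 400 bp    DNA     circular BCT",
    "FEATURES             Location/Qualifiers",
    "     source          1..400",
    "     tRNA            10..85",
    "                     /locus_tag=\"t1\"",
    "                     /product=\"tRNA-Phe\"",
    "     CDS             complement(101..160)",
    "                     /locus_tag=\"c1\"",
    "                     /product=\"widget\"",
    "                     /translation=\"MKLVNNAYIAKQRESTAD\"",
    "ORIGIN",
    "//")
  dir <- withr::local_tempdir()
  gbf <- file.path(dir, "g.gbk")
  writeLines(gb, gbf)
  fna <- file.path(dir, "g.fna")
  set.seed(3)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(chrZ = rand_dna(400))), fna)
  g <- read_genome(fna, gbf, genome_id = "gz")
  expect_equal(nrow(g$features), 2L)
  cds <- g$features[g$features$kind == "CDS", ]
  expect_equal(cds$start, 100L)   # 1-based inclusive -> 0-based
  expect_equal(cds$end, 160L)
  expect_identical(cds$strand, "-")
  expect_identical(cds$protein, "MKLVNNAYIAKQRESTAD")
  tr <- g$features[g$features$kind == "tRNA", ]
  expect_identical(tr$trna_isotype, "Phe")
})

test_that("anchor 3' ends are strand-aware and mirror under reflection", {
  set.seed(5)
  text <- rand_dna(1000)
  feats <- data.frame(
    locus_id = c("tp", "tm"), replicon_id = "chr",
    start = c(100L, 600L), end = c(176L, 676L), strand = c("+", "-"),
    kind = "tRNA", product = c("tRNA-Phe", "tRNA-Gly"), protein = NA,
    trna_isotype = c("Phe", "Gly"), stringsAsFactors = FALSE)
  g <- genome_record("ga", list(replicon("chr", text)), feats)
  a <- locate_anchors(g)
  expect_equal(a$pos3p[a$locus_id == "tp"], 176L)  # + strand: interval end
  expect_equal(a$pos3p[a$locus_id == "tm"], 600L)  # - strand: interval start
  # reflect: reverse-complement sequence, flip strands and coordinates
  L <- nchar(text)
  rfeats <- feats
  rfeats$start <- L - feats$end
  rfeats$end <- L - feats$start
  rfeats$strand <- ifelse(feats$strand == "+", "-", "+")
  gr <- genome_record("gar", list(replicon("chr", rc(text))), rfeats)
  ar <- locate_anchors(gr)
  for (lid in a$locus_id) {
    expect_equal(ar$pos3p[ar$locus_id == lid], L - a$pos3p[a$locus_id == lid])
  }
})

test_that("zero anchors yield an empty list and element writers handle edge cases", {
  set.seed(6)
  g <- genome_record("ge", list(replicon("chr", rand_dna(500))))
  expect_equal(nrow(locate_anchors(g)), 0L)
  dir <- withr::local_tempdir()
  paths <- write_element_outputs(list(), dir)
  expect_identical(readLines(paths[["gff3"]]), "##gff-version 3")
  # one monopartite element produces attL/attR and span rows
  cs <- rand_mono_case()
  gm <- mini_genome(cs$text)
  pair <- data.frame(replicon_id = "chr", attL_start = cs$attL_start,
                     attL_end = cs$attL_start + cs$core_len,
                     attR_start = cs$attR_start,
                     attR_end = cs$attR_start + cs$core_len,
                     core_seq = cs$core, core_len = cs$core_len,
                     anchor_id = "a", anchor_class = "tRNA-Phe", n_seeds = 1L,
                     span = cs$attR_start + cs$core_len - cs$attL_start,
                     stringsAsFactors = FALSE)
  el <- delineate_monopartite(pair, gm, element_id = "E1")
  paths <- write_element_outputs(list(el), dir, prefix = "one")
  gff <- readLines(paths[["gff3"]])
  expect_length(grep("\tattL\t", gff), 1L)
  expect_length(grep("\tattR\t", gff), 1L)
  expect_length(grep("mobile_genetic_element", gff), 1L)
  # duplicate ids are fatal
  expect_error(write_element_outputs(list(el, el), dir, prefix = "dup"),
               "duplicate")
})
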