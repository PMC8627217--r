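# synthetic-data generator: determinism, truth self-consistency, divergence

small_cfg <- function(seed = 5) {
  list(seed = seed, gc = 0.6, core_families = 8, accessory_per_genome = 2,
       core_divergence = 0.03,
       genomes = list(
         list(genome_id = "s1", chromosome_length = 1.2e5,
              bare_anchors = "tRNA-Pro",
              elements = list(
                list(id = "ICEs", class = "ICE", sym = TRUE, partite = 1L,
                     anchor = "tRNA-Phe", circle_length = 40000L,
                     core_len = 18L, divergence = 0.05,
                     qs = list(traR2 = "intact", traI1 = "intact",
                               qseM = "intact", qseC = "intact"),
                     n_filler = 6L)),
              plasmids = list(list(id = "pX", type = "mobilizable",
                                   length = 20000L, divergence = 0.06)))))
}

test_that("the generator is byte-deterministic under a fixed seed", {
  s1 <- simulate_mobilome(small_cfg(5))
  s2 <- simulate_mobilome(small_cfg(5))
  expect_identical(s1$genomes$s1$replicons$s1_chr$sequence,
                   s2$genomes$s1$replicons$s1_chr$sequence)
  expect_identical(s1$genomes$s1$features, s2$genomes$s1$features)
  s3 <- simulate_mobilome(small_cfg(6))
  expect_false(identical(s1$genomes$s1$replicons$s1_chr$sequence,
                         s3$genomes$s1$replicons$s1_chr$sequence))
})

test_that("recorded truth circles equal an independent splice of the chromosome", {
  sim <- simulate_mobilome(small_cfg(9))
  tr <- sim$truth$elements$ICEs
  text <- sim$genomes$s1$replicons$s1_chr$sequence
  mols <- oracle_splice(text, tr$cores$seq)
  circ <- mols[[which(vapply(mols, `[[`, TRUE, "circ"))]]$seq
  expect_true(same_circle(tr$circle, circ))
  expect_equal(nchar(tr$circle), 40000L)
  # planted core guard bytes: maximal extension stays at the planted repeat
  s <- tr$fragments$start[1]
  e <- tr$fragments$end[1]
  cl <- tr$fragments$core_len[1]
  expect_false(substr(text, s, s) == substr(text, e - cl, e - cl))
  expect_false(substr(text, s + cl + 1, s + cl + 1) ==
                 substr(text, e + 1, e + 1))
})

test_that("cargo genes realize their divergence target within 3 identity points", {
  sim <- simulate_mobilome(small_cfg(11))
  panel <- default_reference_panel()
  cargo <- sim$truth$cargo
  f <- sim$genomes$s1$features
  set.seed(1)
  pick <- cargo[sample(nrow(cargo), 8), ]
  for (i in seq_len(nrow(pick))) {
    prot <- f$protein[f$locus_id == pick$locus_id[i]]
    ex <- panel$seq[panel$role == pick$role[i]][1]
    # exhaustive per-position identity (no indels by construction)
    realized <- 100 * mean(strsplit(prot, "")[[1]] == strsplit(ex, "")[[1]])
    expect_lt(abs(realized - 100 * (1 - pick$divergence[i])), 3)
  }
})

test_that("recombination planting edits sequence and registry consistently", {
  cfg <- small_cfg(13)
  cfg$genomes[[1]]$elements[[1]]$n_filler <- 12L
  sim <- simulate_mobilome(cfg)
  before <- sim$genomes$s1$replicons$s1_chr$sequence
  # zero events: unchanged
  expect_identical(plant_recombination(sim, list())$genomes$s1$replicons$s1_chr$sequence,
                   before)
  cfg2 <- cfg
  cfg2$genomes <- c(cfg2$genomes, cfg2$genomes)
  cfg2$genomes[[2]]$genome_id <- "s2"
  cfg2$genomes[[2]]$elements[[1]]$id <- "ICEt"
  cfg2$recombination <- list(list(event_id = "rxA", from = "ICEs",
                                  to = "ICEt", length = 4000L))
  sim2 <- simulate_mobilome(cfg2)
  reg <- sim2$truth$recombination
  expect_equal(nrow(reg), 1L)
  a <- substr(sim2$genomes$s1$replicons$s1_chr$sequence,
              reg$from_global_start + 1, reg$from_global_start + reg$length)
  b <- substr(sim2$genomes$s2$replicons$s2_chr$sequence,
              reg$to_global_start + 1, reg$to_global_start + reg$length)
  expect_identical(a, b)
  # crossing the element boundary is an error
  cfg3 <- cfg2
  cfg3$recombination[[1]]$to_offset <- 39000L
  expect_error(simulate_mobilome(cfg3), "crosses element boundary")
})

test_that("invalid configurations are rejected", {
  cfg <- small_cfg()
  cfg$genomes[[1]]$elements[[1]]$circle_length <- 30L  # < 2 x core
  expect_error(validate_simulation_config(cfg))
  cfg2 <- small_cfg()
  cfg2$genomes[[1]]$elements[[1]]$divergence <- 0.9
  expect_error(validate_simulation_config(cfg2))
})

test_that("the benchmark scenario validates and plants the expected class tally", {
  cfg <- default_benchmark_scenario(seed = 3)
  expect_silent(validate_simulation_config(cfg))
  classes <- unlist(lapply(cfg$genomes, function(g) {
    vapply(g$elements, function(e) {
      if (e$class == "ICE" && (e$partite %||% 1L) == 3L) "tripartite"
      else e$class
    }, "")
  }))
  plasmids <- unlist(lapply(cfg$genomes, function(g) {
    vapply(g$plasmids %||% list(), `[[`, "", "type")
  }))
  expect_equal(sum(classes == "ICE"), 4L)
  expect_equal(sum(classes == "tripartite"), 1L)
  expect_equal(sum(classes == "IME"), 2L)
  expect_equal(sum(plasmids == "conjugative"), 1L)
  expect_equal(sum(plasmids == "mobilizable"), 1L)
  expect_length(cfg$recombination, 2L)
})
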