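# ortholog clustering, backbone, mobilome, trees, ANI, association

test_that("identical proteins form one cluster; divergence splits by threshold", {
  set.seed(61)
  base <- sim_protein(120)
  # identical pair -> same cluster at any threshold
  cs <- cluster_orthologs(c(a1 = base, a2 = base), 95, prefilter = "none")
  expect_equal(length(cs$clusters), 1L)
  # a ~30%-identity pair (test-local mutation, beyond the simulator's cap):
  # split at the 40% threshold, merged at 25%
  mut_aa <- function(p, d) {
    ch <- strsplit(p, "")[[1]]
    for (pos in sample(2:length(ch), round(d * (length(ch) - 1)))) {
      ch[pos] <- sample(setdiff(mobelem:::.AA20, ch[pos]), 1)
    }
    paste(ch, collapse = "")
  }
  pair <- c(x = base, y = mut_aa(base, 0.68))
  id <- pairwise_identity(pair[["x"]], pair[["y"]])
  expect_true(id > 25 && id < 40)
  cs40 <- cluster_orthologs(pair, 40, prefilter = "none")
  cs25 <- cluster_orthologs(pair, 25, prefilter = "none")
  expect_equal(length(cs40$clusters), 2L)
  expect_equal(length(cs25$clusters), 1L)
})

test_that("clustering matches an exhaustive oracle and ignores input order", {
  set.seed(62)
  fams <- replicate(8, sim_protein(60))
  prots <- character()
  for (f in seq_along(fams)) {
    for (k in 1:3) {
      prots[sprintf("f%d_m%d", f, k)] <- mutate_protein(fams[[f]], 0.10)
    }
  }
  cs <- cluster_orthologs(prots, 40, prefilter = "none")
  # oracle: DP-scored identities, union-find single linkage
  n <- length(prots)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nm <- names(prots)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      df <- mobelem:::align_local_set(prots[j], prots[[i]], "protein")
      if (df$percent_identity >= 40 &&
          min(df$query_coverage, df$subject_coverage) >= 0.5 &&
          df$evalue_proxy <= 1e-6) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  oracle_groups <- split(nm, vapply(seq_len(n), find, 0L))
  key <- function(groups) {
    sort(unname(vapply(groups, function(g) paste(sort(g), collapse = ","), "")))
  }
  expect_identical(key(cs$clusters), key(oracle_groups))
  cs_rev <- cluster_orthologs(prots[rev(seq_len(n))], 40, prefilter = "none")
  expect_identical(key(cs_rev$clusters), key(cs$clusters))
})

test_that("core-genome size is monotone non-increasing across thresholds", {
  set.seed(63)
  fams <- replicate(6, sim_protein(80))
  prots <- character(); unit <- character()
  for (g in 1:3) {
    for (f in seq_along(fams)) {
      id <- sprintf("g%d_f%d", g, f)
      prots[id] <- mutate_protein(fams[[f]], 0.05)  # low within-core divergence
      unit[id] <- paste0("g", g)
    }
    acc <- sprintf("g%d_acc", g)
    prots[acc] <- sim_protein(80)
    unit[acc] <- paste0("g", g)
  }
  sw <- sweep_core_size(prots, unit, thresholds = seq(20, 95, 5))
  expect_true(all(diff(sw$core_count) <= 0))
  # plateau at low thresholds: 5% divergence keeps all 6 core families
  expect_equal(sw$core_count[sw$threshold == 20], 6L)
  expect_equal(sw$core_count[sw$threshold == 60], 6L)
  # identical genomes: constant core across all thresholds
  p2 <- c(h1_a = fams[[1]], h2_a = fams[[1]])
  sw2 <- sweep_core_size(p2, c(h1_a = "h1", h2_a = "h2"))
  expect_true(all(sw2$core_count == 1L))
})

test_that("backbone prevalence is >= (19 of 20 passes at 0.95) and shrinks", {
  pa <- matrix(1L, nrow = 3, ncol = 20,
               dimnames = list(c("OG1", "OG2", "OG3"), paste0("e", 1:20)))
  pa["OG2", 1] <- 0L   # 19/20 = 0.95: still backbone
  pa["OG3", 1:2] <- 0L # 18/20: not backbone
  bb <- identify_backbone(pa, 0.95)
  expect_setequal(bb$backbone, c("OG1", "OG2"))
  bb99 <- identify_backbone(pa, 0.99)
  expect_true(all(bb99$backbone %in% bb$backbone))
  expect_setequal(bb99$backbone, "OG1")
})

test_that("mobilome accounting follows the any-member rule and shares sum to 1", {
  cs <- list(clusters = list(OG1 = c("l1", "l2"), OG2 = "l3", OG3 = "l4",
                             OG4 = "l5"),
             membership = setNames(rep(c("OG1", "OG2", "OG3", "OG4"),
                                       c(2, 1, 1, 1)),
                                   paste0("l", 1:5)))
  class(cs) <- "OrthologClusterSet"
  cat0 <- setNames(rep("chromosome", 5), paste0("l", 1:5))
  acc0 <- account_mobilome(cs, cat0)
  expect_equal(acc0$mge_fraction, 0)
  cat1 <- cat0
  cat1[c("l1", "l3", "l4")] <- c("ICESym", "IME", "plasmid")
  expect_message(acc1 <- account_mobilome(cs, cat1), "any-member")
  expect_equal(acc1$mge_fraction, 3 / 4)
  expect_equal(sum(acc1$category_shares), 1)
  expect_equal(acc1$icesym_share_of_ice, 1)
})

test_that("neighbor joining recovers additive 4- and 5-taxon trees exactly", {
  # presence/absence blocks make Manhattan distances additive on a known tree
  mk_pa <- function(blocks) {
    units <- names(blocks)
    cl <- unique(unlist(blocks))
    pa <- matrix(0L, length(cl), length(units), dimnames = list(cl, units))
    for (u in units) pa[blocks[[u]], u] <- 1L
    pa
  }
  I <- paste0("i", 1:4)
  pa4 <- mk_pa(list(A = c(paste0("a", 1:3), I), B = c(paste0("b", 1:5), I),
                    C = paste0("c", 1:2), D = paste0("d", 1:6)))
  tr4 <- gene_content_tree(pa4)
  expect_equal(as.numeric(phangorn::RF.dist(
    ape::unroot(tr4), ape::read.tree(text = "((A,B),(C,D));"))), 0)
  J <- paste0("j", 1:5)
  pa5 <- mk_pa(list(A = c(paste0("a", 1:3), I), B = c(paste0("b", 1:4), I),
                    C = paste0("c", 1:2),
                    D = c(paste0("d", 1:3), J), E = c(paste0("e", 1:6), J)))
  tr5 <- gene_content_tree(pa5)
  expect_equal(as.numeric(phangorn::RF.dist(
    ape::unroot(tr5), ape::read.tree(text = "((A,B),C,(D,E));"))), 0)
  # self-distance zero: identical columns sit on a zero-length split
  d <- stats::dist(t(pa4 > 0), method = "manhattan")
  expect_equal(as.matrix(d)["A", "A"], 0)
})

test_that("ANI is 100 for identical genomes and symmetric", {
  set.seed(65)
  a <- rand_dna(15000, gc = 0.6)
  r <- compute_ani(a, a)
  expect_equal(r$ani, 100)
  b <- mut_nt(a, 0.05)
  r1 <- compute_ani(a, b)
  expect_lt(abs(r1$mean_ab - r1$mean_ba), 0.5)
  expect_error(compute_ani(rand_dna(2000), rand_dna(2000)), "10 fragments")
})

test_that("genospecies partitioning uses >= 95 semantics (95.0 is same species)", {
  tab <- data.frame(genome_a = c("x", "x", "y"), genome_b = c("y", "z", "z"),
                    ani = c(95.0, 80, 80))
  part <- partition_genospecies(tab, 95)
  expect_equal(part[["x"]], part[["y"]])
  expect_false(part[["x"]] == part[["z"]])
})

test_that("Fisher association matches exact hypergeometric arithmetic", {
  # perfect separation 10 vs 10: p = 1/C(20,10)
  pa <- matrix(c(rep(1L, 10), rep(0L, 10)), nrow = 1,
               dimnames = list("OG1", paste0("u", 1:20)))
  traits <- setNames(c(rep(TRUE, 10), rep(FALSE, 10)), paste0("u", 1:20))
  # two-sided: both perfectly-separating tables are equally extreme
  res <- associate_trait(pa, traits)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p_value, enum_fisher_p(10, 0, 0, 10), tolerance = 1e-12)
  expect_true(res$significant)
  # a cluster present everywhere is never significant
  pa2 <- rbind(pa, OG2 = rep(1L, 20))
  res2 <- associate_trait(pa2, traits)
  expect_equal(res2$p_value[res2$cluster_id == "OG2"], 1)
  expect_false(res2$significant[res2$cluster_id == "OG2"])
  # bonferroni multiplies by the number of tested clusters
  expect_equal(res2$bonferroni_p[res2$cluster_id == "OG1"],
               min(1, 2 * 2 / choose(20, 10)))
  expect_error(associate_trait(pa, setNames(rep(TRUE, 20), colnames(pa))),
               "degenerate")
})

test_that("permuted trait labels give super-uniform p-values", {
  set.seed(66)
  pres <- c(rep(1L, 7), rep(0L, 9))
  pa <- matrix(pres, nrow = 1, dimnames = list("OG1", paste0("u", 1:16)))
  tr0 <- c(rep(TRUE, 8), rep(FALSE, 8))
  hits05 <- 0
  B <- 400
  for (b in 1:B) {
    traits <- setNames(sample(tr0), colnames(pa))
    p <- associate_trait(pa, traits)$p_value
    if (p <= 0.05) hits05 <- hits05 + 1
  }
  # P(p <= 0.05) <= 0.05 under the null, plus Monte Carlo slack
  expect_lt(hits05 / B, 0.05 + 2.5 * sqrt(0.05 * 0.95 / B))
})
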