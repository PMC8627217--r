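# Synthetic mobilome simulator: genomes with planted anchors, monopartite
# and tripartite ICEs, IMEs, plasmids, an assembly-artifact region,
# IS elements, QS duplications/pseudogenes, and inter-element recombination,
# with full ground truth. Integration is emplaced in the conservative
# att arrangement (literal attB -> attL/attR splicing), so delineation truth
# is exact by construction. Cargo genes are mutated copies of the bundled
# synthetic exemplar panel; substitutions are uniform over non-initial
# sites and indels are used only for pseudogenization, so identity targets
# stay analytic.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
           "T","V","W","Y")

.codon_table <- function() {
  if (is.null(.mobelem_cache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .mobelem_cache$codons <- split(names(gc), unname(gc))
  }
  .mobelem_cache$codons
}

#' Random protein sequence (starts with M)
#' @param len protein length in residues
#' @return amino-acid string
#' @export
sim_protein <- function(len) {
  paste0("M", paste(sample(.AA20, len - 1L, replace = TRUE), collapse = ""))
}

#' Mutate a protein to a target divergence
#'
#' Exactly `round(divergence * (L - 1))` non-initial positions are replaced
#' with a different residue, so realized identity is analytic:
#' 100 * (1 - divergence) up to rounding.
#'
#' @param protein amino-acid string
#' @param divergence fraction of substituted sites in [0, 0.6]
#' @return mutated protein
#' @export
mutate_protein <- function(protein, divergence) {
  stopifnot(divergence >= 0, divergence <= 0.6)
  L <- nchar(protein)
  k <- round(divergence * (L - 1L))
  if (k == 0L) return(protein)
  pos <- sample(2:L, k)
  chars <- strsplit(protein, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Back-translate a protein with random synonymous codons plus a TAA stop
#' @keywords internal
back_translate <- function(protein) {
  tab <- .codon_table()
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- tab[[a]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, "")
  paste0(paste(codons, collapse = ""), "TAA")
}

.random_dna <- function(len, gc = 0.62, first = NULL, last = NULL) {
  if (len <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sample(names(p), len, replace = TRUE, prob = p)
  if (!is.null(first)) s[1] <- first
  if (!is.null(last) && len >= 2L) s[len] <- last
  paste(s, collapse = "")
}

# sequence+feature accumulator -------------------------------------------

.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$pieces <- list()
  env$len <- 0L
  env$features <- list()
  env
}

.b_add_seq <- function(b, seq) {
  start <- b$len
  if (nchar(seq)) {
    b$pieces[[length(b$pieces) + 1L]] <- seq
    b$len <- b$len + nchar(seq)
  }
  start
}

.b_add_feature <- function(b, locus_id, start, end, strand, kind, product,
                           protein, isotype) {
  b$features[[length(b$features) + 1L]] <- data.frame(
    locus_id = locus_id, replicon_id = NA_character_, start = start, end = end,
    strand = strand, kind = kind, product = product, protein = protein,
    trna_isotype = isotype, stringsAsFactors = FALSE)
}

.b_add_gene <- function(b, locus_id, protein, product = "hypothetical protein",
                        strand = "+", nt = NULL) {
  if (is.null(nt)) nt <- back_translate(protein)
  emplaced <- if (strand == "+") nt else .revcomp(nt)
  start <- .b_add_seq(b, emplaced)
  .b_add_feature(b, locus_id, start, start + nchar(nt), strand, "CDS",
                 product, protein, NA_character_)
  invisible(start)
}

.b_add_trna <- function(b, locus_id, isotype) {
  seq <- .random_dna(76L, last = "A")
  start <- .b_add_seq(b, seq)
  .b_add_feature(b, locus_id, start, start + 76L, "+", "tRNA",
                 paste0("tRNA-", isotype), NA_character_, isotype)
  invisible(start)
}

.b_spacer <- function(b, len, gc = 0.62, first = NULL, last = NULL) {
  .b_add_seq(b, .random_dna(len, gc, first, last))
}

.b_merge <- function(b, sub) {
  offset <- .b_add_seq(b, paste(unlist(sub$pieces), collapse = ""))
  for (f in sub$features) {
    f$start <- f$start + offset
    f$end <- f$end + offset
    b$features[[length(b$features) + 1L]] <- f
  }
  offset
}

.b_features <- function(b, replicon_id) {
  if (!length(b$features)) return(empty_features())
  f <- do.call(rbind, b$features)
  f$replicon_id <- replicon_id
  f
}

.b_seq <- function(b) paste(unlist(b$pieces), collapse = "")

# element payloads --------------------------------------------------------

# a gene copy of a panel exemplar at the element's divergence
.sim_gene <- function(b, genome_id, el_id, role, divergence, panel,
                      strand = "+", suffix = "", product = role,
                      register = NULL) {
  locus <- sprintf("%s_%s_%s%s", genome_id, el_id, role, suffix)
  prot <- mutate_protein(panel[panel$role == role, "seq"][1], divergence)
  .b_add_gene(b, locus, prot, product = product, strand = strand)
  if (!is.null(register)) {
    register$cargo[[length(register$cargo) + 1L]] <- data.frame(
      locus_id = locus, role = role, divergence = divergence,
      stringsAsFactors = FALSE)
  }
  locus
}

.sim_frameshift_gene <- function(b, genome_id, el_id, role, divergence, panel,
                                 suffix = "") {
  locus <- sprintf("%s_%s_%s%s", genome_id, el_id, role, suffix)
  prot <- mutate_protein(panel[panel$role == role, "seq"][1], divergence)
  nt <- back_translate(prot)
  del <- round(2 * nchar(nt) / 3)
  nt <- paste0(substr(nt, 1, del - 1L), substr(nt, del + 1L, nchar(nt)))
  aa_len <- 3L * (nchar(nt) %/% 3L)
  prot_fs <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, aa_len)), no.init.codon = TRUE))
  .b_add_gene(b, locus, prot_fs, product = role, nt = nt)
  locus
}

.sim_remnant_gene <- function(b, genome_id, el_id, role, panel, tail_aa = 33L) {
  locus <- sprintf("%s_%s_%s_remnant", genome_id, el_id, role)
  full <- panel[panel$role == role, "seq"][1]
  prot <- substr(full, nchar(full) - tail_aa + 1L, nchar(full))
  .b_add_gene(b, locus, prot, product = "hypothetical protein")
  locus
}

.default_qs <- function() {
  list(traR1 = "remnant", traR2 = "intact", traI1 = "intact",
       traI2 = "intact", qseM = "intact", qseC = "intact", fseA = "intact")
}

# machinery + cargo payload of an ICE or IME; returns its builder and
# bookkeeping (QS truth, filler gene offsets, backbone intervals)
.build_payload <- function(genome_id, spec, panel, reg) {
  b <- .new_builder()
  div <- spec$divergence
  gid <- genome_id
  eid <- spec$id
  sp <- function(len = 120L, ...) .b_spacer(b, len, ...)
  backbone0 <- b$len
  sp(150L, first = "A")              # guard: payload starts with 'A'
  if (spec$class == "ICE") {
    .sim_gene(b, gid, eid, spec$integrase %||% "intS", div, panel, register = reg)
    sp()
    for (role in c("rdfS", "rlxS", "msi107")) {
      .sim_gene(b, gid, eid, role, div, panel, register = reg); sp()
    }
    if (!spec$sym) {
      .sim_gene(b, gid, eid, "Rep_3", div, panel, register = reg); sp()
      .sim_gene(b, gid, eid, "DUF2840", div, panel, register = reg); sp()
    }
    for (role in c("traF", "traG")) {
      .sim_gene(b, gid, eid, role, div, panel, register = reg); sp()
    }
    for (role in trb_cluster_roles()) {
      .sim_gene(b, gid, eid, role, div, panel, register = reg); sp(60L)
    }
    if (!spec$sym) { .sim_gene(b, gid, eid, "trbK", div, panel, register = reg); sp() }
    .sim_gene(b, gid, eid, "msi110", div, panel, register = reg); sp()
  } else { # IME
    int_role <- if (isTRUE(spec$serine_integrase)) "srtI" else "intP"
    .sim_gene(b, gid, eid, int_role, div, panel, register = reg)
    sp()
    .sim_gene(b, gid, eid, "rdfS", div, panel, register = reg)
    sp(80L)
    .sim_gene(b, gid, eid, "traA", div, panel, strand = "+", register = reg)
    sp(90L)  # oriT-like gap between divergent traA/traC
    .sim_gene(b, gid, eid, "traC", div, panel, strand = "-", register = reg)
    sp(60L)
    .sim_gene(b, gid, eid, "traD", div, panel, register = reg)
    sp()
  }
  machinery_end <- b$len
  # quorum-sensing locus
  qs <- spec$qs %||% list()
  qs_truth <- list()
  if (length(qs)) {
    for (role in names(qs)) {
      st <- qs[[role]]
      if (identical(st, "absent")) next
      if (identical(st, "remnant")) {
        .sim_remnant_gene(b, gid, eid, role, panel)
        qs_truth[[length(qs_truth) + 1L]] <-
          data.frame(role = role, status = "remnant")
        sp(40L)
      } else if (identical(st, "frameshift")) {
        .sim_frameshift_gene(b, gid, eid, role, div, panel)
        qs_truth[[length(qs_truth) + 1L]] <-
          data.frame(role = role, status = "pseudogene")
        sp()
      } else {
        .sim_gene(b, gid, eid, role, div, panel, register = reg)
        qs_truth[[length(qs_truth) + 1L]] <-
          data.frame(role = role, status = "intact")
        sp()
      }
    }
  }
  reg$qs[[eid]] <- if (length(qs_truth)) do.call(rbind, qs_truth) else NULL
  # symbiosis cargo, preceded by a nod box upstream of nodA
  if (isTRUE(spec$sym)) {
    if (!is.null(reg$nodbox)) {
      pos <- .b_add_seq(b, reg$nodbox$instance)
      reg$nodbox_sites[[length(reg$nodbox_sites) + 1L]] <- data.frame(
        element_id = eid, payload_offset = pos,
        stringsAsFactors = FALSE)
      .b_spacer(b, 40L)
    }
    for (role in c("nodD2", "nodA", "nodB", "nodC", "nodI", "nodJ",
                   "nifH", "nifD", "nifK", "nifA", "fixN", "fixO", "fixQ",
                   "fixP", "dctA", "nopP")) {
      .sim_gene(b, gid, eid, role, div, panel, register = reg); sp(80L)
    }
  }
  # IS copies
  for (k in seq_len(spec$is_copies %||% 1L)) {
    .sim_gene(b, gid, eid, "tnpA1", 0.01, panel, suffix = paste0("_", k),
              product = "IS transposase", register = reg)
    sp(70L)
  }
  # private filler cargo
  filler0 <- b$len
  for (k in seq_len(spec$n_filler %||% 8L)) {
    locus <- sprintf("%s_%s_cargo%02d", gid, eid, k)
    .b_add_gene(b, locus, sim_protein(180L))
    sp()
  }
  list(builder = b, filler_iv = c(filler0, b$len),
       backbone_iv = c(backbone0, machinery_end))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# core guard bytes: cores are planted so that the bases flanking the two
# copies differ, keeping maximal repeat extension exactly at the planted core
.sim_core <- function(len) .random_dna(len, gc = 0.5)

# emplace a monopartite element: anchor, attL core, payload, attR core
.emplace_monopartite <- function(chr, genome_id, spec, panel, reg) {
  eid <- spec$id
  anchor_pos <- .plant_anchor(chr, genome_id, spec$anchor, reg)
  core <- .sim_core(spec$core_len)
  attL <- .b_add_seq(chr, core)
  pay <- .build_payload(genome_id, spec, panel, reg)
  pad <- spec$circle_length - spec$core_len - pay$builder$len
  if (pad < 50L) stop("element ", eid, ": payload exceeds target length")
  .b_spacer(pay$builder, pad, last = "C")   # guard before attR
  frag_start <- attL
  off <- .b_merge(chr, pay$builder)
  reg$filler_iv[[eid]] <- off + pay$filler_iv      # global coordinates
  reg$backbone_iv[[eid]] <- off + pay$backbone_iv
  attR <- .b_add_seq(chr, core)
  frag_end <- attR + spec$core_len
  reg$elements[[eid]] <- list(
    element_id = eid, genome_id = genome_id, class = spec$class,
    sym = isTRUE(spec$sym), partite = 1L,
    fragments = data.frame(start = frag_start, end = frag_end, role = "mono",
                           left_family = "S", right_family = "S",
                           core_len = spec$core_len, stringsAsFactors = FALSE),
    cores = data.frame(family = "S", seq = core, len = spec$core_len,
                       stringsAsFactors = FALSE),
    integration_anchor = spec$anchor, anchor_pos3p = anchor_pos)
  invisible(NULL)
}

# emplace a tripartite element in the conservative interleaved arrangement:
# [anchS][S][A ... anchM][M][gap1 ... anchG][G][C][S][gap2][M][B][G]
.emplace_tripartite <- function(chr, genome_id, spec, panel, reg) {
  eid <- spec$id
  stopifnot(length(spec$fragment_lengths) == 3L, length(spec$anchor) == 3L)
  cl <- spec$core_len
  cores <- list(S = .sim_core(cl), M = .sim_core(cl), G = .sim_core(cl))
  fl <- spec$fragment_lengths

  a_pos <- .plant_anchor(chr, genome_id, spec$anchor[1], reg)
  s1 <- .b_add_seq(chr, cores$S)
  # alpha payload: machinery + cargo, ending with the tRNA anchor for M
  specA <- spec
  specA$integrase <- "intS"
  payA <- .build_payload(genome_id, specA, panel, reg)
  .sim_gene(payA$builder, genome_id, eid, "intM", spec$divergence, panel,
            register = reg)
  padA <- fl[1] - 2L * cl - payA$builder$len - 76L
  if (padA < 50L) stop("tripartite alpha fragment too short")
  .b_spacer(payA$builder, padA)
  m_locus <- sprintf("%s_%s_anchM", genome_id, eid)
  offA <- .b_merge(chr, payA$builder)
  reg$filler_iv[[eid]] <- offA + payA$filler_iv
  reg$backbone_iv[[eid]] <- offA + payA$backbone_iv
  m_anchor_pos <- .b_add_trna(chr, m_locus, .trna_isotype(spec$anchor[2])) + 76L
  reg$anchors[[length(reg$anchors) + 1L]] <- data.frame(
    anchor_class = spec$anchor[2], pos3p = m_anchor_pos, strand = "+",
    stringsAsFactors = FALSE)
  m1 <- .b_add_seq(chr, cores$M)

  # gap1 (chromosomal), ending with the G anchor
  .b_spacer(chr, spec$gap_lengths[1] - 76L, first = "G")
  g_locus <- sprintf("%s_%s_anchG", genome_id, eid)
  g_anchor_pos <- .b_add_trna(chr, g_locus, .trna_isotype(spec$anchor[3])) + 76L
  reg$anchors[[length(reg$anchors) + 1L]] <- data.frame(
    anchor_class = spec$anchor[3], pos3p = g_anchor_pos, strand = "+",
    stringsAsFactors = FALSE)
  g1 <- .b_add_seq(chr, cores$G)

  # gamma fragment content: intG plus small cargo
  bC <- .new_builder()
  .b_spacer(bC, 120L, first = "A")
  .sim_gene(bC, genome_id, eid, "intG", spec$divergence, panel, register = reg)
  .b_spacer(bC, 100L)
  locus <- sprintf("%s_%s_cargoC1", genome_id, eid)
  .b_add_gene(bC, locus, sim_protein(160L))
  padC <- fl[3] - 2L * cl - bC$len
  if (padC < 50L) stop("tripartite gamma fragment too short")
  .b_spacer(bC, padC, last = "C")
  .b_merge(chr, bC)
  s2 <- .b_add_seq(chr, cores$S)

  .b_spacer(chr, spec$gap_lengths[2], first = "G", last = "C")
  m2 <- .b_add_seq(chr, cores$M)

  # beta fragment content: cargo + IS
  bB <- .new_builder()
  .b_spacer(bB, 120L, first = "A")
  for (k in seq_len(4L)) {
    locus <- sprintf("%s_%s_cargoB%d", genome_id, eid, k)
    .b_add_gene(bB, locus, sim_protein(180L))
    .b_spacer(bB, 120L)
  }
  .sim_gene(bB, genome_id, eid, "tnpA2", 0.01, panel,
            product = "IS transposase", register = reg)
  padB <- fl[2] - 2L * cl - bB$len
  if (padB < 50L) stop("tripartite beta fragment too short")
  .b_spacer(bB, padB, last = "C")
  .b_merge(chr, bB)
  g2 <- .b_add_seq(chr, cores$G)

  fr <- data.frame(
    start = c(s1, g1, m2),
    end = c(m1 + cl, s2 + cl, g2 + cl),
    role = c("alpha", "gamma", "beta"),
    left_family = c("S", "G", "M"), right_family = c("M", "S", "G"),
    core_len = cl, stringsAsFactors = FALSE)
  reg$elements[[eid]] <- list(
    element_id = eid, genome_id = genome_id, class = spec$class,
    sym = isTRUE(spec$sym), partite = 3L, fragments = fr,
    cores = data.frame(family = c("S", "M", "G"),
                       seq = unlist(cores, use.names = FALSE), len = cl,
                       stringsAsFactors = FALSE),
    integration_anchor = spec$anchor[1], anchor_pos3p = a_pos)
  invisible(NULL)
}

.trna_isotype <- function(anchor_class) sub("^tRNA-", "", anchor_class)

.plant_anchor <- function(chr, genome_id, anchor_class, reg) {
  pos3p <- if (grepl("^tRNA-", anchor_class)) {
    locus <- sprintf("%s_anch_%s_%d", genome_id, .trna_isotype(anchor_class),
                     length(reg$anchors) + 1L)
    .b_add_trna(chr, locus, .trna_isotype(anchor_class)) + 76L
  } else {
    locus <- sprintf("%s_anch_%s", genome_id, anchor_class)
    prot <- mutate_protein(
      default_reference_panel()[default_reference_panel()$role == anchor_class,
                                "seq"][1], 0.05)
    start <- .b_add_gene(chr, locus, prot, product = anchor_class)
    start + nchar(back_translate(prot)) # end not directly returned; recompute
  }
  # for CDS anchors the 3' end is the feature end (last added feature)
  last <- chr$features[[length(chr$features)]]
  pos3p <- last$end
  reg$anchors[[length(reg$anchors) + 1L]] <- data.frame(
    anchor_class = anchor_class, pos3p = pos3p, strand = "+",
    stringsAsFactors = FALSE)
  pos3p
}

.emplace_artifact <- function(chr, genome_id, spec, panel, reg) {
  eid <- spec$id
  b <- .new_builder()
  .b_spacer(b, 200L)
  for (role in c("repA", "repB", "repC")) {
    .sim_gene(b, genome_id, eid, role, 0.05, panel); .b_spacer(b, 120L)
  }
  .sim_gene(b, genome_id, eid, "rlxS", 0.05, panel); .b_spacer(b, 120L)
  for (role in c("trbB", "trbC", "trbD")) {
    .sim_gene(b, genome_id, eid, role, 0.05, panel); .b_spacer(b, 120L)
  }
  start <- .b_merge(chr, b)
  reg$elements[[eid]] <- list(
    element_id = eid, genome_id = genome_id, class = "artifact", sym = FALSE,
    partite = 1L,
    fragments = data.frame(start = start, end = chr$len, role = "mono",
                           left_family = NA, right_family = NA,
                           core_len = NA, stringsAsFactors = FALSE),
    cores = NULL, integration_anchor = NA, anchor_pos3p = NA)
  invisible(NULL)
}

.build_plasmid <- function(genome_id, spec, panel, reg) {
  b <- .new_builder()
  eid <- spec$id
  .b_spacer(b, 300L)
  for (role in c("repA", "repB", "repC")) {
    .sim_gene(b, genome_id, eid, role, spec$divergence, panel, register = reg)
    .b_spacer(b, 120L)
  }
  if (spec$type == "conjugative") {
    .sim_gene(b, genome_id, eid, "rlxS", spec$divergence, panel, register = reg)
    .b_spacer(b, 120L)
    .sim_gene(b, genome_id, eid, "traG", spec$divergence, panel, register = reg)
    .b_spacer(b, 120L)
    for (role in c("traF", "msi107", "msi110")) {
      .sim_gene(b, genome_id, eid, role, spec$divergence, panel, register = reg)
      .b_spacer(b, 120L)
    }
    for (role in trb_cluster_roles()) {
      .sim_gene(b, genome_id, eid, role, spec$divergence, panel, register = reg)
      .b_spacer(b, 60L)
    }
    .sim_gene(b, genome_id, eid, "rdfS", spec$divergence, panel, register = reg)
    .b_spacer(b, 120L)
  } else {
    .sim_gene(b, genome_id, eid, "MOB_Q", spec$divergence, panel,
              product = "relaxase", register = reg)
    .b_spacer(b, 120L)
    .sim_gene(b, genome_id, eid, "virD4", spec$divergence, panel, register = reg)
    .b_spacer(b, 120L)
  }
  for (k in seq_len(spec$n_filler %||% 6L)) {
    locus <- sprintf("%s_%s_cargo%02d", genome_id, eid, k)
    .b_add_gene(b, locus, sim_protein(170L))
    .b_spacer(b, 120L)
  }
  pad <- spec$length - b$len
  if (pad < 50L) stop("plasmid ", eid, " payload exceeds target length")
  .b_spacer(b, pad)
  reg$elements[[eid]] <- list(
    element_id = eid, genome_id = genome_id,
    class = paste0(spec$type, "_plasmid"), sym = FALSE, partite = 1L,
    fragments = data.frame(start = 0L, end = spec$length, role = "mono",
                           left_family = NA, right_family = NA, core_len = NA,
                           stringsAsFactors = FALSE),
    cores = NULL, integration_anchor = NA, anchor_pos3p = NA)
  b
}

#' Validate a simulation configuration
#'
#' @param config a `SimulationConfig` list
#' @return the config, invisibly; errors on violated invariants
#' @export
validate_simulation_config <- function(config) {
  stopifnot(is.numeric(config$seed), length(config$genomes) >= 1L)
  for (g in config$genomes) {
    stopifnot(!is.null(g$genome_id), g$chromosome_length > 1e4)
    for (el in g$elements %||% list()) {
      stopifnot(el$divergence >= 0, el$divergence <= 0.6)
      if ((el$partite %||% 1L) == 1L) {
        stopifnot(el$circle_length > 2 * el$core_len)
      } else {
        stopifnot(all(el$fragment_lengths > 2 * el$core_len))
      }
    }
  }
  invisible(config)
}

#' The default benchmark scenario
#'
#' Five ~2 Mb genomes carrying 4 monopartite ICEs (two of them symbiosis
#' ICEs, one with the 65,889 bp circular length at the small end of the
#' observed ICE size range), 1 tripartite symbiosis ICE, 2 IMEs, 1
#' conjugative and 1 mobilizable plasmid, 1 repABC-without-att artifact
#' region, 16 integration-anchor classes, QS duplications with one
#' frameshift pseudogene and one traR1 remnant, and 2 recombination events.
#'
#' @param seed RNG seed
#' @return a `SimulationConfig`
#' @export
default_benchmark_scenario <- function(seed = 101) {
  qs_lotus <- list(traR1 = "remnant", traR2 = "intact", traI1 = "intact",
                   traI2 = "intact", qseM = "intact", qseC = "intact",
                   fseA = "intact")
  qs_fs <- utils::modifyList(qs_lotus, list(traI2 = "frameshift"))
  qs_plain <- list(traR2 = "intact", traI1 = "intact", qseM = "intact",
                   qseC = "intact", fseA = "intact")
  list(
    seed = seed,
    gc = 0.62,
    core_families = 55,
    accessory_per_genome = 6,
    core_divergence = 0.03,
    genomes = list(
      list(genome_id = "g1", chromosome_length = 2.0e6,
           bare_anchors = c("tRNA-Pro", "tRNA-Leu"),
           elements = list(
             list(id = "ICEa", class = "ICE", sym = TRUE, partite = 1L,
                  anchor = "tRNA-Phe", circle_length = 65889L, core_len = 18L,
                  divergence = 0.04, qs = qs_lotus, n_filler = 14L))),
      list(genome_id = "g2", chromosome_length = 2.0e6,
           bare_anchors = c("tRNA-Val"),
           elements = list(
             list(id = "ICEb", class = "ICE", sym = TRUE, partite = 1L,
                  anchor = "tRNA-Ser", circle_length = 38000L, core_len = 20L,
                  divergence = 0.06, qs = qs_fs, n_filler = 12L),
             list(id = "IMEa", class = "IME", partite = 1L,
                  anchor = "tRNA-Asn", circle_length = 12000L, core_len = 17L,
                  divergence = 0.05, n_filler = 6L))),
      list(genome_id = "g3", chromosome_length = 2.1e6,
           bare_anchors = c("tRNA-Ala"),
           elements = list(
             list(id = "ICEc", class = "ICE", sym = TRUE, partite = 3L,
                  anchor = c("tRNA-Met", "tRNA-Gly", "tRNA-His"),
                  fragment_lengths = c(36000L, 9000L, 5000L),
                  gap_lengths = c(6000L, 5000L), core_len = 19L,
                  divergence = 0.05, qs = qs_lotus, n_filler = 5L)),
           artifact_regions = list(list(id = "ARTa"))),
      list(genome_id = "g4", chromosome_length = 2.0e6,
           bare_anchors = c("tRNA-Thr"),
           elements = list(
             list(id = "ICEd", class = "ICE", sym = FALSE, partite = 1L,
                  anchor = "guaA", circle_length = 30000L, core_len = 21L,
                  divergence = 0.08, qs = qs_plain, n_filler = 12L)),
           plasmids = list(
             list(id = "pCONJ", type = "conjugative", length = 45000L,
                  divergence = 0.07))),
      list(genome_id = "g5", chromosome_length = 2.0e6,
           bare_anchors = c("tRNA-Trp"),
           elements = list(
             list(id = "ICEe", class = "ICE", sym = FALSE, partite = 1L,
                  anchor = "radC", circle_length = 27000L, core_len = 18L,
                  divergence = 0.08, qs = qs_plain, n_filler = 12L),
             list(id = "IMEb", class = "IME", partite = 1L, anchor = "dusA",
                  circle_length = 9000L, core_len = 16L, divergence = 0.05,
                  serine_integrase = TRUE, n_filler = 4L)),
           plasmids = list(
             list(id = "pMOB", type = "mobilizable", length = 22000L,
                  divergence = 0.07)))
    ),
    recombination = list(
      list(event_id = "rx1", from = "ICEa", to = "ICEb", length = 5000L),
      list(event_id = "rx2", from = "ICEd", to = "ICEe", length = 5000L)
    )
  )
}

#' Simulate genomes with planted mobile elements and full ground truth
#'
#' @param config a `SimulationConfig` (see [default_benchmark_scenario()])
#' @param out_dir optional directory; when given, per-genome FASTA/GFF3/
#'   protein FASTA and a truth JSON are written
#' @return a `MobilomeSimulation`: list(genomes, truth, files)
#' @export
simulate_mobilome <- function(config, out_dir = NULL) {
  validate_simulation_config(config)
  panel <- default_reference_panel()
  .with_seed(config$seed, {
    reg <- new.env(parent = emptyenv())
    reg$elements <- list()
    reg$anchors_all <- list()
    reg$qs <- list()
    reg$cargo <- list()
    reg$filler_iv <- list()
    reg$backbone_iv <- list()
    reg$nodbox_sites <- list()
    # nod-box motif: consensus plus a small training set around it
    cons <- .random_dna(47L, gc = 0.5)
    training <- vapply(seq_len(6L), function(i) {
      ch <- strsplit(cons, "")[[1]]
      pos <- sample(47L, 3L)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      paste(ch, collapse = "")
    }, "")
    reg$nodbox <- list(instance = cons, training = training)

    core_prots <- replicate(config$core_families %||% 55L,
                            sim_protein(sample(150:220, 1L)))
    genomes <- list()
    for (g in config$genomes) {
      reg$anchors <- list()
      chr <- .new_builder()
      gid <- g$genome_id
      # plan: background genes with elements/anchors interleaved
      items <- list()
      for (i in seq_along(core_prots)) {
        items[[length(items) + 1L]] <- list(kind = "core", idx = i)
      }
      for (i in seq_len(config$accessory_per_genome %||% 6L)) {
        items[[length(items) + 1L]] <- list(kind = "acc", idx = i)
      }
      specials <- c(
        lapply(g$elements %||% list(), function(e) list(kind = "element", spec = e)),
        lapply(g$bare_anchors %||% character(), function(a) list(kind = "anchor", class = a)),
        lapply(g$artifact_regions %||% list(), function(a) list(kind = "artifact", spec = a))
      )
      # place specials at spread-out positions among background genes
      n_bg <- length(items)
      at <- round(seq(0.15, 0.85, length.out = max(1L, length(specials))) * n_bg)
      plan <- list()
      si <- 1L
      for (i in seq_len(n_bg)) {
        plan[[length(plan) + 1L]] <- items[[i]]
        while (si <= length(specials) && i == at[si]) {
          plan[[length(plan) + 1L]] <- specials[[si]]
          si <- si + 1L
        }
      }
      while (si <= length(specials)) {
        plan[[length(plan) + 1L]] <- specials[[si]]; si <- si + 1L
      }
      # estimated payload length to size inter-item spacers
      est_special <- sum(vapply(g$elements %||% list(), function(e) {
        if ((e$partite %||% 1L) == 1L) e$circle_length + e$core_len + 400
        else sum(e$fragment_lengths) + sum(e$gap_lengths) + 3 * e$core_len + 400
      }, 0)) + length(g$artifact_regions %||% list()) * 6000 +
        length(g$bare_anchors %||% character()) * 100
      est_bg <- n_bg * 700
      spacer_len <- max(600L, floor(
        (g$chromosome_length - est_special - est_bg) / (length(plan) + 1L)))
      for (item in plan) {
        # spacers start with 'G': the byte after any element's attR core then
        # always differs from the 'A' guard after its attL core
        .b_spacer(chr, spacer_len + sample(-200:200, 1L),
                  gc = config$gc %||% 0.62, first = "G")
        if (item$kind == "core") {
          prot <- mutate_protein(core_prots[[item$idx]],
                                 config$core_divergence %||% 0.03)
          .b_add_gene(chr, sprintf("%s_core%03d", gid, item$idx), prot)
        } else if (item$kind == "acc") {
          .b_add_gene(chr, sprintf("%s_acc%02d", gid, item$idx),
                      sim_protein(170L))
        } else if (item$kind == "anchor") {
          .plant_anchor(chr, gid, item$class, reg)
        } else if (item$kind == "artifact") {
          .emplace_artifact(chr, gid, item$spec, panel, reg)
        } else if (item$kind == "element") {
          spec <- item$spec
          if ((spec$partite %||% 1L) == 1L) {
            .emplace_monopartite(chr, gid, spec, panel, reg)
          } else {
            .emplace_tripartite(chr, gid, spec, panel, reg)
          }
        }
      }
      .b_spacer(chr, spacer_len, gc = config$gc %||% 0.62, first = "G")
      chrom_id <- paste0(gid, "_chr")
      reps <- list(replicon(chrom_id, .b_seq(chr), "circular", "chromosome"))
      feats <- .b_features(chr, chrom_id)
      for (ps in g$plasmids %||% list()) {
        pb <- .build_plasmid(gid, ps, panel, reg)
        pid <- paste0(gid, "_", ps$id)
        reps[[length(reps) + 1L]] <- replicon(pid, .b_seq(pb), "circular",
                                              "plasmid")
        pf <- .b_features(pb, pid)
        feats <- rbind(feats, pf)
        reg$elements[[ps$id]]$replicon_id <- pid
      }
      # fill in replicon ids for this genome's chromosomal elements/anchors
      for (eid in names(reg$elements)) {
        if (identical(reg$elements[[eid]]$genome_id, gid) &&
            is.null(reg$elements[[eid]]$replicon_id)) {
          reg$elements[[eid]]$replicon_id <- chrom_id
        }
      }
      anch <- do.call(rbind, reg$anchors)
      anch$replicon_id <- chrom_id
      anch$genome_id <- gid
      reg$anchors_all[[gid]] <- anch
      genomes[[gid]] <- genome_record(gid, reps, feats)
    }
    truth <- list(
      elements = reg$elements,
      anchors = do.call(rbind, reg$anchors_all),
      qs = reg$qs,
      cargo = if (length(reg$cargo)) do.call(rbind, reg$cargo) else NULL,
      filler_iv = reg$filler_iv,
      backbone_iv = reg$backbone_iv,
      nodbox = reg$nodbox,
      nodbox_sites = if (length(reg$nodbox_sites))
        do.call(rbind, reg$nodbox_sites) else NULL,
      recombination = NULL,
      seed = config$seed
    )
    sim <- structure(list(genomes = genomes, truth = truth, files = NULL),
                     class = "MobilomeSimulation")
    if (length(config$recombination %||% list())) {
      sim <- plant_recombination(sim, config$recombination)
    }
    sim$truth$elements <- lapply(sim$truth$elements, function(el) {
      el$circle <- .truth_circle(sim, el)
      el
    })
    if (!is.null(out_dir)) sim <- .write_simulation(sim, out_dir)
    sim
  })
}

# circular form of a truth element from the final replicon sequence
.truth_circle <- function(sim, el) {
  if (el$class %in% c("conjugative_plasmid", "mobilizable_plasmid")) {
    return(sim$genomes[[el$genome_id]]$replicons[[el$replicon_id]]$sequence)
  }
  if (el$class == "artifact") return(NA_character_)
  text <- sim$genomes[[el$genome_id]]$replicons[[el$replicon_id]]$sequence
  fr <- el$fragments
  if (nrow(fr) == 1L) {
    return(substr(text, fr$start + 1L, fr$end - fr$core_len))
  }
  # cycle: alpha, then successor by matching right family to left family
  ord <- integer(nrow(fr))
  ord[1] <- which(fr$role == "alpha")
  for (k in 2:nrow(fr)) {
    ord[k] <- which(fr$left_family == fr$right_family[ord[k - 1L]])
  }
  paste(vapply(ord, function(k) {
    substr(text, fr$start[k] + 1L, fr$end[k] - fr$core_len[k])
  }, ""), collapse = "")
}

#' Plant recombination events between elements
#'
#' A segment of element A overwrites the corresponding (same element-local
#' offset) coordinates of element B: features of B under the segment are
#' removed and A's features inside the segment are copied in with new locus
#' ids. Events are recorded in the truth registry.
#'
#' @param sim a `MobilomeSimulation`
#' @param events list of list(event_id, from, to, length, from_offset,
#'   to_offset); offsets default to the start of each element's private cargo
#'   block
#' @return the modified simulation
#' @export
plant_recombination <- function(sim, events) {
  if (!length(events)) return(sim)
  registry <- list()
  for (ev in events) {
    ea <- sim$truth$elements[[ev$from]]
    eb <- sim$truth$elements[[ev$to]]
    if (is.null(ea) || is.null(eb)) stop("unknown element in recombination event")
    len <- ev$length
    fa <- ea$fragments[1, ]
    fb <- eb$fragments[1, ]
    # default: start of each element's private cargo block (global coords in
    # the truth registry; offsets below are element-local)
    a0 <- if (is.null(ev$from_offset)) sim$truth$filler_iv[[ev$from]][1]
          else fa$start + ev$from_offset
    b0 <- if (is.null(ev$to_offset)) sim$truth$filler_iv[[ev$to]][1]
          else fb$start + ev$to_offset
    if (a0 + len > fa$end || b0 + len > fb$end) {
      stop("recombination segment crosses element boundary")
    }
    ga <- sim$genomes[[ea$genome_id]]
    gb <- sim$genomes[[eb$genome_id]]
    sa <- substr(ga$replicons[[ea$replicon_id]]$sequence, a0 + 1L, a0 + len)
    tseq <- gb$replicons[[eb$replicon_id]]$sequence
    tseq <- paste0(substr(tseq, 1L, b0), sa,
                   substr(tseq, b0 + len + 1L, nchar(tseq)))
    sim$genomes[[eb$genome_id]]$replicons[[eb$replicon_id]]$sequence <- tseq
    # feature surgery on the target
    fb_feats <- sim$genomes[[eb$genome_id]]$features
    drop <- fb_feats$replicon_id == eb$replicon_id &
      fb_feats$start < b0 + len & fb_feats$end > b0
    fb_feats <- fb_feats[!drop, , drop = FALSE]
    fa_feats <- ga$features
    take <- fa_feats$replicon_id == ea$replicon_id &
      fa_feats$start >= a0 & fa_feats$end <= a0 + len
    moved <- fa_feats[take, , drop = FALSE]
    if (nrow(moved)) {
      moved$locus_id <- paste0(moved$locus_id, "_rx_", ev$event_id %||% "e")
      moved$replicon_id <- eb$replicon_id
      moved$start <- moved$start - a0 + b0
      moved$end <- moved$end - a0 + b0
    }
    sim$genomes[[eb$genome_id]]$features <- rbind(fb_feats, moved)
    registry[[length(registry) + 1L]] <- data.frame(
      event_id = ev$event_id %||% paste0("ev", length(registry) + 1L),
      from_element = ev$from, to_element = ev$to,
      from_offset = a0 - fa$start, to_offset = b0 - fb$start, length = len,
      to_replicon = eb$replicon_id, to_global_start = b0,
      from_global_start = a0, stringsAsFactors = FALSE)
  }
  sim$truth$recombination <- rbind(sim$truth$recombination,
                                   do.call(rbind, registry))
  for (gid in names(sim$genomes)) validate_genome_record(sim$genomes[[gid]])
  sim
}

.write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (gid in names(sim$genomes)) {
    files[[gid]] <- write_genome(sim$genomes[[gid]], file.path(out_dir, gid))
  }
  truth_path <- file.path(out_dir, "truth.json")
  tr <- sim$truth
  tr$elements <- lapply(tr$elements, function(el) {
    el$fragments <- as.list(el$fragments)
    el
  })
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  sim$files <- c(unlist(files), truth = truth_path)
  sim
}

#' @export
print.MobilomeSimulation <- function(x, ...) {
  cat("MobilomeSimulation:", length(x$genomes), "genome(s),",
      length(x$truth$elements), "planted element/region record(s)\n")
  invisible(x)
}

#' Simulate a panel of element gene complements for backbone analysis
#'
#' Generates `n_elements` ICE-like protein complements, each carrying the 17
#' conserved backbone families (integrase, relaxase, RDF, the trb
#' conjugation cluster, traF, traG, msi107, msi110) except for one sporadic
#' deletion of one backbone family in one element, plus shared and private
#' accessory cargo and IS content. Used to exercise ortholog clustering,
#' backbone identification at the 95% prevalence rule, and redundancy
#' collapse without building full genomes.
#'
#' @param n_elements number of elements (default 20)
#' @param seed RNG seed
#' @param divergence per-element divergence from the exemplars (default 0.05)
#' @param delete_in element index receiving the sporadic backbone deletion
#' @return list(proteins, unit_of, truth = list(backbone_roles,
#'   deleted_role, deleted_element))
#' @export
simulate_element_panel <- function(n_elements = 20, seed = 7,
                                   divergence = 0.05, delete_in = 1L) {
  panel <- default_reference_panel()
  backbone_roles <- c("rlxS", "rdfS", trb_cluster_roles(),
                      "traF", "traG", "msi107", "msi110")
  stopifnot(length(backbone_roles) == 17L)
  int_rotation <- c("intS", "intM", "intG", "intP", "srtI")
  .with_seed(seed, {
    deleted_role <- "msi107"
    shared_cargo <- replicate(4L, sim_protein(170L))
    proteins <- character()
    unit_of <- character()
    for (e in seq_len(n_elements)) {
      eid <- sprintf("el%02d", e)
      # integrases vary across elements (rotated role, higher divergence), so
      # they stay below backbone prevalence as in real element sets
      int_role <- int_rotation[(e - 1L) %% length(int_rotation) + 1L]
      locus <- paste0(eid, "_", int_role)
      proteins[locus] <- mutate_protein(panel[panel$role == int_role, "seq"][1],
                                        0.25)
      unit_of[locus] <- eid
      roles <- backbone_roles
      if (e == delete_in) roles <- setdiff(roles, deleted_role)
      for (r in roles) {
        locus <- paste0(eid, "_", r)
        proteins[locus] <- mutate_protein(panel[panel$role == r, "seq"][1],
                                          divergence)
        unit_of[locus] <- eid
      }
      # a couple of shared accessory families (below backbone prevalence)
      for (k in seq_len(2L)) {
        if ((e + k) %% 3L == 0L) {
          locus <- sprintf("%s_sh%d", eid, k)
          proteins[locus] <- mutate_protein(shared_cargo[[k]], divergence)
          unit_of[locus] <- eid
        }
      }
      for (k in seq_len(3L)) {   # private cargo
        locus <- sprintf("%s_pr%d", eid, k)
        proteins[locus] <- sim_protein(160L)
        unit_of[locus] <- eid
      }
      if (e %% 3L != 0L) {  # IS content varies across elements
        locus <- paste0(eid, "_is")
        proteins[locus] <- mutate_protein(panel[panel$role == "tnpA1", "seq"][1],
                                          0.01)
        unit_of[locus] <- eid
      }
    }
    list(proteins = proteins, unit_of = unit_of,
         truth = list(backbone_roles = backbone_roles,
                      deleted_role = deleted_role,
                      deleted_element = sprintf("el%02d", delete_in)))
  })
}
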