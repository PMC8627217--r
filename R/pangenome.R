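# Pangenome and mobilome accounting: ortholog clustering, backbone
# identification, core-size sweeps, mobilome fractions, gene-content trees,
# fragment-based ANI with genospecies partitioning, and cargo-trait
# association.

#' All-vs-all protein identities
#'
#' Best local-alignment identity and mutual coverage for every protein pair
#' (optionally k-mer prefiltered for large sets). Deterministic: proteins are
#' processed in sorted name order.
#'
#' @param proteins named character vector
#' @param prefilter "auto", "none" or "kmer" (see [search_panel()])
#' @param min_report only pairs at or above this identity are kept (default 15)
#' @return data.frame: a, b, identity, cov_a, cov_b
#' @export
protein_pairs <- function(proteins, prefilter = c("auto", "none", "kmer"),
                          min_report = 15) {
  prefilter <- match.arg(prefilter)
  proteins <- proteins[order(names(proteins))]
  n <- length(proteins)
  empty <- data.frame(a = character(), b = character(), identity = numeric(),
                      cov_a = numeric(), cov_b = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  use_kmer <- switch(prefilter, none = FALSE, kmer = TRUE,
                     auto = n * (n - 1) / 2 > 20000)
  kms <- if (use_kmer) lapply(proteins, .kmer_set) else NULL
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    js <- seq.int(i + 1L, n)
    if (use_kmer) {
      sk <- kms[[i]]
      js <- js[vapply(kms[js], .shared_kmers, 0L, subject_kmers = sk) >= 2L]
      if (!length(js)) next
    }
    df <- align_local_set(proteins[js], proteins[[i]], "protein")
    keep <- df$percent_identity >= min_report
    if (!any(keep)) next
    df <- df[keep, , drop = FALSE]
    out[[i]] <- data.frame(a = names(proteins)[i], b = df$query,
                           identity = df$percent_identity,
                           cov_a = df$subject_coverage, cov_b = df$query_coverage,
                           evalue = df$evalue_proxy,
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster proteins into ortholog groups
#'
#' Single-linkage components over pairs passing the identity and mutual
#' coverage thresholds plus an alignment-significance gate (the e-value
#' proxy), so short spurious local alignments between unrelated proteins do
#' not bridge clusters at permissive identity thresholds. Multi-copy
#' membership within one unit is allowed, so paralogs are not split.
#' Singletons are retained. Cluster ids are assigned by each cluster's
#' lexicographically smallest member, making the result invariant to input
#' order.
#'
#' @param proteins named character vector
#' @param identity_threshold percent identity (default 40)
#' @param coverage_threshold minimum mutual coverage (default 0.5)
#' @param max_evalue significance gate on the alignment e-value proxy
#'   (default 1e-6)
#' @param pairs optional precomputed [protein_pairs()] table
#' @param prefilter passed to [protein_pairs()]
#' @return an `OrthologClusterSet`: list(clusters, membership,
#'   identity_threshold, coverage_threshold)
#' @export
cluster_orthologs <- function(proteins, identity_threshold = 40,
                              coverage_threshold = 0.5, max_evalue = 1e-6,
                              pairs = NULL,
                              prefilter = c("auto", "none", "kmer")) {
  proteins <- proteins[order(names(proteins))]
  if (is.null(pairs)) pairs <- protein_pairs(proteins, prefilter)
  edges <- pairs[pairs$identity >= identity_threshold &
                   pmin(pairs$cov_a, pairs$cov_b) >= coverage_threshold &
                   pairs$evalue <= max_evalue, ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = names(proteins)))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  names(groups) <- sprintf("OG%05d", seq_along(groups))
  membership <- stats::setNames(rep(names(groups), lengths(groups)),
                                unlist(groups, use.names = FALSE))
  structure(list(clusters = groups, membership = membership,
                 identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold),
            class = "OrthologClusterSet")
}

#' @export
print.OrthologClusterSet <- function(x, ...) {
  cat("OrthologClusterSet:", length(x$clusters), "clusters over",
      length(x$membership), "proteins at", x$identity_threshold, "% identity\n")
  invisible(x)
}

#' Presence/absence (count) matrix of clusters across units
#'
#' @param cluster_set an `OrthologClusterSet`
#' @param unit_of named character vector mapping locus to unit (element or
#'   genome id)
#' @return integer matrix, clusters x units (copy counts)
#' @export
presence_absence <- function(cluster_set, unit_of) {
  loci <- names(cluster_set$membership)
  unit <- unit_of[loci]
  keep <- !is.na(unit)
  tab <- table(cluster = cluster_set$membership[keep], unit = unit[keep])
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Core-genome size across identity thresholds
#'
#' Reclusters at each threshold (reusing one all-vs-all identity table) and
#' counts clusters present in every genome.
#'
#' @param proteins named character vector
#' @param unit_of named locus-to-genome map
#' @param thresholds identity thresholds (default 20..95 by 5)
#' @param coverage_threshold minimum mutual coverage
#' @param pairs optional precomputed pair table
#' @return data.frame: threshold, core_count, n_clusters
#' @export
sweep_core_size <- function(proteins, unit_of,
                            thresholds = seq(20, 95, by = 5),
                            coverage_threshold = 0.5, pairs = NULL) {
  units <- sort(unique(unit_of[names(proteins)]))
  if (length(units) < 2L) stop("need >= 2 genomes")
  if (is.null(pairs)) pairs <- protein_pairs(proteins)
  out <- lapply(thresholds, function(t) {
    cs <- cluster_orthologs(proteins, t, coverage_threshold, pairs = pairs)
    pa <- presence_absence(cs, unit_of)
    core <- sum(rowSums(pa[, units, drop = FALSE] > 0) == length(units))
    data.frame(threshold = t, core_count = core,
               n_clusters = length(cs$clusters))
  })
  do.call(rbind, out)
}

#' Identify backbone clusters among non-redundant elements
#'
#' Backbone = clusters present in at least `prevalence` of the elements (the
#' margin absorbs sporadic deletions). The single-copy subset (exactly one
#' copy in every element carrying it) is flagged for concatenation export.
#'
#' @param pa presence/count matrix restricted to non-redundant elements
#' @param prevalence fraction threshold (default 0.95)
#' @return a `BackboneSet`: list(backbone, single_copy, prevalence, n_elements)
#' @export
identify_backbone <- function(pa, prevalence = 0.95) {
  if (ncol(pa) < 2L) stop("need >= 2 elements")
  frac <- rowSums(pa > 0) / ncol(pa)
  backbone <- rownames(pa)[frac >= prevalence]
  single <- backbone[apply(pa[backbone, , drop = FALSE], 1, function(v) {
    all(v[v > 0] == 1L)
  })]
  structure(list(backbone = backbone, single_copy = single,
                 prevalence = prevalence, n_elements = ncol(pa)),
            class = "BackboneSet")
}

#' Mobilome accounting
#'
#' Fraction of the pangenome's ortholog clusters located on mobile genetic
#' elements (any-member rule: a cluster with one member on an MGE counts as
#' MGE and the conflict is logged), and within the mobilome the shares held
#' by ICEs, ICESyms (as a share of ICE clusters), plasmids, IMEs and phages.
#' Category shares are computed with priority ICE > plasmid > IME > phage so
#' they sum to one.
#'
#' @param cluster_set an `OrthologClusterSet`
#' @param locus_category named vector: per locus one of "ICE", "ICESym",
#'   "IME", "plasmid", "phage", "chromosome" (ICESym loci count as ICE too)
#' @return a `MobilomeAccount` list
#' @export
account_mobilome <- function(cluster_set, locus_category) {
  cl <- cluster_set$clusters
  cat_of <- function(loci) unique(locus_category[loci])
  cats <- lapply(cl, cat_of)
  is_mge <- vapply(cats, function(x) any(x %in% c("ICE", "ICESym", "IME",
                                                  "plasmid", "phage")), TRUE)
  mixed <- vapply(cats, function(x) {
    any(x == "chromosome") && any(x != "chromosome")
  }, TRUE)
  if (any(mixed)) {
    message(sum(mixed), " cluster(s) span MGE and chromosomal loci; ",
            "counted as MGE (any-member rule)")
  }
  mge <- cats[is_mge]
  has <- function(x, what) any(x %in% what)
  n_mge <- length(mge)
  n_ice <- sum(vapply(mge, has, TRUE, what = c("ICE", "ICESym")))
  n_icesym <- sum(vapply(mge, has, TRUE, what = "ICESym"))
  primary <- vapply(mge, function(x) {
    if (has(x, c("ICE", "ICESym"))) "ICE"
    else if (has(x, "plasmid")) "plasmid"
    else if (has(x, "IME")) "IME"
    else "phage"
  }, "")
  shares <- table(factor(primary, levels = c("ICE", "plasmid", "IME", "phage")))
  structure(list(
    n_clusters = length(cl),
    n_mge_clusters = n_mge,
    mge_fraction = n_mge / length(cl),
    ice_share = if (n_mge) n_ice / n_mge else 0,
    icesym_share_of_ice = if (n_ice) n_icesym / n_ice else 0,
    category_shares = if (n_mge) as.numeric(shares) / n_mge else rep(0, 4),
    category_names = names(shares)
  ), class = "MobilomeAccount")
}

#' Neighbor-joining tree from gene presence/absence
#'
#' Pairwise distance = number of clusters differing in presence/absence
#' between two units; tree by standard neighbor joining. Columns are sorted
#' so the result is deterministic.
#'
#' @param pa presence matrix (typically restricted to accessory clusters)
#' @return an unrooted `phylo` object
#' @export
gene_content_tree <- function(pa) {
  if (ncol(pa) < 3L) stop("need >= 3 units")
  pa <- pa[, order(colnames(pa)), drop = FALSE]
  d <- stats::dist(t(pa > 0), method = "manhattan")
  ape::nj(d)
}

# best alignment of a fragment against a subject via exact-seed candidate
# diagonals; returns identity (NA when no seed matches)
.best_fragment_identity <- function(frag, subj_fwd, subj_rev, k = 16L) {
  flen <- nchar(frag)
  offs <- unique(pmax(0L, c(0L, flen %/% 2L - k %/% 2L, flen - k)))
  best <- NA_real_
  for (subj in list(subj_fwd, subj_rev)) {
    if (is.null(subj)) next
    m <- nchar(subj$text)
    diags <- integer(0)
    for (off in offs) {
      probe <- substr(frag, off + 1L, off + k)
      if (grepl("N", probe, fixed = TRUE)) next
      pos <- Biostrings::start(Biostrings::matchPattern(probe, subj$dna)) - 1L
      diags <- c(diags, pos - off)
    }
    if (!length(diags)) next
    diags <- unique(diags)
    # up to 3 candidate windows, most frequent diagonal neighbourhood first
    if (length(diags) > 3L) diags <- diags[1:3]
    for (d in diags) {
      w0 <- max(0L, d - 30L)
      w1 <- min(m, d + flen + 30L)
      if (w1 - w0 < flen %/% 2L) next
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(frag),
        Biostrings::DNAString(substr(subj$text, w0 + 1L, w1)),
        type = "global-local", substitutionMatrix = .nt_submat(),
        gapOpening = 4, gapExtension = 1)
      idy <- 100 * Biostrings::nmatch(aln) /
        nchar(as.character(Biostrings::pattern(aln)))
      if (is.na(best) || idy > best) best <- idy
    }
  }
  best
}

#' Fragment-based average nucleotide identity
#'
#' Both genomes are cut into non-overlapping fragments (default 1020 bp);
#' each fragment's best match in the other genome (either strand, found via
#' exact 16-mer seeds and banded alignment) contributes its identity, and
#' fragments below the inclusion floor (default 80%) or without a seed match
#' are excluded, as in standard whole-genome ANI practice. The reported ANI
#' averages the two directional means, so it is symmetric by construction.
#'
#' @param genome_a,genome_b `GenomeRecord`, `Replicon` or nucleotide string
#' @param fragment fragment length in bp (default 1020)
#' @param min_keep identity floor for inclusion (default 80)
#' @param max_fragments per direction, subsample at most this many fragments
#'   (evenly spaced; keeps large-genome comparisons fast)
#' @return an `ANIResult` list: ani, n_fragments, directional means
#' @export
compute_ani <- function(genome_a, genome_b, fragment = 1020, min_keep = 80,
                        max_fragments = Inf) {
  seq_of <- function(x) {
    if (inherits(x, "GenomeRecord")) {
      paste(vapply(x$replicons, `[[`, "", "sequence"), collapse =
              strrep("N", 50))
    } else if (inherits(x, "Replicon")) x$sequence else x
  }
  a <- seq_of(genome_a)
  b <- seq_of(genome_b)
  if (nchar(a) < 10 * fragment || nchar(b) < 10 * fragment) {
    stop("genomes must span at least 10 fragments")
  }
  direction <- function(qtext, stext) {
    subj_fwd <- list(text = stext, dna = Biostrings::DNAString(stext))
    rtext <- .revcomp(stext)
    subj_rev <- list(text = rtext, dna = Biostrings::DNAString(rtext))
    nfrag <- nchar(qtext) %/% fragment
    idx <- seq_len(nfrag)
    if (is.finite(max_fragments) && nfrag > max_fragments) {
      idx <- unique(round(seq(1, nfrag, length.out = max_fragments)))
    }
    ids <- vapply(idx, function(i) {
      frag <- substr(qtext, (i - 1L) * fragment + 1L, i * fragment)
      if (grepl("N", frag, fixed = TRUE)) return(NA_real_)
      .best_fragment_identity(frag, subj_fwd, subj_rev)
    }, 0)
    ids <- ids[!is.na(ids) & ids >= min_keep]
    list(mean = if (length(ids)) mean(ids) else NA_real_, n = length(ids))
  }
  ab <- direction(a, b)
  ba <- direction(b, a)
  ani <- mean(c(ab$mean, ba$mean), na.rm = TRUE)
  structure(list(ani = ani, n_fragments = ab$n + ba$n,
                 mean_ab = ab$mean, mean_ba = ba$mean),
            class = "ANIResult")
}

#' Partition genomes into genospecies by single linkage on ANI
#'
#' Genomes joined when pairwise ANI is at or above the cutoff (default 95;
#' a pair at exactly 95.0 is the same genospecies).
#'
#' @param ani_table data.frame with columns genome_a, genome_b, ani
#' @param cutoff ANI threshold (default 95)
#' @return named integer vector: genospecies index per genome
#' @export
partition_genospecies <- function(ani_table, cutoff = 95) {
  genomes <- sort(unique(c(ani_table$genome_a, ani_table$genome_b)))
  keep <- ani_table$ani >= cutoff
  g <- igraph::graph_from_data_frame(
    ani_table[keep, c("genome_a", "genome_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = genomes))
  comp <- igraph::components(g)$membership
  comp[genomes]
}

#' Cargo-trait association by Fisher's exact test with Bonferroni correction
#'
#' Two-sided Fisher exact test per cluster on the 2x2 presence-by-trait
#' table; Bonferroni over all tested clusters; significant iff corrected
#' p < alpha. Units can be excluded (e.g. a duplicated element).
#'
#' @param pa presence matrix (clusters x units)
#' @param traits named logical/0-1 vector per unit
#' @param alpha significance level (default 0.05)
#' @param exclude unit ids to drop before testing
#' @return data.frame of `AssociationResult`s
#' @export
associate_trait <- function(pa, traits, alpha = 0.05, exclude = character()) {
  units <- setdiff(colnames(pa), exclude)
  tr <- as.logical(traits[units])
  if (length(unique(tr)) < 2L) stop("degenerate trait: all units in one class")
  pa <- pa[, units, drop = FALSE] > 0
  n_tested <- nrow(pa)
  out <- lapply(rownames(pa), function(cl) {
    pres <- pa[cl, ]
    tab <- table(factor(pres, levels = c(TRUE, FALSE)),
                 factor(tr, levels = c(TRUE, FALSE)))
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    data.frame(cluster_id = cl,
               present_pos = tab[1, 1], present_neg = tab[1, 2],
               absent_pos = tab[2, 1], absent_neg = tab[2, 2],
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$bonferroni_p <- pmin(1, out$p_value * n_tested)
  out$significant <- out$bonferroni_p < alpha
  out[order(out$p_value, out$cluster_id), , drop = FALSE]
}
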