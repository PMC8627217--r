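# Homology engine: panel search, relaxase MOB-family classification,
# conjugation-cluster and integrase detection.

.as_protein_set <- function(x) {
  if (inherits(x, "GenomeRecord")) {
    f <- x$features[x$features$kind == "CDS", , drop = FALSE]
    stats::setNames(f$protein, f$locus_id)
  } else if (is.data.frame(x)) {
    f <- x[x$kind == "CDS", , drop = FALSE]
    stats::setNames(f$protein, f$locus_id)
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    x
  }
}

#' Search query sequences against a reference panel
#'
#' Best local alignment of every query against every panel exemplar; hits
#' passing the identity and query-coverage thresholds are returned sorted by
#' query and descending bit score. Identity is matches / alignment columns of
#' the best local alignment.
#'
#' For large inputs a shared-4-mer prefilter skips clearly unrelated pairs
#' (`prefilter = "auto"` enables it above 20,000 query-exemplar pairs); it is
#' lossless for homologs above roughly 50% identity and can be disabled with
#' `prefilter = "none"`.
#'
#' @param proteins a `GenomeRecord`, feature data.frame, or named character
#'   vector of sequences
#' @param panel data.frame from [read_reference_panel()]
#' @param min_identity percent identity threshold (default 30)
#' @param min_coverage query-coverage threshold (default 0.6)
#' @param type "protein" or "nucleotide"
#' @param prefilter "auto", "none" or "kmer"
#' @return data.frame of `HomologyHit`s: query_locus, exemplar_id, role_label,
#'   percent_identity, query_coverage, subject_coverage, score (bits),
#'   raw_score, evalue_proxy
#' @export
search_panel <- function(proteins, panel, min_identity = 30,
                         min_coverage = 0.6,
                         type = c("protein", "nucleotide"),
                         prefilter = c("auto", "none", "kmer")) {
  type <- match.arg(type)
  prefilter <- match.arg(prefilter)
  queries <- .as_protein_set(proteins)
  empty <- data.frame(query_locus = character(), exemplar_id = character(),
                      role_label = character(), percent_identity = numeric(),
                      query_coverage = numeric(), subject_coverage = numeric(),
                      score = numeric(), raw_score = numeric(),
                      evalue_proxy = numeric(), stringsAsFactors = FALSE)
  if (length(queries) == 0L || nrow(panel) == 0L) return(empty)
  use_kmer <- switch(prefilter,
                     none = FALSE, kmer = TRUE,
                     auto = length(queries) * nrow(panel) > 20000)
  qk <- if (use_kmer) lapply(queries, .kmer_set) else NULL
  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    subj <- panel$seq[i]
    idx <- seq_along(queries)
    if (use_kmer) {
      sk <- .kmer_set(subj)
      idx <- which(vapply(qk, .shared_kmers, 0L, subject_kmers = sk) >= 2L)
      if (!length(idx)) next
    }
    df <- align_local_set(queries[idx], subj, type)
    keep <- df$percent_identity >= min_identity & df$query_coverage >= min_coverage
    if (!any(keep)) next
    df <- df[keep, , drop = FALSE]
    df$exemplar_id <- panel$exemplar_id[i]
    df$role_label <- panel$role[i]
    out[[i]] <- df
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  hits <- do.call(rbind, out)
  hits <- data.frame(query_locus = hits$query, exemplar_id = hits$exemplar_id,
                     role_label = hits$role_label,
                     percent_identity = hits$percent_identity,
                     query_coverage = hits$query_coverage,
                     subject_coverage = hits$subject_coverage,
                     score = hits$score, raw_score = hits$raw_score,
                     evalue_proxy = hits$evalue_proxy,
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$query_locus, -hits$score, hits$exemplar_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Best hit per query locus
#' @keywords internal
best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits[!duplicated(hits$query_locus), , drop = FALSE]
}

#' Read an hmmscan-style domain table
#'
#' Space-delimited domain-table dialect (`--domtblout`): profile name in
#' column 1, query in column 4, full-sequence e-value, score in columns 7-8.
#' Malformed rows are skipped with a warning.
#'
#' @param path file path
#' @return data.frame: query_locus, profile, full_evalue, full_score
#' @export
read_hmm_domtbl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    ev <- suppressWarnings(as.numeric(f[7]))
    sc <- suppressWarnings(as.numeric(f[8]))
    if (length(f) < 8L || is.na(ev) || is.na(sc)) {
      warning("skipping malformed HMM table row: ", substr(l, 1, 60))
      return(NULL)
    }
    data.frame(query_locus = f[4], profile = f[1], full_evalue = ev,
               full_score = sc, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(query_locus = character(), profile = character(),
                      full_evalue = numeric(), full_score = numeric()))
  }
  do.call(rbind, rows)
}

#' Classify relaxase loci into MOB families
#'
#' Either panel hits (roles mapped to families via the gene-name/family map)
#' or an hmmscan domain table may be supplied. A locus gets exactly one
#' family: hits passing the bit-score threshold (default 33) are resolved by
#' best full-sequence e-value, then best score, then lexicographic
#' profile/exemplar id.
#'
#' @param hits panel hits from [search_panel()] (optional)
#' @param hmm_table data.frame from [read_hmm_domtbl()] or a file path
#'   (optional; takes precedence)
#' @param bit_threshold minimum bit score (default 33)
#' @return data.frame of `RelaxaseCall`s: query_locus, family, subtype,
#'   score, decision_basis
#' @export
classify_relaxases <- function(hits = NULL, hmm_table = NULL,
                               bit_threshold = 33) {
  empty <- data.frame(query_locus = character(), family = character(),
                      subtype = character(), score = numeric(),
                      decision_basis = character(), stringsAsFactors = FALSE)
  if (!is.null(hmm_table)) {
    if (is.character(hmm_table)) hmm_table <- read_hmm_domtbl(hmm_table)
    tb <- hmm_table[hmm_table$full_score >= bit_threshold, , drop = FALSE]
    if (!nrow(tb)) return(empty)
    fam <- relaxase_role_map(tb$profile)
    ok <- !is.na(fam$family)
    tb <- tb[ok, , drop = FALSE]
    fam <- fam[ok, , drop = FALSE]
    if (!nrow(tb)) return(empty)
    ord <- order(tb$query_locus, tb$full_evalue, -tb$full_score, tb$profile)
    tb <- tb[ord, , drop = FALSE]
    fam <- fam[ord, , drop = FALSE]
    keep <- !duplicated(tb$query_locus)
    out <- data.frame(query_locus = tb$query_locus[keep],
                      family = fam$family[keep], subtype = fam$subtype[keep],
                      score = tb$full_score[keep],
                      decision_basis = "hmm_table", stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(hits) || !nrow(hits)) return(empty)
  fam <- relaxase_role_map(hits$role_label)
  ok <- !is.na(fam$family) & hits$score >= bit_threshold
  h <- hits[ok, , drop = FALSE]
  fam <- fam[ok, , drop = FALSE]
  if (!nrow(h)) return(empty)
  ord <- order(h$query_locus, h$evalue_proxy, -h$score, h$exemplar_id)
  h <- h[ord, , drop = FALSE]
  fam <- fam[ord, , drop = FALSE]
  keep <- !duplicated(h$query_locus)
  out <- data.frame(query_locus = h$query_locus[keep],
                    family = fam$family[keep], subtype = fam$subtype[keep],
                    score = h$score[keep], decision_basis = "panel_search",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect conjugation-gene clusters
#'
#' Colocated conjugation-role hits (gap between consecutive members at most
#' `locus_window`) are grouped per replicon and typed: `trb_T4SS` when at
#' least 6 of the 9 core trb roles are present, `vir_T4SS` when at least 6
#' vir roles are present, `traACD` when traA and traC are present and
#' divergently oriented (traD optional; an adjacent RDF gene is recorded),
#' else `T4CP_only` when only a coupling protein (traG/virD4) is found.
#'
#' @param genome a `GenomeRecord`
#' @param hits panel hits
#' @param locus_window colocation window in bp (default 10000)
#' @return data.frame of `ConjugationCluster`s (member_loci and roles are
#'   comma-separated, ordered by position)
#' @export
detect_conjugation_clusters <- function(genome, hits, locus_window = 10000) {
  empty <- data.frame(cluster_id = character(), replicon_id = character(),
                      cluster_type = character(), member_loci = character(),
                      roles = character(), completeness = numeric(),
                      start = integer(), end = integer(),
                      rdf_adjacent = logical(), stringsAsFactors = FALSE)
  conj_roles <- c(trb_cluster_roles(), vir_t4ss_roles(), t4cp_roles(),
                  "traA", "traC", "traD", "traF", "rdfS")
  h <- best_hits(hits)
  h <- h[h$role_label %in% conj_roles, , drop = FALSE]
  if (!nrow(h)) return(empty)
  f <- genome$features
  m <- match(h$query_locus, f$locus_id)
  h <- h[!is.na(m), , drop = FALSE]
  m <- m[!is.na(m)]
  if (!nrow(h)) return(empty)
  h$replicon_id <- f$replicon_id[m]
  h$start <- f$start[m]
  h$end <- f$end[m]
  h$strand <- f$strand[m]
  h <- h[order(h$replicon_id, h$start), , drop = FALSE]
  grp <- integer(nrow(h))
  g <- 0L
  for (i in seq_len(nrow(h))) {
    if (i == 1L || h$replicon_id[i] != h$replicon_id[i - 1L] ||
        h$start[i] - h$end[i - 1L] > locus_window) g <- g + 1L
    grp[i] <- g
  }
  out <- lapply(split(seq_len(nrow(h)), grp), function(idx) {
    ch <- h[idx, , drop = FALSE]
    roles <- ch$role_label
    n_trb <- length(intersect(roles, trb_core_roles()))
    n_vir <- length(intersect(roles, vir_t4ss_roles()))
    rdf_adj <- FALSE
    if (n_trb >= 6L) {
      type <- "trb_T4SS"
      completeness <- length(intersect(roles, trb_cluster_roles())) /
        length(trb_cluster_roles())
    } else if (n_vir >= 6L) {
      type <- "vir_T4SS"
      completeness <- n_vir / length(vir_t4ss_roles())
    } else if (all(c("traA", "traC") %in% roles) &&
               .divergent(ch, "traA", "traC")) {
      type <- "traACD"
      completeness <- length(intersect(roles, c("traA", "traC", "traD"))) / 3
      rdf_adj <- "rdfS" %in% roles
    } else if (any(roles %in% t4cp_roles())) {
      type <- "T4CP_only"
      completeness <- 1
    } else {
      return(NULL)
    }
    data.frame(replicon_id = ch$replicon_id[1], cluster_type = type,
               member_loci = paste(ch$query_locus, collapse = ","),
               roles = paste(roles, collapse = ","),
               completeness = completeness,
               start = min(ch$start), end = max(ch$end),
               rdf_adjacent = rdf_adj, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(out$replicon_id, out$start), , drop = FALSE]
  out <- cbind(cluster_id = sprintf("CC%03d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

# traA/traC on opposite strands (divergent, as on the Ti plasmid)
.divergent <- function(ch, a, b) {
  sa <- ch$strand[ch$role_label == a][1]
  sb <- ch$strand[ch$role_label == b][1]
  !is.na(sa) && !is.na(sb) && sa != sb
}

#' Detect and classify integrase genes
#'
#' Integrase-role hits are classified tyrosine/serine from the exemplar role;
#' the family (intS/intM/intG) is assigned when the best exemplar is one of
#' the named tripartite-associated integrases.
#'
#' @param hits panel hits
#' @return data.frame of `IntegraseCall`s: query_locus, int_class, int_family,
#'   score
#' @export
detect_integrases <- function(hits) {
  empty <- data.frame(query_locus = character(), int_class = character(),
                      int_family = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  h <- hits[hits$role_label %in% c(integrase_tyr_roles(), integrase_ser_roles()), ,
            drop = FALSE]
  if (!nrow(h)) return(empty)
  h <- h[order(h$query_locus, -h$score, h$exemplar_id), , drop = FALSE]
  h <- h[!duplicated(h$query_locus), , drop = FALSE]
  fam <- ifelse(h$role_label %in% c("intS", "intM", "intG"), h$role_label, "other")
  out <- data.frame(query_locus = h$query_locus,
                    int_class = ifelse(h$role_label %in% integrase_ser_roles(),
                                       "serine", "tyrosine"),
                    int_family = fam, score = h$score, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
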