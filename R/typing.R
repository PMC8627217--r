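# Element typing: ICE / IME / conjugative plasmid / mobilizable plasmid
# classification, symbiosis-element flagging, quorum-sensing locus profiling
# with pseudogene calling, redundancy collapse, and position-weight-matrix
# motif scanning (nod boxes).

#' Classify a delineated element or plasmid replicon
#'
#' Decision rules, applied in order: integrated + att + integrase + relaxase +
#' (trb or vir T4SS) -> ICE; integrated + att + integrase + relaxase (traACD
#' or lone MOB) without a T4SS -> IME; plasmid replicon + relaxase + T4SS ->
#' conjugative plasmid; plasmid replicon + relaxase and/or coupling protein
#' without a T4SS -> mobilizable plasmid; anything else unclassified.
#' Elements with `att_status = "att_not_found"` but full ICE/IME machinery are
#' classified with the att-not-found override. Entry-exclusion (trbK) and
#' Rep_3/DUF2840 presence are recorded from panel hits.
#'
#' @param el a `DelineatedElement`
#' @param clusters conjugation clusters from [detect_conjugation_clusters()]
#' @param relaxases relaxase calls from [classify_relaxases()]
#' @param integrases integrase calls from [detect_integrases()]
#' @param hits panel hits
#' @return an `ElementClassification` list
#' @export
classify_element <- function(el, clusters, relaxases, integrases, hits) {
  loci <- el$feature_loci
  has <- function(df, col = "query_locus") nrow(df) > 0 && any(df[[col]] %in% loci)
  rel <- relaxases[relaxases$query_locus %in% loci, , drop = FALSE]
  int <- integrases[integrases$query_locus %in% loci, , drop = FALSE]
  in_el <- function(members) {
    any(strsplit(members, ",")[[1]] %in% loci)
  }
  cl <- clusters[vapply(clusters$member_loci, in_el, TRUE), , drop = FALSE]
  t4ss <- intersect(cl$cluster_type, c("trb_T4SS", "vir_T4SS"))
  traacd <- "traACD" %in% cl$cluster_type
  t4cp <- "T4CP_only" %in% cl$cluster_type ||
    any(vapply(cl$roles, function(r) any(strsplit(r, ",")[[1]] %in% t4cp_roles()), TRUE))
  bh <- best_hits(hits)
  bh <- bh[bh$query_locus %in% loci, , drop = FALSE]
  trbk <- "trbK" %in% bh$role_label
  rep3 <- any(c("Rep_3", "DUF2840") %in% bh$role_label)

  # att evidence wins over replicon class: "plasmid" status only ever set for
  # replicons that were not att-delineated
  integrated <- el$att_status %in% c("resolved", "att_not_found")
  mge_class <- "unclassified"
  if (integrated && nrow(int) && nrow(rel) && length(t4ss)) {
    mge_class <- "ICE"
  } else if (integrated && nrow(int) && nrow(rel) && !length(t4ss)) {
    mge_class <- "IME"
  } else if (identical(el$att_status, "plasmid") && nrow(rel) && length(t4ss)) {
    mge_class <- "conjugative_plasmid"
  } else if (identical(el$att_status, "plasmid") &&
             (nrow(rel) || t4cp) && !length(t4ss)) {
    mge_class <- "mobilizable_plasmid"
  }
  t4 <- if ("trb_T4SS" %in% t4ss) "trb" else if ("vir_T4SS" %in% t4ss) "vir" else "none"
  list(element_id = el$element_id,
       mge_class = mge_class,
       t4ss_type = t4,
       relaxase_family = if (nrow(rel)) rel$family[1] else NA_character_,
       relaxase_subtype = if (nrow(rel)) rel$subtype[1] else NA_character_,
       is_ICESym = FALSE,
       trbK_present = trbk,
       rep3_duf2840_present = rep3)
}

#' Flag a symbiosis element (ICESym)
#'
#' TRUE iff the element carries the nod-factor biosynthesis core (nodABC and
#' nodIJ) plus at least one nitrogenase (nif) and one fix role. The rule is
#' configurable through `rule`.
#'
#' @param el a `DelineatedElement`
#' @param hits panel hits
#' @param rule list(nod_all, nif_min, fix_min)
#' @return logical
#' @export
flag_symbiosis <- function(el, hits,
                           rule = list(nod_all = c("nodA", "nodB", "nodC",
                                                   "nodI", "nodJ"),
                                       nif_min = 1L, fix_min = 1L)) {
  bh <- best_hits(hits)
  roles <- bh$role_label[bh$query_locus %in% el$feature_loci]
  all(rule$nod_all %in% roles) &&
    length(intersect(roles, nif_roles())) >= rule$nif_min &&
    length(intersect(roles, fix_roles())) >= rule$fix_min
}

#' Profile the quorum-sensing locus of an element
#'
#' Copy counts and coordinates for traR1/traR2, traI1/traI2, qseM, qseC and
#' fseA; copies are assigned to paralogue classes by best exemplar. Each copy
#' is called intact, pseudogene (frameshift when the CDS length is not a
#' multiple of three, internal stop codons, or length below 80% of the
#' exemplar) or remnant (exemplar coverage below 40%).
#'
#' @param el a `DelineatedElement`
#' @param hits panel hits
#' @param genome the `GenomeRecord`
#' @param panel reference panel (for exemplar lengths)
#' @param len_frac intact-length fraction (default 0.8)
#' @param remnant_cov remnant coverage ceiling (default 0.4)
#' @return list with `profile` (per-copy data.frame), `counts` (named role
#'   counts of non-remnant copies) and `pseudogenes` (PseudogeneCall rows)
#' @export
profile_qs_locus <- function(el, hits, genome, panel = default_reference_panel(),
                             len_frac = 0.8, remnant_cov = 0.4) {
  qs <- hits[hits$role_label %in% qs_roles() &
               hits$query_locus %in% el$feature_loci, , drop = FALSE]
  prof <- data.frame(element_id = character(), role = character(),
                     locus_id = character(), start = integer(), end = integer(),
                     status = character(), basis = character(),
                     exemplar_id = character(), stringsAsFactors = FALSE)
  if (nrow(qs)) {
    qs <- qs[order(qs$query_locus, -qs$score, qs$exemplar_id), , drop = FALSE]
    qs <- qs[!duplicated(qs$query_locus), , drop = FALSE]
    f <- genome$features
    m <- match(qs$query_locus, f$locus_id)
    ex_len <- nchar(panel[qs$exemplar_id, "seq"])
    nt_len <- f$end[m] - f$start[m]
    prot <- f$protein[m]
    status <- character(nrow(qs))
    basis <- rep(NA_character_, nrow(qs))
    for (i in seq_len(nrow(qs))) {
      if (qs$subject_coverage[i] < remnant_cov) {
        status[i] <- "remnant"
      } else if (nt_len[i] %% 3L != 0L) {
        status[i] <- "pseudogene"; basis[i] <- "frameshift"
      } else if (grepl("*", substr(prot[i], 1, nchar(prot[i]) - 1L), fixed = TRUE)) {
        status[i] <- "pseudogene"; basis[i] <- "premature_stop"
      } else if (nchar(prot[i]) < len_frac * ex_len[i]) {
        status[i] <- "pseudogene"; basis[i] <- "truncation"
      } else {
        status[i] <- "intact"
      }
    }
    prof <- data.frame(element_id = el$element_id, role = qs$role_label,
                       locus_id = qs$query_locus, start = f$start[m],
                       end = f$end[m], status = status, basis = basis,
                       exemplar_id = qs$exemplar_id, stringsAsFactors = FALSE)
    prof <- prof[order(prof$start), , drop = FALSE]
    rownames(prof) <- NULL
  }
  counts <- vapply(qs_roles(), function(r) {
    sum(prof$role == r & prof$status != "remnant")
  }, 0L)
  pseudo <- prof[prof$status == "pseudogene", c("locus_id", "basis", "exemplar_id")]
  names(pseudo)[3] <- "reference_exemplar"
  list(profile = prof, counts = counts, pseudogenes = pseudo)
}

#' Collapse redundant elements by accessory gene content
#'
#' Elements sharing an identical accessory ortholog-cluster set (ignoring IS
#' transposase clusters) are grouped; overall gene content, not SNPs, defines
#' redundancy. The representative is the longest member.
#'
#' @param pa presence/absence matrix (clusters x elements, 0/1 or counts)
#' @param is_clusters cluster ids labelled as IS transposases
#' @param accessory_clusters cluster ids to compare on (default: all rows)
#' @param element_lengths named lengths used to pick representatives
#' @return data.frame of `RedundancyGroup`s: representative_element_id,
#'   member_element_ids (comma-separated, sorted)
#' @export
collapse_redundant <- function(pa, is_clusters = character(),
                               accessory_clusters = NULL,
                               element_lengths = NULL) {
  if (is.null(accessory_clusters)) accessory_clusters <- rownames(pa)
  cmp <- setdiff(intersect(accessory_clusters, rownames(pa)), is_clusters)
  sets <- apply(pa[cmp, , drop = FALSE] > 0, 2, function(v) {
    paste(sort(cmp[v]), collapse = ";")
  })
  groups <- split(colnames(pa), sets)
  out <- lapply(groups, function(members) {
    members <- sort(members)
    rep_id <- if (!is.null(element_lengths)) {
      members[which.max(element_lengths[members])]
    } else members[1]
    data.frame(representative_element_id = rep_id,
               member_element_ids = paste(members, collapse = ","),
               n_members = length(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$representative_element_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a log-odds motif model from aligned training sequences
#'
#' Position probabilities with +0.5 pseudocount, log2-odds against the
#' background; the default score threshold is the minimum self-score of the
#' training sequences.
#'
#' @param training character vector (>= 2) of equal-length sequences
#' @param motif_id identifier
#' @param background base frequencies (default uniform)
#' @param pseudocount added per base count (default 0.5)
#' @return a `MotifModel` list: motif_id, length, log_odds (4 x L),
#'   background, threshold
#' @export
build_motif <- function(training, motif_id = "motif",
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        pseudocount = 0.5) {
  training <- toupper(training)
  if (length(training) < 2L) stop("need >= 2 training sequences")
  L <- unique(nchar(training))
  if (length(L) != 1L) stop("training sequences of unequal length")
  mat <- do.call(rbind, strsplit(training, ""))
  bases <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(L), function(j) {
    vapply(bases, function(b) sum(mat[, j] == b), 0)
  }, numeric(4))
  prob <- (counts + pseudocount) / (length(training) + 4 * pseudocount)
  lo <- log2(prob / background)
  rownames(lo) <- bases
  model <- list(motif_id = motif_id, length = L, log_odds = lo,
                background = background, threshold = NA_real_)
  model$threshold <- min(vapply(training, function(s) .motif_score(model, s), 0))
  class(model) <- "MotifModel"
  model
}

.motif_score <- function(model, seq) {
  idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  sum(model$log_odds[cbind(idx, seq_len(model$length))])
}

#' Scan a sequence for motif hits on both strands
#'
#' All windows scoring at or above the model threshold, sorted by position.
#' Windows containing non-ACGT bases are skipped.
#'
#' @param model a `MotifModel`
#' @param x a `Replicon` or nucleotide string
#' @param threshold override the model threshold
#' @return data.frame: start, end (0-based half-open), strand, score
#' @export
scan_motif <- function(model, x, threshold = model$threshold) {
  seq <- if (inherits(x, "Replicon")) x$sequence else x
  seq <- toupper(seq)
  L <- model$length
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else .revcomp(seq)
    idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    if (n < L) break
    nw <- n - L + 1L
    sc <- numeric(nw)
    for (j in seq_len(L)) {
      sc <- sc + model$log_odds[cbind(idx[j:(j + nw - 1L)], j)]
    }
    hit <- which(!is.na(sc) & sc >= threshold)
    if (length(hit)) {
      start <- if (strand == "+") hit - 1L else n - (hit - 1L) - L
      out[[strand]] <- data.frame(start = start, end = start + L,
                                  strand = strand, score = sc[hit],
                                  stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reverse complement
#' @keywords internal
.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
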