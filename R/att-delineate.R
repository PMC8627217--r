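# att-site delineation: direct-repeat cores flanking integrated elements,
# monopartite and tripartite resolution, and the excision/integration splice
# algebra used to reconstruct circular element sequences.
#
# Coordinates are 0-based half-open throughout. A fragment spans attL start
# to attR end, inclusive of both core copies; the excised circle retains one
# core copy per former pair, so circle length = fragment length - core length
# for a monopartite element and sum(fragments) - 3 cores for a tripartite.

#' Construct a delineated element record
#' @keywords internal
new_element <- function(element_id, genome_id, fragments, partite_count,
                        circular_sequence, attP_cores, integration_site_label,
                        att_status, feature_loci = character(),
                        pairs = NULL) {
  structure(list(
    element_id = element_id, genome_id = genome_id,
    replicon_id = fragments$replicon_id[1],
    fragments = fragments, partite_count = partite_count,
    circular_sequence = circular_sequence, attP_cores = attP_cores,
    integration_site_label = integration_site_label, att_status = att_status,
    feature_loci = feature_loci, pairs = pairs,
    classification = NULL, artifact_flag = FALSE
  ), class = "DelineatedElement")
}

#' Element length under the one-core-per-join convention
#'
#' Length of the circular form when resolved (fragment lengths minus one core
#' copy per join); the raw fragment span otherwise.
#' @param el a `DelineatedElement`
#' @return length in bp
#' @export
element_length <- function(el) {
  if (!is.na(el$circular_sequence[1])) return(nchar(el$circular_sequence))
  sum(el$fragments$end - el$fragments$start)
}

#' @export
print.DelineatedElement <- function(x, ...) {
  cat(sprintf("DelineatedElement %s: %d fragment(s), %s, %d bp, att %s\n",
              x$element_id, x$partite_count,
              ifelse(is.null(x$classification), "unclassified",
                     x$classification$mge_class),
              element_length(x), x$att_status))
  invisible(x)
}

# maximal equal extension of a repeat seeded at (s, o) with length len;
# allows up to max_mismatch interior mismatches, never emitting mismatches at
# the extremities. Returns c(start1, start2, length).
.extend_repeat <- function(text, s, o, len, max_mismatch = 0L) {
  n <- nchar(text)
  budget <- max_mismatch
  # right extension
  e1 <- s + len; e2 <- o + len
  pend1 <- e1; pend2 <- e2
  while (e2 < n && e1 < min(o, s + (o - s))) { # do not run copies into each other
    c1 <- substr(text, e1 + 1L, e1 + 1L)
    c2 <- substr(text, e2 + 1L, e2 + 1L)
    if (c1 == c2) { e1 <- e1 + 1L; e2 <- e2 + 1L; pend1 <- e1; pend2 <- e2 }
    else if (budget > 0L) { budget <- budget - 1L; e1 <- e1 + 1L; e2 <- e2 + 1L }
    else break
  }
  e1 <- pend1
  # left extension
  b1 <- s; b2 <- o
  pb1 <- b1; pb2 <- b2
  while (b1 > 0L && b2 > b1 + (e1 - b1)) {
    c1 <- substr(text, b1, b1)
    c2 <- substr(text, b2, b2)
    if (c1 == c2) { b1 <- b1 - 1L; b2 <- b2 - 1L; pb1 <- b1; pb2 <- b2 }
    else if (budget > 0L) { budget <- budget - 1L; b1 <- b1 - 1L; b2 <- b2 - 1L }
    else break
  }
  b1 <- pb1; b2 <- pb2
  c(b1, b2, e1 - b1)
}

#' Find att-site direct-repeat pairs around integration anchors
#'
#' For each anchor, a window of +/- `max_span` around the strand-aware 3' end
#' is scanned (both flanks) for a second same-strand occurrence of a
#' >= `min_core` substring abutting or overlapping the anchor 3' end. Repeats
#' are extended to maximal length; pairs are retained only when the enclosed
#' interval contains at least one seed locus. Per anchor the pair maximizing
#' (core length, enclosed seed count, shortest span) is reported.
#'
#' @param replicon a `Replicon`
#' @param anchors anchor table from [locate_anchors()] (rows for this replicon)
#' @param seeds integer positions of mobility-gene loci on this replicon
#' @param min_core minimum core length in bp (default 15)
#' @param max_span maximum distance scanned from the anchor (default 900000)
#' @param max_mismatch interior mismatch budget for the repeat (default 0)
#' @param slack bp by which a core may miss the exact anchor 3' end (default 10)
#' @return data.frame of `AttSitePair`s: replicon_id, attL_start, attL_end,
#'   attR_start, attR_end, core_seq, core_len, anchor_id, anchor_class,
#'   n_seeds, span; sorted by position
#' @export
find_att_pairs <- function(replicon, anchors, seeds, min_core = 15,
                           max_span = 900000, max_mismatch = 0L, slack = 10) {
  empty <- data.frame(replicon_id = character(), attL_start = integer(),
                      attL_end = integer(), attR_start = integer(),
                      attR_end = integer(), core_seq = character(),
                      core_len = integer(), anchor_id = character(),
                      anchor_class = character(), n_seeds = integer(),
                      span = integer(), stringsAsFactors = FALSE)
  anchors <- anchors[anchors$replicon_id == replicon$id, , drop = FALSE]
  if (!nrow(anchors)) return(empty)
  text <- replicon$sequence
  n <- nchar(text)
  subj <- Biostrings::DNAString(text)
  found <- list()
  for (i in seq_len(nrow(anchors))) {
    a <- anchors$pos3p[i]
    w0 <- max(0L, a - as.integer(max_span))
    w1 <- min(n, a + as.integer(max_span))
    if (replicon$topology == "linear" && (a - max_span < 0 || a + max_span > n)) {
      warning("anchor ", anchors$anchor_id[i],
              ": scan window truncated at linear replicon end")
    }
    starts <- seq(max(0L, a - as.integer(min_core) - as.integer(slack)),
                  min(n - as.integer(min_core), a + as.integer(slack)))
    cand <- list()
    for (s in starts) {
      probe <- substr(text, s + 1L, s + min_core)
      if (grepl("N", probe, fixed = TRUE)) next
      hits <- Biostrings::start(Biostrings::matchPattern(probe, subj[(w0 + 1):w1])) +
        w0 - 1L  # 0-based global starts
      for (o in hits) {
        if (abs(o - s) < min_core) next
        lo <- min(s, o); hi <- max(s, o)
        ext <- .extend_repeat(text, lo, hi, min_core, as.integer(max_mismatch))
        cand[[length(cand) + 1L]] <- ext
      }
    }
    if (!length(cand)) next
    cand <- unique(do.call(rbind, cand))
    for (k in seq_len(nrow(cand))) {
      b1 <- cand[k, 1]; b2 <- cand[k, 2]; len <- cand[k, 3]
      if (len < min_core) next
      # the anchor-side copy must abut/overlap the anchor 3' end
      d1 <- max(b1 - (a + slack), (a - slack) - (b1 + len), 0)
      d2 <- max(b2 - (a + slack), (a - slack) - (b2 + len), 0)
      if (min(d1, d2) > 0) next
      ns <- sum(seeds > b1 + len & seeds < b2)
      if (ns < 1L) next
      found[[length(found) + 1L]] <- data.frame(
        replicon_id = replicon$id, attL_start = b1, attL_end = b1 + len,
        attR_start = b2, attR_end = b2 + len,
        core_seq = substr(text, b1 + 1L, b1 + len), core_len = len,
        anchor_id = anchors$anchor_id[i],
        anchor_class = anchors$anchor_class[i],
        n_seeds = ns, span = b2 + len - b1, stringsAsFactors = FALSE)
    }
  }
  if (!length(found)) return(empty)
  pairs <- do.call(rbind, found)
  # best pair per anchor: (core length, seed count, shortest span)
  pairs <- pairs[order(pairs$anchor_id, -pairs$core_len, -pairs$n_seeds,
                       pairs$span, pairs$attL_start), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$anchor_id), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[, c("attL_start", "attR_start", "core_len")]), ,
                 drop = FALSE]
  pairs <- pairs[order(pairs$attL_start, pairs$attR_start), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# fragment table from a set of interleaved pairs: sorted core copies are
# tiled (1,2), (3,4), ... ; left/right labels are the owning pair indices
.fragments_from_pairs <- function(pairs) {
  cores <- rbind(
    data.frame(pos = pairs$attL_start, len = pairs$core_len,
               pair = seq_len(nrow(pairs)), stringsAsFactors = FALSE),
    data.frame(pos = pairs$attR_start, len = pairs$core_len,
               pair = seq_len(nrow(pairs)), stringsAsFactors = FALSE))
  cores <- cores[order(cores$pos), , drop = FALSE]
  n <- nrow(pairs)
  li <- seq(1L, 2L * n, by = 2L)
  data.frame(
    replicon_id = pairs$replicon_id[1],
    start = cores$pos[li], end = cores$pos[li + 1L] + cores$len[li + 1L],
    left_pair = cores$pair[li], right_pair = cores$pair[li + 1L],
    left_core_len = cores$len[li], right_core_len = cores$len[li + 1L],
    stringsAsFactors = FALSE)
}

# cycle order over fragments: successor of a fragment is the fragment whose
# left pair equals its right pair; errors unless this is a single cycle
.fragment_cycle <- function(fr) {
  n <- nrow(fr)
  succ <- integer(n)
  for (k in seq_len(n)) {
    j <- which(fr$left_pair == fr$right_pair[k])
    if (length(j) != 1L) stop("unresolvable multipartite structure")
    succ[k] <- j
  }
  start <- which.max(fr$end - fr$start)  # alpha fragment
  ord <- integer(n)
  cur <- start
  for (k in seq_len(n)) {
    ord[k] <- cur
    cur <- succ[cur]
  }
  if (cur != start || anyDuplicated(ord)) {
    stop("unresolvable multipartite structure")
  }
  ord
}

# circle = concatenation over the cycle of (fragment minus its right core)
.circle_from_fragments <- function(text, fr, ord) {
  paste(vapply(ord, function(k) {
    substr(text, fr$start[k] + 1L, fr$end[k] - fr$right_core_len[k])
  }, ""), collapse = "")
}

.core_family_letters <- c(intS = "S", intM = "M", intG = "G")

# family label for each pair from the nearest associated integrase inside the
# enclosed interval ("other" when none)
.assign_core_families <- function(pairs, genome, integrases) {
  fam <- rep("other", nrow(pairs))
  if (is.null(integrases) || !nrow(integrases)) return(fam)
  f <- genome$features
  m <- match(integrases$query_locus, f$locus_id)
  ipos <- (f$start[m] + f$end[m]) / 2
  irep <- f$replicon_id[m]
  for (k in seq_len(nrow(pairs))) {
    inside <- which(irep == pairs$replicon_id[k] &
                      ipos > pairs$attL_end[k] & ipos < pairs$attR_start[k])
    if (!length(inside)) next
    d <- pmin(abs(ipos[inside] - pairs$attL_end[k]),
              abs(pairs$attR_start[k] - ipos[inside]))
    best <- inside[which.min(d)]
    ifam <- integrases$int_family[best]
    if (ifam %in% names(.core_family_letters)) {
      fam[k] <- .core_family_letters[[ifam]]
    }
  }
  fam
}

.element_feature_loci <- function(genome, fragments) {
  f <- genome$features
  keep <- rep(FALSE, nrow(f))
  for (k in seq_len(nrow(fragments))) {
    keep <- keep | (f$replicon_id == fragments$replicon_id[k] &
                      f$start >= fragments$start[k] &
                      f$end <= fragments$end[k])
  }
  f$locus_id[keep]
}

#' Delineate a monopartite element from one att-site pair
#'
#' The fragment runs from attL start to attR end; the circular form retains a
#' single core copy (the attP), so its length is fragment length minus core
#' length.
#'
#' @param pair one-row `AttSitePair` data.frame
#' @param genome a `GenomeRecord`
#' @param integrases optional [detect_integrases()] output (core family label)
#' @param element_id identifier for the element
#' @return a `DelineatedElement`
#' @export
delineate_monopartite <- function(pair, genome, integrases = NULL,
                                  element_id = "element") {
  stopifnot(nrow(pair) == 1L)
  rep <- genome$replicons[[pair$replicon_id]]
  frag_len <- pair$attR_end - pair$attL_start
  if (frag_len < 2L * pair$core_len) stop("fragment shorter than two cores")
  fam <- .assign_core_families(pair, genome, integrases)
  fragments <- data.frame(
    replicon_id = pair$replicon_id, start = pair$attL_start,
    end = pair$attR_end, role = "mono",
    left_core_family = fam, right_core_family = fam,
    left_core_len = pair$core_len, right_core_len = pair$core_len,
    anchor_class = pair$anchor_class, stringsAsFactors = FALSE)
  circle <- substr(rep$sequence, pair$attL_start + 1L,
                   pair$attR_end - pair$core_len)
  cores <- data.frame(core_seq = pair$core_seq, family = fam,
                      length = pair$core_len, stringsAsFactors = FALSE)
  new_element(element_id, genome$genome_id, fragments, 1L, circle, cores,
              pair$anchor_class, "resolved",
              .element_feature_loci(genome, fragments), pairs = pair)
}

#' Resolve a multipartite element from interleaved att-site pairs
#'
#' Sorted core copies are tiled into fragments; fragments join when one's
#' right core pair equals the next's left core pair, and must form a single
#' cycle. The circular form concatenates fragments along the cycle with each
#' shared core collapsed to one copy. Roles alpha/beta/gamma are assigned by
#' decreasing fragment size.
#'
#' @param pairs `AttSitePair` rows on one replicon (>= 1)
#' @param genome a `GenomeRecord`
#' @param integrases optional integrase calls for core-family labels
#' @param element_id identifier
#' @return a `DelineatedElement`
#' @export
resolve_multipartite <- function(pairs, genome, integrases = NULL,
                                 element_id = "element") {
  if (nrow(pairs) == 1L) {
    return(delineate_monopartite(pairs, genome, integrases, element_id))
  }
  stopifnot(length(unique(pairs$replicon_id)) == 1L)
  rep <- genome$replicons[[pairs$replicon_id[1]]]
  fr <- .fragments_from_pairs(pairs)
  if (any(fr$left_pair == fr$right_pair)) {
    stop("unresolvable multipartite structure")
  }
  ord <- .fragment_cycle(fr)
  n <- nrow(fr)
  roles <- character(n)
  greek <- c("alpha", "beta", "gamma", "delta", "epsilon")
  roles[order(fr$end - fr$start, decreasing = TRUE)] <-
    greek[seq_len(min(n, length(greek)))]
  fam <- .assign_core_families(pairs, genome, integrases)
  fragments <- data.frame(
    replicon_id = fr$replicon_id, start = fr$start, end = fr$end,
    role = roles,
    left_core_family = fam[fr$left_pair],
    right_core_family = fam[fr$right_pair],
    left_core_len = fr$left_core_len, right_core_len = fr$right_core_len,
    anchor_class = pairs$anchor_class[fr$left_pair],
    stringsAsFactors = FALSE)
  circle <- .circle_from_fragments(rep$sequence, fr, ord)
  cores <- data.frame(core_seq = pairs$core_seq, family = fam,
                      length = pairs$core_len, stringsAsFactors = FALSE)
  alpha <- ord[1]
  new_element(element_id, genome$genome_id, fragments, n, circle, cores,
              pairs$anchor_class[fr$left_pair[alpha]], "resolved",
              .element_feature_loci(genome, fragments), pairs = pairs)
}

#' Excise an element from its replicon
#'
#' String form of integrase-mediated excision: the element leaves as its
#' circular form (one core per former pair) and the replicon retains one core
#' copy per pair as the restored attB. Supported for monopartite and
#' tripartite elements in the conservative interleaved arrangement; for a
#' tripartite the two inter-fragment chromosomal gaps swap order in the scar,
#' as sequential site-specific recombination dictates.
#'
#' @param el a resolved `DelineatedElement`
#' @param genome the `GenomeRecord` it was delineated from
#' @return list with `scar` (post-excision replicon sequence) and `circle`
#' @export
excise_element <- function(el, genome) {
  if (!identical(el$att_status, "resolved")) stop("element has no att sites")
  text <- genome$replicons[[el$replicon_id]]$sequence
  fr <- el$fragments
  n <- nrow(fr)
  if (n == 1L) {
    scar <- paste0(substr(text, 1L, fr$start + fr$left_core_len),
                   substr(text, fr$end + 1L, nchar(text)))
    return(list(scar = scar, circle = el$circular_sequence))
  }
  if (n != 3L) stop("excision closed form supports 1 or 3 fragments")
  pr <- .fragments_from_pairs(el$pairs)
  .fragment_cycle(pr)  # validates the join graph
  if (.succ_of(pr, 1L) != 3L) stop("non-conservative tripartite arrangement")
  g1 <- substr(text, pr$end[1] + 1L, pr$start[2])
  g2 <- substr(text, pr$end[2] + 1L, pr$start[3])
  u1 <- substr(text, pr$start[1] + 1L, pr$start[1] + pr$left_core_len[1])
  u2 <- substr(text, pr$end[1] - pr$right_core_len[1] + 1L, pr$end[1])
  u3 <- substr(text, pr$start[2] + 1L, pr$start[2] + pr$left_core_len[2])
  scar <- paste0(substr(text, 1L, pr$start[1]), u1, g2, u2, g1, u3,
                 substr(text, pr$end[3] + 1L, nchar(text)))
  list(scar = scar, circle = el$circular_sequence)
}

.succ_of <- function(fr, k) {
  j <- which(fr$left_pair == fr$right_pair[k])
  if (length(j) != 1L) stop("unresolvable multipartite structure")
  j
}

#' Re-integrate an excised element into its scar replicon
#'
#' Inverse of [excise_element()]; byte-for-byte reconstruction of the original
#' replicon from the scar, the circular element, and the element record's
#' fragment structure.
#'
#' @param scar post-excision replicon sequence
#' @param el the `DelineatedElement` (carrying original coordinates)
#' @return the reconstructed replicon sequence
#' @export
integrate_element <- function(scar, el) {
  fr <- el$fragments
  n <- nrow(fr)
  circle <- el$circular_sequence
  if (n == 1L) {
    s1 <- fr$start
    return(paste0(substr(scar, 1L, s1), circle, substr(scar, s1 + 1L, nchar(scar))))
  }
  if (n != 3L) stop("integration closed form supports 1 or 3 fragments")
  pr <- .fragments_from_pairs(el$pairs)
  ordc <- .fragment_cycle(pr)
  flens <- pr$end - pr$start
  # circle layout along the cycle: fragment minus its right core
  piece_len <- flens - pr$right_core_len
  off <- cumsum(c(0L, piece_len[ordc]))[seq_len(3L)]
  frag_of <- function(k) {
    i <- which(ordc == k)
    body <- substr(circle, off[i] + 1L, off[i] + piece_len[k])
    nxt <- ordc[(i %% 3L) + 1L]
    right_core <- substr(circle, off[which(ordc == nxt)] + 1L,
                         off[which(ordc == nxt)] + pr$right_core_len[k])
    paste0(body, right_core)
  }
  L <- substr(scar, 1L, pr$start[1])
  p <- pr$start[1]
  u1l <- pr$left_core_len[1]
  g2_len <- pr$start[3] - pr$end[2]
  g1_len <- pr$start[2] - pr$end[1]
  u2l <- pr$right_core_len[1]
  g2 <- substr(scar, p + u1l + 1L, p + u1l + g2_len)
  g1 <- substr(scar, p + u1l + g2_len + u2l + 1L, p + u1l + g2_len + u2l + g1_len)
  tail_start <- p + u1l + g2_len + u2l + g1_len + pr$left_core_len[2]
  R <- substr(scar, tail_start + 1L, nchar(scar))
  paste0(L, frag_of(1L), g1, frag_of(2L), g2, frag_of(3L), R)
}

#' Keep or flag a candidate region as an assembly artifact
#'
#' A candidate with plasmid-like replication genes (repABC) but no att-site
#' pair is flagged as a plasmid artificially joined to the chromosome during
#' assembly; att evidence always wins.
#'
#' @param el a `DelineatedElement` candidate
#' @param hits panel hits for the genome
#' @return "keep_as_element" or "flag_assembly_artifact"
#' @export
disambiguate_integrated_plasmid <- function(el, hits) {
  if (identical(el$att_status, "resolved")) return("keep_as_element")
  rep_hits <- hits[hits$role_label %in% c("repA", "repB", "repC", "Rep_3") &
                     hits$query_locus %in% el$feature_loci, , drop = FALSE]
  if (nrow(rep_hits)) "flag_assembly_artifact" else "keep_as_element"
}

#' Delineate all elements of a genome
#'
#' Runs [find_att_pairs()] over every replicon's anchors, groups pairs whose
#' spans interleave into multipartite candidates, delineates monopartite
#' candidates, and accepts candidates greedily by (core length, span) so that
#' overlapping weaker candidates are dropped. Seed clusters not covered by
#' any att-delineated element become `att_not_found` candidates, which are
#' then screened with [disambiguate_integrated_plasmid()]. Plasmid replicons
#' are emitted as whole-replicon elements.
#'
#' @param genome a `GenomeRecord`
#' @param anchors anchor table from [locate_anchors()]
#' @param hits panel hits from [search_panel()]
#' @param min_core,max_span,max_mismatch,slack see [find_att_pairs()]
#' @param unrecognized_window bp gap for clustering att-less seed loci
#' @return list of `DelineatedElement`s
#' @export
delineate_elements <- function(genome, anchors, hits, min_core = 15,
                               max_span = 900000, max_mismatch = 0L,
                               slack = 10, unrecognized_window = 20000) {
  integrases <- detect_integrases(hits)
  f <- genome$features
  bh <- best_hits(hits)
  seed_loci <- bh$query_locus[is_seed_role(bh$role_label)]
  sf <- f[f$locus_id %in% seed_loci, , drop = FALSE]
  elements <- list()
  for (rep in genome$replicons) {
    if (rep$source_class == "plasmid") next
    seeds <- (sf$start[sf$replicon_id == rep$id] +
                sf$end[sf$replicon_id == rep$id]) / 2
    seeds <- sort(seeds)
    pairs <- find_att_pairs(rep, anchors, seeds, min_core = min_core,
                            max_span = max_span, max_mismatch = max_mismatch,
                            slack = slack)
    if (!nrow(pairs)) next
    # group pairs whose spans overlap
    comp <- .interval_components(pairs$attL_start, pairs$attR_end)
    cands <- list()
    for (cc in unique(comp)) {
      sub <- pairs[comp == cc, , drop = FALSE]
      el <- tryCatch(
        resolve_multipartite(sub, genome, integrases),
        error = function(e) NULL)
      if (!is.null(el)) {
        cands[[length(cands) + 1L]] <- el
      } else {
        for (k in seq_len(nrow(sub))) {
          el1 <- tryCatch(
            delineate_monopartite(sub[k, , drop = FALSE], genome, integrases),
            error = function(e) NULL)
          if (!is.null(el1)) cands[[length(cands) + 1L]] <- el1
        }
      }
    }
    if (!length(cands)) next
    # greedy acceptance: longest core first, then shortest span
    key <- vapply(cands, function(e) {
      c(max(e$attP_cores$length), sum(e$fragments$end - e$fragments$start))
    }, numeric(2))
    ordc <- order(-key[1, ], key[2, ])
    taken <- matrix(numeric(0), ncol = 2)
    for (ci in ordc) {
      fr <- cands[[ci]]$fragments
      clash <- FALSE
      if (nrow(taken)) {
        for (k in seq_len(nrow(fr))) {
          if (any(fr$start[k] < taken[, 2] & fr$end[k] > taken[, 1])) clash <- TRUE
        }
      }
      if (clash) next
      taken <- rbind(taken, cbind(fr$start, fr$end))
      elements[[length(elements) + 1L]] <- cands[[ci]]
    }
  }
  # seed clusters not covered by any accepted element -> att_not_found
  covered <- function(repid, pos) {
    any(vapply(elements, function(e) {
      any(e$fragments$replicon_id == repid & e$fragments$start <= pos &
            e$fragments$end >= pos)
    }, TRUE))
  }
  for (rep in genome$replicons) {
    if (rep$source_class == "plasmid") next
    sr <- sf[sf$replicon_id == rep$id, , drop = FALSE]
    if (!nrow(sr)) next
    sr <- sr[order(sr$start), , drop = FALSE]
    mid <- (sr$start + sr$end) / 2
    free <- !vapply(seq_len(nrow(sr)), function(i) covered(rep$id, mid[i]), TRUE)
    sr <- sr[free, , drop = FALSE]
    if (!nrow(sr)) next
    grp <- cumsum(c(1L, as.integer(
      sr$start[-1L] - sr$end[-nrow(sr)] > unrecognized_window)))
    hf <- f[f$locus_id %in% bh$query_locus & f$replicon_id == rep$id, ,
            drop = FALSE]
    for (gg in unique(grp)) {
      ss <- sr[grp == gg, , drop = FALSE]
      ext0 <- min(ss$start)
      ext1 <- max(ss$end)
      # pull in flanking panel-hit loci (e.g. repABC replication genes) that
      # belong to the same unrecognised region
      near <- hf[hf$end > ext0 - unrecognized_window &
                   hf$start < ext1 + unrecognized_window, , drop = FALSE]
      near <- near[!vapply(seq_len(nrow(near)), function(i) {
        covered(rep$id, (near$start[i] + near$end[i]) / 2)
      }, TRUE), , drop = FALSE]
      if (nrow(near)) {
        ext0 <- min(ext0, min(near$start))
        ext1 <- max(ext1, max(near$end))
      }
      fragments <- data.frame(
        replicon_id = rep$id, start = ext0, end = ext1,
        role = "mono", left_core_family = NA_character_,
        right_core_family = NA_character_, left_core_len = NA_integer_,
        right_core_len = NA_integer_, anchor_class = NA_character_,
        stringsAsFactors = FALSE)
      el <- new_element("cand", genome$genome_id, fragments, 1L, NA_character_,
                        data.frame(core_seq = character(), family = character(),
                                   length = integer()),
                        NA_character_, "att_not_found",
                        .element_feature_loci(genome, fragments))
      el$artifact_flag <-
        disambiguate_integrated_plasmid(el, hits) == "flag_assembly_artifact"
      elements[[length(elements) + 1L]] <- el
    }
  }
  # plasmid replicons as whole-replicon elements
  for (rep in genome$replicons) {
    if (rep$source_class != "plasmid") next
    fragments <- data.frame(
      replicon_id = rep$id, start = 0L, end = nchar(rep$sequence),
      role = "mono", left_core_family = NA_character_,
      right_core_family = NA_character_, left_core_len = NA_integer_,
      right_core_len = NA_integer_, anchor_class = NA_character_,
      stringsAsFactors = FALSE)
    elements[[length(elements) + 1L]] <-
      new_element("cand", genome$genome_id, fragments, 1L, rep$sequence,
                  data.frame(core_seq = character(), family = character(),
                             length = integer()),
                  NA_character_, "plasmid",
                  .element_feature_loci(genome, fragments))
  }
  if (!length(elements)) return(elements)
  ord <- order(vapply(elements, function(e) e$replicon_id, ""),
               vapply(elements, function(e) e$fragments$start[1], 0))
  elements <- elements[ord]
  for (k in seq_along(elements)) {
    elements[[k]]$element_id <- sprintf("%s.E%02d", genome$genome_id, k)
  }
  elements
}

# connected components of overlapping intervals (simple sweep)
.interval_components <- function(starts, ends) {
  n <- length(starts)
  comp <- seq_len(n)
  ord <- order(starts)
  cur_end <- -Inf
  cur_comp <- 0L
  for (i in ord) {
    if (starts[i] > cur_end) {
      cur_comp <- i
      cur_end <- ends[i]
    } else {
      cur_end <- max(cur_end, ends[i])
    }
    comp[i] <- cur_comp
  }
  comp
}
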