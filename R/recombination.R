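# Alignment-free recombination detection: per-position longest-match
# profiles against a subject (both strands), window p-values under an
# explicit null (seeded subject-shuffle permutation by default, analytic
# geometric-tail approximation as the fast option), maximal significant
# segments, the directed gene-flux network, and chimaera painting.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.shuffle_seq <- function(seq) {
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

#' Longest-match profile of a query against a subject
#'
#' For each query position i, the length of the longest substring starting at
#' i that occurs anywhere in the subject (by default including its reverse
#' complement). Computed with a suffix automaton; equals the naive scan.
#'
#' @param query,subject nucleotide strings (or `Replicon`s)
#' @param both_strands index the subject's reverse complement too (default TRUE)
#' @return integer vector of length nchar(query)
#' @export
match_length_profile <- function(query, subject, both_strands = TRUE) {
  q <- if (inherits(query, "Replicon")) query$sequence else query
  s <- if (inherits(subject, "Replicon")) subject$sequence else subject
  stopifnot(nzchar(q), nzchar(s))
  text <- if (both_strands) paste0(s, "|", .revcomp(s)) else s
  cpp_match_profile(q, text)
}

# tiling windows; a short tail (< window/2) is merged into the last window
.window_bounds <- function(n, window) {
  if (window > n) {
    warning("window longer than query; using a single whole-query window")
    return(data.frame(start = 0L, end = n))
  }
  k <- n %/% window
  starts <- (seq_len(k) - 1L) * window
  ends <- starts + window
  if (n - ends[k] >= window / 2) {
    starts <- c(starts, ends[k])
    ends <- c(ends, n)
  } else {
    ends[k] <- n
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

# analytic null: match lengths against an i.i.d. sequence of the indexed
# text's length and composition; per-position P(L >= l) = 1-(1-q^l)^m with
# q = sum of squared base frequencies. The window mean is treated as normal
# with an effective sample size of window/(mu+1) (adjacent positions within
# one match run are dependent). An approximation; the permutation null is
# exactly calibrated.
.analytic_window_p <- function(obs_means, window_len, subject, both_strands) {
  comp <- table(strsplit(subject, "")[[1]])
  comp <- comp[names(comp) %in% c("A", "C", "G", "T")]
  p <- comp / sum(comp)
  q <- if (both_strands) sum(p^2) else sum(p^2)  # rc preserves composition q
  m_eff <- (1 + both_strands) * nchar(subject)
  lmax <- 200L
  surv <- 1 - (1 - q^(0:lmax))^m_eff
  pmf <- -diff(c(surv, 0))
  mu <- sum((0:lmax) * pmf)
  sig2 <- sum(((0:lmax) - mu)^2 * pmf)
  n_eff <- pmax(1, window_len / (mu + 1))
  stats::pnorm(obs_means, mean = mu, sd = sqrt(sig2 / n_eff),
               lower.tail = FALSE)
}

#' Call homologous segments from a longest-match profile
#'
#' The query is tiled into windows (default 1000 bp); each window's mean
#' match length is assigned a p-value under the chosen null, and windows with
#' p < alpha are merged into maximal segments.
#'
#' @param query,subject nucleotide strings
#' @param window window size in bp (default 1000)
#' @param alpha significance level (default 0.05)
#' @param null "permutation" (seeded subject shuffles; exactly calibrated) or
#'   "analytic" (geometric-tail normal approximation)
#' @param n_perm permutations (default 99)
#' @param seed RNG seed for the permutation null
#' @param both_strands index the subject's reverse complement (default TRUE)
#' @param profile optional precomputed observed profile
#' @param perm_texts optional precomputed shuffled subjects (character vector)
#' @param drop_windows optional integer window indices to exclude (masking)
#' @return list with `segments` (start, end, additive, min_p) and `windows`
#'   (start, end, mean_match, p)
#' @export
call_homologous_segments <- function(query, subject, window = 1000,
                                     alpha = 0.05,
                                     null = c("permutation", "analytic"),
                                     n_perm = 99, seed = 1,
                                     both_strands = TRUE, profile = NULL,
                                     perm_texts = NULL, drop_windows = NULL) {
  null <- match.arg(null)
  q <- if (inherits(query, "Replicon")) query$sequence else query
  s <- if (inherits(subject, "Replicon")) subject$sequence else subject
  if (is.null(profile)) profile <- match_length_profile(q, s, both_strands)
  n <- length(profile)
  wb <- .window_bounds(n, window)
  obs <- vapply(seq_len(nrow(wb)), function(i) {
    mean(profile[(wb$start[i] + 1L):wb$end[i]])
  }, 0)
  if (null == "analytic") {
    pvals <- .analytic_window_p(obs, wb$end - wb$start, s, both_strands)
  } else {
    if (is.null(perm_texts)) {
      perm_texts <- .with_seed(seed, replicate(n_perm, .shuffle_seq(s)))
    }
    n_perm <- length(perm_texts)
    exceed <- numeric(nrow(wb))
    for (b in seq_len(n_perm)) {
      pb <- match_length_profile(q, perm_texts[b], both_strands)
      pm <- vapply(seq_len(nrow(wb)), function(i) {
        mean(pb[(wb$start[i] + 1L):wb$end[i]])
      }, 0)
      exceed <- exceed + (pm >= obs)
    }
    pvals <- (1 + exceed) / (n_perm + 1)
  }
  windows <- data.frame(start = wb$start, end = wb$end, mean_match = obs,
                        p = pvals)
  sig <- pvals < alpha
  if (!is.null(drop_windows)) sig[drop_windows] <- FALSE
  segments <- data.frame(start = integer(), end = integer(),
                         additive = integer(), min_p = numeric(),
                         n_windows = integer())
  if (any(sig)) {
    r <- rle(sig)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    keep <- which(r$values)
    segments <- do.call(rbind, lapply(keep, function(k) {
      i0 <- idx_start[k]; i1 <- idx_end[k]
      data.frame(start = wb$start[i0], end = wb$end[i1],
                 additive = wb$end[i1] - wb$start[i0],
                 min_p = min(pvals[i0:i1]), n_windows = i1 - i0 + 1L)
    }))
  }
  list(segments = segments, windows = windows)
}

#' Build the directed recombination network over a set of elements
#'
#' One directed edge per ordered element pair with supporting homologous
#' segments; edge weight is the additive length of homologous sequence and
#' its fraction of the query. Since isolated single-window calls arise at
#' the null rate alpha by construction, an edge requires at least one
#' segment of `min_sig_windows` consecutive significant windows (default 2);
#' weaker single-window segments remain visible in the segment table.
#' Backbone regions of the query can be excluded (`mask_mode = "exclude"`)
#' or the analysis restricted to them (`mask_mode = "restrict"`); windows
#' overlapping a mask interval are dropped or retained accordingly.
#'
#' @param seqs named character vector of element (circle) sequences
#' @param window,alpha,null,n_perm,seed see [call_homologous_segments()]
#' @param mask optional named list: per element, data.frame(start, end) of
#'   query intervals (0-based half-open), e.g. backbone gene regions
#' @param mask_mode "none", "exclude" or "restrict"
#' @param min_sig_windows consecutive significant windows needed for edge
#'   support (default 2)
#' @return list with `edges` (from, to, additive, fraction, n_segments) and
#'   `segments` (per-pair segment table)
#' @export
build_network <- function(seqs, window = 1000, alpha = 0.05,
                          null = c("permutation", "analytic"), n_perm = 99,
                          seed = 1, mask = NULL,
                          mask_mode = c("none", "exclude", "restrict"),
                          min_sig_windows = 2L) {
  null <- match.arg(null)
  mask_mode <- match.arg(mask_mode)
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  ids <- sort(names(seqs))
  perm_cache <- list()
  edges <- list()
  seg_all <- list()
  for (s_id in ids) {
    if (null == "permutation") {
      perm_cache[[s_id]] <- .with_seed(
        seed + match(s_id, ids),
        replicate(n_perm, .shuffle_seq(seqs[[s_id]])))
    }
    for (q_id in ids) {
      if (q_id == s_id) next
      q <- seqs[[q_id]]
      wb <- .window_bounds(nchar(q), window)
      drop <- NULL
      if (mask_mode != "none" && !is.null(mask[[q_id]])) {
        mi <- mask[[q_id]]
        overl <- vapply(seq_len(nrow(wb)), function(i) {
          any(mi$start < wb$end[i] & mi$end > wb$start[i])
        }, TRUE)
        drop <- if (mask_mode == "exclude") which(overl) else which(!overl)
      }
      res <- call_homologous_segments(
        q, seqs[[s_id]], window = window, alpha = alpha, null = null,
        n_perm = n_perm, seed = seed, perm_texts = perm_cache[[s_id]],
        drop_windows = drop)
      strong <- res$segments[res$segments$n_windows >= min_sig_windows, ,
                             drop = FALSE]
      if (nrow(strong)) {
        add <- sum(strong$additive)
        edges[[length(edges) + 1L]] <- data.frame(
          from = q_id, to = s_id, additive = add,
          fraction = add / nchar(q), n_segments = nrow(strong),
          stringsAsFactors = FALSE)
        seg <- strong
        seg$from <- q_id
        seg$to <- s_id
        seg_all[[length(seg_all) + 1L]] <- seg
      }
    }
  }
  list(
    edges = if (length(edges)) do.call(rbind, edges) else
      data.frame(from = character(), to = character(), additive = integer(),
                 fraction = numeric(), n_segments = integer()),
    segments = if (length(seg_all)) do.call(rbind, seg_all) else
      data.frame(start = integer(), end = integer(), additive = integer(),
                 min_p = numeric(), n_windows = integer(),
                 from = character(), to = character())
  )
}

#' Write a network edge list as TSV and SIF
#' @param network result of [build_network()]
#' @param out_prefix path prefix (`.tsv` and `.sif` are appended)
#' @return invisibly, the file paths
#' @export
write_network <- function(network, out_prefix) {
  tsv <- paste0(out_prefix, ".tsv")
  sif <- paste0(out_prefix, ".sif")
  utils::write.table(network$edges, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("%s recombination %s", network$edges$from,
                     network$edges$to), sif)
  invisible(c(tsv = tsv, sif = sif))
}

#' Paint a query element by its closest donor per region
#'
#' The query is tiled into windows; each window is assigned the donor of
#' highest local identity (exact ties broken lexicographically and flagged),
#' and runs of windows with the same best donor are merged into regions with
#' breakpoints where the best donor switches.
#'
#' @param query nucleotide string
#' @param donors named character vector (>= 2 donors)
#' @param window window size in bp (default 1000)
#' @return data.frame: start, end, donor, mean_identity, tie
#' @export
chimaera_painting <- function(query, donors, window = 1000) {
  stopifnot(length(donors) >= 2L, !is.null(names(donors)))
  donors <- donors[order(names(donors))]
  q <- if (inherits(query, "Replicon")) query$sequence else query
  wb <- .window_bounds(nchar(q), window)
  subj <- lapply(donors, function(s) {
    list(fwd = list(text = s, dna = Biostrings::DNAString(s)),
         rev = list(text = .revcomp(s),
                    dna = Biostrings::DNAString(.revcomp(s))))
  })
  n_w <- nrow(wb)
  idmat <- matrix(NA_real_, n_w, length(donors),
                  dimnames = list(NULL, names(donors)))
  for (i in seq_len(n_w)) {
    frag <- substr(q, wb$start[i] + 1L, wb$end[i])
    for (d in names(donors)) {
      idmat[i, d] <- .best_fragment_identity(frag, subj[[d]]$fwd, subj[[d]]$rev)
    }
  }
  idmat[is.na(idmat)] <- 0
  best <- colnames(idmat)[apply(idmat, 1, which.max)]
  tie <- apply(idmat, 1, function(v) sum(v == max(v)) > 1L)
  r <- rle(best)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  out <- do.call(rbind, lapply(seq_along(r$values), function(k) {
    rows <- idx_start[k]:idx_end[k]
    data.frame(start = wb$start[idx_start[k]], end = wb$end[idx_end[k]],
               donor = r$values[k],
               mean_identity = mean(idmat[cbind(rows, match(r$values[k], colnames(idmat)))]),
               tie = any(tie[rows]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write homologous segments as BED (0-based half-open)
#' @param segments segment table with from/to/start/end columns
#' @param path output file
#' @return invisibly the path
#' @export
write_segments_bed <- function(segments, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", segments$from, segments$start,
                   segments$end, segments$to)
  writeLines(lines, path)
  invisible(path)
}
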