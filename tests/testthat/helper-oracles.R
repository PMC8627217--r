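# Independent oracles used across the suite. These deliberately use different
# algorithms/machinery from the package implementation: R's fixed-string
# search, plain dynamic programming, literal molecule-level recombination.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mut_nt <- function(s, d) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), round(d * length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# naive longest-match profile: per start position, binary search over match
# length using R's fixed-string search (prefix occurrence is monotone)
naive_profile <- function(q, s, both = TRUE) {
  text <- if (both) paste0(s, "|", rc(s)) else s
  n <- nchar(q)
  vapply(seq_len(n), function(i) {
    lo <- 0L
    hi <- n - i + 1L
    while (lo < hi) {
      mid <- (lo + hi + 1L) %/% 2L
      if (grepl(substr(q, i, i + mid - 1L), text, fixed = TRUE)) {
        lo <- mid
      } else {
        hi <- mid - 1L
      }
    }
    lo
  }, 0L)
}

# plain Gotoh local-alignment score (BLOSUM62, gap open 11 extend 1)
sw_score <- function(a, b) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - 12, X[i - 1, j] - 1)
      Y[i, j] <- max(M[i, j - 1] - 12, Y[i, j - 1] - 1)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
                       mat[A[i - 1], B[j - 1]])
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# literal sequential site-specific recombination on a molecule set: for each
# core (a direct repeat present in exactly two copies), recombine its two
# copies -- excising, splitting, fusing or integrating molecules as dictated
# by where the copies sit. Returns the final molecules.
oracle_splice <- function(text, cores) {
  mols <- list(list(seq = text, circ = FALSE))
  cyc <- function(s, from, len) {  # 1-based cyclic substring
    d <- paste0(s, s)
    substr(d, from, from + len - 1L)
  }
  for (u in cores) {
    lu <- nchar(u)
    occ <- list()
    for (mi in seq_along(mols)) {
      s <- mols[[mi]]$seq
      search <- if (mols[[mi]]$circ) paste0(s, substr(s, 1, lu - 1L)) else s
      g <- gregexpr(u, search, fixed = TRUE)[[1]]
      if (g[1] != -1) for (p in g) occ[[length(occ) + 1L]] <- c(mi, p)
    }
    stopifnot(length(occ) == 2L)
    m1 <- occ[[1]][1]; p1 <- occ[[1]][2]
    m2 <- occ[[2]][1]; p2 <- occ[[2]][2]
    if (m1 == m2) {
      mol <- mols[[m1]]
      s <- mol$seq
      if (!mol$circ) {
        scar <- paste0(substr(s, 1, p1 - 1L), substr(s, p2, nchar(s)))
        circ <- substr(s, p1, p2 - 1L)
        mols[[m1]] <- list(seq = scar, circ = FALSE)
        mols[[length(mols) + 1L]] <- list(seq = circ, circ = TRUE)
      } else {
        n <- nchar(s)
        c1 <- cyc(s, p1, (p2 - p1) %% n)
        c2 <- cyc(s, p2, (p1 - p2) %% n)
        mols[[m1]] <- list(seq = c1, circ = TRUE)
        mols[[length(mols) + 1L]] <- list(seq = c2, circ = TRUE)
      }
    } else {
      a <- mols[[m1]]; b <- mols[[m2]]
      if (a$circ && !b$circ) { tmp <- a; a <- b; b <- tmp
                               tp <- p1; p1 <- p2; p2 <- tp }
      if (!a$circ && b$circ) {
        ins <- cyc(b$seq, p2, nchar(b$seq))  # opened at its core
        merged <- paste0(substr(a$seq, 1, p1 - 1L), ins,
                         substr(a$seq, p1, nchar(a$seq)))
        keep <- setdiff(seq_along(mols), c(m1, m2))
        mols <- c(mols[keep], list(list(seq = merged, circ = FALSE)))
      } else if (a$circ && b$circ) {
        ins <- cyc(b$seq, p2, nchar(b$seq))
        ra <- cyc(a$seq, p1, nchar(a$seq))
        merged <- paste0(ra, ins)
        keep <- setdiff(seq_along(mols), c(m1, m2))
        mols <- c(mols[keep], list(list(seq = merged, circ = TRUE)))
      } else {
        stop("two linear molecules cannot recombine in this oracle")
      }
    }
  }
  mols
}

same_circle <- function(c1, c2) {
  nchar(c1) == nchar(c2) && grepl(c1, paste0(c2, c2), fixed = TRUE)
}

# random monopartite case: returns text, element record inputs, truth
rand_mono_case <- function(core_len = 20L, inner = sample(1500:5000, 1L)) {
  u <- rand_dna(core_len)
  L <- rand_dna(sample(500:2000, 1L))
  mid <- rand_dna(inner)
  R <- rand_dna(sample(500:2000, 1L))
  text <- paste0(L, u, mid, u, R)
  list(text = text, core = u,
       attL_start = nchar(L), attR_start = nchar(L) + core_len + nchar(mid),
       core_len = core_len)
}

# random tripartite case in the conservative interleaved arrangement
rand_tri_case <- function(core_len = 20L) {
  u <- list(S = rand_dna(core_len), M = rand_dna(core_len),
            G = rand_dna(core_len))
  A <- rand_dna(sample(3000:6000, 1L))
  B <- rand_dna(sample(1500:3000, 1L))
  C <- rand_dna(sample(800:1500, 1L))
  g1 <- rand_dna(sample(500:1500, 1L))
  g2 <- rand_dna(sample(500:1500, 1L))
  L <- rand_dna(sample(500:1500, 1L))
  R <- rand_dna(sample(500:1500, 1L))
  text <- paste0(L, u$S, A, u$M, g1, u$G, C, u$S, g2, u$M, B, u$G, R)
  p <- nchar(L)
  s1 <- p
  m1 <- s1 + core_len + nchar(A)
  g1p <- m1 + core_len + nchar(g1)
  s2 <- g1p + core_len + nchar(C)
  m2 <- s2 + core_len + nchar(g2)
  g2p <- m2 + core_len + nchar(B)
  pairs <- data.frame(
    replicon_id = "chr",
    attL_start = c(s1, m1, g1p), attL_end = c(s1, m1, g1p) + core_len,
    attR_start = c(s2, m2, g2p), attR_end = c(s2, m2, g2p) + core_len,
    core_seq = c(u$S, u$M, u$G), core_len = core_len,
    anchor_id = c("aS", "aM", "aG"), anchor_class = c("tRNA-Met", "tRNA-Gly",
                                                      "tRNA-His"),
    n_seeds = 1L,
    span = c(s2, m2, g2p) + core_len - c(s1, m1, g1p),
    stringsAsFactors = FALSE)
  list(text = text, cores = u, pairs = pairs, core_len = core_len)
}

mini_genome <- function(text, id = "chr") {
  genome_record("toy", list(replicon(id, text)))
}

# exhaustive two-sided Fisher p by hypergeometric enumeration over all
# tables with the observed margins
enum_fisher_p <- function(a, b, c, d) {
  m1 <- a + b
  n1 <- a + c
  N <- a + b + c + d
  ks <- max(0, n1 - (N - m1)):min(m1, n1)
  logp <- lchoose(m1, ks) + lchoose(N - m1, n1 - ks) - lchoose(N, n1)
  p <- exp(logp)
  obs <- p[ks == a]
  sum(p[p <= obs * (1 + 1e-7)])
}
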