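# Local-alignment primitives shared by the homology engine and the pangenome
# module. Identity is defined as identities / alignment columns (gaps counted
# as columns) of the best local alignment: BLOSUM62 with gap open 11 / extend
# 1 for proteins, +1/-1 with linear gap -2 for nucleotide.

.aa_submat <- function() {
  if (is.null(.mobelem_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .mobelem_cache$blosum62 <- e$BLOSUM62
  }
  .mobelem_cache$blosum62
}

.nt_submat <- function() {
  if (is.null(.mobelem_cache$ntmat)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    .mobelem_cache$ntmat <- m
  }
  .mobelem_cache$ntmat
}

# Karlin-Altschul-style bit-score conversion; parameters for the two scoring
# schemes above. The e-value proxy is m*n*2^-bits -- a ranking statistic, not
# a database e-value.
.ka_params <- function(type) {
  if (type == "protein") c(lambda = 0.267, K = 0.041)
  else c(lambda = 1.28, K = 0.46)
}

.to_bits <- function(raw, type) {
  p <- .ka_params(type)
  (p[["lambda"]] * raw - log(p[["K"]])) / log(2)
}

#' Best local alignments of a set of queries against one subject
#'
#' @param queries named character vector of sequences
#' @param subject single sequence
#' @param type "protein" or "nucleotide"
#' @return data.frame: query, raw_score, score (bits), percent_identity,
#'   query_coverage, subject_coverage, evalue_proxy
#' @keywords internal
align_local_set <- function(queries, subject, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  stopifnot(length(subject) == 1L, !is.null(names(queries)))
  if (length(queries) == 0L) {
    return(data.frame(query = character(), raw_score = numeric(),
                      score = numeric(), percent_identity = numeric(),
                      query_coverage = numeric(), subject_coverage = numeric(),
                      evalue_proxy = numeric(), stringsAsFactors = FALSE))
  }
  if (type == "protein") {
    pat <- Biostrings::AAStringSet(queries)
    subj <- Biostrings::AAString(subject)
    aln <- Biostrings::pairwiseAlignment(
      pat, subj, type = "local", substitutionMatrix = .aa_submat(),
      gapOpening = 11, gapExtension = 1)
  } else {
    pat <- Biostrings::DNAStringSet(queries)
    subj <- Biostrings::DNAString(subject)
    aln <- Biostrings::pairwiseAlignment(
      pat, subj, type = "local", substitutionMatrix = .nt_submat(),
      gapOpening = 0, gapExtension = 2)
  }
  raw <- Biostrings::score(aln)
  # alignment columns incl. gaps: width of the gapped aligned pattern
  ncols <- nchar(as.character(Biostrings::pattern(aln)))
  nm <- Biostrings::nmatch(aln)
  qlen <- nchar(queries)
  slen <- nchar(subject)
  qspan <- IRanges::width(Biostrings::pattern(aln))
  sspan <- IRanges::width(Biostrings::subject(aln))
  bits <- .to_bits(raw, type)
  data.frame(
    query = names(queries),
    raw_score = raw,
    score = bits,
    percent_identity = ifelse(ncols > 0, 100 * nm / ncols, 0),
    query_coverage = qspan / qlen,
    subject_coverage = sspan / slen,
    evalue_proxy = qlen * slen * 2^(-bits),
    stringsAsFactors = FALSE
  )
}

#' Local-alignment identity between two sequences
#'
#' @param a,b sequences
#' @param type "protein" or "nucleotide"
#' @return percent identity of the best local alignment (0 if empty)
#' @export
pairwise_identity <- function(a, b, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  align_local_set(c(q = a), b, type)$percent_identity
}

# distinct k-mer sets for the shared-kmer prefilter
.kmer_set <- function(seq, k = 4L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Count shared distinct k-mers between one sequence and a set
#' @keywords internal
.shared_kmers <- function(query_kmers, subject_kmers) {
  sum(query_kmers %in% subject_kmers)
}
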