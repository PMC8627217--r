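# Genome input/output: a uniform coordinate model over replicons and
# annotated gene features. Internal coordinates are 0-based half-open;
# emitted GFF3 is 1-based inclusive.

#' Construct a replicon
#'
#' @param id replicon identifier (unique within a genome)
#' @param sequence nucleotide string (A/C/G/T/N)
#' @param topology "circular" or "linear"
#' @param source_class "chromosome", "plasmid" or "unplaced"
#' @return a `Replicon` list
#' @export
replicon <- function(id, sequence,
                     topology = c("circular", "linear"),
                     source_class = c("chromosome", "plasmid", "unplaced")) {
  topology <- match.arg(topology)
  source_class <- match.arg(source_class)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("replicon '", id, "': empty sequence")
  if (grepl("[^ACGTN]", sequence)) {
    warning("replicon '", id, "': non-ACGT residues kept as N")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  structure(list(id = id, sequence = sequence, topology = topology,
                 source_class = source_class), class = "Replicon")
}

#' Empty gene-feature table
#' @keywords internal
empty_features <- function() {
  data.frame(locus_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character(),
             kind = character(), product = character(), protein = character(),
             trna_isotype = character(), stringsAsFactors = FALSE)
}

#' Construct a genome record
#'
#' @param genome_id genome identifier
#' @param replicons list of [replicon()] objects
#' @param features data.frame with columns locus_id, replicon_id, start, end
#'   (0-based half-open), strand (+/-), kind (CDS/tRNA/other), product,
#'   protein (CDS), trna_isotype (tRNA)
#' @param host_metadata optional free-form list (e.g. legume host of isolation)
#' @return a `GenomeRecord`
#' @export
genome_record <- function(genome_id, replicons, features = empty_features(),
                          host_metadata = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  names(replicons) <- vapply(replicons, `[[`, "", "id")
  if (anyDuplicated(names(replicons))) stop("duplicate replicon ids")
  gr <- structure(list(genome_id = genome_id, replicons = replicons,
                       features = features, host_metadata = host_metadata),
                  class = "GenomeRecord")
  validate_genome_record(gr)
  gr
}

#' Validate a genome record's invariants
#' @param genome a `GenomeRecord`
#' @return the record, invisibly; errors on violation
#' @export
validate_genome_record <- function(genome) {
  f <- genome$features
  if (nrow(f)) {
    missing_rep <- setdiff(unique(f$replicon_id), names(genome$replicons))
    if (length(missing_rep)) {
      stop("features reference unknown replicon(s): ",
           paste(missing_rep, collapse = ", "))
    }
    lens <- vapply(genome$replicons, function(r) nchar(r$sequence), 0L)
    bad <- f$start < 0L | f$start >= f$end | f$end > lens[f$replicon_id]
    if (any(bad)) {
      stop("feature(s) out of replicon bounds: ",
           paste(f$locus_id[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
    }
    if (anyDuplicated(f$locus_id)) stop("duplicate locus ids")
    cds <- f$kind == "CDS"
    if (any(cds & (is.na(f$protein) | !nzchar(f$protein)))) {
      stop("CDS feature(s) without protein sequence")
    }
    trna <- f$kind == "tRNA"
    if (any(trna & (is.na(f$trna_isotype) | !nzchar(f$trna_isotype)))) {
      stop("tRNA feature(s) without isotype")
    }
  }
  invisible(genome)
}

#' @export
print.GenomeRecord <- function(x, ...) {
  lens <- vapply(x$replicons, function(r) nchar(r$sequence), 0L)
  cat("GenomeRecord", x$genome_id, "--", length(x$replicons), "replicon(s),",
      sum(lens), "bp,", nrow(x$features), "feature(s)\n")
  invisible(x)
}

# FASTA description tags of the form [topology=circular] [class=plasmid]
.parse_fasta_tags <- function(desc) {
  get <- function(tag, default) {
    m <- regmatches(desc, regexec(paste0("\\[", tag, "=([^]]+)\\]"), desc))[[1]]
    if (length(m) == 2L) m[2] else default
  }
  list(topology = get("topology", "circular"),
       source_class = get("class", "chromosome"))
}

#' Read a genome from FASTA plus GenBank or GFF3 annotation
#'
#' GFF3 mode requires a protein FASTA keyed by locus id (CDS translations are
#' taken from annotation, never re-predicted). FASTA descriptions may carry
#' `[topology=...]` and `[class=...]` tags naming replicon topology and
#' source class; defaults are circular chromosome.
#'
#' @param nucleotide_file replicon FASTA
#' @param annotation_file GenBank flat file or GFF3
#' @param protein_file protein FASTA (required with GFF3 annotation)
#' @param genome_id genome identifier; defaults to the annotation file stem
#' @return a `GenomeRecord`
#' @export
read_genome <- function(nucleotide_file, annotation_file, protein_file = NULL,
                        genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(annotation_file))
  }
  dna <- Biostrings::readDNAStringSet(nucleotide_file)
  ids <- vapply(strsplit(names(dna), "\\s+"), `[`, "", 1L)
  reps <- lapply(seq_along(dna), function(i) {
    tags <- .parse_fasta_tags(names(dna)[i])
    replicon(ids[i], as.character(dna[[i]]), topology = tags$topology,
             source_class = tags$source_class)
  })
  first <- readLines(annotation_file, n = 5L, warn = FALSE)
  if (any(grepl("^LOCUS", first))) {
    feats <- .read_genbank_features(annotation_file)
  } else {
    feats <- .read_gff3_features(annotation_file, protein_file)
  }
  genome_record(genome_id, reps, feats)
}

.isotype_from_product <- function(product) {
  m <- regmatches(product, regexec("tRNA-([A-Za-z]{3})", product))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

.read_gff3_features <- function(annotation_file, protein_file) {
  gff <- rtracklayer::import(annotation_file)
  type <- as.character(gff$type)
  keep <- type %in% c("CDS", "tRNA")
  gff <- gff[keep]
  type <- type[keep]
  if (!length(gff)) return(empty_features())
  meta <- S4Vectors::mcols(gff)
  locus <- if ("ID" %in% names(meta)) as.character(meta$ID) else NA_character_
  if ("locus_tag" %in% names(meta)) {
    lt <- as.character(meta$locus_tag)
    locus <- ifelse(is.na(locus), lt, locus)
  }
  if (anyNA(locus)) stop("GFF3 features must carry ID or locus_tag")
  product <- if ("product" %in% names(meta)) as.character(meta$product)
             else rep(NA_character_, length(gff))
  prot <- rep(NA_character_, length(gff))
  if (any(type == "CDS")) {
    if (is.null(protein_file)) {
      stop("GFF3 annotation requires a protein FASTA keyed by locus id")
    }
    aa <- Biostrings::readAAStringSet(protein_file)
    names(aa) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
    hit <- match(locus, names(aa))
    prot[type == "CDS"] <- as.character(aa)[hit[type == "CDS"]]
  }
  iso <- rep(NA_character_, length(gff))
  if ("isotype" %in% names(meta)) iso <- as.character(meta$isotype)
  need <- type == "tRNA" & is.na(iso)
  iso[need] <- .isotype_from_product(product[need])
  data.frame(
    locus_id = locus,
    replicon_id = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff) - 1L,   # 1-based inclusive -> 0-based half-open
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    kind = type,
    product = product,
    protein = prot,
    trna_isotype = iso,
    stringsAsFactors = FALSE
  )
}

# Minimal GenBank flat-file feature reader: CDS and tRNA features with simple
# `start..end` / `complement(start..end)` locations and /locus_tag, /product,
# /translation qualifiers. Compound (join) locations are not supported.
.read_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  locus_name <- NA_character_
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (grepl("^LOCUS", line)) {
      locus_name <- strsplit(trimws(sub("^LOCUS", "", line)), "\\s+")[[1]][1]
      i <- i + 1L
    } else if (grepl("^FEATURES", line)) {
      i <- i + 1L
      while (i <= n && !grepl("^(ORIGIN|CONTIG|//)", lines[i])) {
        if (grepl("^ {5}\\S", lines[i])) {
          key <- trimws(substr(lines[i], 6, 20))
          loc <- trimws(substr(lines[i], 21, nchar(lines[i])))
          quals <- character()
          i <- i + 1L
          while (i <= n && grepl("^ {21}", lines[i])) {
            quals <- c(quals, trimws(lines[i]))
            i <- i + 1L
          }
          if (key %in% c("CDS", "tRNA")) {
            qtxt <- paste(quals, collapse = " ")
            getq <- function(q) {
              m <- regmatches(qtxt, regexec(paste0("/", q, "=\"([^\"]*)\""), qtxt))[[1]]
              if (length(m) == 2L) m[2] else NA_character_
            }
            strand <- if (grepl("^complement", loc)) "-" else "+"
            nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
            if (length(nums) != 2L) {
              warning("skipping compound location: ", loc)
            } else {
              prot <- getq("translation")
              if (!is.na(prot)) prot <- gsub("\\s", "", prot)
              product <- getq("product")
              out[[length(out) + 1L]] <- data.frame(
                locus_id = getq("locus_tag"),
                replicon_id = locus_name,
                start = as.integer(nums[1]) - 1L,
                end = as.integer(nums[2]),
                strand = strand, kind = key,
                product = product, protein = prot,
                trna_isotype = .isotype_from_product(product),
                stringsAsFactors = FALSE)
            }
          }
        } else i <- i + 1L
      }
    } else i <- i + 1L
  }
  if (!length(out)) return(empty_features())
  do.call(rbind, out)
}

#' Write a genome record as FASTA + GFF3 + protein FASTA
#'
#' Writers produce deterministic ordering (replicon, then start coordinate).
#'
#' @param genome a `GenomeRecord`
#' @param out_prefix path prefix; writes `<prefix>.fna`, `<prefix>.gff3`,
#'   `<prefix>.faa`
#' @return invisibly, the three file paths
#' @export
write_genome <- function(genome, out_prefix) {
  fna <- paste0(out_prefix, ".fna")
  gff <- paste0(out_prefix, ".gff3")
  faa <- paste0(out_prefix, ".faa")
  hdr <- vapply(genome$replicons, function(r) {
    sprintf("%s [topology=%s] [class=%s]", r$id, r$topology, r$source_class)
  }, "")
  seqs <- Biostrings::DNAStringSet(vapply(genome$replicons, `[[`, "", "sequence"))
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, fna, width = 80L)

  f <- genome$features
  f <- f[order(f$replicon_id, f$start, f$locus_id), , drop = FALSE]
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  for (r in genome$replicons) {
    writeLines(sprintf("##sequence-region %s 1 %d", r$id, nchar(r$sequence)), con)
  }
  if (nrow(f)) {
    attrs <- sprintf("ID=%s", f$locus_id)
    has_prod <- !is.na(f$product) & nzchar(f$product)
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=", f$product[has_prod])
    has_iso <- !is.na(f$trna_isotype) & nzchar(f$trna_isotype)
    attrs[has_iso] <- paste0(attrs[has_iso], ";isotype=", f$trna_isotype[has_iso])
    writeLines(sprintf("%s\tmobelem\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                       f$replicon_id, f$kind, f$start + 1L, f$end, f$strand,
                       ifelse(f$kind == "CDS", "0", "."), attrs), con)
  }
  close(con)

  cds <- f[f$kind == "CDS", , drop = FALSE]
  aa <- Biostrings::AAStringSet(if (nrow(cds)) cds$protein else character())
  names(aa) <- cds$locus_id
  Biostrings::writeXStringSet(aa, faa, width = 80L)
  invisible(c(fna = fna, gff3 = gff, faa = faa))
}

#' Default anchor rules: tRNA isotypes and anchor protein genes
#'
#' The integration anchors observed for rhizobial ICEs/IMEs: a set of tRNA
#' genes plus the protein-coding genes guaA, radC and dusA.
#' @return list with elements `trna` (isotype labels) and `genes` (role labels)
#' @export
default_anchor_spec <- function() {
  list(trna = c("Phe", "Ser", "Met", "Arg", "Gly", "His", "Pro", "Asn",
                "Thr", "Trp", "Leu", "Val", "Ala"),
       genes = anchor_gene_roles())
}

#' Locate integration anchors and their strand-aware 3' ends
#'
#' tRNA anchors are matched by annotated isotype; protein anchors (guaA, radC,
#' dusA) by their best panel hit at >= 40% identity and >= 70% query coverage.
#' The 3'-end coordinate is the feature end on the + strand and the feature
#' start on the - strand (0-based).
#'
#' @param genome a `GenomeRecord`
#' @param anchor_spec as [default_anchor_spec()]
#' @param hits panel hits (from [search_panel()]); required if `anchor_spec`
#'   names protein anchor genes and the genome has CDS features
#' @return data.frame: anchor_id, replicon_id, locus_id, anchor_class, strand,
#'   pos3p; ordered by (replicon, position)
#' @export
locate_anchors <- function(genome, anchor_spec = default_anchor_spec(),
                           hits = NULL) {
  f <- genome$features
  res <- list()
  if (length(anchor_spec$trna) && nrow(f)) {
    tr <- f[f$kind == "tRNA" & f$trna_isotype %in% anchor_spec$trna, , drop = FALSE]
    if (nrow(tr)) {
      res$trna <- data.frame(
        replicon_id = tr$replicon_id, locus_id = tr$locus_id,
        anchor_class = paste0("tRNA-", tr$trna_isotype),
        strand = tr$strand,
        pos3p = ifelse(tr$strand == "+", tr$end, tr$start),
        stringsAsFactors = FALSE)
    }
  }
  if (length(anchor_spec$genes) && !is.null(hits) && nrow(hits)) {
    gh <- hits[hits$role_label %in% anchor_spec$genes &
                 hits$percent_identity >= 40 & hits$query_coverage >= 0.7, ,
               drop = FALSE]
    if (nrow(gh)) {
      gh <- gh[order(gh$query_locus, -gh$score), , drop = FALSE]
      gh <- gh[!duplicated(gh$query_locus), , drop = FALSE]
      m <- match(gh$query_locus, f$locus_id)
      res$genes <- data.frame(
        replicon_id = f$replicon_id[m], locus_id = gh$query_locus,
        anchor_class = gh$role_label,
        strand = f$strand[m],
        pos3p = ifelse(f$strand[m] == "+", f$end[m], f$start[m]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(anchor_id = character(), replicon_id = character(),
                      locus_id = character(), anchor_class = character(),
                      strand = character(), pos3p = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$replicon_id, out$pos3p, out$locus_id), , drop = FALSE]
  out$anchor_id <- sprintf("%s:%s:%d", out$anchor_class, out$replicon_id, out$pos3p)
  rownames(out) <- NULL
  out[, c("anchor_id", "replicon_id", "locus_id", "anchor_class", "strand",
          "pos3p")]
}

#' Write delineated elements as GFF3 + circle FASTA + summary TSV
#'
#' @param elements list of `DelineatedElement` objects (classification fields
#'   are used in the summary when present)
#' @param out_dir output directory (created if needed)
#' @param prefix file-name prefix
#' @return invisibly, the file paths
#' @export
write_element_outputs <- function(elements, out_dir, prefix = "elements") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(elements, `[[`, "", "element_id")
  if (anyDuplicated(ids)) stop("duplicate element ids")
  gff <- file.path(out_dir, paste0(prefix, ".gff3"))
  fas <- file.path(out_dir, paste0(prefix, ".fasta"))
  tsv <- file.path(out_dir, paste0(prefix, ".tsv"))

  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  for (el in elements) {
    fr <- el$fragments
    if (is.null(fr) || !nrow(fr)) next
    for (k in seq_len(nrow(fr))) {
      writeLines(sprintf(
        "%s\tmobelem\tmobile_genetic_element\t%d\t%d\t.\t+\t.\tID=%s_frag%d;Parent=%s;role=%s",
        fr$replicon_id[k], fr$start[k] + 1L, fr$end[k], el$element_id, k,
        el$element_id, fr$role[k]), con)
    }
    if (identical(el$att_status, "resolved")) {
      for (k in seq_len(nrow(fr))) {
        writeLines(sprintf(
          "%s\tmobelem\tattL\t%d\t%d\t.\t+\t.\tID=%s_attL%d;Parent=%s;core_family=%s",
          fr$replicon_id[k], fr$start[k] + 1L, fr$start[k] + fr$left_core_len[k],
          el$element_id, k, el$element_id, fr$left_core_family[k]), con)
        writeLines(sprintf(
          "%s\tmobelem\tattR\t%d\t%d\t.\t+\t.\tID=%s_attR%d;Parent=%s;core_family=%s",
          fr$replicon_id[k], fr$end[k] - fr$right_core_len[k] + 1L, fr$end[k],
          el$element_id, k, el$element_id, fr$right_core_family[k]), con)
      }
    }
  }
  close(con)

  circ <- !vapply(elements, function(e) is.na(e$circular_sequence[1]), TRUE)
  seqs <- Biostrings::DNAStringSet(vapply(elements[circ], `[[`, "", "circular_sequence"))
  names(seqs) <- vapply(elements[circ], function(e) {
    sprintf("%s|%d|%s", e$element_id, e$partite_count,
            ifelse(is.na(e$integration_site_label), "NA", e$integration_site_label))
  }, "")
  Biostrings::writeXStringSet(seqs, fas, width = 80L)

  summ <- do.call(rbind, lapply(elements, function(e) {
    data.frame(element_id = e$element_id,
               mge_class = if (!is.null(e$classification)) e$classification$mge_class else NA,
               length = element_length(e),
               integration_site = e$integration_site_label,
               partite_count = e$partite_count,
               is_ICESym = if (!is.null(e$classification)) e$classification$is_ICESym else NA,
               att_status = e$att_status,
               stringsAsFactors = FALSE)
  }))
  if (is.null(summ)) {
    summ <- data.frame(element_id = character(), mge_class = character(),
                       length = integer(), integration_site = character(),
                       partite_count = integer(), is_ICESym = logical(),
                       att_status = character())
  }
  utils::write.table(summ, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gff3 = gff, fasta = fas, tsv = tsv))
}
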