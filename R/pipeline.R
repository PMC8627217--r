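# Pipeline orchestration: configuration, staged execution
# (io -> homology -> delineate -> classify -> pangenome -> recombination),
# deterministic outputs, and evaluation against simulator truth.

#' Build a pipeline configuration
#'
#' Unknown keys are rejected; the effective configuration (defaults merged
#' with overrides) is echoed to the run log and stored in the result.
#'
#' @param ... overrides of the defaults listed below
#' @return a `PipelineConfig` list
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    genomes = NULL,          # list of GenomeRecord, or
    input_files = NULL,      # list of list(fna=, annot=, faa=)
    panel_path = NULL,       # default: bundled exemplar panel
    out_dir = NULL,
    seed = 1L,
    min_identity = 30, min_coverage = 0.6,
    bit_threshold = 33, locus_window = 10000,
    min_core = 15, max_span = 900000, max_mismatch = 0L, att_slack = 10,
    unrecognized_window = 20000,
    cluster_identity = 40, cluster_coverage = 0.5,
    backbone_prevalence = 0.95,
    run_ani = FALSE, ani_fragment = 1020, ani_max_fragments = 200,
    ani_cutoff = 95,
    run_recombination = TRUE, recomb_window = 1000, recomb_alpha = 0.05,
    recomb_null = "permutation", recomb_n_perm = 99,
    verbose = TRUE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "PipelineConfig"
  cfg
}

.log <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

#' Run the full element-delineation pipeline
#'
#' Stages: genome input, panel homology, att-site delineation, element
#' classification (with symbiosis flag and QS profiling), pangenome and
#' mobilome accounting (ortholog clustering, redundancy collapse, backbone,
#' accessory gene-content tree, optional ANI/genospecies), and the
#' recombination network over non-redundant element circles. All outputs are
#' reproducible from the configuration and inputs.
#'
#' @param config a `PipelineConfig` (see [pipeline_config()])
#' @return a `mobelem_run` list of stage results
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  .log(config, "effective config: ",
       paste(names(config), vapply(config, function(v) {
         if (is.null(v)) "NULL" else if (is.list(v)) paste0("<", length(v), ">")
         else paste(format(v), collapse = ",")
       }, ""), sep = "=", collapse = "; "))

  # --- stage io ---
  genomes <- config$genomes
  if (is.null(genomes)) {
    if (is.null(config$input_files)) stop("no genomes or input files given")
    genomes <- lapply(config$input_files, function(x) {
      read_genome(x$fna, x$annot, x$faa)
    })
    names(genomes) <- vapply(genomes, `[[`, "", "genome_id")
  }
  panel <- if (is.null(config$panel_path)) default_reference_panel()
           else read_reference_panel(config$panel_path)
  .log(config, "io: ", length(genomes), " genome(s), panel of ", nrow(panel),
       " exemplars")

  # --- stage homology ---
  proteins <- unlist(lapply(genomes, .as_protein_set))
  prot_names <- unlist(lapply(genomes, function(g) {
    f <- g$features[g$features$kind == "CDS", ]
    f$locus_id
  }), use.names = FALSE)
  names(proteins) <- prot_names
  hits <- search_panel(proteins, panel, config$min_identity,
                       config$min_coverage)
  relaxases <- classify_relaxases(hits, bit_threshold = config$bit_threshold)
  integrases <- detect_integrases(hits)
  clusters_conj <- do.call(rbind, lapply(genomes, function(g) {
    cc <- detect_conjugation_clusters(g, hits, config$locus_window)
    if (nrow(cc)) cc$genome_id <- g$genome_id
    cc
  }))
  .log(config, "homology: ", nrow(hits), " hits, ", nrow(relaxases),
       " relaxases, ", nrow(integrases), " integrases, ",
       if (is.null(clusters_conj)) 0 else nrow(clusters_conj),
       " conjugation clusters")

  # --- stage delineate ---
  elements <- list()
  anchors_all <- list()
  for (g in genomes) {
    ghits <- hits[hits$query_locus %in% g$features$locus_id, , drop = FALSE]
    anch <- locate_anchors(g, default_anchor_spec(), ghits)
    anchors_all[[g$genome_id]] <- anch
    els <- delineate_elements(g, anch, ghits, min_core = config$min_core,
                              max_span = config$max_span,
                              max_mismatch = config$max_mismatch,
                              slack = config$att_slack,
                              unrecognized_window = config$unrecognized_window)
    elements <- c(elements, els)
  }
  names(elements) <- vapply(elements, `[[`, "", "element_id")
  .log(config, "delineate: ", length(elements), " candidate element(s), ",
       sum(vapply(elements, function(e) identical(e$att_status, "resolved"), TRUE)),
       " att-resolved")

  # --- stage classify ---
  qs_profiles <- list()
  pseudogenes <- list()
  for (i in seq_along(elements)) {
    el <- elements[[i]]
    g <- genomes[[el$genome_id]]
    cls <- classify_element(el, clusters_conj, relaxases, integrases, hits)
    cls$is_ICESym <- cls$mge_class == "ICE" && flag_symbiosis(el, hits)
    el$classification <- cls
    qp <- profile_qs_locus(el, hits, g, panel)
    qs_profiles[[el$element_id]] <- qp
    if (nrow(qp$pseudogenes)) pseudogenes[[el$element_id]] <- qp$pseudogenes
    elements[[i]] <- el
  }
  classification <- do.call(rbind, lapply(elements, function(e) {
    data.frame(element_id = e$element_id, genome_id = e$genome_id,
               replicon_id = e$replicon_id,
               mge_class = e$classification$mge_class,
               t4ss_type = e$classification$t4ss_type,
               relaxase_family = e$classification$relaxase_family,
               is_ICESym = e$classification$is_ICESym,
               trbK_present = e$classification$trbK_present,
               rep3_duf2840_present = e$classification$rep3_duf2840_present,
               partite_count = e$partite_count,
               att_status = e$att_status,
               artifact_flag = e$artifact_flag,
               length = element_length(e), stringsAsFactors = FALSE)
  }))
  rownames(classification) <- NULL
  .log(config, "classify: ",
       paste(names(table(classification$mge_class)),
             table(classification$mge_class), collapse = ", "))

  # --- stage pangenome ---
  locus_element <- unlist(unname(lapply(elements, function(e) {
    stats::setNames(rep(e$element_id, length(e$feature_loci)), e$feature_loci)
  })))
  pairs <- protein_pairs(proteins)
  cs <- cluster_orthologs(proteins, config$cluster_identity,
                          config$cluster_coverage, pairs = pairs)
  real_ids <- classification$element_id[!classification$artifact_flag &
    classification$mge_class != "unclassified"]
  pa_el <- presence_absence(cs, locus_element[names(locus_element) %in%
    unlist(lapply(elements[real_ids], `[[`, "feature_loci"))])
  pa_el <- pa_el[, intersect(colnames(pa_el), real_ids), drop = FALSE]
  bh <- best_hits(hits)
  is_loci <- bh$query_locus[bh$role_label %in% is_element_roles()]
  is_clusters <- unique(cs$membership[intersect(names(cs$membership), is_loci)])
  el_lengths <- stats::setNames(classification$length,
                                classification$element_id)
  redundancy <- if (ncol(pa_el) >= 1L) {
    collapse_redundant(pa_el, is_clusters, element_lengths = el_lengths)
  } else NULL
  nonred <- if (!is.null(redundancy)) redundancy$representative_element_id
            else character()
  # backbone over non-redundant ICEs (and trb-carrying conjugative plasmids)
  bb_units <- classification$element_id[
    classification$element_id %in% nonred &
      (classification$mge_class == "ICE" |
         (classification$mge_class == "conjugative_plasmid" &
            classification$t4ss_type == "trb"))]
  backbone <- if (length(bb_units) >= 2L) {
    identify_backbone(pa_el[, bb_units, drop = FALSE],
                      config$backbone_prevalence)
  } else NULL
  accessory <- if (!is.null(backbone)) {
    setdiff(rownames(pa_el)[rowSums(pa_el > 0) > 0], backbone$backbone)
  } else rownames(pa_el)
  tree_units <- intersect(nonred, classification$element_id[
    classification$mge_class %in% c("ICE", "IME")])
  acc_tree <- if (length(tree_units) >= 3L) {
    gene_content_tree(pa_el[accessory, tree_units, drop = FALSE])
  } else NULL
  # mobilome accounting over all clusters
  cat_of_el <- stats::setNames(
    ifelse(classification$is_ICESym, "ICESym",
           ifelse(classification$mge_class == "ICE", "ICE",
                  ifelse(classification$mge_class == "IME", "IME",
                         ifelse(grepl("plasmid", classification$mge_class),
                                "plasmid", "chromosome")))),
    classification$element_id)
  cat_of_el[classification$artifact_flag] <- "chromosome"
  locus_category <- rep("chromosome", length(proteins))
  names(locus_category) <- names(proteins)
  inel <- names(locus_element)[locus_element %in% names(cat_of_el)]
  locus_category[inel] <- cat_of_el[locus_element[inel]]
  mobilome <- account_mobilome(cs, locus_category)
  ani <- NULL
  genospecies <- NULL
  if (isTRUE(config$run_ani) && length(genomes) >= 2L) {
    gid <- names(genomes)
    combs <- utils::combn(gid, 2L)
    ani <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      r <- compute_ani(genomes[[combs[1, k]]], genomes[[combs[2, k]]],
                       fragment = config$ani_fragment,
                       max_fragments = config$ani_max_fragments)
      data.frame(genome_a = combs[1, k], genome_b = combs[2, k], ani = r$ani,
                 n_fragments = r$n_fragments, stringsAsFactors = FALSE)
    }))
    genospecies <- partition_genospecies(ani, config$ani_cutoff)
  }
  .log(config, "pangenome: ", length(cs$clusters), " clusters; backbone ",
       if (is.null(backbone)) 0 else length(backbone$backbone),
       "; mobilome fraction ", round(mobilome$mge_fraction, 3))

  # --- stage recombination ---
  network <- NULL
  if (isTRUE(config$run_recombination)) {
    circ_ids <- intersect(nonred, classification$element_id[
      classification$mge_class %in% c("ICE", "IME", "conjugative_plasmid",
                                      "mobilizable_plasmid")])
    circ <- vapply(elements[circ_ids], function(e) {
      if (is.na(e$circular_sequence[1])) NA_character_ else e$circular_sequence
    }, "")
    circ <- circ[!is.na(circ)]
    if (length(circ) >= 2L) {
      network <- build_network(circ, window = config$recomb_window,
                               alpha = config$recomb_alpha,
                               null = config$recomb_null,
                               n_perm = config$recomb_n_perm,
                               seed = config$seed)
      .log(config, "recombination: ", nrow(network$edges), " edge(s)")
    }
  }

  res <- structure(list(
    config = config, genomes = genomes, panel = panel, hits = hits,
    relaxases = relaxases, integrases = integrases,
    conjugation_clusters = clusters_conj, anchors = anchors_all,
    elements = elements, classification = classification,
    qs_profiles = qs_profiles, pseudogenes = pseudogenes,
    ortholog_clusters = cs, pa_elements = pa_el, redundancy = redundancy,
    backbone = backbone, accessory_clusters = accessory,
    accessory_tree = acc_tree, mobilome = mobilome, ani = ani,
    genospecies = genospecies, network = network,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "mobelem_run")
  if (!is.null(config$out_dir)) .write_run_outputs(res, config$out_dir)
  res
}

#' @export
print.mobelem_run <- function(x, ...) {
  cat("mobelem pipeline run:", length(x$genomes), "genome(s),",
      nrow(x$classification), "element call(s) in",
      round(x$elapsed, 1), "s\n")
  print(table(x$classification$mge_class))
  invisible(x)
}

.write_run_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    wt(res$classification, "classification.tsv"),
    wt(res$hits, "panel_hits.tsv"),
    wt(res$relaxases, "relaxases.tsv"))
  paths <- c(paths, write_element_outputs(res$elements, out_dir))
  qp <- do.call(rbind, lapply(res$qs_profiles, `[[`, "profile"))
  if (!is.null(qp)) paths <- c(paths, wt(qp, "qs_profiles.tsv"))
  if (!is.null(res$network)) {
    paths <- c(paths, write_network(res$network, file.path(out_dir, "network")))
  }
  if (!is.null(res$accessory_tree)) {
    tp <- file.path(out_dir, "accessory_nj.nwk")
    ape::write.tree(res$accessory_tree, tp)
    paths <- c(paths, tp)
  }
  if (!is.null(res$ani)) paths <- c(paths, wt(res$ani, "ani.tsv"))
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.table(manifest, file.path(out_dir, "MANIFEST"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Evaluate a pipeline run against simulator truth
#'
#' Matches element calls to planted elements by replicon and reciprocal
#' overlap, requiring class agreement for true positives; reports per-class
#' precision/recall, the boundary-error distribution (bp; exact means
#' bp-identical attL/attR for every fragment), att recovery, a confusion
#' matrix, artifact detection and recombination-event recall.
#'
#' @param run a `mobelem_run`
#' @param truth the `truth` component of a `MobilomeSimulation`
#' @return an `EvaluationReport` list
#' @export
evaluate_run <- function(run, truth) {
  cls <- run$classification
  truth_els <- Filter(function(e) e$class != "artifact", truth$elements)
  truth_art <- Filter(function(e) e$class == "artifact", truth$elements)
  if (!all(vapply(truth_els, function(e) e$genome_id %in% names(run$genomes),
                  TRUE))) {
    stop("truth and results disagree on genome ids")
  }
  pred <- cls[!cls$artifact_flag & cls$mge_class != "unclassified", ,
              drop = FALSE]
  t_ids <- vapply(truth_els, `[[`, "", "element_id")
  t_class <- vapply(truth_els, function(e) {
    if (e$class == "ICE" && isTRUE(e$sym)) "ICE" else e$class
  }, "")
  # matching by replicon + any overlap of fragment spans
  matches <- data.frame(truth_id = character(), pred_id = character(),
                        class_ok = logical(), exact = logical(),
                        boundary_err = numeric(), stringsAsFactors = FALSE)
  for (i in seq_along(truth_els)) {
    te <- truth_els[[i]]
    cand <- NULL
    for (j in seq_len(nrow(pred))) {
      pe <- run$elements[[pred$element_id[j]]]
      if (pe$replicon_id != te$replicon_id) next
      ov <- 0
      for (k in seq_len(nrow(te$fragments))) {
        ov <- ov + sum(pmax(0, pmin(pe$fragments$end, te$fragments$end[k]) -
                              pmax(pe$fragments$start, te$fragments$start[k])))
      }
      if (ov > 0.5 * sum(te$fragments$end - te$fragments$start)) {
        cand <- pe
        break
      }
    }
    if (is.null(cand)) next
    exact <- nrow(cand$fragments) == nrow(te$fragments) &&
      all(sort(cand$fragments$start) == sort(te$fragments$start)) &&
      all(sort(cand$fragments$end) == sort(te$fragments$end))
    berr <- if (nrow(cand$fragments) == nrow(te$fragments)) {
      sum(abs(sort(cand$fragments$start) - sort(te$fragments$start))) +
        sum(abs(sort(cand$fragments$end) - sort(te$fragments$end)))
    } else NA_real_
    matches <- rbind(matches, data.frame(
      truth_id = te$element_id, pred_id = cand$element_id,
      class_ok = cls$mge_class[cls$element_id == cand$element_id] ==
        unname(t_class[i]),
      exact = exact, boundary_err = berr, stringsAsFactors = FALSE))
  }
  tp <- sum(matches$class_ok)
  recall <- tp / length(truth_els)
  precision <- if (nrow(pred)) tp / nrow(pred) else NA_real_
  per_class <- do.call(rbind, lapply(
    unique(t_class), function(cl) {
      t_in <- t_ids[t_class == cl]
      p_in <- pred$element_id[pred$mge_class == cl]
      tp_c <- sum(matches$class_ok & matches$truth_id %in% t_in)
      data.frame(class = cl, n_truth = length(t_in), n_pred = length(p_in),
                 recall = tp_c / length(t_in),
                 precision = if (length(p_in)) tp_c / length(p_in) else NA_real_)
    }))
  att_truth <- vapply(truth_els, function(e) {
    !(e$class %in% c("conjugative_plasmid", "mobilizable_plasmid"))
  }, TRUE)
  att_rec <- sum(matches$exact[matches$truth_id %in% t_ids[att_truth]]) /
    sum(att_truth)
  confusion <- table(
    truth = t_class[match(matches$truth_id, t_ids)],
    predicted = pred$mge_class[match(matches$pred_id, pred$element_id)])
  artifact_detected <- if (length(truth_art)) {
    all(vapply(truth_art, function(ta) {
      any(cls$artifact_flag &
            cls$replicon_id == ta$replicon_id &
            vapply(run$elements[cls$element_id[cls$artifact_flag]],
                   function(pe) {
                     pe$replicon_id == ta$replicon_id &&
                       pe$fragments$start[1] < ta$fragments$end[1] &&
                       pe$fragments$end[1] > ta$fragments$start[1]
                   }, TRUE))
    }, TRUE))
  } else NA
  recomb_recall <- NA_real_
  if (!is.null(truth$recombination) && !is.null(run$network) &&
      nrow(truth$recombination)) {
    ev_ok <- vapply(seq_len(nrow(truth$recombination)), function(i) {
      ev <- truth$recombination[i, ]
      from_pred <- matches$pred_id[matches$truth_id == ev$from_element]
      to_pred <- matches$pred_id[matches$truth_id == ev$to_element]
      if (!length(from_pred) || !length(to_pred)) return(FALSE)
      seg <- run$network$segments
      hit <- (seg$from == to_pred & seg$to == from_pred &
                seg$start < ev$to_offset + ev$length &
                seg$end > ev$to_offset) |
        (seg$from == from_pred & seg$to == to_pred &
           seg$start < ev$from_offset + ev$length & seg$end > ev$from_offset)
      any(hit)
    }, TRUE)
    recomb_recall <- mean(ev_ok)
  }
  structure(list(
    precision = precision, recall = recall, per_class = per_class,
    matches = matches, boundary_exact_rate = mean(matches$exact),
    att_recovery_rate = att_rec, confusion = confusion,
    artifact_detected = artifact_detected,
    recombination_recall = recomb_recall,
    n_truth = length(truth_els), n_pred = nrow(pred)
  ), class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf(
    "EvaluationReport: precision %.3f, recall %.3f, exact boundaries %.3f, att recovery %.3f\n",
    x$precision, x$recall, x$boundary_exact_rate, x$att_recovery_rate))
  print(x$per_class)
  invisible(x)
}
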