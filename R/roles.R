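# Controlled role vocabulary for the reference panel and all homology-based
# calls. Roles are gene names; higher-level groupings (relaxase family, T4SS
# membership, seed categories for att-site search) are metadata over roles.

#' @keywords internal
trb_core_roles <- function() {
  c("trbB", "trbC", "trbD", "trbE", "trbJ", "trbL", "trbF", "trbG", "trbI")
}

#' @keywords internal
trb_cluster_roles <- function() c("msi031", trb_core_roles(), "msi021")

#' @keywords internal
vir_t4ss_roles <- function() {
  c("virB2", "virB3", "virB4", "virB5", "virB6", "virB8", "virB9", "virB10",
    "virB11")
}

#' @keywords internal
t4cp_roles <- function() c("traG", "virD4")

#' @keywords internal
qs_roles <- function() {
  c("traR1", "traR2", "traI1", "traI2", "qseM", "qseC", "fseA")
}

#' @keywords internal
nod_roles <- function() {
  c("nodA", "nodB", "nodC", "nodI", "nodJ", "nodD2", "nodH", "nodS",
    "noeJ", "noeK", "nopP")
}

#' @keywords internal
nif_roles <- function() c("nifH", "nifD", "nifK", "nifA", "nifB")

#' @keywords internal
fix_roles <- function() c("fixN", "fixO", "fixQ", "fixP", "fixV")

#' @keywords internal
sym_other_roles <- function() c("dctA", "dctB", "dctD", "queC", "queD", "queE")

#' @keywords internal
anchor_gene_roles <- function() c("guaA", "radC", "dusA")

#' @keywords internal
integrase_tyr_roles <- function() c("intS", "intM", "intG", "intP")

#' @keywords internal
integrase_ser_roles <- function() c("srtI")

#' @keywords internal
is_element_roles <- function() c("tnpA1", "tnpA2")

#' @keywords internal
replication_roles <- function() c("repA", "repB", "repC", "Rep_3")

#' Map a panel role to its relaxase MOB family (NA if not a relaxase)
#'
#' Gene-name roles that are themselves relaxases (rlxS is the MOB_P subtype 1
#' relaxase; traA is the Ti-plasmid-like MOB_F relaxase) map to their family,
#' alongside the generic per-family exemplar roles.
#'
#' @param roles character vector of role labels
#' @return data.frame with columns `role`, `family`, `subtype`
#' @keywords internal
relaxase_role_map <- function(roles = NULL) {
  map <- data.frame(
    role = c("MOB_F", "MOB_H", "MOB_Q", "MOB_C", "MOB_P1", "MOB_V",
             "rlxS", "traA"),
    family = c("MOB_F", "MOB_H", "MOB_Q", "MOB_C", "MOB_P", "MOB_V",
               "MOB_P", "MOB_F"),
    subtype = c(NA, NA, NA, NA, "P1", NA, "P1", NA),
    stringsAsFactors = FALSE
  )
  if (is.null(roles)) return(map)
  map[match(roles, map$role), , drop = FALSE]
}

#' All role labels recognised by the package
#' @return character vector
#' @export
panel_role_vocabulary <- function() {
  unique(c(
    relaxase_role_map()$role,
    trb_cluster_roles(), vir_t4ss_roles(), t4cp_roles(),
    "traC", "traD", "rdfS", "traF", "msi107", "trbK", "msi110", "DUF2840",
    replication_roles(),
    integrase_tyr_roles(), integrase_ser_roles(),
    qs_roles(), nod_roles(), nif_roles(), fix_roles(), sym_other_roles(),
    anchor_gene_roles(), is_element_roles()
  ))
}

#' Seed categories used by the att-site delineator
#'
#' Seeds are loci whose homology role indicates mobile-element machinery:
#' relaxases, conjugation-cluster genes (trb/vir T4SS, traACD relaxosome,
#' T4CP) and integrases. IS transposases and cargo are not seeds.
#'
#' @param roles character vector of role labels
#' @return logical vector, TRUE where the role is a delineation seed
#' @export
is_seed_role <- function(roles) {
  seeds <- c(relaxase_role_map()$role,
             trb_cluster_roles(), vir_t4ss_roles(), t4cp_roles(),
             "traC", "traD",
             integrase_tyr_roles(), integrase_ser_roles())
  roles %in% seeds
}

#' Read a reference panel FASTA with structured headers
#'
#' Headers are `exemplar_id|role_label`; role labels must come from
#' [panel_role_vocabulary()]. Exemplar ids must be unique.
#'
#' @param path FASTA file of exemplar protein sequences
#' @return data.frame with columns `exemplar_id`, `role`, `seq`
#' @export
read_reference_panel <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("panel headers must be 'exemplar_id|role_label'; offending: ",
         paste(names(aa)[bad][1:min(3, sum(bad))], collapse = ", "))
  }
  panel <- data.frame(
    exemplar_id = vapply(parts, `[`, "", 1L),
    role = vapply(parts, `[`, "", 2L),
    seq = as.character(aa),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(panel$exemplar_id)) {
    stop("duplicate exemplar ids in panel")
  }
  unknown <- setdiff(panel$role, panel_role_vocabulary())
  if (length(unknown)) {
    stop("unknown role labels in panel: ", paste(unknown, collapse = ", "))
  }
  rownames(panel) <- panel$exemplar_id
  panel
}

.mobelem_cache <- new.env(parent = emptyenv())

#' The bundled synthetic exemplar panel
#'
#' A small panel of synthetic exemplar proteins, one (or two) per role, used
#' both by the simulator (cargo genes are mutated copies of these exemplars)
#' and as the default search panel. Real profile-HMM databases can be used
#' instead through the HMM-table input of [classify_relaxases()] or a user
#' panel via [read_reference_panel()].
#'
#' @return data.frame as from [read_reference_panel()]
#' @export
default_reference_panel <- function() {
  if (is.null(.mobelem_cache$panel)) {
    path <- system.file("extdata", "exemplar_panel.faa", package = "mobelem")
    if (!nzchar(path)) stop("bundled exemplar panel not found")
    .mobelem_cache$panel <- read_reference_panel(path)
  }
  .mobelem_cache$panel
}
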