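# Lipid templates: map residue names to membrane roles (phosphate, central
# glycerol carbon, ordered sn1/sn2 acyl carbons, aliphatic set). The same
# machinery serves all-atom and coarse-grained models; for coarse-grained
# lipids the bead names stand in for carbons and the "terminal CH3" is the
# last tail bead.

#' Define a lipid template
#'
#' A template names, for one residue type, the atoms that carry membrane
#' roles: the phosphate (headgroup reference), the central glycerol carbon,
#' and the ordered sn1/sn2 acyl-carbon lists whose last elements are the
#' terminal CH3 carbons. `aliphatic` defaults to both carbon lists minus
#' their first element (the carbonyl carbon bonded to glycerol).
#'
#' @param residue_name Residue name this template matches.
#' @param phosphate Atom name of the phosphate (or head bead).
#' @param glycerol Atom name of the central glycerol carbon.
#' @param sn1,sn2 Ordered character vectors of acyl carbon names, glycerol
#'   end first; the last entry is the terminal carbon.
#' @param aliphatic Optional character vector of solvent-scorable aliphatic
#'   atom names; default drops the first (carbonyl) carbon of each chain.
#' @return An object of class `lipid_template`.
#' @export
lipid_template <- function(residue_name, phosphate, glycerol, sn1, sn2,
                           aliphatic = NULL) {
  if (length(intersect(sn1, sn2)) > 0L) {
    abort("sn1 and sn2 atom-name lists must be disjoint.")
  }
  if (is.null(aliphatic)) {
    aliphatic <- c(sn1[-1], sn2[-1])
  }
  structure(list(
    residue_name = residue_name,
    phosphate = phosphate,
    glycerol = glycerol,
    sn1 = sn1,
    sn2 = sn2,
    aliphatic = aliphatic
  ), class = "lipid_template")
}

#' @export
print.lipid_template <- function(x, ...) {
  cat(sprintf("<lipid_template> %s: sn1 %d carbons, sn2 %d carbons\n",
              x$residue_name, length(x$sn1), length(x$sn2)))
  invisible(x)
}

#' Read a template configuration from YAML
#'
#' The YAML layout is:
#' ```yaml
#' water_names: [SOL, TIP3, W]
#' ignore_residues: [CHOL, NA, CL]
#' templates:
#'   - residue_name: POPC
#'     phosphate: P
#'     glycerol: C2
#'     sn1: [C11, C12, ...]
#'     sn2: [C21, C22, ...]
#' ```
#'
#' @param path Path to the YAML file.
#' @return A list with `templates` (list of [lipid_template()]),
#'   `water_names` and `ignore_residues`.
#' @export
read_template_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  templates <- lapply(cfg$templates, function(t) {
    lipid_template(t$residue_name, t$phosphate, t$glycerol,
                   as.character(t$sn1), as.character(t$sn2),
                   aliphatic = if (!is.null(t$aliphatic)) as.character(t$aliphatic))
  })
  list(
    templates = templates,
    water_names = as.character(cfg$water_names %||% c("SOL", "TIP3", "W")),
    ignore_residues = as.character(cfg$ignore_residues %||% character())
  )
}

resolve_one <- function(atom_names, ids, wanted, residue_id) {
  idx <- match(wanted, atom_names)
  if (anyNA(idx)) {
    abort(sprintf("residue %d: template atom(s) %s absent from residue.",
                  residue_id, paste(wanted[is.na(idx)], collapse = ", ")))
  }
  ids[idx]
}

#' Annotate a topology with membrane roles
#'
#' Matches every non-water residue against the supplied lipid templates and
#' resolves the role atoms of each lipid. Residues named in `water_names`
#' (default SOL/TIP3/W) are collected as waters, tracked by their oxygen
#' atom (the first atom whose element is O, or the single bead of a
#' coarse-grained water). Residues in `ignore_residues` are dropped from
#' lipid metrics. Any other unmatched residue name is an error.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param templates A list of [lipid_template()] objects (or the result of
#'   [read_template_config()], whose water/ignore lists are then used).
#' @param water_names Residue names treated as water.
#' @param ignore_residues Residue names excluded from lipid metrics.
#' @return An object of class `annotated_topology`: a list with `atoms`,
#'   `lipids` (tibble with one row per lipid: residue_id, residue_name,
#'   phosphate_id, glycerol_id, list-columns sn1_ids/sn2_ids/aliphatic_ids,
#'   sn1_terminal, sn2_terminal) and `water_oxygens` (atom ids).
#' @export
apply_lipid_templates <- function(atoms, templates,
                                  water_names = c("SOL", "TIP3", "W"),
                                  ignore_residues = character()) {
  if (!is.null(templates$templates)) {
    if (missing(water_names)) water_names <- templates$water_names
    if (missing(ignore_residues)) ignore_residues <- templates$ignore_residues
    templates <- templates$templates
  }
  if (inherits(templates, "lipid_template")) templates <- list(templates)
  tmpl_names <- vapply(templates, function(t) t$residue_name, character(1))
  if (anyDuplicated(tmpl_names)) {
    abort("every lipid residue name must be matched by exactly one template.")
  }

  res <- dplyr::distinct(atoms, .data$residue_id, .data$residue_name)
  is_water <- res$residue_name %in% water_names
  is_ignored <- res$residue_name %in% ignore_residues
  is_lipid <- res$residue_name %in% tmpl_names & !is_water & !is_ignored
  unmatched <- unique(res$residue_name[!is_water & !is_ignored & !is_lipid])
  if (length(unmatched) > 0L) {
    abort(sprintf("unmatched residue name(s) not in ignore set: %s",
                  paste(unmatched, collapse = ", ")))
  }

  names_by_res <- split(atoms$atom_name, atoms$residue_id)
  ids_by_res <- split(atoms$atom_id, atoms$residue_id)
  res_key <- as.character(res$residue_id)

  lipid_idx <- which(is_lipid)
  n_lip <- length(lipid_idx)
  phosphate_id <- glycerol_id <- sn1_terminal <- sn2_terminal <- integer(n_lip)
  sn1_ids <- sn2_ids <- aliphatic_ids <- vector("list", n_lip)
  for (k in seq_len(n_lip)) {
    i <- lipid_idx[k]
    rid <- res$residue_id[i]
    t <- templates[[match(res$residue_name[i], tmpl_names)]]
    nm <- names_by_res[[res_key[i]]]
    ids <- ids_by_res[[res_key[i]]]
    if (anyDuplicated(nm[nm %in% c(t$phosphate, t$glycerol, t$sn1, t$sn2)])) {
      abort(sprintf("residue %d: template atom names resolve ambiguously.", rid))
    }
    sn1 <- resolve_one(nm, ids, t$sn1, rid)
    sn2 <- resolve_one(nm, ids, t$sn2, rid)
    phosphate_id[k] <- resolve_one(nm, ids, t$phosphate, rid)
    glycerol_id[k] <- resolve_one(nm, ids, t$glycerol, rid)
    sn1_ids[[k]] <- sn1
    sn2_ids[[k]] <- sn2
    sn1_terminal[k] <- sn1[length(sn1)]
    sn2_terminal[k] <- sn2[length(sn2)]
    aliphatic_ids[[k]] <- resolve_one(nm, ids, t$aliphatic, rid)
  }
  lipids <- tibble(
    residue_id = res$residue_id[lipid_idx],
    residue_name = res$residue_name[lipid_idx],
    phosphate_id = phosphate_id,
    glycerol_id = glycerol_id,
    sn1_ids = sn1_ids,
    sn2_ids = sn2_ids,
    sn1_terminal = sn1_terminal,
    sn2_terminal = sn2_terminal,
    aliphatic_ids = aliphatic_ids
  )

  water_idx <- which(is_water)
  water_oxygens <- vapply(water_idx, function(i) {
    nm <- names_by_res[[res_key[i]]]
    ids <- ids_by_res[[res_key[i]]]
    ox <- ids[guess_element(nm) == "O"]
    if (length(ox) >= 1L) ox[1] else ids[1]
  }, integer(1))

  structure(list(
    atoms = atoms,
    lipids = lipids,
    water_oxygens = as.integer(water_oxygens)
  ), class = "annotated_topology")
}

#' @export
print.annotated_topology <- function(x, ...) {
  cat(sprintf("<annotated_topology> %d atoms, %d lipids, %d waters\n",
              nrow(x$atoms), nrow(x$lipids), length(x$water_oxygens)))
  invisible(x)
}
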