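#' @import methods
NULL

FEATURE_KINDS <- c("HBA", "HBD", "HYD", "PI", "NI", "AR")

INTERACTION_KINDS <- c("HBOND_LIG_ACCEPTOR", "HBOND_LIG_DONOR",
                       "HYDROPHOBIC", "IONIC", "AROMATIC_PI")

#' Single-model molecular structure
#'
#' Holds the atoms of one PDB MODEL block as a data frame with one row per
#' atom: \code{serial}, \code{name}, \code{element}, \code{resname},
#' \code{resno}, \code{chain}, \code{x}, \code{y}, \code{z} (angstrom),
#' \code{charge} (formal charge, 0 when absent) and \code{record}
#' (\code{ATOM}/\code{HETATM}).
#'
#' @slot atoms data.frame of atom records.
#' @slot modelId integer model number.
#' @export
setClass("StructureModel",
         representation(atoms = "data.frame", modelId = "integer"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resno", "chain",
            "x", "y", "z", "charge", "record")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1L) return("structure must contain at least one atom")
  if (anyDuplicated(a$serial)) return("atom serials must be unique")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("atom positions must be finite")
  if (any(is.na(a$element) | a$element == ""))
    return("all atoms must carry an element symbol")
  TRUE
})

#' Multi-frame trajectory
#'
#' An ordered list of \linkS4class{StructureModel} frames with identical
#' atom identity (same serial and element sequence in every frame), e.g.
#' parsed from a multi-MODEL PDB file.
#'
#' @slot frames list of StructureModel.
#' @slot frameTimes numeric frame times in ns, or length 0 when unknown.
#' @export
setClass("Trajectory",
         representation(frames = "list", frameTimes = "numeric"))

setValidity("Trajectory", function(object) {
  fr <- object@frames
  if (length(fr) < 1L) return("trajectory must contain at least one frame")
  if (!all(vapply(fr, is, logical(1), "StructureModel")))
    return("frames must all be StructureModel objects")
  ref <- fr[[1]]@atoms
  for (i in seq_along(fr)) {
    a <- fr[[i]]@atoms
    if (nrow(a) != nrow(ref) ||
        !identical(a$serial, ref$serial) ||
        !identical(a$element, ref$element))
      return(sprintf("frame %d does not share the atom identity of frame 1", i))
  }
  if (length(object@frameTimes) > 0L &&
      length(object@frameTimes) != length(fr))
    return("frameTimes must be empty or one per frame")
  TRUE
})

#' 3D pharmacophore model
#'
#' A set of typed chemical features. \code{features} has one row per
#' feature: \code{kind} (HBA, HBD, HYD, PI, NI, AR), position \code{x},
#' \code{y}, \code{z} (angstrom), \code{tolerance} (sphere radius,
#' angstrom), optional unit direction \code{dirx}, \code{diry},
#' \code{dirz} (NA when absent) and a list column \code{anchors} of
#' protein residue labels recording provenance.
#'
#' @slot features data.frame of features (may be empty, e.g. a consensus
#'   whose retention threshold no feature reached).
#' @slot frameLabel character label of the coordinate frame (reference
#'   complex id).
#' @slot provenance character vector of source model ids.
#' @export
setClass("PharmacophoreModel",
         representation(features = "data.frame", frameLabel = "character",
                        provenance = "character"))

setValidity("PharmacophoreModel", function(object) {
  f <- object@features
  need <- c("kind", "x", "y", "z", "tolerance", "dirx", "diry", "dirz",
            "anchors")
  if (!all(need %in% names(f)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  if (nrow(f) > 0L) {
    if (!all(f$kind %in% FEATURE_KINDS))
      return(paste("unknown feature kind:",
                   paste(setdiff(f$kind, FEATURE_KINDS), collapse = ", ")))
    if (!all(f$tolerance > 0)) return("tolerances must be positive")
    hasdir <- !is.na(f$dirx)
    if (any(hasdir)) {
      nrm <- sqrt(f$dirx[hasdir]^2 + f$diry[hasdir]^2 + f$dirz[hasdir]^2)
      if (any(abs(nrm - 1) > 1e-6))
        return("feature directions must be unit vectors")
    }
  }
  TRUE
})

#' Per-frame interaction timeline
#'
#' The dynamic interaction profile of a trajectory: one column per distinct
#' interaction key (kind, ligand atom set, protein residue), one row per
#' frame, with the 3D feature position recorded wherever the interaction
#' is present.
#'
#' @slot keys data.frame describing each interaction key (\code{kind},
#'   \code{ligAtoms} comma-joined ligand serials, \code{chain},
#'   \code{resno}, \code{resname}, \code{label}).
#' @slot presence logical matrix, frames x keys.
#' @slot sites list (one per key) of frames x 3 numeric matrices, NA rows
#'   where the interaction is absent.
#' @export
setClass("InteractionTimeline",
         representation(keys = "data.frame", presence = "matrix",
                        sites = "list"))

setValidity("InteractionTimeline", function(object) {
  if (ncol(object@presence) != nrow(object@keys))
    return("presence must have one column per key")
  if (!is.logical(object@presence)) return("presence must be logical")
  if (length(object@sites) != nrow(object@keys))
    return("sites must have one entry per key")
  if (nrow(object@keys) > 0L && any(colSums(object@presence) == 0L))
    return("every key must be present in at least one frame")
  TRUE
})

#' Library screening report
#'
#' Per-molecule best-conformer match results for a screened library.
#' \code{results} has one row per molecule: \code{id}, \code{hit},
#' \code{conformer} (index of best conformer, NA for no-match),
#' \code{nMatched}, \code{nValid}, \code{rmsd}, \code{score} (NA / -Inf
#' sentinels for no-match).
#'
#' @slot results data.frame of per-molecule outcomes.
#' @slot settings list of screening settings used.
#' @slot modelLabel character label of the query model.
#' @export
setClass("ScreenReport",
         representation(results = "data.frame", settings = "list",
                        modelLabel = "character"))

setValidity("ScreenReport", function(object) {
  need <- c("id", "hit", "conformer", "nMatched", "nValid", "rmsd", "score")
  if (!all(need %in% names(object@results)))
    return(paste("results must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(object@results$id)) return("molecule ids must be unique")
  TRUE
})
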