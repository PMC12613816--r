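# Structure-based pharmacophore models: derivation from interaction
# events, overlay onto a reference, and consensus by a feature-retention
# rule across overlaid models.

EVENT_TO_FEATURE <- c(HBOND_LIG_ACCEPTOR = "HBA", HBOND_LIG_DONOR = "HBD",
                      HYDROPHOBIC = "HYD", AROMATIC_PI = "AR")

#' Default feature tolerance radii
#'
#' Sphere radii (angstrom) used for newly derived features, one per
#' feature kind. 1.5 A is the typical pharmacophore sphere radius.
#'
#' @param default radius applied to every kind.
#' @param ... per-kind overrides, e.g. \code{HBA = 1.0}.
#' @return named numeric vector over HBA, HBD, HYD, PI, NI, AR.
#' @export
featureTolerances <- function(default = 1.5, ...) {
  tol <- stats::setNames(rep(default, length(FEATURE_KINDS)), FEATURE_KINDS)
  over <- c(...)
  tol[names(over)] <- over
  tol
}

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Residue anchor label
#'
#' Renders a protein residue as a compact one-letter label, with the
#' conventional asterisk suffix for residues on a chain other than the
#' reference (ligand-contacting) chain, e.g. \code{"F494*"}.
#'
#' @param resname three-letter residue name.
#' @param resno residue number.
#' @param chain chain id.
#' @param referenceChain chain regarded as the primary chain; others get
#'   an asterisk. NULL suppresses the convention.
#' @return character labels.
#' @export
residueLabel <- function(resname, resno, chain, referenceChain = NULL) {
  one <- AA1[resname]
  one[is.na(one)] <- resname[is.na(one)]
  star <- if (is.null(referenceChain)) "" else
    ifelse(chain == referenceChain, "", "*")
  paste0(one, resno, star, ifelse(rep(is.null(referenceChain),
                                      length(one)), paste0(":", chain), ""))
}

#' Construct a pharmacophore model
#'
#' @param features data.frame with columns kind, x, y, z, tolerance and
#'   optionally dirx, diry, dirz, anchors.
#' @param frameLabel coordinate frame label.
#' @param provenance source model ids.
#' @return A \linkS4class{PharmacophoreModel}, features in canonical order
#'   (kind, then position lexicographically).
#' @export
pharmacophoreModel <- function(features, frameLabel = "",
                               provenance = character(0)) {
  if (!"dirx" %in% names(features))
    features$dirx <- features$diry <- features$dirz <- NA_real_
  if (!"anchors" %in% names(features))
    features$anchors <- I(replicate(nrow(features), character(0),
                                    simplify = FALSE))
  features <- features[, c("kind", "x", "y", "z", "tolerance",
                           "dirx", "diry", "dirz", "anchors")]
  ord <- order(match(features$kind, FEATURE_KINDS), features$x,
               features$y, features$z)
  features <- features[ord, , drop = FALSE]
  rownames(features) <- NULL
  m <- new("PharmacophoreModel", features = features,
           frameLabel = frameLabel, provenance = as.character(provenance))
  validObject(m)
  m
}

#' @describeIn PharmacophoreModel-class feature table accessor
#' @param object a PharmacophoreModel.
#' @export
features <- function(object) object@features

#' @describeIn PharmacophoreModel-class number of features
#' @param x a PharmacophoreModel.
#' @export
nFeatures <- function(x) nrow(x@features)

setMethod("show", "PharmacophoreModel", function(object) {
  f <- object@features
  cat(sprintf("PharmacophoreModel '%s': %d features", object@frameLabel,
              nrow(f)))
  if (nrow(f))
    cat(" (", paste(sprintf("%s x%d", names(table(f$kind)),
                            as.integer(table(f$kind))), collapse = ", "),
        ")", sep = "")
  cat("\n")
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = ", "), "\n")
})

#' Derive a pharmacophore model from interaction events
#'
#' Maps each detected interaction to one chemical feature at the ligand
#' site position: ligand-acceptor hydrogen bonds to HBA, ligand-donor to
#' HBD, hydrophobic contacts to HYD, ionic contacts to PI or NI by the
#' sign of the ligand charge, aromatic interactions to AR. The protein
#' residue of each event is recorded as the feature's anchor. Duplicate
#' events (same kind, ligand atoms, residue) collapse to one feature;
#' several events sharing a ligand site (e.g. one hydrophobic group
#' contacting several residues) merge into one feature whose anchors are
#' the union.
#'
#' @param events event data.frame from [detectInteractions()].
#' @param tolerances named radii from [featureTolerances()].
#' @param frameLabel label for the resulting model.
#' @param referenceChain passed to [residueLabel()] for anchor rendering.
#' @return A \linkS4class{PharmacophoreModel}.
#' @export
deriveModel <- function(events, tolerances = featureTolerances(),
                        frameLabel = "", referenceChain = NULL) {
  if (nrow(events) == 0L) stop("cannot derive a model from zero events")
  kind <- unname(EVENT_TO_FEATURE[events$kind])
  ionic <- events$kind == "IONIC"
  kind[ionic] <- ifelse(!is.na(events$ligChargeSign[ionic]) &
                          events$ligChargeSign[ionic] < 0, "NI", "PI")
  anchors <- residueLabel(events$resname, events$resno, events$chain,
                          referenceChain)
  df <- data.frame(kind = kind, ligSerials = events$ligSerials,
                   x = events$x, y = events$y, z = events$z,
                   anchor = anchors, stringsAsFactors = FALSE)
  # one feature per (kind, ligand site); anchors unioned
  key <- paste(df$kind, df$ligSerials)
  sp <- split(seq_len(nrow(df)), key)
  feat <- do.call(rbind, lapply(sp, function(idx) {
    data.frame(kind = df$kind[idx[1]], x = df$x[idx[1]], y = df$y[idx[1]],
               z = df$z[idx[1]],
               tolerance = unname(tolerances[df$kind[idx[1]]]),
               stringsAsFactors = FALSE)
  }))
  feat$anchors <- I(lapply(sp, function(idx) sort(unique(df$anchor[idx]))))
  pharmacophoreModel(feat, frameLabel = frameLabel, provenance = frameLabel)
}

#' Overlay a pharmacophore model onto a reference
#'
#' Finds the best same-kind feature correspondence between the two models
#' (internal-distance-consistent, at least three non-collinear pairs) and
#' returns the least-squares rigid superposition: the largest
#' correspondence, ties resolved to the lowest RMSD.
#'
#' @param model model to transform.
#' @param reference target model.
#' @param toleranceScale multiplier on tolerances in the
#'   distance-consistency test during correspondence search.
#' @return list with \code{rotation}, \code{translation}, \code{rmsd},
#'   \code{mapping} (2-column matrix: model row, reference row) and
#'   \code{model} (the transformed copy; the input is unchanged).
#' @export
overlayModels <- function(model, reference, toleranceScale = 1) {
  mf <- model@features; rf <- reference@features
  maps <- enumerateCorrespondences(
    reference, mf[, c("kind", "x", "y", "z")],
    screenSettings(minRequired = 3L, toleranceScale = toleranceScale))
  best <- NULL
  for (mp in maps) {
    if (nrow(mp) < 3L) next
    P <- as.matrix(mf[mp[, 2], c("x", "y", "z")])
    Q <- as.matrix(rf[mp[, 1], c("x", "y", "z")])
    if (isCollinear(Q) || isCollinear(P)) next
    k <- kabsch(P, Q)
    if (is.null(best) || nrow(mp) > nrow(best$mapping) ||
        (nrow(mp) == nrow(best$mapping) && k$rmsd < best$rmsd - 1e-12))
      best <- list(rotation = k$R, translation = k$t, rmsd = k$rmsd,
                   mapping = cbind(model = mp[, 2], reference = mp[, 1]))
  }
  if (is.null(best))
    stop("overlay failed: fewer than 3 usable same-kind correspondences")
  out <- model
  xyz <- as.matrix(mf[, c("x", "y", "z")])
  xyz <- applyRigid(xyz, best$rotation, best$translation)
  out@features$x <- xyz[, 1]; out@features$y <- xyz[, 2]
  out@features$z <- xyz[, 3]
  hasdir <- !is.na(out@features$dirx)
  if (any(hasdir)) {
    dirs <- as.matrix(mf[hasdir, c("dirx", "diry", "dirz")]) %*%
      best$rotation
    out@features$dirx[hasdir] <- dirs[, 1]
    out@features$diry[hasdir] <- dirs[, 2]
    out@features$dirz[hasdir] <- dirs[, 3]
  }
  best$model <- out
  best
}

#' Consensus pharmacophore across overlaid models
#'
#' Clusters same-kind features across models by greedy centroid linkage
#' within \code{mergeRadius} and retains a cluster when it contains
#' features from strictly more than \code{threshold} distinct source
#' models (the feature-retention rule; set \code{strictGreater = FALSE}
#' for at-least semantics). Retained feature position is the member
#' centroid, tolerance the member maximum, anchors the union. Cluster
#' membership uses kind and position only; direction vectors are carried
#' along from the first member but play no role in merging.
#'
#' @param models list of \linkS4class{PharmacophoreModel}, already in a
#'   common frame (see [overlayModels()]).
#' @param threshold model-count threshold (default 4: features present in
#'   more than four models are retained).
#' @param mergeRadius clustering radius in angstrom.
#' @param strictGreater if TRUE (default) retain when count > threshold,
#'   else when count >= threshold.
#' @param frameLabel label of the consensus (defaults to the first
#'   model's).
#' @return A \linkS4class{PharmacophoreModel}; may have zero features when
#'   no cluster reaches the threshold.
#' @export
consensusModel <- function(models, threshold = 4, mergeRadius = 1.5,
                           strictGreater = TRUE, frameLabel = NULL) {
  stopifnot(length(models) >= 1L, threshold >= 1, mergeRadius > 0)
  all <- do.call(rbind, lapply(seq_along(models), function(i) {
    f <- models[[i]]@features
    if (nrow(f) == 0L) return(NULL)
    f$source <- i
    f
  }))
  if (is.null(frameLabel)) frameLabel <- models[[1]]@frameLabel
  prov <- unlist(lapply(models, function(m)
    if (nzchar(m@frameLabel)) m@frameLabel else NA_character_))
  prov <- as.character(stats::na.omit(prov))
  keep <- if (strictGreater) function(n) n > threshold else
    function(n) n >= threshold
  clusters <- list()  # each: list(kind, members = row indices)
  if (!is.null(all)) {
    xyz <- as.matrix(all[, c("x", "y", "z")])
    for (i in seq_len(nrow(all))) {
      bestCl <- NA_integer_; bestD <- Inf
      for (ci in seq_along(clusters)) {
        cl <- clusters[[ci]]
        if (cl$kind != all$kind[i]) next
        cen <- colMeans(xyz[cl$members, , drop = FALSE])
        d <- vecNorm(xyz[i, ] - cen)
        if (d <= mergeRadius && d < bestD - 1e-12) {
          bestD <- d; bestCl <- ci
        }
      }
      if (is.na(bestCl)) {
        clusters[[length(clusters) + 1L]] <-
          list(kind = all$kind[i], members = i)
      } else {
        clusters[[bestCl]]$members <- c(clusters[[bestCl]]$members, i)
      }
    }
  }
  rows <- list()
  for (cl in clusters) {
    nSrc <- length(unique(all$source[cl$members]))
    if (!keep(nSrc)) next
    cen <- colMeans(as.matrix(all[cl$members, c("x", "y", "z"),
                                  drop = FALSE]))
    first <- cl$members[1]
    rows[[length(rows) + 1L]] <- data.frame(
      kind = cl$kind, x = cen[1], y = cen[2], z = cen[3],
      tolerance = max(all$tolerance[cl$members]),
      dirx = all$dirx[first], diry = all$diry[first],
      dirz = all$dirz[first],
      anchors = I(list(sort(unique(unlist(all$anchors[cl$members]))))),
      stringsAsFactors = FALSE)
  }
  feat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), tolerance = numeric(0), dirx = numeric(0),
               diry = numeric(0), dirz = numeric(0),
               anchors = I(list()), stringsAsFactors = FALSE)
  pharmacophoreModel(feat, frameLabel = frameLabel, provenance = prov)
}
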