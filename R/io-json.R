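# JSON interchange: pharmacophore models and conformer feature libraries.

PHARMACOPHORE_SCHEMA_VERSION <- 1L

#' Write a pharmacophore model to JSON
#'
#' Schema: \code{{schema_version, frame_label, features: [{kind,
#' position: [x,y,z], tolerance, direction: [x,y,z]|null,
#' anchors: [...]}], provenance: [...]}}.
#'
#' @param model a \linkS4class{PharmacophoreModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePharmacophore <- function(model, path) {
  f <- model@features
  feats <- lapply(seq_len(nrow(f)), function(i) {
    list(kind = f$kind[i],
         position = c(f$x[i], f$y[i], f$z[i]),
         tolerance = f$tolerance[i],
         direction = if (is.na(f$dirx[i])) NULL else
           c(f$dirx[i], f$diry[i], f$dirz[i]),
         anchors = as.list(f$anchors[[i]]))
  })
  obj <- list(schema_version = PHARMACOPHORE_SCHEMA_VERSION,
              frame_label = model@frameLabel,
              features = feats,
              provenance = as.list(model@provenance))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a pharmacophore model from JSON
#'
#' @param path path to a JSON file written by [writePharmacophore()].
#' @return A \linkS4class{PharmacophoreModel}.
#' @export
readPharmacophore <- function(path) {
  obj <- jsonlite::read_json(path)
  feats <- obj$features
  kinds <- vapply(feats, function(ft) ft$kind, character(1))
  bad <- setdiff(kinds, FEATURE_KINDS)
  if (length(bad))
    stop(sprintf("unknown feature kind '%s' in '%s'", bad[1], path))
  df <- data.frame(
    kind = kinds,
    x = vapply(feats, function(ft) as.numeric(ft$position[[1]]), 1),
    y = vapply(feats, function(ft) as.numeric(ft$position[[2]]), 1),
    z = vapply(feats, function(ft) as.numeric(ft$position[[3]]), 1),
    tolerance = vapply(feats, function(ft) as.numeric(ft$tolerance), 1),
    dirx = vapply(feats, function(ft)
      if (is.null(ft$direction)) NA_real_ else
        as.numeric(ft$direction[[1]]), 1),
    diry = vapply(feats, function(ft)
      if (is.null(ft$direction)) NA_real_ else
        as.numeric(ft$direction[[2]]), 1),
    dirz = vapply(feats, function(ft)
      if (is.null(ft$direction)) NA_real_ else
        as.numeric(ft$direction[[3]]), 1),
    stringsAsFactors = FALSE)
  df$anchors <- I(lapply(feats, function(ft)
    as.character(unlist(ft$anchors))))
  pharmacophoreModel(df,
                     frameLabel = as.character(obj$frame_label),
                     provenance = as.character(unlist(obj$provenance)))
}

#' Read a conformer feature library from JSON
#'
#' Schema: a list of molecules, each \code{{id, label?, properties?,
#' conformers: [[{kind, position: [x,y,z]}, ...], ...]}}. Labels default
#' to \code{"unlabeled"}; properties to an empty map.
#'
#' @param path JSON path.
#' @return A \code{FeatureLibrary}: list of molecule entries, each with
#'   \code{id}, \code{label}, \code{properties} (named numeric) and
#'   \code{conformers} (list of data.frames with kind, x, y, z).
#' @export
readFeatureLibrary <- function(path) {
  obj <- jsonlite::read_json(path)
  entries <- lapply(obj, function(mol) {
    conformers <- lapply(mol$conformers, function(cf) {
      kinds <- vapply(cf, function(ft) ft$kind, character(1))
      bad <- setdiff(kinds, FEATURE_KINDS)
      if (length(bad))
        stop(sprintf("unknown feature kind '%s' in library '%s'",
                     bad[1], path))
      data.frame(
        kind = kinds,
        x = vapply(cf, function(ft) as.numeric(ft$position[[1]]), 1),
        y = vapply(cf, function(ft) as.numeric(ft$position[[2]]), 1),
        z = vapply(cf, function(ft) as.numeric(ft$position[[3]]), 1),
        stringsAsFactors = FALSE)
    })
    list(id = as.character(mol$id),
         label = if (is.null(mol$label)) "unlabeled" else
           as.character(mol$label),
         properties = unlist(mol$properties) %||% stats::setNames(
           numeric(0), character(0)),
         conformers = conformers)
  })
  class(entries) <- "FeatureLibrary"
  entries
}

#' Write a conformer feature library to JSON
#'
#' @param library a \code{FeatureLibrary} (see [readFeatureLibrary()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureLibrary <- function(library, path) {
  obj <- lapply(library, function(mol) {
    list(id = mol$id, label = mol$label,
         properties = as.list(mol$properties),
         conformers = lapply(mol$conformers, function(cf) {
           lapply(seq_len(nrow(cf)), function(i)
             list(kind = cf$kind[i],
                  position = c(cf$x[i], cf$y[i], cf$z[i])))
         }))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.FeatureLibrary <- function(x, ...) {
  labs <- vapply(x, function(m) m$label, character(1))
  cat(sprintf("FeatureLibrary: %d molecules (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(labs)),
                            as.integer(table(labs))), collapse = ", ")))
  invisible(x)
}

#' Read an SDF file as a conformer feature library
#'
#' Each molecule's conformers (consecutive SDF records sharing a molecule
#' name) are converted to pharmacophore feature sets via
#' [classifyLigandFeatures()] on the SDF atom block (elements, formal
#' charges and coordinates). Requires the ChemmineR package.
#'
#' @param path SDF path.
#' @param protonateAmines see [classifyLigandFeatures()].
#' @return A \code{FeatureLibrary}.
#' @export
readSDFLibrary <- function(path, protonateAmines = TRUE) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("SDF input requires the ChemmineR package")
  sdf <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdf)
  entries <- list()
  for (u in unique(ids)) {
    confs <- which(ids == u)
    conformers <- lapply(confs, function(ci) {
      ab <- ChemmineR::atomblock(sdf[[ci]])
      elem <- gsub("_.*$", "", rownames(ab))
      at <- data.frame(serial = seq_len(nrow(ab)), name = elem,
                       element = elem, resname = "LIG", resno = 1L,
                       chain = "L", x = ab[, 1], y = ab[, 2], z = ab[, 3],
                       charge = if (ncol(ab) >= 5) as.integer(ab[, 5])
                       else 0L,
                       record = "HETATM", stringsAsFactors = FALSE)
      cf <- classifyLigandFeatures(at, protonateAmines)
      cf[, c("kind", "x", "y", "z")]
    })
    entries[[length(entries) + 1L]] <-
      list(id = u, label = "unlabeled",
           properties = stats::setNames(numeric(0), character(0)),
           conformers = conformers)
  }
  class(entries) <- "FeatureLibrary"
  entries
}
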