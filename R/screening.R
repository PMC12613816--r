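# Conformer-vs-pharmacophore matching: correspondence-graph clique
# search, rigid least-squares alignment, scoring and the hit rule.

#' Screening settings
#'
#' @param minRequired minimum number of matched (geometry-valid) features
#'   for a hit. Default 3.
#' @param maxOmitted number of model features a hit may leave
#'   unsatisfied. Default 0: a hit must validate every model feature.
#' @param toleranceScale positive multiplier applied to per-feature
#'   tolerance radii.
#' @return list of class \code{ScreenSettings}.
#' @export
screenSettings <- function(minRequired = 3L, maxOmitted = 0L,
                           toleranceScale = 1) {
  stopifnot(minRequired >= 1L, maxOmitted >= 0L, toleranceScale > 0)
  structure(list(minRequired = as.integer(minRequired),
                 maxOmitted = as.integer(maxOmitted),
                 toleranceScale = toleranceScale),
            class = "ScreenSettings")
}

# Precomputed model-side quantities reused across conformers.
modelMatchData <- function(model, settings) {
  f <- model@features
  list(kind = f$kind, xyz = as.matrix(f[, c("x", "y", "z")]),
       tol = f$tolerance,
       dist = crossDist(f[, c("x", "y", "z")], f[, c("x", "y", "z")]),
       tolSum = outer(f$tolerance, f$tolerance, "+") *
         settings$toleranceScale,
       n = nrow(f))
}

#' Enumerate candidate feature correspondences
#'
#' Builds the correspondence graph between model and conformer features
#' (nodes: same-kind feature pairs; edges: pairs whose internal distances
#' agree within the summed, scaled tolerances) and returns its maximal
#' cliques of size at least \code{minRequired} as candidate mappings.
#'
#' @param model a \linkS4class{PharmacophoreModel}.
#' @param conformer data.frame of conformer features (kind, x, y, z).
#' @param settings a [screenSettings()] list.
#' @return list of 2-column integer matrices (model row, conformer row),
#'   each sorted by model row; possibly empty.
#' @export
enumerateCorrespondences <- function(model, conformer,
                                     settings = screenSettings()) {
  md <- modelMatchData(model, settings)
  enumerateCorrespondencesFast(md, conformer, settings)
}

enumerateCorrespondencesFast <- function(md, conformer, settings) {
  if (md$n == 0L || nrow(conformer) == 0L) return(list())
  nodes <- which(outer(md$kind, conformer$kind, "=="), arr.ind = TRUE)
  if (nrow(nodes) < settings$minRequired) return(list())
  cd <- crossDist(conformer[, c("x", "y", "z")],
                  conformer[, c("x", "y", "z")])
  nn <- nrow(nodes)
  pairs <- which(upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
  a <- pairs[, 1]; b <- pairs[, 2]
  ok <- nodes[a, 1] != nodes[b, 1] & nodes[a, 2] != nodes[b, 2]
  dm <- md$dist[cbind(nodes[a, 1], nodes[b, 1])]
  dc <- cd[cbind(nodes[a, 2], nodes[b, 2])]
  ok <- ok & abs(dm - dc) <= md$tolSum[cbind(nodes[a, 1], nodes[b, 1])]
  edges <- pairs[ok, , drop = FALSE]
  if (nrow(edges) + 1L < settings$minRequired) {
    # not enough edges for any clique of the required size
    if (settings$minRequired > 1L) return(list())
  }
  g <- igraph::make_graph(edges = t(edges), n = nn, directed = FALSE)
  cl <- igraph::max_cliques(g, min = settings$minRequired)
  lapply(cl, function(v) {
    m <- nodes[as.integer(v), , drop = FALSE]
    m <- m[order(m[, 1]), , drop = FALSE]
    dimnames(m) <- list(NULL, c("model", "conformer"))
    m
  })
}

#' Fit a rigid alignment for one mapping
#'
#' Least-squares (Kabsch) superposition of the mapped conformer features
#' onto the model features. A mapped pair is valid when its post-transform
#' distance is within the model feature's (scaled) tolerance. The score is
#' \code{nValid - rmsdValid / meanTolerance}: monotone up in matched
#' features, down in geometric deviation.
#'
#' @param model a \linkS4class{PharmacophoreModel}.
#' @param conformer data.frame of conformer features (kind, x, y, z).
#' @param mapping 2-column matrix (model row, conformer row), at least 3
#'   rows with non-collinear model points.
#' @param settings a [screenSettings()] list.
#' @return list of class \code{MatchResult}: \code{mapping},
#'   \code{rotation}, \code{translation}, \code{rmsd} (over all mapped
#'   pairs), \code{valid} (logical per pair), \code{nMatched},
#'   \code{nValid}, \code{score}, \code{hit}.
#' @export
fitMapping <- function(model, conformer, mapping,
                       settings = screenSettings()) {
  md <- modelMatchData(model, settings)
  fitMappingFast(md, conformer, mapping, settings)
}

fitMappingFast <- function(md, conformer, mapping, settings) {
  if (nrow(mapping) < 3L)
    stop("alignment requires at least 3 correspondences")
  P <- as.matrix(conformer[mapping[, 2], c("x", "y", "z")])
  Q <- md$xyz[mapping[, 1], , drop = FALSE]
  if (isCollinear(Q) || isCollinear(P))
    stop("degenerate alignment: mapped points are collinear")
  k <- kabsch(P, Q)
  dev <- sqrt(rowSums((k$fitted - Q)^2))
  tol <- md$tol[mapping[, 1]] * settings$toleranceScale
  valid <- dev <= tol
  nValid <- sum(valid)
  rmsdValid <- if (nValid) sqrt(mean(dev[valid]^2)) else 0
  score <- nValid - rmsdValid / mean(md$tol[mapping[, 1]])
  structure(list(mapping = mapping, rotation = k$R, translation = k$t,
                 rmsd = k$rmsd, valid = valid,
                 nMatched = nrow(mapping), nValid = nValid,
                 score = score,
                 hit = nValid >= max(md$n - settings$maxOmitted,
                                     settings$minRequired)),
            class = "MatchResult")
}

noMatch <- function() {
  structure(list(mapping = NULL, rotation = NULL, translation = NULL,
                 rmsd = NA_real_, valid = logical(0), nMatched = 0L,
                 nValid = 0L, score = -Inf, hit = FALSE),
            class = "MatchResult")
}

#' @export
print.MatchResult <- function(x, ...) {
  if (x$nMatched == 0L) {
    cat("MatchResult: no match\n")
  } else {
    cat(sprintf(
      "MatchResult: %s, %d matched (%d valid), rmsd %.3f A, score %.3f\n",
      if (x$hit) "HIT" else "no hit", x$nMatched, x$nValid, x$rmsd,
      x$score))
  }
  invisible(x)
}

#' Best match of one conformer against a model
#'
#' Runs the correspondence search, fits every candidate mapping with at
#' least three non-collinear pairs, and returns the best result by score
#' (ties: lower RMSD, then lexicographically smallest mapping). A result
#' is a hit when its valid-feature count reaches both
#' \code{nFeatures(model) - maxOmitted} and \code{minRequired}; with the
#' default of zero omitted features a hit must validate every model
#' feature.
#'
#' @inheritParams fitMapping
#' @return A \code{MatchResult}; \code{noMatch} (score \code{-Inf}, zero
#'   matches) when no candidate mapping can be aligned.
#' @export
matchConformer <- function(model, conformer,
                           settings = screenSettings()) {
  md <- modelMatchData(model, settings)
  matchConformerFast(md, conformer, settings)
}

matchConformerFast <- function(md, conformer, settings) {
  maps <- enumerateCorrespondencesFast(md, conformer, settings)
  best <- noMatch()
  bestKey <- NULL
  for (mp in maps) {
    if (nrow(mp) < 3L) next
    res <- tryCatch(fitMappingFast(md, conformer, mp, settings),
                    error = function(e) NULL)
    if (is.null(res)) next
    key <- paste(t(mp), collapse = ",")
    better <- res$score > best$score + 1e-12 ||
      (abs(res$score - best$score) <= 1e-12 &&
         (is.na(best$rmsd) || res$rmsd < best$rmsd - 1e-12 ||
            (abs(res$rmsd - best$rmsd) <= 1e-12 && !is.null(bestKey) &&
               key < bestKey)))
    if (better) { best <- res; bestKey <- key }
  }
  best
}

#' Screen a conformer library against a pharmacophore model
#'
#' For every molecule, matches each conformer and keeps the best result
#' (highest score, then lowest RMSD). Molecules without conformers are
#' recorded as no-match with a warning.
#'
#' @param model a \linkS4class{PharmacophoreModel}.
#' @param library a \code{FeatureLibrary} (see [readFeatureLibrary()],
#'   [genLibrary()]).
#' @param settings a [screenSettings()] list.
#' @return A \linkS4class{ScreenReport}.
#' @export
screenLibrary <- function(model, library, settings = screenSettings()) {
  md <- modelMatchData(model, settings)
  rows <- vector("list", length(library))
  for (i in seq_along(library)) {
    mol <- library[[i]]
    if (length(mol$conformers) == 0L) {
      warning(sprintf("molecule '%s' has no conformers; recorded as no-match",
                      mol$id))
      best <- noMatch(); bestConf <- NA_integer_
    } else {
      best <- noMatch(); bestConf <- NA_integer_
      for (ci in seq_along(mol$conformers)) {
        res <- matchConformerFast(md, mol$conformers[[ci]], settings)
        if (res$score > best$score ||
            (res$score == best$score && res$nMatched > 0L &&
               !is.na(best$rmsd) && res$rmsd < best$rmsd)) {
          best <- res; bestConf <- ci
        }
      }
    }
    rows[[i]] <- data.frame(
      id = mol$id, hit = best$hit, conformer = bestConf,
      nMatched = best$nMatched, nValid = best$nValid,
      rmsd = best$rmsd, score = best$score, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  new("ScreenReport", results = res, settings = unclass(settings),
      modelLabel = model@frameLabel)
}

#' @describeIn ScreenReport-class per-molecule results accessor
#' @param object a ScreenReport.
#' @export
screenResults <- function(object) object@results

#' @describeIn ScreenReport-class number of screened molecules
#' @param x a ScreenReport.
#' @export
nScreened <- function(x) nrow(x@results)

#' @describeIn ScreenReport-class number of hits
#' @export
nHits <- function(x) sum(x@results$hit)

setMethod("show", "ScreenReport", function(object) {
  cat(sprintf("ScreenReport vs '%s': %d screened, %d hits\n",
              object@modelLabel, nScreened(object), nHits(object)))
})
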