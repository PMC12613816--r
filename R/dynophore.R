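# Dynamic interaction profiling: per-frame interaction detection over a
# trajectory, replica concatenation, occurrence frequencies and feature
# point clouds.

interactionKey <- function(ev) {
  paste(ev$kind, ev$ligSerials, paste0(ev$chain, ev$resno), sep = "|")
}

atomSignature <- function(st) {
  a <- st@atoms
  paste(paste(a$serial, a$element, sep = ":"), collapse = ";")
}

#' Profile a trajectory into an interaction timeline
#'
#' Runs [detectInteractions()] on every frame and assembles the
#' per-frame presence matrix over all interaction keys discovered in any
#' frame. A key is (interaction kind, sorted ligand atom serials, protein
#' chain + residue number) - stable across frames. The ligand site
#' position is recorded wherever the interaction is present.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param ligandSelector see [detectInteractions()].
#' @param rules a [geometricRules()] list.
#' @param protonateAmines see [detectInteractions()].
#' @return An \linkS4class{InteractionTimeline}.
#' @export
profileTrajectory <- function(traj, ligandSelector,
                              rules = geometricRules(),
                              protonateAmines = TRUE) {
  nf <- length(traj@frames)
  if (nf == 0L) stop("empty trajectory")
  perFrame <- lapply(traj@frames, function(fr)
    detectInteractions(fr, ligandSelector, rules, protonateAmines))
  allKeys <- unique(unlist(lapply(perFrame, interactionKey)))
  allKeys <- sort(allKeys)
  nk <- length(allKeys)
  presence <- matrix(FALSE, nf, nk, dimnames = list(NULL, allKeys))
  sites <- lapply(seq_len(nk), function(i)
    matrix(NA_real_, nf, 3, dimnames = list(NULL, c("x", "y", "z"))))
  keyInfo <- vector("list", nk); names(keyInfo) <- allKeys
  for (f in seq_len(nf)) {
    ev <- perFrame[[f]]
    if (nrow(ev) == 0L) next
    kk <- interactionKey(ev)
    for (j in seq_len(nrow(ev))) {
      ki <- match(kk[j], allKeys)
      presence[f, ki] <- TRUE
      sites[[ki]][f, ] <- c(ev$x[j], ev$y[j], ev$z[j])
      if (is.null(keyInfo[[ki]]))
        keyInfo[[ki]] <- ev[j, c("kind", "ligSerials", "chain", "resno",
                                 "resname")]
    }
  }
  keys <- do.call(rbind, keyInfo)
  if (is.null(keys))
    keys <- data.frame(kind = character(0), ligSerials = character(0),
                       chain = character(0), resno = integer(0),
                       resname = character(0), stringsAsFactors = FALSE)
  keys$label <- rownames(keys) <- NULL
  keys$label <- allKeys
  names(sites) <- allKeys
  tl <- new("InteractionTimeline", keys = keys, presence = presence,
            sites = sites)
  attr(tl, "atomSignature") <- atomSignature(traj@frames[[1]])
  validObject(tl)
  tl
}

#' Concatenate replica timelines
#'
#' Appends frames in argument order; interaction keys are unioned, with
#' absent keys back-filled as not-present. Replicas must share the atom
#' identity of their source trajectories.
#'
#' @param timelines list of \linkS4class{InteractionTimeline} from
#'   [profileTrajectory()].
#' @return A combined \linkS4class{InteractionTimeline}.
#' @export
concatReplicas <- function(timelines) {
  stopifnot(length(timelines) >= 1L)
  sigs <- lapply(timelines, attr, "atomSignature")
  known <- !vapply(sigs, is.null, logical(1))
  if (any(known) && length(unique(unlist(sigs[known]))) > 1L)
    stop("replicas do not share atom identity")
  allKeys <- sort(unique(unlist(lapply(timelines, function(tl)
    tl@keys$label))))
  frameCounts <- vapply(timelines, function(tl) nrow(tl@presence),
                        integer(1))
  total <- sum(frameCounts)
  presence <- matrix(FALSE, total, length(allKeys),
                     dimnames = list(NULL, allKeys))
  sites <- lapply(allKeys, function(k)
    matrix(NA_real_, total, 3, dimnames = list(NULL, c("x", "y", "z"))))
  names(sites) <- allKeys
  keys <- NULL
  off <- 0L
  for (tl in timelines) {
    rows <- off + seq_len(nrow(tl@presence))
    for (k in tl@keys$label) {
      presence[rows, k] <- tl@presence[, k]
      sites[[k]][rows, ] <- tl@sites[[k]]
    }
    keys <- rbind(keys, tl@keys)
    off <- off + nrow(tl@presence)
  }
  keys <- keys[!duplicated(keys$label), , drop = FALSE]
  keys <- keys[match(allKeys, keys$label), , drop = FALSE]
  rownames(keys) <- NULL
  out <- new("InteractionTimeline", keys = keys, presence = presence,
             sites = sites)
  attr(out, "atomSignature") <- if (any(known)) sigs[known][[1]] else NULL
  validObject(out)
  out
}

#' Interaction occurrence frequencies
#'
#' Per-key occurrence percentage (100 x frames-present / frame count),
#' reported both at full precision and rounded to integer percent (the
#' usual reporting convention), plus the per-kind aggregate: the
#' percentage of frames in which any key of that kind is present.
#'
#' @param timeline an \linkS4class{InteractionTimeline}.
#' @return list of class \code{FrequencyReport}: \code{perKey}
#'   (data.frame label, kind, resno, chain, count, percent, percentInt)
#'   and \code{perKind} (data.frame kind, percent, percentInt);
#'   \code{frameCount}.
#' @export
interactionFrequencies <- function(timeline) {
  nf <- nrow(timeline@presence)
  stopifnot(nf >= 1L)
  counts <- colSums(timeline@presence)
  perKey <- data.frame(label = timeline@keys$label,
                       kind = timeline@keys$kind,
                       chain = timeline@keys$chain,
                       resno = timeline@keys$resno,
                       count = as.integer(counts),
                       percent = 100 * counts / nf,
                       stringsAsFactors = FALSE)
  perKey$percentInt <- as.integer(round(perKey$percent))
  kinds <- unique(timeline@keys$kind)
  perKind <- do.call(rbind, lapply(kinds, function(k) {
    cols <- which(timeline@keys$kind == k)
    anyP <- rowSums(timeline@presence[, cols, drop = FALSE]) > 0
    data.frame(kind = k, percent = 100 * sum(anyP) / nf,
               stringsAsFactors = FALSE)
  }))
  if (is.null(perKind))
    perKind <- data.frame(kind = character(0), percent = numeric(0))
  perKind$percentInt <- as.integer(round(perKind$percent))
  structure(list(perKey = perKey, perKind = perKind, frameCount = nf),
            class = "FrequencyReport")
}

#' @export
print.FrequencyReport <- function(x, ...) {
  cat(sprintf("FrequencyReport over %d frames:\n", x$frameCount))
  for (i in seq_len(nrow(x$perKey)))
    cat(sprintf("  %-45s %3d%%\n", x$perKey$label[i], x$perKey$percentInt[i]))
  invisible(x)
}

#' Interaction point clouds
#'
#' The multiset of ligand site positions at which each interaction is
#' present - the spatial spread of each dynamic feature.
#'
#' @param timeline an \linkS4class{InteractionTimeline}.
#' @return named list (one per key) of n x 3 matrices of positions.
#' @export
interactionClouds <- function(timeline) {
  lapply(timeline@sites, function(m)
    m[!is.na(m[, 1]), , drop = FALSE])
}

setMethod("show", "InteractionTimeline", function(object) {
  cat(sprintf("InteractionTimeline: %d frames x %d interaction keys\n",
              nrow(object@presence), nrow(object@keys)))
})
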