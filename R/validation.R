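# Screening-campaign statistics: confusion counts, ROC/AUC, enrichment,
# and property-matched decoy selection.

#' Confusion statistics for a screening report
#'
#' Counts hits against active / non-active labels. Actives are entries
#' labeled \code{"active"}; inactives and decoys both count as
#' non-active.
#'
#' @param report a \linkS4class{ScreenReport}.
#' @param labels named character vector (molecule id to label in
#'   \code{active}, \code{inactive}, \code{decoy}) or a data.frame with
#'   columns \code{id} and \code{label}.
#' @return list with \code{TP}, \code{FP}, \code{TN}, \code{FN},
#'   \code{sensitivity}, \code{specificity} (NA when undefined, i.e. a
#'   0/0 rate).
#' @export
evaluateScreen <- function(report, labels) {
  res <- report@results
  labels <- asLabelVector(labels)
  missing <- setdiff(res$id, names(labels))
  if (length(missing))
    stop(paste("unlabeled molecule ids:",
               paste(utils::head(missing, 10), collapse = ", ")))
  lab <- labels[res$id]
  bad <- setdiff(unique(lab), c("active", "inactive", "decoy"))
  if (length(bad))
    stop(paste("unknown labels:", paste(bad, collapse = ", ")))
  act <- lab == "active"
  TP <- sum(res$hit & act); FN <- sum(!res$hit & act)
  FP <- sum(res$hit & !act); TN <- sum(!res$hit & !act)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
}

asLabelVector <- function(labels) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$id)
  labels
}

#' ROC curve, AUC and enrichment factors
#'
#' Sweeps a decision threshold over the distinct scores (no-match
#' molecules enter with a score of \code{-Inf}, below every real score;
#' tied scores share one threshold step), accumulating true- and
#' false-positive rates. AUC is computed by the trapezoid rule.
#' \code{EF(f)} is the precision among the top-\code{f} fraction of the
#' ranking divided by the active base rate.
#'
#' @param scores numeric vector of per-molecule scores (use \code{-Inf}
#'   for no-match).
#' @param labels character vector parallel to \code{scores} (or named
#'   vector/data.frame as in [evaluateScreen()] when \code{scores} is
#'   named).
#' @param hits optional logical vector of hit decisions; when given, the
#'   confusion table at the hit threshold is included.
#' @param efFractions fractions for enrichment factors.
#' @return list of class \code{ROCReport}: \code{points} (data.frame
#'   \code{fpr}, \code{tpr}), \code{auc}, \code{ef} (named vector),
#'   \code{confusion} (or NULL).
#' @export
rocCurve <- function(scores, labels, hits = NULL,
                     efFractions = c(0.01, 0.05, 0.1)) {
  if (!is.null(names(scores)) && (is.data.frame(labels) ||
                                  !is.null(names(labels)))) {
    labels <- asLabelVector(labels)[names(scores)]
  }
  act <- labels == "active"
  nA <- sum(act); nN <- sum(!act)
  if (nA == 0L || nN == 0L)
    stop("ROC needs at least one active and one non-active")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; a <- act[ord]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tpA <- tapply(a, grp, sum); fpA <- tapply(!a, grp, sum)
  tpr <- c(0, cumsum(tpA) / nA)
  fpr <- c(0, cumsum(fpA) / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  n <- length(scores)
  baseRate <- nA / n
  ef <- vapply(efFractions, function(f) {
    k <- max(1L, ceiling(f * n))
    mean(a[seq_len(k)]) / baseRate
  }, numeric(1))
  names(ef) <- paste0("EF", efFractions * 100)
  confusion <- NULL
  if (!is.null(hits)) {
    confusion <- list(TP = sum(hits & act), FP = sum(hits & !act),
                      TN = sum(!hits & !act), FN = sum(!hits & act))
  }
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
                 ef = ef, confusion = confusion,
                 nActive = nA, nNonactive = nN),
            class = "ROCReport")
}

#' @export
print.ROCReport <- function(x, ...) {
  cat(sprintf("ROCReport: AUC %.3f (%d actives, %d non-actives)\n",
              x$auc, x$nActive, x$nNonactive))
  cat("  ", paste(sprintf("%s = %.2f", names(x$ef), x$ef),
                  collapse = ", "), "\n")
  if (!is.null(x$confusion))
    cat(sprintf("  at hit threshold: TP %d, FP %d, TN %d, FN %d\n",
                x$confusion$TP, x$confusion$FP, x$confusion$TN,
                x$confusion$FN))
  invisible(x)
}

#' Default decoy-matching property tolerances
#'
#' The classic property sextet used for property-matched decoy selection:
#' molecular weight, apolar-atom fraction, hydrogen-bond acceptor and
#' donor counts, rotatable bonds and formal charge.
#'
#' @return named list of tolerances (charge must match exactly).
#' @export
decoyTolerances <- function() {
  list(mw = 25, apolar_frac = 0.1, hba = 1, hbd = 1, rotb = 1, charge = 0)
}

#' Select property-matched decoys
#'
#' Picks pool entries whose properties match some active within all
#' tolerances. When more eligible candidates exist than requested, a
#' seeded sample is drawn; a shortfall (fewer eligible than requested) is
#' reported explicitly, never padded.
#'
#' @param actives data.frame with column \code{id} plus the property
#'   columns named in \code{tolerances}.
#' @param pool candidate data.frame, same columns.
#' @param tolerances named list, see [decoyTolerances()].
#' @param ratio requested decoys per active.
#' @param seed integer seed for the selection sample.
#' @return list with \code{decoys} (subset of \code{pool}),
#'   \code{requested}, \code{selected}, \code{shortfall},
#'   \code{matchedActive} (id of a matching active per decoy).
#' @export
pickDecoys <- function(actives, pool, tolerances = decoyTolerances(),
                       ratio = 50, seed = 1L) {
  props <- names(tolerances)
  miss <- setdiff(props, intersect(names(actives), names(pool)))
  if (length(miss))
    stop(paste("missing property columns:", paste(miss, collapse = ", ")))
  requested <- ratio * nrow(actives)
  # eligibility: within tolerance of at least one active on all properties
  matchOf <- rep(NA_character_, nrow(pool))
  for (i in seq_len(nrow(pool))) {
    ok <- rep(TRUE, nrow(actives))
    for (p in props)
      ok <- ok & abs(pool[[p]][i] - actives[[p]]) <= tolerances[[p]]
    if (any(ok)) matchOf[i] <- actives$id[which(ok)[1]]
  }
  eligible <- which(!is.na(matchOf))
  eligible <- eligible[!duplicated(pool$id[eligible])]
  nSel <- min(length(eligible), requested)
  sel <- if (length(eligible) > nSel) {
    withSeed(seed, sort(sample(eligible, nSel)))
  } else eligible
  list(decoys = pool[sel, , drop = FALSE], requested = requested,
       selected = nSel, shortfall = requested - nSel,
       matchedActive = matchOf[sel])
}

# Evaluate expr with a locally fixed RNG state; restores the caller's.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
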