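# Concentration-response analytics: four-parameter logistic fits, dose
# ratios and Schild regression with competitive-antagonism diagnostics.

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of
#' \deqn{r(c) = bottom + \frac{top - bottom}{1 + (half/c)^{hill}}}
#' parameterised in \code{log10(half)}, by Levenberg-Marquardt with
#' multi-start initialisation (quartile-based log-EC50 starts, several
#' Hill slopes). The Hill slope is positive for stimulation
#' (response rising with concentration) and negative for inhibition;
#' parameters are canonicalised to \code{bottom <= top}. The 95 percent
#' confidence interval on the half-maximal concentration is asymptotic on
#' the log scale.
#'
#' @param conc concentrations (must be positive; any consistent unit).
#' @param response responses (assay units), same length.
#' @param direction \code{"auto"} (default; both slope signs tried),
#'   \code{"stimulation"} or \code{"inhibition"}.
#' @return object of class \code{fourPL}: \code{bottom}, \code{top},
#'   \code{hill}, \code{halfMax} (EC50 or IC50 by context),
#'   \code{logHalf}, \code{logHalfSE}, \code{ci95} (on halfMax),
#'   \code{topSE}, \code{bottomSE}, \code{hillSE}, \code{residualSD},
#'   \code{converged}, \code{nObs}.
#' @export
fit4PL <- function(conc, response,
                   direction = c("auto", "stimulation", "inhibition")) {
  direction <- match.arg(direction)
  stopifnot(length(conc) == length(response))
  keep <- is.finite(conc) & is.finite(response)
  conc <- conc[keep]; response <- response[keep]
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(unique(conc)) < 4L)
    stop("4PL fitting needs at least 4 distinct concentrations")
  if (stats::var(response) == 0)
    stop("degenerate fit: responses have zero variance")
  x <- log10(conc)
  df <- data.frame(x = x, y = response)
  hillSigns <- switch(direction, auto = c(1, -1), stimulation = 1,
                      inhibition = -1)
  starts <- expand.grid(
    logE = unname(stats::quantile(x, c(0.25, 0.5, 0.75))),
    hill = as.vector(outer(c(0.7, 1, 2), hillSigns)))
  b0 <- min(response); t0 <- max(response)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (logE - x))),
      data = df,
      start = list(bottom = b0, top = t0, logE = starts$logE[s],
                   hill = starts$hill[s]),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(structure(list(converged = FALSE), class = "fourPL"))
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  bottom <- cf[["bottom"]]; top <- cf[["top"]]
  hill <- cf[["hill"]]; logE <- cf[["logE"]]
  bottomSE <- se[["bottom"]]; topSE <- se[["top"]]
  if (bottom > top) {  # same curve with swapped asymptotes, flipped slope
    tmp <- bottom; bottom <- top; top <- tmp
    tmp <- bottomSE; bottomSE <- topSE; topSE <- tmp
    hill <- -hill
  }
  logHalfSE <- se[["logE"]]
  ci <- 10^(logE + c(-1, 1) * 1.96 * logHalfSE)
  structure(list(bottom = bottom, top = top, hill = hill,
                 halfMax = 10^logE, logHalf = logE,
                 logHalfSE = logHalfSE, ci95 = ci,
                 topSE = topSE, bottomSE = bottomSE,
                 hillSE = se[["hill"]],
                 residualSD = sqrt(best$rss /
                                     max(1, length(response) - 4)),
                 converged = TRUE, nObs = length(response),
                 direction = direction),
            class = "fourPL")
}

#' @export
print.fourPL <- function(x, ...) {
  if (!x$converged) {
    cat("fourPL fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "fourPL fit: bottom %.3g, top %.3g, hill %.3g\n  halfMax %.4g (95%% CI %.4g - %.4g), residual SD %.3g, n = %d\n",
    x$bottom, x$top, x$hill, x$halfMax, x$ci95[1], x$ci95[2],
    x$residualSD, x$nObs))
  invisible(x)
}

#' Dose ratios from 4PL fits
#'
#' \code{DR(B) = halfMax(B) / halfMax(0)}: the fold-shift of the agonist
#' half-maximal concentration caused by antagonist concentration B.
#' Ratios of at most 1 are flagged unusable and excluded downstream.
#'
#' @param control \code{fourPL} fit of the control (no antagonist) curve.
#' @param treated list of \code{fourPL} fits at increasing antagonist
#'   concentrations.
#' @param B numeric antagonist concentrations, parallel to
#'   \code{treated}.
#' @return data.frame with columns \code{B}, \code{DR}, \code{usable}.
#' @export
doseRatios <- function(control, treated, B) {
  stopifnot(length(treated) == length(B))
  if (is.null(control) || !isTRUE(control$converged))
    stop("control fit missing or not converged")
  conv <- vapply(treated, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv))
    stop("all treated fits must be converged")
  DR <- vapply(treated, function(f) f$halfMax, numeric(1)) /
    control$halfMax
  data.frame(B = B, DR = DR, usable = DR > 1)
}

#' Schild regression
#'
#' Ordinary least squares of \eqn{\log_{10}(DR - 1)} on
#' \eqn{\log_{10} B} over the usable (DR > 1) dose ratios. The pA2 is the
#' negated abscissa at which the regression line crosses
#' \eqn{\log_{10}(DR - 1) = 0}; for a competitive antagonist with unit
#' slope it equals \eqn{-\log_{10} K_B}. The unity-constrained fit is the
#' intercept-only regression of \eqn{\log_{10}(DR-1) - \log_{10} B},
#' whose mean estimates \eqn{pK_B} directly. When the underlying 4PL
#' fits are supplied, the competitive-antagonism diagnostics are
#' evaluated: the unconstrained slope 95 percent CI must contain 1 and
#' the top (Emax) asymptotes must be statistically unchanged
#' (overlapping 95 percent CIs against the control).
#'
#' @param ratios data.frame from [doseRatios()] (columns B, DR).
#' @param controlFit,treatedFits optional \code{fourPL} fits enabling the
#'   Emax / parallelism diagnostics.
#' @return object of class \code{schildResult}: \code{slope},
#'   \code{intercept}, \code{slopeCI}, \code{pA2},
#'   \code{pKBConstrained}, \code{nUsable}, \code{excluded} (B values
#'   with DR <= 1), \code{emaxUnchangedOk}, \code{parallelShiftOk},
#'   \code{competitiveOk}, \code{points} (the regression data).
#' @export
schildRegression <- function(ratios, controlFit = NULL,
                             treatedFits = NULL) {
  use <- ratios$DR > 1
  if (!any(use))
    stop("no antagonism: all dose ratios are at most 1")
  if (sum(use) < 2L)
    stop("Schild regression needs at least 2 usable (DR > 1) points")
  excluded <- ratios$B[!use]
  pts <- data.frame(logB = log10(ratios$B[use]),
                    logDRm1 = log10(ratios$DR[use] - 1))
  fit <- stats::lm(logDRm1 ~ logB, data = pts)
  cf <- stats::coef(fit)
  slope <- unname(cf["logB"]); intercept <- unname(cf["(Intercept)"])
  slopeCI <- if (nrow(pts) >= 3L) {
    suppressWarnings(unname(stats::confint(fit)["logB", ]))
  } else c(NA_real_, NA_real_)
  pA2 <- intercept / slope  # -log10 B at log10(DR-1) = 0
  pKB <- mean(pts$logDRm1 - pts$logB)
  emaxOk <- NA; parOk <- NA
  if (!is.null(controlFit) && !is.null(treatedFits)) {
    emaxOk <- emaxUnchanged(controlFit, treatedFits)
    parOk <- hillParallel(controlFit, treatedFits)
  }
  competitive <- if (is.na(emaxOk) || any(is.na(slopeCI))) NA else
    (slopeCI[1] <= 1 && 1 <= slopeCI[2] && emaxOk)
  structure(list(slope = slope, intercept = intercept,
                 slopeCI = slopeCI, pA2 = pA2, pKBConstrained = pKB,
                 nUsable = nrow(pts), excluded = excluded,
                 emaxUnchangedOk = emaxOk, parallelShiftOk = parOk,
                 competitiveOk = competitive, points = pts),
            class = "schildResult")
}

#' @export
print.schildResult <- function(x, ...) {
  cat(sprintf(
    "Schild regression (%d points): slope %.3f (95%% CI %.3f - %.3f)\n",
    x$nUsable, x$slope, x$slopeCI[1], x$slopeCI[2]))
  cat(sprintf("  pA2 %.3f; unity-constrained pKB %.3f\n", x$pA2,
              x$pKBConstrained))
  if (!is.na(x$competitiveOk))
    cat(sprintf("  competitive-antagonism diagnostic: %s (Emax unchanged: %s)\n",
                x$competitiveOk, x$emaxUnchangedOk))
  if (length(x$excluded))
    cat("  excluded (DR <= 1) at B =",
        paste(signif(x$excluded, 3), collapse = ", "), "\n")
  invisible(x)
}

ciOverlap <- function(a, aSE, b, bSE) {
  (a - 1.96 * aSE) <= (b + 1.96 * bSE) &&
    (b - 1.96 * bSE) <= (a + 1.96 * aSE)
}

#' Emax-unchanged diagnostic
#'
#' A competitive antagonist shifts the agonist curve rightward without
#' depressing its maximum: the treated top asymptotes must be
#' statistically indistinguishable from the control's (overlapping 95
#' percent asymptotic CIs). Returns FALSE when any antagonist
#' concentration suppresses Emax - the signature of non-competitive
#' antagonism.
#'
#' @inheritParams doseRatios
#' @return logical.
#' @export
emaxUnchanged <- function(control, treated) {
  all(vapply(treated, function(f)
    ciOverlap(control$top, control$topSE, f$top, f$topSE), logical(1)))
}

#' Parallel-shift diagnostic
#'
#' TRUE when every treated Hill slope is statistically indistinguishable
#' from the control's (overlapping 95 percent CIs): rightward shifts are
#' parallel.
#'
#' @inheritParams doseRatios
#' @return logical.
#' @export
hillParallel <- function(control, treated) {
  all(vapply(treated, function(f)
    ciOverlap(control$hill, control$hillSE, f$hill, f$hillSE),
    logical(1)))
}

#' Full Schild analysis from fitted curves
#'
#' Convenience wrapper: dose ratios from the fits, then
#' [schildRegression()] with the diagnostics enabled.
#'
#' @inheritParams doseRatios
#' @return A \code{schildResult}.
#' @export
schildAnalysis <- function(control, treated, B) {
  ratios <- doseRatios(control, treated, B)
  schildRegression(ratios, controlFit = control, treatedFits = treated)
}

#' Schild analysis straight from a dose-response table
#'
#' Fits one 4PL curve per antagonist concentration (0 = control) and runs
#' the Schild analysis.
#'
#' @param data data.frame with columns \code{antagonist_conc},
#'   \code{agonist_conc}, \code{response} (see [readDoseResponse()]).
#' @param direction passed to [fit4PL()].
#' @return list with \code{fits} (named by antagonist concentration),
#'   \code{schild} (a \code{schildResult}).
#' @export
schildFromData <- function(data, direction = "stimulation") {
  Bs <- sort(unique(data$antagonist_conc))
  if (!0 %in% Bs) stop("control (antagonist_conc = 0) missing")
  fits <- lapply(Bs, function(b) {
    d <- data[data$antagonist_conc == b, ]
    fit4PL(d$agonist_conc, d$response, direction)
  })
  names(fits) <- as.character(Bs)
  treated <- fits[-1]
  sch <- schildAnalysis(fits[[1]], treated, Bs[-1])
  list(fits = fits, schild = sch)
}
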