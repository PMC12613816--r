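# Independent oracles and fixture builders shared across the suite.

# --- monoisotopic mass oracle: own copy of the isotope constants, summed
# term by term in a different order than the implementation -------------
ORACLE_MASS <- list(
  H = 1.00782503, C = 12.0, N = 14.00307401, O = 15.99491462,
  S = 31.97207117, F = 18.99840316, Cl = 34.96885268, Br = 78.91833760,
  P = 30.97376200, I = 126.90447190)
ORACLE_ELECTRON <- 0.00054858

oracleMz <- function(counts, charge = 1) {
  total <- 0
  for (el in rev(sort(names(counts)))) {
    for (k in seq_len(counts[[el]])) total <- total + ORACLE_MASS[[el]]
  }
  (total - charge * ORACLE_ELECTRON) / charge
}

randomFormula <- function() {
  els <- sample(names(ORACLE_MASS), sample(2:6, 1))
  counts <- sample(1:40, length(els), replace = TRUE)
  stats::setNames(as.list(counts), els)
}

# --- correspondence-search oracle: exhaustive enumeration of
# kind-compatible injections with the pairwise consistency filter -------
oracleMappings <- function(model, conf, settings = screenSettings()) {
  mf <- features(model)
  nM <- nrow(mf); nC <- nrow(conf)
  dM <- as.matrix(dist(mf[, c("x", "y", "z")]))
  dC <- as.matrix(dist(conf[, c("x", "y", "z")]))
  tolSum <- outer(mf$tolerance, mf$tolerance, "+") *
    settings$toleranceScale
  all <- list()
  recurse <- function(i, used, pairs) {
    if (i > nM) {
      if (nrow(pairs) >= settings$minRequired)
        all[[length(all) + 1L]] <<- pairs
      return()
    }
    recurse(i + 1L, used, pairs)  # skip model feature i
    for (j in setdiff(which(conf$kind == mf$kind[i]), used)) {
      ok <- TRUE
      for (r in seq_len(nrow(pairs))) {
        if (abs(dM[pairs[r, 1], i] - dC[pairs[r, 2], j]) >
            tolSum[pairs[r, 1], i]) { ok <- FALSE; break }
      }
      if (ok) recurse(i + 1L, c(used, j), rbind(pairs, c(i, j)))
    }
  }
  recurse(1L, integer(0), matrix(integer(0), 0, 2))
  if (!length(all)) return(list())
  keys <- vapply(all, function(p) paste(t(p), collapse = ","),
                 character(1))
  all <- all[!duplicated(keys)]
  # maximal only: not a strict subset of another consistent mapping
  pairSets <- lapply(all, function(p) paste(p[, 1], p[, 2]))
  maximal <- vapply(seq_along(all), function(a) {
    !any(vapply(seq_along(all), function(b) {
      b != a && length(pairSets[[b]]) > length(pairSets[[a]]) &&
        all(pairSets[[a]] %in% pairSets[[b]])
    }, logical(1)))
  }, logical(1))
  all[maximal]
}

mappingKeySet <- function(maps) {
  sort(vapply(maps, function(m) {
    m <- m[order(m[, 1]), , drop = FALSE]
    paste(t(m), collapse = ",")
  }, character(1)))
}

# independent superposition for the score oracle (explicit centred
# cross-covariance + svd, written separately from the package's)
oracleFitScore <- function(model, conf, mapping, settings) {
  mf <- features(model)
  Q <- as.matrix(mf[mapping[, 1], c("x", "y", "z")])
  P <- as.matrix(conf[mapping[, 2], c("x", "y", "z")])
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  degen <- function(M) {
    d <- svd(M, nu = 0, nv = 0)$d
    d[2] <= 1e-8 * max(d[1], 1)
  }
  if (degen(Qc) || degen(Pc)) return(NULL)
  sv <- svd(t(Pc) %*% Qc)
  R <- sv$u %*% diag(c(1, 1, sign(det(sv$u) * det(sv$v)))) %*% t(sv$v)
  fitted <- Pc %*% R
  dev <- sqrt(rowSums((fitted - Qc)^2))
  tol <- mf$tolerance[mapping[, 1]] * settings$toleranceScale
  valid <- dev <= tol
  nValid <- sum(valid)
  rmsdValid <- if (nValid) sqrt(mean(dev[valid]^2)) else 0
  nValid - rmsdValid / mean(mf$tolerance[mapping[, 1]])
}

oracleBestScore <- function(model, conf, settings = screenSettings()) {
  maps <- oracleMappings(model, conf, settings)
  best <- -Inf
  for (m in maps) {
    if (nrow(m) < 3L) next
    s <- oracleFitScore(model, conf, m, settings)
    if (!is.null(s) && s > best) best <- s
  }
  best
}

# --- Mann-Whitney pair-counting AUC oracle -----------------------------
oracleAUC <- function(scores, labels) {
  a <- scores[labels == "active"]
  n <- scores[labels != "active"]
  tot <- 0
  for (x in a) tot <- tot + sum(x > n) + 0.5 * sum(x == n)
  tot / (length(a) * length(n))
}

# --- consensus cluster-and-count oracle (exhaustive, order-free) -------
# single-kind, well-separated planted positions: count distinct source
# models contributing a feature within mergeRadius of each planted site
oracleConsensusRetained <- function(models, plantedPos, mergeRadius,
                                    threshold, strictGreater = TRUE) {
  srcs <- integer(0)
  for (i in seq_along(models)) {
    f <- features(models[[i]])
    if (nrow(f) == 0L) next
    d <- sqrt((f$x - plantedPos[1])^2 + (f$y - plantedPos[2])^2 +
                (f$z - plantedPos[3])^2)
    if (any(d <= mergeRadius)) srcs <- c(srcs, i)
  }
  n <- length(unique(srcs))
  if (strictGreater) n > threshold else n >= threshold
}

# --- shared fixtures ---------------------------------------------------
toyModel <- function(seed = 1L, kinds = c("HBA", "PI", "HYD", "HYD",
                                          "HYD")) {
  cx <- genComplex(seed = seed)
  deriveModel(detectInteractions(cx$structure, cx$ligand),
              frameLabel = sprintf("toy%d", seed))
}

randomModel <- function(n = 5, tol = 1.5) {
  kinds <- sample(c("HBA", "HBD", "HYD", "PI", "AR"), n, replace = TRUE)
  pharmacophoreModel(data.frame(
    kind = kinds, x = runif(n, -5, 5), y = runif(n, -5, 5),
    z = runif(n, -5, 5), tolerance = tol, stringsAsFactors = FALSE))
}

jitterConf <- function(model, sd = 0.2) {
  f <- features(model)
  data.frame(kind = f$kind, x = f$x + rnorm(nrow(f), 0, sd),
             y = f$y + rnorm(nrow(f), 0, sd),
             z = f$z + rnorm(nrow(f), 0, sd), stringsAsFactors = FALSE)
}
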