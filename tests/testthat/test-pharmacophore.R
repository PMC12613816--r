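test_that("derived models map event kinds and carry residue anchors", {
  cx <- genComplex(seed = 4)  # 1 acceptor H-bond, 1 ionic, 3 hydrophobic
  ev <- detectInteractions(cx$structure, cx$ligand)
  m <- deriveModel(ev, frameLabel = "pocket")
  expect_s4_class(m, "PharmacophoreModel")
  expect_equal(sort(features(m)$kind), c("HBA", "HYD", "HYD", "HYD", "PI"))
  expect_equal(nFeatures(m), 5L)
  anchors <- unlist(features(m)$anchors)
  expect_true(all(grepl("^[A-Z]\\d+", anchors)))
  # single event -> single feature
  m1 <- deriveModel(ev[1, , drop = FALSE])
  expect_equal(nFeatures(m1), 1L)
  # duplicated events collapse to one feature with unioned anchors
  m2 <- deriveModel(rbind(ev, ev))
  expect_equal(nFeatures(m2), 5L)
  expect_error(deriveModel(ev[0, ]), "zero events")
})

test_that("overlay recovers an applied rigid motion", {
  m <- toyModel(seed = 6)
  self <- overlayModels(m, m)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)
  set.seed(31)
  R <- phoreseek:::randomRotation(); t <- c(4, -7, 2)
  f <- features(m)
  xyz <- phoreseek:::applyRigid(as.matrix(f[, c("x", "y", "z")]), R, t)
  f$x <- xyz[, 1]; f$y <- xyz[, 2]; f$z <- xyz[, 3]
  moved <- pharmacophoreModel(f, "moved")
  ov <- overlayModels(moved, m)
  expect_lt(ov$rmsd, 1e-6)
  # re-canonicalise: the moved model's feature order differs from m's
  back <- features(pharmacophoreModel(features(ov$model)))
  expect_equal(as.matrix(back[, c("x", "y", "z")]),
               as.matrix(features(m)[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(overlayModels(pharmacophoreModel(f[1:2, ]), m),
               "overlay failed")
})

test_that("overlay RMSD equals the exhaustive-assignment oracle", {
  set.seed(17)
  for (rep in 1:10) {
    ref <- randomModel(5)
    f <- features(ref)[sample(5, 4), ]
    f$x <- f$x + rnorm(4, 0, 0.3); f$y <- f$y + rnorm(4, 0, 0.3)
    f$z <- f$z + rnorm(4, 0, 0.3)
    sib <- pharmacophoreModel(f, "sib")
    ov <- tryCatch(overlayModels(sib, ref), error = function(e) NULL)
    # oracle: every same-kind injection of max size, closed-form fit
    maps <- oracleMappings(ref, features(sib)[, c("kind", "x", "y", "z")],
                           screenSettings(minRequired = 3L))
    best <- NULL
    for (mp in maps) {
      if (nrow(mp) < 3L) next
      P <- as.matrix(features(sib)[mp[, 2], c("x", "y", "z")])
      Q <- as.matrix(features(ref)[mp[, 1], c("x", "y", "z")])
      k <- tryCatch(phoreseek:::kabsch(P, Q), error = function(e) NULL)
      if (is.null(k)) next
      if (is.null(best) || nrow(mp) > best$n ||
          (nrow(mp) == best$n && k$rmsd < best$rmsd))
        best <- list(n = nrow(mp), rmsd = k$rmsd)
    }
    if (is.null(best)) {
      expect_null(ov)
    } else {
      expect_equal(ov$rmsd, best$rmsd, tolerance = 1e-9)
    }
  }
})

consensusSuite <- function(k, nModels = 8, strictGreater = TRUE,
                           threshold = 4) {
  # one HBA planted at a fixed site in exactly k of nModels models; every
  # model also carries a far-away PI so no model is empty
  models <- lapply(seq_len(nModels), function(i) {
    rows <- data.frame(kind = "PI", x = 40, y = 0, z = 0, tolerance = 1.5,
                       stringsAsFactors = FALSE)
    if (i <= k)
      rows <- rbind(rows, data.frame(kind = "HBA", x = runif(1, -0.3, 0.3),
                                     y = runif(1, -0.3, 0.3),
                                     z = runif(1, -0.3, 0.3),
                                     tolerance = 1.5))
    pharmacophoreModel(rows, sprintf("m%d", i))
  })
  cons <- consensusModel(models, threshold = threshold,
                         strictGreater = strictGreater)
  list(models = models, retained = "HBA" %in% features(cons)$kind,
       cons = cons)
}

test_that("consensus retains features by the more-than-threshold rule", {
  set.seed(5)
  for (k in 1:8) {
    r <- consensusSuite(k)
    expect_identical(r$retained, k > 4)
    expect_identical(
      oracleConsensusRetained(r$models, c(0, 0, 0), 1.5, 4), k > 4)
    # at-least semantics behind the flag
    r2 <- consensusSuite(k, strictGreater = FALSE)
    expect_identical(r2$retained, k >= 4)
  }
})

test_that("eight identical models keep all features at their positions", {
  m <- toyModel(seed = 8)
  cons <- consensusModel(rep(list(m), 8), threshold = 4)
  expect_equal(features(cons)[, c("kind", "x", "y", "z")],
               features(m)[, c("kind", "x", "y", "z")])
  # a single model cannot pass a more-than-four rule: empty consensus
  empty <- consensusModel(list(m), threshold = 4)
  expect_equal(nFeatures(empty), 0L)
})

test_that("consensus feature count is non-increasing in the threshold", {
  set.seed(23)
  models <- lapply(1:8, function(i) {
    f <- features(toyModel(seed = 2))
    keep <- sort(sample(nrow(f), sample(2:nrow(f), 1)))
    pharmacophoreModel(f[keep, ], sprintf("m%d", i))
  })
  counts <- vapply(1:8, function(th)
    nFeatures(consensusModel(models, threshold = th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("consensus is invariant to the order of input models", {
  set.seed(41)
  r <- consensusSuite(6)
  base <- features(r$cons)
  for (i in 1:5) {
    perm <- sample(8)
    shuffled <- consensusModel(r$models[perm], threshold = 4)
    expect_equal(features(shuffled)[, c("kind", "x", "y", "z")], base[
      , c("kind", "x", "y", "z")], tolerance = 1e-12)
  }
})

test_that("pharmacophore JSON round-trips through the schema", {
  m <- toyModel(seed = 12)
  f <- features(m)
  f$dirx[1] <- 1; f$diry[1] <- 0; f$dirz[1] <- 0
  m <- pharmacophoreModel(f, m@frameLabel, provenance = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".json")
  writePharmacophore(m, path)
  back <- readPharmacophore(path)
  expect_equal(features(back)$x, features(m)$x)
  expect_equal(features(back)$dirx, features(m)$dirx)
  expect_equal(features(back)$anchors[[2]], features(m)$anchors[[2]])
  expect_equal(back@provenance, c("a", "b"))
  expect_equal(jsonlite::read_json(path)$schema_version, 1L)
})
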