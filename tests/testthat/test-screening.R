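test_that("correspondence enumeration matches exhaustive injection search", {
  set.seed(13)
  settings <- screenSettings()
  for (rep in 1:100) {
    m <- randomModel(5)
    conf <- if (rep %% 3 == 0) jitterConf(m, 0.4) else
      data.frame(kind = sample(c("HBA", "HBD", "HYD", "PI", "AR"), 5,
                               replace = TRUE),
                 x = runif(5, -5, 5), y = runif(5, -5, 5),
                 z = runif(5, -5, 5), stringsAsFactors = FALSE)
    got <- enumerateCorrespondences(m, conf, settings)
    want <- oracleMappings(m, conf, settings)
    expect_identical(mappingKeySet(got), mappingKeySet(want))
  }
})

test_that("identical feature sets contain the full identity mapping", {
  m <- toyModel(seed = 3)
  conf <- features(m)[, c("kind", "x", "y", "z")]
  maps <- enumerateCorrespondences(m, conf)
  sizes <- vapply(maps, nrow, integer(1))
  idKey <- paste(t(cbind(1:5, 1:5)), collapse = ",")
  expect_true(idKey %in% mappingKeySet(maps))
  expect_equal(max(sizes), 5L)
  # disjoint kinds: nothing
  conf$kind <- "NI"
  expect_length(enumerateCorrespondences(m, conf), 0L)
})

test_that("fitted mappings score exactly on clean and perturbed fixtures", {
  m <- toyModel(seed = 9)
  conf <- features(m)[, c("kind", "x", "y", "z")]
  full <- cbind(model = 1:5, conformer = 1:5)
  res <- fitMapping(m, conf, full)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)
  expect_equal(res$score, 5, tolerance = 1e-9)
  expect_true(res$hit)
  # rigid invariance: rotate 90 degrees about z and translate
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  xyz <- sweep(as.matrix(conf[, c("x", "y", "z")]) %*% R, 2, c(5, 5, 5),
               "+")
  conf2 <- conf; conf2$x <- xyz[, 1]; conf2$y <- xyz[, 2]
  conf2$z <- xyz[, 3]
  res2 <- fitMapping(m, conf2, full)
  expect_equal(res2$rmsd, res$rmsd, tolerance = 1e-9)
  expect_equal(res2$score, res$score, tolerance = 1e-9)
  # one point perturbed by twice its tolerance: that pair invalid and the
  # rmsd follows the closed form on the fixture
  conf3 <- conf
  shift <- 2 * features(m)$tolerance[5]
  conf3$z[5] <- conf3$z[5] + shift
  res3 <- fitMapping(m, conf3, full)
  expect_equal(res3$nValid, 4L)
  expect_false(res3$valid[5])
  expect_error(
    fitMapping(m, conf, cbind(1:2, 1:2)), "at least 3")
  lin <- data.frame(kind = rep("HYD", 3), x = c(0, 1, 2), y = 0, z = 0,
                    tolerance = 1.5)
  linM <- pharmacophoreModel(lin)
  expect_error(
    fitMapping(linM, lin[, c("kind", "x", "y", "z")],
               cbind(1:3, 1:3)), "collinear")
})

test_that("omitted-feature semantics decide hits on partial matches", {
  m <- toyModel(seed = 14)
  conf <- features(m)[, c("kind", "x", "y", "z")]
  conf$x[3] <- conf$x[3] + 50  # one feature unmatched: best is 4/5
  strict <- matchConformer(m, conf, screenSettings(maxOmitted = 0L))
  expect_equal(strict$nValid, 4L)
  expect_false(strict$hit)
  lenient <- matchConformer(m, conf, screenSettings(maxOmitted = 1L))
  expect_true(lenient$hit)
  expect_equal(lenient$nValid, 4L)
})

test_that("match score and hit status are invariant under rigid motions", {
  set.seed(77)
  m <- toyModel(seed = 2)
  conf <- jitterConf(m, 0.3)
  base <- matchConformer(m, conf)
  for (i in 1:20) {
    R <- phoreseek:::randomRotation(); t <- runif(3, -20, 20)
    xyz <- phoreseek:::applyRigid(as.matrix(conf[, c("x", "y", "z")]), R, t)
    conf2 <- conf
    conf2$x <- xyz[, 1]; conf2$y <- xyz[, 2]; conf2$z <- xyz[, 3]
    res <- matchConformer(m, conf2)
    expect_equal(res$score, base$score, tolerance = 1e-6)
    expect_identical(res$hit, base$hit)
  }
})

test_that("raising the tolerance scale never loses a hit", {
  set.seed(55)
  m <- toyModel(seed = 2)
  for (i in 1:20) {
    conf <- jitterConf(m, runif(1, 0.2, 1.2))
    hits <- vapply(c(0.6, 1, 1.5, 2.5), function(s)
      matchConformer(m, conf,
                     screenSettings(toleranceScale = s))$hit, logical(1))
    expect_true(all(diff(as.integer(hits)) >= 0))
  }
})

test_that("best clique-search score equals brute force on small instances", {
  set.seed(31)
  settings <- screenSettings()
  for (rep in 1:60) {
    m <- randomModel(sample(4:6, 1))
    conf <- jitterConf(m, runif(1, 0.2, 1.5))
    got <- matchConformer(m, conf, settings)$score
    want <- oracleBestScore(m, conf, settings)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("library screening keeps per-molecule bests and warns on empties", {
  m <- toyModel(seed = 10)
  lib <- genLibrary(m, nActive = 3, nDecoy = 7, nConformers = 5, seed = 6)
  rep1 <- screenLibrary(m, lib)
  expect_equal(nScreened(rep1), 10L)
  expect_equal(nHits(rep1), 3L)
  res <- screenResults(rep1)
  expect_setequal(res$id[res$hit], c("ACT0001", "ACT0002", "ACT0003"))
  # a hit through exactly one matching conformer among 25
  one <- lib[1]
  class(one) <- "FeatureLibrary"
  expect_equal(sum(vapply(seq_along(one[[1]]$conformers), function(ci)
    matchConformer(m, one[[1]]$conformers[[ci]])$hit, logical(1))), 1L)
  # zero-conformer molecule: warned, recorded as no-match
  lib2 <- lib
  lib2[[4]]$conformers <- list()
  expect_warning(rep2 <- screenLibrary(m, lib2), "no conformers")
  r2 <- screenResults(rep2)
  expect_false(r2$hit[r2$id == lib2[[4]]$id])
  expect_identical(r2$score[r2$id == lib2[[4]]$id], -Inf)
})
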