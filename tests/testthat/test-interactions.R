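mkComplex <- function(df) {
  new("StructureModel", atoms = df, modelId = 1L)
}

atomRow <- function(serial, name, element, resname, resno, chain, pos,
                    charge = 0L) {
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resno = resno, chain = chain,
             x = pos[1], y = pos[2], z = pos[3], charge = charge,
             record = if (resname == "LIG") "HETATM" else "ATOM",
             stringsAsFactors = FALSE)
}

test_that("a ligand donor with explicit hydrogen needs distance AND angle", {
  # ligand N-H pointing at a backbone O 2.9 A away, D-H...A about 165 deg
  mk <- function(oPos) mkComplex(rbind(
    atomRow(1, "N1", "N", "LIG", 1, "L", c(0, 0, 0)),
    atomRow(2, "H1", "H", "LIG", 1, "L", c(0.97, 0.1, 0)),
    atomRow(3, "O", "O", "ALA", 10, "A", oPos),
    atomRow(4, "C", "C", "ALA", 10, "A", oPos + c(0, 1.23, 0))))
  ev <- detectInteractions(mk(c(2.9, 0, 0)), "LIG:L")
  expect_equal(ev$kind, "HBOND_LIG_DONOR")
  expect_equal(ev$distance, 2.9, tolerance = 1e-9)
  expect_gt(ev$angle, 160)
  # stretched beyond the distance cutoff: nothing
  expect_equal(nrow(detectInteractions(mk(c(4.0, 0, 0)), "LIG:L")), 0L)
  # bad geometry: acceptor perpendicular to the N-H bond at 2.9 A
  expect_equal(nrow(detectInteractions(mk(c(0, 2.9, 0)), "LIG:L")), 0L)
})

test_that("planted pockets are recovered exactly, event per site", {
  planted <- c("HBOND_LIG_ACCEPTOR", "HBOND_LIG_DONOR", "HYDROPHOBIC",
               "HYDROPHOBIC", "IONIC", "AROMATIC_PI")
  cx <- genComplex(seed = 11, planted = planted)
  ev <- detectInteractions(cx$structure, cx$ligand)
  expect_equal(sort(ev$kind), sort(planted))
  expect_setequal(paste(ev$kind, ev$resno),
                  paste(cx$events$kind, cx$events$resno))
  rules <- geometricRules()
  expect_true(all(ev$distance[ev$kind %in% c("HBOND_LIG_ACCEPTOR",
                                             "HBOND_LIG_DONOR")] <=
                    rules$hbondDistMax))
  expect_true(all(ev$distance[ev$kind == "HYDROPHOBIC"] <=
                    rules$hydrophobicDistMax))
  expect_true(all(ev$distance[ev$kind == "IONIC"] <= rules$ionicDistMax))
})

test_that("events are equivariant under rigid motion of the complex", {
  cx <- genComplex(seed = 21)
  ev <- detectInteractions(cx$structure, cx$ligand)
  set.seed(99)
  R <- phoreseek:::randomRotation(); t <- runif(3, -10, 10)
  st2 <- cx$structure
  xyz <- as.matrix(atoms(st2)[, c("x", "y", "z")])
  xyz <- phoreseek:::applyRigid(xyz, R, t)
  st2@atoms$x <- xyz[, 1]; st2@atoms$y <- xyz[, 2]; st2@atoms$z <- xyz[, 3]
  ev2 <- detectInteractions(st2, cx$ligand)
  expect_identical(paste(ev$kind, ev$resno), paste(ev2$kind, ev2$resno))
  expect_equal(ev2$distance, ev$distance, tolerance = 1e-6)
  mapped <- phoreseek:::applyRigid(as.matrix(ev[, c("x", "y", "z")]), R, t)
  expect_equal(as.matrix(ev2[, c("x", "y", "z")]), mapped,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("tightening any rule threshold never increases the event count", {
  for (seed in 1:5) {
    cx <- genComplex(seed = seed,
                     planted = c("HBOND_LIG_ACCEPTOR", "HBOND_LIG_DONOR",
                                 "HYDROPHOBIC", "IONIC", "AROMATIC_PI"))
    base <- geometricRules()
    n0 <- nrow(detectInteractions(cx$structure, cx$ligand, base))
    for (frac in c(0.9, 0.7, 0.5)) {
      tight <- geometricRules(
        hbondDistMax = base$hbondDistMax * frac,
        hydrophobicDistMax = base$hydrophobicDistMax * frac,
        ionicDistMax = base$ionicDistMax * frac,
        aromaticDistMax = base$aromaticDistMax * frac)
      n1 <- nrow(detectInteractions(cx$structure, cx$ligand, tight))
      expect_lte(n1, n0)
      n0 <- n1
    }
  }
})

test_that("ligand feature classification follows the chemistry rules", {
  # protonated amine nitrogen -> PI at that nitrogen
  amine <- rbind(
    atomRow(1, "N1", "N", "LIG", 1, "L", c(0, 0, 0), charge = 1L),
    atomRow(2, "C1", "C", "LIG", 1, "L", c(1.5, 0, 0)))
  f <- classifyLigandFeatures(amine)
  expect_true("PI" %in% f$kind)
  expect_equal(f[f$kind == "PI", c("x", "y", "z")],
               data.frame(x = 0, y = 0, z = 0), ignore_attr = TRUE)
  # a butyl-like chain -> one HYD feature at the member centroid
  chain <- do.call(rbind, lapply(1:4, function(i)
    atomRow(i, paste0("C", i), "C", "LIG", 1, "L",
            c(1.5 * (i - 1), 0.3 * (i %% 2), 0))))
  f <- classifyLigandFeatures(chain)
  hyd <- f[f$kind == "HYD", ]
  expect_equal(nrow(hyd), 1L)
  expect_equal(c(hyd$x, hyd$y, hyd$z),
               colMeans(as.matrix(chain[, c("x", "y", "z")])),
               ignore_attr = TRUE)
  # a planar 5-ring with an N: ring nitrogen counts as HBA, ring as AR
  ring <- do.call(rbind, lapply(0:4, function(k) {
    ang <- 2 * pi * k / 5
    atomRow(k + 1, paste0(ifelse(k == 0, "N", "C"), k + 1),
            ifelse(k == 0, "N", "C"), "LIG", 1, "L",
            1.33 * c(cos(ang), sin(ang), 0))
  }))
  f <- classifyLigandFeatures(ring)
  expect_true("AR" %in% f$kind)
  expect_true("HBA" %in% f$kind)
  # empty input chemistry: a lone carbon has no features
  lone <- atomRow(1, "C1", "C", "LIG", 1, "L", c(0, 0, 0))
  expect_equal(nrow(classifyLigandFeatures(lone)), 0L)
})

test_that("selector errors are informative", {
  cx <- genComplex(seed = 1)
  expect_error(detectInteractions(cx$structure, "XXX:9"), "no atoms")
})
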