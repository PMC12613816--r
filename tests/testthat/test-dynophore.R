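test_that("planted schedules are recovered column for column", {
  cx <- genComplex(seed = 2, planted = c("HBOND_LIG_ACCEPTOR", "IONIC"))
  sched <- list(c(TRUE, TRUE, FALSE, TRUE), rep(TRUE, 4))
  tr <- genTrajectory(cx, sched, nFrames = 4, seed = 3)
  tl <- profileTrajectory(tr, cx$ligand)
  hb <- grep("HBOND", tl@keys$label)
  expect_equal(unname(tl@presence[, hb]), c(TRUE, TRUE, FALSE, TRUE))
  fr <- interactionFrequencies(tl)
  expect_equal(fr$perKey$percent[fr$perKey$kind == "HBOND_LIG_ACCEPTOR"],
               75)
  expect_equal(fr$perKey$percent[fr$perKey$kind == "IONIC"], 100)
})

test_that("a static trajectory reports every key at 100 percent", {
  cx <- genComplex(seed = 6)
  tr <- genTrajectory(cx, rep(list(rep(TRUE, 5)), length(cx$sites)),
                      nFrames = 5, noiseSd = 0, seed = 1)
  tl <- profileTrajectory(tr, cx$ligand)
  fr <- interactionFrequencies(tl)
  expect_equal(nrow(fr$perKey), 5L)
  expect_true(all(fr$perKey$percent == 100))
})

test_that("profiling equals independent frame-by-frame detection", {
  cx <- genComplex(seed = 9, planted = c("HYDROPHOBIC", "AROMATIC_PI",
                                         "HBOND_LIG_DONOR"))
  sched <- list(dutyCycleSchedule(6, 0.5, 1), dutyCycleSchedule(6, 5 / 6, 2),
                rep(TRUE, 6))
  tr <- genTrajectory(cx, sched, nFrames = 6, seed = 5)
  tl <- profileTrajectory(tr, cx$ligand)
  for (f in seq_len(6)) {
    ev <- detectInteractions(frames(tr)[[f]], cx$ligand)
    keys <- sort(paste(ev$kind, ev$ligSerials,
                       paste0(ev$chain, ev$resno), sep = "|"))
    expect_identical(sort(tl@keys$label[tl@presence[f, ]]), keys)
  }
})

test_that("replica concatenation appends frames and back-fills keys", {
  cx <- genComplex(seed = 2, planted = c("HBOND_LIG_ACCEPTOR", "IONIC"))
  t1 <- genTrajectory(cx, list(rep(TRUE, 4), rep(FALSE, 4)), 4, seed = 1)
  t2 <- genTrajectory(cx, list(rep(TRUE, 4), rep(TRUE, 4)), 4, seed = 2)
  t3 <- genTrajectory(cx, list(c(TRUE, TRUE, FALSE, FALSE),
                               rep(FALSE, 4)), 4, seed = 3)
  tls <- lapply(list(t1, t2, t3), profileTrajectory, cx$ligand)
  comb <- concatReplicas(tls)
  expect_equal(nrow(comb@presence), 12L)
  fr <- interactionFrequencies(comb)
  # the ionic key exists only in replica 2: back-filled zero elsewhere
  ionic <- fr$perKey[fr$perKey$kind == "IONIC", ]
  expect_equal(ionic$count, 4L)
  expect_equal(ionic$percent, 100 * 4 / 12)
  # concatenated frequencies equal the frame-weighted replica average
  hbKey <- grep("HBOND", comb@keys$label, value = TRUE)
  perRep <- vapply(tls, function(tl)
    if (hbKey %in% tl@keys$label) sum(tl@presence[, hbKey]) else 0L,
    integer(1))
  expect_equal(fr$perKey$percent[fr$perKey$label == hbKey],
               100 * sum(perRep) / 12)
  # single replica concatenation is the identity
  solo <- concatReplicas(tls[2])
  expect_identical(solo@presence, tls[[2]]@presence)
  # mismatched atom identity is refused
  cx2 <- genComplex(seed = 2, planted = c("HBOND_LIG_ACCEPTOR", "IONIC",
                                          "HYDROPHOBIC"))
  t4 <- genTrajectory(cx2, rep(list(rep(TRUE, 2)), 3), 2, seed = 1)
  expect_error(concatReplicas(list(tls[[1]],
                                   profileTrajectory(t4, cx2$ligand))),
               "atom identity")
})

test_that("frequencies are invariant to frame order; clouds conserve counts", {
  cx <- genComplex(seed = 4)
  sched <- lapply(seq_along(cx$sites), function(i)
    dutyCycleSchedule(10, 0.6, i))
  tr <- genTrajectory(cx, sched, nFrames = 10, seed = 7)
  tl <- profileTrajectory(tr, cx$ligand)
  perm <- c(7, 3, 1, 10, 2, 9, 4, 8, 5, 6)
  tr2 <- new("Trajectory", frames = frames(tr)[perm],
             frameTimes = numeric(0))
  tl2 <- profileTrajectory(tr2, cx$ligand)
  f1 <- interactionFrequencies(tl)
  f2 <- interactionFrequencies(tl2)
  expect_equal(f2$perKey[order(f2$perKey$label), c("label", "percent")],
               f1$perKey[order(f1$perKey$label), c("label", "percent")],
               ignore_attr = TRUE)
  cl <- interactionClouds(tl)
  expect_equal(vapply(cl, nrow, integer(1))[tl@keys$label],
               stats::setNames(colSums(tl@presence), tl@keys$label))
  # aggregate per-kind percentage is at least every member key's
  expect_true(all(vapply(seq_len(nrow(f1$perKey)), function(i) {
    kindP <- f1$perKind$percent[f1$perKind$kind == f1$perKey$kind[i]]
    kindP >= f1$perKey$percent[i] - 1e-12
  }, logical(1))))
})

test_that("clouds move with a rigid motion of all frames", {
  cx <- genComplex(seed = 8, planted = c("IONIC", "HYDROPHOBIC"))
  tr <- genTrajectory(cx, list(rep(TRUE, 3), c(TRUE, FALSE, TRUE)), 3,
                      seed = 4)
  tl <- profileTrajectory(tr, cx$ligand)
  set.seed(1)
  R <- phoreseek:::randomRotation(); t <- c(1, 2, 3)
  moved <- lapply(frames(tr), function(st) {
    xyz <- phoreseek:::applyRigid(as.matrix(atoms(st)[, c("x", "y", "z")]),
                                  R, t)
    st@atoms$x <- xyz[, 1]; st@atoms$y <- xyz[, 2]; st@atoms$z <- xyz[, 3]
    st
  })
  tl2 <- profileTrajectory(new("Trajectory", frames = moved,
                               frameTimes = numeric(0)), cx$ligand)
  c1 <- interactionClouds(tl)
  c2 <- interactionClouds(tl2)
  for (k in names(c1))
    expect_equal(c2[[k]], phoreseek:::applyRigid(c1[[k]], R, t),
                 tolerance = 1e-6, ignore_attr = TRUE)
})
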