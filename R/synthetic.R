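# Seeded synthetic-data generators with known ground truth: toy
# protein-ligand complexes, screening libraries, trajectories with
# planted interaction schedules, and dose-response data under competitive
# or non-competitive antagonism. Every generator validates its own output
# against the planted ground truth before returning.

# 14 well-separated unit directions: 6 axes + 8 cube diagonals.
siteDirections <- function() {
  ax <- rbind(diag(3), -diag(3))
  dg <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  unname(rbind(ax, dg))
}

# orthonormal frame completing direction d
orthoFrame <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- unitVec(pracmaCross(d, ref))
  q <- pracmaCross(d, p)
  list(p = p, q = q)
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

LIG_RADIUS <- 4.0  # distance of ligand site atoms from the ligand centre

# planted geometry per interaction kind: ligand/protein atoms and the
# realized distance, chosen just inside the default rule thresholds
SITE_GEOMETRY <- list(
  HBOND_LIG_ACCEPTOR = list(dist = 2.9, resname = "GLY"),
  HBOND_LIG_DONOR    = list(dist = 2.9, resname = "ALA"),
  HYDROPHOBIC        = list(dist = 3.8, resname = "LEU"),
  IONIC              = list(dist = 4.3, resname = "GLU"),
  AROMATIC_PI        = list(dist = 3.8, resname = "PHE"))

#' Generate a synthetic protein-ligand complex with planted interactions
#'
#' Builds a toy binding pocket: a small ligand (residue LIG, chain L)
#' surrounded by partial protein residues (chain A), one site per planted
#' interaction, each realised just inside the default geometric rule
#' thresholds, plus inert scaffold atoms. Sites are placed on
#' well-separated directions so no accidental cross-site interaction can
#' occur. The whole complex is given a seeded random rigid placement, so
#' different seeds give different coordinates but identical ground truth.
#' Before returning, the generator verifies that [detectInteractions()]
#' recovers exactly the planted events.
#'
#' @param seed integer seed.
#' @param planted character vector of interaction kinds (each of
#'   HBOND_LIG_ACCEPTOR, HBOND_LIG_DONOR, HYDROPHOBIC, IONIC,
#'   AROMATIC_PI; repeats allowed, at most 14 sites).
#' @param rules the [geometricRules()] the complex is built against.
#' @return list with \code{structure} (\linkS4class{StructureModel}),
#'   \code{events} (ground-truth data.frame: kind, chain, resno,
#'   ligSerials), \code{sites} (internal site geometry, used by
#'   [genTrajectory()]), \code{ligand} (selector string).
#' @export
genComplex <- function(seed = 1L,
                       planted = c("HBOND_LIG_ACCEPTOR", "IONIC",
                                   "HYDROPHOBIC", "HYDROPHOBIC",
                                   "HYDROPHOBIC"),
                       rules = geometricRules()) {
  bad <- setdiff(planted, names(SITE_GEOMETRY))
  if (length(bad)) stop(paste("unknown interaction kind:", bad[1]))
  nSites <- length(planted)
  dirs <- siteDirections()
  if (nSites > nrow(dirs))
    stop(sprintf("infeasible packing: at most %d sites supported",
                 nrow(dirs)))
  placement <- withSeed(seed, list(
    perm = sample(nrow(dirs)), R = randomRotation(),
    t = stats::runif(3, -5, 5)))
  dirs <- dirs[placement$perm[seq_len(nSites)], , drop = FALSE]

  rows <- list(); serial <- 0L
  addAtom <- function(name, element, resname, resno, chain, pos,
                      charge = 0L, record = "ATOM") {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, resname = resname,
      resno = resno, chain = chain, x = pos[1], y = pos[2], z = pos[3],
      charge = charge, record = record, stringsAsFactors = FALSE)
    serial
  }
  addAtom("C0", "C", "LIG", 1L, "L", c(0, 0, 0), record = "HETATM")
  sites <- list()
  truth <- list()
  for (i in seq_len(nSites)) {
    kind <- planted[i]
    g <- SITE_GEOMETRY[[kind]]
    d <- dirs[i, ]; fr <- orthoFrame(d)
    resno <- 350L + i
    ligBase <- LIG_RADIUS * d
    protBase <- (LIG_RADIUS + g$dist) * d
    ligS <- integer(0); protS <- integer(0)
    if (kind == "HBOND_LIG_ACCEPTOR") {
      ligS <- addAtom(sprintf("O%d", i), "O", "LIG", 1L, "L", ligBase,
                      record = "HETATM")
      protS <- c(addAtom("N", "N", g$resname, resno, "A", protBase),
                 addAtom("CA", "C", g$resname, resno, "A",
                         protBase + 1.45 * fr$p))
      measureAtoms <- list(lig = ligS, prot = protS[1])
    } else if (kind == "HBOND_LIG_DONOR") {
      ligS <- addAtom(sprintf("N%d", i), "N", "LIG", 1L, "L", ligBase,
                      record = "HETATM")
      protS <- c(addAtom("O", "O", g$resname, resno, "A", protBase),
                 addAtom("C", "C", g$resname, resno, "A",
                         protBase + 1.23 * fr$p))
      measureAtoms <- list(lig = ligS, prot = protS[1])
    } else if (kind == "HYDROPHOBIC") {
      ligS <- c(addAtom(sprintf("C%dA", i), "C", "LIG", 1L, "L",
                        ligBase + 0.75 * fr$p, record = "HETATM"),
                addAtom(sprintf("C%dB", i), "C", "LIG", 1L, "L",
                        ligBase - 0.75 * fr$p, record = "HETATM"))
      protS <- addAtom("CD1", "C", g$resname, resno, "A", protBase)
      measureAtoms <- list(lig = ligS, prot = protS)
    } else if (kind == "IONIC") {
      ligS <- addAtom(sprintf("N%d", i), "N", "LIG", 1L, "L", ligBase,
                      charge = 1L, record = "HETATM")
      protS <- c(addAtom("OE1", "O", g$resname, resno, "A",
                         protBase + 1.1 * fr$p),
                 addAtom("OE2", "O", g$resname, resno, "A",
                         protBase - 1.1 * fr$p),
                 addAtom("CD", "C", g$resname, resno, "A",
                         protBase + 0.7 * d))
      measureAtoms <- list(lig = ligS, prot = protS[1:2])
    } else {  # AROMATIC_PI
      ligS <- vapply(0:5, function(k) {
        ang <- k * pi / 3
        addAtom(sprintf("C%d%d", i, k), "C", "LIG", 1L, "L",
                ligBase + 1.39 * (cos(ang) * fr$p + sin(ang) * fr$q),
                record = "HETATM")
      }, integer(1))
      nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      protS <- vapply(0:5, function(k) {
        ang <- k * pi / 3 + pi / 6
        addAtom(nm[k + 1], "C", g$resname, resno, "A",
                protBase + 1.39 * (cos(ang) * fr$p + sin(ang) * fr$q))
      }, integer(1))
      measureAtoms <- list(lig = ligS, prot = protS)
    }
    sites[[i]] <- list(kind = kind, dir = d, resno = resno,
                       ligSerials = ligS, protSerials = protS,
                       measure = measureAtoms, plantedDist = g$dist,
                       cutoff = switch(kind,
                                       HBOND_LIG_ACCEPTOR = ,
                                       HBOND_LIG_DONOR = rules$hbondDistMax,
                                       HYDROPHOBIC = rules$hydrophobicDistMax,
                                       IONIC = rules$ionicDistMax,
                                       AROMATIC_PI = rules$aromaticDistMax))
    truth[[i]] <- data.frame(kind = kind, chain = "A", resno = resno,
                             ligSerials = paste(sort(ligS), collapse = ","),
                             stringsAsFactors = FALSE)
  }
  # inert scaffold far outside every cutoff
  for (k in 1:3)
    addAtom("CA", "C", "GLY", 900L + k, "A",
            18 * siteDirections()[k, ])
  atomsDf <- do.call(rbind, rows)
  xyz <- as.matrix(atomsDf[, c("x", "y", "z")])
  xyz <- applyRigid(xyz, placement$R, placement$t)
  atomsDf$x <- xyz[, 1]; atomsDf$y <- xyz[, 2]; atomsDf$z <- xyz[, 3]
  st <- new("StructureModel", atoms = atomsDf, modelId = 1L)
  validObject(st)
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(0), chain = character(0),
               resno = integer(0), ligSerials = character(0))
  out <- list(structure = st, events = truthDf, sites = sites,
              ligand = "LIG:L", rules = rules)
  # self-check: detection must recover exactly the planted events
  det <- detectInteractions(st, out$ligand, rules)
  got <- sort(paste(det$kind, det$resno))
  want <- sort(paste(truthDf$kind, truthDf$resno))
  if (!identical(got, want))
    stop(sprintf(
      "genComplex self-check failed: planted [%s] but detected [%s]",
      paste(want, collapse = "; "), paste(got, collapse = "; ")))
  out
}

#' Generate a trajectory with planted per-frame interaction schedules
#'
#' Replays a [genComplex()] pocket over \code{nFrames} frames. In frames
#' where an interaction is scheduled off, its protein partner atoms are
#' displaced radially outward beyond the rule threshold plus a safety
#' margin; elsewhere the planted geometry is kept. Gaussian positional
#' noise is added to every atom in every frame. The generator validates
#' post-hoc that the realised geometry reproduces the schedule in every
#' frame (an over-large noise level fails loudly rather than silently
#' corrupting the ground truth).
#'
#' @param complex result of [genComplex()].
#' @param schedules list of logical vectors (one per planted site, each
#'   of length \code{nFrames}): TRUE where the interaction is present.
#' @param nFrames number of frames.
#' @param noiseSd positional noise standard deviation per coordinate (A).
#' @param seed integer seed.
#' @return A \linkS4class{Trajectory}.
#' @export
genTrajectory <- function(complex, schedules, nFrames,
                          noiseSd = 0.03, seed = 1L) {
  sites <- complex$sites
  stopifnot(length(schedules) == length(sites))
  if (!all(lengths(schedules) == nFrames))
    stop("every schedule must have length nFrames")
  at0 <- complex$structure@atoms
  xyz0 <- as.matrix(at0[, c("x", "y", "z")])
  # global placement applied by genComplex: recover outward direction per
  # site from the ligand-site -> protein-partner axis in current coords
  frames <- withSeed(seed, lapply(seq_len(nFrames), function(f) {
    xyz <- xyz0
    for (si in seq_along(sites)) {
      s <- sites[[si]]
      if (!schedules[[si]][f]) {
        ligC <- colMeans(xyz0[match(s$ligSerials, at0$serial), ,
                              drop = FALSE])
        protC <- colMeans(xyz0[match(s$protSerials, at0$serial), ,
                               drop = FALSE])
        outward <- unitVec(protC - ligC)
        shift <- (s$cutoff - s$plantedDist + 1.0)
        rowsIdx <- match(s$protSerials, at0$serial)
        xyz[rowsIdx, ] <- sweep(xyz[rowsIdx, , drop = FALSE], 2,
                                shift * outward, "+")
      }
    }
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noiseSd),
                        ncol = 3)
    at <- at0
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    new("StructureModel", atoms = at, modelId = as.integer(f))
  }))
  tr <- new("Trajectory", frames = frames, frameTimes = numeric(0))
  validObject(tr)
  # post-hoc ground-truth validation on the realised geometry
  for (si in seq_along(sites)) {
    s <- sites[[si]]
    for (f in seq_len(nFrames)) {
      xyz <- as.matrix(frames[[f]]@atoms[, c("x", "y", "z")])
      lig <- xyz[match(s$measure$lig, at0$serial), , drop = FALSE]
      prot <- xyz[match(s$measure$prot, at0$serial), , drop = FALSE]
      d <- if (s$kind %in% c("IONIC", "AROMATIC_PI")) {
        vecNorm(colMeans(lig) - colMeans(prot))
      } else {
        min(crossDist(lig, prot))
      }
      realised <- d <= s$cutoff
      if (realised != schedules[[si]][f])
        stop(sprintf(
          "genTrajectory self-check failed at frame %d, site %d (%s): noise too large for the planted margins",
          f, si, s$kind))
    }
  }
  tr
}

#' Exact-count presence schedule
#'
#' A seeded random schedule with exactly \code{round(duty * nFrames)}
#' frames on - duty cycles are recovered exactly, not only in
#' expectation.
#'
#' @param nFrames number of frames.
#' @param duty fraction of frames present, in [0, 1].
#' @param seed integer seed.
#' @return logical vector of length \code{nFrames}.
#' @export
dutyCycleSchedule <- function(nFrames, duty, seed = 1L) {
  nOn <- round(duty * nFrames)
  withSeed(seed, {
    on <- sample(nFrames, nOn)
    seq_len(nFrames) %in% on
  })
}

#' Generate a labeled screening library with known ground truth
#'
#' Actives are per-conformer jittered copies of the model's features
#' (Gaussian, sd \code{jitterSd}) with exactly one matching conformer
#' each (verified at generation time); the remaining conformers, and all
#' decoy/inactive conformers, are kind-preserving geometry-scrambled
#' feature sets whose internal distances are inflated threefold, which
#' provably breaks the distance-consistency filter - each is additionally
#' verified to admit no candidate correspondence. Properties (molecular
#' weight, apolar fraction, HBA/HBD counts, rotatable bonds, formal
#' charge) are filled so that decoys are property-matched to actives
#' within the default tolerances.
#'
#' @param model query \linkS4class{PharmacophoreModel}.
#' @param nActive,nDecoy,nInactive library composition.
#' @param jitterSd per-coordinate Gaussian jitter of active conformers
#'   (A).
#' @param nConformers conformers per molecule.
#' @param seed integer seed.
#' @param settings the [screenSettings()] the guarantees are made under.
#' @return A \code{FeatureLibrary} with \code{label} in active /
#'   inactive / decoy and a \code{properties} vector per molecule.
#' @export
genLibrary <- function(model, nActive, nDecoy, nInactive = 0L,
                       jitterSd = 0.3, nConformers = 25L, seed = 1L,
                       settings = screenSettings()) {
  stopifnot(nConformers >= 1L)
  f <- model@features
  if (nrow(f) < 3L) stop("library generation needs a model with >= 3 features")
  md <- modelMatchData(model, settings)
  xyz <- as.matrix(f[, c("x", "y", "z")])
  centre <- colMeans(xyz)
  nHBA <- sum(f$kind == "HBA"); nHBD <- sum(f$kind == "HBD")
  charge <- as.integer(sum(f$kind == "PI") - sum(f$kind == "NI"))

  scrambled <- function() {
    for (try in 1:100) {
      pos <- sweep(sweep(xyz, 2, centre) %*% randomRotation() * 3, 2,
                   centre, "+") +
        matrix(stats::rnorm(length(xyz), sd = 0.5), ncol = 3)
      cf <- data.frame(kind = f$kind, x = pos[, 1], y = pos[, 2],
                       z = pos[, 3], stringsAsFactors = FALSE)
      if (length(enumerateCorrespondencesFast(md, cf, settings)) == 0L)
        return(cf)
    }
    stop("library generation: could not scramble a guaranteed non-matching conformer in 100 tries")
  }
  jittered <- function() {
    for (try in 1:100) {
      pos <- xyz + matrix(stats::rnorm(length(xyz), sd = jitterSd),
                          ncol = 3)
      cf <- data.frame(kind = f$kind, x = pos[, 1], y = pos[, 2],
                       z = pos[, 3], stringsAsFactors = FALSE)
      if (matchConformerFast(md, cf, settings)$hit) return(cf)
    }
    stop("library generation: jitterSd too large to produce a matching conformer in 100 tries")
  }

  withSeed(seed, {
    entries <- vector("list", nActive + nInactive + nDecoy)
    idx <- 0L
    activeMW <- stats::rnorm(max(nActive, 1L), 350, 15)
    activeAF <- stats::runif(max(nActive, 1L), 0.3, 0.5)
    activeRB <- sample(3:7, max(nActive, 1L), replace = TRUE)
    for (i in seq_len(nActive)) {
      hitConf <- sample(nConformers, 1L)
      confs <- lapply(seq_len(nConformers), function(ci)
        if (ci == hitConf) jittered() else scrambled())
      idx <- idx + 1L
      entries[[idx]] <- list(
        id = sprintf("ACT%04d", i), label = "active",
        properties = c(mw = activeMW[i], apolar_frac = activeAF[i],
                       hba = nHBA, hbd = nHBD, rotb = activeRB[i],
                       charge = charge),
        conformers = confs)
    }
    mkNonActive <- function(i, label, tag) {
      ref <- sample(max(nActive, 1L), 1L)
      idx <<- idx + 1L
      entries[[idx]] <<- list(
        id = sprintf("%s%04d", tag, i), label = label,
        properties = c(mw = activeMW[ref] + stats::runif(1, -20, 20),
                       apolar_frac = activeAF[ref] +
                         stats::runif(1, -0.08, 0.08),
                       hba = nHBA, hbd = nHBD,
                       rotb = activeRB[ref] + sample(-1:1, 1L),
                       charge = charge),
        conformers = lapply(seq_len(nConformers),
                            function(ci) scrambled()))
    }
    for (i in seq_len(nInactive)) mkNonActive(i, "inactive", "INA")
    for (i in seq_len(nDecoy)) mkNonActive(i, "decoy", "DEC")
    class(entries) <- "FeatureLibrary"
    entries
  })
}

#' Library labels as a lookup vector
#'
#' @param library a \code{FeatureLibrary}.
#' @return named character vector, molecule id to label.
#' @export
libraryLabels <- function(library) {
  stats::setNames(vapply(library, function(m) m$label, character(1)),
                  vapply(library, function(m) m$id, character(1)))
}

#' Library properties as a data.frame
#'
#' @param library a \code{FeatureLibrary}.
#' @return data.frame with id, label and one column per property.
#' @export
libraryProperties <- function(library) {
  props <- do.call(rbind, lapply(library, function(m) m$properties))
  cbind(data.frame(id = vapply(library, function(m) m$id, character(1)),
                   label = vapply(library, function(m) m$label,
                                  character(1)),
                   stringsAsFactors = FALSE),
        as.data.frame(props))
}

#' Generate dose-response data under a known antagonism mechanism
#'
#' Simulates 4PL agonist concentration-response observations at several
#' antagonist concentrations. Under competitive antagonism the agonist
#' half-maximal concentration is shifted by the Gaddum/Schild factor
#' \code{(1 + B/KB)} with asymptotes unchanged; under non-competitive
#' antagonism the top asymptote is depressed by \code{1/(1 + B/KB)}
#' instead. Gaussian noise of sd \code{noiseSd} is added per observation.
#'
#' @param bottom,top,hill,ec50 control-curve 4PL parameters
#'   (concentrations molar).
#' @param antagonistConcs antagonist concentrations (molar; include 0
#'   for the control curve).
#' @param KB antagonist equilibrium dissociation constant (molar).
#' @param mechanism \code{"competitive"} or \code{"noncompetitive"}.
#' @param noiseSd response noise sd (assay units).
#' @param nReplicates replicates per concentration.
#' @param concentrations agonist concentrations; default 9 half-log
#'   steps centred on \code{ec50}.
#' @param seed integer seed.
#' @return data.frame with columns molecule, antagonist_conc,
#'   agonist_conc, response, replicate; ground truth in
#'   \code{attr(, "truth")}.
#' @export
genDoseResponse <- function(bottom = 0, top = 100, hill = 1, ec50 = 5e-7,
                            antagonistConcs = c(0, 1, 3, 10, 30) * 1e-7,
                            KB = 1e-7,
                            mechanism = c("competitive",
                                          "noncompetitive"),
                            noiseSd = 5, nReplicates = 3,
                            concentrations = NULL, seed = 1L) {
  mechanism <- match.arg(mechanism)
  stopifnot(ec50 > 0, KB > 0, all(antagonistConcs >= 0))
  if (is.null(concentrations))
    concentrations <- ec50 * 10^seq(-2, 2, by = 0.5)
  grid <- expand.grid(agonist_conc = concentrations,
                      antagonist_conc = antagonistConcs,
                      replicate = seq_len(nReplicates))
  shift <- 1 + grid$antagonist_conc / KB
  ec <- if (mechanism == "competitive") ec50 * shift else ec50
  tp <- if (mechanism == "noncompetitive") top / shift else top
  mu <- bottom + (tp - bottom) / (1 + (ec / grid$agonist_conc)^hill)
  resp <- withSeed(seed, mu + stats::rnorm(nrow(grid), sd = noiseSd))
  out <- data.frame(molecule = "synthetic",
                    antagonist_conc = grid$antagonist_conc,
                    agonist_conc = grid$agonist_conc,
                    response = resp, replicate = grid$replicate)
  attr(out, "truth") <- list(bottom = bottom, top = top, hill = hill,
                             ec50 = ec50, KB = KB, mechanism = mechanism,
                             noiseSd = noiseSd)
  out
}

#' Scenario presets
#'
#' Named library shapes and the antagonism study design used throughout
#' the documentation and tests: \code{"setA"} (158 actives, 231
#' inactives, 8406 decoys), \code{"setB"} (47 actives, 231 inactives,
#' 2538 decoys), \code{"fig6"} (Schild design: KB 100 nM, antagonist at
#' 1, 3, 10 and 30 times KB).
#'
#' @param name preset name.
#' @return named list of generator parameters.
#' @export
scenarioPreset <- function(name = c("setA", "setB", "fig6")) {
  name <- match.arg(name)
  switch(name,
         setA = list(nActive = 158L, nInactive = 231L, nDecoy = 8406L,
                     jitterSd = 0.3, nConformers = 25L),
         setB = list(nActive = 47L, nInactive = 231L, nDecoy = 2538L,
                     jitterSd = 0.3, nConformers = 25L),
         fig6 = list(ec50 = 5e-7, KB = 1e-7,
                     antagonistConcs = c(0, 1, 3, 10, 30) * 1e-7,
                     noiseSd = 5, nReplicates = 3))
}
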