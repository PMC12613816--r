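# Geometric perception of typed protein-ligand interactions: the
# hydrogen-bond / hydrophobic / ionic / aromatic vocabulary used by
# structure-based pharmacophore modelling.

#' Geometric interaction rules
#'
#' Distance and angle cutoffs for interaction perception. Defaults follow
#' standard structural-biology criteria: heavy-atom hydrogen-bond distance
#' at most 3.5 A with a D-H...A angle of at least 130 degrees (distance
#' only when no hydrogens are present, as in most raw PDB files), apolar
#' carbon-carbon contacts at most 4.5 A, charged-centre distance at most
#' 5.5 A, aromatic centroid distance at most 5.5 A with inter-plane angle
#' at most 30 degrees (stacked) or at least 60 degrees (T-shaped).
#'
#' @param hbondDistMax heavy-atom donor-acceptor distance cutoff (A).
#' @param hbondAngleMin minimum D-H...A angle (degrees), applied only when
#'   an explicit donor hydrogen is present.
#' @param hydrophobicDistMax apolar C...C distance cutoff (A).
#' @param ionicDistMax charged-centre distance cutoff (A).
#' @param aromaticDistMax ring-centroid distance cutoff (A).
#' @param aromaticPlaneAngleMax maximum inter-plane angle for stacked
#'   geometry (degrees); angles of at least \code{aromaticTShapeAngleMin}
#'   count as T-shaped.
#' @param aromaticTShapeAngleMin minimum inter-plane angle for T-shaped
#'   geometry (degrees).
#' @return A list of class \code{GeometricRules}.
#' @export
geometricRules <- function(hbondDistMax = 3.5, hbondAngleMin = 130,
                           hydrophobicDistMax = 4.5, ionicDistMax = 5.5,
                           aromaticDistMax = 5.5,
                           aromaticPlaneAngleMax = 30,
                           aromaticTShapeAngleMin = 60) {
  r <- list(hbondDistMax = hbondDistMax, hbondAngleMin = hbondAngleMin,
            hydrophobicDistMax = hydrophobicDistMax,
            ionicDistMax = ionicDistMax, aromaticDistMax = aromaticDistMax,
            aromaticPlaneAngleMax = aromaticPlaneAngleMax,
            aromaticTShapeAngleMin = aromaticTShapeAngleMin)
  dists <- unlist(r[c(1, 3, 4, 5)])
  if (any(dists <= 0)) stop("all distance cutoffs must be positive")
  angs <- unlist(r[c(2, 6, 7)])
  if (any(angs <= 0 | angs > 180)) stop("angles must lie in (0, 180]")
  class(r) <- "GeometricRules"
  r
}

# -- protein-side residue templates (no pKa calculation) ----------------

PROTEIN_DONOR <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", CYS = "SG")

PROTEIN_ACCEPTOR <- list(
  backbone = c("O", "OXT"),
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  MET = "SD")

PROTEIN_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

PROTEIN_POSITIVE <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"))

PROTEIN_AROMATIC <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

PROTEIN_APOLAR <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "CE"), PRO = c("CB", "CG", "CD"),
  LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  GLU = c("CB", "CG"), GLN = c("CB", "CG"), ASP = "CB", ASN = "CB",
  THR = "CG2", PHE = "CB", TYR = "CB", TRP = "CB", CYS = "CB")

# -- ligand-side geometric perception -----------------------------------

BOND_DIST_MAX <- 1.85  # covalent neighbour cutoff between heavy atoms (A)
POLAR_NEIGHBOUR <- c("N", "O", "F")

ligandBonds <- function(atoms) {
  heavy <- which(atoms$element != "H")
  if (length(heavy) < 2L) return(cbind(integer(0), integer(0)))
  D <- crossDist(atoms[heavy, c("x", "y", "z")],
                 atoms[heavy, c("x", "y", "z")])
  idx <- which(D > 0.1 & D < BOND_DIST_MAX, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  cbind(heavy[idx[, 1]], heavy[idx[, 2]])
}

# Ring perception: per-edge shortest alternative path of length 4-5 gives
# 5- and 6-membered rings; near-planar rings are treated as aromatic.
perceiveRings <- function(atoms, bonds, planarTol = 0.15) {
  if (nrow(bonds) < 5L) return(list())
  g <- igraph::make_graph(edges = t(bonds), n = nrow(atoms),
                          directed = FALSE)
  rings <- list()
  for (e in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, bonds[e, ]))
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = bonds[e, 1], to = bonds[e, 2]))$vpath[[1]]
    if (length(sp) %in% c(5L, 6L)) {
      ring <- sort(as.integer(sp))
      key <- paste(ring, collapse = ",")
      if (!key %in% names(rings)) rings[[key]] <- ring
    }
  }
  keep <- vapply(rings, function(r) {
    if (!all(atoms$element[r] %in% c("C", "N", "O", "S"))) return(FALSE)
    P <- as.matrix(atoms[r, c("x", "y", "z")])
    n <- planeNormal(P)
    Pc <- sweep(P, 2, colMeans(P))
    max(abs(Pc %*% n)) <= planarTol
  }, logical(1))
  unname(rings[keep])
}

# Full ligand perception from geometry + formal charges. Returns atom
# index sets (relative to the ligand atom table).
perceiveLigand <- function(atoms, protonateAmines = TRUE) {
  bonds <- ligandBonds(atoms)
  nbr <- vector("list", nrow(atoms))
  for (i in seq_len(nrow(bonds))) {
    nbr[[bonds[i, 1]]] <- c(nbr[[bonds[i, 1]]], bonds[i, 2])
    nbr[[bonds[i, 2]]] <- c(nbr[[bonds[i, 2]]], bonds[i, 1])
  }
  hIdx <- which(atoms$element == "H")
  if (length(hIdx)) {
    D <- crossDist(atoms[hIdx, c("x", "y", "z"), drop = FALSE],
                   atoms[, c("x", "y", "z")])
    hParent <- apply(D, 1, function(d) {
      d[hIdx] <- Inf; cand <- which(d < 1.3)
      if (length(cand)) cand[which.min(d[cand])] else NA_integer_
    })
  } else hParent <- integer(0)
  hasH <- length(hIdx) > 0L
  rings <- perceiveRings(atoms, bonds)
  ringMember <- unique(unlist(rings))
  isNO <- atoms$element %in% c("N", "O")
  acceptors <- which(isNO & atoms$charge <= 0)
  if (hasH) {
    withH <- unique(hParent[!is.na(hParent)])
    donors <- intersect(which(isNO), withH)
  } else {
    donors <- which(isNO & atoms$charge >= 0)  # heavy-atom fallback
  }
  positive <- which(atoms$charge > 0)
  if (protonateAmines) {
    # protonatable aliphatic amine heuristic: uncharged N, no ring
    # membership, all heavy neighbours carbon
    amine <- which(atoms$element == "N" & atoms$charge == 0 &
                     !(seq_len(nrow(atoms)) %in% ringMember))
    amine <- amine[vapply(amine, function(i) {
      hn <- setdiff(nbr[[i]], hIdx)
      length(hn) > 0L && all(atoms$element[hn] == "C")
    }, logical(1))]
    positive <- sort(union(positive, amine))
  }
  negative <- which(atoms$charge < 0)
  apolar <- which(atoms$element == "C" &
                    !(seq_len(nrow(atoms)) %in% ringMember))
  apolar <- apolar[vapply(apolar, function(i) {
    !any(atoms$element[nbr[[i]]] %in% POLAR_NEIGHBOUR)
  }, logical(1))]
  # contiguous apolar groups (connected components of the apolar subgraph)
  groups <- list()
  if (length(apolar)) {
    sub <- bonds[bonds[, 1] %in% apolar & bonds[, 2] %in% apolar, ,
                 drop = FALSE]
    g <- igraph::make_graph(edges = t(match(t(sub), apolar)),
                            n = length(apolar), directed = FALSE)
    comp <- igraph::components(g)$membership
    groups <- lapply(split(apolar, comp), identity)
    groups <- unname(groups[lengths(groups) >= 2L])
  }
  list(bonds = bonds, nbr = nbr, hIdx = hIdx, hParent = hParent,
       hasH = hasH, rings = rings, acceptors = acceptors, donors = donors,
       positive = positive, negative = negative, apolarGroups = groups)
}

# -- selector helpers ---------------------------------------------------

resolveSelector <- function(atoms, selector) {
  if (is.function(selector)) return(which(selector(atoms)))
  if (is.character(selector) && length(selector) == 1L) {
    parts <- strsplit(selector, ":", fixed = TRUE)[[1]]
    sel <- atoms$resname == parts[1]
    if (length(parts) > 1L) sel <- sel & atoms$chain == parts[2]
    return(which(sel))
  }
  stop("ligand selector must be a predicate function or 'RES' / 'RES:CHAIN'")
}

# -- detection ----------------------------------------------------------

#' Detect protein-ligand interactions in a complex
#'
#' Perceives typed geometric interactions between a ligand and its protein
#' environment: hydrogen bonds (ligand acceptor or donor), hydrophobic
#' contacts between apolar carbon groups, ionic contacts between opposite
#' formal charges, and aromatic ring-ring interactions. Ligand chemistry
#' is perceived geometrically (covalent neighbours from interatomic
#' distances, 5/6-rings by cycle search with a planarity test); the
#' protein side uses a fixed residue template table.
#'
#' @param complex a \linkS4class{StructureModel} containing ligand and
#'   protein.
#' @param ligandSelector \code{"RES"}, \code{"RES:CHAIN"}, or a predicate
#'   \code{function(atoms)} returning a logical vector.
#' @param rules a [geometricRules()] list.
#' @param protonateAmines flag aliphatic ligand amines as positive
#'   ionizable even without an explicit formal charge.
#' @return data.frame of events with columns \code{kind},
#'   \code{ligSerials} (comma-joined), \code{chain}, \code{resname},
#'   \code{resno}, \code{distance}, \code{angle}, \code{x}, \code{y},
#'   \code{z} (ligand site centroid) and \code{ligChargeSign}; ordered by
#'   kind, residue number, chain, and deduplicated at (kind, ligand atom
#'   set, residue) granularity.
#' @export
detectInteractions <- function(complex, ligandSelector,
                               rules = geometricRules(),
                               protonateAmines = TRUE) {
  at <- complex@atoms
  ligIdx <- resolveSelector(at, ligandSelector)
  if (length(ligIdx) == 0L) stop("ligand selector matched no atoms")
  protIdx <- setdiff(seq_len(nrow(at)), ligIdx)
  protIdx <- protIdx[!at$resname[protIdx] %in% c("HOH", "WAT")]
  if (length(protIdx) == 0L)
    stop("complex contains no non-ligand atoms")
  lig <- at[ligIdx, , drop = FALSE]
  prot <- at[protIdx, , drop = FALSE]
  rownames(lig) <- rownames(prot) <- NULL
  perc <- perceiveLigand(lig, protonateAmines)
  ligXYZ <- as.matrix(lig[, c("x", "y", "z")])
  protXYZ <- as.matrix(prot[, c("x", "y", "z")])
  events <- list()
  emit <- function(kind, ligRows, pRow, distance, angle = NA_real_,
                   sign = NA_integer_) {
    pos <- colMeans(ligXYZ[ligRows, , drop = FALSE])
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind,
      ligSerials = paste(sort(lig$serial[ligRows]), collapse = ","),
      chain = prot$chain[pRow], resname = prot$resname[pRow],
      resno = prot$resno[pRow], distance = distance, angle = angle,
      x = pos[1], y = pos[2], z = pos[3], ligChargeSign = sign,
      stringsAsFactors = FALSE)
  }
  protNamesOf <- function(tmpl) {
    sel <- rep(FALSE, nrow(prot))
    if (!is.null(tmpl$backbone))
      sel <- sel | prot$name %in% tmpl$backbone
    for (rn in setdiff(names(tmpl), "backbone"))
      sel <- sel | (prot$resname == rn & prot$name %in% tmpl[[rn]])
    which(sel)
  }

  # hydrogen bonds: ligand acceptor vs protein donor
  pDon <- protNamesOf(PROTEIN_DONOR)
  if (length(perc$acceptors) && length(pDon)) {
    D <- crossDist(ligXYZ[perc$acceptors, , drop = FALSE],
                   protXYZ[pDon, , drop = FALSE])
    hit <- which(D <= rules$hbondDistMax, arr.ind = TRUE)
    for (h in seq_len(nrow(hit))) {
      emit("HBOND_LIG_ACCEPTOR", perc$acceptors[hit[h, 1]],
           pDon[hit[h, 2]], D[hit[h, 1], hit[h, 2]])
    }
  }
  # hydrogen bonds: ligand donor vs protein acceptor (angle when H known)
  pAcc <- protNamesOf(PROTEIN_ACCEPTOR)
  if (length(perc$donors) && length(pAcc)) {
    D <- crossDist(ligXYZ[perc$donors, , drop = FALSE],
                   protXYZ[pAcc, , drop = FALSE])
    hit <- which(D <= rules$hbondDistMax, arr.ind = TRUE)
    for (h in seq_len(nrow(hit))) {
      dRow <- perc$donors[hit[h, 1]]; aRow <- pAcc[hit[h, 2]]
      ang <- NA_real_
      ok <- TRUE
      if (perc$hasH) {
        hs <- perc$hIdx[which(perc$hParent == dRow)]
        if (length(hs)) {
          angs <- vapply(hs, function(hh) {
            vecAngle(ligXYZ[dRow, ] - ligXYZ[hh, ],
                     protXYZ[aRow, ] - ligXYZ[hh, ])
          }, numeric(1))
          ang <- max(angs)
          ok <- ang >= rules$hbondAngleMin
        }
      }
      if (ok) emit("HBOND_LIG_DONOR", dRow, aRow,
                   D[hit[h, 1], hit[h, 2]], ang)
    }
  }
  # hydrophobic: ligand apolar group vs protein apolar carbons, per residue
  pApo <- protNamesOf(PROTEIN_APOLAR)
  for (grp in perc$apolarGroups) {
    if (!length(pApo)) break
    D <- crossDist(ligXYZ[grp, , drop = FALSE],
                   protXYZ[pApo, , drop = FALSE])
    close <- which(D <= rules$hydrophobicDistMax, arr.ind = TRUE)
    if (!nrow(close)) next
    res <- paste(prot$chain[pApo[close[, 2]]], prot$resno[pApo[close[, 2]]])
    for (rk in unique(res)) {
      rows <- close[res == rk, , drop = FALSE]
      emit("HYDROPHOBIC", grp, pApo[rows[1, 2]],
           min(D[rows]))
    }
  }
  # ionic: ligand charged centre vs protein opposite charge
  ionic <- function(ligRows, tmpl, sign) {
    pChg <- protNamesOf(tmpl)
    if (!length(ligRows) || !length(pChg)) return()
    # protein charge centre: centroid of the template atoms per residue
    resKey <- paste(prot$chain[pChg], prot$resno[pChg])
    for (rk in unique(resKey)) {
      rows <- pChg[resKey == rk]
      centre <- colMeans(protXYZ[rows, , drop = FALSE])
      for (lr in ligRows) {
        d <- vecNorm(ligXYZ[lr, ] - centre)
        if (d <= rules$ionicDistMax)
          emit("IONIC", lr, rows[1], d, sign = sign)
      }
    }
  }
  ionic(perc$positive, PROTEIN_NEGATIVE, +1L)
  ionic(perc$negative, PROTEIN_POSITIVE, -1L)
  # aromatic: ring centroid distance + inter-plane angle
  pAroRes <- unique(prot[prot$resname %in% names(PROTEIN_AROMATIC),
                         c("chain", "resno", "resname")])
  if (length(perc$rings) && nrow(pAroRes)) {
    for (ring in perc$rings) {
      lC <- colMeans(ligXYZ[ring, , drop = FALSE])
      lN <- planeNormal(ligXYZ[ring, , drop = FALSE])
      for (pr in seq_len(nrow(pAroRes))) {
        nm <- PROTEIN_AROMATIC[[pAroRes$resname[pr]]]
        rows <- which(prot$chain == pAroRes$chain[pr] &
                        prot$resno == pAroRes$resno[pr] & prot$name %in% nm)
        if (length(rows) < 5L) next
        pC <- colMeans(protXYZ[rows, , drop = FALSE])
        d <- vecNorm(lC - pC)
        if (d > rules$aromaticDistMax) next
        pN <- planeNormal(protXYZ[rows, , drop = FALSE])
        ang <- vecAngle(lN, pN)
        ang <- min(ang, 180 - ang)
        if (ang <= rules$aromaticPlaneAngleMax ||
            ang >= rules$aromaticTShapeAngleMin) {
          pos <- colMeans(ligXYZ[ring, , drop = FALSE])
          events[[length(events) + 1L]] <- data.frame(
            kind = "AROMATIC_PI",
            ligSerials = paste(sort(lig$serial[ring]), collapse = ","),
            chain = pAroRes$chain[pr], resname = pAroRes$resname[pr],
            resno = pAroRes$resno[pr], distance = d, angle = ang,
            x = pos[1], y = pos[2], z = pos[3],
            ligChargeSign = NA_integer_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else emptyEvents()
  # dedup at (kind, ligand atom set, protein residue)
  key <- paste(ev$kind, ev$ligSerials, ev$chain, ev$resno)
  ev <- ev[!duplicated(key), , drop = FALSE]
  ord <- order(match(ev$kind, INTERACTION_KINDS), ev$resno, ev$chain,
               ev$ligSerials)
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

emptyEvents <- function() {
  data.frame(kind = character(0), ligSerials = character(0),
             chain = character(0), resname = character(0),
             resno = integer(0), distance = numeric(0), angle = numeric(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             ligChargeSign = integer(0), stringsAsFactors = FALSE)
}

#' Classify ligand atoms into pharmacophore feature types
#'
#' Perceives ligand-side chemical features from geometry and formal
#' charges: hydrogen-bond acceptors (N/O with lone-pair capacity), donors
#' (N/O bearing hydrogen, or any neutral N/O when the structure has no
#' hydrogens), positive ionizable centres (formal charge > 0, plus
#' flagged protonatable aliphatic amines), negative ionizable centres,
#' hydrophobic centroids of contiguous apolar-carbon groups of at least
#' two atoms, and aromatic ring centroids.
#'
#' @param ligand a \linkS4class{StructureModel} (or its atom data.frame)
#'   containing only the ligand atoms.
#' @param protonateAmines see [detectInteractions()].
#' @return data.frame with columns \code{kind} (HBA, HBD, HYD, PI, NI,
#'   AR), \code{x}, \code{y}, \code{z} and \code{serials} (comma-joined
#'   member atom serials). Empty when no atoms qualify.
#' @export
classifyLigandFeatures <- function(ligand, protonateAmines = TRUE) {
  at <- if (is(ligand, "StructureModel")) ligand@atoms else ligand
  perc <- perceiveLigand(at, protonateAmines)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rows <- list()
  addRow <- function(kind, idx) {
    pos <- colMeans(xyz[idx, , drop = FALSE])
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, x = pos[1], y = pos[2], z = pos[3],
      serials = paste(sort(at$serial[idx]), collapse = ","),
      stringsAsFactors = FALSE)
  }
  for (i in perc$acceptors) addRow("HBA", i)
  for (i in perc$donors) addRow("HBD", i)
  for (i in perc$positive) addRow("PI", i)
  for (i in perc$negative) addRow("NI", i)
  for (g in perc$apolarGroups) addRow("HYD", g)
  for (r in perc$rings) addRow("AR", r)
  if (!length(rows))
    return(data.frame(kind = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), serials = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(match(out$kind, FEATURE_KINDS), out$x, out$y, out$z), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
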