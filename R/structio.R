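#' Read the first model of a PDB file
#'
#' Parses ATOM/HETATM records of the first MODEL block (or the whole file
#' when no MODEL keyword is present). Both record types are ingested;
#' ANISOU/TER are ignored. When alternate locations are present, the
#' highest-occupancy altloc is kept (ties resolved to the first
#' encountered). Elements missing from columns 77-78 are inferred from the
#' atom name.
#'
#' @param path path to a PDB file.
#' @return A \linkS4class{StructureModel}.
#' @export
readStructure <- function(path) {
  tr <- readTrajectory(path, .checkConsistency = FALSE)
  tr@frames[[1]]
}

#' Read a multi-MODEL PDB file as a trajectory
#'
#' Every MODEL block becomes one frame. All frames must contain the same
#' number of atoms with the same serial and element sequence.
#'
#' @param path path to a (possibly multi-MODEL) PDB file.
#' @param frameTimes optional numeric vector of frame times in ns.
#' @param .checkConsistency internal; skip the cross-model check when only
#'   the first model is wanted.
#' @return A \linkS4class{Trajectory}.
#' @export
readTrajectory <- function(path, frameTimes = numeric(0),
                           .checkConsistency = TRUE) {
  lines <- readLines(path, warn = FALSE)
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(isAtom))
    stop(sprintf("no ATOM/HETATM records found in '%s'", path))
  modelStarts <- grep("^MODEL", lines)
  if (length(modelStarts) == 0L) {
    blocks <- list(which(isAtom))
  } else {
    ends <- c(modelStarts[-1] - 1L, length(lines))
    blocks <- lapply(seq_along(modelStarts), function(i) {
      idx <- modelStarts[i]:ends[i]
      idx[isAtom[idx]]
    })
    blocks <- blocks[lengths(blocks) > 0L]
  }
  if (.checkConsistency && length(unique(lengths(blocks))) > 1L)
    stop(sprintf("inconsistent atom counts across MODEL blocks in '%s': %s",
                 path, paste(lengths(blocks), collapse = ", ")))
  frames <- lapply(seq_along(blocks), function(i)
    parsePdbAtoms(lines[blocks[[i]]], modelId = i))
  tr <- new("Trajectory", frames = frames, frameTimes = frameTimes)
  validObject(tr)
  tr
}

# Fixed-column ATOM/HETATM parsing (PDB v3.3 columns). bio3d::atom2ele
# supplies the element fallback for legacy files without columns 77-78.
parsePdbAtoms <- function(atomLines, modelId = 1L) {
  fx <- function(from, to) trimws(substring(atomLines, from, to))
  record <- fx(1, 6)
  serial <- as.integer(fx(7, 11))
  name <- fx(13, 16)
  alt <- fx(17, 17)
  resname <- fx(18, 20)
  chain <- fx(22, 22)
  resno <- as.integer(fx(23, 26))
  x <- as.numeric(fx(31, 38)); y <- as.numeric(fx(39, 46))
  z <- as.numeric(fx(47, 54))
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  occ[is.na(occ)] <- 1
  element <- fx(77, 78)
  chargeTxt <- fx(79, 80)
  if (any(bad <- is.na(x) | is.na(y) | is.na(z)))
    stop(sprintf("unparseable coordinates in PDB line: '%s'",
                 atomLines[which(bad)[1]]))
  noEle <- element == "" | is.na(element)
  if (any(noEle))
    element[noEle] <- suppressWarnings(
      bio3d::atom2ele(name[noEle], rescue = TRUE))
  charge <- rep(0L, length(chargeTxt))
  signed <- grepl("^[0-9][+-]$", chargeTxt)
  charge[signed] <- as.integer(substring(chargeTxt[signed], 1, 1)) *
    ifelse(substring(chargeTxt[signed], 2, 2) == "-", -1L, 1L)
  plain <- grepl("^[+-]?[0-9]$", chargeTxt)
  charge[plain] <- as.integer(chargeTxt[plain])
  atoms <- data.frame(serial = serial, name = name, element = element,
                      resname = resname, resno = resno, chain = chain,
                      x = x, y = y, z = z, charge = charge,
                      record = record, stringsAsFactors = FALSE)
  # altloc policy: keep the highest-occupancy location per atom site
  if (any(alt != "")) {
    site <- paste(atoms$name, atoms$resname, atoms$chain, atoms$resno)
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), site), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    atoms <- atoms[sort(keep), , drop = FALSE]
    rownames(atoms) <- NULL
  }
  st <- new("StructureModel", atoms = atoms, modelId = as.integer(modelId))
  validObject(st)
  st
}

#' Write a structure or trajectory to PDB
#'
#' Coordinates are written at PDB precision (3 decimals); record type,
#' formal charges and element symbols are preserved.
#'
#' @param x a \linkS4class{StructureModel} or \linkS4class{Trajectory}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(x, path) {
  if (is(x, "StructureModel")) {
    writeLines(c(pdbLines(x), "END"), path)
  } else if (is(x, "Trajectory")) {
    out <- unlist(lapply(seq_along(x@frames), function(i)
      c(sprintf("MODEL     %4d", i), pdbLines(x@frames[[i]]), "ENDMDL")))
    writeLines(c(out, "END"), path)
  } else stop("x must be a StructureModel or Trajectory")
  invisible(path)
}

pdbLines <- function(st) {
  a <- st@atoms
  name <- ifelse(nchar(a$name) < 4L & nchar(a$element) == 1L,
                 paste0(" ", a$name), a$name)
  chg <- ifelse(a$charge == 0L, "",
                paste0(abs(a$charge), ifelse(a$charge < 0L, "-", "+")))
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%-2s",
          a$record, a$serial, name, "", a$resname, a$chain, a$resno, "",
          a$x, a$y, a$z, 1, 0, a$element, chg)
}

#' @describeIn StructureModel-class number of atoms
#' @param x object.
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' @describeIn StructureModel-class atom table accessor
#' @param object a StructureModel.
#' @export
atoms <- function(object) object@atoms

#' @describeIn Trajectory-class frames accessor
#' @export
frames <- function(object) object@frames

#' @describeIn Trajectory-class number of frames
#' @export
nFrames <- function(object) length(object@frames)

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat(sprintf("StructureModel: %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain, a$resno))),
              paste(sort(unique(a$chain)), collapse = " ")))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d frames of %d atoms\n",
              length(object@frames), nrow(object@frames[[1]]@atoms)))
})

#' Read a dose-response CSV table
#'
#' Expected columns: \code{molecule}, \code{antagonist_conc},
#' \code{agonist_conc}, \code{response}, \code{replicate}.
#'
#' @param path CSV path.
#' @return data.frame with the columns above.
#' @export
readDoseResponse <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule", "antagonist_conc", "agonist_conc", "response",
            "replicate")
  if (!all(need %in% names(d)))
    stop(paste("dose-response CSV must have columns:",
               paste(need, collapse = ", ")))
  d
}
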