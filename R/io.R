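# Readers and writers.  Internal units are nm; PDB and PQR files are
# written in Angstrom as the formats require.  Base-pair triads are encoded
# as pseudo-atoms: ORI at the base-pair origin, LAX at origin + 0.5 nm
# along the long axis, SAX at origin + 0.5 nm along the short axis, from
# which the reader reconstructs the orthonormal triad.

.pdbAtomLine <- function(record, serial, name, resName, chain, resSeq,
                         xyz_nm, occ = 1, bfac = 0) {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          record, serial %% 100000, name, resName, chain, resSeq %% 10000,
          xyz_nm[1] * 10, xyz_nm[2] * 10, xyz_nm[3] * 10, occ, bfac)
}

.frameAtomLines <- function(frame, serial0 = 0) {
  n <- nBasePairs(frame)
  lines <- character(0)
  s <- serial0
  for (i in seq_len(n)) {
    s <- s + 1
    lines <- c(lines, .pdbAtomLine("ATOM", s, "P", "DN", "A", i,
                                   frame@p1[i, ]))
  }
  for (i in seq_len(n)) {
    s <- s + 1
    lines <- c(lines, .pdbAtomLine("ATOM", s, "P", "DN", "B", i,
                                   frame@p2[i, ]))
  }
  for (i in seq_len(n)) {
    lines <- c(lines,
               .pdbAtomLine("ATOM", s + 1, "ORI", "BPF", "X", i,
                            frame@origin[i, ]),
               .pdbAtomLine("ATOM", s + 2, "LAX", "BPF", "X", i,
                            frame@origin[i, ] + 0.5 * frame@lng[i, ]),
               .pdbAtomLine("ATOM", s + 3, "SAX", "BPF", "X", i,
                            frame@origin[i, ] + 0.5 * frame@shrt[i, ]))
    s <- s + 3
  }
  lines
}

#' Write a trajectory as multi-model PDB
#'
#' One MODEL/ENDMDL block per frame with ATOM records for the phosphorus
#' atoms (chains A and B) and the base-pair pseudo-atoms (chain X), and
#' HETATM records for ions (chain I).  A REMARK line records the helix form
#' and phosphate charge so the file round-trips.
#'
#' @param traj a [HelixTrajectory-class] or single [HelixFrame-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path) {
  if (is(traj, "HelixFrame")) {
    fr <- traj
    traj <- NULL
    frames <- 1
  } else {
    stopifnot(is(traj, "HelixTrajectory"))
    frames <- nFrames(traj)
  }
  con <- file(path, "w")
  on.exit(close(con))
  form <- if (is.null(traj)) fr@form else traj@form
  qP <- if (is.null(traj)) fr@phosphate_charge else traj@phosphate_charge
  writeLines(sprintf("REMARK 100 HELIXBEND FORM %s CHARGE %g",
                     form@name, qP), con)
  for (f in seq_len(frames)) {
    frame <- if (is.null(traj)) fr else getFrame(traj, f)
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(.frameAtomLines(frame), con)
    if (!is.null(traj)) {
      io <- frameIons(traj, f)
      if (nrow(io)) {
        for (j in seq_len(nrow(io))) {
          nm <- toupper(io$species[j])
          writeLines(.pdbAtomLine("HETATM", j, nm, nm, "I", j,
                                  c(io$x[j], io$y[j], io$z[j]),
                                  occ = io$charge[j]), con)
        }
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

.parsePdbAtoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[keep]
  data.frame(
    record = trimws(substr(lines, 1, 6)),
    name = trimws(substr(lines, 13, 16)),
    resName = trimws(substr(lines, 18, 20)),
    chain = substr(lines, 22, 22),
    resSeq = as.integer(substr(lines, 23, 26)),
    x = as.numeric(substr(lines, 31, 38)) / 10,
    y = as.numeric(substr(lines, 39, 46)) / 10,
    z = as.numeric(substr(lines, 47, 54)) / 10,
    occ = as.numeric(substr(lines, 55, 60)),
    stringsAsFactors = FALSE)
}

.frameFromAtoms <- function(at, form, qP) {
  pick <- function(chain, name = NULL) {
    sel <- at$chain == chain
    if (!is.null(name)) sel <- sel & at$name == name
    sub <- at[sel, , drop = FALSE]
    sub <- sub[order(sub$resSeq), , drop = FALSE]
    as.matrix(sub[, c("x", "y", "z")])
  }
  p1 <- pick("A"); p2 <- pick("B")
  ori <- pick("X", "ORI"); laxp <- pick("X", "LAX"); saxp <- pick("X", "SAX")
  if (!nrow(p1) || nrow(p1) != nrow(ori))
    stop("malformed frame: phosphate and base-pair records inconsistent")
  lng <- (laxp - ori) / 0.5
  shrt <- (saxp - ori) / 0.5
  lng <- lng / sqrt(rowSums(lng^2))
  shrt <- shrt / sqrt(rowSums(shrt^2))
  nrm <- .rowcross(shrt, lng)
  new("HelixFrame", p1 = p1, p2 = p2, origin = ori, nrm = nrm, lng = lng,
      shrt = shrt, form = form, phosphate_charge = qP)
}

#' Read a trajectory from multi-model PDB or a CSV frame table
#'
#' @param path input file.
#' @param format "auto" (by extension), "pdb" or "csv".
#' @return a [HelixTrajectory-class].
#' @export
readTrajectory <- function(path, format = c("auto", "pdb", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "pdb"
  if (format == "csv") return(.readTrajectoryCSV(path))

  lines <- readLines(path)
  if (!length(lines)) stop("parse error: empty PDB file")
  form <- helixForm("B"); qP <- -1
  rem <- grep("^REMARK 100 HELIXBEND", lines, value = TRUE)
  if (length(rem)) {
    tok <- strsplit(rem[1], "\\s+")[[1]]
    form <- helixForm(tok[which(tok == "FORM") + 1])
    qP <- as.numeric(tok[which(tok == "CHARGE") + 1])
  }
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) {
    warning("no MODEL records; reading as a single frame")
    starts <- 1; ends <- length(lines)
  }
  if (length(starts) != length(ends))
    stop("parse error: unbalanced MODEL/ENDMDL records near line ",
         if (length(starts)) starts[length(starts)] else 1)
  if (!any(grepl("^(ATOM|HETATM)", lines)))
    stop("parse error: no ATOM records found")

  frames <- vector("list", length(starts))
  ion_list <- vector("list", length(starts))
  for (f in seq_along(starts)) {
    at <- .parsePdbAtoms(lines[starts[f]:ends[f]])
    frames[[f]] <- .frameFromAtoms(at[at$record == "ATOM", , drop = FALSE],
                                   form, qP)
    het <- at[at$record == "HETATM", , drop = FALSE]
    if (nrow(het)) {
      sp <- paste0(substr(het$name, 1, 1),
                   tolower(substr(het$name, 2, 10)))
      ion_list[[f]] <- data.frame(frame = f, species = sp,
                                  charge = het$occ,
                                  x = het$x, y = het$y, z = het$z)
    }
  }
  .trajFromFrames(frames, do.call(rbind, ion_list), form, qP)
}

# assemble a HelixTrajectory from a list of HelixFrame objects
.trajFromFrames <- function(frames, ions, form, qP, config = list()) {
  n <- nBasePairs(frames[[1]])
  m <- length(frames)
  mk <- function(slotname) {
    a <- array(0, c(n, 3, m))
    for (f in seq_len(m)) a[, , f] <- slot(frames[[f]], slotname)
    a
  }
  if (is.null(ions))
    ions <- data.frame(frame = numeric(), species = character(),
                       charge = numeric(), x = numeric(), y = numeric(),
                       z = numeric())
  new("HelixTrajectory", p1 = mk("p1"), p2 = mk("p2"),
      origin = mk("origin"), nrm = mk("nrm"), lng = mk("lng"),
      shrt = mk("shrt"), ions = ions,
      frameMeta = data.frame(frame = seq_len(m)),
      form = form, phosphate_charge = qP, config = config)
}

#' Write a trajectory as a CSV frame table
#'
#' Long-format table with one row per entity: columns frame, entity_type
#' (phosphate1, phosphate2, bp_origin, bp_long, bp_short, ion), chain,
#' residue_index, species, charge, x, y, z (nm), form.  Triad direction
#' rows store origin + 0.5 nm along the axis, as in the PDB encoding.
#'
#' @param traj a [HelixTrajectory-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  stopifnot(is(traj, "HelixTrajectory"))
  m <- nFrames(traj)
  n <- nBasePairs(traj)
  rows <- vector("list", m)
  for (f in seq_len(m)) {
    fr <- getFrame(traj, f)
    base <- function(type, chain, xyz)
      data.frame(frame = f, entity_type = type, chain = chain,
                 residue_index = seq_len(n), species = "",
                 charge = ifelse(type %in% c("phosphate1", "phosphate2"),
                                 traj@phosphate_charge, 0),
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    part <- rbind(base("phosphate1", "A", fr@p1),
                  base("phosphate2", "B", fr@p2),
                  base("bp_origin", "X", fr@origin),
                  base("bp_long", "X", fr@origin + 0.5 * fr@lng),
                  base("bp_short", "X", fr@origin + 0.5 * fr@shrt))
    io <- frameIons(traj, f)
    if (nrow(io))
      part <- rbind(part,
                    data.frame(frame = f, entity_type = "ion", chain = "I",
                               residue_index = seq_len(nrow(io)),
                               species = io$species, charge = io$charge,
                               x = io$x, y = io$y, z = io$z))
    rows[[f]] <- part
  }
  out <- do.call(rbind, rows)
  out$form <- traj@form@name
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

.readTrajectoryCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("parse error: empty CSV trajectory")
  need <- c("frame", "entity_type", "residue_index", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("parse error: CSV trajectory missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  form <- helixForm(if ("form" %in% names(df)) df$form[1] else "B")
  qP <- if ("charge" %in% names(df))
    df$charge[df$entity_type == "phosphate1"][1] else -1
  fids <- sort(unique(df$frame))
  frames <- vector("list", length(fids))
  ion_list <- vector("list", length(fids))
  for (f in seq_along(fids)) {
    sub <- df[df$frame == fids[f], , drop = FALSE]
    grab <- function(type) {
      g <- sub[sub$entity_type == type, , drop = FALSE]
      g <- g[order(g$residue_index), , drop = FALSE]
      as.matrix(g[, c("x", "y", "z")])
    }
    ori <- grab("bp_origin")
    lng <- (grab("bp_long") - ori) / 0.5
    shrt <- (grab("bp_short") - ori) / 0.5
    lng <- lng / sqrt(rowSums(lng^2))
    shrt <- shrt / sqrt(rowSums(shrt^2))
    frames[[f]] <- new("HelixFrame", p1 = grab("phosphate1"),
                       p2 = grab("phosphate2"), origin = ori,
                       nrm = .rowcross(shrt, lng), lng = lng, shrt = shrt,
                       form = form, phosphate_charge = qP)
    io <- sub[sub$entity_type == "ion", , drop = FALSE]
    if (nrow(io))
      ion_list[[f]] <- data.frame(frame = f, species = io$species,
                                  charge = io$charge, x = io$x, y = io$y,
                                  z = io$z)
  }
  .trajFromFrames(frames, do.call(rbind, ion_list), form, qP)
}

#' Write a conformation as PQR for external Poisson-Boltzmann solvers
#'
#' Phosphorus sites with their charges and a 1.5 Angstrom radius, in the
#' whitespace-separated PQR variant accepted by APBS-compatible tools.
#'
#' @param frame a [HelixFrame-class].
#' @param path output file.
#' @param radius_A site radius in Angstrom.
#' @return the path, invisibly.
#' @export
writePQR <- function(frame, path, radius_A = 1.5) {
  stopifnot(is(frame, "HelixFrame"))
  pts <- rbind(frame@p1, frame@p2) * 10
  q <- rep(frame@phosphate_charge, nrow(pts))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(pts)))
    writeLines(sprintf(
      "ATOM  %5d  P   DN  %4d    %8.3f %8.3f %8.3f %7.4f %6.3f",
      i, i, pts[i, 1], pts[i, 2], pts[i, 3], q[i], radius_A), con)
  writeLines("END", con)
  invisible(path)
}

#' Read force-extension curves from CSV
#'
#' Expects columns molecule_id, salt_mM, ion, extension_nm, force_pN and
#' optionally temperature_K; one [ForceExtensionCurve-class] is returned
#' per (molecule_id, ion, salt_mM) combination.
#'
#' @param path input CSV.
#' @return list of [ForceExtensionCurve-class] objects.
#' @export
readForceExtension <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "salt_mM", "ion", "extension_nm", "force_pN")
  if (!all(need %in% names(df)))
    stop("force-extension CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!"temperature_K" %in% names(df)) df$temperature_K <- 298
  key <- interaction(df$molecule_id, df$ion, df$salt_mM, drop = TRUE)
  lapply(split(df, key), function(g)
    new("ForceExtensionCurve", extension_nm = g$extension_nm,
        force_pN = g$force_pN, temperature_K = g$temperature_K[1],
        molecule_id = as.character(g$molecule_id[1]), ion = g$ion[1],
        conc_mM = g$salt_mM[1]))
}

#' Write force-extension curves to CSV
#'
#' @param curves list of [ForceExtensionCurve-class] objects (or one).
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
writeForceExtension <- function(curves, path) {
  if (is(curves, "ForceExtensionCurve")) curves <- list(curves)
  rows <- lapply(curves, function(cu)
    data.frame(molecule_id = cu@molecule_id, salt_mM = cu@conc_mM,
               ion = cu@ion, extension_nm = cu@extension_nm,
               force_pN = cu@force_pN, temperature_K = cu@temperature_K))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
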