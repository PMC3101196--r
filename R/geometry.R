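#' Build a structure model from an atom table
#'
#' A structure model is the package's residue-indexed coordinate container:
#' a data.frame of atoms (author residue numbering preserved, coordinates in
#' Angstrom) from which the C-alpha trace is extracted for superposition and
#' angle measurements, while the full table remains available for atom-level
#' distance queries.
#'
#' @param atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resid}, \code{elety}, \code{x}, \code{y}, \code{z}; optional
#'   \code{insert}, \code{o} (occupancy), \code{altloc}.
#' @return Object of class \code{"structure_model"}.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  key <- paste(ca$chain, ca$resno, ca$insert)
  if (anyDuplicated(key))
    stop("duplicate C-alpha for residue(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  structure(list(atoms = atoms, ca = ca), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d atoms, %d C-alpha residues, chain(s) %s\n",
              nrow(x$atoms), nrow(x$ca),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Read a structure model from a PDB file or text
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}) preserving author residue
#' numbering and insertion codes.  Alternate locations are resolved per
#' (chain, residue, atom name): the highest-occupancy conformer is kept,
#' ties broken alphabetically by altloc identifier.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines.
#' @return a [structure_model()].
#' @export
read_structure <- function(pdb) {
  path <- pdb
  if (length(pdb) > 1 || !file.exists(pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(pdb, path)
    on.exit(unlink(path))
  }
  parsed <- bio3d::read.pdb(path, verbose = FALSE)
  at <- parsed$atom
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resid = at$resid, elety = at$elety,
                      altloc = ifelse(is.na(at$alt), "", at$alt),
                      o = ifelse(is.na(at$o), 1, at$o),
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- atoms[idx, ]
    idx[order(-sub$o, sub$altloc)][1]
  }), use.names = FALSE)
  structure_model(atoms[sort(keep), , drop = FALSE])
}

#' Write a structure model to a PDB file
#'
#' @param model a [structure_model()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = a$resid, chain = a$chain, elety = a$elety,
                   insert = a$insert, o = a$o)
  invisible(path)
}

ca_coords <- function(model, chain = NULL) {
  ca <- model$ca
  if (!is.null(chain)) ca <- ca[ca$chain %in% chain, , drop = FALSE]
  ca
}

#' Optimal rigid-body (Kabsch) superposition of matched C-alpha atoms
#'
#' Least-squares superposition of the mobile structure onto the reference
#' over residues matched by (chain, residue number), restricted to
#' \code{residue_selection} when given.  The optimal proper rotation is
#' obtained from the SVD of the cross-covariance of the centred coordinate
#' sets with the usual determinant correction, so reflections are never
#' returned.
#'
#' @param mobile,reference [structure_model()] objects with >= 3 matched
#'   residues.
#' @param residue_selection optional integer vector of residue numbers to
#'   superpose on.
#' @param chain optional chain id(s) to restrict the match.
#' @return Object of class \code{"superposition"}: \code{rotation} (3x3,
#'   det +1), \code{translation} (length 3), \code{rmsd} (Angstrom),
#'   \code{resno} used, and the centred coordinate means.  Apply with
#'   [apply_superposition()].
#' @export
kabsch_superpose <- function(mobile, reference, residue_selection = NULL,
                             chain = NULL) {
  stopifnot(inherits(mobile, "structure_model"),
            inherits(reference, "structure_model"))
  ma <- ca_coords(mobile, chain); ra <- ca_coords(reference, chain)
  mkey <- paste(ma$chain, ma$resno); rkey <- paste(ra$chain, ra$resno)
  common <- intersect(mkey, rkey)
  if (!is.null(residue_selection)) {
    sel <- ma$resno[match(common, mkey)] %in% residue_selection
    common <- common[sel]
  }
  if (length(common) < 3)
    stop("need at least 3 matched residues for superposition (got ",
         length(common), ")")
  X <- as.matrix(ma[match(common, mkey), c("x", "y", "z")])  # mobile
  Y <- as.matrix(ra[match(common, rkey), c("x", "y", "z")])  # reference
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2, xc); Yc <- sweep(Y, 2, yc)
  s <- svd(crossprod(Xc, Yc))            # X^T Y
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(list(rotation = R, translation = yc - as.vector(R %*% xc),
                 rmsd = rmsd, resno = ma$resno[match(common, mkey)],
                 center_mobile = xc, center_reference = yc),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Kabsch superposition over %d residues: rmsd = %.4f A\n",
              length(x$resno), x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to a structure model
#'
#' @param model a [structure_model()].
#' @param transform a [kabsch_superpose()] result.
#' @return the transformed [structure_model()].
#' @export
apply_superposition <- function(model, transform) {
  stopifnot(inherits(model, "structure_model"),
            inherits(transform, "superposition"))
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(transform$rotation)
  xyz <- sweep(xyz, 2, transform$translation, `+`)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  structure_model(a)
}

#' Marker triple for the aperture angle
#'
#' Three conserved residues, one per conserved motif, whose C-alpha atoms
#' define the domain-closure (aperture) angle.  The default corresponds to
#' the Cys/His/Ile conserved triad (Cys91, His137, Ile42 in plant PDF1B
#' numbering); the vertex defaults to the second listed residue (the His),
#' which sits between the two domain anchors.  The vertex choice is a
#' documented convention, not a measured constant: configure it when
#' calibrating against a reference ensemble.
#'
#' @param resno1,resno2,resno3 residue numbers of the three markers.
#' @param vertex which of the three (1, 2 or 3) is the angle vertex.
#' @param chain optional chain id (applies to all three).
#' @return Object of class \code{"marker_triple"}.
#' @export
marker_triple <- function(resno1 = 91, resno2 = 137, resno3 = 42,
                          vertex = 2, chain = NULL) {
  resno <- c(resno1, resno2, resno3)
  if (length(unique(resno)) != 3) stop("the three marker residues must be distinct")
  if (!vertex %in% 1:3) stop("vertex must be 1, 2 or 3")
  structure(list(resno = resno, vertex = as.integer(vertex), chain = chain),
            class = "marker_triple")
}

marker_xyz <- function(model, markers) {
  ca <- ca_coords(model, markers$chain)
  idx <- match(markers$resno, ca$resno)
  if (anyNA(idx))
    stop("marker residue(s) missing a C-alpha: ",
         paste(markers$resno[is.na(idx)], collapse = ", "))
  as.matrix(ca[idx, c("x", "y", "z")])
}

#' Aperture (domain-closure) angle of a structure
#'
#' The planar angle, in degrees, at the vertex marker between the C-alpha
#' positions of the two flanking markers.  Being an internal coordinate it
#' is invariant under any rigid transform of the model.
#'
#' @param model a [structure_model()].
#' @param markers a [marker_triple()].
#' @return angle in degrees (0-180).
#' @export
aperture_angle <- function(model, markers = marker_triple()) {
  P <- marker_xyz(model, markers)
  v <- P[markers$vertex, ]
  flank <- P[setdiff(1:3, markers$vertex), , drop = FALSE]
  u1 <- flank[1, ] - v; u2 <- flank[2, ] - v
  n1 <- sqrt(sum(u1^2)); n2 <- sqrt(sum(u2^2))
  if (n1 < 1e-9 || n2 < 1e-9)
    stop("undefined angle: coincident marker C-alpha positions")
  cosang <- sum(u1 * u2) / (n1 * n2)
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Per-residue C-alpha displacement after superposition
#'
#' Applies a superposition transform to the mobile model and reports the
#' residual C-alpha distance per matched residue, together with the maximum
#' and the residue attaining it.
#'
#' @param mobile,reference [structure_model()] objects.
#' @param transform a [kabsch_superpose()] result (computed between the two
#'   models, possibly on a sub-selection of residues).
#' @param chain optional chain restriction.
#' @return list with \code{per_residue} (data.frame \code{resno},
#'   \code{displacement}), \code{max}, \code{argmax}.
#' @export
residue_displacement <- function(mobile, reference, transform, chain = NULL) {
  moved <- apply_superposition(mobile, transform)
  ma <- ca_coords(moved, chain); ra <- ca_coords(reference, chain)
  mkey <- paste(ma$chain, ma$resno); rkey <- paste(ra$chain, ra$resno)
  common <- intersect(mkey, rkey)
  X <- as.matrix(ma[match(common, mkey), c("x", "y", "z")])
  Y <- as.matrix(ra[match(common, rkey), c("x", "y", "z")])
  d <- sqrt(rowSums((X - Y)^2))
  resno <- ma$resno[match(common, mkey)]
  list(per_residue = data.frame(resno = resno, displacement = d),
       max = max(d), argmax = resno[which.max(d)])
}

#' Euclidean distance between two atoms of a structure model
#'
#' @param model a [structure_model()].
#' @param a,b atom references: lists with \code{resno} and \code{elety}
#'   (optionally \code{chain}).
#' @return distance in Angstrom.
#' @export
atom_distance <- function(model, a, b) {
  find <- function(ref) {
    at <- model$atoms
    sel <- at$resno == ref$resno & at$elety == ref$elety
    if (!is.null(ref$chain)) sel <- sel & at$chain == ref$chain
    hit <- which(sel)
    if (!length(hit))
      stop("atom not found: residue ", ref$resno, " atom ", ref$elety)
    as.numeric(at[hit[1], c("x", "y", "z")])
  }
  pa <- find(a); pb <- find(b)
  sqrt(sum((pa - pb)^2))
}

#' Conformational-state zones in the (aperture angle, rmsd) plane
#'
#' Rectangular zones assigning (delta_ap, rmsd) pairs to conformational
#' states: open (O), intermediate (I), closed (C) and super-closed (S).
#' Zones are checked for pairwise-disjoint interiors at construction; any
#' point outside every zone is \code{"unassigned"}, and a point on a shared
#' boundary goes to the first zone (in list order) whose closed rectangle
#' contains it.
#'
#' The default zones shipped by [default_state_zones()] are an explicitly
#' approximate calibration for the synthetic conformer families generated
#' here: the only hard constraint carried over from experimental practice is
#' that like-state structures superpose to within 0.25 Angstrom rmsd, which
#' anchors the rmsd edge of the open zone.  Real ensembles require
#' user-calibrated zones.
#'
#' @param zones named list; each element is
#'   \code{c(delta_min, delta_max, rmsd_min, rmsd_max)}.
#' @return Object of class \code{"state_zones"}.
#' @export
state_zones <- function(zones) {
  if (!length(zones) || is.null(names(zones)) || any(names(zones) == ""))
    stop("zones must be a named list")
  for (nm in names(zones)) {
    z <- zones[[nm]]
    if (length(z) != 4 || z[1] >= z[2] || z[3] >= z[4])
      stop("zone '", nm, "' must be c(delta_min, delta_max, rmsd_min, rmsd_max) ",
           "with min < max")
  }
  nms <- names(zones)
  for (i in seq_along(zones)) for (j in seq_len(i - 1)) {
    a <- zones[[i]]; b <- zones[[j]]
    if (a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4])
      stop("zones '", nms[i], "' and '", nms[j], "' overlap")
  }
  structure(zones, class = "state_zones")
}

#' Default approximate state zones
#'
#' @return a [state_zones()] object with O/I/C/S rectangles.
#' @export
default_state_zones <- function() {
  state_zones(list(
    O = c(90, 105, 0.00, 0.25),
    I = c(85, 90, 0.25, 2.00),
    C = c(78, 85, 2.00, 4.00),
    S = c(65, 78, 4.00, 8.00)
  ))
}

#' Classify a conformer by its aperture angle and rmsd
#'
#' @param delta_ap aperture angle in degrees.
#' @param rmsd superposition rmsd against the open reference (Angstrom).
#' @param zones a [state_zones()].
#' @return the zone label, or \code{"unassigned"}.
#' @export
classify_state <- function(delta_ap, rmsd, zones = default_state_zones()) {
  if (!inherits(zones, "state_zones")) zones <- state_zones(zones)
  if (delta_ap < 0 || delta_ap > 180) stop("delta_ap must be in [0, 180]")
  if (rmsd < 0) stop("rmsd must be >= 0")
  for (nm in names(zones)) {
    z <- zones[[nm]]
    if (delta_ap >= z[1] && delta_ap <= z[2] && rmsd >= z[3] && rmsd <= z[4])
      return(nm)
  }
  "unassigned"
}

#' Aperture analysis of one structure against an open reference
#'
#' Convenience wrapper computing the three quantities of the
#' conformational-state map in one call: the aperture angle, the Kabsch
#' rmsd against the reference, and the state label.
#'
#' @param model a [structure_model()].
#' @param reference the open-reference [structure_model()].
#' @param markers a [marker_triple()].
#' @param zones a [state_zones()].
#' @return list of class \code{"aperture_result"}: \code{delta_ap},
#'   \code{rmsd}, \code{state}.
#' @export
aperture_result <- function(model, reference, markers = marker_triple(),
                            zones = default_state_zones()) {
  sup <- kabsch_superpose(model, reference)
  delta <- aperture_angle(model, markers)
  structure(list(delta_ap = delta, rmsd = sup$rmsd,
                 state = classify_state(delta, sup$rmsd, zones)),
            class = "aperture_result")
}

#' @export
print.aperture_result <- function(x, ...) {
  cat(sprintf("delta_ap = %.2f deg, rmsd = %.3f A, state = %s\n",
              x$delta_ap, x$rmsd, x$state))
  invisible(x)
}
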