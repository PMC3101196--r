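#' Generate a toy C-alpha conformer with a prescribed aperture angle
#'
#' Builds a deterministic single-chain C-alpha scaffold whose three marker
#' residues are placed so that [aperture_angle()] evaluates exactly to
#' \code{target_delta_ap} at zero noise.  The two flanking markers sit on
#' 8-Angstrom arms from the vertex; the remaining residues fan out between
#' the arms so that the whole backbone opens and closes with the target
#' angle (making the superposition rmsd against a reference conformer grow
#' smoothly with the angle difference).  Optional isotropic Gaussian
#' coordinate noise is added, and a rigid-body pose (rotation + translation)
#' is applied last, so the generated internal geometry is pose-independent.
#'
#' @param scaffold_size number of residues (must cover the marker numbers).
#' @param target_delta_ap aperture angle in degrees, in (0, 180).
#' @param rigid_pose optional list with \code{angles} (xyz Euler angles,
#'   radians) and \code{translation} (Angstrom).
#' @param coord_noise isotropic Gaussian noise SD per coordinate (Angstrom).
#' @param seed integer seed (noise only; the scaffold is deterministic).
#' @param markers a [marker_triple()] naming the three marker residues.
#' @return a [structure_model()] (CA atoms only, chain "A").
#' @examples
#' m <- generate_conformer(target_delta_ap = 90)
#' aperture_angle(m)   # 90
#' @export
generate_conformer <- function(scaffold_size = 150, target_delta_ap = 95,
                               rigid_pose = NULL, coord_noise = 0,
                               seed = 1L, markers = marker_triple()) {
  if (target_delta_ap <= 0 || target_delta_ap >= 180)
    stop("target_delta_ap must be strictly between 0 and 180 degrees")
  if (scaffold_size < max(markers$resno))
    stop("scaffold_size must cover the marker residue numbers")
  theta <- target_delta_ap * pi / 180
  vertex <- c(0, 0, 0)
  arm <- 8
  u1 <- c(cos(theta / 2), sin(theta / 2), 0)
  u2 <- c(cos(theta / 2), -sin(theta / 2), 0)
  resno <- seq_len(scaffold_size)
  xyz <- matrix(NA_real_, scaffold_size, 3)
  # non-marker residues fan between the two arm directions, stacked in z
  for (i in resno) {
    f <- (i - 1) / max(scaffold_size - 1, 1)
    ang <- (theta / 2) * (1 - 2 * f)             # +theta/2 -> -theta/2
    dirn <- c(cos(ang), sin(ang), 0)
    r <- 5 + 3.8 * (i %% 17)
    xyz[i, ] <- vertex + dirn * r + c(0, 0, 1.5 * (i %/% 17))
  }
  flank <- setdiff(1:3, markers$vertex)
  xyz[markers$resno[markers$vertex], ] <- vertex
  xyz[markers$resno[flank[1]], ] <- vertex + arm * u1
  xyz[markers$resno[flank[2]], ] <- vertex + arm * u2
  if (coord_noise > 0) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, coord_noise), ncol = 3)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  if (!is.null(rigid_pose)) {
    R <- euler_rotation(rigid_pose$angles %||% c(0, 0, 0))
    tr <- rigid_pose$translation %||% c(0, 0, 0)
    xyz <- sweep(xyz %*% t(R), 2, tr, `+`)
  }
  resid <- rep("ALA", scaffold_size)
  resid[markers$resno[1]] <- "CYS"
  resid[markers$resno[2]] <- "HIS"
  resid[markers$resno[3]] <- "ILE"
  structure_model(data.frame(
    chain = "A", resno = resno, resid = resid, elety = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

#' Rotation matrix from xyz Euler angles
#'
#' @param angles length-3 numeric (radians), rotations about x, y, z applied
#'   in that order.
#' @return 3x3 proper rotation matrix.
#' @export
euler_rotation <- function(angles) {
  a <- angles[1]; b <- angles[2]; g <- angles[3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid motion to a structure model
#'
#' @param model a [structure_model()].
#' @param angles xyz Euler angles (radians).
#' @param translation length-3 translation (Angstrom).
#' @return the transformed [structure_model()].
#' @export
rigid_move <- function(model, angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"))
  R <- euler_rotation(angles)
  a <- model$atoms
  xyz <- sweep(as.matrix(a[, c("x", "y", "z")]) %*% t(R), 2, translation, `+`)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  structure_model(a)
}
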