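# six-membered-ring atom names shared by all five bases (for purines this
# is the pyrimidine ring of the fused system)
.SIX_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

# reference (standard-frame) coordinates of the six-ring atoms of a base
.ref_ring_coords <- function(base) {
  spec <- .BASE_HEAVY[[base]]
  idx <- match(.SIX_RING, spec$atoms)
  cbind(spec$xy[idx, , drop = FALSE], 0)
}

# guess which base a labelled molecule is, from its characteristic atoms
.guess_base <- function(mol) {
  lab <- mol$labels
  if (!all(.SIX_RING %in% lab)) return(NULL)
  has <- function(a) a %in% lab
  if (has("N9")) { if (has("O6")) "G" else "A" }
  else if (has("N4")) "C"
  else if (has("C7") || has("C5M")) "T"
  else if (has("O4")) "U"
  else NULL
}

#' Fit the standard reference frame of a base
#'
#' Least-squares (Kabsch) superposition of the standard planar reference
#' geometry of the base onto the observed coordinates, using the
#' six-membered ring atoms (N1, C2, N3, C4, C5, C6; atoms are matched by
#' label, with \code{C5M} accepted for thymine's methyl carbon). The
#' returned frame is the image of the standard base-pair reference frame:
#' origin at the image of (0,0,0), x toward the major groove, y toward the
#' leading-strand sugar and z along the base normal, so that the two bases
#' of a Watson--Crick pair carry anti-parallel y and z.
#'
#' @param mol an \code{lcao_molecule} with standard atom labels.
#' @param base base identity (\code{"A","G","C","T","U"}); guessed from
#'   the labels when omitted.
#' @return A list with \code{origin}, \code{axes} (3 x 3, columns x, y,
#'   z, right-handed orthonormal) and \code{rmsd} of the ring fit
#'   (Angstrom).
#' @examples
#' fr <- fit_base_frame(nucleobase("A"))
#' fr$axes[, "z"]   # +z for a strand-1 base
#' @export
fit_base_frame <- function(mol, base = NULL) {
  if (is.null(base)) base <- .guess_base(mol)
  if (is.null(base))
    stop("cannot identify the base of '", mol$name,
         "' from its atom labels; pass base = \"A\",...")
  idx <- match(.SIX_RING, mol$labels)
  if (any(is.na(idx)))
    stop("molecule '", mol$name, "' lacks labelled ring atoms ",
         paste(.SIX_RING[is.na(idx)], collapse = ", "))
  obs <- mol$coords[idx, , drop = FALSE]
  ref <- .ref_ring_coords(base)
  oc <- colMeans(obs); rc <- colMeans(ref)
  A <- t(sweep(ref, 2L, rc)) %*% sweep(obs, 2L, oc)
  sv <- svd(A)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12))
    stop("degenerate frame: ring atoms of '", mol$name,
         "' are collinear")
  sgn <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, sgn)) %*% t(sv$u)
  origin <- drop(oc - R %*% rc)
  fitted <- sweep(sweep(ref, 2L, rc) %*% t(R), 2L, -oc)
  colnames(R) <- c("x", "y", "z")
  list(origin = origin, axes = R,
       rmsd = sqrt(mean(rowSums((fitted - obs)^2))))
}

.axis_angle <- function(D) {
  tr <- sum(diag(D))
  cth <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cth)
  if (theta < 1e-12) return(list(theta = 0, axis = c(0, 0, 1)))
  if (abs(pi - theta) < 1e-8) {
    # 180-degree rotation: axis from the symmetric part
    B <- (D + diag(3)) / 2
    axis <- .unit(B[, which.max(diag(B))])
    return(list(theta = pi, axis = axis))
  }
  axis <- c(D[3L, 2L] - D[2L, 3L], D[1L, 3L] - D[3L, 1L],
            D[2L, 1L] - D[1L, 2L]) / (2 * sin(theta))
  list(theta = theta, axis = axis)
}

.axis_angle_matrix <- function(axis, theta) {
  u <- .unit(axis)
  K <- rbind(c(0, -u[3L], u[2L]), c(u[3L], 0, -u[1L]),
             c(-u[2L], u[1L], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Intra-base-pair translation and rotation parameters
#'
#' Computes the six complementary base-pair parameters -- shear, stretch,
#' stagger (Angstrom) and buckle, propeller twist, opening (degrees) --
#' describing base 1 relative to base 2 in the mid-frame convention. The
#' base-2 frame is first flipped (y and z negated, as it sits on the
#' complementary strand), the mid-frame is the half-way rotation between
#' the two frames, translations are the components of the
#' origin-1-minus-origin-2 vector along the mid-frame x, y, z axes, and
#' rotations are the components of the frame-2-to-frame-1 rotation (angle
#' times unit axis) along the same axes: buckle about x, propeller about
#' y, opening about z. For an undistorted standard pair all six parameters
#' are zero. The convention's symmetry under swapping the two bases (as in the
#' field's standard implementations): shear and buckle change sign;
#' stretch, stagger, propeller and opening are preserved.
#'
#' @param base1,base2 \code{lcao_molecule} bases with standard atom
#'   labels (base 1 on the leading strand).
#' @param frame1,frame2 optional frames as returned by
#'   \code{\link{fit_base_frame}}; fitted automatically when omitted.
#' @return An object of class \code{lcao_bp_params} with fields
#'   \code{shear}, \code{stretch}, \code{stagger} (Angstrom),
#'   \code{buckle}, \code{propeller}, \code{opening} (degrees, in
#'   (-180, 180]).
#' @examples
#' pr <- wc_pair("G")
#' base_pair_parameters(pr$base1, pr$base2)   # all zero
#' @export
base_pair_parameters <- function(base1, base2, frame1 = NULL,
                                 frame2 = NULL) {
  if (is.null(frame1)) frame1 <- fit_base_frame(base1)
  if (is.null(frame2)) frame2 <- fit_base_frame(base2)
  R1 <- frame1$axes
  R2 <- frame2$axes %*% diag(c(1, -1, -1))  # flip the strand-II frame
  if (sum(R1[, 3L] * R2[, 3L]) < 0)
    warning("base normals are not anti-parallel; parameters may be ",
            "meaningless for this geometry")
  D <- R1 %*% t(R2)
  aa <- .axis_angle(D)
  Rm <- .axis_angle_matrix(aa$axis, aa$theta / 2) %*% R2
  tv <- drop(t(Rm) %*% (frame1$origin - frame2$origin))
  rot <- aa$theta * drop(t(Rm) %*% aa$axis) * 180 / pi
  structure(list(shear = tv[1L], stretch = tv[2L], stagger = tv[3L],
                 buckle = rot[1L], propeller = rot[2L],
                 opening = rot[3L]),
            class = "lcao_bp_params")
}

#' @export
print.lcao_bp_params <- function(x, ...) {
  cat(sprintf(paste0("Base-pair parameters:\n",
                     "  shear %+.3f A  stretch %+.3f A  stagger %+.3f A\n",
                     "  buckle %+.2f deg  propeller %+.2f deg  ",
                     "opening %+.2f deg\n"),
              x$shear, x$stretch, x$stagger, x$buckle, x$propeller,
              x$opening))
  invisible(x)
}
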