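# Talairach -> MNI coordinate conversion.
#
# The de-facto standard in the ALE literature is the Lancaster "tal2icbm"
# transform, i.e. the inverse of the published icbm2tal affine fitted on
# pooled (non-SPM) normalised data; the SPM-specific fit and the older Brett
# piecewise transform are provided as alternatives, plus identity for
# debugging.

# Lancaster et al. (2007) icbm2tal affines (world mm, row-major).
ICBM2TAL_POOLED <- matrix(c(
   0.9357,  0.0029, -0.0072, -1.0423,
  -0.0065,  0.9396, -0.0726, -1.3940,
   0.0103,  0.0752,  0.8967,  3.6475,
   0,       0,       0,       1), nrow = 4, byrow = TRUE)

ICBM2TAL_SPM <- matrix(c(
   0.9254,  0.0024, -0.0118, -1.0207,
  -0.0048,  0.9316, -0.0871, -1.7667,
   0.0152,  0.0883,  0.8924,  4.0926,
   0,       0,       0,       1), nrow = 4, byrow = TRUE)

# Brett mni2tal piecewise affines (z >= 0 and z < 0 halves).
BRETT_MNI2TAL_POS <- matrix(c(
  0.99, 0,       0,      0,
  0,    0.9688,  0.046,  0,
  0,   -0.0485,  0.9189, 0,
  0,    0,       0,      1), nrow = 4, byrow = TRUE)

BRETT_MNI2TAL_NEG <- matrix(c(
  0.99, 0,       0,      0,
  0,    0.9688,  0.042,  0,
  0,   -0.0485,  0.839,  0,
  0,    0,       0,      1), nrow = 4, byrow = TRUE)

apply_affine <- function(A, xyz) {
  xyz <- rbind_coords(xyz)
  out <- t(A %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Convert Talairach coordinates to MNI space
#'
#' @param xyz numeric(3) or n x 3 matrix of Talairach mm coordinates.
#' @param method `"lancaster"` (inverse pooled icbm2tal, the GingerALE
#'   convention; default), `"lancaster_spm"`, `"brett"` (piecewise inverse,
#'   branch chosen by the sign of the Talairach z), or `"identity"`.
#' @return matrix of MNI coordinates, same shape as input.
#' @export
tal_to_mni_xyz <- function(xyz, method = c("lancaster", "lancaster_spm",
                                           "brett", "identity")) {
  method <- match.arg(method)
  xyz <- rbind_coords(xyz)
  switch(method,
    lancaster     = apply_affine(solve(ICBM2TAL_POOLED), xyz),
    lancaster_spm = apply_affine(solve(ICBM2TAL_SPM), xyz),
    identity      = { colnames(xyz) <- c("x", "y", "z"); xyz },
    brett = {
      pos <- xyz[, 3] >= 0
      out <- xyz
      if (any(pos))
        out[pos, ] <- apply_affine(solve(BRETT_MNI2TAL_POS),
                                   xyz[pos, , drop = FALSE])
      if (any(!pos))
        out[!pos, ] <- apply_affine(solve(BRETT_MNI2TAL_NEG),
                                    xyz[!pos, , drop = FALSE])
      colnames(out) <- c("x", "y", "z")
      out
    })
}

#' Convert a single focus from Talairach to MNI
#'
#' A focus is a list with fields `x`, `y`, `z` (mm) and `space` (`"MNI"` or
#' `"Talairach"`).  An already-MNI focus is returned unchanged with a
#' warning (not an error).
#'
#' @param focus a focus list.
#' @inheritParams tal_to_mni_xyz
#' @return the focus in MNI space.
#' @export
tal_to_mni <- function(focus, method = "lancaster") {
  stopifnot(is.list(focus), all(c("x", "y", "z", "space") %in% names(focus)))
  if (identical(focus$space, "MNI")) {
    warning("focus already in MNI space; returned unchanged")
    return(focus)
  }
  if (!identical(focus$space, "Talairach"))
    stop("unknown space: ", focus$space)
  m <- tal_to_mni_xyz(c(focus$x, focus$y, focus$z), method = method)
  list(x = m[1, 1], y = m[1, 2], z = m[1, 3], space = "MNI")
}
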