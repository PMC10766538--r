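# volume_stack: the in-memory image container handed from DICOM assembly to
# BIDS writing and quality control. Spatial axes come first; an echo axis is
# present only for multi-echo series and a frame (time) axis only for dynamic
# series, always last. World coordinates follow the NIfTI RAS+ convention and
# orientation codes are the familiar three-letter axis codes (RAS, LPS, RPI...),
# each letter naming the anatomical direction in which the voxel index grows.

#' Construct a volume stack
#'
#' @param voxels Numeric array: `(x, y, z)`, `(x, y, z, echo)`,
#'   `(x, y, z, frame)` or `(x, y, z, echo, frame)`. Which trailing axes are
#'   present is declared through `echo_times` / `frame_times`.
#' @param spacing Numeric length-3 voxel size in mm, all positive.
#' @param affine 4x4 voxel-to-world (RAS+, mm) transform; voxel indices are
#'   0-based as in NIfTI.
#' @param echo_times Echo times in seconds (length = echo axis, or length 1
#'   with no echo axis). `NULL` for single-echo with no axis.
#' @param frame_times Frame start times in seconds for dynamic series, else
#'   `NULL`.
#' @param frame_durations Frame durations in seconds, same length as
#'   `frame_times`.
#' @param intensity_units Free-text unit label (e.g. `"arbitrary"`, `"Bq/mL"`).
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(voxels, spacing, affine,
                         echo_times = NULL, frame_times = NULL,
                         frame_durations = NULL,
                         intensity_units = "arbitrary") {
  stopifnot(is.array(voxels), length(dim(voxels)) >= 3L, length(dim(voxels)) <= 5L)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("affine spatial block is singular")
  nd <- length(dim(voxels))
  n_echo <- if (is.null(echo_times)) 1L else length(echo_times)
  has_echo_axis <- n_echo > 1L
  has_frame_axis <- !is.null(frame_times) && length(frame_times) > 1L
  expected_nd <- 3L + has_echo_axis + has_frame_axis
  if (nd != expected_nd)
    stop("voxel array has ", nd, " dims but echo/frame declaration implies ",
         expected_nd)
  if (has_echo_axis && any(diff(echo_times) <= 0))
    stop("echo_times must be strictly increasing")
  if (has_frame_axis) {
    if (is.null(frame_durations) || length(frame_durations) != length(frame_times))
      stop("frame_durations must accompany frame_times, same length")
    if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  }
  structure(list(
    voxels = voxels,
    spacing = as.numeric(spacing),
    affine = affine,
    echo_times = echo_times,
    frame_times = frame_times,
    frame_durations = frame_durations,
    intensity_units = intensity_units
  ), class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<volume_stack> ", paste(d, collapse = " x "),
      " | spacing ", paste(signif(x$spacing, 4), collapse = "x"), " mm",
      " | orientation ", orientation_code(x$affine), "\n", sep = "")
  if (!is.null(x$echo_times) && length(x$echo_times) > 1L)
    cat("  echoes:", length(x$echo_times), " TE(s):",
        paste(signif(x$echo_times, 4), collapse = ", "), "\n")
  if (!is.null(x$frame_times) && length(x$frame_times) > 1L)
    cat("  frames:", length(x$frame_times), " span:",
        max(x$frame_times + x$frame_durations), "s\n")
  invisible(x)
}

.n_echo <- function(vol) if (is.null(vol$echo_times)) 1L else length(vol$echo_times)
.n_frame <- function(vol) if (is.null(vol$frame_times)) 1L else length(vol$frame_times)
.has_echo_axis <- function(vol) .n_echo(vol) > 1L
.has_frame_axis <- function(vol) .n_frame(vol) > 1L

# 3-D sub-volume at a given echo/frame index (1-based), always a 3-D array
.get_volume3d <- function(vol, echo = 1L, frame = 1L) {
  v <- vol$voxels
  nd <- length(dim(v))
  if (nd == 3L) return(v)
  if (nd == 4L) {
    idx <- if (.has_echo_axis(vol)) echo else frame
    return(array(v[, , , idx], dim = dim(v)[1:3]))
  }
  array(v[, , , echo, frame], dim = dim(v)[1:3])
}

.axis_letters <- matrix(c("L", "R", "P", "A", "I", "S"), nrow = 2,
                        dimnames = list(c("neg", "pos"), c("x", "y", "z")))

#' Orientation code of an affine
#'
#' Maps each voxel axis to the closest signed anatomical world axis and
#' returns the three-letter code (e.g. `"RAS"`, `"LPS"`, `"RPI"`): letter k
#' names the world direction along which voxel index k increases.
#'
#' @param affine 4x4 RAS+ voxel-to-world transform.
#' @param max_obliquity_deg Maximal tolerated angle (degrees) between a voxel
#'   axis and its nearest cardinal world axis before a warning is emitted and
#'   the nearest code is still returned (snap-with-warning).
#' @return Three-letter character scalar.
#' @export
orientation_code <- function(affine, max_obliquity_deg = 20) {
  R <- affine[1:3, 1:3]
  cols <- sweep(R, 2, sqrt(colSums(R^2)), "/")
  letters3 <- character(3)
  used <- integer(0)
  worst <- 0
  for (k in 1:3) {
    ax <- which.max(abs(cols[, k]))
    if (ax %in% used) stop("degenerate affine: two voxel axes map to one world axis")
    used <- c(used, ax)
    ang <- acos(min(1, abs(cols[ax, k]))) * 180 / pi
    worst <- max(worst, ang)
    letters3[k] <- .axis_letters[if (cols[ax, k] >= 0) "pos" else "neg", ax]
  }
  if (worst > max_obliquity_deg)
    warning(sprintf(paste0("affine is oblique (max axis deviation %.1f deg > %g deg); ",
                           "snapping to nearest code '%s' - flag for manual review"),
                    worst, max_obliquity_deg, paste(letters3, collapse = "")))
  paste(letters3, collapse = "")
}

.parse_code <- function(code) {
  stopifnot(is.character(code), nchar(code) == 3L)
  letters3 <- strsplit(toupper(code), "")[[1]]
  axis <- integer(3); sign <- integer(3)
  for (k in 1:3) {
    hit <- which(.axis_letters == letters3[k], arr.ind = TRUE)
    if (nrow(hit) != 1L) stop("invalid orientation letter: ", letters3[k])
    axis[k] <- hit[1, "col"]
    sign[k] <- if (hit[1, "row"] == 2L) 1L else -1L
  }
  if (length(unique(axis)) != 3L) stop("invalid orientation code: ", code)
  list(axis = axis, sign = sign)
}

#' Reorient a volume stack to a target axis code
#'
#' Permutes and flips the spatial axes (echo/frame axes untouched) so that the
#' volume's orientation code equals `target`, updating the affine so world
#' coordinates of every voxel are preserved. Reorienting back to the original
#' code reproduces the original voxel array exactly.
#'
#' @param vol A `volume_stack`.
#' @param target Three-letter code, e.g. `"RPI"`.
#' @param max_obliquity_deg Passed to [orientation_code()].
#' @return A reoriented `volume_stack`.
#' @export
reorient <- function(vol, target, max_obliquity_deg = 20) {
  stopifnot(inherits(vol, "volume_stack"))
  cur <- orientation_code(vol$affine, max_obliquity_deg)
  if (identical(cur, toupper(target))) return(vol)
  pc <- .parse_code(cur)
  pt <- .parse_code(target)

  perm <- integer(3); flip <- logical(3)
  for (k in 1:3) {
    j <- which(pc$axis == pt$axis[k])
    perm[k] <- j
    flip[k] <- pc$sign[j] != pt$sign[k]
  }

  v <- vol$voxels
  nd <- length(dim(v))
  full_perm <- c(perm, if (nd > 3L) 4:nd)
  v <- aperm(v, full_perm)
  idx <- rep(list(quote(expr = )), nd)
  for (k in 1:3) if (flip[k]) idx[[k]] <- rev(seq_len(dim(v)[k]))
  v <- do.call(`[`, c(list(v), idx, list(drop = FALSE)))

  # new affine: column k is +/- old column perm[k]; flipped axes shift origin
  A <- vol$affine
  R <- A[1:3, 1:3]
  newR <- matrix(0, 3, 3)
  origin <- A[1:3, 4]
  dims <- dim(vol$voxels)[1:3]
  for (k in 1:3) {
    col <- R[, perm[k]]
    if (flip[k]) {
      origin <- origin + col * (dims[perm[k]] - 1L)
      col <- -col
    }
    newR[, k] <- col
  }
  A2 <- diag(4)
  A2[1:3, 1:3] <- newR
  A2[1:3, 4] <- origin

  out <- vol
  out$voxels <- v
  out$affine <- A2
  out$spacing <- vol$spacing[perm]
  out
}

#' Re-express diffusion gradient vectors after a change of axis code
#'
#' Applies the same axis permutation and sign flips that [reorient()] applies
#' to the voxel grid, so gradient directions stay aligned with the image axes.
#'
#' @param bvecs Matrix with one unit (or zero) 3-vector per row.
#' @param from,to Three-letter orientation codes before and after.
#' @return Matrix of transformed vectors, same shape.
#' @export
reorient_bvecs <- function(bvecs, from, to) {
  bvecs <- as.matrix(bvecs)
  stopifnot(ncol(bvecs) == 3L)
  pf <- .parse_code(from)
  pt <- .parse_code(to)
  out <- matrix(0, nrow(bvecs), 3L)
  for (k in 1:3) {
    j <- which(pf$axis == pt$axis[k])
    s <- if (pf$sign[j] != pt$sign[k]) -1 else 1
    out[, k] <- s * bvecs[, j]
  }
  out
}

# world coordinate of a 0-based voxel index
.voxel_to_world <- function(affine, ijk) {
  as.numeric(affine %*% c(ijk, 1))[1:3]
}
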