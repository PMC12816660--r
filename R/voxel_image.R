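#' 3D voxel image with a voxel-to-world affine
#'
#' Lightweight carrier for binary masks, label volumes and statistical maps.
#' Data are stored as a plain 3D array; `affine` maps 0-based voxel indices
#' (i, j, k, 1) to world coordinates in mm, following the NIfTI convention.
#'
#' @param data 3D numeric or integer array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices); default
#'   identity with 1 mm isotropic voxels.
#' @param space_tag free-text label for the coordinate frame.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(data, affine = diag(4), space_tag = "synthetic") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    stop("affine is not invertible")
  }
  structure(list(data = data, affine = affine, space_tag = space_tag),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d [%s]\n", d[1], d[2], d[3], x$space_tag))
  cat(sprintf("  voxel size: %s mm; nonzero voxels: %d\n",
              paste(signif(voxel_dims(x), 4), collapse = " x "),
              sum(x$data != 0)))
  invisible(x)
}

#' Edge lengths of a voxel in mm
#' @param img a `voxel_image`
#' @return numeric length-3 vector.
#' @export
voxel_dims <- function(img) {
  sqrt(colSums(img$affine[1:3, 1:3]^2))
}

#' Voxel volume in mm^3
#' @param img a `voxel_image`
#' @return scalar volume of one voxel.
#' @export
voxel_volume <- function(img) abs(det(img$affine[1:3, 1:3]))

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}

#' Map world coordinates (mm) to 1-based voxel indices
#'
#' @param img a `voxel_image`
#' @param xyz n x 3 matrix of world coordinates.
#' @param round round to nearest voxel (default TRUE).
#' @return n x 3 matrix of voxel indices (1-based; may fall outside the grid).
#' @export
world_to_voxel <- function(img, xyz, round = TRUE) {
  xyz <- matrix(xyz, ncol = 3L)
  inv <- solve(img$affine)
  v <- cbind(xyz, 1) %*% t(inv)
  v <- v[, 1:3, drop = FALSE] + 1  # 0-based -> 1-based
  if (round) v <- round(v)
  v
}

#' Map 1-based voxel indices to world coordinates (mm)
#' @param img a `voxel_image`
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates.
#' @export
voxel_to_world <- function(img, ijk) {
  ijk <- matrix(ijk, ncol = 3L)
  w <- cbind(ijk - 1, 1) %*% t(img$affine)
  w[, 1:3, drop = FALSE]
}

in_grid <- function(ijk, dims) {
  ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
  ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
  ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
}

#' Read a NIfTI volume as a voxel_image
#' @param path NIfTI file (.nii or .nii.gz).
#' @param space_tag coordinate-frame label to attach.
#' @return a `voxel_image`.
#' @export
read_volume <- function(path, space_tag = "file") {
  nii <- RNifti::readNifti(path)
  aff <- RNifti::xform(nii)
  arr <- as.array(nii)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  voxel_image(arr, affine = structure(aff, class = NULL), space_tag = space_tag)
}

#' Write a voxel_image to NIfTI-1
#'
#' Binary masks should be passed with integer data (written as-is); maps are
#' written as floating point.
#' @param img a `voxel_image`
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  nii <- RNifti::asNifti(img$data)
  RNifti::sform(nii) <- structure(img$affine, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Connected-component labelling of a binary mask (26-connectivity)
#'
#' @param mask a `voxel_image` with values in {0, 1} (or a 3D array).
#' @return integer array of the same shape; 0 = background, clusters labelled
#'   1..k in decreasing order of size.
#' @export
label_clusters <- function(mask) {
  arr <- if (inherits(mask, "voxel_image")) mask$data else mask
  dims <- dim(arr)
  lab <- array(0L, dims)
  idx <- which(arr != 0)
  if (length(idx) == 0L) return(lab)
  # 26-neighbourhood offsets in linear index space
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  coord <- arrayInd(idx, dims)
  inmask <- array(FALSE, dims); inmask[idx] <- TRUE
  visited <- array(FALSE, dims)
  comp_id <- 0L
  comps <- list()
  for (s in seq_along(idx)) {
    if (visited[idx[s]]) next
    comp_id <- comp_id + 1L
    queue <- idx[s]; visited[idx[s]] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      members <- c(members, cur)
      cc <- arrayInd(cur, dims)
      for (r in seq_len(nrow(off))) {
        nb <- cc + matrix(off[r, ], nrow(cc), 3, byrow = TRUE)
        ok <- in_grid(nb, dims)
        if (!any(ok)) next
        nb <- nb[ok, , drop = FALSE]
        lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * dims[1] * dims[2]
        keep <- inmask[lin] & !visited[lin]
        if (any(keep)) {
          lin <- lin[keep]
          visited[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    comps[[comp_id]] <- members
  }
  ord <- order(vapply(comps, length, 1L), decreasing = TRUE)
  for (k in seq_along(ord)) lab[comps[[ord[k]]]] <- k
  lab
}

#' Overlap statistics between two binary masks
#'
#' Dice coefficient and the two directed overlap fractions, on a shared grid.
#' An empty mask yields Dice 0 with a warning.
#'
#' @param mask_a,mask_b `voxel_image` binary masks (or 3D arrays) on one grid.
#' @return list with `dice`, `frac_a_in_b`, `frac_b_in_a`, and voxel counts.
#' @export
convergence_overlap <- function(mask_a, mask_b) {
  a <- if (inherits(mask_a, "voxel_image")) mask_a$data else mask_a
  b <- if (inherits(mask_b, "voxel_image")) mask_b$data else mask_b
  if (!identical(dim(a), dim(b))) stop("masks are not on a shared grid")
  a <- a != 0; b <- b != 0
  na <- sum(a); nb <- sum(b); nab <- sum(a & b)
  if (na == 0L || nb == 0L) {
    warning("empty mask; Dice defined as 0")
    return(list(dice = 0, frac_a_in_b = if (na) 0 else NA_real_,
                frac_b_in_a = if (nb) 0 else NA_real_,
                n_a = na, n_b = nb, n_intersect = nab))
  }
  list(dice = 2 * nab / (na + nb),
       frac_a_in_b = nab / na,
       frac_b_in_a = nab / nb,
       n_a = na, n_b = nb, n_intersect = nab)
}
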