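#' Weighted streamline set
#'
#' Polylines in world coordinates (mm) with per-streamline SIFT2-style
#' weights and the subject-level proportionality coefficient `mu` that
#' converts summed weights into an absolute cross-sectional area (mm^2).
#'
#' @param streamlines list of k x 3 numeric matrices (k >= 2 points each).
#' @param weights non-negative per-streamline weights (default all 1).
#' @param mu positive proportionality coefficient (default 1).
#' @param subject_id identifier.
#' @return object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, weights = NULL, mu = 1,
                           subject_id = "subject") {
  if (is.null(weights)) weights <- rep(1, length(streamlines))
  if (length(weights) != length(streamlines))
    stop("one weight per streamline required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (mu <= 0) stop("mu must be positive")
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L)
      stop("each streamline must be a k x 3 matrix with k >= 2")
  }
  structure(list(streamlines = streamlines, weights = as.numeric(weights),
                 mu = mu, subject_id = subject_id),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set> %s: %d streamlines, total weight %.3f, mu = %.4g\n",
              x$subject_id, length(x$streamlines), sum(x$weights), x$mu))
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Write streamlines to an MRtrix TCK file
#'
#' Text header terminated by `END`, then little-endian float32 (x,y,z)
#' triplets; streamlines separated by a NaN triplet, file terminated by an
#' Inf triplet.
#' @param set a `streamline_set`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_tck <- function(set, path) {
  n <- length(set$streamlines)
  header <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n, "\n")
  # file_offset placeholder: header length is computed after fixing the field
  probe <- paste0(header, "file: . 000000\nEND\n")
  offset <- nchar(probe, type = "bytes")
  header <- paste0(header, sprintf("file: . %6d", offset), "\nEND\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (s in set$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRtrix TCK file
#' @param path TCK file.
#' @param weights optional numeric vector or path to a one-weight-per-line
#'   text file.
#' @param mu proportionality coefficient (scalar, or path to a JSON sidecar
#'   with field `mu`).
#' @param subject_id identifier.
#' @return a `streamline_set`.
#' @export
read_tck <- function(path, weights = NULL, mu = 1, subject_id = "subject") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^mrtrix tracks", magic)) stop("not a TCK file: ", path)
  datatype <- "Float32LE"; offset <- NA_integer_
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unterminated TCK header")
    if (trimws(line) == "END") break
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "datatype") datatype <- val
    if (key == "file") offset <- as.integer(sub("^\\.\\s*", "", val))
  }
  if (datatype != "Float32LE") stop("unsupported TCK datatype: ", datatype)
  seek(con, where = offset, origin = "start")
  raw <- readBin(con, what = numeric(), size = 4, endian = "little", n = 3e7)
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  streamlines <- list()
  start <- 1L
  for (i in seq_len(nrow(m))) {
    if (any(is.nan(m[i, ])) || any(is.infinite(m[i, ]))) {
      if (i > start) streamlines[[length(streamlines) + 1L]] <-
          m[start:(i - 1L), , drop = FALSE]
      start <- i + 1L
      if (any(is.infinite(m[i, ]))) break
    }
  }
  if (is.character(weights)) weights <- scan(weights, quiet = TRUE)
  if (is.character(mu)) mu <- jsonlite::read_json(mu)$mu
  streamline_set(streamlines, weights = weights, mu = mu,
                 subject_id = subject_id)
}

# supersample a polyline at uniform steps along every segment (vectorized)
supersample_polyline <- function(points, step) {
  np <- nrow(points)
  a <- points[-np, , drop = FALSE]
  d <- points[-1L, , drop = FALSE] - a
  len <- sqrt(rowSums(d^2))
  nsub <- pmax(1L, ceiling(len / step))
  seg <- rep.int(seq_len(np - 1L), nsub)
  tfrac <- unlist(lapply(nsub, function(k) (seq_len(k) - 1L) / k),
                  use.names = FALSE)
  rbind(a[seg, , drop = FALSE] + d[seg, , drop = FALSE] * tfrac,
        points[np, , drop = FALSE])
}

# voxels traversed by one streamline (unique 1-based ijk rows).
# mode "points": nearest voxel of each vertex. mode "segment": vertices plus
# supersampled points along each segment at quarter-voxel steps, catching
# crossings between coarsely spaced vertices.
traversed_voxels <- function(points, img, mode = c("points", "segment")) {
  mode <- match.arg(mode)
  if (mode == "segment")
    points <- supersample_polyline(points, min(voxel_dims(img)) / 4)
  ijk <- world_to_voxel(img, points)
  ijk <- ijk[in_grid(ijk, dim(img$data)), , drop = FALSE]
  unique(ijk)
}

streamline_hits_roi <- function(points, roi, mode) {
  v <- traversed_voxels(points, roi, mode)
  if (nrow(v) == 0L) return(FALSE)
  lin <- v[, 1] + (v[, 2] - 1) * dim(roi$data)[1] +
    (v[, 3] - 1) * dim(roi$data)[1] * dim(roi$data)[2]
  any(roi$data[lin] != 0)
}

# vectorised ROI-hit test over a whole set: one affine transform for the
# pooled (supersampled) points of all streamlines
set_hits_roi <- function(set, roi, mode) {
  ns <- length(set$streamlines)
  if (ns == 0L) return(logical(0))
  pts <- set$streamlines
  if (mode == "segment") {
    step <- min(voxel_dims(roi)) / 4
    pts <- lapply(pts, supersample_polyline, step = step)
  }
  counts <- vapply(pts, nrow, 1L)
  all_pts <- do.call(rbind, pts)
  id <- rep.int(seq_len(ns), counts)
  ijk <- world_to_voxel(roi, all_pts)
  dims <- dim(roi$data)
  ok <- in_grid(ijk, dims)
  if (!any(ok)) return(rep(FALSE, ns))
  lin <- ijk[ok, 1] + (ijk[ok, 2] - 1) * dims[1] +
    (ijk[ok, 3] - 1) * dims[1] * dims[2]
  hit_pts <- roi$data[lin] != 0
  out <- rep(FALSE, ns)
  if (any(hit_pts)) out[unique(id[ok][hit_pts])] <- TRUE
  out
}

#' Keep streamlines traversing a region of interest
#'
#' A streamline is retained when at least one of its (optionally
#' supersampled) points maps into a nonzero ROI voxel. Weights and `mu` are
#' preserved.
#'
#' @param set a `streamline_set`.
#' @param roi binary `voxel_image`.
#' @param mode `"points"` tests the polyline vertices only (suits densely
#'   sampled streamlines); `"segment"` also samples along segments so coarse
#'   polylines crossing a voxel between vertices are caught.
#' @return filtered `streamline_set`.
#' @export
filter_by_roi <- function(set, roi, mode = c("points", "segment")) {
  mode <- match.arg(mode)
  if (all(roi$data == 0)) {
    warning("empty ROI: no streamlines retained")
    return(streamline_set(list(), numeric(0), set$mu, set$subject_id))
  }
  keep <- set_hits_roi(set, roi, mode)
  out <- set
  out$streamlines <- set$streamlines[keep]
  out$weights <- set$weights[keep]
  out
}

#' Track-density image from a weighted streamline set
#'
#' Every voxel a streamline traverses (counted once per streamline) receives
#' that streamline's `weight * mu`; the raw density is then z-scored across
#' in-mask voxels (nonzero voxels by default).
#'
#' @param set a `streamline_set`.
#' @param grid `voxel_image` defining the output grid (data ignored).
#' @param mode traversal mode, see [filter_by_roi()] (default `"segment"`).
#' @return list of class `tdi_map` with `density` and `z` (`voxel_image`s),
#'   and `core_mask` (z > 2).
#' @export
tdi <- function(set, grid, mode = "segment") {
  dims <- dim(grid$data)
  dens <- array(0, dims)
  clipped <- 0L
  for (i in seq_along(set$streamlines)) {
    v <- traversed_voxels(set$streamlines[[i]], grid, mode)
    npts <- nrow(traversed_voxels(set$streamlines[[i]], grid, "points"))
    if (nrow(v) == 0L) { clipped <- clipped + 1L; next }
    lin <- v[, 1] + (v[, 2] - 1) * dims[1] + (v[, 3] - 1) * dims[1] * dims[2]
    dens[lin] <- dens[lin] + set$weights[i] * set$mu
  }
  inmask <- dens > 0
  z <- array(NA_real_, dims)
  if (sum(inmask) > 1L && stats::sd(dens[inmask]) > 0) {
    z[inmask] <- (dens[inmask] - mean(dens[inmask])) / stats::sd(dens[inmask])
  } else if (sum(inmask) >= 1L) {
    z[inmask] <- 0
  }
  core <- array(0L, dims)
  core[!is.na(z) & z > 2] <- 1L
  structure(list(density = voxel_image(dens, grid$affine, grid$space_tag),
                 z = voxel_image(z, grid$affine, grid$space_tag),
                 core_mask = voxel_image(core, grid$affine, grid$space_tag),
                 n_clipped = clipped),
            class = "tdi_map")
}

#' Population-average TDI map
#'
#' Voxelwise mean of subject z-maps (NA outside each subject's support is
#' treated as missing); core mask at mean z > 2.
#' @param tdis list of `tdi_map`s on one grid.
#' @return list with `mean_z` (`voxel_image`) and `core_mask`.
#' @export
tdi_population <- function(tdis) {
  zs <- lapply(tdis, function(t) t$z$data)
  grid <- tdis[[1]]$z
  stack <- simplify2array(zs)
  mz <- apply(stack, 1:3, function(v) if (all(is.na(v))) NA_real_
              else mean(v, na.rm = TRUE))
  core <- array(0L, dim(mz)); core[!is.na(mz) & mz > 2] <- 1L
  list(mean_z = voxel_image(mz, grid$affine, grid$space_tag),
       core_mask = voxel_image(core, grid$affine, grid$space_tag))
}
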