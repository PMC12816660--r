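#' Eloquence rule for a stimulation site
#'
#' A site is eloquent when a missed target occurred in at least three
#' stimulated trials, no two of which are adjacent in the stimulated-trial
#' sequence (the strict "non-consecutive" reading). The alternative reading
#' — merely requiring that the qualifying trials are not all consecutive —
#' is available via `rule = "not_all_consecutive"`.
#'
#' @param stimulated logical vector over trials, in presentation order.
#' @param omitted logical vector: did the trial contain an omission.
#' @param rule `"strict"` (default) or `"not_all_consecutive"`.
#' @return logical; fewer than 3 stimulated trials returns FALSE with a
#'   warning.
#' @export
eloquence_rule <- function(stimulated, omitted,
                           rule = c("strict", "not_all_consecutive")) {
  rule <- match.arg(rule)
  stopifnot(length(stimulated) == length(omitted))
  stim_idx <- which(stimulated)
  if (length(stim_idx) < 3L) {
    warning("fewer than 3 stimulated trials")
    return(FALSE)
  }
  # positions of error trials within the stimulated-trial sequence
  err_pos <- which(omitted[stim_idx])
  if (length(err_pos) < 3L) return(FALSE)
  if (rule == "strict") {
    # all error trials pairwise non-adjacent in the stimulated sequence
    no_two_adjacent(err_pos)
  } else {
    # merely not all in one consecutive run
    !all(diff(err_pos) == 1L)
  }
}

no_two_adjacent <- function(pos) all(diff(sort(pos)) > 1L)

#' Lateralisation index of a stimulation site
#'
#' The iVSAT presents 10 letters with two 'H' targets; a missed target at
#' position 1 is an error at the far left, position 10 far right. The index
#' is the mean omitted position over all trials of the site; the site is
#' neglect-like when all omissions fall in the left half (positions 1-5)
#' under the strict rule, or when the majority do under `rule = "majority"`.
#'
#' @param omitted_positions integer vector of omitted target positions
#'   (1-10) pooled over the site's trials.
#' @param rule `"all"` (default) or `"majority"`.
#' @return list with `index` (mean position) and `neglect_like`.
#' @export
lateralisation <- function(omitted_positions, rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (length(omitted_positions) == 0L)
    stop("lateralisation undefined without omissions")
  if (any(omitted_positions < 1 | omitted_positions > 10))
    stop("positions must be in 1..10")
  idx <- mean(omitted_positions)
  left <- omitted_positions <= 5
  nl <- if (rule == "all") all(left) else mean(left) > 0.5
  list(index = idx, neglect_like = nl)
}

#' 3D Gaussian kernel density map of stimulation sites
#'
#' Isotropic Gaussian kernel density over the site world coordinates,
#' evaluated on a voxel grid. The raw density integrates to 1 (up to
#' quadrature error on a grid extending several bandwidths beyond the
#' sites); a normalized-to-max variant and a threshold mask at a fraction of
#' the maximum are included.
#'
#' @param sites n x 3 matrix of world coordinates (mm), n >= 2.
#' @param grid `voxel_image` defining the evaluation grid.
#' @param bandwidth kernel standard deviation in mm (default 5, matching a
#'   5 mm stimulation-site sphere).
#' @param threshold fraction of the maximum for the mask (default 0.5).
#' @return object of class `pde_map`: `density`, `normalized`, `mask`
#'   (`voxel_image`s), `bandwidth`.
#' @export
pde <- function(sites, grid, bandwidth = 5, threshold = 0.5) {
  sites <- matrix(sites, ncol = 3L)
  if (nrow(sites) < 2L) stop("need at least 2 sites")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  dims <- dim(grid$data)
  # world coordinates of all voxel centres, separable by axis only for
  # axis-aligned affines; general case evaluated directly
  ijk <- arrayInd(seq_len(prod(dims)), dims)
  xyz <- voxel_to_world(grid, ijk)
  dens <- numeric(nrow(xyz))
  norm_const <- (2 * pi)^(-3 / 2) / bandwidth^3
  for (s in seq_len(nrow(sites))) {
    d2 <- (xyz[, 1] - sites[s, 1])^2 + (xyz[, 2] - sites[s, 2])^2 +
      (xyz[, 3] - sites[s, 3])^2
    dens <- dens + exp(-d2 / (2 * bandwidth^2))
  }
  dens <- dens * norm_const / nrow(sites)
  arr <- array(dens, dims)
  mx <- max(arr)
  normed <- arr / mx
  mask <- array(0L, dims); mask[normed >= threshold] <- 1L
  structure(list(density = voxel_image(arr, grid$affine, grid$space_tag),
                 normalized = voxel_image(normed, grid$affine, grid$space_tag),
                 mask = voxel_image(mask, grid$affine, grid$space_tag),
                 bandwidth = bandwidth, threshold = threshold,
                 n_sites = nrow(sites)),
            class = "pde_map")
}

#' @export
print.pde_map <- function(x, ...) {
  cat(sprintf("<pde_map> %d sites, bandwidth %.1f mm; mask %d voxels at >= %.0f%% of max\n",
              x$n_sites, x$bandwidth, sum(x$mask$data), 100 * x$threshold))
  invisible(x)
}

#' Hemifield summary of omission errors by site group
#'
#' Omissions at positions 1-5 are left-hemifield, 6-10 right-hemifield.
#' Returns per-group percentages plus a totals row.
#'
#' @param positions integer vector of omitted positions (1-10).
#' @param group grouping labels (e.g. gyrus under the stimulation site).
#' @return data frame with `group`, `n`, `pct_left`, `pct_right`.
#' @export
hemifield_error_summary <- function(positions, group) {
  stopifnot(length(positions) == length(group))
  keep <- !is.na(positions)
  positions <- positions[keep]; group <- group[keep]
  left <- positions <= 5
  gs <- unique(group)
  rows <- lapply(gs, function(g) {
    sel <- group == g
    data.frame(group = g, n = sum(sel),
               pct_left = 100 * mean(left[sel]),
               pct_right = 100 * mean(!left[sel]))
  })
  tot <- data.frame(group = "total", n = length(positions),
                    pct_left = 100 * mean(left),
                    pct_right = 100 * mean(!left))
  rbind(do.call(rbind, rows), tot)
}

#' Read stimulation sites and trials from CSV
#'
#' @param sites_path CSV: site_id, x, y, z, hemisphere, gyrus_label,
#'   error_type.
#' @param trials_path CSV long format: site_id, trial_idx, stimulated,
#'   omitted_positions (semicolon-separated, empty = none).
#' @return list with `sites` data frame and `trials` data frame (positions
#'   parsed into list-column `positions`).
#' @export
read_stim_sites <- function(sites_path, trials_path) {
  sites <- utils::read.csv(sites_path, stringsAsFactors = FALSE)
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE,
                            colClasses = c(omitted_positions = "character"))
  trials$positions <- lapply(trials$omitted_positions, function(s) {
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  list(sites = sites, trials = trials)
}

#' Classify all sites of a stimulation record
#'
#' Applies the eloquence rule and lateralisation scoring per site.
#' @param record list from [read_stim_sites()] (or equivalent in-memory
#'   structure).
#' @param rule eloquence rule variant.
#' @param lat_rule neglect-like rule variant.
#' @return `sites` data frame with `eloquent`, `lateralisation_index`,
#'   `neglect_like` columns appended.
#' @export
classify_stim_sites <- function(record, rule = "strict", lat_rule = "all") {
  sites <- record$sites
  trials <- record$trials
  sites$eloquent <- NA
  sites$lateralisation_index <- NA_real_
  sites$neglect_like <- NA
  for (i in seq_len(nrow(sites))) {
    tr <- trials[trials$site_id == sites$site_id[i], ]
    tr <- tr[order(tr$trial_idx), ]
    omitted <- vapply(tr$positions, function(p) length(p) > 0, logical(1))
    sites$eloquent[i] <- suppressWarnings(
      eloquence_rule(as.logical(tr$stimulated), omitted, rule = rule))
    pos <- unlist(tr$positions[as.logical(tr$stimulated)])
    if (length(pos)) {
      lat <- lateralisation(pos, rule = lat_rule)
      sites$lateralisation_index[i] <- lat$index
      sites$neglect_like[i] <- lat$neglect_like
    }
  }
  sites
}
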