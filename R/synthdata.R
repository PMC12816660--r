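#' Specification of the synthetic study conditions
#'
#' Default parameters define the cohort conditions under which the pipeline
#' is exercised and validated: a lesion cohort with a planted deficit-critical
#' region, a connectome cohort with planted hubs and top edges, resection
#' scenarios with a planted edge-deficit link, and clustered stimulation
#' sites with position-coded omission errors. All randomness is driven by the
#' single `seed`.
#'
#' @param seed integer master seed.
#' @param lesion,connectome,stim,resection per-stage parameter lists; any
#'   element supplied overrides the default.
#' @return nested list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 7L, lesion = list(), connectome = list(),
                       stim = list(), resection = list()) {
  merge_defaults <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  structure(list(
    seed = as.integer(seed),
    lesion = merge_defaults(list(
      grid_shape = c(16L, 16L, 16L),
      n_subjects = 60L,
      blob_radius_range = c(2, 5),        # ellipsoid semi-axes, voxels
      planted_centre = c(8, 8, 8),
      planted_radius = 2.2,               # ~40-voxel critical region
      effect_size = 1.5,                  # in units of the noise sd
      noise_sd = 1.0,
      covariate_coefficients = c(age = 0.02, education = -0.03, grade = 0.3)),
      lesion),
    connectome = merge_defaults(list(
      n_subjects = 20L,
      n_nodes = 60L,
      n_hubs = 5L,
      edges_per_hub = 2L,                 # planted top edges per hub
      base_edge_prob = 0.15,
      base_weight = 1,
      hub_weight = 3,
      top_edge_multiplier = 10,
      noise_fraction = 0.2,
      streamlines_per_edge = 3L,
      world_shape = c(32L, 32L, 32L),
      mu_range = c(0.8, 1.2)),
      connectome),
    stim = merge_defaults(list(
      centroids = rbind(c(12, 16, 14)),
      spread = 3,                          # mm, site scatter around centroid
      n_sites = 40L,
      left_bias = 0.93,
      trials_per_site = 8L,
      omissions_per_site = 8L,
      prop_eloquent = 0.7,
      world_shape = c(32L, 32L, 32L)),
      stim),
    resection = merge_defaults(list(
      n_patients = 15L,
      n_critical_edges = 3L,
      noise_sd = 0.2,
      deficit_scale = 3,
      severity_range = c(0.1, 1))
      , resection)),
    class = "synth_spec")
}

sphere_mask <- function(dims, centre, radius) {
  ijk <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- (ijk[, 1] - centre[1])^2 + (ijk[, 2] - centre[2])^2 +
    (ijk[, 3] - centre[3])^2
  array(as.integer(d2 <= radius^2), dims)
}

ellipsoid_mask <- function(dims, centre, semi_axes) {
  ijk <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- ((ijk[, 1] - centre[1]) / semi_axes[1])^2 +
    ((ijk[, 2] - centre[2]) / semi_axes[2])^2 +
    ((ijk[, 3] - centre[3]) / semi_axes[3])^2
  array(as.integer(d2 <= 1), dims)
}

#' Generate a synthetic lesion cohort with a planted critical region
#'
#' Each subject receives a random ellipsoidal resection blob; the change in
#' the asymmetry score is `effect_size * (overlap fraction with the planted
#' region)` plus covariate terms plus Gaussian noise (the effect size is in
#' units of the noise sd). The change in total score adds an independent
#' bilateral component. Bells pre/post omission counts are constructed to be
#' consistent with the (integer-rounded) deltas and the test's invariants.
#'
#' @param spec a [synth_spec()].
#' @return list of class `lesion_cohort`: `masks` (list of `voxel_image`),
#'   `behaviour` (behaviour table), `planted_mask`, `overlap` (per-subject
#'   overlap fraction with the planted region).
#' @export
make_lesion_cohort <- function(spec = synth_spec()) {
  p <- spec$lesion
  dims <- p$grid_shape
  if (any(p$planted_centre < 1 | p$planted_centre > dims))
    stop("planted region outside grid")
  rng_state <- local_rng(spec$seed)
  on.exit(restore_rng(rng_state), add = TRUE)
  planted <- sphere_mask(dims, p$planted_centre, p$planted_radius)
  n <- p$n_subjects
  masks <- vector("list", n)
  overlap <- numeric(n)
  # blob centres concentrated around the grid interior so the planted region
  # is lesioned with varying fractions across the cohort
  for (s in seq_len(n)) {
    centre <- pmin(pmax(round(stats::rnorm(3, mean = dims / 2, sd = dims / 5)),
                        2), dims - 1)
    semi <- stats::runif(3, p$blob_radius_range[1], p$blob_radius_range[2])
    blob <- ellipsoid_mask(dims, centre, semi)
    masks[[s]] <- voxel_image(blob)
    overlap[s] <- sum(blob & planted) / sum(planted)
  }
  age <- round(stats::rnorm(n, 45, 13))
  education <- round(stats::rnorm(n, 12, 3.5))
  grade <- sample(2:4, n, replace = TRUE)
  cov_part <- p$covariate_coefficients["age"] * (age - mean(age)) +
    p$covariate_coefficients["education"] * (education - mean(education)) +
    p$covariate_coefficients["grade"] * (grade - mean(grade))
  noise <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else numeric(n)
  # the planted component is scaled so its cohort sd equals
  # effect_size * noise_sd: "effect 1.5 SD" is the standardized magnitude of
  # the planted deficit, not a raw regression coefficient on the overlap
  sd_unit <- if (p$noise_sd > 0) p$noise_sd else 1
  ov_scale <- if (stats::sd(overlap) > 0) stats::sd(overlap) else 1
  delta_asym <- p$effect_size * sd_unit * overlap / ov_scale +
    cov_part + noise
  bilateral <- pmax(0, stats::rpois(n, 1))
  da_int <- round(delta_asym)
  pre_left <- stats::rpois(n, 0.8)
  pre_right <- stats::rpois(n, 0.8)
  dR <- bilateral
  dL <- da_int + dR
  post_left <- pmin(pmax(pre_left + dL, 0L), 17L)
  post_right <- pmin(pmax(pre_right + dR, 0L), 17L)
  behaviour <- behaviour_table(data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    hemisphere = "right",
    pre_left = pre_left, pre_right = pre_right,
    post_left = post_left, post_right = post_right,
    age = age, education = education, grade = grade,
    resection_volume_mm3 = vapply(masks, function(m) sum(m$data), 0) *
      voxel_volume(masks[[1]])))
  # delta actually used downstream carries the continuous planted signal
  behaviour$delta_asymmetry_cont <- delta_asym
  structure(list(masks = masks, behaviour = behaviour,
                 planted_mask = voxel_image(planted),
                 overlap = overlap, spec = spec),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("<lesion_cohort> %d subjects on a %s grid; planted region %d voxels\n",
              length(x$masks), paste(dim(x$masks[[1]]$data), collapse = "x"),
              sum(x$planted_mask$data)))
  invisible(x)
}

# deterministic lattice placement of node centroids inside the world grid
node_lattice <- function(n_nodes, world_shape) {
  k <- ceiling(n_nodes^(1 / 3))
  sp <- world_shape / (k + 1)
  g <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k)))
  centres <- sweep(g, 2, sp, "*")
  centres[seq_len(n_nodes), , drop = FALSE]
}

# per-edge deterministic corridor offset at the midpoint, perpendicular-ish
edge_offset <- function(i, j, magnitude = 2.5) {
  h <- (as.numeric(i) * 73856093 + as.numeric(j) * 19349663) %% 1000
  ang1 <- 2 * pi * (h %% 100) / 100
  ang2 <- pi * ((h %/% 100) %% 10) / 10
  magnitude * c(cos(ang1) * sin(ang2), sin(ang1) * sin(ang2), cos(ang2))
}

make_edge_streamlines <- function(a, b, i, j, n_stream, weight_each, jitter_sd,
                                  control = NULL) {
  mid <- if (is.null(control)) (a + b) / 2 + edge_offset(i, j) else control
  lapply(seq_len(n_stream), function(s) {
    jit <- stats::rnorm(3, 0, jitter_sd)
    m <- mid + jit
    t <- seq(0, 1, length.out = 9)
    # quadratic Bezier through the displaced midpoint
    pts <- outer((1 - t)^2, a) + outer(2 * t * (1 - t), m) + outer(t^2, b)
    pts
  })
}

#' Generate a synthetic connectome cohort with planted hubs and top edges
#'
#' Node centroids sit on a lattice; streamlines are arced polylines between
#' node pairs with per-streamline weights. Planted hub nodes connect to every
#' other node with heavier edges; each hub additionally owns
#' `edges_per_hub` planted top edges whose weight is multiplied by
#' `top_edge_multiplier`. Weights are jittered by `noise_fraction`; `mu` is
#' drawn per subject.
#'
#' @param spec a [synth_spec()].
#' @return list of class `connectome_cohort`: `sets` (list of
#'   `streamline_set`), `atlas` (`node_atlas`), `planted_hubs`,
#'   `planted_edges` (data frame hub/partner), `edge_list`.
#' @export
make_connectome_cohort <- function(spec = synth_spec()) {
  p <- spec$connectome
  rng_state <- local_rng(spec$seed + 1L)
  on.exit(restore_rng(rng_state), add = TRUE)
  centres <- node_lattice(p$n_nodes, p$world_shape)
  nn <- p$n_nodes
  hemi <- ifelse(centres[, 1] <= p$world_shape[1] / 2, "left", "right")
  cls <- ifelse(seq_len(nn) %% 10 == 0, "subcortical", "cortical")
  node_table <- data.frame(label = seq_len(nn),
                           name = sprintf("N%02d", seq_len(nn)),
                           class = cls, hemisphere = hemi,
                           stringsAsFactors = FALSE)
  lab_arr <- array(0L, p$world_shape)
  idx <- round(centres)
  for (i in seq_len(nn)) lab_arr[idx[i, 1], idx[i, 2], idx[i, 3]] <- i
  atlas <- node_atlas(voxel_image(lab_arr), node_table)
  # lattice voxel centres: world coord of voxel (i,j,k) is (i-1,j-1,k-1);
  # place streamline endpoints exactly at the labelled voxel centres
  endpts <- idx - 1
  hubs <- seq_len(p$n_hubs) * max(1L, floor(nn / (p$n_hubs + 1)))
  # fixed base topology shared by all subjects: a circulant (ring-lattice)
  # graph, so no non-hub node is structurally central by accident and a
  # cohort without planted hubs carries no consensus hubs
  k_side <- max(1L, round(p$base_edge_prob * (nn - 1) / 2))
  ring <- do.call(rbind, lapply(seq_len(nn), function(i) {
    j <- ((i + seq_len(k_side) - 1L) %% nn) + 1L
    cbind(pmin(i, j), pmax(i, j))
  }))
  ring <- unique(ring)
  hub_pairs <- do.call(rbind, lapply(hubs, function(h) {
    others <- setdiff(seq_len(nn), h)
    cbind(pmin(h, others), pmax(h, others))
  }))
  if (is.null(hub_pairs)) hub_pairs <- matrix(integer(0), 0, 2)
  hub_key <- paste(hub_pairs[, 1], hub_pairs[, 2])
  ring <- ring[!(paste(ring[, 1], ring[, 2]) %in% hub_key), , drop = FALSE]
  edges <- rbind(ring, hub_pairs)
  colnames(edges) <- c("row", "col")
  w0 <- ifelse(edges[, 1] %in% hubs | edges[, 2] %in% hubs,
               p$hub_weight, p$base_weight)
  planted <- do.call(rbind, lapply(seq_along(hubs), function(h) {
    partners <- setdiff(seq_len(nn), hubs)
    pick <- partners[(h - 1) * p$edges_per_hub + seq_len(p$edges_per_hub)]
    cbind(hub = rep(hubs[h], p$edges_per_hub), partner = pick)
  }))
  if (is.null(planted))
    planted <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("hub", "partner")))
  for (r in seq_len(nrow(planted))) {
    i <- min(planted[r, ]); j <- max(planted[r, ])
    row <- which(edges[, 1] == i & edges[, 2] == j)
    if (length(row) == 0L) {
      edges <- rbind(edges, c(i, j))
      w0 <- c(w0, p$hub_weight)
      row <- length(w0)
    }
    w0[row] <- w0[row] * p$top_edge_multiplier
  }
  sets <- vector("list", p$n_subjects)
  for (s in seq_len(p$n_subjects)) {
    mu <- stats::runif(1, p$mu_range[1], p$mu_range[2])
    streamlines <- list(); weights <- numeric(0)
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      sl <- make_edge_streamlines(endpts[i, ], endpts[j, ], i, j,
                                  p$streamlines_per_edge,
                                  jitter_sd = 0.6,
                                  weight_each = NULL)
      wj <- (w0[e] / p$streamlines_per_edge) *
        (1 + stats::rnorm(p$streamlines_per_edge, 0, p$noise_fraction))
      wj <- pmax(wj, 0.01)
      streamlines <- c(streamlines, sl)
      weights <- c(weights, wj / mu)  # so that FBC = mu * sum(w) ~ w0
    }
    sets[[s]] <- streamline_set(streamlines, weights, mu = mu,
                                subject_id = sprintf("HC%02d", s))
  }
  structure(list(sets = sets, atlas = atlas,
                 planted_hubs = node_table$name[hubs],
                 planted_edges = data.frame(
                   hub = node_table$name[planted[, "hub"]],
                   partner = node_table$name[planted[, "partner"]],
                   stringsAsFactors = FALSE),
                 edge_list = edges, edge_weights = w0,
                 node_centres = endpts, spec = spec),
            class = "connectome_cohort")
}

#' @export
print.connectome_cohort <- function(x, ...) {
  cat(sprintf("<connectome_cohort> %d subjects, %d nodes, %d planted hubs, %d planted edges\n",
              length(x$sets), nrow(x$atlas$node_table),
              length(x$planted_hubs), nrow(x$planted_edges)))
  invisible(x)
}

#' Generate synthetic stimulation sites and trial logs
#'
#' Site coordinates are drawn from a Gaussian mixture at the configured
#' centroids; omission positions are drawn left (1-5) with probability
#' `left_bias`, otherwise right (6-10). Sites are eloquent (errors in at
#' least three pairwise non-adjacent stimulated trials) in proportion
#' `prop_eloquent`, with the remaining sites violating the rule.
#'
#' @param spec a [synth_spec()].
#' @return list of class `stim_cohort`: `sites` data frame (site_id, x, y,
#'   z, gyrus_label), `trials` data frame (site_id, trial_idx, stimulated,
#'   positions list-column), `omitted_positions` (pooled integer vector).
#' @export
make_stim_sites <- function(spec = synth_spec()) {
  p <- spec$stim
  rng_state <- local_rng(spec$seed + 2L)
  on.exit(restore_rng(rng_state), add = TRUE)
  nc <- nrow(p$centroids)
  comp <- sample(nc, p$n_sites, replace = TRUE)
  xyz <- p$centroids[comp, , drop = FALSE] +
    matrix(stats::rnorm(3 * p$n_sites, 0, p$spread), ncol = 3)
  draw_pos <- function(k) {
    ifelse(stats::runif(k) < p$left_bias,
           sample(1:5, k, replace = TRUE),
           sample(6:10, k, replace = TRUE))
  }
  sites <- data.frame(site_id = sprintf("site%03d", seq_len(p$n_sites)),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      gyrus_label = sprintf("cluster%d", comp),
                      stringsAsFactors = FALSE)
  trials <- list()
  eloquent_flag <- stats::runif(p$n_sites) < p$prop_eloquent
  for (i in seq_len(p$n_sites)) {
    nt <- p$trials_per_site
    err_trials <- if (eloquent_flag[i]) {
      # three pairwise non-adjacent stimulated trials, e.g. 1, 3, 5
      c(1L, 3L, 5L)
    } else {
      c(1L, 2L)  # two errors only: rule not met
    }
    for (t in seq_len(nt)) {
      npos <- if (t %in% err_trials)
        max(1L, stats::rpois(1, p$omissions_per_site / length(err_trials)))
      else 0L
      trials[[length(trials) + 1L]] <- data.frame(
        site_id = sites$site_id[i], trial_idx = t, stimulated = TRUE,
        omitted_positions = paste(draw_pos(npos), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, trials)
  trials$positions <- lapply(trials$omitted_positions, function(s) {
    if (!nzchar(s)) integer(0) else as.integer(strsplit(s, ";")[[1]])
  })
  structure(list(sites = sites, trials = trials,
                 omitted_positions = unlist(trials$positions),
                 eloquent_flag = eloquent_flag, spec = spec),
            class = "stim_cohort")
}

#' Generate resection scenarios with a planted edge-deficit link
#'
#' For each synthetic patient, a tractogram restricted to the bundles under
#' test is generated (patient-specific tractography reduced to the consensus
#' edges of interest plus distractor hub edges), and a cavity is placed in
#' the corridor of the planted "critical" edges (the first
#' `n_critical_edges` planted top edges) with a graded severity: the cavity
#' radius scales with severity, removing a growing fraction of those edges'
#' streamline weight. The behavioural delta is a monotone function of the
#' realized critical-edge disconnection plus Gaussian noise.
#'
#' @param spec a [synth_spec()].
#' @param cohort optional `connectome_cohort` supplying atlas/geometry and
#'   the planted-edge list; a fresh one is generated from `spec` when
#'   omitted.
#' @param n_distractors distractor hub edges added to the tested set
#'   (default: enough for 39 tested edges in total).
#' @return list of class `resection_cohort`: `scenarios` (list of
#'   subject_id / preop_set / cavity_mask / behaviour_delta), `atlas`,
#'   `critical_edges`, `test_edges` (critical + planted + distractor hub
#'   edges).
#' @export
make_resection_scenarios <- function(spec = synth_spec(), cohort = NULL,
                                     n_distractors = NULL) {
  if (is.null(cohort)) cohort <- make_connectome_cohort(spec)
  p <- spec$resection
  pc <- spec$connectome
  rng_state <- local_rng(spec$seed + 3L)
  on.exit(restore_rng(rng_state), add = TRUE)
  crit <- cohort$planted_edges[seq_len(p$n_critical_edges), , drop = FALSE]
  nodes <- cohort$atlas$node_table
  centres <- cohort$node_centres
  edge_labels <- function(e) {
    c(nodes$label[match(e[["hub"]], nodes$name)],
      nodes$label[match(e[["partner"]], nodes$name)])
  }
  # tested set: planted edges plus distractor hub edges, 39 total by default
  all_planted <- cohort$planted_edges
  if (is.null(n_distractors)) n_distractors <- 39L - nrow(all_planted)
  hubs_lab <- nodes$label[match(cohort$planted_hubs, nodes$name)]
  cand <- cohort$edge_list[cohort$edge_list[, 1] %in% hubs_lab |
                             cohort$edge_list[, 2] %in% hubs_lab, ,
                           drop = FALSE]
  cand_df <- data.frame(hub = nodes$name[cand[, 1]],
                        partner = nodes$name[cand[, 2]],
                        stringsAsFactors = FALSE)
  pkey <- function(d) paste(pmin(d$hub, d$partner), pmax(d$hub, d$partner))
  cand_df <- cand_df[!(pkey(cand_df) %in% pkey(all_planted)), , drop = FALSE]
  pick <- sample(nrow(cand_df), min(n_distractors, nrow(cand_df)))
  test_edges <- rbind(crit, all_planted, cand_df[pick, ])
  test_edges <- test_edges[!duplicated(pkey(test_edges)), , drop = FALSE]
  rownames(test_edges) <- NULL
  # critical bundles are routed through dedicated peripheral corridors so
  # the cavity severs them selectively; the arc passes through half the
  # control-point displacement at mid-course
  world_centre <- pc$world_shape / 2
  crit_geom <- lapply(seq_len(nrow(crit)), function(e) {
    l <- edge_labels(crit[e, ])
    mid0 <- (centres[l[1], ] + centres[l[2], ]) / 2
    outward <- mid0 - world_centre
    if (sqrt(sum(outward^2)) < 1e-6) outward <- c(0, 0, 1)
    outward <- outward / sqrt(sum(outward^2))
    disp <- 5 * outward
    list(labels = l, corridor = mid0 + disp, control = mid0 + 2 * disp)
  })
  crit_mid <- t(vapply(crit_geom, `[[`, numeric(3), "corridor"))
  is_crit <- pkey(test_edges) %in% pkey(crit)
  dims <- pc$world_shape
  scenarios <- vector("list", p$n_patients)
  sev <- stats::runif(p$n_patients, p$severity_range[1], p$severity_range[2])
  for (pt in seq_len(p$n_patients)) {
    streamlines <- list(); weights <- numeric(0); edge_id <- integer(0)
    mu <- stats::runif(1, pc$mu_range[1], pc$mu_range[2])
    for (e in seq_len(nrow(test_edges))) {
      l <- edge_labels(test_edges[e, ])
      ns <- if (is_crit[e]) 8L else 2L
      ctrl <- NULL; jit <- 0.6
      if (is_crit[e]) {
        ctrl <- crit_geom[[match(pkey(test_edges[e, ]), pkey(crit))]]$control
        jit <- 2.4   # wide fan: cavity radius grades the severed fraction
      }
      sl <- make_edge_streamlines(centres[l[1], ], centres[l[2], ],
                                  min(l), max(l), ns, NULL, jitter_sd = jit,
                                  control = ctrl)
      w <- (pc$hub_weight / ns) *
        pmax(1 + stats::rnorm(ns, 0, pc$noise_fraction), 0.01)
      streamlines <- c(streamlines, sl)
      weights <- c(weights, w / mu)
      edge_id <- c(edge_id, rep.int(e, ns))
    }
    pset <- streamline_set(streamlines, weights, mu = mu,
                           subject_id = sprintf("PT%02d", pt))
    cav <- array(FALSE, dims)
    r <- 0.4 + 2.6 * sev[pt]
    for (cmi in seq_len(nrow(crit_mid)))
      cav <- cav | sphere_mask(dims, crit_mid[cmi, ] + 1, r) > 0
    cavity <- voxel_image(array(as.integer(cav), dims))
    # realized severed weight fraction of the critical bundles
    hit <- set_hits_roi(pset, cavity, "segment")
    fr <- mean(vapply(which(is_crit), function(e) {
      sel <- edge_id == e
      sum(weights[sel & hit]) / sum(weights[sel])
    }, 0))
    delta <- p$deficit_scale * fr + stats::rnorm(1, 0, p$noise_sd)
    scenarios[[pt]] <- list(subject_id = pset$subject_id, preop_set = pset,
                            cavity_mask = cavity, behaviour_delta = delta,
                            severity = sev[pt], critical_fraction = fr)
  }
  structure(list(scenarios = scenarios, atlas = cohort$atlas,
                 critical_edges = crit, test_edges = test_edges,
                 severity = sev, spec = spec),
            class = "resection_cohort")
}
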