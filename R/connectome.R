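#' Node atlas: label volume plus node table
#'
#' @param label_volume `voxel_image` of integer labels (0 = background).
#' @param node_table data frame with columns `label`, `name`, and optionally
#'   `class` (e.g. cortical/subcortical) and `hemisphere` (left/right).
#' @return object of class `node_atlas`.
#' @export
node_atlas <- function(label_volume, node_table) {
  labs <- unique(label_volume$data[label_volume$data != 0])
  if (!all(labs %in% node_table$label))
    stop("label volume contains labels missing from the node table")
  structure(list(label_volume = label_volume,
                 node_table = node_table[order(node_table$label), ]),
            class = "node_atlas")
}

#' @export
print.node_atlas <- function(x, ...) {
  cat(sprintf("<node_atlas> %d nodes on a %s grid\n",
              nrow(x$node_table),
              paste(dim(x$label_volume$data), collapse = "x")))
  invisible(x)
}

# nearest labelled voxel within `radius` mm of a world point; 0 if none
assign_endpoint <- function(atlas, xyz, radius = 2) {
  img <- atlas$label_volume
  ijk <- world_to_voxel(img, matrix(xyz, 1))
  dims <- dim(img$data)
  vd <- voxel_dims(img)
  r_vox <- ceiling(radius / vd)
  lo <- pmax(1, ijk - r_vox); hi <- pmin(dims, ijk + r_vox)
  if (any(lo > hi)) return(0L)
  best <- 0L; bestd <- Inf
  for (k in lo[3]:hi[3]) for (j in lo[2]:hi[2]) for (i in lo[1]:hi[1]) {
    l <- img$data[i, j, k]
    if (l == 0) next
    w <- voxel_to_world(img, matrix(c(i, j, k), 1))
    d <- sqrt(sum((w - xyz)^2))
    if (d <= radius && d < bestd) { bestd <- d; best <- as.integer(l) }
  }
  best
}

#' Fibre-bundle-capacity matrix from a weighted streamline set
#'
#' Each streamline is assigned to the node pair of its two endpoints (nearest
#' labelled voxel within `radius` mm); the edge weight is `mu` times the sum
#' of SIFT2-style weights of streamlines joining the pair, an estimate of the
#' bundle's total intra-axonal cross-sectional area (mm^2). Streamlines with
#' an unassignable endpoint, or with both endpoints in one node, are excluded
#' and counted.
#'
#' @param set a `streamline_set`.
#' @param atlas a `node_atlas`.
#' @param radius endpoint search radius in mm (default 2).
#' @return object of class `fbc_matrix`: symmetric `values` matrix (nodes in
#'   node-table order), `node_table`, `subject_id`, `n_unassigned`.
#' @export
build_fbc <- function(set, atlas, radius = 2) {
  labs <- atlas$node_table$label
  nn <- length(labs)
  vals <- matrix(0, nn, nn, dimnames = list(atlas$node_table$name,
                                            atlas$node_table$name))
  ns <- length(set$streamlines)
  if (ns > 0L) {
    img <- atlas$label_volume
    dims <- dim(img$data)
    ends <- do.call(rbind, lapply(set$streamlines,
                                  function(s) s[c(1L, nrow(s)), ]))
    ijk <- world_to_voxel(img, ends)
    lab <- integer(nrow(ijk))
    ok <- in_grid(ijk, dims)
    lin <- ijk[ok, 1] + (ijk[ok, 2] - 1) * dims[1] +
      (ijk[ok, 3] - 1) * dims[1] * dims[2]
    lab[ok] <- img$data[lin]
    # slow path only for endpoints whose nearest voxel is unlabelled
    for (r in which(lab == 0L))
      lab[r] <- assign_endpoint(atlas, ends[r, ], radius)
    a <- lab[seq(1L, 2L * ns, by = 2L)]
    b <- lab[seq(2L, 2L * ns, by = 2L)]
    good <- a != 0L & b != 0L & a != b
    if (any(good)) {
      ia <- match(a[good], labs); ib <- match(b[good], labs)
      w <- set$weights[good] * set$mu
      for (k in seq_along(ia)) {
        vals[ia[k], ib[k]] <- vals[ia[k], ib[k]] + w[k]
        vals[ib[k], ia[k]] <- vals[ia[k], ib[k]]
      }
    }
    unassigned <- sum(!good)
  } else unassigned <- 0L
  structure(list(values = vals, node_table = atlas$node_table,
                 subject_id = set$subject_id, n_unassigned = unassigned),
            class = "fbc_matrix")
}

#' @export
print.fbc_matrix <- function(x, ...) {
  cat(sprintf("<fbc_matrix> %s: %d nodes, %d nonzero edges, total FBC %.3f mm^2\n",
              x$subject_id, nrow(x$values),
              sum(x$values[upper.tri(x$values)] > 0),
              sum(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Node-level graph metrics of an FBC matrix
#'
#' Strength (row sum of FBC weights), degree (number of nonzero partners),
#' and betweenness centrality on the length graph with edge length
#' `1/weight`, normalized by `(n-1)(n-2)/2` for an undirected graph. Shortest
#' paths are exact (Dijkstra, via igraph); disconnected components contribute
#' paths only within themselves.
#'
#' @param m an `fbc_matrix` (or plain symmetric non-negative matrix).
#' @return data frame with `node`, `strength`, `degree`, `betweenness`.
#' @export
node_metrics <- function(m) {
  vals <- if (inherits(m, "fbc_matrix")) m$values else m
  if (any(vals < 0) || max(abs(vals - t(vals))) > 1e-8)
    stop("FBC matrix must be symmetric and non-negative")
  n <- nrow(vals)
  strength <- rowSums(vals)
  degree <- rowSums(vals > 0)
  g <- igraph::graph_from_adjacency_matrix(vals, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  btw <- if (igraph::ecount(g) > 0) {
    igraph::betweenness(g, weights = 1 / igraph::E(g)$weight, directed = FALSE)
  } else rep(0, n)
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  nodes <- if (!is.null(rownames(vals))) rownames(vals) else as.character(seq_len(n))
  data.frame(node = nodes, strength = strength, degree = degree,
             betweenness = as.numeric(btw) / norm, row.names = NULL)
}

zscore <- function(x) {
  s <- stats::sd(x)   # n-1 denominator
  if (is.na(s) || s == 0) {
    warning("constant metric across nodes: z-scores set to 0")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Consensus hubs from a cohort of FBC matrices
#'
#' Within each subject, strength, degree and betweenness are z-scored across
#' nodes and averaged into a composite hub score; a node is a consensus hub
#' when its composite z exceeds `z_threshold` in at least `consensus` of
#' subjects (>= ceiling(consensus * n)).
#'
#' @param cohort list of `fbc_matrix` objects sharing a node list.
#' @param z_threshold composite z cutoff (default 1.5, strict >).
#' @param consensus minimum fraction of subjects (default 0.5).
#' @return object of class `hub_report`: `per_subject` (list of data frames
#'   with z columns), `composite` (nodes x subjects matrix),
#'   `consensus_fraction`, `median_composite_z`, `hubs` (node names).
#' @export
composite_hubs <- function(cohort, z_threshold = 1.5, consensus = 0.5) {
  if (length(cohort) < 2L) stop("need at least 2 subjects")
  nodes <- cohort[[1]]$node_table$name
  comp <- sapply(cohort, function(m) {
    if (!identical(m$node_table$name, nodes))
      stop("cohort matrices do not share a node list")
    met <- node_metrics(m)
    (zscore(met$strength) + zscore(met$degree) + zscore(met$betweenness)) / 3
  })
  rownames(comp) <- nodes
  nsub <- ncol(comp)
  need <- ceiling(consensus * nsub)
  exceed <- rowSums(comp > z_threshold)
  hubs <- nodes[exceed >= need]
  structure(list(composite = comp,
                 consensus_fraction = exceed / nsub,
                 median_composite_z = apply(comp, 1, stats::median),
                 hubs = hubs,
                 z_threshold = z_threshold, consensus = consensus),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("<hub_report> %d consensus hubs (z > %.2f in >= %.0f%% of %d subjects)\n",
              length(x$hubs), x$z_threshold, 100 * x$consensus, ncol(x$composite)))
  if (length(x$hubs)) {
    ord <- order(x$median_composite_z[x$hubs], decreasing = TRUE)
    for (h in x$hubs[ord])
      cat(sprintf("  %s  median Z = %.2f, consensus = %.0f%%\n", h,
                  x$median_composite_z[h], 100 * x$consensus_fraction[h]))
  }
  invisible(x)
}

edge_class <- function(node_table, a, b) {
  cls <- function(nm) node_table$class[match(nm, node_table$name)]
  hemi <- function(nm) node_table$hemisphere[match(nm, node_table$name)]
  if (is.null(node_table$class)) return(NA_character_)
  ca <- cls(a); cb <- cls(b)
  if (ca == "subcortical" || cb == "subcortical") return("projection")
  if (!is.null(node_table$hemisphere) && hemi(a) != hemi(b))
    return("transcallosal")
  "cortico-cortical"
}

#' Consensus top edges of the consensus hubs
#'
#' For each subject and hub, the hub's nonzero FBC connections are z-scored
#' (self-loops excluded); an edge is a consensus top edge when its z exceeds
#' `z_threshold` in at least `consensus` of subjects. Edges are deduplicated
#' across hubs and classified as cortico-cortical, projection, or
#' transcallosal from the node table.
#'
#' @param cohort list of `fbc_matrix` objects.
#' @param hubs character vector of hub node names (see [composite_hubs()]).
#' @param z_threshold z cutoff (default 1.5).
#' @param consensus minimum subject fraction (default 0.5).
#' @param all_partners z-score over all non-self partners including zeros
#'   (default FALSE: nonzero connections only).
#' @return data frame of class `consensus_edges` with columns `hub`,
#'   `partner`, `consensus_fraction`, `median_fbc`, `class`.
#' @export
consensus_top_edges <- function(cohort, hubs, z_threshold = 1.5,
                                consensus = 0.5, all_partners = FALSE) {
  if (length(hubs) == 0L) stop("hubs must be nonempty")
  nodes <- cohort[[1]]$node_table$name
  nsub <- length(cohort)
  need <- ceiling(consensus * nsub)
  rows <- list()
  for (h in hubs) {
    hi <- match(h, nodes)
    exceed <- integer(length(nodes))
    fbc_store <- matrix(NA_real_, length(nodes), nsub)
    skip <- FALSE
    for (s in seq_len(nsub)) {
      w <- cohort[[s]]$values[hi, ]
      w[hi] <- NA                     # exclude self-loop
      sel <- if (all_partners) !is.na(w) else (!is.na(w) & w > 0)
      if (sum(sel) < 3L) {
        warning(sprintf("hub %s has < 3 connections in subject %s: skipped",
                        h, cohort[[s]]$subject_id))
        skip <- TRUE
        break
      }
      z <- rep(NA_real_, length(nodes))
      z[sel] <- zscore(w[sel])
      exceed <- exceed + (!is.na(z) & z > z_threshold)
      fbc_store[, s] <- ifelse(sel, w, NA_real_)
    }
    if (skip) next
    sel_edges <- which(exceed >= need)
    for (e in sel_edges) {
      rows[[length(rows) + 1L]] <- data.frame(
        hub = h, partner = nodes[e],
        consensus_fraction = exceed[e] / nsub,
        median_fbc = stats::median(fbc_store[e, ], na.rm = TRUE),
        class = edge_class(cohort[[1]]$node_table, h, nodes[e]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hub = character(), partner = character(),
               consensus_fraction = numeric(), median_fbc = numeric(),
               class = character())
  # deduplicate hub-hub edges counted from both ends
  key <- apply(out[, c("hub", "partner")], 1,
               function(r) paste(sort(r), collapse = "|"))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_edges", class(out))
  out
}
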