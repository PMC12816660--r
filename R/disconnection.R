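#' Simulate surgical disconnection by a resection cavity
#'
#' Removes streamlines that transect the cavity mask (same traversal test as
#' [filter_by_roi()], inverted); weights and `mu` are preserved on the
#' survivors. Idempotent, and monotone in the cavity.
#'
#' @param set preoperative `streamline_set`.
#' @param cavity binary `voxel_image` coregistered to the streamline frame.
#' @param mode traversal mode (see [filter_by_roi()]); default `"segment"`.
#' @return postoperatively simulated `streamline_set`.
#' @export
simulate_resection <- function(set, cavity, mode = "segment") {
  if (all(cavity$data == 0)) {
    warning("empty cavity: tractogram unchanged")
    return(set)
  }
  hit <- set_hits_roi(set, cavity, mode)
  out <- set
  out$streamlines <- set$streamlines[!hit]
  out$weights <- set$weights[!hit]
  out
}

#' Percentage disconnection of an edge
#'
#' `100 * (FBC_pre - FBC_post) / FBC_pre`, clipped to [0, 100]. Undefined
#' (NA) when the preoperative FBC is zero.
#' @param fbc_pre,fbc_post scalar edge FBC before/after simulated resection.
#' @return percentage in [0, 100], or NA.
#' @export
percent_disconnection <- function(fbc_pre, fbc_post) {
  ifelse(fbc_pre > 0,
         pmin(100, pmax(0, 100 * (fbc_pre - fbc_post) / fbc_pre)),
         NA_real_)
}

#' Edge-wise disconnection table for a patient cohort
#'
#' For each consensus edge and patient, computes pre/post FBC from the
#' patient's tractogram and the simulated postoperative tractogram, and the
#' percentage disconnection.
#'
#' @param scenarios list of scenarios, each a list with `subject_id`,
#'   `preop_set` (`streamline_set`), `cavity_mask` (`voxel_image`), and
#'   `behaviour_delta` (postoperative change in the asymmetry score).
#' @param edges data frame with columns `hub`, `partner` (node names).
#' @param atlas `node_atlas` shared across patients.
#' @param radius endpoint assignment radius in mm.
#' @param mode traversal mode.
#' @return list of class `disconnection_table`: `percent` (edges x patients),
#'   `fbc_pre`, `fbc_post` (same shape), `deltas`, `edges`.
#' @export
disconnection_table <- function(scenarios, edges, atlas, radius = 2,
                                mode = "segment") {
  ne <- nrow(edges); np <- length(scenarios)
  pre <- post <- matrix(NA_real_, ne, np)
  deltas <- numeric(np)
  for (p in seq_len(np)) {
    sc <- scenarios[[p]]
    deltas[p] <- sc$behaviour_delta
    fpre <- build_fbc(sc$preop_set, atlas, radius)
    fpost <- build_fbc(simulate_resection(sc$preop_set, sc$cavity_mask, mode),
                       atlas, radius)
    nodes <- fpre$node_table$name
    for (e in seq_len(ne)) {
      ia <- match(edges$hub[e], nodes); ib <- match(edges$partner[e], nodes)
      pre[e, p] <- fpre$values[ia, ib]
      post[e, p] <- fpost$values[ia, ib]
    }
  }
  pct <- percent_disconnection(pre, post)
  dimnames(pct) <- list(paste(edges$hub, edges$partner, sep = "-"),
                        vapply(scenarios, function(s) s$subject_id, ""))
  structure(list(percent = pct, fbc_pre = pre, fbc_post = post,
                 deltas = deltas, edges = edges),
            class = "disconnection_table")
}

#' Correlate per-edge disconnection with deficit severity
#'
#' Spearman rank correlation of each edge's percentage disconnection with the
#' behavioural delta across patients, two-sided p from the t reference
#' (df = n - 2), Bonferroni-adjusted over `m` edges. Patients with undefined
#' disconnection for an edge are excluded pairwise; edges with constant
#' disconnection or fewer than `min_n` usable patients are flagged.
#'
#' @param table a `disconnection_table` (or edges x patients percentage
#'   matrix).
#' @param deltas behavioural deltas (taken from the table when omitted).
#' @param m number of comparisons for Bonferroni; must be supplied
#'   explicitly.
#' @param min_n minimum usable patients per edge (default 5).
#' @return data frame sorted by rho (descending): `edge`, `n`, `rho`, `p`,
#'   `p_adjusted`, `flagged`.
#' @export
edgewise_correlation <- function(table, deltas = NULL, m, min_n = 5L) {
  if (missing(m)) stop("`m` (number of tested edges) must be given explicitly")
  pct <- if (inherits(table, "disconnection_table")) table$percent else table
  if (is.null(deltas)) deltas <- table$deltas
  rows <- lapply(seq_len(nrow(pct)), function(e) {
    x <- pct[e, ]
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < min_n || stats::sd(x[ok]) == 0 || stats::sd(deltas[ok]) == 0) {
      return(data.frame(edge = rownames(pct)[e], n = n, rho = NA_real_,
                        p = NA_real_, p_adjusted = NA_real_, flagged = TRUE))
    }
    sp <- spearman_report(x[ok], deltas[ok])
    padj <- if (is.na(sp$p)) NA_real_ else min(1, m * sp$p)
    data.frame(edge = rownames(pct)[e], n = n, rho = sp$rho, p = sp$p,
               p_adjusted = padj, flagged = sp$degenerate)
  })
  out <- do.call(rbind, rows)
  out[order(-out$rho, na.last = TRUE), , drop = FALSE]
}
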