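# shared fixtures and independent oracles, built in code at test time

# tiny binary mask on an n^3 grid with given linear indices set
mask_from_idx <- function(idx, dims = c(4, 4, 4), affine = diag(4)) {
  a <- array(0L, dims)
  a[idx] <- 1L
  voxel_image(a, affine)
}

# straight streamline between two world points, k vertices
straight_streamline <- function(a, b, k = 5) {
  t <- seq(0, 1, length.out = k)
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
        a[3] + t * (b[3] - a[3]))
}

# exhaustive betweenness oracle: enumerate all simple paths per pair,
# keep those of minimal length (edge length = 1/weight), count pass-through
# fractions; normalized by (n-1)(n-2)/2. Independent of igraph.
betweenness_oracle <- function(w, tol = 1e-9) {
  n <- nrow(w)
  btw <- numeric(n)
  adj <- lapply(seq_len(n), function(i) which(w[i, ] > 0))
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, visited, len) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- list(nodes = visited, len = len)
        return(invisible())
      }
      for (u in adj[[v]]) {
        if (!(u %in% visited))
          walk(u, c(visited, u), len + 1 / w[v, u])
      }
    }
    walk(s, c(s), 0)
    paths
  }
  for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n)) {
    ps <- all_paths(s, t)
    if (length(ps) == 0L) next
    lens <- vapply(ps, `[[`, 0, "len")
    short <- ps[lens <= min(lens) + tol]
    k <- length(short)
    inner <- table(unlist(lapply(short, function(p)
      setdiff(p$nodes, c(s, t)))))
    if (length(inner))
      btw[as.integer(names(inner))] <- btw[as.integer(names(inner))] +
        as.numeric(inner) / k
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# random symmetric weighted graph for oracle comparisons
random_fbc <- function(n, p = 0.35, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    if (runif(1) < p) w[i, j] <- w[j, i] <- runif(1, 0.5, 3)
  }
  w
}

# undirected edge key for comparing edge sets
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# small fbc_matrix object from a plain matrix
as_fbc <- function(w, id = "S1") {
  nn <- nrow(w)
  nt <- data.frame(label = seq_len(nn), name = sprintf("N%02d", seq_len(nn)),
                   class = "cortical", hemisphere = "right",
                   stringsAsFactors = FALSE)
  dimnames(w) <- list(nt$name, nt$name)
  structure(list(values = w, node_table = nt, subject_id = id,
                 n_unassigned = 0L), class = "fbc_matrix")
}
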