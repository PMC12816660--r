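test_that("FBC assembly: endpoint pairing, mu scaling, conservation", {
  # 3-node atlas on a 9x5x5 grid, nodes at x = 1, 5, 9 (world 0, 4, 8)
  lab <- array(0L, c(9, 5, 5))
  lab[1, 3, 3] <- 1L; lab[5, 3, 3] <- 2L; lab[9, 3, 3] <- 3L
  atlas <- node_atlas(voxel_image(lab),
                      data.frame(label = 1:3, name = c("A", "B", "C"),
                                 class = "cortical", hemisphere = "right"))
  ab <- straight_streamline(c(0, 2, 2), c(4, 2, 2))
  sset <- streamline_set(list(ab, ab, ab, straight_streamline(c(4, 2, 2), c(8, 2, 2))),
                         weights = c(0.5, 0.25, 0.25, 1), mu = 2)
  f <- build_fbc(sset, atlas)
  expect_equal(f$values["A", "B"], 2)        # mu * (0.5 + 0.25 + 0.25)
  expect_equal(f$values["B", "C"], 2)
  expect_equal(f$values["A", "C"], 0)
  expect_true(isSymmetric(f$values))
  expect_equal(diag(f$values), c(A = 0, B = 0, C = 0))
  # conservation: total FBC = mu * total assigned weight
  expect_equal(sum(f$values[upper.tri(f$values)]),
               sset$mu * sum(sset$weights), tolerance = 1e-9)
  # empty set -> zero matrix
  f0 <- build_fbc(streamline_set(list(), numeric(0)), atlas)
  expect_true(all(f0$values == 0))
  # streamline ending far from any node is counted unassigned
  off <- straight_streamline(c(0, 2, 2), c(4, 0, 0))
  f1 <- build_fbc(streamline_set(list(off)), atlas, radius = 0.4)
  expect_equal(f1$n_unassigned, 1L)
})

test_that("node metrics: strength, degree, and betweenness basics", {
  # path graph a-b-c with equal weights: b carries the unique a-c path
  w <- as_fbc(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
  m <- node_metrics(w)
  expect_equal(m$strength, c(1, 2, 1))
  expect_equal(m$degree, c(1, 2, 1))
  expect_equal(m$betweenness, c(0, 1, 0))    # normalized by (n-1)(n-2)/2
  # complete graph, equal weights: no intermediaries
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(node_metrics(as_fbc(k4))$betweenness, rep(0, 4))
  expect_error(node_metrics(as_fbc(matrix(c(0, -1, -1, 0), 2))), "non-negative")
})

test_that("betweenness equals the exhaustive path-enumeration oracle", {
  for (cfg in list(c(n = 8, seed = 1), c(n = 10, seed = 2), c(n = 12, seed = 3),
                   c(n = 12, seed = 4), c(n = 9, seed = 5))) {
    w <- random_fbc(cfg[["n"]], p = 0.35, seed = cfg[["seed"]])
    got <- node_metrics(as_fbc(w))$betweenness
    expect_equal(got, betweenness_oracle(w), tolerance = 1e-9,
                 info = sprintf("n=%d seed=%d", cfg[["n"]], cfg[["seed"]]))
  }
  # disconnected graph: paths within components only
  w <- matrix(0, 5, 5); w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
  w[4, 5] <- w[5, 4] <- 1
  expect_equal(node_metrics(as_fbc(w))$betweenness, betweenness_oracle(w),
               tolerance = 1e-9)
})

test_that("z-scoring is idempotent and constant metrics degrade to zero", {
  z <- convergemap:::zscore
  set.seed(6)
  x <- rnorm(30)
  expect_equal(z(z(x)), z(x), tolerance = 1e-12)
  expect_warning(z0 <- z(rep(2, 10)), "constant")
  expect_equal(z0, rep(0, 10))
})

test_that("consensus hubs: identical matrices give 0/1 consensus; threshold limit empties", {
  w <- random_fbc(10, p = 0.5, seed = 8)
  cohort <- list(as_fbc(w, "a"), as_fbc(w, "b"), as_fbc(w, "c"))
  hr <- composite_hubs(cohort)
  expect_true(all(hr$consensus_fraction %in% c(0, 1)))
  hr_inf <- composite_hubs(cohort, z_threshold = 1e6)
  expect_length(hr_inf$hubs, 0)
})

test_that("planted hubs and top edges are recovered from the synthetic cohort", {
  spec <- synth_spec(seed = 19,
                     connectome = list(n_subjects = 8L, n_nodes = 40L,
                                       n_hubs = 4L))
  ccoh <- make_connectome_cohort(spec)
  fbcs <- lapply(ccoh$sets, build_fbc, atlas = ccoh$atlas)
  hr <- composite_hubs(fbcs)
  expect_setequal(hr$hubs, ccoh$planted_hubs)
  edges <- consensus_top_edges(fbcs, hr$hubs)
  expect_setequal(edge_key(edges$hub, edges$partner),
                  edge_key(ccoh$planted_edges$hub, ccoh$planted_edges$partner))
  # edge classes come from the node table
  expect_true(all(edges$class %in%
                    c("cortico-cortical", "projection", "transcallosal")))
})

test_that("top-edge selection: dominant edge found, uniform weights yield none", {
  base <- matrix(0, 8, 8)
  for (j in 2:8) base[1, j] <- base[j, 1] <- 1
  dom <- base; dom[1, 2] <- dom[2, 1] <- 10
  cohort <- list(as_fbc(dom, "a"), as_fbc(dom, "b"))
  sel <- consensus_top_edges(cohort, hubs = "N01")
  expect_equal(nrow(sel), 1L)
  expect_setequal(c(sel$hub, sel$partner), c("N01", "N02"))
  unif <- list(as_fbc(base, "a"), as_fbc(base, "b"))
  # uniform weights are the expected degenerate case: z collapses to 0
  expect_equal(nrow(suppressWarnings(consensus_top_edges(unif, hubs = "N01"))),
               0L)
})

test_that("track-density maps accumulate weight*mu once per voxel and scale out in z", {
  grid <- voxel_image(array(0L, c(10, 4, 4)))
  sl <- straight_streamline(c(0, 1, 1), c(9, 1, 1), k = 4)
  tm <- tdi(streamline_set(list(sl), weights = 0.5, mu = 3), grid)
  vals <- tm$density$data[, 2, 2]
  expect_equal(vals, rep(1.5, 10))           # 0.5 * 3 in every traversed voxel
  expect_equal(sum(tm$density$data != 0), 10)
  # doubling weights doubles density, leaves the z-map unchanged
  tm2 <- tdi(streamline_set(list(sl, straight_streamline(c(0, 2, 2), c(9, 2, 1), k = 6)),
                            weights = c(1, 2), mu = 1), grid)
  tm3 <- tdi(streamline_set(list(sl, straight_streamline(c(0, 2, 2), c(9, 2, 1), k = 6)),
                            weights = c(2, 4), mu = 1), grid)
  expect_equal(tm3$density$data, 2 * tm2$density$data, tolerance = 1e-12)
  expect_equal(tm3$z$data, tm2$z$data, tolerance = 1e-12)
})

test_that("a heavy bundle stands out of a diffuse background in the TDI core", {
  grid <- voxel_image(array(0L, c(12, 8, 8)))
  # one heavy bundle against a broad carpet of light ones: the core mask
  # (z > 2) must retain only the heavy corridor
  heavy <- list(straight_streamline(c(0, 2, 2), c(11, 2, 2), k = 12))
  light <- list()
  for (y in 3:7) for (z in 3:7)
    light[[length(light) + 1L]] <-
      straight_streamline(c(0, y, z), c(11, y, z), k = 12)
  sset <- streamline_set(c(heavy, light), weights = c(10, rep(1, length(light))))
  tm <- tdi(sset, grid)
  core <- which(tm$core_mask$data != 0, arr.ind = TRUE)
  expect_gt(nrow(core), 0)
  expect_true(all(core[, 2] == 3 & core[, 3] == 3))  # heavy row only
})
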