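test_that("generated connectomes satisfy all structural invariants", {
  cfg <- connectome_sim_config(n_regions = 78, edge_density = 0.3, seed = 3)
  cn <- generate_connectome(cfg)
  W <- cn$weights
  expect_equal(dim(W), c(78, 78))
  expect_equal(W, t(W))
  expect_true(all(W >= 0))
  expect_equal(diag(W), rep(0, 78))
  expect_equal(max(W), 1)
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                           diag = FALSE)
  expect_equal(igraph::components(g)$no, 1)
  # near-target edge density (bridging may add a few edges)
  dens <- mean(W[upper.tri(W)] > 0)
  expect_lt(abs(dens - 0.3), 0.02)
})

test_that("connectome generation is deterministic and density-extremes work", {
  a <- generate_connectome(connectome_sim_config(seed = 7))
  b <- generate_connectome(connectome_sim_config(seed = 7))
  expect_identical(a$weights, b$weights)
  full <- generate_connectome(connectome_sim_config(n_regions = 10,
                                                    edge_density = 1, seed = 1))
  expect_true(all(full$weights[upper.tri(full$weights)] > 0))
})

test_that("connectome write/read round-trip preserves the matrix", {
  cn <- small_connectome(n = 12, seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_connectome(cn, path)
  back <- read_connectome(path, global_coupling = cn$global_coupling)
  expect_equal(back$weights, cn$weights, tolerance = 1e-12)
  expect_equal(back$labels, cn$labels)
  # comma-delimited, no header
  path2 <- tempfile(fileext = ".csv")
  write_connectome(cn, path2, sep = ",", labels = FALSE)
  back2 <- read_connectome(path2)
  expect_equal(back2$weights, cn$weights, tolerance = 1e-12)
})

test_that("read_connectome symmetrizes small asymmetry and rejects large", {
  cn <- small_connectome(n = 6, seed = 4)
  W <- cn$weights
  edge <- which(W > 0.1, arr.ind = TRUE)[1, ]
  i <- edge[1]; j <- edge[2]
  W[1, 2] <- W[1, 2] * (1 + 1e-10)
  path <- tempfile(fileext = ".tsv")
  write.table(W, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  back <- read_connectome(path)
  expect_equal(back$weights, (W + t(W)) / 2)
  W[i, j] <- W[i, j] * 2
  write.table(W, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_error(read_connectome(path), "asymmetry")
})

test_that("histology generator reproduces the nested design counts", {
  rec <- generate_histology(histology_sim_config(seed = 1))
  agg <- aggregate_rois(rec)
  units <- unique(agg[agg$marker == "inh_synapse" & agg$layer == "VI",
                      c("subject_id", "group")])
  counts <- table(units$group)
  expect_equal(unname(counts[["NC"]]), 9)
  expect_equal(unname(counts[["NAGM"]]), 29)
  expect_equal(unname(counts[["DEMYEL"]]), 13)
})

test_that("histology generator is deterministic and respects config errors", {
  a <- generate_histology(histology_sim_config(seed = 5))
  b <- generate_histology(histology_sim_config(seed = 5))
  expect_identical(a$density, b$density)
  expect_error(histology_sim_config(n_ms = 10, n_ms_with_demyel = 13),
               "n_ms")
})

test_that("noise-free generation hits baseline x multiplier exactly", {
  cfg <- histology_sim_config(between_subject_sd = 0, within_subject_sd = 0,
                              seed = 1)
  rec <- generate_histology(cfg)
  vi <- rec[rec$marker == "inh_synapse" & rec$layer == "VI", ]
  expect_equal(unique(vi$density[vi$group == "NC"]), 1000)
  expect_equal(unique(vi$density[vi$group == "NAGM"]), 1000 * 0.851)
  expect_equal(unique(vi$density[vi$group == "DEMYEL"]), 1000 * 0.707)
  ex1 <- rec[rec$marker == "exc_synapse" & rec$layer == "I", ]
  expect_equal(unique(ex1$density), 1200)  # layer-I preset off by default
})

test_that("group-mean ratios converge to the injected multipliers", {
  ratios <- vapply(1:60, function(s) {
    rec <- generate_histology(histology_sim_config(seed = 1000 + s))
    vi <- rec[rec$marker == "inh_synapse" & rec$layer == "VI", ]
    mean(vi$density[vi$group == "NAGM"]) / mean(vi$density[vi$group == "NC"])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.851), 0.02)
})

test_that("round-trip through aggregation and write/read validates bit-exactly", {
  cn <- generate_connectome(connectome_sim_config(n_regions = 20, seed = 9))
  path <- tempfile(fileext = ".tsv")
  write_connectome(cn, path)
  expect_silent(validate_connectome(read_connectome(path)))
})
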