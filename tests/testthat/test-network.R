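test_that("pearson_r handles affine, boundary and degenerate inputs", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 3), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8)   # the threshold boundary
  expect_warning(r <- pearson_r(x, rep(1, 4)), "constant")
  expect_true(is.na(r))
  expect_error(pearson_r(1:2, 1:2), ">= 3")
  expect_error(pearson_r(1:4, 1:5), "length")
})

test_that("an r exactly at the threshold yields an edge", {
  em <- make_em(rbind(c(1, 2, 3, 4), c(1, 3, 2, 4)),
                feat = c("LNC_0001", "MRNA_0001"))
  net <- build_network(em, threshold = 0.8)
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$r, 0.8)
  # threshold 1 with no exactly collinear pair: empty edge set
  expect_identical(nrow(build_network(em, threshold = 1)$edges), 0L)
})

test_that("network construction equals the brute-force all-pairs oracle", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      n_feat <- sample(10:50, 1)
      em <- make_em(matrix(rnorm(n_feat * 10), n_feat, 10),
                    feat = sprintf("%s_%04d",
                                   sample(c("LNC", "MRNA"), n_feat,
                                          replace = TRUE),
                                   seq_len(n_feat)))
      for (mode in c("absolute", "signed")) {
        net <- build_network(em, threshold = 0.3, mode = mode)
        expect_equal(net$edges, brute_edges(em, 0.3, mode))
        # bipartite: edges only join a lncRNA to an mRNA
        bt <- biotypes(em)
        expect_true(all(bt[net$edges$lnc_id] == "lncRNA"))
        expect_true(all(bt[net$edges$mrna_id] == "mRNA"))
        expect_false(anyDuplicated(paste(net$edges$lnc_id,
                                         net$edges$mrna_id)) > 0)
      }
    }
  })
  em1 <- make_em(matrix(rnorm(40), 4, 10))  # mRNA only
  expect_error(build_network(em1), "both lncRNA and mRNA")
})

test_that("planted co-expressed pairs pass the 0.8 threshold", {
  sim <- generate_expression(
    synthetic_config(n_informative = 0, n_redundant = 0, n_noise = 60,
                     n_coexpressed = 8, within_correlation = 0.9,
                     effect_size = 0, seed = 3))
  net <- build_network(sim$matrix, threshold = 0.8)
  pairs <- sim$ground_truth$coexpressed_pairs
  found <- paste(net$edges$lnc_id, net$edges$mrna_id)
  expect_gte(mean(paste(pairs$lnc_id, pairs$mrna_id) %in% found), 7 / 8)
})

test_that("degree summaries tally exactly and satisfy the handshake identity", {
  # star: one lncRNA against 5 perfectly collinear mRNAs
  base <- c(1, 2, 3, 4, 5, 6)
  em <- make_em(rbind(base, base + 1, base * 2, base - 3, base * 0.5,
                      base + 0.1),
                feat = c("LNC_0001", sprintf("MRNA_%04d", 1:5)))
  net <- build_network(em, threshold = 0.8)
  ds <- degree_summary(net)
  expect_identical(unname(ds$degree["LNC_0001"]), 5L)
  expect_identical(ds$lnc$max, 5L)
  expect_true(all(ds$degree[sprintf("MRNA_%04d", 1:5)] == 1L))
  expect_identical(ds$n_edges, 5L)

  withr::with_seed(42, {
    for (rep in 1:20) {
      em <- make_em(matrix(rnorm(200), 20, 10),
                    feat = sprintf("%s_%04d",
                                   rep(c("LNC", "MRNA"), 10), 1:20))
      net <- build_network(em, threshold = runif(1, 0.2, 0.9))
      d <- degree_summary(net)$degree
      expect_identical(sum(d), 2L * nrow(net$edges))
      bt <- biotypes(em)
      expect_identical(sum(d[bt[names(d)] == "lncRNA"]),
                       nrow(net$edges))
    }
  })

  empty <- build_network(em, threshold = 1)
  expect_true(all(degree_summary(empty)$degree == 0L))
})

test_that("pathway subnetworks keep the gene set's mRNAs and their lncRNA partners", {
  # wire 6 "pathway" mRNAs to a known lncRNA set via shared latent factors
  withr::with_seed(8, {
    n <- 30
    z <- rnorm(n)
    mk <- function(w) sqrt(w) * z + sqrt(1 - w) * rnorm(n)
    rows <- rbind(t(replicate(4, mk(0.95))),   # lncRNAs on the factor
                  t(replicate(6, mk(0.95))),   # pathway mRNAs on the factor
                  matrix(rnorm(5 * n), 5))     # unrelated mRNAs
    em <- make_em(rows, feat = c(sprintf("LNC_%04d", 1:4),
                                 sprintf("MRNA_%04d", 1:11)))
    net <- build_network(em, threshold = 0.8)
    path_genes <- sprintf("MRNA_%04d", 1:6)
    sub <- pathway_subnetwork(net, path_genes)
    expect_setequal(sub$nodes$id[sub$nodes$biotype == "mRNA"], path_genes)
    expect_setequal(sub$nodes$id[sub$nodes$biotype == "lncRNA"],
                    sprintf("LNC_%04d", 1:4))
    expect_true(all(sub$edges$mrna_id %in% path_genes))

    # gene set covering all mRNAs leaves the edge set unchanged
    all_sub <- pathway_subnetwork(net, sprintf("MRNA_%04d", 1:11))
    expect_equal(all_sub$edges, net$edges)
    expect_warning(pathway_subnetwork(net, "MRNA_9999"), "intersect")
  })
})

test_that("graph exports are Cytoscape-compatible and edge TSVs round trip", {
  em <- make_em(rbind(c(1, 2, 3, 4, 5), c(1.1, 2, 3.2, 4, 5.1),
                      c(5, 3, 4, 1, 2)),
                feat = c("LNC_0001", "MRNA_0001", "MRNA_0002"))
  net <- build_network(em, threshold = 0.8)
  sp <- withr::local_tempfile(fileext = ".sif")
  export_graph(net, sp, "sif")
  lines <- readLines(sp)
  expect_identical(length(lines), nrow(net$edges))
  expect_true(all(grepl("\tcoexp\t", lines)))

  gp <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, gp, "graphml")
  g <- igraph::read_graph(gp, format = "graphml")
  expect_identical(igraph::ecount(g), as.numeric(nrow(net$edges)))
  expect_setequal(igraph::vertex_attr(g, "biotype"), net$nodes$biotype)

  tp <- withr::local_tempfile(fileext = ".tsv")
  export_graph(net, tp, "edge-tsv")
  back <- read_edge_tsv(tp)
  expect_identical(back$edges[, c("lnc_id", "mrna_id")],
                   net$edges[, c("lnc_id", "mrna_id")])
  expect_equal(back$edges$r, net$edges$r, tolerance = 1e-6)

  empty <- build_network(em, threshold = 1)
  ep <- withr::local_tempfile(fileext = ".sif")
  export_graph(empty, ep, "sif")
  expect_identical(readLines(ep), character(0))
})
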