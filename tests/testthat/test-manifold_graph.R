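# independent JSD oracle: two-term KL sum against the mixture
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

test_that("sqrt-JSD distances: bounds, oracle equivalence, metric property", {
  # identical samples -> 0; disjoint support -> 1 (max JSD = 1 bit)
  v <- matrix(c(1, 2, 3, 1, 2, 3,   5, 0, 0, 0, 0, 4), 6, 2,
              dimnames = list(paste0("P", 1:6), c("A", "B")))
  v2 <- cbind(v, C = c(0, 7, 0, 2, 0, 0))
  co <- cohort_from_matrix(v2, is_control = rep(FALSE, 3))
  D <- js_distance_matrix(co, paste0("P", 1:6))
  expect_equal(D["A", "A"], 0)
  expect_equal(D["B", "C"], 1)   # disjoint support

  # random 5-sample fixture vs the independent oracle, <= 1e-12
  set.seed(31)
  m <- matrix(rexp(40), 8, 5,
              dimnames = list(paste0("P", 1:8), paste0("S", 1:5)))
  co2 <- cohort_from_matrix(m, is_control = rep(FALSE, 5))
  D2 <- js_distance_matrix(co2, paste0("P", 1:8))
  P <- sweep(m, 2, colSums(m), "/")
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(D2[i, j], sqrt(jsd_oracle(P[, i], P[, j])), tolerance = 1e-12)

  # triangle inequality on 1,000 random triples
  set.seed(32)
  big <- matrix(rexp(20 * 12), 20, 12,
                dimnames = list(paste0("P", 1:20), paste0("S", 1:12)))
  co3 <- cohort_from_matrix(big, is_control = rep(FALSE, 12))
  D3 <- js_distance_matrix(co3, paste0("P", 1:20))
  for (t in 1:1000) {
    ijk <- sample(12, 3)
    expect_lte(D3[ijk[1], ijk[3]],
               D3[ijk[1], ijk[2]] + D3[ijk[2], ijk[3]] + 1e-9)
  }

  # all-zero sample after shift is a hard error naming the sample
  bad <- matrix(c(1, 2, 0, 0), 2, 2,
                dimnames = list(paste0("P", 1:2), c("OK", "ZERO")))
  cob <- cohort_from_matrix(bad, is_control = rep(FALSE, 2))
  expect_error(js_distance_matrix(cob, paste0("P", 1:2)), "ZERO")
})

test_that("MST-kNN pruning matches hand enumeration and an igraph MST oracle", {
  # 4 collinear points, spacing 1, k = 1: chain MST; under the union rule
  # every chain edge has one endpoint whose nearest neighbour is the other
  D <- dist_fixture(c(0, 1, 2, 3))
  g <- build_mst_knn(D, 1)
  expect_equal(max(g$membership), 1L)
  expect_equal(igraph::ecount(g$graph), 3L)

  # k >= N-1: the graph is the full MST, a single component with N-1 edges
  set.seed(33)
  D2 <- dist_fixture(matrix(rnorm(20), 10, 2))
  gf <- build_mst_knn(D2, 9)
  expect_equal(max(gf$membership), 1L)
  expect_equal(igraph::ecount(gf$graph), 9L)
  # edge set equals an independent MST implementation (unique weights)
  gi <- igraph::graph_from_adjacency_matrix(D2, weighted = TRUE,
                                            mode = "undirected")
  mst <- igraph::mst(gi, algorithm = "prim")
  e_mine <- apply(igraph::as_edgelist(gf$graph), 1,
                  function(r) paste(sort(r), collapse = "-"))
  e_orac <- apply(igraph::as_edgelist(mst), 1,
                  function(r) paste(sort(r), collapse = "-"))
  expect_setequal(e_mine, e_orac)

  # pruned edges are always a subset of the MST edges
  g3 <- build_mst_knn(D2, 2)
  e3 <- apply(igraph::as_edgelist(g3$graph), 1,
              function(r) paste(sort(r), collapse = "-"))
  expect_true(all(e3 %in% e_orac))

  # two well-separated blobs, k = 3: exactly two pure components
  set.seed(34)
  x <- c(rnorm(20, 0, 0.05), rnorm(20, 10, 0.05))
  gb <- build_mst_knn(dist_fixture(x), 3)
  expect_equal(max(gb$membership), 2L)
  expect_length(unique(gb$membership[1:20]), 1L)
  expect_length(unique(gb$membership[21:40]), 1L)
})

test_that("select_k returns the smallest k joining the controls", {
  # tight control blob among scattered tumours: k stays small
  set.seed(35)
  x <- c(rnorm(10, 0, 0.1), runif(30, 5, 50))
  D <- dist_fixture(x)
  ctl <- rownames(D)[1:10]
  k <- select_k(D, ctl)
  expect_lte(k, 2)
  # defining property: controls joined at k, not at k-1
  expect_length(unique(build_mst_knn(D, k)$membership[ctl]), 1L)
  if (k > 1)
    expect_gt(length(unique(build_mst_knn(D, k - 1)$membership[ctl])), 1L)

  # controls in two distant blobs: k must rise to retain a bridging edge;
  # verify against an exhaustive k sweep on a 10-point instance
  y <- c(0, 0.5, 1, 20, 20.5, 21, 9, 10, 11, 12)
  Dy <- dist_fixture(y)
  cty <- rownames(Dy)[1:6]
  ky <- select_k(Dy, cty, k_max = 9)
  sweep_k <- NA
  for (kk in 1:9)
    if (length(unique(build_mst_knn(Dy, kk)$membership[cty])) == 1L) {
      sweep_k <- kk; break
    }
  expect_equal(ky, sweep_k)
  expect_gt(ky, 1)

  # a single control sample is trivially one cluster
  expect_equal(select_k(D, rownames(D)[1]), 1L)

  # impossible request errors with the split report
  expect_error(select_k(Dy, cty, k_max = max(1, sweep_k - 1)), "not joined")
})

test_that("centrality_split isolates hubs and matches closed-form betweenness", {
  # star: hub betweenness 1, leaves 0 -> central = {hub}
  n <- 21
  Ds <- matrix(2, n, n); Ds[1, ] <- Ds[, 1] <- 1; diag(Ds) <- 0
  dimnames(Ds) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  gs <- build_mst_knn(Ds, n - 1)
  expect_equal(unname(gs$centrality["n01"]), 1)
  expect_true(all(gs$centrality[-1] == 0))
  expect_equal(centrality_split(gs)$central_ids, "n01")

  # path of 21 nodes: closed form b_i = (i-1)(n-i) / ((n-1)(n-2)/2)
  Dp <- dist_fixture(1:21)
  gp <- build_mst_knn(Dp, 2)
  i <- 1:21
  closed <- (i - 1) * (21 - i) / (20 * 19 / 2)
  expect_equal(unname(gp$centrality[rownames(Dp)]), closed)
  sp <- centrality_split(gp)
  # central nodes are a contiguous middle block (by construction symmetric)
  idx <- sort(match(sp$central_ids, rownames(Dp)))
  expect_equal(idx, seq(min(idx), max(idx)))
  expect_true(11 %in% idx)   # the path centre is always central
  # and the split reproduces the knee on the exact closed-form sequence
  ord <- order(-closed, rownames(Dp), method = "radix")
  thr <- knee_threshold(closed[ord])
  expect_equal(sort(sp$central_ids),
               sort(rownames(Dp)[ord][seq_len(thr)]))

  # balanced binary tree (depth 4, 31 nodes): exact betweenness oracle
  nt <- 31
  childs <- function(v) c(2 * v, 2 * v + 1)
  edges <- do.call(rbind, lapply(1:15, function(v) cbind(v, childs(v))))
  # tree metric: unit edges; D = hop distance => MST is the tree itself
  gt <- igraph::graph_from_edgelist(edges, directed = FALSE)
  Dt <- igraph::distances(gt)
  ids <- sprintf("v%02d", 1:nt)
  dimnames(Dt) <- list(ids, ids)
  gtree <- build_mst_knn(Dt, nt - 1)
  # exact: pairs of nodes whose unique path passes through v
  sub_size <- function(v) { # nodes in the subtree rooted at v
    if (v > 15) return(1L)
    1L + sub_size(2 * v) + sub_size(2 * v + 1)
  }
  btw <- vapply(1:nt, function(v) {
    if (v > 15) return(0)
    l <- sub_size(2 * v); r <- sub_size(2 * v + 1); u <- nt - 1L - l - r
    (l * r + l * u + r * u) / ((nt - 1) * (nt - 2) / 2)
  }, numeric(1))
  expect_equal(unname(gtree$centrality[ids]), btw)
  st <- centrality_split(gtree)
  # the root and its two children dominate all shortest paths
  expect_true(all(c("v01", "v02", "v03") %in% st$central_ids))
})

test_that("binomial enrichment equals exhaustive enumeration for n <= 30
           and is 1 at the most likely outcome", {
  for (n in c(5, 12, 30)) for (pr in c(0.25, 0.337, 0.5)) for (k in 0:n) {
    expect_equal(binomial_enrichment_test(k, n, pr),
                 binom.test(k, n, pr)$p.value, tolerance = 1e-12)
  }
  expect_equal(binomial_enrichment_test(20, 60, 1 / 3), 1)
})

test_that("central_enrichment counts labelled central nodes only", {
  n <- 21
  Ds <- matrix(2, n, n); Ds[1, ] <- Ds[, 1] <- 1; diag(Ds) <- 0
  ids <- sprintf("n%02d", 1:n)
  dimnames(Ds) <- list(ids, ids)
  gs <- build_mst_knn(Ds, n - 1)
  labels <- setNames(rep(c("A", "B"), c(7, 14)), ids)
  enr <- central_enrichment(gs, labels, "A")
  expect_equal(enr$n_central, 1L)
  expect_equal(enr$cohort_proportion, 7 / 21)
  expect_equal(enr$count_in_central, as.integer(labels["n01"] == "A"))
  expect_error(central_enrichment(gs, labels[-3], "A"), "unlabelled")
})

test_that("t-SNE contract: deterministic, centred, separates far blobs", {
  skip_if_not_installed("Rtsne")
  set.seed(36)
  x <- c(rnorm(15, 0, 0.3), rnorm(15, 25, 0.3))
  D <- dist_fixture(x)
  y1 <- embed_tsne(D, seed = 4, perplexity = 5)
  y2 <- embed_tsne(D, seed = 4, perplexity = 5)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(30L, 2L))
  expect_equal(colMeans(y1), c(x = 0, y = 0), tolerance = 1e-8)
  # silhouette of the embedding against the true blob labels
  lab <- rep(1:2, each = 15)
  d2 <- as.matrix(dist(y1))
  sil <- vapply(1:30, function(i) {
    a <- mean(d2[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(d2[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.8)

  expect_error(embed_tsne(D, seed = 1, perplexity = 10), "perplexity")

  # tiny instance runs and has the right shape
  y5 <- embed_tsne(dist_fixture(1:5), seed = 1, perplexity = 1)
  expect_equal(dim(y5), c(5L, 2L))
})

test_that("confidence ellipses match the chi-square quantile and overlap
           detection is sound", {
  set.seed(37)
  pts <- matrix(rnorm(20000), ncol = 2)
  e <- confidence_ellipse(pts, level = 0.75)
  target <- sqrt(qchisq(0.75, 2))
  expect_equal(unname(e$semi_axes[1]), target, tolerance = 0.05)
  expect_equal(unname(e$semi_axes[2]), target, tolerance = 0.05)

  e2 <- confidence_ellipse(pts, level = 0.75)
  expect_true(ellipses_overlap(e, e2))

  far <- confidence_ellipse(sweep(pts, 2, c(100, 0), "+"), level = 0.75)
  expect_false(ellipses_overlap(e, far))

  line <- cbind(1:10, 2 * (1:10))
  expect_error(confidence_ellipse(line), "singular")
})

test_that("knn_robustness reproduces a single run and flags planted
           core/periphery structure at every probe count", {
  # planted geometry: label-A tumours form a homogeneous core around the
  # shared tumour signature, label-B tumours scatter as far-flung
  # satellites (large private deviations on the signature probes, so
  # each B attaches to the core as a leaf), controls are a separate blob
  set.seed(38)
  n_probe <- 60; nA <- 30; nB <- 20; nC <- 10
  n <- nA + nB + nC
  v <- matrix(rnorm(n_probe * n, 7, 0.1), n_probe,
              dimnames = list(sprintf("P%02d", 1:n_probe),
                              sprintf("S%02d", 1:n)))
  tum <- 1:(nA + nB)
  v[1:30, tum] <- v[1:30, tum] + 2          # shared tumour signature
  for (j in nA + 1:nB)                      # B: large private scatter
    v[1:30, j] <- v[1:30, j] + rnorm(30, 0, 0.8)
  v[, nA + nB + 1:nC] <- v[, nA + nB + 1:nC] +
    matrix(rnorm(n_probe * nC, 0, 0.25), n_probe)
  co <- cohort_from_matrix(v, is_control = rep(c(FALSE, TRUE), c(nA + nB, nC)))
  fr <- differential_filter(co, n_select = 20)
  labels <- setNames(rep(c("A", "B", NA), c(nA, nB, nC)), colnames(v))
  tab <- knn_robustness(co, fr, base_n = 20, control_ids = control_ids(co),
                        labels = labels, target_label = "B", k_max = 30)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$p_value < 0.01))   # B depleted from the core everywhere

  # the base row equals a direct single invocation
  D <- js_distance_matrix(co, fr$probe_id[1:20])
  k <- select_k(D, control_ids(co), k_max = 30)
  g <- build_mst_knn(D, k)
  enr <- central_enrichment(g, labels, "B")
  base <- tab[tab$n_probes == 20, ]
  expect_equal(base$k, k)
  expect_equal(base$p_value, enr$p_value)
  expect_equal(base$count_in_central, enr$count_in_central)
})
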