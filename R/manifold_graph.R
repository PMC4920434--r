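#' Square-root Jensen-Shannon distance matrix between samples
#'
#' Each sample's expression vector over the selected probes is turned
#' into a discrete probability distribution (values shifted to be
#' non-negative by subtracting the global minimum of the submatrix when
#' negative, then normalised to sum 1). The distance between two samples
#' is the square root of the Jensen-Shannon divergence with base-2
#' logarithms — a true metric bounded by 1.
#'
#' @param cohort an [expression_cohort()].
#' @param probe_subset non-empty vector of probe ids.
#' @return symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
js_distance_matrix <- function(cohort, probe_subset) {
  if (!length(probe_subset)) stop("probe_subset must be non-empty")
  miss <- setdiff(probe_subset, rownames(cohort$values))
  if (length(miss)) stop("unknown probe id(s): ", paste(miss, collapse = ", "))
  X <- cohort$values[probe_subset, , drop = FALSE]
  if (min(X) < 0) X <- X - min(X)
  tot <- colSums(X)
  if (any(tot == 0))
    stop("sample(s) with all-zero vector after shift: ",
         paste(colnames(X)[tot == 0], collapse = ", "))
  P <- sweep(X, 2L, tot, "/")
  n <- ncol(P)
  plogp <- function(m) { r <- m * log2(m); r[m == 0] <- 0; r }
  h <- -colSums(plogp(P))                 # per-sample entropy (bits)
  D <- matrix(0, n, n, dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    M <- (P[, j, drop = FALSE] + P[, i]) / 2
    hm <- -colSums(plogp(M))
    jsd <- pmax(hm - (h[i] + h[j]) / 2, 0)
    D[i, j] <- D[j, i] <- sqrt(jsd)
  }
  D
}

# deterministic MST (Kruskal; edges ordered by weight, then by the
# lexicographic node-id pair) and per-node neighbour rankings
.mst_scaffold <- function(D) {
  ids <- rownames(D)
  n <- length(ids)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[ut]
  ord <- order(w, ids[ut[, 1L]], ids[ut[, 2L]], method = "radix")
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  keep <- integer(0)
  for (e in ord) {
    a <- find(ut[e, 1L]); b <- find(ut[e, 2L])
    if (a != b) { parent[a] <- b; keep <- c(keep, e)
      if (length(keep) == n - 1L) break }
  }
  # neighbour ranking per node: by distance, ties by node id
  nbr <- lapply(seq_len(n), function(u) {
    others <- setdiff(seq_len(n), u)
    others[order(D[u, others], ids[others], method = "radix")]
  })
  list(ids = ids, edges = cbind(ut[keep, 1L], ut[keep, 2L]), nbr = nbr)
}

.prune_mst <- function(scaffold, k) {
  knn <- lapply(scaffold$nbr, function(v) v[seq_len(min(k, length(v)))])
  e <- scaffold$edges
  keep <- vapply(seq_len(nrow(e)), function(i) {
    u <- e[i, 1L]; v <- e[i, 2L]
    (v %in% knn[[u]]) || (u %in% knn[[v]])   # union rule
  }, logical(1L))
  e[keep, , drop = FALSE]
}

.graph_from_edges <- function(ids, edges) {
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  g
}

#' MST-kNN graph over a distance matrix
#'
#' Builds the minimum spanning tree of the complete weighted graph
#' (distance ties broken by the lexicographic node-id pair, so the tree
#' is deterministic), then retains an MST edge (u,v) iff v is among u's k
#' nearest neighbours or u is among v's (union rule). Connected
#' components are recomputed on the pruned graph and betweenness
#' centrality is computed per component and rescaled to \[0,1\] by the
#' standard (n-1)(n-2)/2 factor.
#'
#' @param D symmetric distance matrix with sample ids as dimnames.
#' @param k number of nearest neighbours, k >= 1.
#' @return an object of class `mst_knn`: list with `graph` (igraph),
#'   `k`, `membership` (named component index), `centrality` (named,
#'   rescaled to \[0,1\]).
#' @export
build_mst_knn <- function(D, k) {
  stopifnot(k >= 1, isTRUE(all.equal(D, t(D))))
  scaffold <- .mst_scaffold(D)
  .build_from_scaffold(scaffold, k)
}

.build_from_scaffold <- function(scaffold, k) {
  edges <- .prune_mst(scaffold, k)
  g <- .graph_from_edges(scaffold$ids, edges)
  comp <- igraph::components(g)
  centrality <- stats::setNames(numeric(length(scaffold$ids)), scaffold$ids)
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    nc <- length(vs)
    if (nc >= 3L) {
      sub <- igraph::induced_subgraph(g, vs)
      b <- igraph::betweenness(sub, directed = FALSE)
      centrality[igraph::V(sub)$name] <- b / ((nc - 1) * (nc - 2) / 2)
    }
  }
  structure(list(graph = g, k = k,
                 membership = stats::setNames(comp$membership, scaffold$ids),
                 centrality = centrality),
            class = "mst_knn")
}

#' @export
print.mst_knn <- function(x, ...) {
  cat(sprintf("mst_knn graph: %d nodes, %d edges, k = %d, %d component(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$k,
              max(x$membership)))
  invisible(x)
}

#' Smallest k joining all control samples in one component
#'
#' Scans k = 1..k_max and returns the smallest k for which every control
#' sample lies in a single connected component of the MST-kNN graph —
#' the reference point where within-cluster connections are as close as
#' those among controls.
#'
#' @param D distance matrix.
#' @param control_ids non-empty subset of the sample ids.
#' @param k_max largest k to try (default N-1, which always succeeds).
#' @return the selected integer k.
#' @export
select_k <- function(D, control_ids, k_max = nrow(D) - 1L) {
  stopifnot(length(control_ids) > 0L)
  miss <- setdiff(control_ids, rownames(D))
  if (length(miss)) stop("unknown control id(s): ", paste(miss, collapse = ", "))
  scaffold <- .mst_scaffold(D)
  for (k in seq_len(k_max)) {
    g <- .build_from_scaffold(scaffold, k)
    if (length(unique(g$membership[control_ids])) == 1L) return(k)
  }
  split <- table(g$membership[control_ids])
  stop("controls are not joined by any k <= ", k_max, "; at k_max they split ",
       "across components of sizes ", paste(split, collapse = ", "))
}

#' Split a graph into central and peripheral nodes
#'
#' Within the largest connected component, the rescaled betweenness
#' values are sorted in descending order and the maximum-curvature knee
#' ([knee_threshold()]) is applied; nodes above the threshold with
#' non-zero betweenness form the central set (leaves can never be
#' central), the rest of the component is peripheral.
#'
#' @param graph an `mst_knn` object whose largest component has >= 10
#'   nodes.
#' @return list with `central_ids`, `peripheral_ids` (both restricted to
#'   the largest component) and `threshold_rank`.
#' @export
centrality_split <- function(graph) {
  sizes <- table(graph$membership)
  comp <- as.integer(names(sizes)[which.max(sizes)])
  nodes <- names(graph$membership)[graph$membership == comp]
  if (length(nodes) < 10L) stop("largest component has fewer than 10 nodes")
  cen <- graph$centrality[nodes]
  ord <- order(-cen, nodes, method = "radix")
  thr <- knee_threshold(cen[ord])
  central <- nodes[ord][seq_len(thr)]
  central <- central[cen[central] > 0]
  list(central_ids = central,
       peripheral_ids = setdiff(nodes, central),
       threshold_rank = thr)
}

#' Two-sided minimum-likelihood exact binomial tail probability
#'
#' Probability, under Binomial(n, prob), of any outcome whose likelihood
#' does not exceed that of the observed count — the two-sided convention
#' of [stats::binom.test()], implemented by direct enumeration.
#'
#' @param count observed successes.
#' @param n number of trials.
#' @param prob null success probability.
#' @return the two-sided p-value.
#' @export
binomial_enrichment_test <- function(count, n, prob) {
  stopifnot(count >= 0, count <= n, prob >= 0, prob <= 1)
  d <- stats::dbinom(0:n, n, prob)
  sum(d[d <= d[count + 1L] * (1 + 1e-7)])
}

#' Label enrichment in the central part of a graph
#'
#' Tests whether the composition of the central node set diverges from
#' the cohort: an exact two-sided binomial test of `count_in_central`
#' successes in `n_central` trials at the cohort proportion of the
#' target label. Nodes with `NA` labels (e.g. controls) are excluded
#' from the cohort proportion and from the central count.
#'
#' @param graph an `mst_knn` object.
#' @param labels named character vector over the graph's nodes (NA =
#'   not part of the labelled cohort).
#' @param target_label the label whose enrichment is tested.
#' @return list with `count_in_central`, `n_central`,
#'   `cohort_proportion` and `p_value`.
#' @export
central_enrichment <- function(graph, labels, target_label) {
  nodes <- names(graph$membership)
  miss <- setdiff(nodes, names(labels))
  if (length(miss)) stop("unlabelled node(s): ", paste(utils::head(miss, 5), collapse = ", "))
  labels <- labels[nodes]
  split <- centrality_split(graph)
  central <- split$central_ids[!is.na(labels[split$central_ids])]
  if (!length(central)) stop("no labelled nodes in the central set")
  pool <- labels[!is.na(labels)]
  prop <- mean(pool == target_label)
  k <- sum(labels[central] == target_label)
  list(count_in_central = k, n_central = length(central),
       cohort_proportion = prop,
       p_value = binomial_enrichment_test(k, length(central), prop))
}

#' t-SNE embedding of a precomputed distance matrix
#'
#' Contract over an established t-SNE implementation (Rtsne): the
#' embedding minimises the t-SNE objective on the supplied distances, is
#' deterministic for a fixed seed, and is returned centred at the
#' origin.
#'
#' @param D distance matrix.
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity; must satisfy `perplexity < N/3`.
#' @param max_iter optimisation iterations (default 1000).
#' @return N x 2 matrix of coordinates with sample ids as rownames.
#' @export
embed_tsne <- function(D, seed, perplexity = 30, max_iter = 1000L) {
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("embed_tsne requires the Rtsne package")
  n <- nrow(D)
  if (perplexity >= n / 3) stop("perplexity must be < N/3")
  set.seed(seed)
  fit <- Rtsne::Rtsne(as.matrix(D), is_distance = TRUE,
                      perplexity = perplexity, theta = 0.0,
                      max_iter = as.integer(max_iter), num_threads = 1L)
  y <- fit$Y
  y <- sweep(y, 2L, colMeans(y))
  rownames(y) <- rownames(D)
  colnames(y) <- c("x", "y")
  y
}

#' Normal-theory confidence ellipse of a 2D point cloud
#'
#' Ellipse centred at the sample mean with semi-axes
#' `sqrt(eigenvalue * qchisq(level, 2))` along the eigenvectors of the
#' sample covariance.
#'
#' @param points_2d matrix with >= 3 non-collinear rows.
#' @param level coverage level in (0,1), default 0.75.
#' @return object of class `confidence_ellipse`: list with `centre`,
#'   `semi_axes`, `angle` (radians), `level`, `cov`.
#' @export
confidence_ellipse <- function(points_2d, level = 0.75) {
  stopifnot(level > 0, level < 1)
  pts <- as.matrix(points_2d)
  if (nrow(pts) < 3L) stop("need at least 3 points")
  S <- stats::cov(pts)
  if (abs(det(S)) < 1e-12 * max(diag(S), 1)^2)
    stop("singular covariance (collinear points); consider jittering")
  eig <- eigen(S, symmetric = TRUE)
  structure(list(centre = colMeans(pts),
                 semi_axes = sqrt(eig$values * stats::qchisq(level, 2)),
                 angle = atan2(eig$vectors[2L, 1L], eig$vectors[1L, 1L]),
                 level = level, cov = S),
            class = "confidence_ellipse")
}

.ellipse_boundary <- function(e, n = 720L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  R <- matrix(c(cos(e$angle), sin(e$angle), -sin(e$angle), cos(e$angle)), 2L)
  xy <- R %*% rbind(e$semi_axes[1L] * cos(t), e$semi_axes[2L] * sin(t))
  t(xy + e$centre)
}

.inside_ellipse <- function(e, pts) {
  R <- matrix(c(cos(e$angle), sin(e$angle), -sin(e$angle), cos(e$angle)), 2L)
  z <- t(R) %*% (t(pts) - e$centre)
  (z[1L, ] / e$semi_axes[1L])^2 + (z[2L, ] / e$semi_axes[2L])^2 <= 1 + 1e-12
}

#' Do two confidence ellipses overlap?
#'
#' Tests 720 boundary points of each ellipse for membership in the
#' other, plus mutual centre containment.
#'
#' @param e1,e2 `confidence_ellipse` objects.
#' @return logical flag.
#' @export
ellipses_overlap <- function(e1, e2) {
  any(.inside_ellipse(e2, .ellipse_boundary(e1))) ||
    any(.inside_ellipse(e1, .ellipse_boundary(e2))) ||
    .inside_ellipse(e2, matrix(e1$centre, 1L)) ||
    .inside_ellipse(e1, matrix(e2$centre, 1L))
}

#' Robustness of central-region enrichment to the probe count
#'
#' Repeats select_k -> build_mst_knn -> centrality_split ->
#' central_enrichment for several probe-count settings (by default half,
#' base and double the base probe count taken from the top of a
#' differential-filter ranking).
#'
#' @param cohort an [expression_cohort()].
#' @param diff_result a `filter_result` from [differential_filter()].
#' @param base_n base probe count (default: the filter's selected count).
#' @param control_ids controls used for the k-selection rule.
#' @param labels named label vector for [central_enrichment()].
#' @param target_label enriched label to test.
#' @param k_max passed to [select_k()].
#' @return data.frame with one row per setting: probes used, selected k,
#'   central counts, cohort proportion and binomial p-value.
#' @export
knn_robustness <- function(cohort, diff_result, base_n = NULL, control_ids,
                           labels, target_label, k_max = 30L) {
  if (is.null(base_n)) base_n <- sum(diff_result$selected)
  sizes <- unique(pmin(pmax(c(round(base_n / 2), base_n, 2 * base_n), 2L),
                       nrow(diff_result)))
  rows <- lapply(sizes, function(m) {
    probes <- diff_result$probe_id[seq_len(m)]
    D <- js_distance_matrix(cohort, probes)
    k <- select_k(D, control_ids, k_max = k_max)
    g <- build_mst_knn(D, k)
    enr <- central_enrichment(g, labels, target_label)
    data.frame(n_probes = m, k = k,
               count_in_central = enr$count_in_central,
               n_central = enr$n_central,
               cohort_proportion = enr$cohort_proportion,
               p_value = enr$p_value)
  })
  do.call(rbind, rows)
}

#' Export an MST-kNN graph as GraphML
#' @param graph an `mst_knn` object.
#' @param path output path.
#' @param central_ids optional central node set to flag.
#' @return the path, invisibly.
#' @export
write_mst_knn_graphml <- function(graph, path, central_ids = NULL) {
  g <- graph$graph
  g <- igraph::set_vertex_attr(g, "centrality",
                               value = unname(graph$centrality[igraph::V(g)$name]))
  flag <- if (is.null(central_ids)) rep(FALSE, igraph::vcount(g))
    else igraph::V(g)$name %in% central_ids
  g <- igraph::set_vertex_attr(g, "central_flag", value = flag)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
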