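test_that("marker extraction applies run-length and support filters", {
  # 6 bins, 2 clones; clone 1 loses B over bins 1-3 (passes), clone 2 loses A
  # over bins 1-3 (mirrored: distinct marker), clone 1 loses B over 5-6
  # (too short)
  A <- rbind(c(1, 0), c(1, 0), c(1, 0), c(1, 1), c(1, 1), c(1, 1))
  B <- rbind(c(0, 1), c(0, 1), c(0, 1), c(1, 1), c(0, 1), c(0, 1))
  cn <- structure(list(A = A, B = B), class = "integer_cn")
  Y <- matrix(5, 6, 4); D <- matrix(20, 6, 4)
  bg <- toy_bg(NULL, Y, D)
  ell <- c(1L, 1L, 2L, 2L)
  mk <- extract_loh_markers(cn, bg, ell, min_bins = 3, min_umis = 30)
  expect_equal(ncol(mk$presence), 2)      # mirrored pair = two characters
  expect_setequal(mk$markers$lost, c("A", "B"))
  expect_equal(mk$presence[, mk$markers$lost == "B"], c(1L, 0L))
  expect_equal(mk$presence[, mk$markers$lost == "A"], c(0L, 1L))
  # raising the support threshold above a carrier's UMIs drops the marker
  mk2 <- suppressWarnings(
    extract_loh_markers(cn, bg, ell, min_bins = 3, min_umis = 1000))
  expect_equal(ncol(mk2$presence), 0)
  expect_warning(extract_loh_markers(cn, bg, ell, min_bins = 10, min_umis = 1),
                 "no LOH markers")
})

test_that("parsimony tree matches the exhaustive oracle on three clones", {
  # clones 1, 2 share m1; clone 3 has only m2
  pres <- rbind(c(1, 0), c(1, 0), c(0, 1))
  tree <- build_tree(list(presence = pres))
  expect_equal(tree$score, 2)
  # clone 3 attaches closer to the root than the (1,2) clade
  lab <- tree$nodes
  anc12 <- tree$parent[which(lab$clone == 1)]
  expect_equal(tree$parent[which(lab$clone == 2)], anc12)
  expect_true(tree$parent[which(lab$clone == 3)] != anc12)
  # m1 sits on the (1,2) stem
  expect_equal(tree$edge_weight[anc12], 1)
})

test_that("conflict-free markers give the perfect phylogeny with one gain each", {
  # nested clades: m1 in {1,2,3}, m2 in {1,2}, m3 in {1}
  pres <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
  tree <- build_tree(list(presence = pres))
  expect_equal(tree$score, 3)
})

test_that("a clone without unique markers becomes an ancestor", {
  # clone 1 = {m1}; clone 2 = {m1, m2}: clone 1 is the ancestor of clone 2
  pres <- rbind(c(1, 0), c(1, 1))
  tree <- build_tree(list(presence = pres))
  n1 <- which(tree$nodes$clone == 1); n2 <- which(tree$nodes$clone == 2)
  expect_equal(tree$parent[n2], n1)
  expect_equal(tree$score, 2)
})

test_that("internal gain counting matches brute-force search over gain placements", {
  set.seed(12)
  for (M in c(3, 4)) {
    trees <- spacna:::enumerate_rooted_trees(M)
    for (rep_ in 1:5) {
      pres <- rbinom(M, 1, 0.5)
      if (!any(pres)) pres[1] <- 1
      tr <- trees[[sample.int(length(trees), 1)]]
      expect_equal(length(spacna:::marker_gain_nodes(tr, M, pres)),
                   brute_min_gains(tr, M, pres))
    }
  }
})

test_that("exhaustive search finds the minimum over all topologies", {
  set.seed(4)
  M <- 5
  pres <- matrix(rbinom(M * 6, 1, 0.4), M, 6)
  pres <- pres[, colSums(pres) > 0, drop = FALSE]
  tree <- build_tree(list(presence = pres))
  scores <- vapply(spacna:::enumerate_rooted_trees(M), function(tr)
    sum(vapply(seq_len(ncol(pres)), function(j)
      brute_min_gains(tr, M, pres[, j]), numeric(1))), numeric(1))
  expect_equal(tree$score, min(scores))
})

test_that("marker assignments respect irreversibility", {
  set.seed(5)
  pres <- matrix(rbinom(4 * 8, 1, 0.4), 4, 8)
  pres <- pres[, colSums(pres) > 0, drop = FALSE]
  tree <- build_tree(list(presence = pres))
  # leaves below any gain edge of marker j are exactly its carriers
  ch <- spacna:::tree_children(tree$parent)
  leaves_below <- function(v) {
    cl <- tree$nodes$clone[v]
    if (!is.na(cl) && !length(ch[[v]])) return(cl)
    out <- if (!is.na(cl)) cl else integer(0)
    c(out, unlist(lapply(ch[[v]], leaves_below)))
  }
  for (j in seq_len(ncol(pres))) {
    gains <- which(vapply(tree$edge_markers, function(e) j %in% e, logical(1)))
    carriers <- sort(unique(unlist(lapply(gains, leaves_below))))
    expect_equal(carriers, which(pres[, j] > 0))
  }
})

test_that("generated tree profiles round-trip through tree building", {
  # cherry: two clones, one unique marker each (plus shared truncal ones)
  prof <- simulate_tree_profiles(2, n_bins = 40, n_loh = 4,
                                 chrom_of = rep(c("chr1", "chr2"), each = 20),
                                 seed = 3)
  carriers <- lapply(strsplit(prof$markers$carriers, ","), as.integer)
  pres <- vapply(carriers, function(cc) as.integer(1:2 %in% cc), integer(2))
  tree <- build_tree(list(presence = pres))
  # minimal score: one gain per marker (all markers are clade-compatible on
  # a 2-leaf tree)
  expect_equal(tree$score, ncol(pres))
  expect_equal(sum(tree$nodes$type == "clone"), 2)
})

test_that("clone centroids are member means, optionally in 3D", {
  S <- rbind(c(0, 0), c(2, 2), c(5, 5))
  expect_equal(unname(clone_centroids(c(1, 1, 2), S)[1, ]), c(1, 1))
  expect_equal(unname(clone_centroids(c(1, 1, 2), S)[2, ]), c(5, 5))
  cents <- clone_centroids(c(1, 1, 1), S, slice_id = c("a", "a", "b"),
                           z_offsets = c(a = 0, b = 100))
  expect_equal(unname(cents[1, 3]), 100 / 3)
})

test_that("ancestor placement solves the diffusion system", {
  # two leaves with unequal edge weights: root minimises weighted quadratics
  pres <- rbind(c(1, 0, 0, 0), c(0, 1, 1, 1))
  tree <- build_tree(list(presence = pres))   # cherry, weights 1 and 3
  expect_setequal(tree$edge_weight[tree$nodes$type == "clone"], c(1, 3))
  leaf_loc <- rbind(c(0, 0), c(2, 0))
  loc <- place_ancestors(tree, leaf_loc)
  mrca <- setdiff(which(tree$nodes$type != "clone"),
                  which(tree$nodes$type == "root"))
  # analytic optimum of x^2 / (2*1) + (2 - x)^2 / (2*3): x = 0.5
  expect_equal(loc[mrca[1], 1], 0.5, tolerance = 1e-10)
  # root (zero-gain edge, weight eps) coincides with the MRCA here
  expect_equal(loc[which(tree$nodes$type == "root"), ],
               loc[mrca[1], ], tolerance = 1e-10)
  # stationarity: every free node is the precision-weighted neighbour average
  w <- pmax(tree$edge_weight, 0.5)
  for (v in which(is.na(tree$nodes$clone))) {
    nbrs <- c(if (tree$parent[v] > 0) tree$parent[v], which(tree$parent == v))
    wts <- c(if (tree$parent[v] > 0) 1 / w[v], 1 / w[which(tree$parent == v)])
    avg <- colSums(loc[nbrs, , drop = FALSE] * wts) / sum(wts)
    expect_lt(max(abs(loc[v, ] - avg)), 1e-8)
  }
  # translation equivariance
  loc2 <- place_ancestors(tree, leaf_loc + 7)
  expect_equal(loc2, loc + 7, tolerance = 1e-9)
})

test_that("a single-leaf chain collapses ancestors onto the leaf", {
  tree <- build_tree(list(presence = matrix(1, 1, 2)))
  loc <- place_ancestors(tree, cbind(3, 4))
  expect_true(all(abs(loc[, 1] - 3) < 1e-9))
  expect_true(all(abs(loc[, 2] - 4) < 1e-9))
})

test_that("newick export is readable and carries edge weights", {
  pres <- rbind(c(1, 0), c(1, 0), c(0, 1))
  tree <- build_tree(list(presence = pres))
  ph <- ape::read.tree(text = tree_newick(tree))
  expect_s3_class(ph, "phylo")
  expect_setequal(ph$tip.label, c("clone1", "clone2", "clone3"))
})
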