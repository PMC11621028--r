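# Clone phylogeny from irreversible LOH markers (star homoplasy parsimony)
# and spatial placement of ancestral nodes by Gaussian diffusion.

#' Extract LOH phylogenetic markers
#'
#' A marker is a maximal run of consecutive bins (within a chromosome) over
#' which the set of clones having lost a given haplotype (a = 0 or b = 0) is
#' constant and nonempty. Losses of opposite haplotypes over the same region
#' are distinct markers (mirrored events are independent characters). Markers
#' must span at least \code{min_bins} bins and be supported by at least
#' \code{min_umis} SNP-covering UMIs (summed over the marker's bins and the
#' carrier clone's spots) in every carrier clone.
#'
#' @param cn an \code{integer_cn}.
#' @param bg the \code{binned_genome}.
#' @param ell per-spot clone labels (1..M as in the \code{cn} columns;
#'   0 = normal, ignored).
#' @param min_bins minimum genomic bins per marker (default 3).
#' @param min_umis minimum supporting UMIs per carrier clone (default 100).
#' @return list with \code{presence} (clone x marker 0/1 matrix) and
#'   \code{markers} (data.frame: chrom, bin range, lost haplotype, n_bins).
#' @export
extract_loh_markers <- function(cn, bg, ell, min_bins = 3, min_umis = 100) {
  M <- ncol(cn$A)
  chrom <- bg$bins$chrom
  clone_D <- vapply(seq_len(M), function(m)
    rowSums(bg$D[, ell == m, drop = FALSE]), numeric(nrow(bg$D)))
  clone_D <- matrix(clone_D, nrow = nrow(bg$D))
  presence <- NULL
  meta <- NULL
  for (hap in c("A", "B")) {
    lost <- if (hap == "A") cn$A == 0 else cn$B == 0   # bins x clones
    key <- paste(chrom, apply(lost, 1L, paste, collapse = ""))
    newrun <- c(TRUE, key[-1] != key[-length(key)])
    run <- cumsum(newrun)
    for (r in unique(run)) {
      idx <- which(run == r)
      pat <- lost[idx[1], ]
      if (!any(pat)) next
      if (length(idx) < min_bins) next
      supp <- colSums(clone_D[idx, , drop = FALSE])
      if (any(supp[pat] < min_umis)) next
      presence <- cbind(presence, as.integer(pat))
      meta <- rbind(meta, data.frame(
        chrom = chrom[idx[1]], bin_start = idx[1], bin_end = idx[length(idx)],
        lost = hap, n_bins = length(idx)))
    }
  }
  if (is.null(presence)) {
    warning("no LOH markers pass the filters; tree building will be skipped")
    presence <- matrix(0L, M, 0)
    meta <- data.frame(chrom = character(0), bin_start = integer(0),
                       bin_end = integer(0), lost = character(0),
                       n_bins = integer(0))
  }
  rownames(meta) <- NULL
  list(presence = matrix(presence, nrow = M), markers = meta)
}

# --- rooted-tree machinery -------------------------------------------------
# Trees over M clone leaves are stored as parent vectors: nodes 1..M are the
# clones, higher ids are internal; exactly one node (the clone MRCA) has
# parent 0. Children lists derived on demand.

tree_children <- function(parent) {
  ch <- vector("list", length(parent))
  for (v in seq_along(parent)) if (parent[v] > 0)
    ch[[parent[v]]] <- c(ch[[parent[v]]], v)
  ch
}

tree_postorder <- function(parent) {
  ch <- tree_children(parent)
  root <- which(parent == 0)
  out <- integer(0)
  visit <- function(v) {
    for (c_ in ch[[v]]) visit(c_)
    out <<- c(out, v)
  }
  visit(root)
  out
}

# Star-homoplasy parsimony: a marker may be gained on several edges but never
# lost, so its minimum number of gains on a fixed tree is the number of
# maximal subtrees whose leaves all carry it. Returns per-node gain
# indicators (gain on the edge into that node; a gain at the root means the
# marker arose on the lineage leading to the clone MRCA).
marker_gain_nodes <- function(parent, nleaf, pres) {
  n <- length(parent)
  allpos <- logical(n)
  for (v in tree_postorder(parent)) {
    if (v <= nleaf) allpos[v] <- pres[v] > 0
    else {
      ch <- which(parent == v)
      allpos[v] <- length(ch) > 0 && all(allpos[ch])
    }
  }
  gain <- logical(n)
  gain[parent == 0] <- allpos[parent == 0]
  idx <- which(parent > 0)
  gain[idx] <- allpos[idx] & !allpos[parent[idx]]
  which(gain)
}

tree_parsimony_score <- function(parent, nleaf, presence) {
  if (ncol(presence) == 0) return(0)
  sum(vapply(seq_len(ncol(presence)), function(j)
    length(marker_gain_nodes(parent, nleaf, presence[, j])), numeric(1)))
}

# enumerate all rooted binary topologies on nleaf leaves as parent vectors
# ((2*nleaf - 3)!! of them), by sequential leaf insertion on every edge and
# above the current root. Deterministic order.
enumerate_rooted_trees <- function(nleaf) {
  if (nleaf == 1) return(list(c(0L)))
  base <- rep(0L, 2L * nleaf - 1L)
  base[1] <- base[2] <- nleaf + 1L         # root joins leaves 1, 2
  trees <- list(list(parent = base, used = nleaf + 1L, root = nleaf + 1L))
  if (nleaf >= 3) for (k in 3:nleaf) {
    nxt <- list()
    for (tr in trees) {
      # insertion above any current node (leaves 1..k-1 and internal nodes)
      active <- c(seq_len(k - 1L), (nleaf + 1L):tr$used)
      newint <- tr$used + 1L
      for (v in active) {                  # insert on edge above v
        p <- tr$parent
        if (v == tr$root) {
          p[newint] <- 0L; p[v] <- newint; p[k] <- newint
          nxt[[length(nxt) + 1L]] <- list(parent = p, used = newint, root = newint)
        } else {
          p[newint] <- p[v]; p[v] <- newint; p[k] <- newint
          nxt[[length(nxt) + 1L]] <- list(parent = p, used = newint, root = tr$root)
        }
      }
    }
    trees <- nxt
  }
  lapply(trees, `[[`, "parent")
}

# greedy agglomerative fallback for many clones: join the pair of current
# groups sharing the most markers, repeatedly. Deterministic.
greedy_tree <- function(presence) {
  M <- nrow(presence)
  parent <- rep(0L, 2L * M - 1L)
  groups <- as.list(seq_len(M))
  ids <- seq_len(M)
  nxt <- M + 1L
  while (length(groups) > 1) {
    best <- c(1L, 2L); bestscore <- -1
    for (a in seq_len(length(groups) - 1L)) for (b in (a + 1L):length(groups)) {
      sc <- sum(apply(presence[unique(c(groups[[a]], groups[[b]])), , drop = FALSE],
                      2L, min))
      if (sc > bestscore) { bestscore <- sc; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    parent[ids[a]] <- nxt; parent[ids[b]] <- nxt
    groups[[a]] <- c(groups[[a]], groups[[b]]); ids[a] <- nxt
    groups[[b]] <- NULL; ids <- ids[-b]
    nxt <- nxt + 1L
  }
  parent[seq_len(nxt - 1L)]
}

#' Build the clone tree from LOH markers
#'
#' Finds the rooted clone topology minimising the total number of marker
#' gains under star homoplasy (markers gained possibly more than once,
#' never lost), by exhaustive search over rooted binary topologies for up to
#' \code{exact_max} clones and a greedy agglomerative heuristic above. Each
#' marker is then assigned to the stem edges of its maximal carrier
#' subtrees; edge weights count markers gained. Leaves whose pendant edge
#' gains no marker are collapsed into their parent, making that clone an
#' ancestor of its siblings. A diploid, LOH-free root node is placed above
#' the clone MRCA.
#'
#' @param markers output of [extract_loh_markers()] (or any list with a
#'   clone x marker 0/1 \code{presence} matrix).
#' @param exact_max largest clone count for exhaustive search (default 7).
#' @return a \code{clone_tree}: \code{parent} vector, node table
#'   (\code{id}, \code{type}, \code{clone}), \code{edge_weight} (markers
#'   gained on the edge into each node), \code{edge_markers} (list),
#'   \code{score}, and \code{heuristic} flag.
#' @export
build_tree <- function(markers, exact_max = 7) {
  presence <- markers$presence
  M <- nrow(presence)
  heuristic <- FALSE
  if (M == 1) {
    parent <- c(0L)
  } else if (M <= exact_max) {
    cands <- enumerate_rooted_trees(M)
    scores <- vapply(cands, tree_parsimony_score, numeric(1),
                     nleaf = M, presence = presence)
    parent <- cands[[which.min(scores)]]
  } else {
    heuristic <- TRUE
    warning("more than ", exact_max, " clones; using greedy heuristic tree")
    parent <- greedy_tree(presence)
  }
  score <- tree_parsimony_score(parent, M, presence)
  # edge marker assignment
  n <- length(parent)
  edge_markers <- vector("list", n)
  if (ncol(presence) > 0) for (j in seq_len(ncol(presence))) {
    for (v in marker_gain_nodes(parent, M, presence[, j]))
      edge_markers[[v]] <- c(edge_markers[[v]], j)
  }
  ew <- vapply(edge_markers, length, numeric(1))
  # collapse a leaf with a zero-gain pendant edge into its parent, making
  # the clone the ancestor of its former siblings -- but only when it is the
  # unique such child (two zero-gain siblings are indistinguishable clones
  # and stay siblings)
  is_clone <- c(rep(TRUE, M), rep(FALSE, n - M))
  repeat {
    ch <- tree_children(parent)
    is_zero_leaf <- vapply(seq_len(n), function(v)
      is_clone[v] && ew[v] == 0 && parent[v] > 0 && !length(ch[[v]]),
      logical(1))
    cand <- which(is_zero_leaf)
    cand <- cand[vapply(cand, function(v) {
      sibs <- ch[[parent[v]]]
      length(sibs) >= 2 && sum(is_zero_leaf[sibs]) == 1
    }, logical(1))]
    if (!length(cand)) break
    v <- cand[1]; p <- parent[v]
    for (sib in setdiff(ch[[p]], v)) parent[sib] <- v
    parent[v] <- parent[p]
    ew[v] <- ew[p]; edge_markers[v] <- edge_markers[p]
    parent[p] <- -1L                      # mark removed
    ew[p] <- 0; edge_markers[p] <- list(integer(0))
  }
  keep <- which(parent >= 0)
  remap <- match(seq_len(n), keep)
  parent2 <- parent[keep]
  parent2[parent2 > 0] <- remap[parent2[parent2 > 0]]
  ew <- ew[keep]; edge_markers <- edge_markers[keep]
  mrca <- which(parent2 == 0)
  # diploid root anchor above the MRCA
  root_id <- length(parent2) + 1L
  parent2[mrca] <- root_id
  parent2 <- c(parent2, 0L)
  ew <- c(ew, 0)
  edge_markers[[root_id]] <- integer(0)
  # markers gained at the MRCA stem now sit on the root->MRCA edge already
  clone_of <- rep(NA_integer_, length(parent2))
  clone_of[remap[seq_len(M)]] <- seq_len(M)
  nodes <- data.frame(
    id = seq_along(parent2),
    type = ifelse(seq_along(parent2) == root_id, "root",
                  ifelse(!is.na(clone_of), "clone", "ancestor")),
    clone = clone_of)
  structure(list(parent = parent2, nodes = nodes, edge_weight = ew,
                 edge_markers = edge_markers, score = score,
                 heuristic = heuristic),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree: %d clones, %d nodes, parsimony score %d%s\n",
              sum(x$nodes$type == "clone"), nrow(x$nodes), x$score,
              if (x$heuristic) " (heuristic)" else ""))
  invisible(x)
}

#' Newick string for a clone tree
#'
#' Branch lengths are the per-edge marker gain counts; readable with
#' \code{ape::read.tree}.
#'
#' @param tree a \code{clone_tree}.
#' @return single-element character vector (with trailing semicolon).
#' @export
tree_newick <- function(tree) {
  ch <- tree_children(tree$parent)
  lab <- ifelse(tree$nodes$type == "clone",
                paste0("clone", tree$nodes$clone),
                ifelse(tree$nodes$type == "root", "root",
                       paste0("anc", tree$nodes$id)))
  rec <- function(v) {
    kids <- ch[[v]]
    core <- if (length(kids))
      paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")",
             lab[v])
    else lab[v]
    if (tree$parent[v] > 0) paste0(core, ":", tree$edge_weight[v]) else core
  }
  paste0(rec(which(tree$parent == 0)), ";")
}

#' Clone centroids in physical space
#'
#' Arithmetic mean of member-spot coordinates per clone; with per-slice
#' z offsets supplied, centroids are 3D.
#'
#' @param ell per-spot clone labels (0 ignored).
#' @param S spot x 2 coordinates.
#' @param slice_id per-spot slice labels.
#' @param z_offsets optional named vector of per-slice z coordinates.
#' @return clone x dim matrix (rows ordered by clone id).
#' @export
clone_centroids <- function(ell, S, slice_id = NULL, z_offsets = NULL) {
  coords <- S
  if (!is.null(z_offsets)) {
    stopifnot(!is.null(slice_id))
    coords <- cbind(S, z = as.numeric(z_offsets[slice_id]))
  }
  clones <- sort(unique(ell[ell > 0]))
  out <- t(vapply(clones, function(m)
    colMeans(coords[ell == m, , drop = FALSE]), numeric(ncol(coords))))
  rownames(out) <- paste0("clone", clones)
  out
}

#' Place ancestral nodes in space by Gaussian diffusion
#'
#' Clone nodes are clamped at their centroids; every other node location
#' maximises the joint Gaussian likelihood in which a child's location is
#' normal around its parent's with variance proportional to the number of
#' markers gained on the edge. The maximiser solves a positive-definite
#' linear system per coordinate: each free node is the precision-weighted
#' (1/w) average of its tree neighbours. Zero-weight edges get weight
#' \code{eps} so variances stay positive.
#'
#' @param tree a \code{clone_tree}.
#' @param leaf_locations clone x dim matrix from [clone_centroids()] (row
#'   order = clone id order).
#' @param eps weight substituted for zero-gain edges (default 0.5).
#' @return node x dim matrix of locations (rows follow \code{tree$nodes}).
#' @export
place_ancestors <- function(tree, leaf_locations, eps = 0.5) {
  n <- length(tree$parent)
  dim_ <- ncol(leaf_locations)
  w <- pmax(tree$edge_weight, eps)        # weight of edge into each node
  loc <- matrix(NA_real_, n, dim_)
  clone_rows <- which(tree$nodes$type == "clone")
  loc[clone_rows, ] <- leaf_locations[match(
    tree$nodes$clone[clone_rows],
    sort(unique(tree$nodes$clone[clone_rows]))), , drop = FALSE]
  free <- which(is.na(loc[, 1]))
  if (!length(free)) return(loc)
  # neighbours of v: parent (edge weight w[v]) and children (edge weight w[child])
  A <- matrix(0, length(free), length(free))
  b <- matrix(0, length(free), dim_)
  fidx <- match(seq_len(n), free)
  for (ii in seq_along(free)) {
    v <- free[ii]
    nbrs <- c(if (tree$parent[v] > 0) tree$parent[v], which(tree$parent == v))
    wts <- c(if (tree$parent[v] > 0) 1 / w[v],
             1 / w[which(tree$parent == v)])
    if (!length(nbrs)) stop("disconnected node in tree")
    A[ii, ii] <- sum(wts)
    for (jj in seq_along(nbrs)) {
      u <- nbrs[jj]
      if (is.na(fidx[u])) b[ii, ] <- b[ii, ] + wts[jj] * loc[u, ]
      else A[ii, fidx[u]] <- A[ii, fidx[u]] - wts[jj]
    }
  }
  loc[free, ] <- solve(A, b)
  loc
}

#' Full phylogeography from a fitted model
#'
#' @param cn an \code{integer_cn}.
#' @param bg the \code{binned_genome}.
#' @param ell per-spot clone labels.
#' @param min_bins,min_umis marker filters (defaults 3 and 100).
#' @param z_offsets optional per-slice z coordinates for 3D placement.
#' @param eps zero-gain edge weight for the diffusion system.
#' @return list with \code{tree}, \code{markers}, \code{locations} (node x
#'   dim), and \code{newick}; NULL if no marker passes the filters.
#' @export
phylogeography <- function(cn, bg, ell, min_bins = 3, min_umis = 100,
                           z_offsets = NULL, eps = 0.5) {
  mk <- extract_loh_markers(cn, bg, ell, min_bins = min_bins,
                            min_umis = min_umis)
  if (ncol(mk$presence) == 0) return(NULL)
  tree <- build_tree(mk)
  cents <- clone_centroids(ell, bg$S, bg$slice_id, z_offsets)
  loc <- place_ancestors(tree, cents, eps = eps)
  list(tree = tree, markers = mk, locations = loc, newick = tree_newick(tree))
}
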