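# Synthetic Visium-like data with planted clone geography, allele-specific
# CNAs, normal admixture and phasing switch errors, plus full ground truth.
# Every downstream module can be exercised against these datasets without
# any external download.

#' Simulation configuration
#'
#' Defaults emulate a modest Visium section: a hexagonal lattice of spots
#' (6-neighbour geometry, 100-unit pitch standing in for the 55 um spot
#' pitch), three tumor clones laid out as Voronoi territories, a genome of
#' 100 bins on 5 chromosomes with 10 SNPs and 5 genes per bin, ~3,000
#' transcript UMIs and ~250 SNP-covering UMIs per spot (the scale of the
#' published Visium datasets), negative-binomial transcript noise,
#' beta-binomial allele noise, and block switch errors at rate 0.02 in the
#' population phasing.
#'
#' @param n_rows,n_cols lattice dimensions per slice.
#' @param n_slices number of slices.
#' @param z_spacing z distance between consecutive slices.
#' @param M number of tumor clones.
#' @param n_chrom,bins_per_chrom genome layout.
#' @param snps_per_bin,genes_per_bin per-bin content.
#' @param transcripts_per_spot,allele_umis_per_spot mean sequencing depths.
#' @param tumor_purity scalar or per-spot tumor proportion of tumor-clone
#'   territories (1 = pure).
#' @param normal_region also plant a normal (diploid, balanced) territory,
#'   as real tumor sections contain substantial normal tissue; its spots
#'   have clone label 0 and tumor proportion 0 in the truth.
#' @param normal_frac fraction of spots in the normal territory (the spots
#'   nearest a seeded location; default 0.2).
#' @param switch_error_rate per-SNP probability that the population phasing
#'   switches haplotype blocks.
#' @param nb_phi negative-binomial dispersion (variance = mu + phi mu^2).
#' @param bb_tau beta-binomial concentration.
#' @param n_loh number of planted LOH marker segments on the clone tree.
#' @param marker_bins genomic bins per planted event (default 8, i.e.
#'   chromosome-arm scale: large CNAs dominate real tumor genomes).
#' @param mirrored also plant one mirrored segment (clone 1 gains the A
#'   haplotype, clone 2 the B haplotype) when M >= 2.
#' @param seed RNG seed.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_rows = 25, n_cols = 20, n_slices = 1, z_spacing = 100,
                       M = 3, n_chrom = 5, bins_per_chrom = 20,
                       snps_per_bin = 10, genes_per_bin = 5,
                       transcripts_per_spot = 3000, allele_umis_per_spot = 250,
                       tumor_purity = 1, normal_region = TRUE,
                       normal_frac = 0.2, switch_error_rate = 0.02,
                       nb_phi = 0.1, bb_tau = 30, n_loh = 5,
                       marker_bins = 8, mirrored = TRUE, seed = 0) {
  structure(as.list(environment()), class = "sim_config")
}

# hexagonal lattice coordinates: odd rows offset by half a pitch
hex_lattice <- function(n_rows, n_cols, pitch = 100) {
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  x <- (g$col - 1) * pitch + ifelse(g$row %% 2 == 0, pitch / 2, 0)
  y <- (g$row - 1) * pitch * sqrt(3) / 2
  cbind(x = x, y = y)
}

#' Drop LOH markers along a random clone tree
#'
#' Generates a random rooted binary tree over \code{M} clones and assigns
#' \code{n_loh} disjoint genomic segments as irreversible LOH markers:
#' the first \code{M} markers go to the leaves' pendant edges (one private
#' event per clone, so the planted clone structure is identifiable — every
#' clone differs from every other clone and from normal tissue), the rest
#' to uniformly chosen tree edges (the clone-MRCA stem included). Every
#' clone below a marker's edge loses one haplotype over the segment, as
#' either a deletion LOH (1, 0) or a copy-neutral LOH (2, 0). Remaining
#' bins stay diploid (1, 1).
#'
#' @param M number of clones.
#' @param n_bins total genomic bins.
#' @param n_loh number of markers (>= M - 1 recommended so every clone
#'   split is witnessed).
#' @param chrom_of per-bin chromosome labels (markers stay within one
#'   chromosome).
#' @param seg_bins bins per marker segment (default 4).
#' @param seed RNG seed.
#' @return list with \code{A}, \code{B} (bin x clone), \code{parent} (true
#'   tree parent vector, leaves first), and \code{markers} table.
#' @export
simulate_tree_profiles <- function(M, n_bins, n_loh, chrom_of = NULL,
                                   seg_bins = 4, seed = 0) {
  set.seed(seed)
  if (is.null(chrom_of)) chrom_of <- rep("chr1", n_bins)
  # random rooted binary tree by sequential leaf insertion
  if (M == 1) {
    parent <- c(0L)
  } else {
    parent <- rep(0L, 2L * M - 1L)
    parent[1] <- parent[2] <- M + 1L
    used <- M + 1L
    if (M >= 3) for (k in 3:M) {
      active <- c(seq_len(k - 1L), (M + 1L):used)
      v <- active[sample.int(length(active), 1L)]
      newint <- used + 1L
      if (parent[v] == 0L) { parent[newint] <- 0L } else parent[newint] <- parent[v]
      parent[v] <- newint; parent[k] <- newint
      used <- newint
    }
    parent <- parent[seq_len(used)]
  }
  leaves_below <- function(v) {
    if (v <= M) return(v)
    unlist(lapply(which(parent == v), leaves_below))
  }
  # disjoint marker segments, each within one chromosome
  slots <- split(seq_len(n_bins), chrom_of)[unique(chrom_of)]
  avail <- unlist(lapply(slots, function(ix) {
    starts <- ix[seq_len(max(length(ix) - seg_bins + 1L, 0L))]
    starts
  }))
  chosen <- integer(0)
  markers <- NULL
  A <- matrix(1L, n_bins, M); B <- matrix(1L, n_bins, M)
  nodes <- seq_along(parent)             # gain edge = edge into this node
  for (j in seq_len(n_loh)) {
    blocked <- unique(unlist(lapply(chosen, function(c_)
      (c_ - seg_bins + 1L):(c_ + seg_bins - 1L))))
    ok <- setdiff(avail, blocked)
    if (!length(ok)) break
    s <- ok[sample.int(length(ok), 1L)]
    seg <- s:(s + seg_bins - 1L)
    chosen <- c(chosen, seg)
    # markers 1..M are private to one clone each; the rest fall anywhere
    v <- if (j <= M) j else nodes[sample.int(length(nodes), 1L)]
    carriers <- leaves_below(v)
    hap <- sample(c("A", "B"), 1L)
    cnloh <- stats::runif(1) < 0.5
    for (m in carriers) {
      if (hap == "B") { B[seg, m] <- 0L; A[seg, m] <- if (cnloh) 2L else 1L }
      else            { A[seg, m] <- 0L; B[seg, m] <- if (cnloh) 2L else 1L }
    }
    markers <- rbind(markers, data.frame(
      bin_start = seg[1], bin_end = seg[length(seg)], lost = hap,
      cnloh = cnloh, node = v,
      carriers = paste(sort(carriers), collapse = ",")))
  }
  list(A = A, B = B, parent = parent, markers = markers)
}

#' Simulate a spatial transcriptomics dataset with known ground truth
#'
#' Generates a [raw_bundle()] following the package's own generative model:
#' clone territories are Voronoi cells of randomly seeded spots (contiguous
#' in 3D when several slices are present); per-clone allele-specific copy
#' numbers come from [simulate_tree_profiles()] (plus an optional mirrored
#' segment); transcript counts are negative binomial with per-gene baseline
#' weights scaled by the admixture-mixed relative copy number; allele
#' counts are beta-binomial around the admixture-mixed BAF of the spot's
#' clone; and the population phasing of each SNP is corrupted by a
#' first-order Markov switch process, producing block switch errors.
#'
#' @param config a [sim_config()].
#' @return list with \code{bundle} (a [raw_bundle()]) and \code{truth}
#'   (clone labels \code{ell}, per-spot \code{theta}, true per-bin
#'   \code{A}/\code{B}, per-SNP phase \code{h} (1 = population haplotype 1
#'   is the B haplotype), \code{snp_bin}, \code{gene_bin}, the generating
#'   tree, marker table, and the mirrored segment if planted).
#' @export
simulate_srt <- function(config = sim_config()) {
  cf <- config
  set.seed(cf$seed)
  n_bins <- cf$n_chrom * cf$bins_per_chrom
  chrom_of <- rep(paste0("chr", seq_len(cf$n_chrom)), each = cf$bins_per_chrom)
  prof <- simulate_tree_profiles(cf$M, n_bins, cf$n_loh, chrom_of,
                                 seg_bins = cf$marker_bins,
                                 seed = cf$seed + 1L)
  A <- prof$A; B <- prof$B
  mirror_seg <- NULL
  if (cf$mirrored && cf$M >= 2) {
    used <- unique(unlist(lapply(seq_len(nrow(prof$markers %||% data.frame())),
      function(i) prof$markers$bin_start[i]:prof$markers$bin_end[i])))
    free <- setdiff(seq_len(n_bins), used)
    brk <- cumsum(c(1, diff(free) != 1 |
                      chrom_of[free][-1] != chrom_of[free][-length(free)]))
    runs <- split(free, brk)
    runs <- Filter(function(r) length(r) >= cf$marker_bins, runs)
    if (length(runs)) {
      seg <- runs[[length(runs)]][seq_len(cf$marker_bins)]
      A[seg, 1] <- 2L; B[seg, 1] <- 1L
      A[seg, 2] <- 1L; B[seg, 2] <- 2L
      mirror_seg <- seg
    }
  }

  # spots: hex lattice per slice, clone labels by 3D Voronoi seeds
  one <- hex_lattice(cf$n_rows, cf$n_cols)
  n_per <- nrow(one)
  S <- do.call(rbind, replicate(cf$n_slices, one, simplify = FALSE))
  slice_id <- rep(paste0("s", seq_len(cf$n_slices)), each = n_per)
  z <- (match(slice_id, unique(slice_id)) - 1) * cf$z_spacing
  N <- nrow(S)
  coords3 <- cbind(S, z)
  seeds <- sample.int(N, cf$M + as.integer(isTRUE(cf$normal_region)))
  d2 <- vapply(seeds[seq_len(cf$M)], function(sd)
    rowSums((coords3 - matrix(coords3[sd, ], N, 3, byrow = TRUE))^2),
    numeric(N))
  ell <- max.col(-d2, ties.method = "first")
  if (isTRUE(cf$normal_region)) {
    # normal territory: the normal_frac of spots nearest its seed (label 0)
    dn <- rowSums((coords3 - matrix(coords3[seeds[cf$M + 1L], ], N, 3,
                                    byrow = TRUE))^2)
    ell[order(dn)[seq_len(ceiling(cf$normal_frac * N))]] <- 0L
  }
  theta <- rep_len(cf$tumor_purity, N)
  theta[ell == 0L] <- 0

  # genome annotation: SNP and gene positions laid out within bins
  bin_span <- 1e6
  snp_bin <- rep(seq_len(n_bins), each = cf$snps_per_bin)
  pos_in_bin <- (seq_len(cf$snps_per_bin)) * (bin_span / (cf$snps_per_bin + 2))
  snp_pos <- ((snp_bin - 1) %% cf$bins_per_chrom) * bin_span +
    rep(pos_in_bin, n_bins)
  snp_chrom <- chrom_of[snp_bin]
  G_snp <- length(snp_bin)
  # genes tile each bin so simulated SNPs are genic
  gene_bin <- rep(seq_len(n_bins), each = cf$genes_per_bin)
  gwidth <- bin_span / cf$genes_per_bin
  gpos <- (seq_len(cf$genes_per_bin) - 1) * gwidth
  gene_start <- ((gene_bin - 1) %% cf$bins_per_chrom) * bin_span +
    rep(gpos, n_bins)
  G_gene <- length(gene_bin)
  gene_index <- data.frame(
    gene = sprintf("g%04d", seq_len(G_gene)), chrom = chrom_of[gene_bin],
    start = gene_start, end = gene_start + gwidth, ig = FALSE, hla = FALSE)
  snp_index <- data.frame(chrom = snp_chrom, pos = snp_pos, phase = 0L)

  # per-gene / per-SNP baseline weights (Dirichlet via gamma)
  w_gene <- stats::rgamma(G_gene, shape = 2, rate = 1); w_gene <- w_gene / sum(w_gene)
  w_snp <- stats::rgamma(G_snp, shape = 2, rate = 1); w_snp <- w_snp / sum(w_snp)

  tot_cn <- (A + B) / 2                       # relative copy number, bins x M
  baf <- B / (A + B)                          # true B-haplotype fraction
  X0 <- matrix(0L, G_gene, N)
  Y0 <- matrix(0L, G_snp, N)
  D0 <- matrix(0L, G_snp, N)
  # block switch errors in the population phasing: e = 1 means the
  # population haplotype 1 actually tracks the A haplotype there
  e <- integer(G_snp)
  for (ch in unique(snp_chrom)) {
    idx <- which(snp_chrom == ch)
    flips <- stats::runif(length(idx)) < cf$switch_error_rate
    st <- as.integer(stats::runif(1) < 0.5)
    ei <- integer(length(idx))
    for (i in seq_along(idx)) { if (flips[i]) st <- 1L - st; ei[i] <- st }
    e[idx] <- ei
  }
  h_true <- ifelse(e == 0L, 1L, 2L)

  depth_fac <- exp(stats::rnorm(N, 0, 0.15))
  for (m in c(if (any(ell == 0L)) 0L, seq_len(cf$M))) {
    sp <- which(ell == m)
    if (!length(sp)) next
    for (s in sp) {
      if (m == 0L) {                     # normal territory: diploid balanced
        re_bin <- rep(1, n_bins)
        be_bin <- rep(0.5, n_bins)
      } else {
        re_bin <- rdr_eff(tot_cn[, m], theta[s])
        be_bin <- baf_eff(baf[, m], tot_cn[, m], theta[s])
      }
      wg <- w_gene * re_bin[gene_bin]
      mu_g <- cf$transcripts_per_spot * depth_fac[s] * wg / sum(wg)
      X0[, s] <- rnbinom_mu_phi(G_gene, mu_g, cf$nb_phi)
      ws <- w_snp * re_bin[snp_bin]
      mu_s <- cf$allele_umis_per_spot * depth_fac[s] * ws / sum(ws)
      d <- stats::rpois(G_snp, mu_s)
      bafs <- pmin(pmax(be_bin[snp_bin], 1e-6), 1 - 1e-6)
      yB <- rbetabinom(G_snp, d, cf$bb_tau * bafs, cf$bb_tau * (1 - bafs))
      Y0[, s] <- ifelse(e == 0L, yB, d - yB)
      D0[, s] <- d
    }
  }
  barcodes <- sprintf("%s_spot%04d", slice_id, rep(seq_len(n_per), cf$n_slices))
  colnames(X0) <- colnames(Y0) <- colnames(D0) <- barcodes
  bundle <- raw_bundle(X0, Y0, D0, S, slice_id, snp_index, gene_index)
  list(bundle = bundle,
       truth = list(ell = ell, theta = theta, A = A, B = B, h = h_true,
                    snp_bin = snp_bin, gene_bin = gene_bin,
                    tree_parent = prof$parent, markers = prof$markers,
                    mirror_seg = mirror_seg, chrom_of = chrom_of,
                    w_gene = w_gene, w_snp = w_snp))
}

#' Write a simulated bundle in the on-disk layout [read_bundle()] expects
#'
#' @param sim output of [simulate_srt()].
#' @param dir output directory (created).
#' @return invisibly, the slice path list suitable for [read_bundle()].
#' @export
write_bundle <- function(sim, dir) {
  bundle <- sim$bundle
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slices <- list()
  for (sl in unique(bundle$slice_id)) {
    idx <- which(bundle$slice_id == sl)
    bc <- sub(paste0("^", sl, "_"), "", colnames(bundle$X0)[idx])
    cdir <- file.path(dir, sl, "counts"); adir <- file.path(dir, sl, "alleles")
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    dir.create(adir, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(as(bundle$X0[, idx, drop = FALSE], "CsparseMatrix"),
                    file.path(cdir, "matrix.mtx"))
    writeLines(bundle$gene_index$gene, file.path(cdir, "features.tsv"))
    writeLines(bc, file.path(cdir, "barcodes.tsv"))
    Matrix::writeMM(as(bundle$Y0[, idx, drop = FALSE], "CsparseMatrix"),
                    file.path(adir, "allele_hap1.mtx"))
    Matrix::writeMM(as(bundle$D0[, idx, drop = FALSE], "CsparseMatrix"),
                    file.path(adir, "allele_total.mtx"))
    data.table::fwrite(bundle$snp_index, file.path(adir, "snps.tsv"), sep = "\t")
    writeLines(bc, file.path(adir, "barcodes.tsv"))
    pos <- data.frame(barcode = bc, x = bundle$S[idx, 1], y = bundle$S[idx, 2])
    data.table::fwrite(pos, file.path(dir, sl, "positions.csv"))
    slices[[sl]] <- list(counts = cdir, alleles = adir,
                         positions = file.path(dir, sl, "positions.csv"))
  }
  data.table::fwrite(bundle$gene_index, file.path(dir, "annotation.tsv"), sep = "\t")
  invisible(list(slices = slices, annotation = file.path(dir, "annotation.tsv")))
}
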