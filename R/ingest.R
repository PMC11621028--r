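#' Raw spatial allele-count bundle
#'
#' Container for the inputs to the pipeline: a gene x spot transcript count
#' matrix \code{X0}, SNP x spot allele-count matrices \code{Y0} (UMIs
#' supporting population-phased haplotype 1) and \code{D0} (total UMIs at the
#' SNP), spot coordinates \code{S}, per-spot slice labels, and SNP/gene
#' annotation tables.
#'
#' @param X0 gene x spot integer count matrix (dense or \pkg{Matrix} sparse).
#' @param Y0,D0 SNP x spot allele count matrices; \code{0 <= Y0 <= D0}.
#' @param S spot x 2 numeric coordinate matrix.
#' @param slice_id character/factor vector of per-spot slice labels.
#' @param snp_index data.frame with columns \code{chrom}, \code{pos} (1-based)
#'   and \code{phase} (0/1 population-phase flag), one row per SNP, sorted by
#'   (chrom, pos).
#' @param gene_index data.frame with columns \code{gene}, \code{chrom},
#'   \code{start}, \code{end} and logical \code{ig}, \code{hla} flags.
#' @return an object of class \code{raw_bundle}.
#' @export
raw_bundle <- function(X0, Y0, D0, S, slice_id, snp_index, gene_index) {
  tocsc <- function(m) {
    if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
    as(as(m, "dMatrix"), "CsparseMatrix")
  }
  X0 <- tocsc(X0); Y0 <- tocsc(Y0); D0 <- tocsc(D0)
  n <- ncol(X0)
  stopifnot(ncol(Y0) == n, ncol(D0) == n, nrow(S) == n, length(slice_id) == n)
  stopifnot(nrow(Y0) == nrow(D0), nrow(Y0) == nrow(snp_index))
  stopifnot(nrow(X0) == nrow(gene_index))
  if (any(Y0@x < 0) || any(D0@x < 0) || any(X0@x < 0))
    stop("counts must be nonnegative")
  if (any((D0 - Y0)@x < 0)) stop("Y0 must be <= D0 elementwise")
  ord <- order(snp_index$chrom, snp_index$pos)
  if (is.unsorted(ord)) {
    snp_index <- snp_index[ord, , drop = FALSE]
    Y0 <- Y0[ord, , drop = FALSE]
    D0 <- D0[ord, , drop = FALSE]
  }
  structure(list(
    X0 = X0, Y0 = Y0, D0 = D0,
    S = as.matrix(S), slice_id = as.character(slice_id),
    snp_index = as.data.frame(snp_index),
    gene_index = as.data.frame(gene_index)
  ), class = "raw_bundle")
}

#' @export
print.raw_bundle <- function(x, ...) {
  cat(sprintf("raw_bundle: %d genes x %d spots, %d SNPs, %d slice(s)\n",
              nrow(x$X0), ncol(x$X0), nrow(x$Y0), length(unique(x$slice_id))))
  invisible(x)
}

n_spots <- function(bundle) ncol(bundle$X0)

read_tsv_quiet <- function(path, ...) {
  as.data.frame(data.table::fread(path, header = FALSE, ...))
}

#' Read a bundle from on-disk matrices
#'
#' Reads the standard file layout into a [raw_bundle()]: per slice a 10x-style
#' gene-count directory (\code{matrix.mtx}, \code{features.tsv},
#' \code{barcodes.tsv}), an allele-count directory (\code{allele_hap1.mtx},
#' \code{allele_total.mtx}, \code{snps.tsv} with columns CHROM POS PHASE,
#' \code{barcodes.tsv}) and a coordinate CSV (\code{barcode,x,y} or the
#' Visium tissue-positions dialect), plus a shared gene annotation table
#' (4+ column TSV: gene, chrom, start, end[, ig, hla]). Spots are restricted
#' to the barcodes shared by the gene-count and allele-count inputs; matrices
#' are concatenated across slices.
#'
#' @param slices named list; each element a list with paths \code{counts},
#'   \code{alleles}, \code{positions}.
#' @param annotation path to the gene annotation TSV.
#' @return a [raw_bundle()].
#' @export
read_bundle <- function(slices, annotation) {
  ann <- as.data.frame(data.table::fread(annotation, header = TRUE))
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(ann))) stop("annotation must have columns gene, chrom, start, end")
  if (is.null(ann$ig)) ann$ig <- FALSE
  if (is.null(ann$hla)) ann$hla <- FALSE

  per_slice <- lapply(names(slices), function(sl) {
    p <- slices[[sl]]
    for (f in c("counts", "alleles", "positions"))
      if (!file.exists(p[[f]]) && !dir.exists(p[[f]])) stop("missing input: ", p[[f]])
    X <- Matrix::readMM(file.path(p$counts, "matrix.mtx"))
    feats <- read_tsv_quiet(file.path(p$counts, "features.tsv"))[[1]]
    bc_x <- read_tsv_quiet(file.path(p$counts, "barcodes.tsv"))[[1]]
    if (nrow(X) != length(feats) || ncol(X) != length(bc_x))
      stop("gene count matrix dimensions do not match features/barcodes")
    Y <- Matrix::readMM(file.path(p$alleles, "allele_hap1.mtx"))
    D <- Matrix::readMM(file.path(p$alleles, "allele_total.mtx"))
    snps <- as.data.frame(data.table::fread(file.path(p$alleles, "snps.tsv"), header = TRUE))
    bc_a <- read_tsv_quiet(file.path(p$alleles, "barcodes.tsv"))[[1]]
    if (!identical(dim(Y), dim(D))) stop("allele matrices must have identical dimensions")
    if (nrow(Y) != nrow(snps) || ncol(Y) != length(bc_a))
      stop("allele matrix dimensions do not match snps/barcodes")
    pos <- as.data.frame(data.table::fread(p$positions, header = TRUE))
    if (all(c("barcode", "x", "y") %in% names(pos))) {
      coords <- pos[, c("barcode", "x", "y")]
    } else if (ncol(pos) >= 6) {
      # Visium tissue_positions dialect: barcode, in_tissue, array_row,
      # array_col, pxl_row, pxl_col
      coords <- data.frame(barcode = pos[[1]], x = pos[[5]], y = pos[[6]])
    } else stop("unrecognised coordinate file format")
    shared <- intersect(intersect(bc_x, bc_a), coords$barcode)
    if (length(shared) == 0) stop("no overlapping barcodes between inputs in slice ", sl)
    X <- X[, match(shared, bc_x), drop = FALSE]
    Y <- Y[, match(shared, bc_a), drop = FALSE]
    D <- D[, match(shared, bc_a), drop = FALSE]
    coords <- coords[match(shared, coords$barcode), ]
    list(X = X, Y = Y, D = D, genes = feats, snps = snps,
         S = as.matrix(coords[, c("x", "y")]), barcodes = paste0(sl, "_", shared),
         slice = rep(sl, length(shared)))
  })

  genes <- per_slice[[1]]$genes
  snps <- per_slice[[1]]$snps
  for (ps in per_slice[-1]) {
    if (!identical(ps$genes, genes)) stop("slices must share an identical feature list")
    if (!identical(ps$snps, snps)) stop("slices must share an identical SNP list")
  }
  X0 <- do.call(cbind, lapply(per_slice, `[[`, "X"))
  Y0 <- do.call(cbind, lapply(per_slice, `[[`, "Y"))
  D0 <- do.call(cbind, lapply(per_slice, `[[`, "D"))
  colnames(X0) <- colnames(Y0) <- colnames(D0) <-
    unlist(lapply(per_slice, `[[`, "barcodes"))
  S <- do.call(rbind, lapply(per_slice, `[[`, "S"))
  slice_id <- unlist(lapply(per_slice, `[[`, "slice"))
  names(snps) <- tolower(names(snps))
  snp_index <- data.frame(chrom = snps$chrom, pos = snps$pos,
                          phase = snps$phase)
  gi <- ann[match(genes, ann$gene), ]
  if (anyNA(gi$gene)) stop("annotation is missing ", sum(is.na(gi$gene)), " gene(s)")
  raw_bundle(X0, Y0, D0, S, slice_id, snp_index, gi)
}

subset_bundle <- function(bundle, spots = NULL, genes = NULL, snps = NULL) {
  if (!is.null(spots)) {
    bundle$X0 <- bundle$X0[, spots, drop = FALSE]
    bundle$Y0 <- bundle$Y0[, spots, drop = FALSE]
    bundle$D0 <- bundle$D0[, spots, drop = FALSE]
    bundle$S <- bundle$S[spots, , drop = FALSE]
    bundle$slice_id <- bundle$slice_id[spots]
  }
  if (!is.null(genes)) {
    bundle$X0 <- bundle$X0[genes, , drop = FALSE]
    bundle$gene_index <- bundle$gene_index[genes, , drop = FALSE]
  }
  if (!is.null(snps)) {
    bundle$Y0 <- bundle$Y0[snps, , drop = FALSE]
    bundle$D0 <- bundle$D0[snps, , drop = FALSE]
    bundle$snp_index <- bundle$snp_index[snps, , drop = FALSE]
  }
  bundle
}

filter_report <- function(kind, removed, reason) {
  if (!length(removed))
    return(data.frame(kind = character(0), item = character(0),
                      reason = character(0)))
  data.frame(kind = rep_len(kind, length(removed)),
             item = as.character(removed),
             reason = rep_len(reason, length(removed)))
}

#' Remove low-coverage spots
#'
#' Drops spots whose total transcript UMI count or total SNP-covering UMI
#' count falls below a threshold (default 50 for both, the value used for
#' all datasets in the original analyses).
#'
#' @param bundle a [raw_bundle()].
#' @param min_umi minimum transcript UMIs per spot.
#' @param min_snp_umi minimum SNP-covering UMIs per spot.
#' @return list with elements \code{bundle} (filtered) and \code{report}.
#' @export
filter_spots <- function(bundle, min_umi = 50, min_snp_umi = 50) {
  stopifnot(min_umi >= 0, min_snp_umi >= 0)
  tot_x <- Matrix::colSums(bundle$X0)
  tot_d <- Matrix::colSums(bundle$D0)
  keep <- tot_x >= min_umi & tot_d >= min_snp_umi
  if (!any(keep)) stop("all spots removed; lower min_umi/min_snp_umi")
  reasons <- ifelse(tot_x < min_umi, "low_umi", "low_snp_umi")
  ids <- colnames(bundle$X0) %||% as.character(seq_along(keep))
  report <- filter_report("spot", ids[!keep], reasons[!keep])
  list(bundle = subset_bundle(bundle, spots = which(keep)), report = report)
}

#' Default high-expression outlier detector
#'
#' Flags genes whose total expression is anomalously high relative to a local
#' neighbourhood in log expression space: a gene is an outlier when its mean
#' distance to its k nearest neighbours (in log10 total counts) exceeds the
#' population by a large factor, keeping at most \code{contamination} of genes
#' flagged and only flagging genes above the median. Plugs into
#' [filter_genes()]; any function mapping a vector of per-gene totals to a
#' logical vector can be substituted.
#'
#' @param k neighbourhood size.
#' @param contamination maximum fraction of genes flagged.
#' @return a function \code{totals -> logical}.
#' @export
lof_outlier_detector <- function(k = 20, contamination = 0.005) {
  function(totals) {
    n <- length(totals)
    out <- rep(FALSE, n)
    if (n < 5 || contamination <= 0) return(out)
    lx <- log10(totals + 1)
    kk <- min(k, n - 1L)
    srt <- sort(lx)
    # mean distance to the kk nearest order-statistic neighbours
    score <- vapply(lx, function(v) {
      d <- sort(abs(srt - v))[seq_len(kk + 1L)]  # includes self (0)
      mean(d[-1L])
    }, numeric(1))
    med <- stats::median(score)
    mad_ <- stats::mad(score) + 1e-12
    cand <- which(score > med + 6 * mad_ & lx > stats::median(lx))
    n_max <- floor(contamination * n)
    if (length(cand) > n_max) cand <- cand[order(score[cand], decreasing = TRUE)][seq_len(n_max)]
    out[cand] <- TRUE
    out
  }
}

#' Remove uninformative genes
#'
#' Applies three independent gene filters: (1) genes expressed (count > 0) in
#' fewer than \code{min_frac_spots} of spots (default 0.5\%); (2) genes flagged
#' by the high-expression outlier detector; (3) immunoglobulin genes and genes
#' in HLA regions (flags from the annotation), which vary strongly without
#' CNAs. The retained set is the intersection of the three rules.
#'
#' @param bundle a [raw_bundle()].
#' @param min_frac_spots fraction of spots a gene must be expressed in.
#' @param outlier_detector function mapping per-gene totals to a logical
#'   outlier flag; see [lof_outlier_detector()].
#' @return list with elements \code{bundle} and \code{report}.
#' @export
filter_genes <- function(bundle, min_frac_spots = 0.005,
                         outlier_detector = lof_outlier_detector()) {
  stopifnot(min_frac_spots >= 0, min_frac_spots <= 1)
  nspot <- n_spots(bundle)
  frac <- Matrix::rowSums(bundle$X0 > 0) / nspot
  totals <- Matrix::rowSums(bundle$X0)
  low <- frac < min_frac_spots
  hi <- outlier_detector(totals)
  ighla <- as.logical(bundle$gene_index$ig) | as.logical(bundle$gene_index$hla)
  keep <- !low & !hi & !ighla
  if (!any(keep)) warning("all genes removed by gene filters")
  reason <- ifelse(low, "low_expression", ifelse(hi, "expression_outlier", "ig_hla"))
  report <- filter_report("gene", bundle$gene_index$gene[!keep], reason[!keep])
  list(bundle = subset_bundle(bundle, genes = which(keep)), report = report)
}

#' Remove intergenic and HLA-region SNPs
#'
#' Keeps SNPs that fall inside the closed interval [start, end] of at least
#' one retained gene on the same chromosome and inside no HLA-flagged gene.
#'
#' @param bundle a [raw_bundle()] (gene filtering should run first so that
#'   "retained gene" reflects the final gene set).
#' @return list with elements \code{bundle} and \code{report}.
#' @export
filter_snps <- function(bundle) {
  gi <- bundle$gene_index
  si <- bundle$snp_index
  genic <- logical(nrow(si))
  in_hla <- logical(nrow(si))
  for (ch in unique(si$chrom)) {
    s_idx <- which(si$chrom == ch)
    g <- gi[gi$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    for (i in s_idx) {
      hit <- si$pos[i] >= g$start & si$pos[i] <= g$end
      genic[i] <- any(hit & !as.logical(g$hla))
      in_hla[i] <- any(hit & as.logical(g$hla))
    }
  }
  keep <- genic & !in_hla
  reason <- ifelse(in_hla, "hla_region", "intergenic")
  ids <- paste0(si$chrom, ":", si$pos)
  report <- filter_report("snp", ids[!keep], reason[!keep])
  list(bundle = subset_bundle(bundle, snps = which(keep)), report = report)
}

#' Apply all quality filters
#'
#' Convenience wrapper running [filter_spots()], [filter_genes()] and
#' [filter_snps()] in order and concatenating their reports.
#'
#' @inheritParams filter_spots
#' @inheritParams filter_genes
#' @return list with elements \code{bundle} and \code{report}.
#' @export
apply_filters <- function(bundle, min_umi = 50, min_snp_umi = 50,
                          min_frac_spots = 0.005,
                          outlier_detector = lof_outlier_detector()) {
  a <- filter_spots(bundle, min_umi, min_snp_umi)
  b <- filter_genes(a$bundle, min_frac_spots, outlier_detector)
  c_ <- filter_snps(b$bundle)
  list(bundle = c_$bundle, report = rbind(a$report, b$report, c_$report))
}
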