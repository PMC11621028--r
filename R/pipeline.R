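#' Pipeline configuration
#'
#' Collects every stage threshold with its default: spot/gene/SNP quality
#' filters (50 UMIs, 50 SNP UMIs, 0.5\% of spots), phasing (5 BAF clusters),
#' binning (300 allele UMIs per bin), baseline (5 BAF clusters, ASE level
#' 0.05), purity (LOH threshold 0.2, minimum per-spot support 10), clone
#' inference (5 initial clones, 7 states, coherence 2.0, merge threshold
#' 0.02), integer copy numbers (max 6 per haplotype), phylogeography
#' (3 bins / 100 UMIs per marker) and the SNV cascade (alt >= 5, VAF > 0.3,
#' normal depth 15).
#'
#' @param ... overrides of any default listed above.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_umi = 50, min_snp_umi = 50, min_frac_spots = 0.005,
    K_phase = 5, min_bin_total = 300,
    n_baf_clusters = 5, ase_alpha = 0.05,
    purity_mode = FALSE, loh_threshold = 0.2, min_loh_support = 10,
    M_init = 5, K = 7, beta = 2.0, normal_clone = TRUE,
    merge_threshold = 0.02,
    max_cn = 6, ploidy_candidates = c(1.5, 2, 2.5, 3, 3.5, 4),
    min_marker_bins = 3, min_marker_umis = 100,
    min_alt = 5, min_vaf = 0.3, normal_depth_min = 15,
    k_spatial = 6, expr_weight = 0,
    seed = 0)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full inference pipeline
#'
#' Executes the stages in order on a [raw_bundle()]: quality filters,
#' pseudobulk phasing and binning, baseline/normal identification, an
#' optional BAF-only pass for LOH detection and per-spot tumor proportions
#' (used to pin normal spots and mix emissions), joint clone/state
#' inference with clone merging, integer copy-number assignment, event
#' classification, and LOH phylogeography. When \code{out} is given, stage
#' outputs are written there as plain-text tables plus a JSON run manifest.
#'
#' @param bundle a [raw_bundle()] (already-read input data).
#' @param config a [pipeline_config()].
#' @param W optional slice alignment matrix (or list of matrices).
#' @param z_offsets optional named per-slice z coordinates for 3D
#'   phylogeography.
#' @param out optional output directory.
#' @return list with all stage results: \code{filtered}, \code{phasing},
#'   \code{bg}, \code{baseline}, \code{purity} (if enabled), \code{model},
#'   \code{cn}, \code{events}, \code{phylo}, and \code{config}.
#' @export
run_pipeline <- function(bundle, config = pipeline_config(), W = NULL,
                         z_offsets = NULL, out = NULL) {
  cf <- config
  flt <- apply_filters(bundle, cf$min_umi, cf$min_snp_umi, cf$min_frac_spots)
  bundle <- flt$bundle
  pb <- phase_and_bin(bundle, K_phase = cf$K_phase, min_total = cf$min_bin_total)
  bg <- pb$bg
  graph <- build_graph(bg$S, bg$slice_id, W = W, k_spatial = cf$k_spatial,
                       expr_weight = cf$expr_weight)
  purity <- NULL
  theta <- NULL
  if (cf$purity_mode) {
    loh <- detect_loh(bg, threshold = cf$loh_threshold, K = cf$K)
    if (length(loh$bins)) {
      purity <- estimate_theta(bg, loh, min_support = cf$min_loh_support,
                               graph = graph)
      theta <- purity$theta
    } else warning("no LOH regions found; continuing without tumor proportions")
  }
  base <- baseline_profile(bg, n_clusters = cf$n_baf_clusters, theta = theta,
                           alpha = cf$ase_alpha, seed = cf$seed)
  model <- fit_clones(bg, base, graph, M_init = cf$M_init, K = cf$K,
                      theta = theta, beta = cf$beta,
                      normal_clone = cf$normal_clone,
                      seed = cf$seed, merge = TRUE,
                      sim_threshold = cf$merge_threshold)
  cn <- assign_integer_cn(model$states, model$Z, max_cn = cf$max_cn,
                          ploidy_candidates = cf$ploidy_candidates)
  events <- classify_events(cn, bg$bins)
  phylo <- phylogeography(cn, bg, model$ell,
                          min_bins = cf$min_marker_bins,
                          min_umis = cf$min_marker_umis,
                          z_offsets = z_offsets)
  res <- list(filtered = flt, phasing = pb$phasing, bg = bg, baseline = base,
              purity = purity, model = model, cn = cn, events = events,
              phylo = phylo, config = cf)
  if (!is.null(out)) write_pipeline_outputs(res, out)
  res
}

write_pipeline_outputs <- function(res, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  bg <- res$bg
  data.table::fwrite(data.frame(barcode = colnames(bg$X),
                                slice = bg$slice_id,
                                x = bg$S[, 1], y = bg$S[, 2],
                                clone = res$model$ell),
                     file.path(out, "clone_labels.tsv"), sep = "\t")
  data.table::fwrite(cbind(bg$bins, as.data.frame(res$model$Z) |>
                             stats::setNames(paste0("clone", seq_len(ncol(res$model$Z))))),
                     file.path(out, "states.tsv"), sep = "\t")
  cnw <- cbind(bg$bins,
               stats::setNames(as.data.frame(res$cn$A), paste0("A_clone", seq_len(ncol(res$cn$A)))),
               stats::setNames(as.data.frame(res$cn$B), paste0("B_clone", seq_len(ncol(res$cn$B)))))
  data.table::fwrite(cnw, file.path(out, "integer_cn.tsv"), sep = "\t")
  data.table::fwrite(res$events, file.path(out, "events.tsv"), sep = "\t")
  if (!is.null(res$purity))
    data.table::fwrite(cbind(barcode = colnames(bg$X), res$purity),
                       file.path(out, "tumor_proportion.tsv"), sep = "\t")
  if (!is.null(res$phylo)) {
    writeLines(res$phylo$newick, file.path(out, "tree.nwk"))
    locs <- res$phylo$locations
    jsonlite::write_json(
      stats::setNames(lapply(seq_len(nrow(locs)), function(i) unname(locs[i, ])),
                      paste0(res$phylo$tree$nodes$type, "_", res$phylo$tree$nodes$id)),
      file.path(out, "node_locations.json"), auto_unbox = FALSE, digits = NA)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("spacna")),
    config = unclass(res$config),
    n_spots = ncol(bg$X), n_bins = nrow(bg$bins),
    n_clones = ncol(res$model$Z),
    objective = res$model$objective)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
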