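#' Run the per-subject network pipeline
#'
#' Composes the subject-level stages: fa_max sweep and FLT filter, FAT_max,
#' VR, fiber selection at each VR threshold, endpoint connection counting,
#' binarization, the five matrix kinds (whole / left / right / positive /
#' negative mapping regions) and their graph metrics, plus the
#' low-minus-high threshold differences.  A subject with no fiber spanning
#' the length threshold yields all-zero matrices and metrics with a warning.
#'
#' @param subject_id subject identifier.
#' @param fibers list of [fiber_record()]s.
#' @param parcellation a `parcellation`.
#' @param pos_regions,neg_regions the subject's mapped region-id sets.
#' @param vr_thresholds two increasing VR thresholds (percent).
#' @param flt_mm fiber length threshold (mm).
#' @param grid_step FA threshold grid.
#' @param min_fiber_count binarization cut (edges need strictly more).
#' @param kinds matrix kinds to compute.
#' @return List with `metrics` (data frame: subject, kind, block, ad, eg,
#'   el), `matrices` (per threshold: counts + adjacency), `fat_max`, and a
#'   `manifest` of per-stage fiber counts.
#' @export
run_subject <- function(subject_id, fibers, parcellation,
                        pos_regions = integer(0), neg_regions = integer(0),
                        vr_thresholds = c(25, 50), flt_mm = 30,
                        grid_step = 0.01, min_fiber_count = 3L,
                        kinds = c("whole", "left", "right", "pos", "neg")) {
  stopifnot(length(vr_thresholds) == 2L, diff(vr_thresholds) > 0)
  tract <- subject_tractogram(subject_id, fibers, flt_mm = flt_mm,
                              grid_step = grid_step)
  ids <- parcellation$regions$id
  hemi <- parcellation$regions$hemisphere
  node_sets <- list(
    whole = ids, left = ids[hemi == "L"], right = ids[hemi == "R"],
    pos = intersect(ids, pos_regions), neg = intersect(ids, neg_regions)
  )
  kinds <- match.arg(kinds, names(node_sets), several.ok = TRUE)
  empty <- length(tract$fibers) == 0L
  if (empty) {
    warning("subject ", subject_id, ": no fiber reaches the ", flt_mm,
            " mm length threshold; metrics are all zero")
  } else {
    tract <- compute_vr(tract)
  }
  blocks <- sprintf("vr%g", vr_thresholds)
  matrices <- list()
  manifest <- list(subject = subject_id,
                   fibers_read = length(fibers),
                   dropped_short = tract$n_dropped_short,
                   fat_max = tract$fat_max)
  per_kind <- list()
  for (ti in seq_along(vr_thresholds)) {
    sel <- if (empty) list() else select_fibers(tract, vr_thresholds[ti])
    cc <- count_connections(lapply(sel, function(f) f$points), parcellation)
    adj <- binarize(cc$counts, min_fiber_count)
    matrices[[blocks[ti]]] <- list(counts = cc$counts, adjacency = adj,
                                   vr_threshold = vr_thresholds[ti])
    manifest[[paste0(blocks[ti], "_selected")]] <- length(sel)
    manifest[[paste0(blocks[ti], "_used")]] <- cc$used
    manifest[[paste0(blocks[ti], "_dropped_unassigned")]] <-
      cc$dropped_unassigned
    manifest[[paste0(blocks[ti], "_dropped_same_region")]] <-
      cc$dropped_same_region
    for (k in kinds) {
      sub_adj <- submatrix(adj, node_sets[[k]])
      per_kind[[paste(k, blocks[ti])]] <- c(
        list(kind = k, block = blocks[ti]), graph_metrics(sub_adj)
      )
    }
  }
  rows <- lapply(per_kind, function(x) {
    data.frame(subject = subject_id, kind = x$kind, block = x$block,
               ad = x$ad, eg = x$eg, el = x$el, stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  for (k in kinds) {
    lo <- per_kind[[paste(k, blocks[1L])]]
    hi <- per_kind[[paste(k, blocks[2L])]]
    dd <- diff_metrics(lo, hi)
    metrics <- rbind(metrics, data.frame(
      subject = subject_id, kind = k, block = "diff",
      ad = dd$ad_diff, eg = dd$eg_diff, el = dd$el_diff,
      stringsAsFactors = FALSE
    ))
  }
  rownames(metrics) <- NULL
  list(metrics = metrics, matrices = matrices, fat_max = tract$fat_max,
       manifest = manifest)
}

#' Metrics for every subject of a synthetic cohort
#'
#' @param cohort_obj a `synthetic_cohort` from [make_cohort()].
#' @param kinds matrix kinds to compute (restricting saves time when only
#'   one compartment is analyzed).
#' @return List with `metrics` (stacked data frame), `fat_max` (per-subject
#'   vector), `manifests` (list).
#' @export
cohort_metrics <- function(cohort_obj,
                           kinds = c("whole", "left", "right", "pos", "neg")) {
  cfg <- cohort_obj$config
  res <- lapply(seq_along(cohort_obj$subjects), function(i) {
    s <- cohort_obj$subjects[[i]]
    run_subject(
      s$subject, s$fibers, cohort_obj$parcellation,
      pos_regions = cohort_obj$cohort$pos_regions[[i]],
      neg_regions = cohort_obj$cohort$neg_regions[[i]],
      vr_thresholds = cfg$vr_thresholds, flt_mm = cfg$flt_mm,
      grid_step = cfg$grid_step, min_fiber_count = cfg$min_fiber_count,
      kinds = kinds
    )
  })
  list(
    metrics = do.call(rbind, lapply(res, function(r) r$metrics)),
    fat_max = vapply(res, function(r) r$fat_max, 0),
    manifests = lapply(res, function(r) r$manifest)
  )
}

#' Run a full cohort analysis
#'
#' Simulates (or accepts) a cohort, runs every subject through the network
#' pipeline, computes the group statistics layer, and optionally writes the
#' metric and statistics tables plus a manifest.  Deterministic under a
#' fixed configuration: rerunning writes byte-identical CSVs.
#'
#' @param config a [synthetic_config()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param cohort_obj optional pre-built `synthetic_cohort` (skips
#'   simulation).
#' @param kinds matrix kinds to compute.
#' @return List with `cohort`, `metrics`, `fat_max`, `comparison`
#'   (ANCOVA table), `correlation`, `mapping` (intragroup proportions), and
#'   `manifest`.
#' @export
run_cohort <- function(config, out_dir = NULL, cohort_obj = NULL,
                       kinds = c("whole", "left", "right", "pos", "neg")) {
  if (is.null(cohort_obj)) cohort_obj <- make_cohort(config)
  cm <- cohort_metrics(cohort_obj, kinds = kinds)
  cohort <- cohort_obj$cohort
  cohort$fat_max <- cm$fat_max
  comparison <- group_comparison_table(cm$metrics, cohort)
  correlation <- correlation_table(cm$metrics, cohort)
  mapping <- intragroup_proportions(cohort, cohort_obj$parcellation,
                                    highlight_min = round(2 * config$n_per_group / 3))
  reads <- vapply(cm$manifests, function(m) m$fibers_read, 0L)
  manifest <- list(
    package_version = as.character(utils::packageVersion("vrconn")),
    r_version = R.version.string,
    config = config[setdiff(names(config), "bundles")],
    n_bundles = length(cohort_obj$phantom$bundles),
    n_subjects = nrow(cohort),
    fibers_read_total = sum(reads),
    per_subject = cm$manifests
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metrics_table(cm$metrics, file.path(out_dir, "metrics.csv"))
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    write_metrics_table(comparison, file.path(out_dir, "group_comparison.csv"))
    write_metrics_table(correlation, file.path(out_dir, "aphasia_correlation.csv"))
    write_metrics_table(mapping, file.path(out_dir, "mapping_proportions.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cohort = cohort, metrics = cm$metrics, fat_max = cm$fat_max,
       comparison = comparison, correlation = correlation,
       mapping = mapping, manifest = manifest)
}
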