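#' End-to-end connectivity pipeline
#'
#' Runs the full post-tractography analysis: seed-track selection,
#' optional random subsampling, direct-segment cutting with count and
#' percentage matrices, the seed-target connectivity table with the
#' inclusion threshold, requested voxel projection maps, and structure
#' volumes. Writes all tables as CSV (one-decimal percentages, full
#' precision in parallel JSON), maps as NIfTI, and a \code{report.json}
#' with the stage-count bookkeeping (tracks read, selected, subsampled,
#' segments cut).
#'
#' @param config a named list (or path to a YAML file) with either
#'   \itemize{
#'     \item \code{phantom}: a \code{\link{phantom_spec}} (or
#'       \code{phantom_preset: "paper-like"} with optional
#'       \code{phantom_n_tracks}, \code{phantom_seed} in YAML), or
#'     \item \code{tck}, \code{labels}, \code{structures}: paths to real
#'       inputs;
#'   }
#'   exactly one of the two. Optional: \code{subsample} (track count for
#'   the direct-connection step; NULL = all), \code{subsample_seed}
#'   (default 1), \code{threshold} (inclusion percentage, default 1),
#'   \code{voxmaps} (list of \code{c(structure, target)} pairs),
#'   \code{out_dir} (default: no files written).
#' @return A report list: stage counts, tables, volumes, output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_phantom <- !is.null(config$phantom) || !is.null(config$phantom_preset)
  has_real <- !is.null(config$tck) || !is.null(config$labels) ||
    !is.null(config$structures)
  if (has_phantom == has_real)
    stopf("config must provide exactly one of phantom spec or real inputs")
  threshold <- config$threshold %||% 1
  if (threshold < 0 || threshold > 100)
    stopf("threshold must be in [0, 100]")
  if (!is.null(config$subsample) && config$subsample < 0)
    stopf("subsample must be >= 0")

  truth <- NULL
  if (has_phantom) {
    spec <- config$phantom
    if (is.null(spec)) {
      if (!identical(config$phantom_preset, "paper-like"))
        stopf("unknown phantom preset: %s", config$phantom_preset)
      spec <- paper_like_spec(
        n_tracks = config$phantom_n_tracks %||% 1100,
        rng_seed = config$phantom_seed %||% 1L)
    }
    ph <- make_phantom(spec)
    tract <- ph$tract; volume <- ph$volume; structures <- ph$structures
    truth <- ph$truth
  } else {
    if (is.null(config$tck) || is.null(config$labels) ||
        is.null(config$structures))
      stopf("real-input config needs tck, labels and structures paths")
    tract <- read_tck(config$tck)
    volume <- read_label_volume(config$labels)
    structures <- read_structure_set(config$structures)
  }

  sel <- select_seed_tracks(tract, volume, structures)
  direct <- direct_connectivity(sel$sequences, structures,
                                subsample = config$subsample,
                                seed = config$subsample_seed %||% 1L)
  tab <- seed_target_table(sel$sequences, structures)
  tab_kept <- apply_inclusion_threshold(tab, threshold)
  vols <- vapply(structures$core_five, function(nm)
    structure_volume(volume, resolve_labels(structures, nm)), 0)
  maps <- lapply(config$voxmaps, function(vm)
    voxel_projection_map(tract, volume, structures, vm[[1L]], vm[[2L]],
                         ids = sel$selected))

  report <- list(
    n_tracks_read = n_streamlines(tract),
    n_selected = length(sel$selected),
    n_subsampled = length(direct$ids),
    n_direct_segments = nrow(direct$segments),
    threshold = threshold,
    dropped_targets = attr(tab_kept, "dropped"),
    seeds = list(phantom = if (has_phantom) spec$rng_seed,
                 subsample = config$subsample_seed %||% 1L),
    volumes_mm3 = vols)

  out <- list(report = report, selection = sel, direct = direct,
              table = tab, table_thresholded = tab_kept, maps = maps,
              volumes = vols, truth = truth,
              structures = structures, volume = volume)

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    write_percent_csv <- function(m, path, diag_x = FALSE) {
      fm <- formatC(round(m, 1L), format = "f", digits = 1L)
      fm[is.na(m)] <- if (diag_x) "x" else ""
      utils::write.csv(as.data.frame(fm), path)
    }
    utils::write.csv(as.data.frame(direct$counts),
                     file.path(od, "direct_counts.csv"))
    write_percent_csv(direct$percent, file.path(od, "direct_percent.csv"),
                      diag_x = TRUE)
    write_percent_csv(tab_kept$percent, file.path(od, "table2.csv"))
    utils::write.csv(
      data.frame(structure = names(vols), volume_mm3 = unname(vols)),
      file.path(od, "volumes.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(direct_percent = direct$percent, table2 = tab_kept$percent,
           total_tracks = tab$total_tracks),
      file.path(od, "tables_full_precision.json"),
      auto_unbox = TRUE, digits = NA, matrix = "rowmajor", na = "null")
    jsonlite::write_json(report, file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    for (i in seq_along(maps))
      write_voxel_map(maps[[i]], file.path(
        od, sprintf("voxmap_%s_to_%s.nii.gz",
                    maps[[i]]$structure, maps[[i]]$target)))
    out$out_dir <- od
  }
  out
}
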