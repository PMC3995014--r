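## End-to-end orchestration: build a template database + groupwise
## template on disk, segment subjects, and report volumetry/agreement
## tables. Every run writes a provenance JSON (config, seeds, package
## version) sufficient to reproduce its outputs exactly.

#' Default pipeline configuration
#'
#' Flag defaults mirror the method's published operating point: 75
#' coarse-selected templates, 15 fused per voxel, LNCC sigma 2 voxels,
#' MRF beta 0.5.
#'
#' @param ... Overrides of the defaults.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_templates = 20, seed = 1,
    atrophy_mix = c(left = 0.25, right = 0.25, bilateral = 0.25, normal = 0.25),
    k_coarse = 75, k_local = 15, lncc_sigma = 2, beta = 0.5,
    margin_voxels = 2, fine_preset = "fine",
    threshold = 0.5, sides = c("left", "right"),
    template_max_iter = 3, slice_mode = "all")
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  cfg$atrophy_mix <- unlist(cfg$atrophy_mix)
  if (is.null(names(cfg$atrophy_mix)) && length(cfg$atrophy_mix) == 4)
    names(cfg$atrophy_mix) <- c("left", "right", "bilateral", "normal")
  cfg$sides <- unlist(cfg$sides)
  cfg
}

#' Read / write a pipeline config as YAML
#' @param path File path.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config] list.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

provenance <- function(dir, config, extra = list()) {
  obj <- c(list(package = "stepseg",
                version = as.character(utils::packageVersion("stepseg")),
                config = config), extra)
  jsonlite::write_json(obj, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write / read a template database directory
#'
#' NIfTI image/label pairs plus a CSV manifest (id, class, true volumes,
#' ICV, seed).
#' @param db A `template_db`.
#' @param dir Output directory (created if missing).
#' @export
write_template_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in db$entries) {
    write_volume(e$image, file.path(dir, paste0(e$id, "_img.nii.gz")))
    write_volume(e$label, file.path(dir, paste0(e$id, "_lab.nii.gz")))
  }
  write.csv(db$meta, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_template_db
#' @export
read_template_db <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  meta <- read.csv(mf)
  entries <- lapply(meta$id, function(id) {
    list(id = id,
         image = read_volume(file.path(dir, paste0(id, "_img.nii.gz"))),
         label = read_volume(file.path(dir, paste0(id, "_lab.nii.gz")),
                             label = TRUE))
  })
  structure(list(entries = entries, meta = meta), class = "template_db")
}

save_group_template <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(gt$mean, file.path(dir, "template_mean.nii.gz"))
  write_volume(gt$prior$left, file.path(dir, "template_prior_left.nii.gz"))
  write_volume(gt$prior$right, file.path(dir, "template_prior_right.nii.gz"))
  jsonlite::write_json(
    list(ids = gt$ids, iterations = gt$iterations, trace = gt$trace,
         converged = gt$converged),
    file.path(dir, "template_info.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

load_group_template <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "template_info.json"),
                              simplifyVector = TRUE)
  structure(list(
    mean = read_volume(file.path(dir, "template_mean.nii.gz")),
    prior = list(
      left = read_volume(file.path(dir, "template_prior_left.nii.gz")),
      right = read_volume(file.path(dir, "template_prior_right.nii.gz"))),
    transforms = NULL, iterations = info$iterations, trace = info$trace,
    converged = info$converged, ids = info$ids), class = "group_template")
}

#' Build a synthetic template database and groupwise template on disk
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the `template_db` and `group_template`.
#' @export
pipeline_build_db <- function(out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  db <- make_template_database(config$n_templates,
                               atrophy_mix = config$atrophy_mix,
                               seed = config$seed)
  write_template_db(db, out_dir)
  gt <- build_group_template(db, list(max_iter = config$template_max_iter))
  save_group_template(gt, out_dir)
  provenance(out_dir, config, list(stage = "build-db"))
  invisible(list(db = db, template = gt))
}

#' Segment one subject with the full pipeline
#'
#' Propagates the groupwise prior to localize each hippocampus, extracts
#' the ROI, ranks and refines templates, and fuses the locally selected
#' labels. Returns per-side masks plus fusion diagnostics.
#'
#' @param subject [volume3d] (or path to a NIfTI file).
#' @param db A `template_db`.
#' @param template A `group_template` built from `db`.
#' @param config A [pipeline_config].
#' @return `segmentation`: per-side list with `mask`, `state`, `roi`,
#'   `ranking`; plus `priors`.
#' @export
segment_subject <- function(subject, db, template,
                            config = pipeline_config()) {
  if (is.character(subject)) subject <- read_volume(subject)
  priors <- propagate_prior(template, subject)
  fc <- fusion_config(k_local = config$k_local,
                      lncc_sigma = config$lncc_sigma,
                      beta = config$beta, threshold = config$threshold)
  sides <- lapply(config$sides, function(s) {
    roi <- extract_roi(priors[[s]], config$margin_voxels, side = s)
    subject_roi <- roi_crop(subject, roi)
    prior_roi_full <- roi_crop(priors[[s]], roi)
    Wc <- grid_world_coords(prior_roi_full)
    ctr <- as.vector(colSums(Wc * as.vector(prior_roi_full$data)) /
                       sum(prior_roi_full$data))
    ranked <- select_templates(subject_roi, db, side = s,
                               k_coarse = config$k_coarse,
                               fixed_center = ctr)
    refined <- refine_templates(ranked, subject_roi,
                                reg_preset(config$fine_preset),
                                min_templates = config$k_local)
    prior_roi <- roi_crop(priors[[s]], roi)
    fused <- fuse(subject, roi, refined, prior = prior_roi, config = fc)
    list(mask = fused$mask, state = fused$state, roi = roi,
         ranking = ranked$ranking,
         fine_ncc = vapply(refined, `[[`, 0, "fine_ncc"))
  })
  names(sides) <- config$sides
  structure(list(sides = sides, priors = priors, config = config),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat("<segmentation>\n")
  for (s in names(x$sides)) {
    v <- mask_volume(x$sides[[s]]$mask)
    cat(sprintf("  %s: %.3f cm^3, %d EM iterations\n",
                s, v, x$sides[[s]]$state$iterations))
  }
  invisible(x)
}

#' Run segmentation against an on-disk database and write outputs
#'
#' @param db_dir Directory from [pipeline_build_db].
#' @param subject_path NIfTI path of the subject scan.
#' @param out_dir Output directory.
#' @param config A [pipeline_config].
#' @return Invisibly, the `segmentation`.
#' @export
pipeline_segment <- function(db_dir, subject_path, out_dir,
                             config = pipeline_config()) {
  db <- read_template_db(db_dir)
  gt <- load_group_template(db_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seg <- segment_subject(subject_path, db, gt, config)
  sid <- sub("\\.nii(\\.gz)?$", "", basename(subject_path))
  reports <- list()
  for (s in names(seg$sides)) {
    side <- seg$sides[[s]]
    write_volume(side$mask, file.path(out_dir, paste0(sid, "_", s, "_mask.nii.gz")))
    write.csv(summary(side$state),
              file.path(out_dir, paste0(sid, "_", s, "_performance.csv")),
              row.names = FALSE)
    write.csv(side$ranking,
              file.path(out_dir, paste0(sid, "_", s, "_ranking.csv")),
              row.names = FALSE)
    reports[[s]] <- volume_report(sid, s, side$mask,
                                  slice_mode = config$slice_mode)
  }
  write.csv(do.call(rbind, reports), file.path(out_dir, paste0(sid, "_volumes.csv")),
            row.names = FALSE)
  provenance(out_dir, config, list(stage = "segment", subject = sid))
  invisible(seg)
}

#' Aggregate volume reports into normative and classification tables
#'
#' Fits the normative ICV model on control rows, corrects all volumes,
#' classifies each subject on the sum/difference plane, and writes the
#' combined tables.
#'
#' @param volumes Data frame with columns subject, side, raw_cm3, icv_cm3
#'   and a logical `control` column.
#' @param out_dir Output directory (optional; tables are also returned).
#' @return List: `model`, `table` (per-subject classification).
#' @export
pipeline_report <- function(volumes, out_dir = NULL) {
  stopifnot(all(c("subject", "side", "raw_cm3", "icv_cm3", "control")
                %in% names(volumes)))
  ctrl <- volumes[volumes$control, ]
  model <- fit_normative(ctrl$raw_cm3, ctrl$icv_cm3)
  volumes$corrected_cm3 <- correct_volume(volumes$raw_cm3, volumes$icv_cm3,
                                          model)
  subjects <- unique(volumes$subject)
  rows <- lapply(subjects, function(id) {
    v <- volumes[volumes$subject == id, ]
    l <- v$corrected_cm3[v$side == "left"][1]
    r <- v$corrected_cm3[v$side == "right"][1]
    cl <- classify_volumes(l, r, model)
    data.frame(subject = id, left_cm3 = round(l, 3), right_cm3 = round(r, 3),
               sum_cm3 = round(cl$sum, 3), diff_cm3 = round(cl$difference, 3),
               class = cl$class)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(out_dir, "classification.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(model), file.path(out_dir, "normative_model.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(model = model, table = tab)
}
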