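#' Study configuration
#'
#' Stage toggles and the numeric parameters of every processing stage, with
#' defaults equal to the protocol values used throughout the package. The
#' configuration round-trips through YAML unchanged and every parameter is
#' echoed into the run log.
#'
#' @param stages Character vector of enabled stages, a subset of
#'   `c("t2map", "t1map", "mtmaps", "dti", "wml", "gratio", "psmd",
#'   "volumes")`.
#' @param te Dual-echo TEs, ms.
#' @param wml A [wml_seg_config()].
#' @param mask_prep A [mask_prep_config()].
#' @param fa_skeleton_threshold,fa_masking_threshold FA cutoffs of the
#'   peak-width stage.
#' @param g_target Splenium g-ratio assumed for calibration.
#' @param k_gratio Fixed calibration constant; `NULL` calibrates per
#'   subject from the splenium mask.
#' @param dti_shells Optional b-value subset for the tensor fit (`NULL`
#'   fits all forward shells).
#' @param dti_weighted One-iteration weighted tensor refit.
#' @param seed Integer seed recorded in the log (processing itself is
#'   deterministic; the seed governs phantom generation when the pipeline
#'   is used on synthetic data).
#' @param output_dir Output directory; default
#'   `<dataset_root>/derivatives/msqmap`.
#' @return A list of class `study_config`.
#' @export
study_config <- function(stages = c("t2map", "t1map", "mtmaps", "dti", "wml",
                                    "gratio", "psmd", "volumes"),
                         te = c(9.6, 96),
                         wml = wml_seg_config(),
                         mask_prep = mask_prep_config(),
                         fa_skeleton_threshold = 0.2,
                         fa_masking_threshold = 0.3,
                         g_target = 0.7,
                         k_gratio = NULL,
                         dti_shells = NULL,
                         dti_weighted = FALSE,
                         seed = 1L,
                         output_dir = NULL) {
  known <- c("t2map", "t1map", "mtmaps", "dti", "wml", "gratio", "psmd", "volumes")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, te = te, wml = unclass(wml),
                 mask_prep = unclass(mask_prep),
                 fa_skeleton_threshold = fa_skeleton_threshold,
                 fa_masking_threshold = fa_masking_threshold,
                 g_target = g_target, k_gratio = k_gratio,
                 dti_shells = dti_shells, dti_weighted = dti_weighted,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "study_config")
}

#' Read and write study configurations as YAML
#'
#' @param config A [study_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `study_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- study_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# --- BIDS-like dataset layout -----------------------------------------------

bids_file <- function(dir, subject, session, suffix, ext = ".nii.gz")
  file.path(dir, paste0(subject, "_", session, "_", suffix, ext))

#' Write a phantom as a BIDS-like subject dataset
#'
#' Persists every generated volume under
#' `root/<subject>/<session>/{anat,mt,dwi,noddi,masks,ground_truth}` using
#' NIfTI-1, FSL-style bvals/bvecs and a YAML sidecar for the MT acquisition
#' parameters, so the full pipeline can be exercised from files alone.
#'
#' @param phantom Output of [build_phantom()].
#' @param root Dataset root directory (created if needed).
#' @param subject,session Entity labels (`sub-*`, `ses-*`).
#' @return The session directory, invisibly.
#' @export
write_phantom_dataset <- function(phantom, root, subject = "sub-001",
                                  session = "ses-baseline") {
  ses <- file.path(root, subject, session)
  for (d in c("anat", "mt", "dwi", "noddi", "masks", "ground_truth"))
    dir.create(file.path(ses, d), recursive = TRUE, showWarnings = FALSE)
  gt <- phantom$gt
  write_volume(phantom$flair, bids_file(file.path(ses, "anat"), subject, session, "FLAIR"))
  write_volume(phantom$dual_echo$pd_echo, bids_file(file.path(ses, "anat"), subject, session, "PDw"))
  write_volume(phantom$dual_echo$t2w_echo, bids_file(file.path(ses, "anat"), subject, session, "T2w"))
  trip <- phantom$mt
  write_volume(trip$mt_on, bids_file(file.path(ses, "mt"), subject, session, "mt-on"))
  write_volume(trip$mt_off, bids_file(file.path(ses, "mt"), subject, session, "mt-off"))
  write_volume(trip$t1w, bids_file(file.path(ses, "mt"), subject, session, "mt-t1w"))
  yaml::write_yaml(list(tr_on = trip$tr_on, tr_off = trip$tr_off,
                        tr_t1w = trip$tr_t1w, flip_on = trip$flip_on,
                        flip_off = trip$flip_off, flip_t1w = trip$flip_t1w,
                        te = as.list(trip$te)),
                   file.path(ses, "mt", "mt_acq.yaml"))
  if (!is.null(phantom$dwi)) {
    write_volume(phantom$dwi$series, bids_file(file.path(ses, "dwi"), subject, session, "dwi"))
    write_bvals_bvecs(phantom$dwi$scheme,
                      bids_file(file.path(ses, "dwi"), subject, session, "dwi", ".bval"),
                      bids_file(file.path(ses, "dwi"), subject, session, "dwi", ".bvec"))
    writeLines(paste(as.integer(phantom$dwi$scheme$reverse), collapse = " "),
               bids_file(file.path(ses, "dwi"), subject, session, "dwi", ".reverse"))
  }
  write_volume(gt$vic_map, bids_file(file.path(ses, "noddi"), subject, session, "ICVF"))
  write_volume(gt$viso_map, bids_file(file.path(ses, "noddi"), subject, session, "ISOVF"))
  write_volume(gt$odi_map, bids_file(file.path(ses, "noddi"), subject, session, "ODI"))
  for (nm in names(phantom$masks))
    write_volume(phantom$masks[[nm]], file.path(ses, "masks", paste0(nm, ".nii.gz")))
  write_volume(gt$template, file.path(ses, "masks", "template.nii.gz"))
  for (nm in names(gt$tract_prob_maps))
    write_volume(gt$tract_prob_maps[[nm]],
                 file.path(ses, "masks", paste0("tract-", nm, ".nii.gz")))
  gtdir <- file.path(ses, "ground_truth")
  for (nm in c("t2_map", "pd_map", "t1_map", "mtsat_map", "vic_map",
               "viso_map", "odi_map", "lesion_mask", "label_map"))
    write_volume(gt[[nm]], file.path(gtdir, paste0(sub("_map$|_mask$", "", nm),
                                                   ".nii.gz")))
  invisible(ses)
}

# Locate the single file matching a modality suffix; NULL when absent.
find_bids <- function(dir, suffix, ext = "\\.nii(\\.gz)?$") {
  if (!dir.exists(dir)) return(NULL)
  hits <- list.files(dir, pattern = paste0("_", suffix, ext), full.names = TRUE)
  if (length(hits) == 0) return(NULL)
  hits[1L]
}

# Long-format rows from a roi_summary data frame.
melt_summary <- function(df, subject, session) {
  if (is.null(df)) return(NULL)
  stats <- c("mean", "weighted_mean", "median", "iqr", "sd", "cv",
             "voxel_count", "volume_mm3")
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    vals <- unlist(df[i, stats])
    keep <- !is.na(vals)
    data.frame(subject = subject, session = session, roi = df$roi[i],
               metric = df$metric[i], statistic = stats[keep],
               value = unname(vals[keep]), stringsAsFactors = FALSE)
  }))
  out
}

scalar_row <- function(subject, session, roi, metric, statistic, value)
  data.frame(subject = subject, session = session, roi = roi, metric = metric,
             statistic = statistic, value = value, stringsAsFactors = FALSE)

# --- the per-subject stage graph --------------------------------------------

run_subject_session <- function(config, ses_dir, subject, session, log) {
  rows <- list()
  note <- function(fmt, ...) log(sprintf(paste0("[%s/%s] ", fmt), subject,
                                         session, ...))
  need <- function(path, stage) {
    if (is.null(path)) {
      note("stage '%s' skipped: missing required input", stage)
      return(FALSE)
    }
    TRUE
  }
  anat <- file.path(ses_dir, "anat"); mtd <- file.path(ses_dir, "mt")
  dwid <- file.path(ses_dir, "dwi"); noddid <- file.path(ses_dir, "noddi")
  maskd <- file.path(ses_dir, "masks")

  # masks: prepared tissue masks (threshold/binarise/erode; WML exempt)
  prep_cfg <- do.call(mask_prep_config, config$mask_prep)
  tissue_names <- c("brain", "csf", "nawm", "cortical_gm", "subcortical_gm",
                    "brainstem", "wml")
  masks <- list()
  raw_masks <- list()
  if (dir.exists(maskd)) {
    for (f in list.files(maskd, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)) {
      nm <- sub("\\.nii(\\.gz)?$", "", basename(f))
      raw_masks[[nm]] <- read_volume(f)
    }
  }
  for (nm in intersect(tissue_names, names(raw_masks)))
    masks[[nm]] <- prepare_mask(raw_masks[[nm]], prep_cfg, is_wml = nm == "wml")
  # brain mask is an extraction product, not a probabilistic segmentation
  if (!is.null(raw_masks$brain))
    masks$brain <- like_volume(array(as.integer(raw_masks$brain$data > 0.5),
                                     dim(raw_masks$brain$data)), raw_masks$brain)

  add_roi_stats <- function(map, metric, rois = setdiff(names(masks), "csf"),
                            weights = NULL) {
    for (roi in rois) {
      s <- tryCatch(roi_summary(map, masks[[roi]], roi = roi, metric = metric),
                    warning = function(w) NULL)
      rows[[length(rows) + 1L]] <<- melt_summary(s, subject, session)
    }
  }

  maps <- list()

  if ("t2map" %in% config$stages) {
    fpd <- find_bids(anat, "PDw"); ft2 <- find_bids(anat, "T2w")
    if (need(fpd, "t2map") && need(ft2, "t2map")) {
      res <- t2map_from_dual_echo(read_volume(fpd), read_volume(ft2),
                                  te1 = config$te[1], te2 = config$te[2])
      maps$T2 <- res$t2_map
      add_roi_stats(res$t2_map, "T2")
    }
  }

  trip <- NULL
  if (any(c("t1map", "mtmaps", "gratio") %in% config$stages)) {
    fon <- find_bids(mtd, "mt-on"); foff <- find_bids(mtd, "mt-off")
    ft1w <- find_bids(mtd, "mt-t1w")
    facq <- file.path(mtd, "mt_acq.yaml")
    if (!is.null(fon) && !is.null(foff) && !is.null(ft1w) && file.exists(facq)) {
      acq <- yaml::read_yaml(facq)
      trip <- mt_triplet(read_volume(fon, series = TRUE),
                         read_volume(foff, series = TRUE),
                         read_volume(ft1w, series = TRUE),
                         tr_on = acq$tr_on, tr_off = acq$tr_off,
                         tr_t1w = acq$tr_t1w, flip_on = acq$flip_on,
                         flip_off = acq$flip_off, flip_t1w = acq$flip_t1w,
                         te = unlist(acq$te))
    }
  }

  if ("t1map" %in% config$stages) {
    if (!is.null(trip)) {
      res <- t1map_from_mt_pair(trip)
      maps$T1 <- res$t1_map
      add_roi_stats(res$t1_map, "T1")
    } else note("stage 't1map' skipped: missing required input")
  }

  if ("mtmaps" %in% config$stages) {
    if (!is.null(trip)) {
      mt <- compute_mt_maps(trip)
      maps$MTR <- mt$mtr_map; maps$MTsat <- mt$mtsat_map
      add_roi_stats(mt$mtr_map, "MTR")
      add_roi_stats(mt$mtsat_map, "MTsat")
    } else note("stage 'mtmaps' skipped: missing required input")
  }

  if (any(c("dti", "psmd") %in% config$stages)) {
    fdwi <- find_bids(dwid, "dwi")
    fbval <- find_bids(dwid, "dwi", "\\.bval$")
    fbvec <- find_bids(dwid, "dwi", "\\.bvec$")
    if (!is.null(fdwi) && !is.null(fbval) && !is.null(fbvec)) {
      scheme <- read_bvals_bvecs(fbval, fbvec)
      frev <- find_bids(dwid, "dwi", "\\.reverse$")
      if (!is.null(frev)) scheme$reverse <- scan(frev, quiet = TRUE) > 0
      series <- read_volume(fdwi, series = TRUE)
      tm <- tensor_scalars(fit_tensor(series, scheme,
                                      shells = config$dti_shells,
                                      mask = masks$brain,
                                      weighted = config$dti_weighted))
      maps$FA <- tm$fa_map; maps$MD <- tm$md_map
      maps$AD <- tm$ad_map; maps$RD <- tm$rd_map
      if ("dti" %in% config$stages)
        for (mn in c("FA", "MD", "AD", "RD")) add_roi_stats(maps[[mn]], mn)
    } else if ("dti" %in% config$stages) {
      note("stage 'dti' skipped: missing required input")
    }
  }

  noddi <- list()
  for (nn in c("ICVF", "ISOVF", "ODI")) {
    f <- find_bids(noddid, nn)
    if (!is.null(f)) noddi[[nn]] <- read_volume(f)
  }

  if ("wml" %in% config$stages) {
    fflair <- find_bids(anat, "FLAIR")
    ftempl <- if (!is.null(raw_masks$template)) raw_masks$template else NULL
    if (need(fflair, "wml") && !is.null(masks$brain) && !is.null(ftempl)) {
      seg <- segment_wml(read_volume(fflair), masks$brain, ftempl,
                         do.call(wml_seg_config, config$wml))
      rows[[length(rows) + 1L]] <- scalar_row(subject, session, "wml",
                                              "wml_volume", "volume_mm3",
                                              seg$lesion_volume_mm3)
      if (is.null(masks$wml)) masks$wml <- seg$lesion_mask
    } else if (is.null(masks$brain) || is.null(ftempl)) {
      note("stage 'wml' skipped: missing required input")
    }
  }

  if ("gratio" %in% config$stages) {
    if (!is.null(maps$MTsat) && !is.null(noddi$ICVF) && !is.null(noddi$ISOVF)) {
      k <- config$k_gratio
      if (is.null(k)) {
        spl <- raw_masks$splenium
        if (is.null(spl)) {
          note("stage 'gratio' skipped: no calibration constant and no splenium mask")
        } else {
          spl <- like_volume(array(as.integer(spl$data > 0.5), dim(spl$data)), spl)
          cal <- calibrate_k(maps$MTsat, noddi$ICVF, noddi$ISOVF, spl,
                             g_target = config$g_target)
          k <- cal$k
          note("g-ratio calibration: k = %.5f over %d splenium voxels", k,
               cal$splenium_voxel_count)
        }
      }
      if (!is.null(k)) {
        gm <- compute_gratio_map(compute_mvf_avf(maps$MTsat, noddi$ICVF,
                                                 noddi$ISOVF, k))
        rows[[length(rows) + 1L]] <- scalar_row(subject, session, "global",
                                                "gratio_k", "value", k)
        for (roi in intersect(c("nawm", "wml"), names(masks))) {
          s <- tryCatch(roi_summary(gm$g_map, masks[[roi]], roi = roi,
                                    metric = "gratio"),
                        warning = function(w) NULL)
          rows[[length(rows) + 1L]] <- melt_summary(s, subject, session)
        }
      }
    } else {
      note("stage 'gratio' skipped: missing required input")
    }
  }

  if ("psmd" %in% config$stages) {
    skel <- raw_masks$skeleton
    if (!is.null(skel) && !is.null(maps$FA)) {
      pw_maps <- maps[intersect(c("MD", "AD", "RD", "FA"), names(maps))]
      names(pw_maps) <- paste0("PS", names(pw_maps))
      for (nn in names(noddi)) pw_maps[[paste0("PS", nn)]] <- noddi[[nn]]
      tab <- peak_width_table(pw_maps, maps$FA, skel,
                              fa_skeleton_threshold = config$fa_skeleton_threshold,
                              fa_masking_threshold = config$fa_masking_threshold)
      for (i in seq_len(nrow(tab)))
        rows[[length(rows) + 1L]] <- scalar_row(subject, session, "skeleton",
                                                tab$metric[i], "peak_width",
                                                tab$peak_width[i])
    } else {
      note("stage 'psmd' skipped: missing required input")
    }
  }

  if ("volumes" %in% config$stages) {
    for (roi in names(masks))
      rows[[length(rows) + 1L]] <- scalar_row(subject, session, roi, "volume",
                                              "volume_mm3",
                                              mask_volume(masks[[roi]]))
  }

  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Run the full per-subject pipeline over a dataset
#'
#' Walks a BIDS-like dataset (`sub-*/ses-*/...`), runs every enabled stage
#' per subject and session, and writes a long-format TSV of results (one
#' row per subject/session/ROI/metric/statistic) plus a run log recording
#' the package version, configuration, its hash and the seed. Missing
#' inputs cause a named per-stage skip with a log entry, never a hard
#' failure. Processing is deterministic: two runs with the same
#' configuration produce byte-identical tables.
#'
#' @param config A [study_config()].
#' @param dataset_root Dataset root directory.
#' @return The results data frame, invisibly; written to
#'   `<output_dir>/results.tsv` alongside `run_log.txt`.
#' @export
run_pipeline <- function(config, dataset_root) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- if (!is.null(config$output_dir)) config$output_dir
             else file.path(dataset_root, "derivatives", "msqmap")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  log(sprintf("msqmap version %s", as.character(utils::packageVersion("msqmap"))))
  log(sprintf("config hash %s", unname(tools::md5sum(cfg_path))))
  log(sprintf("seed %d", config$seed))
  for (nm in setdiff(names(config), "output_dir"))
    log(sprintf("config %s = %s", nm,
                paste(utils::capture.output(utils::str(config[[nm]],
                                                       give.head = FALSE)),
                      collapse = " ")))
  subjects <- list.dirs(dataset_root, recursive = FALSE, full.names = FALSE)
  subjects <- grep("^sub-", subjects, value = TRUE)
  all_rows <- list()
  for (sub in sort(subjects)) {
    sessions <- grep("^ses-", list.dirs(file.path(dataset_root, sub),
                                        recursive = FALSE, full.names = FALSE),
                     value = TRUE)
    for (ses in sort(sessions)) {
      log(sprintf("processing %s/%s", sub, ses))
      all_rows[[length(all_rows) + 1L]] <-
        run_subject_session(config, file.path(dataset_root, sub, ses), sub,
                            ses, log)
    }
  }
  res <- do.call(rbind, Filter(Negate(is.null), all_rows))
  if (is.null(res)) {
    warning("empty dataset: no subject/session directories found")
    res <- data.frame(subject = character(0), session = character(0),
                      roi = character(0), metric = character(0),
                      statistic = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  utils::write.table(format(res, digits = 12, trim = TRUE, scientific = FALSE),
                     file.path(out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(res)
}
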