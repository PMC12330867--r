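#' Analyze one cine dataset: segmentation, flow, normalization
#'
#' @param dataset a [cine_dataset()]
#' @param extrapolation passed to [normalize_profile()]
#' @param ... passed to [segment_series()]
#' @return list with `lumen` (segmentation result), `series` (named list of
#'   [vessel_series()]) and `profiles` (named list of [flow_profile32()])
#' @export
analyze_dataset <- function(dataset, extrapolation = "periodic", ...) {
  lumen <- segment_series(dataset, ...)
  series <- quantify_dataset(dataset, lumen)
  profiles <- lapply(series, normalize_profile, extrapolation = extrapolation)
  list(lumen = lumen, series = series, profiles = profiles)
}

#' Analyze one subject (arterial + venous slices)
#'
#' Runs the full per-subject chain: segmentation, velocity decoding and flow
#' computation, 32-step normalization, composite (Art = BT+RC+LC,
#' Ven = SS+StS) profiles, waveform features, peak-arrival lags, and the
#' volume/coupling summary.
#'
#' @param bundle list with `spec` ([subject_spec()]), `arterial` and `venous`
#'   ([cine_dataset()]s) — one element of a [make_cohort()] cohort
#' @param ... passed to [analyze_dataset()]
#' @return list with `spec`, `profiles` (5 vessels + Art + Ven), `features`
#'   (data.frame, one row per vessel/composite), `lags` ([peak_lags()]),
#'   `haemo` ([subject_haemodynamics()]), and the per-slice `arterial` /
#'   `venous` analysis results
#' @export
analyze_subject <- function(bundle, ...) {
  art <- analyze_dataset(bundle$arterial, ...)
  ven <- analyze_dataset(bundle$venous, ...)
  profiles <- c(art$profiles, ven$profiles)
  profiles$Art <- sum_profiles(profiles[ARTERIAL_VESSELS])
  profiles$Ven <- sum_profiles(profiles[VENOUS_VESSELS])
  features <- do.call(rbind, lapply(profiles, profile_features))
  rownames(features) <- NULL
  haemo <- subject_haemodynamics(profiles[ALL_VESSELS], bundle$spec)
  list(spec = bundle$spec, profiles = profiles, features = features,
       lags = peak_lags(features), haemo = haemo,
       arterial = art, venous = ven)
}

#' Analyze a whole cohort
#'
#' @param cohort a [make_cohort()] cohort (or any list of subject bundles)
#' @param ... passed to [analyze_subject()]
#' @return list with `subjects` (per-subject [analyze_subject()] results),
#'   `table` (tidy [cohort_table()]) and `summary` ([summarize_cohort()])
#' @export
analyze_cohort <- function(cohort, ...) {
  subjects <- lapply(cohort, analyze_subject, ...)
  names(subjects) <- vapply(subjects, function(s) s$spec$subject_id, "")
  features <- lapply(subjects, `[[`, "features")
  tab <- cohort_table(lapply(subjects, `[[`, "haemo"), features)
  list(subjects = subjects, table = tab, summary = summarize_cohort(tab))
}

#' One-command synthetic-cohort pipeline run
#'
#' Generates a cohort, runs the full analysis, and writes every stage output
#' (per-subject NIfTI/JSON images if requested, tidy CSV tables, group
#' summary, provenance manifest with the seed and configuration) into
#' `out_dir`. Rerunning with the same configuration reproduces identical
#' outputs.
#'
#' @param out_dir output directory (created if missing)
#' @param n_young,n_old group sizes
#' @param seed RNG seed (recorded in the manifest and all outputs)
#' @param noise_sd renderer noise SD
#' @param write_images also write the cine stacks as NIfTI + JSON sidecars
#' @param ... passed to [make_cohort()]
#' @return (invisibly) the [analyze_cohort()] result
#' @export
run_pipeline <- function(out_dir, n_young = 7, n_old = 7, seed = 1,
                         noise_sd = 0.5, write_images = FALSE, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- make_cohort(n_young, n_old, seed, noise_sd = noise_sd, ...)
  res <- analyze_cohort(cohort)

  if (write_images) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (b in cohort) {
      write_cine_dataset(b$arterial,
                         file.path(img_dir, paste0(b$spec$subject_id, "_art")))
      write_cine_dataset(b$venous,
                         file.path(img_dir, paste0(b$spec$subject_id, "_ven")))
    }
  }

  utils::write.csv(res$table, file.path(out_dir, "cohort_table.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  area_rows <- do.call(rbind, lapply(res$subjects, function(s) {
    rbind(
      cbind(subject_id = s$spec$subject_id,
            do.call(rbind, lapply(s$arterial$series, as.data.frame))),
      cbind(subject_id = s$spec$subject_id,
            do.call(rbind, lapply(s$venous$series, as.data.frame)))
    )
  }))
  rownames(area_rows) <- NULL
  utils::write.csv(area_rows, file.path(out_dir, "vessel_series.csv"),
                   row.names = FALSE)
  prof_rows <- do.call(rbind, lapply(res$subjects, function(s) {
    do.call(rbind, lapply(s$profiles, function(p) data.frame(
      subject_id = s$spec$subject_id, vessel = p$vessel, step = p$step,
      pct_cc = p$pct_cc, flow_ul_s = p$flow_ul_s,
      extrapolated = p$extrapolated)))
  }))
  rownames(prof_rows) <- NULL
  utils::write.csv(prof_rows, file.path(out_dir, "profiles32.csv"),
                   row.names = FALSE)

  cfg <- list(n_young = n_young, n_old = n_old, seed = seed,
              noise_sd = noise_sd, package_version =
                as.character(utils::packageVersion("cineflow")))
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(config = cfg,
                   outputs = data.frame(file = basename(outputs),
                                        md5 = unname(tools::md5sum(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
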