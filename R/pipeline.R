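#' Pipeline run configuration
#'
#' @param phantoms Named list of [phantom()] objects forming the library.
#' @param hu_threshold Bone HU threshold for skeleton extraction.
#' @param icp An [icp_config()].
#' @param acceptance `"flags"` (use the evaluator flags carried by the
#'   manifest, mirroring the two-independent-evaluator review) or
#'   `"auto"` (accept every registration; for synthetic runs).
#' @param region_keywords Keyword map for treatment-region
#'   categorization.
#' @param render_overlays Write overlay PNGs per session.
#' @param out_dir Optional output directory for reports.
#' @param seed Integer seed forwarded to seeded stages.
#' @return List of class `run_config`.
#' @export
run_config <- function(phantoms, hu_threshold = 200, icp = icp_config(),
                       acceptance = c("flags", "auto"),
                       region_keywords = default_region_keywords(),
                       render_overlays = FALSE, out_dir = NULL,
                       seed = 1L) {
  acceptance <- match.arg(acceptance)
  stopifnot(length(phantoms) >= 1L,
            all(vapply(phantoms, inherits, NA, "phantom")))
  structure(
    list(phantoms = phantoms, hu_threshold = hu_threshold, icp = icp,
         acceptance = acceptance, region_keywords = region_keywords,
         render_overlays = render_overlays, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# library data frame for select_phantom from a run_config
phantom_library_df <- function(config) {
  do.call(rbind, lapply(names(config$phantoms), function(nm) {
    m <- config$phantoms[[nm]]$meta
    data.frame(id = nm, age = m$age_years, sex = m$sex,
               height = m$height_cm, weight = m$weight_kg,
               stringsAsFactors = FALSE)
  }))
}

#' Run the full reconstruction workflow for one treatment session
#'
#' Stage order: read DICOM objects, prescribed/recorded dose consistency
#' check, phantom selection, CT skeleton extraction, ICP registration,
#' VOF and review, marrow-fraction weighting, dose sampling, metrics.
#' Any stage failure produces a rejected record with the failing stage
#' and reason rather than an error.
#'
#' @param session One-row data frame (or list) with `session_id`,
#'   `ct_dir`, `dose_file`, `plan_file`, `age`, `sex`, `height`,
#'   `weight`, `recorded_dose` and (for the `"flags"` policy)
#'   `evaluator_1`, `evaluator_2`.
#' @param config A [run_config()].
#' @param phantom_id Force the phantom (used to share one phantom across
#'   a patient's sessions); default selects by characteristics.
#' @return List of class `session_result`: `session_id`, `status`
#'   (`"accepted"`/`"rejected"`), `stage` reached, `reason`, `vof`,
#'   `region`, `phantom_id`, `metrics` (an `abm_dose_result` or NULL),
#'   `sample` (the dosed `abm_sample`), `total_prescribed`,
#'   `dose_direction`.
#' @export
run_session <- function(session, config, phantom_id = NULL) {
  session <- as.list(session)
  rec <- list(session_id = session$session_id, status = "rejected",
              stage = "read", reason = NA_character_, vof = NA_real_,
              region = NA_character_, phantom_id = NA_character_,
              metrics = NULL, sample = NULL, total_prescribed = NA_real_,
              dose_direction = NA_character_)
  class(rec) <- "session_result"
  fail <- function(stage, msg) {
    rec$stage <- stage; rec$reason <- msg
    rec
  }
  chars <- try(patient_characteristics(
    session$age, session$sex, session$height, session$weight,
    session$recorded_dose), silent = TRUE)
  if (inherits(chars, "try-error")) {
    return(fail("read", "invalid patient characteristics"))
  }
  plan <- try(read_rt_plan(session$plan_file), silent = TRUE)
  if (inherits(plan, "try-error")) return(fail("read", "unreadable RT-plan"))
  rec$total_prescribed <- plan$total_prescribed
  dgrid <- try(read_rt_dose(session$dose_file), silent = TRUE)
  if (inherits(dgrid, "try-error")) return(fail("read", "unreadable RT-dose"))
  ct <- try(read_ct_series(session$ct_dir), silent = TRUE)
  if (inherits(ct, "try-error")) return(fail("read", "unreadable CT series"))

  cons <- check_dose_consistency(plan, chars)
  rec$dose_direction <- cons$direction
  if (cons$decision == "reject") {
    return(fail("dose_consistency", cons$reason))
  }

  if (is.null(phantom_id)) {
    sel <- try(select_phantom(chars, phantom_library_df(config)),
               silent = TRUE)
    if (inherits(sel, "try-error")) {
      return(fail("phantom_selection", "phantom selection failed"))
    }
    phantom_id <- sel$id
  }
  rec$phantom_id <- phantom_id
  ph <- config$phantoms[[phantom_id]]

  pat_sk <- try(extract_skeleton(ct, config$hu_threshold), silent = TRUE)
  if (inherits(pat_sk, "try-error")) {
    return(fail("skeleton_extraction", "no bone voxels above threshold"))
  }
  pha_sk <- try(phantom_skeleton_points(ph), silent = TRUE)
  if (inherits(pha_sk, "try-error")) {
    return(fail("skeleton_extraction", "boneless phantom"))
  }
  fit <- try(icp_register(pha_sk, pat_sk, config$icp), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(fail("registration", "ICP failed"))
  }
  pha_pts <- predict(fit, pha_sk)
  rec$vof <- compute_vof(pat_sk$voxel_index, pha_pts, ct$spacing,
                         ct$origin)
  overlay <- NA_character_
  if (isTRUE(config$render_overlays) && !is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    overlay <- file.path(config$out_dir,
                         paste0(session$session_id, "_overlay.png"))
    render_overlay(pat_sk$points, pha_pts, overlay)
  }
  flags <- if (config$acceptance == "auto") c(TRUE, TRUE) else {
    c(isTRUE(session$evaluator_1), isTRUE(session$evaluator_2))
  }
  qa <- record_review(rec$vof, flags[1], flags[2], overlay,
                      session$session_id)
  z_ext <- range(pha_pts[, 3])
  rec$region <- categorize_treatment_region(
    plan, keywords = config$region_keywords, z_extent = z_ext)
  if (!qa$accepted) {
    return(fail("review", "registration rejected by evaluator(s)"))
  }

  smp <- try(assign_voxel_weights(ph, fit$transform, chars$age,
                                  chars$sex), silent = TRUE)
  if (inherits(smp, "try-error")) {
    return(fail("weighting", "marrow-fraction assignment failed"))
  }
  smp <- sample_dose(dgrid, smp)
  rec$sample <- smp
  rec$metrics <- dose_metrics(smp, total_prescribed = plan$total_prescribed,
                              sessions_included = session$session_id)
  rec$status <- "accepted"
  rec$stage <- "complete"
  rec
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("Session %s: %s at stage '%s'%s\n", x$session_id, x$status,
              x$stage,
              if (is.na(x$reason)) "" else paste0(" (", x$reason, ")")))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Run the reconstruction workflow over a cohort manifest
#'
#' Processes every session, applies the record-completeness filter and
#' the review policy, enforces the all-sessions-accepted patient
#' inclusion rule, sums multi-session patients on their shared phantom
#' (selected from the first session's characteristics), and tallies the
#' selection flowchart. When `config$out_dir` is set, per-session and
#' per-patient CSV reports and the flowchart JSON are written there.
#'
#' @param manifest Data frame as written by [make_cohort()]
#'   (`cohort_manifest.csv`).
#' @param config A [run_config()].
#' @return List of class `cohort_report`: `sessions` (per-session data
#'   frame), `patients` (per-patient cumulative data frame), `flowchart`
#'   (selection counts), `region_summary` (mean-per-Rx quartiles by
#'   region).
#' @export
run_cohort <- function(manifest, config) {
  manifest <- as.data.frame(manifest)
  if (!nrow(manifest)) {
    warning("empty manifest: nothing to run")
    return(structure(list(sessions = data.frame(),
                          patients = data.frame(),
                          flowchart = list(total_sessions = 0L),
                          region_summary = data.frame()),
                     class = "cohort_report"))
  }
  results <- list()
  pat_phantom <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    pid <- row$patient_id
    res <- run_session(row, config, phantom_id = pat_phantom[[pid]])
    if (is.null(pat_phantom[[pid]]) && !is.na(res$phantom_id)) {
      pat_phantom[[pid]] <- res$phantom_id
    }
    results[[row$session_id]] <- res
  }
  sess_df <- do.call(rbind, lapply(results, function(r) {
    m <- r$metrics
    data.frame(
      session_id = r$session_id,
      patient_id = manifest$patient_id[match(r$session_id,
                                             manifest$session_id)],
      status = r$status, stage = r$stage, reason = r$reason,
      vof_percent = r$vof, region = r$region, phantom_id = r$phantom_id,
      dose_direction = r$dose_direction,
      total_prescribed_gy = r$total_prescribed,
      mean_gy = if (is.null(m)) NA_real_ else m$mean_dose,
      mean_per_rx = if (is.null(m)) NA_real_ else m$mean_per_rx,
      d50 = if (is.null(m)) NA_real_ else m$d_metrics[["D50"]],
      d10 = if (is.null(m)) NA_real_ else m$d_metrics[["D10"]],
      d1 = if (is.null(m)) NA_real_ else m$d_metrics[["D1"]],
      v5 = if (is.null(m)) NA_real_ else m$v_metrics[["V5"]],
      v10 = if (is.null(m)) NA_real_ else m$v_metrics[["V10"]],
      v20 = if (is.null(m)) NA_real_ else m$v_metrics[["V20"]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(sess_df) <- NULL

  # flowchart bookkeeping
  dose_rej <- sess_df$stage == "dose_consistency"
  align_rej <- sess_df$status == "rejected" & !dose_rej
  # patient inclusion: all sessions past the dose filter must be accepted
  pat_ids <- unique(sess_df$patient_id)
  pat_rows <- list()
  for (pid in pat_ids) {
    sel <- sess_df$patient_id == pid
    all_accepted <- all(sess_df$status[sel] == "accepted")
    cum <- NULL
    if (all_accepted) {
      smps <- lapply(sess_df$session_id[sel],
                     function(s) results[[s]]$sample)
      rx <- sum(sess_df$total_prescribed_gy[sel])
      cum <- accumulate_sessions(smps, total_prescribed = rx,
                                 sessions_included =
                                   sess_df$session_id[sel])
    }
    pat_rows[[pid]] <- data.frame(
      patient_id = pid, n_sessions = sum(sel),
      n_accepted = sum(sess_df$status[sel] == "accepted"),
      included = all_accepted,
      cumulative_mean_gy = if (is.null(cum)) NA_real_ else cum$mean_dose,
      cumulative_mean_per_rx = if (is.null(cum)) NA_real_ else
        cum$mean_per_rx,
      d50 = if (is.null(cum)) NA_real_ else cum$d_metrics[["D50"]],
      d10 = if (is.null(cum)) NA_real_ else cum$d_metrics[["D10"]],
      d1 = if (is.null(cum)) NA_real_ else cum$d_metrics[["D1"]],
      stringsAsFactors = FALSE
    )
  }
  pat_df <- do.call(rbind, pat_rows)
  rownames(pat_df) <- NULL

  flowchart <- list(
    total_sessions = nrow(sess_df),
    total_patients = length(pat_ids),
    excluded_dose_mismatch = sum(dose_rej),
    excluded_dose_plan_low = sum(dose_rej &
                                   sess_df$dose_direction == "plan-low"),
    excluded_dose_plan_high = sum(dose_rej &
                                    sess_df$dose_direction == "plan-high"),
    excluded_dose_missing = sum(dose_rej &
                                  sess_df$dose_direction == "missing"),
    excluded_alignment = sum(align_rej),
    accepted_sessions = sum(sess_df$status == "accepted"),
    included_patients = sum(pat_df$included),
    excluded_patients = sum(!pat_df$included),
    selected_sessions = sum(sess_df$status == "accepted" &
                              sess_df$patient_id %in%
                              pat_df$patient_id[pat_df$included])
  )

  acc <- sess_df[sess_df$status == "accepted" &
                   sess_df$patient_id %in%
                   pat_df$patient_id[pat_df$included], , drop = FALSE]
  region_summary <- if (nrow(acc)) {
    do.call(rbind, lapply(split(acc, acc$region), function(g) {
      q <- stats::quantile(g$mean_per_rx, c(0.25, 0.5, 0.75), na.rm = TRUE,
                           names = FALSE)
      data.frame(region = g$region[1], n = nrow(g),
                 mean_per_rx_q1 = q[1], mean_per_rx_median = q[2],
                 mean_per_rx_q3 = q[3], stringsAsFactors = FALSE)
    }))
  } else data.frame()
  rownames(region_summary) <- NULL

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sess_df, file.path(config$out_dir, "sessions.csv"),
                     row.names = FALSE)
    utils::write.csv(pat_df, file.path(config$out_dir, "patients.csv"),
                     row.names = FALSE)
    jsonlite::write_json(flowchart,
                         file.path(config$out_dir, "flowchart.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(
    list(sessions = sess_df, patients = pat_df, flowchart = flowchart,
         region_summary = region_summary),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  f <- x$flowchart
  cat("Cohort selection flowchart\n")
  cat(sprintf(
    "  sessions: %d total, %d dose-mismatch, %d alignment-rejected,\n",
    f$total_sessions, f$excluded_dose_mismatch, f$excluded_alignment))
  cat(sprintf("    %d accepted (%d finally selected)\n",
              f$accepted_sessions, f$selected_sessions))
  cat(sprintf("  patients: %d total, %d included, %d excluded\n",
              f$total_patients, f$included_patients, f$excluded_patients))
  invisible(x)
}
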