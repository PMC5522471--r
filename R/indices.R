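#' Nodular MIBI wash-out index (WOind)
#'
#' Percentage change of background-subtracted mean nodular counts between
#' the early (~10 min) and late (~60 min) acquisitions:
#'
#'   ER = mean(nodule, early) - mean(background, early)
#'   LR = mean(nodule, late)  - mean(background, late)
#'   WOind = 100 * LR / ER - 100
#'
#' The background ROI is the nodule ROI mirrored outside the thyroid. A
#' negative value means the nodule washed tracer out between the two scans;
#' values at or above the decision cutoff (-19% by default downstream) are
#' read as tracer retention, the malignant-direction finding.
#'
#' @param nodule_early,bkg_early,nodule_late,bkg_late [roi_stats] for the
#'   nodule and mirrored-background ROIs at the two timepoints.
#' @param decay A [decay_spec]; when enabled, means are decay-corrected to
#'   the reference time before the ratio is formed.
#' @return An `index_result` with fields `method = "WOind"`, `value`,
#'   `early_ratio_ER`, `late_term` (LR), `decay_corrected`, `flags`.
#' @export
washout_index <- function(nodule_early, bkg_early, nodule_late, bkg_late,
                          decay = decay_spec()) {
  check_labels(nodule_early, "nodule"); check_labels(nodule_late, "nodule")
  check_labels(bkg_early, "mirror_background")
  check_labels(bkg_late, "mirror_background")
  check_timepoints(early = list(nodule_early, bkg_early),
                   late = list(nodule_late, bkg_late))
  ne <- maybe_decay_correct(nodule_early, decay)
  be <- maybe_decay_correct(bkg_early, decay)
  nl <- maybe_decay_correct(nodule_late, decay)
  bl <- maybe_decay_correct(bkg_late, decay)
  er <- ne$mean_counts_per_pixel - be$mean_counts_per_pixel
  lr <- nl$mean_counts_per_pixel - bl$mean_counts_per_pixel
  if (er <= 0) {
    stop(format_error(
      "early nodular counts do not exceed background (ER <= 0)",
      "mibiquant_non_positive_net_uptake"
    ))
  }
  flags <- character(0)
  if (lr < 0) flags <- c(flags, "deep_washout_late_below_background")
  index_result("WOind", 100 * lr / er - 100, er, lr,
               isTRUE(decay$enabled), flags)
}

#' Nodule-to-normal-tissue retention index (R.I.)
#'
#' Ratio-based index: at each timepoint the thorax-background-subtracted
#' mean nodular counts are divided by the thorax-background-subtracted mean
#' counts of the contralateral normal lobe, giving the early ratio ER and
#' delayed ratio DR; then
#'
#'   R.I. = 100 * (DR - ER) / ER
#'
#' A positive value means nodular contrast over normal tissue rose from the
#' early to the delayed scan (relative retention). Because each timepoint's
#' ratio divides two same-time means, any common per-timepoint factor
#' (physical decay included) cancels exactly.
#'
#' @param nodule_early,contralateral_early,thorax_bkg_early [roi_stats] at
#'   the early timepoint.
#' @param nodule_late,contralateral_late,thorax_bkg_late [roi_stats] at the
#'   late timepoint.
#' @param decay A [decay_spec].
#' @return An `index_result` with `method = "RI"`, `value`,
#'   `early_ratio_ER`, `late_term` (DR), `decay_corrected`, `flags`.
#' @export
retention_index <- function(nodule_early, contralateral_early,
                            thorax_bkg_early, nodule_late,
                            contralateral_late, thorax_bkg_late,
                            decay = decay_spec()) {
  check_labels(nodule_early, "nodule"); check_labels(nodule_late, "nodule")
  check_labels(contralateral_early, "contralateral")
  check_labels(contralateral_late, "contralateral")
  check_labels(thorax_bkg_early, "thorax_background")
  check_labels(thorax_bkg_late, "thorax_background")
  check_timepoints(
    early = list(nodule_early, contralateral_early, thorax_bkg_early),
    late = list(nodule_late, contralateral_late, thorax_bkg_late)
  )
  m <- function(s) maybe_decay_correct(s, decay)$mean_counts_per_pixel
  den_e <- m(contralateral_early) - m(thorax_bkg_early)
  den_l <- m(contralateral_late) - m(thorax_bkg_late)
  if (den_e <= 0 || den_l <= 0) {
    stop(format_error(
      "contralateral lobe counts do not exceed thorax background",
      "mibiquant_degenerate_ratio"
    ))
  }
  er <- (m(nodule_early) - m(thorax_bkg_early)) / den_e
  dr <- (m(nodule_late) - m(thorax_bkg_late)) / den_l
  if (er <= 0) {
    stop(format_error(
      "early nodule-to-normal ratio is not positive",
      "mibiquant_degenerate_ratio"
    ))
  }
  index_result("RI", 100 * (dr - er) / er, er, dr,
               isTRUE(decay$enabled), character(0))
}

index_result <- function(method, value, er, late_term, decay_corrected,
                         flags) {
  structure(
    list(method = method, value = value, early_ratio_ER = er,
         late_term = late_term, decay_corrected = decay_corrected,
         flags = flags),
    class = "index_result"
  )
}

#' @export
print.index_result <- function(x, ...) {
  cat(sprintf("<index_result> %s = %.4g (ER %.4g, %s %.4g%s)%s\n",
              x$method, x$value, x$early_ratio_ER,
              if (x$method == "WOind") "LR" else "DR", x$late_term,
              if (x$decay_corrected) ", decay-corrected" else "",
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

check_labels <- function(stats, expected) {
  if (!identical(stats$label, expected)) {
    stop(format_error(sprintf("expected ROI label '%s', got '%s'",
                              expected, stats$label)))
  }
  invisible(stats)
}

check_timepoints <- function(early, late) {
  te <- vapply(early, `[[`, numeric(1), "t_acq_min")
  tl <- vapply(late, `[[`, numeric(1), "t_acq_min")
  if (anyNA(c(te, tl))) return(invisible(NULL))  # timepoints optional
  if (length(unique(te)) > 1 || length(unique(tl)) > 1) {
    stop(format_error("ROI statistics mix acquisition timepoints"))
  }
  if (te[1] >= tl[1]) {
    stop(format_error("early acquisition must precede late acquisition"))
  }
  invisible(NULL)
}

#' Bundle one patient's dual-time-point MIBI study
#'
#' @param early,late [planar_image]s of the MIBI acquisitions;
#'   `early$t_acq_min < late$t_acq_min`.
#' @param rois Named list of [roi_mask]s drawn on the early image, keyed by
#'   label. Quantification needs `nodule` plus `mirror_background` (WOind)
#'   and/or `contralateral` + `thorax_background` (R.I.).
#' @param pertechnetate Optional pertechnetate [planar_image], carried for
#'   completeness (visual reading is out of scope).
#' @return An object of class `study_bundle`.
#' @export
study_bundle <- function(early, late, rois, pertechnetate = NULL) {
  stopifnot(inherits(early, "planar_image"), inherits(late, "planar_image"))
  if (!is.na(early$t_acq_min) && !is.na(late$t_acq_min) &&
      early$t_acq_min >= late$t_acq_min) {
    stop(format_error("early image must precede late image"))
  }
  for (nm in names(rois)) {
    r <- rois[[nm]]
    stopifnot(inherits(r, "roi_mask"))
    if (!all(r$source_grid == dim(early$counts))) {
      stop(format_error(sprintf("ROI '%s' grid does not match early image", nm)))
    }
  }
  structure(list(early = early, late = late, rois = rois,
                 pertechnetate = pertechnetate),
            class = "study_bundle")
}

#' Quantify a study with both indices
#'
#' Measures every required ROI on the early image, copies the ROIs onto the
#' late image grid, and computes the wash-out index and the retention index
#' from the same acquisitions. Intermediate [roi_stats] are retained for
#' audit.
#'
#' @param study A [study_bundle].
#' @param decay A [decay_spec].
#' @param methods Which indices to compute (default both).
#' @return List with elements `woind` and/or `ri` ([index_result]s) and
#'   `stats`, a named list of all intermediate [roi_stats].
#' @export
quantify_study <- function(study, decay = decay_spec(),
                           methods = c("WOind", "RI")) {
  methods <- match.arg(methods, several.ok = TRUE)
  need <- c("nodule",
            if ("WOind" %in% methods) "mirror_background",
            if ("RI" %in% methods) c("contralateral", "thorax_background"))
  missing <- setdiff(need, names(study$rois))
  if (length(missing)) {
    stop(format_error(paste0("missing ROI label(s): ",
                             paste(missing, collapse = ", "))))
  }
  eg <- dim(study$early$counts); lg <- dim(study$late$counts)
  stats <- list()
  for (nm in need) {
    roi_e <- study$rois[[nm]]
    roi_l <- copy_roi_to_late(roi_e, eg, lg)
    stats[[paste0(nm, "_early")]] <- roi_mean_counts(study$early, roi_e)
    stats[[paste0(nm, "_late")]] <- roi_mean_counts(study$late, roi_l)
  }
  out <- list(stats = stats)
  if ("WOind" %in% methods) {
    out$woind <- washout_index(stats$nodule_early,
                               stats$mirror_background_early,
                               stats$nodule_late,
                               stats$mirror_background_late, decay)
  }
  if ("RI" %in% methods) {
    out$ri <- retention_index(stats$nodule_early, stats$contralateral_early,
                              stats$thorax_background_early,
                              stats$nodule_late, stats$contralateral_late,
                              stats$thorax_background_late, decay)
  }
  out
}
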