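#' Configuration for a simulated patient cohort
#'
#' Class-conditional kinetics for a cohort of phantom studies. Retention
#' fractions are drawn from truncated normal distributions on `(0, 1]`:
#' malignant nodules retain most of their early uptake (mean 0.90), benign
#' nodules wash out more (mean 0.70), and normal parenchyma clears fastest
#' (mean 0.50), the kinetic ordering that motivates the wash-out method.
#' With the default −19% cutoff the noiseless class means sit at WOind −10
#' (malignant) and −30 (benign).
#'
#' @param n_patients Number of simulated patients.
#' @param malignant_fraction Fraction of malignant truth labels (default
#'   0.2, the malignancy rate of indeterminate-cytology series); the count
#'   is fixed by deterministic rounding.
#' @param f_nodule_benign,f_nodule_malignant,f_parenchyma Means of the
#'   truncated normal retention distributions.
#' @param f_sd Standard deviation of each retention distribution.
#' @param f_background Body-background retention (held fixed).
#' @param count_scale Multiplier on all count-rate densities; 1 gives a
#'   ~120 counts/pixel early nodule over a 600 s frame.
#' @param geometry A [phantom_geometry] shared by all patients.
#' @param times,frame_s Acquisition protocol.
#' @param apply_physical_decay Passed to each patient's [kinetic_params].
#' @param seed RNG seed governing every stochastic draw.
#' @return A `cohort_sim_config` object.
#' @export
cohort_sim_config <- function(n_patients = 20, malignant_fraction = 0.2,
                              f_nodule_benign = 0.70,
                              f_nodule_malignant = 0.90,
                              f_parenchyma = 0.50, f_sd = 0.05,
                              f_background = 0.50, count_scale = 1,
                              geometry = phantom_geometry(),
                              times = c(10, 60), frame_s = 600,
                              apply_physical_decay = FALSE,
                              seed = 1L) {
  stopifnot(n_patients >= 1, malignant_fraction >= 0,
            malignant_fraction <= 1, f_sd > 0, count_scale > 0)
  structure(list(n_patients = as.integer(n_patients),
                 malignant_fraction = malignant_fraction,
                 f_nodule_benign = f_nodule_benign,
                 f_nodule_malignant = f_nodule_malignant,
                 f_parenchyma = f_parenchyma, f_sd = f_sd,
                 f_background = f_background, count_scale = count_scale,
                 geometry = geometry, times = times, frame_s = frame_s,
                 apply_physical_decay = apply_physical_decay,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# normal truncated to (0, 1], by per-element rejection so each draw stays
# aligned with its own mean
rtrunc01 <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0 | x > 1)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- bad[x[bad] <= 0 | x[bad] > 1]
  }
  x
}

#' Simulate a cohort of dual-time-point phantom studies
#'
#' Draws per-patient kinetics from the class-conditional distributions in
#' `config`, builds a Poisson-noise phantom study for each patient, and
#' returns studies with ground-truth labels and kinetics. Fully
#' reproducible: the same config (including seed) yields identical output.
#'
#' @param config A [cohort_sim_config].
#' @return List with `patients` (each: `patient_id`, `study`, `truth_label`
#'   `"malignant"`/`"benign"`, `kinetics`, `woind_true`, `ri_true`),
#'   `truth` (data frame summary), and `config`.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  n <- config$n_patients
  n_mal <- round(n * config$malignant_fraction)
  labels <- rep(c("malignant", "benign"), c(n_mal, n - n_mal))
  set.seed(config$seed)
  f_nod <- rtrunc01(n, ifelse(labels == "malignant",
                              config$f_nodule_malignant,
                              config$f_nodule_benign), config$f_sd)
  f_par <- rtrunc01(n, config$f_parenchyma, config$f_sd)
  seeds <- sample.int(.Machine$integer.max, n)
  base <- kinetic_params()
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    kin <- kinetic_params(
      a0_nodule = base$a0_nodule * config$count_scale,
      a0_parenchyma = base$a0_parenchyma * config$count_scale,
      a0_body_background = base$a0_body_background * config$count_scale,
      f_nodule = f_nod[i], f_parenchyma = f_par[i],
      f_background = config$f_background,
      apply_physical_decay = config$apply_physical_decay
    )
    ph <- build_phantom(config$geometry, kin, config$times, config$frame_s,
                        noise = "poisson", seed = seeds[i])
    patients[[i]] <- list(
      patient_id = i, study = ph$study, truth_label = labels[i],
      kinetics = kin,
      woind_true = analytic_index(kin, "WOind", config$times,
                                  config$frame_s),
      ri_true = analytic_index(kin, "RI", config$times, config$frame_s)
    )
  }
  truth <- data.frame(
    patient_id = seq_len(n), truth_label = labels,
    f_nodule = f_nod, f_parenchyma = f_par,
    woind_true = vapply(patients, `[[`, numeric(1), "woind_true"),
    ri_true = vapply(patients, `[[`, numeric(1), "ri_true")
  )
  list(patients = patients, truth = truth, config = config)
}

#' Quantify and classify a simulated cohort
#'
#' Runs the full measurement pipeline (ROI statistics, both indices,
#' threshold classification) over a simulated cohort and evaluates the
#' calls against the simulation truth labels.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param thresholds A [decision_thresholds].
#' @param decay A [decay_spec].
#' @return List: `results` (data frame with both measured indices, calls
#'   and truth per patient), `performance` (per-method
#'   [performance_report][evaluate]s).
#' @export
quantify_cohort <- function(cohort, thresholds = decision_thresholds(),
                            decay = decay_spec()) {
  res <- lapply(cohort$patients, function(p) {
    q <- quantify_study(p$study, decay)
    data.frame(
      patient_id = p$patient_id,
      truth_label = p$truth_label,
      woind = q$woind$value, ri = q$ri$value,
      woind_call = classify(q$woind, thresholds)$call,
      ri_call = classify(q$ri, thresholds)$call,
      woind_true = p$woind_true, ri_true = p$ri_true
    )
  })
  results <- do.call(rbind, res)
  conf <- function(call) {
    pos <- call == "suspicious"
    truth <- results$truth_label == "malignant"
    performance_report(list(tp = sum(pos & truth), fp = sum(pos & !truth),
                            tn = sum(!pos & !truth), fn = sum(!pos & truth)))
  }
  list(results = results,
       performance = list(woind = conf(results$woind_call),
                          ri = conf(results$ri_call)))
}

#' Write a study bundle to a directory
#'
#' Emits `early.pgm` / `late.pgm` with JSON sidecars, one `roi_<label>.pgm`
#' mask per ROI, and a `study.json` manifest.
#'
#' @param study A [study_bundle] with integer counts.
#' @param dir Output directory (created if needed).
#' @param ascii Write ASCII PGM (default) or binary.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, ascii = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_planar_image(study$early, file.path(dir, "early.pgm"), ascii)
  write_planar_image(study$late, file.path(dir, "late.pgm"), ascii)
  for (nm in names(study$rois)) {
    write_roi_mask(study$rois[[nm]], file.path(dir, paste0("roi_", nm, ".pgm")))
  }
  jsonlite::write_json(list(rois = names(study$rois)),
                       file.path(dir, "study.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study bundle from a directory written by [write_study()]
#' @param dir Study directory.
#' @return A [study_bundle].
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "study.json"),
                                  simplifyVector = TRUE)
  early <- read_planar_image(file.path(dir, "early.pgm"))
  late <- read_planar_image(file.path(dir, "late.pgm"))
  rois <- lapply(manifest$rois, function(nm) {
    read_roi_mask(file.path(dir, paste0("roi_", nm, ".pgm")),
                  dim(early$counts), label = nm)
  })
  names(rois) <- manifest$rois
  study_bundle(early, late, rois)
}
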