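#' Default configuration for a full synthetic study
#'
#' Returns the study conditions emulated by the generators: eight virtual
#' subjects with liver volumes 65-97 mL, administered activities
#' 128-171 MBq, liver backgrounds 69-110 HU with 3-6 HU noise, CT grid
#' 0.313 x 0.313 x 2 mm, PET grid 2.039 mm isotropic with 5-10 mm system
#' blur, a 4 mm PET post-filter, and up to 1 cm respiratory smearing.
#' Every field can be overridden through `run_full_study(config = ...)`.
#'
#' @return Nested list of configuration defaults.
#' @export
default_study_config <- function() {
  list(
    n_subjects = 8,
    seed = 1,
    phantom = list(),               # phantom_spec() arguments
    subject = list(),               # fixed generate_virtual_subject() overrides
    subject_ranges = list(          # per-subject sampled conditions
      liver_volume_ml = c(65, 97),
      A0_mbq = c(128.1, 171.0),
      mu_bkg_hu = c(69.2, 109.9),
      ct_noise_hu = c(3.0, 5.6),
      pet_fwhm_mm = c(5, 10),
      resp_amplitude_mm = c(5, 10)),
    kernel = list(histories = 2e5, nbatch = 50),
    pet_postfilter_fwhm_mm = 4,
    liver_density_g_ml = 1.03,
    out_dir = NULL)
}

kernel_cached <- function(spacing, histories, nbatch, cache_dir) {
  if (is.null(cache_dir)) return(simulate_dvk(spacing, histories, nbatch = nbatch))
  key <- paste0("dvk_", paste(signif(spacing, 6), collapse = "x"), "_",
                format(histories, scientific = FALSE), ".nii.gz")
  path <- file.path(cache_dir, key)
  if (file.exists(path)) return(read_kernel(path))
  k <- simulate_dvk(spacing, histories, nbatch = nbatch)
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  write_kernel(k, path)
  k
}

#' Run the full synthetic study end to end
#'
#' Orchestrates phantom generation, calibration, virtual-subject
#' generation, CT and PET quantification, kernel generation, convolution
#' dosimetry, per-structure dose metrics, and cross-modality agreement —
#' the complete workflow — deterministically for a given seed.
#'
#' @param config list merged over [default_study_config()], or the path of
#'   a YAML file holding one.
#' @return Object of class `StudyReport`: `calibration` (curve +
#'   per-diameter slopes), `activity` (per-subject recovery table),
#'   `dose_metrics` (per-subject, per-structure, per-modality table),
#'   `agreement`, `config`, `manifest`.
#' @export
run_full_study <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_study_config(), config)
  set.seed(cfg$seed)

  # calibration phantom and curve (15 mm posts only, the default analysis)
  ph_args <- utils::modifyList(list(seed = cfg$seed + 1000L), cfg$phantom)
  phantom <- generate_phantom_ct(do.call(phantom_spec, ph_args))
  seg <- segment_posts(phantom)
  pts <- post_mean_table(phantom, seg)
  curve <- fit_calibration(pts[pts$diameter_mm == max(pts$diameter_mm), ])
  slopes <- slope_by_diameter(pts)

  subj_fixed <- cfg$subject
  ct_spacing <- subj_fixed$ct_spacing %||% c(0.313, 0.313, 2.0)
  pet_spacing <- rep_len(subj_fixed$pet_spacing %||% 2.039, 3)
  cache <- if (!is.null(cfg$out_dir)) file.path(cfg$out_dir, "kernels") else NULL
  kern_ct <- kernel_cached(ct_spacing, cfg$kernel$histories, cfg$kernel$nbatch, cache)
  kern_pet <- kernel_cached(pet_spacing, cfg$kernel$histories, cfg$kernel$nbatch, cache)
  const <- y90_constants()

  draw <- function(rng) runif(1, rng[1], rng[2])
  act_rows <- list(); met_rows <- list(); mird <- numeric(cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    sr <- cfg$subject_ranges
    args <- utils::modifyList(list(
      liver_volume_ml = draw(sr$liver_volume_ml),
      A0_bq = draw(sr$A0_mbq) * 1e6,
      mu_bkg_hu = draw(sr$mu_bkg_hu),
      ct_noise_hu = draw(sr$ct_noise_hu),
      pet_fwhm_mm = draw(sr$pet_fwhm_mm),
      resp_amplitude_mm = draw(sr$resp_amplitude_mm),
      seed = cfg$seed + i), subj_fixed)
    subj <- do.call(generate_virtual_subject, args)
    m <- subj$masks

    bkg <- background_stats(subj$ct, m$L_bkg)
    b_cal <- compute_intercept(bkg)
    conc <- ct_to_concentration(subj$ct, curve, intercept = b_cal, mask = m$L)
    a_ct <- concentration_to_activity(conc, subj$record)
    rc_ct <- recovery_coefficient(a_ct, m$L, subj$record)

    pet_f <- gaussian_postfilter(subj$pet, cfg$pet_postfilter_fwhm_mm)
    a_pet <- pet_to_activity(pet_f)
    pm <- lapply(m[c("L", "L_shell", "B")], resample_mask, target = subj$pet)
    rc_pet <- recovery_coefficient(a_pet, pm$L, subj$record)
    rc_pet_shell <- recovery_coefficient(a_pet, pm$L_shell, subj$record)
    ratio_out <- activity_ratio_outside(a_pet, pm$L_shell, pm$B)

    dd_ct <- convolve_dose(cumulated_activity(a_ct, const), kern_ct)
    dd_pet <- convolve_dose(cumulated_activity(a_pet, const), kern_pet)

    liver_ml <- mask_volume_ml(m$L)
    mird[i] <- mird_mean_dose(subj$record$A0 / 1e9, subj$record$residual_fraction,
                              liver_ml * cfg$liver_density_g_ml / 1000)

    act_rows[[i]] <- data.frame(
      subject = sprintf("S%02d", i), A0_mbq = subj$record$A0 / 1e6,
      liver_ml = liver_ml, mu_bkg = bkg$mu_bkg, sigma_bkg = bkg$sigma_bkg,
      b_cal = b_cal, rc_ct = rc_ct, rc_pet = rc_pet,
      rc_pet_shell = rc_pet_shell, pet_ratio_outside = ratio_out,
      d_mird = mird[i])
    mm_ct <- dose_metrics_by_structure(dd_ct, m[c("L", "L_shell", "B")])
    mm_ct$modality <- "CT"
    mm_pet <- dose_metrics_by_structure(dd_pet, pm)
    mm_pet$modality <- "PET"
    met <- rbind(mm_ct, mm_pet)
    met$subject <- sprintf("S%02d", i)
    met_rows[[i]] <- met
  }
  activity <- do.call(rbind, act_rows)
  metrics <- do.call(rbind, met_rows)

  ct_dmu <- metrics$D_mu[metrics$modality == "CT" & metrics$structure == "L"]
  pet_dmu <- metrics$D_mu[metrics$modality == "PET" & metrics$structure == "L_shell"]
  agree <- if (cfg$n_subjects >= 3)
    agreement_summary(ct_dmu, pet_dmu, mird) else NULL

  manifest <- list(seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   n_subjects = cfg$n_subjects,
                   kernel_histories = cfg$kernel$histories,
                   generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  report <- structure(list(calibration = list(curve = curve, slopes = slopes,
                                              fit_points = pts),
                           activity = activity, dose_metrics = metrics,
                           agreement = agree, mird = mird, config = cfg,
                           manifest = manifest),
                      class = "StudyReport")
  if (!is.null(cfg$out_dir)) write_study_report(report, cfg$out_dir)
  report
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$activity, file.path(out_dir, "activity.csv"), row.names = FALSE)
  write.csv(report$dose_metrics, file.path(out_dir, "dose_metrics.csv"),
            row.names = FALSE)
  cal <- report$calibration
  jsonlite::write_json(
    list(m_cal = cal$curve$m_cal, m_cal_ci95 = cal$curve$m_cal_ci95,
         b_cal_fit = cal$curve$b_cal, r_squared = cal$curve$r_squared,
         fit_points = cal$curve$fit_points),
    file.path(out_dir, "calibration.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$agreement)) {
    ag <- report$agreement
    jsonlite::write_json(
      list(regression = ag$regression[c("slope", "intercept", "r_squared",
                                        "slope_ci95")],
           bland_altman = ag$bland_altman[c("bias", "sd", "limits")],
           anova = ag$anova),
      file.path(out_dir, "agreement.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.StudyReport <- function(x, ...) {
  cat(sprintf("<StudyReport> %d subjects, m_cal = %.3f (r^2 = %.4f)\n",
              nrow(x$activity), x$calibration$curve$m_cal,
              x$calibration$curve$r_squared))
  cat(sprintf("  RC_CT %.1f%% (mean), RC_PET %.1f%%, RC_PET_shell %.1f%%\n",
              mean(x$activity$rc_ct), mean(x$activity$rc_pet),
              mean(x$activity$rc_pet_shell)))
  if (!is.null(x$agreement)) print(x$agreement)
  invisible(x)
}
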