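#' Pearson product-moment correlation with a t-test
#'
#' Sample Pearson r with the two-sided p-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. The
#' significance level used throughout the studies is 5%.
#'
#' @param x,y numeric series of equal length `n >= 3`, both non-constant.
#' @return a list with `r`, `p`, `n`, `df` and `significant` (p < 0.05).
#' @export
pearson_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant series")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- clip(r, -1, 1)
  p <- if (abs(r) == 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(r = r, p = p, n = n, df = n - 2, significant = p < 0.05),
            class = "pearson_test")
}

#' @export
print.pearson_test <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f, p = %.3g (n = %d)%s\n", x$r, x$p, x$n,
              if (x$significant) " *" else ""))
  invisible(x)
}

default_backends <- function() c("akaze", "brisk", "orb", "ref")

# score one reference/target pair across backends; returns record rows
condition_records <- function(series, label, param, ref_feats, tgt8, ref8,
                              backends, params_list, ssim_par) {
  s_val <- ssim(ref8, tgt8, ssim_par)
  p_val <- psnr(ref8, tgt8)
  rows <- lapply(backends, function(b) {
    ft <- detect_and_describe(tgt8, params_list[[b]])
    fr <- ref_feats[[b]]
    m <- brute_force_match(fr$descriptors, ft$descriptors)
    pi_val <- if (m$N >= 1) mean(m$pairs$distance) else NA_real_
    data.frame(series = series, label = label, param = param, backend = b,
               keypoints_ref = nrow(fr$keypoints),
               keypoints_tgt = nrow(ft$keypoints),
               n_matches = m$N, pi = pi_val, ssim = s_val, psnr = p_val)
  })
  do.call(rbind, rows)
}

correlate_records <- function(records) {
  out <- list()
  for (s in unique(records$series)) {
    rs <- records[records$series == s, ]
    for (b in unique(rs$backend)) {
      rb <- rs[rs$backend == b & !is.na(rs$pi), ]
      if (nrow(rb) < 3) next
      if (stats::sd(rb$pi) == 0 || stats::sd(rb$ssim) == 0) {
        # a perfectly constant index across the series is the extreme case
        # of "no correlation with SSIM": recorded as NA, not an error
        out[[length(out) + 1]] <- data.frame(
          series = s, metric = "pi", backend = b, r = NA_real_, p = NA_real_,
          n = nrow(rb), significant = FALSE)
        next
      }
      ct <- pearson_test(rb$pi, rb$ssim)
      out[[length(out) + 1]] <- data.frame(
        series = s, metric = "pi", backend = b, r = ct$r, p = ct$p,
        n = ct$n, significant = ct$significant)
    }
    r1 <- rs[!duplicated(rs$label), ]
    r1 <- r1[is.finite(r1$psnr) & is.finite(r1$ssim), ]  # identity has PSNR Inf
    if (nrow(r1) >= 3 && stats::sd(r1$psnr) > 0 && stats::sd(r1$ssim) > 0) {
      ct <- pearson_test(r1$psnr, r1$ssim)
      out[[length(out) + 1]] <- data.frame(
        series = s, metric = "psnr", backend = "-", r = ct$r, p = ct$p,
        n = ct$n, significant = ct$significant)
    }
  }
  do.call(rbind, out)
}

study_result <- function(records, correlations, stability, params) {
  structure(list(records = records, correlations = correlations,
                 stability = stability, params = params),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d condition records, %d correlation summaries\n",
              nrow(x$records), nrow(x$correlations)))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' Validity study: noise and blur series against SSIM
#'
#' Reproduces the validity experiment: target images degraded by
#' dose-dependent quantum noise and by Gaussian blur are scored with the
#' keypoint index per backend, and with SSIM and PSNR; Pearson correlations
#' of index-vs-SSIM (per backend and series) and PSNR-vs-SSIM (per series)
#' are summarized. Image quality degrading should drive the index up while
#' SSIM falls, i.e. strongly negative correlations.
#'
#' Noise conditions are built by adding noise to `base` (by default the
#' reference itself; pass the clean phantom so the reference can carry its
#' own acquisition noise) and windowing to 8 bits; blur conditions blur the
#' 8-bit reference directly. Conditions with zero matches are recorded but
#' excluded from the correlations, with a warning.
#'
#' @param ref the reference image (windowed to 8-bit with `window` if
#'   necessary).
#' @param noise_series list of [dose_noise_spec()], e.g. [dose_series()].
#' @param blur_series list of [blur_spec()], e.g. [blur_series()].
#' @param backends character vector of backend names.
#' @param base image the noise conditions degrade; default `ref`.
#' @param window a [window_spec()] used to bring CT-like images to 8 bits.
#' @param ssim_par an [ssim_params()].
#' @return a `study_result` with `records`, `correlations` and `params`.
#' @export
run_validity_study <- function(ref, noise_series = dose_series(),
                               blur_series = kpiqa::blur_series(),
                               backends = default_backends(),
                               base = NULL, window = NULL,
                               ssim_par = ssim_params()) {
  base <- base %||% ref
  ref8 <- to_eight_bit(ref, window)
  params_list <- lapply(stats::setNames(backends, backends), backend_params)
  ref_feats <- lapply(params_list, function(p) detect_and_describe(ref8, p))
  recs <- list()
  for (i in seq_along(noise_series)) {
    sp <- noise_series[[i]]
    tgt8 <- to_eight_bit(simulate_dose_noise(base, sp), window)
    recs[[length(recs) + 1]] <- condition_records(
      "noise", names(noise_series)[i] %||% sprintf("noise-%d", i),
      sp$ctdi, ref_feats, tgt8, ref8, backends, params_list, ssim_par)
  }
  for (i in seq_along(blur_series)) {
    sp <- blur_series[[i]]
    tgt8 <- gaussian_blur(ref8, sp)
    recs[[length(recs) + 1]] <- condition_records(
      "blur", names(blur_series)[i] %||% sprintf("blur-%d", i),
      sp$k, ref_feats, tgt8, ref8, backends, params_list, ssim_par)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  if (any(records$n_matches == 0)) {
    warning(sum(records$n_matches == 0),
            " condition(s) had zero matches and were excluded from correlation")
  }
  study_result(records, correlate_records(records), stability = NULL,
               params = list(study = "validity", backends = backends,
                             ssim = unclass(ssim_par),
                             n_noise = length(noise_series),
                             n_blur = length(blur_series)))
}

#' Robustness study: affine series that leave image quality unchanged
#'
#' Scores targets produced by translating, rotating and scaling the
#' reference. A robust quality index should stay nearly constant (the
#' transforms do not change intrinsic quality) while SSIM and PSNR degrade.
#' Besides the correlation summaries, a stability table reports, per series
#' and backend, the coefficient of variation of the index alongside SSIM's
#' relative range.
#'
#' @inheritParams run_validity_study
#' @param series named list of affine series (lists of [affine_spec()]),
#'   default the standard translation/rotation/reduction/enlargement grids.
#' @export
run_robustness_study <- function(ref,
                                 series = list(
                                   translation = translation_series(),
                                   rotation = rotation_series(),
                                   reduction = reduction_series(),
                                   enlargement = enlargement_series()),
                                 backends = default_backends(),
                                 window = NULL, ssim_par = ssim_params()) {
  ref8 <- to_eight_bit(ref, window)
  params_list <- lapply(stats::setNames(backends, backends), backend_params)
  ref_feats <- lapply(params_list, function(p) detect_and_describe(ref8, p))
  recs <- list()
  for (sname in names(series)) {
    sers <- series[[sname]]
    for (i in seq_along(sers)) {
      sp <- sers[[i]]
      tgt8 <- apply_affine(ref8, sp)
      par <- switch(sp$kind, translate = sp$dx, rotate = sp$angle,
                    scale = sp$factor)
      recs[[length(recs) + 1]] <- condition_records(
        sname, names(sers)[i] %||% sprintf("%s-%d", sname, i),
        par, ref_feats, tgt8, ref8, backends, params_list, ssim_par)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  if (any(records$n_matches == 0)) {
    warning(sum(records$n_matches == 0),
            " condition(s) had zero matches and were excluded from correlation")
  }
  stab <- list()
  for (s in unique(records$series)) {
    rs <- records[records$series == s, ]
    for (b in unique(rs$backend)) {
      rb <- rs[rs$backend == b & !is.na(rs$pi), ]
      stab[[length(stab) + 1]] <- data.frame(
        series = s, backend = b, n = nrow(rb),
        pi_mean = mean(rb$pi), pi_sd = stats::sd(rb$pi),
        pi_cv = coef_variation(rb$pi),
        ssim_rel_range = relative_range(rb$ssim))
    }
  }
  study_result(records, correlate_records(records),
               stability = do.call(rbind, stab),
               params = list(study = "robustness", backends = backends,
                             ssim = unclass(ssim_par),
                             series = names(series)))
}

#' One-call standard studies on the synthetic phantom
#'
#' `phantom_validity_study()` generates the default head phantom, derives a
#' reference image carrying reference-dose acquisition noise (CTDIvol
#' 89.1 mGy), degrades the phantom over the standard ten-dose noise series
#' and ten-kernel blur series, and runs [run_validity_study()].
#' `phantom_robustness_study()` runs the full affine battery
#' ([run_robustness_study()]) against the noise-free windowed phantom, so
#' the series isolates geometric effects. All randomness derives from
#' `seed`: the phantom uses `seed`, the reference acquisition `seed + 998`,
#' and noise condition `i` uses `seed + i`.
#'
#' @param seed integer master seed.
#' @param size phantom side length in pixels.
#' @param backends backends to evaluate.
#' @return a `study_result`.
#' @export
phantom_validity_study <- function(seed = 1L, size = 512L,
                                   backends = default_backends()) {
  ph <- generate_head_phantom(phantom_spec(size = size, seed = seed))
  ref <- simulate_dose_noise(ph, dose_noise_spec(89.1, seed = seed + 998L))
  run_validity_study(ref, noise_series = dose_series(seed = seed),
                     blur_series = blur_series(), backends = backends,
                     base = ph)
}

#' @rdname phantom_validity_study
#' @export
phantom_robustness_study <- function(seed = 1L, size = 512L,
                                     backends = default_backends()) {
  ph <- generate_head_phantom(phantom_spec(size = size, seed = seed))
  run_robustness_study(to_eight_bit(ph), backends = backends)
}
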