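#' Run a longitudinal phantom study in memory
#'
#' Streams the full pipeline over every subject and wave of a phantom
#' cohort — simulate DWI, fit tensors, track, extract each bundle, measure
#' tract mean FA (and optionally the along-tract profile) — without
#' writing intermediate volumes to disk. One subject-wave is held in
#' memory at a time, so cohort size is not memory-bound.
#'
#' @param spec a [phantom_cohort_spec()].
#' @param bundles list of [curve_bundle_spec()]s (default the three
#'   built-in fixtures).
#' @param geom a [vol_geometry()].
#' @param scheme a [gradient_scheme()].
#' @param params a [tracking_params()].
#' @param min_fibers per-subject bundle recognition threshold.
#' @param profile also compute the 100-segment two-ROI profile per
#'   subject-wave-bundle (slower).
#' @param n_segments profile segments.
#' @param verbose print progress.
#' @return list with \code{cohort} (a [cohort_table()] that additionally
#'   carries \code{n_fibers}), \code{truth} (the generative ground truth),
#'   \code{detection} (per-connection subject detection counts), and, when
#'   \code{profile = TRUE}, \code{profiles} (long per-subject segment
#'   table).
#' @export
run_phantom_study <- function(spec, bundles = bundle_fixtures(geom),
                              geom = default_geometry(),
                              scheme = default_gradient_scheme(),
                              params = tracking_params(),
                              min_fibers = 20L, profile = FALSE,
                              n_segments = 100L, verbose = FALSE) {
  if (inherits(bundles, "curve_bundle_spec")) bundles <- list(bundles)
  nms <- names(bundles) %||% vapply(bundles, function(b) b$name, "")
  truth <- cohort_truth(spec, length(bundles), nms)
  rows <- vector("list", spec$n_subjects * spec$waves * length(bundles))
  prows <- list()
  ri <- 0L
  for (s in seq_len(spec$n_subjects)) for (w in seq_len(spec$waves)) {
    if (verbose) message(sprintf("subject %d wave %d", s, w))
    sw <- simulate_subject_wave(spec, truth, s, w, bundles, geom, scheme)
    eig <- tensor_eigensystem(fit_tensor(sw$dwi))
    fa <- fa_map(eig)
    sl <- fact_track(eig, fa, params)
    for (bi in seq_along(bundles)) {
      bs <- bundles[[bi]]
      bd <- extract_bundle(sl, sw$labels, bs$seed_label, bs$target_label,
                           geom = geom, name = nms[bi])
      tr <- sw$truth[sw$truth$bundle == nms[bi], ]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(subject = s, wave = w, connection = nms[bi],
                               mean_fa = tract_mean_fa(bd, fa),
                               n_fibers = bd$n_fibers,
                               age = tr$age[1], interval = tr$interval[1])
      if (profile && bd$n_fibers > 0L) {
        bdo <- orient_bundle(bd, sw$labels == bs$seed_label)
        pr <- profile_two_roi(bdo, fa, n = n_segments)
        prows[[length(prows) + 1L]] <- data.frame(
          subject = s, wave = w, connection = nms[bi],
          segment = pr$segment, mean_fa = pr$mean_fa, se = pr$se, n = pr$n)
      }
    }
  }
  tab <- do.call(rbind, rows)
  cohort <- cohort_table(tab$subject, tab$wave, tab$connection, tab$mean_fa,
                         tab$age, tab$interval)
  cohort$n_fibers <- tab$n_fibers
  out <- list(cohort = cohort, truth = truth,
              detection = detection_counts(tab, min_fibers))
  if (profile) out$profiles <- do.call(rbind, prows)
  out
}
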