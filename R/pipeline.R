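#' Pipeline run configuration
#'
#' All knobs of an end-to-end phantom study run, with the package defaults.
#' Values can be overridden by a plain-text \code{key = value} config file
#' ([read_run_config()]) and again by arguments (later wins).
#'
#' @param out_dir output directory.
#' @param seed master RNG seed (drives cohort design and acquisition noise).
#' @param n_subjects,waves,interval_years,interval_sd,baseline_fa
#'   cohort design, see [phantom_cohort_spec()].
#' @param annual_decline_pct,annual_decline_sd true FA change distribution
#'   (percent per year; recycled per bundle).
#' @param snr,s0,trace acquisition model.
#' @param bundles character vector naming [bundle_fixtures()] members.
#' @param dim,voxel_size grid geometry.
#' @param fa_stop,angle_stop tracking termination parameters.
#' @param min_fibers,detect_fraction bundle recognition criteria.
#' @param n_segments along-tract segments.
#' @param alpha nominal alpha before Bonferroni correction.
#' @param log_level "quiet" or "info".
#' @return list of class \code{run_config}.
#' @export
pipeline_config <- function(out_dir = "tractwise_run", seed = 1L,
                            n_subjects = 10L, waves = 2L,
                            interval_years = 3.6, interval_sd = 0.3,
                            baseline_fa = 0.45,
                            annual_decline_pct = 1.5,
                            annual_decline_sd = 0.5,
                            snr = 25, s0 = 100, trace = 2.1e-3,
                            bundles = c("straight", "arc", "scurve"),
                            dim = c(40L, 40L, 20L), voxel_size = c(2, 2, 2),
                            fa_stop = 0.15, angle_stop = 35,
                            min_fibers = 20L, detect_fraction = 0.9,
                            n_segments = 100L, alpha = 0.05,
                            log_level = "info") {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Read a plain-text run configuration
#'
#' \code{key = value} lines; \code{#} starts a comment; comma-separated
#' values become vectors. Keys must match [pipeline_config()] arguments.
#'
#' @param path config file.
#' @param ... overrides applied after the file (arguments win).
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L) stop("malformed config line: ", ln)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    kv[[key]] <- if (any(is.na(num))) vals else num
  }
  kv <- utils::modifyList(kv, list(...))
  do.call(pipeline_config, kv)
}

pl_log <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message(sprintf("[tractwise] %s", sprintf(...)))
  invisible(NULL)
}

stage_done <- function(cfg, stage) {
  file.exists(file.path(cfg$out_dir, sprintf(".stage_%s.done", stage)))
}

mark_stage <- function(cfg, stage) {
  writeLines(format(Sys.time()), file.path(cfg$out_dir,
                                           sprintf(".stage_%s.done", stage)))
}

run_geom <- function(cfg) vol_geometry(cfg$dim, cfg$voxel_size)

run_spec <- function(cfg) {
  phantom_cohort_spec(n_subjects = cfg$n_subjects, waves = cfg$waves,
                      interval_years = cfg$interval_years,
                      interval_sd = cfg$interval_sd,
                      baseline_fa = cfg$baseline_fa,
                      annual_decline_pct = cfg$annual_decline_pct,
                      annual_decline_sd = cfg$annual_decline_sd,
                      snr = cfg$snr, s0 = cfg$s0, trace = cfg$trace,
                      rng_seed = cfg$seed)
}

run_bundles <- function(cfg) bundle_fixtures(run_geom(cfg), which = cfg$bundles)

sw_tag <- function(s, w) sprintf("sub-%02d_wave-%d", s, w)

#' Run the tractometry pipeline end to end
#'
#' Executes the stages \code{simulate}, \code{fit}, \code{track},
#' \code{extract}, \code{profile}, \code{stats} in order, writing each
#' stage's products under \code{out_dir} and recording a run manifest
#' (seed, parameters, package version, output checksums). Completed stages
#' are skipped on re-run, so any prefix is resumable from cached outputs;
#' deleting a stage's \code{.stage_*.done} marker (and outputs) recomputes
#' it. With a fixed seed the report TSVs are byte-identical across runs.
#'
#' @param cfg a [pipeline_config()] (or path to a config file).
#' @param stages subset of stages to run, default all.
#' @return invisibly, the path of the output directory.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("simulate", "fit", "track", "extract",
                                    "profile", "stats")) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  all_stages <- c("simulate", "fit", "track", "extract", "profile", "stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("raw", "fa", "trk", "tables"))
    dir.create(file.path(cfg$out_dir, sub), showWarnings = FALSE)
  runner <- list(simulate = stage_simulate, fit = stage_fit,
                 track = stage_track, extract = stage_extract,
                 profile = stage_profile, stats = stage_stats)
  for (st in all_stages[all_stages %in% stages]) {
    if (stage_done(cfg, st)) {
      pl_log(cfg, "stage %s: cached, skipping", st)
      next
    }
    pl_log(cfg, "stage %s: running", st)
    ok <- tryCatch({
      runner[[st]](cfg)
      TRUE
    }, error = function(e) {
      stop(sprintf("stage %s failed: %s", st, conditionMessage(e)),
           call. = FALSE)
    })
    if (ok) mark_stage(cfg, st)
  }
  write_manifest(cfg)
  invisible(cfg$out_dir)
}

stage_simulate <- function(cfg) {
  spec <- run_spec(cfg)
  geom <- run_geom(cfg)
  bundles <- run_bundles(cfg)
  scheme <- default_gradient_scheme()
  truth <- cohort_truth(spec, length(bundles), names(bundles))
  write.table(truth, file.path(cfg$out_dir, "raw", "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in seq_len(spec$n_subjects)) for (w in seq_len(spec$waves)) {
    sw <- simulate_subject_wave(spec, truth, s, w, bundles, geom, scheme)
    base <- file.path(cfg$out_dir, "raw", sw_tag(s, w))
    write_dwi(sw$dwi, paste0(base, "_dwi.nii.gz"),
              paste0(base, ".bval"), paste0(base, ".bvec"))
    write_label_volume(sw$labels, geom, paste0(base, "_labels.nii.gz"))
  }
  invisible(NULL)
}

stage_fit <- function(cfg) {
  geom <- run_geom(cfg)
  for_each_sw(cfg, function(s, w) {
    base <- file.path(cfg$out_dir, "raw", sw_tag(s, w))
    dwi <- read_dwi(paste0(base, "_dwi.nii.gz"), paste0(base, ".bval"),
                    paste0(base, ".bvec"))
    tv <- fit_tensor(dwi)
    eig <- tensor_eigensystem(tv)
    fa <- fa_map(eig)
    out <- file.path(cfg$out_dir, "fa", sw_tag(s, w))
    write_fa(fa, paste0(out, "_fa.nii.gz"), eig = eig,
             template = dwi$template)
  })
}

stage_track <- function(cfg) {
  for_each_sw(cfg, function(s, w) {
    fa <- read_fa_volume(file.path(cfg$out_dir, "fa",
                                   paste0(sw_tag(s, w), "_fa.nii.gz")))
    v1 <- as.array(RNifti::readNifti(
      file.path(cfg$out_dir, "fa", paste0(sw_tag(s, w), "_fa_v1.nii.gz"))))
    params <- tracking_params(fa_stop = cfg$fa_stop,
                              angle_stop = cfg$angle_stop)
    sl <- fact_track(v1, fa, params, geom = fa$geom)
    write_trk(sl, file.path(cfg$out_dir, "trk",
                            paste0(sw_tag(s, w), ".trk")))
  })
}

stage_extract <- function(cfg) {
  geom <- run_geom(cfg)
  bundles <- run_bundles(cfg)
  truth <- read.table(file.path(cfg$out_dir, "raw", "truth.tsv"),
                      header = TRUE, sep = "\t")
  rows <- list()
  for_each_sw(cfg, function(s, w) {
    sl <- read_trk(file.path(cfg$out_dir, "trk", paste0(sw_tag(s, w), ".trk")))
    lab <- read_label_volume(file.path(cfg$out_dir, "raw",
                                       paste0(sw_tag(s, w), "_labels.nii.gz")))
    fa <- read_fa_volume(file.path(cfg$out_dir, "fa",
                                   paste0(sw_tag(s, w), "_fa.nii.gz")))
    for (bn in names(bundles)) {
      bs <- bundles[[bn]]
      bd <- extract_bundle(sl, lab$labels, bs$seed_label, bs$target_label,
                           geom = geom, name = bn)
      tr <- truth[truth$subject == s & truth$wave == w &
                    truth$bundle == bn, ]
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = s, wave = w, connection = bn, n_fibers = bd$n_fibers,
        mean_fa = tract_mean_fa(bd, fa),
        age = tr$age[1], interval = tr$interval[1])
    }
  })
  tab <- do.call(rbind, rows)
  write.table(tab, file.path(cfg$out_dir, "tables", "cohort_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  det <- detection_counts(tab, cfg$min_fibers)
  qual <- cohort_detection_filter(det, cfg$n_subjects, cfg$detect_fraction)
  dtab <- data.frame(connection = names(det), n_subjects_detected = det,
                     qualifies = as.vector(qual))
  write.table(dtab, file.path(cfg$out_dir, "tables", "detection.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

stage_profile <- function(cfg) {
  geom <- run_geom(cfg)
  bundles <- run_bundles(cfg)
  rows <- list()
  for_each_sw(cfg, function(s, w) {
    sl <- read_trk(file.path(cfg$out_dir, "trk", paste0(sw_tag(s, w), ".trk")))
    lab <- read_label_volume(file.path(cfg$out_dir, "raw",
                                       paste0(sw_tag(s, w), "_labels.nii.gz")))
    fa <- read_fa_volume(file.path(cfg$out_dir, "fa",
                                   paste0(sw_tag(s, w), "_fa.nii.gz")))
    for (bn in names(bundles)) {
      bs <- bundles[[bn]]
      bd <- extract_bundle(sl, lab$labels, bs$seed_label, bs$target_label,
                           geom = geom, name = bn)
      if (bd$n_fibers == 0L) next
      bd <- orient_bundle(bd, lab$labels == bs$seed_label)
      pr <- profile_two_roi(bd, fa, n = cfg$n_segments)
      rows[[length(rows) + 1L]] <<- data.frame(
        subject = s, wave = w, connection = bn, segment = pr$segment,
        mean_fa = pr$mean_fa, se = pr$se, n = pr$n)
    }
  })
  tab <- do.call(rbind, rows)
  write.table(tab, file.path(cfg$out_dir, "tables", "profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

stage_stats <- function(cfg) {
  tabdir <- file.path(cfg$out_dir, "tables")
  cohort <- read.table(file.path(tabdir, "cohort_table.tsv"), header = TRUE,
                       sep = "\t")
  det <- read.table(file.path(tabdir, "detection.tsv"), header = TRUE,
                    sep = "\t")
  keep <- det$connection[det$qualifies]
  cohort <- cohort[cohort$connection %in% keep & cohort$n_fibers >= cfg$min_fibers, ]
  ct <- connection_change_table(cohort, alpha = cfg$alpha)
  write.table(as.data.frame(ct), file.path(tabdir, "change_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- read.table(file.path(tabdir, "profiles.tsv"), header = TRUE,
                     sep = "\t")
  seg_rows <- list()
  for (cn in unique(prof$connection)) {
    sub <- prof[prof$connection == cn, ]
    arr <- profiles_to_array(sub)
    ints <- tapply(cohort$interval[cohort$connection == cn],
                   cohort$subject[cohort$connection == cn],
                   function(v) sum(v, na.rm = TRUE))
    ints <- ints[match(sort(unique(sub$subject)), names(ints))]
    ints[is.na(ints) | ints <= 0] <- cfg$interval_years * (dim(arr)[2] - 1L)
    st <- segmentwise_longitudinal_test(arr, intervals = as.numeric(ints),
                                        alpha = cfg$alpha)
    st <- as.data.frame(st)
    st <- cbind(connection = cn, st)
    seg_rows[[length(seg_rows) + 1L]] <- st
  }
  seg <- do.call(rbind, seg_rows)
  write.table(seg, file.path(tabdir, "segment_tests.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

for_each_sw <- function(cfg, f) {
  for (s in seq_len(cfg$n_subjects)) for (w in seq_len(cfg$waves)) f(s, w)
  invisible(NULL)
}

#' Read an FA NIfTI as an \code{fa_volume}
#' @param path NIfTI path; masked voxels are stored as 0 on disk.
#' @export
read_fa_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  geom <- vol_geometry(dim(arr)[1:3], RNifti::pixdim(img)[1:3])
  structure(list(fa = arr, mask = array(TRUE, geom$dim), geom = geom),
            class = "fa_volume")
}

write_manifest <- function(cfg) {
  scalar <- function(v) paste(format(v, trim = TRUE), collapse = ",")
  keys <- setdiff(names(cfg), "log_level")
  lines <- c(sprintf("package_version\t%s",
                     as.character(packageVersion("tractwise"))),
             vapply(keys, function(k) sprintf("%s\t%s", k, scalar(cfg[[k]])),
                    ""))
  tabs <- list.files(file.path(cfg$out_dir, "tables"), full.names = TRUE)
  if (length(tabs)) {
    sums <- tools::md5sum(tabs)
    lines <- c(lines, sprintf("md5_%s\t%s", basename(names(sums)), sums))
  }
  writeLines(lines, file.path(cfg$out_dir, "manifest.tsv"))
  invisible(NULL)
}
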