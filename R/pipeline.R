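#' Pipeline configuration
#'
#' One object configures an end-to-end run: where the data come from
#' (a [study_spec()] for in-memory synthesis, or a directory written by
#' [generate_study()]), the per-stage parameter blocks, the analysis
#' channel, and the global seed from which every stage seed derives.
#'
#' @param input either a `study_spec` (synthetic layout) or a path to a
#'   study directory containing `manifest.json` (bids-like layout).
#' @param gait [gait_params()] block.
#' @param preproc [preproc_params()] block.
#' @param tf [tf_params()] block.
#' @param stats [stats_params()] block.
#' @param analysis_channel channel for the group statistics; `NULL` = the
#'   montage vertex channel.
#' @param do_ica run ICA eye removal (slowest stage; the synthetic world
#'   only needs it when blinks are injected)?
#' @param do_spca fit and apply the spectral-PCA artifact attenuation?
#' @param do_footprint compute the data-quality footprint (requires
#'   `do_spca`)?
#' @param profile `"full"` runs the complete cleaning chain on every
#'   channel; `"minimal"` is the scaled-down recovery profile (resample,
#'   full-rank CAR, light band-pass on the `tf_channels` subset only) used
#'   when only the phase-locked statistics at the analysis channel are of
#'   interest and compute is constrained.
#' @param tf_channels channel labels to carry through time-frequency
#'   analysis (`NULL` = all); the analysis channel is always included.
#' @param out_dir optional directory for the results manifest.
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, gait = gait_params(),
                            preproc = preproc_params(), tf = tf_params(),
                            stats = stats_params(),
                            analysis_channel = NULL,
                            do_ica = TRUE, do_spca = TRUE,
                            do_footprint = TRUE,
                            profile = c("full", "minimal"),
                            tf_channels = NULL,
                            out_dir = NULL, seed = 1L) {
  profile <- match.arg(profile)
  if (do_footprint && !do_spca) {
    stop("the footprint comparison requires the spectral-PCA stage")
  }
  blocks <- list(gait = gait, preproc = preproc, tf = tf, stats = stats)
  classes <- c(gait = "gait_params", preproc = "preproc_params",
               tf = "tf_params", stats = "stats_params")
  for (nm in names(classes)) {
    if (is.null(blocks[[nm]])) {
      stop("pipeline config is missing the '", nm, "' stage block")
    }
    if (!inherits(blocks[[nm]], classes[[nm]])) {
      stop("stage block '", nm, "' must be a ", classes[[nm]], " object")
    }
  }
  if (!inherits(input, "study_spec")) {
    if (!is.character(input) ||
        !file.exists(file.path(input, "manifest.json"))) {
      stop("input must be a study_spec or a study directory with ",
           "manifest.json")
    }
  }
  structure(list(input = input, gait = gait, preproc = preproc, tf = tf,
                 stats = stats, analysis_channel = analysis_channel,
                 do_ica = do_ica, do_spca = do_spca,
                 do_footprint = do_footprint, profile = profile,
                 tf_channels = tf_channels,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# keep only the named channels of a recording
subset_channels <- function(rec, labels) {
  idx <- match(intersect(labels, rec$montage$label), rec$montage$label)
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$montage <- rec$montage[idx, , drop = FALSE]
  rec
}

# scaled-down cleaning: resample -> full-rank CAR -> channel subset ->
# light zero-phase band-pass (0.5 Hz transitions); CAR and linear filtering
# commute, so subsetting after CAR is exact
preprocess_minimal <- function(rec, params, channels = NULL) {
  if (rec$srate != params$target_rate) {
    ratio <- rec$srate / params$target_rate
    if (abs(ratio - round(ratio)) > 1e-9) stop("non-integer resample factor")
    ratio <- as.integer(round(ratio))
    h <- fir_design(16L * ratio, 0, 0.4 * params$target_rate, rec$srate)
    keep <- seq(1L, ncol(rec$data), by = ratio)
    rec$data <- fir_filtfilt_mat(h, rec$data)[, keep, drop = FALSE]
    rec$srate <- params$target_rate
  }
  rec <- rereference_car(rec)
  if (!is.null(channels)) rec <- subset_channels(rec, channels)
  ord <- 2L * round(3.3 / 0.5 * rec$srate / 2)
  h <- fir_design(ord, params$band[1], params$band[2], rec$srate)
  rec$data <- fir_filtfilt_mat(h, rec$data)
  rec
}

# basic cleaning chain shared by standing and walking recordings:
# resample/filter -> bad channels -> (burst hook) -> line noise ->
# interpolate -> full-rank CAR
preprocess_basic <- function(rec, params, hook = NULL) {
  rec <- resample_and_filter(rec, params)
  rec$bads <- as.character(find_bad_channels(rec, params))
  rec <- burst_correct_hook(rec, params, hook)
  rec <- remove_line_noise(rec, params)
  rec <- interpolate_bads(rec)
  rec <- rereference_car(rec)
  rec
}

#' Run the full analysis pipeline
#'
#' Executes, per subject: gait-event detection from the foot accelerometers;
#' EEG cleaning (filtering, bad channels, line noise, interpolation,
#' full-rank common average, optional ICA eye removal); Morlet decomposition
#' of the standing baseline and each walking condition; gait-cycle warping
#' and dB baselining into condition ERSPs plus the all-condition average;
#' spectral-PCA fitting on the average and application of the same projector
#' to every condition map; the artifact footprint before and after
#' attenuation; and finally the group statistics: 2x2 rmANOVA on stride time
#' and stride-time CV, and three cluster-based permutation tests (terrain,
#' task, interaction) on the GPMs at the analysis channel within the
#' statistics band.
#'
#' @param config [pipeline_config()].
#' @param progress print per-subject progress?
#' @return a results bundle (list) with elements `gait` (per
#'   subject/condition stride metrics), `footprint` (features and
#'   distances), `cluster_tests`, `anova`, `gpm_maps`, and `provenance`.
#'   When `config$out_dir` is set, a JSON manifest is written there.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  synthetic <- inherits(config$input, "study_spec")
  if (synthetic) {
    spec <- config$input
    n_sub <- spec$n_subjects
    montage <- montage_1020(spec$n_channels)
  } else {
    manifest <- jsonlite::read_json(file.path(config$input, "manifest.json"))
    n_sub <- length(manifest$subjects)
  }
  conds <- condition_grid()
  ana_chan <- config$analysis_channel
  tfp <- config$tf
  band <- tfp$stats_band
  fsel <- which(tfp$freqs >= band[1] & tfp$freqs <= band[2])

  gait_rows <- list()
  fp_rows <- list()
  distances <- numeric(0)
  gpm_maps <- vector("list", n_sub)
  stride_mat <- matrix(NA_real_, n_sub, length(conds),
                       dimnames = list(NULL, conds))
  cv_mat <- stride_mat
  prov <- list(subjects = list())

  for (s in seq_len(n_sub)) {
    if (progress) message("subject ", s, "/", n_sub)
    if (synthetic) {
      sim <- simulate_subject(spec, s, montage)
      standing_rec <- sim$standing$rec
      get_cond <- function(cond) sim$conditions[[cond]]
    } else {
      sub <- manifest$subjects[[s]]
      sid <- names(manifest$subjects)[s]
      sdir <- file.path(config$input, sid)
      standing_rec <- read_brainvision(file.path(sdir, sub$standing))
      get_cond <- function(cond) {
        entry <- sub$conditions[[cond]]
        list(
          accel = list(
            left = read_accel_tsv(file.path(sdir, entry$accel$left),
                                  foot = "left"),
            right = read_accel_tsv(file.path(sdir, entry$accel$right),
                                   foot = "right")),
          eeg = list(rec = read_brainvision(file.path(sdir, entry$eeg))))
      }
    }
    if (is.null(ana_chan)) {
      ana_chan <- channel_sets(standing_rec$montage)$vertex
    }
    minimal <- config$profile == "minimal"
    keep_ch <- if (is.null(config$tf_channels)) NULL
               else union(config$tf_channels, ana_chan)
    prep <- if (minimal) {
      function(rec) preprocess_minimal(rec, config$preproc, keep_ch)
    } else {
      function(rec) preprocess_basic(rec, config$preproc)
    }
    # standing baseline
    st <- prep(standing_rec)
    tf_st <- morlet_power(st, tfp)
    spans <- event_spans(st$events, "standing")
    baseline <- standing_baseline_power(tf_st, spans, tfp)

    seg_all <- list()
    cond_seg <- list()
    cond_cycles <- list()
    sub_prov <- list(bads = character(0), removed_ics = integer(0),
                     n_detected = 0, n_valid = 0, n_kept = 0)
    for (cond in conds) {
      cd <- get_cond(cond)
      ev_l <- detect_gait_events(cd$accel$left, config$gait)
      ev_r <- detect_gait_events(cd$accel$right, config$gait)
      cycles <- assemble_gait_cycles(ev_l, ev_r, config$gait)
      sm <- stride_metrics(cycles)
      stride_mat[s, cond] <- sm$mean_stride
      cv_mat[s, cond] <- sm$cv_pct
      gait_rows[[length(gait_rows) + 1L]] <- data.frame(
        subject = s, condition = cond, mean_stride_s = sm$mean_stride,
        cv_pct = sm$cv_pct, n_cycles_detected = sm$n_detected,
        n_cycles_valid = sm$n_valid)
      rec <- prep(cd$eeg$rec)
      sub_prov$bads <- union(sub_prov$bads, rec$provenance$interpolated)
      if (config$do_ica && !minimal) {
        icr <- ica_eye_removal(rec, config$preproc,
                               seed = sub_seed(config$seed, s, 7))
        rec <- icr$rec
        sub_prov$removed_ics <- union(sub_prov$removed_ics, icr$removed)
      }
      tf_walk <- morlet_power(rec, tfp)
      segs <- extract_and_warp_cycles(tf_walk, rec, cycles, tfp)
      cond_seg[[cond]] <- segs
      cond_cycles[[cond]] <- cycles
      sub_prov$n_detected <- sub_prov$n_detected + nrow(cycles)
      sub_prov$n_valid <- sub_prov$n_valid + sum(cycles$valid)
      sub_prov$n_kept <- sub_prov$n_kept + dim(segs)[3]
      seg_all[[cond]] <- segs
    }
    tf_meta <- list(labels = st$montage$label, freqs = tfp$freqs)
    pooled <- array(unlist(seg_all),
                    dim = c(dim(seg_all[[1]])[1], tfp$phase_bins,
                            sum(sapply(seg_all, function(x) dim(x)[3]))))
    ersp_all <- average_to_ersp(pooled, baseline, tf_meta, "all")
    ersp_cond <- lapply(conds, function(cond) {
      average_to_ersp(cond_seg[[cond]], baseline, tf_meta, cond)
    })
    names(ersp_cond) <- conds
    if (config$do_spca) {
      model <- fit_spca(ersp_all)
      sub_prov$spca_first_share <- model$eigval[1] / sum(model$eigval)
      ersp_cond_clean <- lapply(ersp_cond, function(e) apply_spca(model, e))
      ersp_all_clean <- apply_spca(model, ersp_all)
    } else {
      ersp_cond_clean <- ersp_cond
      ersp_all_clean <- ersp_all
    }

    if (config$do_footprint) {
      support <- support_phase_bins(do.call(rbind, cond_cycles),
                                    tfp$phase_bins)
      sets <- channel_sets(st$montage)
      fp_before <- compute_footprint(ersp_all, ersp_to_gpm(ersp_all),
                                     support, sets)
      fp_after <- compute_footprint(ersp_all_clean,
                                    ersp_to_gpm(ersp_all_clean),
                                    support, sets)
      fp_rows[[length(fp_rows) + 1L]] <- list(before = fp_before,
                                              after = fp_after)
    }
    chan_idx <- match(ana_chan, st$montage$label)
    gpm_maps[[s]] <- lapply(ersp_cond_clean, function(e) {
      g <- ersp_to_gpm(e)
      unclass(g)[chan_idx, fsel, ]
    })
    prov$subjects[[s]] <- sub_prov
  }

  # footprint distances under joint cohort scaling
  footprint <- NULL
  if (config$do_footprint && length(fp_rows)) {
    all_fp <- c(lapply(fp_rows, `[[`, "before"),
                lapply(fp_rows, `[[`, "after"))
    scaled <- scale_footprints(all_fp)
    nb <- length(fp_rows)
    distances <- vapply(seq_len(nb), function(i) {
      footprint_distance(scaled[[i]], scaled[[i + nb]])
    }, numeric(1))
    footprint <- list(
      raw = do.call(rbind, lapply(seq_len(nb), function(i) {
        rbind(data.frame(subject = i, state = "raw",
                         t(unclass(fp_rows[[i]]$before))),
              data.frame(subject = i, state = "cleaned",
                         t(unclass(fp_rows[[i]]$after))))
      })),
      distance = distances)
  }

  cluster_tests <- lapply(
    stats::setNames(nm = c("terrain", "task", "interaction")),
    function(eff) {
      pairs <- effect_maps(gpm_maps, eff)
      cp <- config$stats
      cp$seed <- sub_seed(config$seed, match(eff, c("terrain", "task",
                                                    "interaction")), 11)
      res <- cluster_permutation_test(pairs, cp)
      if (length(res$p) && min(res$p) < cp$alpha) {
        res$effect_size <- cluster_effect_size(pairs, res$masks[[1]])
      }
      res
    })

  anova <- list(stride_time = rm_anova_2x2(stride_mat),
                cv = rm_anova_2x2(cv_mat))

  bundle <- list(
    gait = do.call(rbind, gait_rows),
    stride_time = stride_mat, cv = cv_mat,
    footprint = footprint,
    cluster_tests = cluster_tests,
    anova = anova,
    gpm_maps = gpm_maps,
    analysis_channel = ana_chan,
    stats_freqs = tfp$freqs[fsel],
    provenance = prov,
    seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    summary <- list(
      seed = config$seed,
      analysis_channel = ana_chan,
      anova = lapply(anova, function(a) a[, c("effect", "F", "p", "pes")]),
      cluster_p = lapply(cluster_tests, function(ct) ct$p),
      footprint_distance = if (!is.null(footprint)) footprint$distance,
      provenance = prov)
    jsonlite::write_json(summary, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
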