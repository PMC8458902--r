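# End-to-end study runner: phantom cohort -> ADC fitting -> preprocessing ->
# classifier pre-training -> one GAN per input b-value -> synthesis ->
# image-quality metrics -> simulated-reader measurements -> agreement and
# diagnostic statistics -> report tables.
#
# Every stage is cached (when out_dir is set) under a key derived from the
# configuration hash, so an interrupted run resumes at stage granularity and
# a re-run with the same seed reproduces byte-identical report tables.

#' Study configuration
#'
#' Profiles fix a coherent scale: `desk` (60/20/5 cases, 64 x 64, 20 epochs,
#' reduced widths) runs on one CPU in minutes; `paper` (150/50/10, 224 x 224,
#' 50 epochs, full widths) matches the scale of a full clinical study. Any field
#' can be overridden through `...`.
#'
#' @param profile scale profile.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory for caches and report tables (`NULL` keeps
#'   everything in memory).
#' @param ... named overrides of any configuration field.
#' @export
study_config <- function(profile = c("desk", "paper"), seed = 1L,
                         out_dir = NULL, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "desk") {
    list(n_train = 60L, n_test = 20L, n_volunteer = 5L, image_size = 64L,
         epochs = 20L, cls_epochs = 10L, gen_width = 16L, disc_width = 16L,
         recog_width = 8L)
  } else {
    list(n_train = 150L, n_test = 50L, n_volunteer = 10L, image_size = 224L,
         epochs = 50L, cls_epochs = 20L, gen_width = 64L, disc_width = 64L,
         recog_width = 32L)
  }
  cfg <- c(base, list(
    profile = profile, seed = as.integer(seed), out_dir = out_dir,
    learning_rate = 0.001, batch_size = 5L, lambda1 = 0.1,
    feature_levels = c(0L, 1L, 3L, 5L),
    b_models = c(50, 1000, 1500), reference_b = 1000,
    roi_area_lesion = c(0.5, 0.8), roi_area_zone = c(0.35, 0.55),
    roi_jitter_px = 1, align = FALSE))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  # the phantom grid matches the training resolution; spacing preserves a
  # fixed ~61 mm field of view so anatomy in mm is profile-invariant
  if (is.null(cfg$phantom)) {
    sp <- 0.95 * 64 / cfg$image_size
    cfg$phantom <- phantom_spec(grid_shape = c(cfg$image_size, cfg$image_size),
                                voxel_spacing = c(sp, sp))
  }
  structure(cfg, class = "study_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

stage_cached <- function(name, config, hash, fn, env) {
  if (!is.null(config$out_dir)) {
    cdir <- file.path(config$out_dir, "cache")
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(cdir, sprintf("%s_%s.rds", name, hash))
    if (file.exists(f)) return(readRDS(f))
  }
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(fn(), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  env$times[[name]] <- round(proc.time()[["elapsed"]] - t0, 2)
  if (!is.null(config$out_dir)) saveRDS(out, f)
  out
}

norm_by_clip <- function(data, clip = c(0, 4e-3)) {
  pmin(pmax((data - clip[1]) / (clip[2] - clip[1]), 0), 1)
}

case_inputs <- function(case, config) {
  z_adc <- fit_adc(case$clean_dwi)
  f_adc <- fit_adc(case$degraded_dwi)
  x <- lapply(config$b_models, function(b) {
    i <- which(case$degraded_dwi$b_values == b)
    if (!length(i)) stop("model b-value ", b, " not acquired")
    normalize_intensity(case$degraded_dwi$data[i, , ])
  })
  names(x) <- paste0("b", config$b_models)
  list(z_adc = z_adc, f_adc = f_adc, x = x,
       y = norm_by_clip(z_adc$data), f_norm = norm_by_clip(f_adc$data))
}

metric_row <- function(pred, ref) {
  c(rmse = img_rmse(pred, ref), psnr = img_psnr(pred, ref),
    ssim = img_ssim(pred, ref)$mean, fsim = img_fsim(pred, ref))
}

roi_seed <- function(base, case_i, reader, rep, method_i) {
  (base + case_i * 9973L + reader * 641L + rep * 97L + method_i * 7L) %%
    2147483647L
}

#' Run the full synthetic study
#'
#' @param config a [study_config()].
#' @param verbose print stage progress.
#' @return a report bundle: per-slice metric table, diameter table, reader
#'   measurements, ICC / ROC / test tables, trained models, and a manifest.
#' @export
run_study <- function(config = study_config(), verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  hash <- config_hash(config)
  env <- new.env(); env$times <- list()
  seeds <- child_seeds(config$seed, 20)
  say <- function(...) if (verbose) message(sprintf(...))

  # -- stage 1: cohort ------------------------------------------------------
  say("stage 1/8: generating phantom cohort")
  cohort <- stage_cached("cohort", config, hash, function() {
    nb <- config$n_train %/% 2L; nm <- config$n_train - nb
    tb <- config$n_test %/% 2L; tm <- config$n_test - tb
    list(train = make_cohort(nb, nm, 0L, config$phantom, seed = seeds[1]),
         test = make_cohort(tb, tm, 0L, config$phantom, seed = seeds[2]),
         vols = make_cohort(0L, 0L, config$n_volunteer, config$phantom,
                            seed = seeds[3]))
  }, env)

  # -- stage 2: ADC fitting + normalization ---------------------------------
  say("stage 2/8: fitting ADC maps")
  prep <- stage_cached("prep", config, hash, function() {
    lapply(cohort, function(group) lapply(group, case_inputs, config = config))
  }, env)

  # -- stage 3: classifier pre-training -------------------------------------
  say("stage 3/8: pre-training the recognition model")
  cls <- stage_cached("classifier", config, hash, function() {
    lab <- vapply(cohort$train, `[[`, "", "label")
    keep <- lab %in% c("benign", "malignant")
    pretrain_classifier(lapply(prep$train[keep], `[[`, "y"), lab[keep],
                        spec = recognition_spec(base_width = config$recog_width),
                        config = train_config(learning_rate = config$learning_rate,
                                              batch_size = config$batch_size,
                                              epochs = config$cls_epochs,
                                              seed = seeds[4],
                                              image_size = config$image_size))
  }, env)

  # -- stage 4: GAN training, one model per input b-value -------------------
  models <- list()
  for (k in seq_along(config$b_models)) {
    b <- config$b_models[k]
    say("stage 4/8: training model M_%g (%d/%d)", b, k, length(config$b_models))
    models[[paste0("b", b)]] <- stage_cached(paste0("gan_b", b), config, hash,
      function() {
        train_gan(lapply(prep$train, function(p) p$x[[paste0("b", b)]]),
                  lapply(prep$train, `[[`, "y"),
                  recognizer = cls$model,
                  gen_spec = generator_spec(base_width = config$gen_width),
                  disc_spec = discriminator_spec(base_width = config$disc_width),
                  config = train_config(learning_rate = config$learning_rate,
                                        batch_size = config$batch_size,
                                        epochs = config$epochs,
                                        lambda1 = config$lambda1,
                                        seed = seeds[4 + k],
                                        image_size = config$image_size,
                                        feature_levels = config$feature_levels),
                  verbose = FALSE)
      }, env)
  }

  # -- stage 5: synthesis on held-out cases ---------------------------------
  say("stage 5/8: synthesizing held-out ADC maps")
  synth <- stage_cached("synth", config, hash, function() {
    ref <- paste0("b", config$reference_b)
    run_group <- function(group) lapply(group, function(p) {
      out <- lapply(names(models), function(mn)
        synthesize(models[[mn]], p$x[[mn]]))
      names(out) <- names(models)
      out$init <- synthesize(models[[ref]], p$x[[ref]],
                             generator = models[[ref]]$generator_init)
      out
    })
    list(test = run_group(prep$test), vols = run_group(prep$vols))
  }, env)

  eval_cases <- c(cohort$test, cohort$vols)
  eval_prep <- c(prep$test, prep$vols)
  eval_synth <- c(synth$test, synth$vols)
  n_pat <- length(cohort$test)

  # -- stage 6: image-quality metrics + diameters ---------------------------
  say("stage 6/8: image-quality metrics and diameter distortion")
  quality <- stage_cached("quality", config, hash, function() {
    methods <- c(paste0("s_adc_", names(models)), "s_adc_init", "f_adc")
    rows <- list()
    for (i in seq_along(eval_cases)) {
      p <- eval_prep[[i]]
      preds <- c(lapply(eval_synth[[i]][names(models)], `[[`, "norm"),
                 list(eval_synth[[i]]$init$norm, p$f_norm))
      for (j in seq_along(methods)) {
        rows[[length(rows) + 1L]] <- data.frame(
          case = i, label = eval_cases[[i]]$label, method = methods[j],
          t(metric_row(preds[[j]], p$y)))
      }
    }
    metrics <- do.call(rbind, rows)

    ref_b <- paste0("b", config$reference_b)
    dia_rows <- list()
    for (i in seq_along(eval_cases)) {
      truth <- eval_cases[[i]]$masks$prostate
      sp <- eval_cases[[i]]$true_adc$voxel_spacing
      maps <- list(f_adc = eval_prep[[i]]$f_adc$data,
                   z_adc = eval_prep[[i]]$z_adc$data,
                   s_adc = eval_synth[[i]][[ref_b]]$adc$data)
      for (mn in names(maps)) {
        m <- mask_from_adc(maps[[mn]])
        if (!any(m)) next
        d <- diameter_distortion(m, truth, sp)
        dia_rows[[length(dia_rows) + 1L]] <- data.frame(
          case = i, method = mn, delta_ap = d$delta_ap, delta_lr = d$delta_lr)
      }
    }
    list(metrics = metrics, diameters = do.call(rbind, dia_rows))
  }, env)

  # -- stage 7: simulated-reader ADC measurements ---------------------------
  say("stage 7/8: simulated-reader ROI measurements")
  measurements <- stage_cached("measurements", config, hash, function() {
    ref_b <- paste0("b", config$reference_b)
    rows <- list()
    add <- function(case_i, tissue, label, method, map, mask, bounds) {
      for (reader in 1:2) for (rep in 1:2) {
        mi <- match(method, c("f_adc", "z_adc", "s_adc"))
        roi <- simulate_reader_rois(mask, config$phantom$voxel_spacing,
                                    area_bounds_cm2 = bounds,
                                    jitter_px = config$roi_jitter_px,
                                    reader_id = reader, repetition = rep,
                                    seed = roi_seed(seeds[10], case_i, reader,
                                                    rep, mi))
        rows[[length(rows) + 1L]] <<- data.frame(
          case = case_i, tissue = tissue, label = label, method = method,
          reader = reader, repetition = rep, adc = roi_mean(map, roi))
      }
    }
    for (i in seq_len(n_pat)) {
      case <- cohort$test[[i]]
      if (case$label == "none") next
      add(i, "lesion", case$label, "f_adc", prep$test[[i]]$f_adc$data,
          case$masks_degraded$lesion, config$roi_area_lesion)
      add(i, "lesion", case$label, "z_adc", prep$test[[i]]$z_adc$data,
          case$masks$lesion, config$roi_area_lesion)
      add(i, "lesion", case$label, "s_adc", synth$test[[i]][[ref_b]]$adc$data,
          case$masks$lesion, config$roi_area_lesion)
    }
    for (v in seq_along(cohort$vols)) {
      case <- cohort$vols[[v]]
      i <- n_pat + v
      for (zone in c("pz", "tz")) {
        add(i, zone, "none", "f_adc", prep$vols[[v]]$f_adc$data,
            case$masks[[zone]], config$roi_area_zone)
        add(i, zone, "none", "z_adc", prep$vols[[v]]$z_adc$data,
            case$masks[[zone]], config$roi_area_zone)
        add(i, zone, "none", "s_adc", synth$vols[[v]][[ref_b]]$adc$data,
            case$masks[[zone]], config$roi_area_zone)
      }
    }
    do.call(rbind, rows)
  }, env)

  # -- stage 8: agreement + diagnostic statistics ---------------------------
  say("stage 8/8: statistics")
  stats_out <- stage_cached("stats", config, hash, function() {
    study_statistics(measurements)
  }, env)

  report <- list(config = config,
                 metrics = quality$metrics,
                 metrics_summary = summarize_metrics(quality$metrics),
                 diameters = quality$diameters,
                 diameters_summary = stats::aggregate(
                   cbind(delta_ap, delta_lr) ~ method, quality$diameters, mean),
                 measurements = measurements,
                 icc = stats_out$icc, roc = stats_out$roc,
                 tests = stats_out$tests,
                 models = models, classifier = cls,
                 manifest = list(seed = config$seed, profile = config$profile,
                                 config_hash = unname(hash),
                                 package_version = as.character(utils::packageVersion("adcgan")),
                                 n_train = config$n_train, n_test = config$n_test,
                                 n_volunteer = config$n_volunteer,
                                 stage_seconds = env$times))
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  invisible(report)
}

summarize_metrics <- function(metrics) {
  agg <- lapply(split(metrics, metrics$method), function(d) {
    fin <- is.finite(d$psnr)
    data.frame(method = d$method[1], n = nrow(d),
               rmse_mean = mean(d$rmse), rmse_sd = sd(d$rmse),
               psnr_mean = mean(d$psnr[fin]), psnr_sd = sd(d$psnr[fin]),
               psnr_inf_n = sum(!fin),
               ssim_mean = mean(d$ssim), ssim_sd = sd(d$ssim),
               fsim_mean = mean(d$fsim), fsim_sd = sd(d$fsim))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$method), ]
}

# Ratings matrices and ICC/ROC/test tables from the measurement long table.
study_statistics <- function(meas) {
  icc_rows <- list(); roc_rows <- list(); test_rows <- list()
  pick <- function(d, reader, rep) {
    d <- d[d$reader == reader & d$repetition == rep, ]
    d[order(d$case), c("case", "adc")]
  }
  ratings <- function(d, cols) {
    m <- Reduce(function(a, b) merge(a, b, by = "case"), cols)
    as.matrix(m[, -1, drop = FALSE])
  }
  add_icc <- function(tissue, design, method, tab, form) {
    if (nrow(tab) < 2L) return()
    r <- icc(tab, form = form)
    icc_rows[[length(icc_rows) + 1L]] <<- data.frame(
      tissue = tissue, design = design, method = method, icc = r$estimate,
      ci_low = r$ci_low, ci_high = r$ci_high, n = r$n)
  }
  for (tissue in unique(meas$tissue)) {
    dt <- meas[meas$tissue == tissue, ]
    for (method in unique(dt$method)) {
      d <- dt[dt$method == method, ]
      for (reader in 1:2)
        add_icc(tissue, paste0("intra_reader_", reader), method,
                ratings(d, list(pick(d, reader, 1), pick(d, reader, 2))),
                "two_way_mixed_consistency")
      add_icc(tissue, "inter_reader", method,
              ratings(d, list(pick(d, 1, 1), pick(d, 2, 1))),
              "two_way_random_absolute")
    }
    for (other in c("s_adc", "f_adc")) {
      for (reader in 1:2) {
        dz <- dt[dt$method == "z_adc", ]; do_ <- dt[dt$method == other, ]
        add_icc(tissue, paste0("inter_method_reader_", reader),
                paste0(other, "_vs_z_adc"),
                ratings(dz, list(pick(dz, reader, 1), pick(do_, reader, 1))),
                "two_way_random_absolute")
      }
    }
  }

  les <- meas[meas$tissue == "lesion", ]
  if (nrow(les) && length(unique(les$label)) == 2L) {
    for (reader in 1:2) {
      per <- lapply(c("f_adc", "z_adc", "s_adc"), function(m) {
        d <- les[les$method == m & les$reader == reader & les$repetition == 1, ]
        d <- d[order(d$case), ]
        list(method = m, scores = -d$adc, labels = d$label == "malignant",
             adc = d$adc)
      })
      names(per) <- vapply(per, `[[`, "", "method")
      for (m in names(per)) {
        r <- roc_auc(per[[m]]$scores, per[[m]]$labels)
        roc_rows[[length(roc_rows) + 1L]] <- data.frame(
          reader = reader, comparison = m, auc = r$estimate,
          ci_low = r$ci_low, ci_high = r$ci_high, z = NA_real_,
          p = NA_real_, n = r$n)
      }
      pairs <- list(c("z_adc", "s_adc"), c("z_adc", "f_adc"), c("s_adc", "f_adc"))
      for (pr in pairs) {
        r <- delong_test(per[[pr[1]]]$scores, per[[pr[2]]]$scores,
                         per[[pr[1]]]$labels)
        roc_rows[[length(roc_rows) + 1L]] <- data.frame(
          reader = reader, comparison = paste(pr[1], "vs", pr[2]),
          auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          z = r$statistic, p = r$p_value, n = r$n)
      }
      for (m in names(per)) {
        d <- les[les$method == m & les$reader == reader & les$repetition == 1, ]
        mw <- mann_whitney(d$adc[d$label == "malignant"],
                           d$adc[d$label == "benign"])
        test_rows[[length(test_rows) + 1L]] <- data.frame(
          reader = reader, test = "mann_whitney_malignant_vs_benign",
          method = m, statistic = mw$statistic, p = mw$p_value)
      }
      sp <- spearman_cor(per$s_adc$adc, per$z_adc$adc)
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        reader = reader, test = "spearman_s_adc_vs_z_adc", method = "s_adc",
        statistic = sp$estimate, p = sp$p_value)
    }
  }
  list(icc = do.call(rbind, icc_rows),
       roc = do.call(rbind, roc_rows),
       tests = if (length(test_rows)) do.call(rbind, test_rows) else NULL)
}

#' Write the report tables of a study run
#'
#' @param report a bundle from [run_study()].
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(report$metrics, "metrics.csv")
  wr(report$metrics_summary, "metrics_summary.csv")
  wr(report$diameters, "diameters.csv")
  wr(report$diameters_summary, "diameters_summary.csv")
  wr(report$measurements, "measurements.csv")
  wr(report$icc, "icc.csv")
  wr(report$roc, "roc.csv")
  wr(report$tests, "tests.csv")
  hist <- do.call(rbind, lapply(names(report$models), function(m)
    cbind(model = m, report$models[[m]]$history)))
  wr(hist, "training_log.csv")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Miniature fixture dataset for tests and examples
#'
#' Eight 32 x 32 cases (3 benign, 3 malignant, 2 volunteers) generated in
#' seconds; the checksum is the MD5 of a canonical CSV rendering, stable for
#' a fixed seed.
#'
#' @param seed integer seed.
#' @export
make_fixtures <- function(seed = 1L) {
  sp <- phantom_spec(grid_shape = c(32L, 32L), voxel_spacing = c(1.9, 1.9))
  cases <- make_cohort(3L, 3L, 2L, sp, seed = seed)
  tab <- do.call(rbind, lapply(seq_along(cases), function(i) {
    c <- cases[[i]]
    data.frame(case = i, label = c$label,
               prostate_mean_adc = round(mean(c$true_adc$data[c$masks$prostate]), 9),
               lesion_mean_adc = round(if (any(c$masks$lesion))
                 mean(c$true_adc$data[c$masks$lesion]) else NA_real_, 9))
  }))
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(tab, tmp, row.names = FALSE)
  checksum <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(cases = cases, spec = sp, table = tab, checksum = checksum)
}
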