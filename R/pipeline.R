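#' Build a pipeline run configuration
#'
#' Bundles the generator, split, model and CNN parameters for an end-to-end
#' run. Defaults reproduce the package's reference synthetic cohort: 95
#' samples (19 per species), Kennard-Stone 2/3 split, 7-fold CV PLS-DA, 30
#' synthetic samples with a 20/10 Kennard-Stone duplex split for the
#' per-marker PLSR models.
#'
#' @param mode `"NIR"`, `"FTIR"` or `"both"`.
#' @param n_per_species Replicates per species (default 19).
#' @param noise_sd Spectral noise SD (default 0.002 AU).
#' @param train_frac Kennard-Stone train fraction (default 2/3).
#' @param max_lv Largest latent-variable count scanned (default 12).
#' @param folds CV folds (default 7).
#' @param n_perm Permutations for the overfitting test (default 200).
#' @param plsr_n_per_species Replicates per species for the PLSR cohort
#'   (default 6, i.e. 30 samples split 20/10).
#' @param cnn Run the CNN stage (default `TRUE`).
#' @param cnn_epochs,cnn_image_edge CNN training epochs (30) and image edge
#'   (128; must be divisible by 16).
#' @param out_dir Output directory.
#' @param seed Global seed; per-stage seeds are derived from it and logged.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(mode = "NIR", n_per_species = 19,
                            noise_sd = 0.002, train_frac = 2 / 3,
                            max_lv = 12, folds = 7, n_perm = 200,
                            plsr_n_per_species = 6, cnn = TRUE,
                            cnn_epochs = 30, cnn_image_edge = 128,
                            out_dir = "boletespec_run", seed = 1) {
  structure(list(mode = mode, n_per_species = n_per_species,
                 noise_sd = noise_sd, train_frac = train_frac,
                 max_lv = max_lv, folds = folds, n_perm = n_perm,
                 plsr_n_per_species = plsr_n_per_species, cnn = cnn,
                 cnn_epochs = cnn_epochs, cnn_image_edge = cnn_image_edge,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

stage_log <- function(report, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  c(report, line)
}

#' Run the full analysis pipeline
#'
#' simulate -> split -> 2DCOS -> PLS-DA (+ permutation test) -> per-marker
#' PLSR -> marker screening -> CNN, writing every stage's outputs under
#' `config$out_dir` and returning a summary report. The same config and seed
#' give identical outputs. Any stage failure aborts with a stage-named
#' error; outputs of completed stages are kept.
#'
#' @param config A `run_config` from [pipeline_config].
#' @return Invisibly, a list with the per-stage results and the path of the
#'   JSON summary.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  modes <- if (config$mode == "both") c("NIR", "FTIR") else config$mode
  log <- character(0)
  summary <- list(seed = config$seed, modes = modes)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  results <- list()
  for (mode in modes) {
    mdir <- file.path(out, mode)
    dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
    # 1. simulate
    ds <- stage("simulate", {
      d <- generate_dataset(config$n_per_species, mode = mode,
                            noise_sd = config$noise_sd, seed = config$seed)
      write_dataset(d, file.path(mdir, "dataset"))
      d
    })
    log <- stage_log(log, "simulate",
                     sprintf("%s cohort: %d samples", mode, nrow(ds$spectra)))
    # 2. split
    split <- stage("split", {
      s <- kennard_stone(ds$spectra, n_train = round(nrow(ds$spectra) *
                                                       config$train_frac))
      # small cohorts can leave a species underrepresented in the training
      # split; pull the first held-out samples of that species back in so
      # the discriminant stages stay feasible
      for (lv in levels(ds$labels)) {
        while (sum(ds$labels[s$train_idx] == lv) < 2 &&
               any(ds$labels[s$test_idx] == lv)) {
          warning("species '", lv, "' underrepresented in the training ",
                  "split; moving a test sample in (CV feasibility)")
          mv <- s$test_idx[ds$labels[s$test_idx] == lv][1]
          s$train_idx <- c(s$train_idx, mv)
          s$test_idx <- setdiff(s$test_idx, mv)
        }
      }
      write_split(s, ds$sample_ids, file.path(mdir, "split.csv"))
      s
    })
    log <- stage_log(log, "split", sprintf("K-S %d/%d", length(split$train_idx),
                                           length(split$test_idx)))
    # 3. 2DCOS maps and images
    maps <- stage("twodcos", {
      m <- correlation_maps(ds)
      write_map(m, "sync", file.path(mdir, "sync_map.csv"))
      write_map(m, "async", file.path(mdir, "async_map.csv"))
      render_maps(m, file.path(mdir, "sync_2dcos.png"), "sync", "contour2d")
      render_maps(m, file.path(mdir, "async_2dcos.png"), "async", "contour2d")
      render_maps(m, file.path(mdir, "sync_3dcos.png"), "sync", "surface3d")
      m
    })
    rep_peaks <- peak_report(maps)
    log <- stage_log(log, "twodcos",
                     sprintf("%d auto peak(s)", nrow(rep_peaks$auto_peaks)))
    # 4. PLS-DA
    plsda <- stage("plsda", {
      if (min(table(ds$labels[split$train_idx])) < 2)
        warning("a class has < 2 training samples; CV may be infeasible")
      folds <- min(config$folds, length(split$train_idx))
      sel <- select_latent_variables(ds$spectra[split$train_idx, ],
                                     one_hot(ds$labels[split$train_idx]),
                                     max_lv = config$max_lv, folds = folds)
      fit <- plsda_fit(ds$spectra[split$train_idx, ],
                       ds$labels[split$train_idx], n_lv = sel$n_lv)
      cv <- cross_validate(ds$spectra[split$train_idx, ],
                           one_hot(ds$labels[split$train_idx]),
                           n_lv = sel$n_lv, folds = folds)
      perm <- permutation_test(ds$spectra[split$train_idx, ],
                               ds$labels[split$train_idx], n_lv = sel$n_lv,
                               n_perm = config$n_perm,
                               seed = config$seed + 2, folds = folds)
      list(n_lv = sel$n_lv,
           train_acc = classification_accuracy(fit, ds$spectra[split$train_idx, ],
                                               ds$labels[split$train_idx]),
           test_acc = classification_accuracy(fit, ds$spectra[split$test_idx, ],
                                              ds$labels[split$test_idx]),
           Q2 = cv$Q2, RMSECV = cv$RMSECV,
           R2 = perm$R2, perm_intercept_R2 = perm$intercept_R2,
           perm_intercept_Q2 = perm$intercept_Q2, perm_verdict = perm$verdict)
    })
    jsonlite::write_json(plsda, file.path(mdir, "plsda_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    log <- stage_log(log, "plsda",
                     sprintf("LVs %d, test acc %.1f%%, perm intercept R2 %.3f",
                             plsda$n_lv, plsda$test_acc, plsda$perm_intercept_R2))
    # 5. per-marker PLSR on the 20/10 duplex cohort
    plsr <- stage("plsr", {
      dsr <- generate_dataset(config$plsr_n_per_species, mode = mode,
                              noise_sd = config$noise_sd,
                              seed = config$seed + 1)
      sp <- ks_duplex(dsr$spectra, ratio = 2 / 3)
      tab <- plsr_marker_table(dsr, sp)
      utils::write.csv(tab, file.path(mdir, "plsr_markers.csv"),
                       row.names = FALSE)
      tab
    })
    log <- stage_log(log, "plsr",
                     sprintf("16 markers: min R2p %.3f, min RPD %.2f",
                             min(plsr$R2p), min(plsr$RPD)))
    # 6. marker screening
    screen <- stage("screen", {
      pan_nir <- vip_filter(vip(plsda_refit(ds, split)), 1.0)
      letters <- marker_letter_table(ds$concentrations, ds$labels,
                                     units = ds$units)
      utils::write.csv(letters, file.path(mdir, "marker_letters.csv"))
      list(vip_panel = pan_nir, letters = letters)
    })
    log <- stage_log(log, "screen",
                     sprintf("%d wavenumber features with VIP > 1",
                             length(screen$vip_panel)))
    # 7. CNN
    cnn <- NULL
    if (isTRUE(config$cnn)) {
      cnn <- stage("cnn", {
        imgs <- sample_correlation_images(ds, reference = split$train_idx,
                                          style = "surface3d",
                                          size_px = config$cnn_image_edge)
        net <- build_resnet(nlevels(ds$labels), config$cnn_image_edge,
                            seed = config$seed + 3)
        res <- resnet_train(net, imgs, ds$labels, split,
                            epochs = config$cnn_epochs,
                            seed = config$seed + 4, early_stop_acc = 100)
        utils::write.csv(res$trace, file.path(mdir, "cnn_trace.csv"),
                         row.names = FALSE)
        list(best_test_acc = max(res$trace$test_acc),
             final_loss = res$trace$loss[nrow(res$trace)],
             epochs_run = nrow(res$trace))
      })
      log <- stage_log(log, "cnn", sprintf("best test acc %.1f%% in %d epoch(s)",
                                           cnn$best_test_acc, cnn$epochs_run))
    }
    results[[mode]] <- list(plsda = plsda,
                            plsr_min_R2p = min(plsr$R2p),
                            plsr_min_RPD = min(plsr$RPD),
                            auto_peaks = rep_peaks$auto_peaks,
                            vip_panel_size = length(screen$vip_panel),
                            cnn = cnn)
  }
  summary$results <- results
  summary$log <- log
  cfg <- unclass(config)
  jsonlite::write_json(list(config = cfg, summary = results),
                       file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(log, file.path(out, "run.log"))
  invisible(list(summary = summary, report = file.path(out, "report.json")))
}

# PLS-DA refit on the training split, for the VIP panel
plsda_refit <- function(ds, split) {
  sel <- select_latent_variables(ds$spectra[split$train_idx, ],
                                 one_hot(ds$labels[split$train_idx]),
                                 max_lv = 12,
                                 folds = min(7, length(split$train_idx)))
  plsda_fit(ds$spectra[split$train_idx, ], ds$labels[split$train_idx],
            n_lv = sel$n_lv)
}

#' Per-marker PLSR models on a split synthetic cohort
#'
#' Fits one PLSR model per marker and evaluates it on the validation set,
#' mirroring the standard per-marker calibration table (component, R2c,
#' RMSEC, R2p, RMSEP, RPD). The latent-variable count is fixed (default 10)
#' rather than cross-validated: on a Kennard-Stone-duplex calibration set
#' the held-out CV points are the design extremes, making RMSECV an
#' extrapolation error that is unreliable for component selection at n ~ 20.
#'
#' @param ds A `synthetic_dataset`.
#' @param split A `split_result` on its samples.
#' @param n_lv Latent variables per marker model (default 10, capped at
#'   n_train - 1).
#' @return data.frame with one row per marker.
#' @export
plsr_marker_table <- function(ds, split, n_lv = 10) {
  Xtr <- ds$spectra[split$train_idx, , drop = FALSE]
  Xte <- ds$spectra[split$test_idx, , drop = FALSE]
  n_lv <- min(n_lv, length(split$train_idx) - 1)
  out <- NULL
  for (j in seq_len(ncol(ds$concentrations))) {
    ytr <- ds$concentrations[split$train_idx, j]
    yte <- ds$concentrations[split$test_idx, j]
    fit <- pls_fit(Xtr, ytr, n_lv = n_lv)
    cal <- calibration_metrics(fit, Xtr, ytr)
    met <- evaluate(fit, Xte, yte)
    out <- rbind(out, data.frame(
      marker = colnames(ds$concentrations)[j],
      unit = ds$units[j], LVs = fit$n_lv,
      R2c = cal$R2c, RMSEC = cal$RMSEC,
      R2p = met$R2p, RMSEP = met$RMSEP, RPD = met$RPD))
  }
  out
}
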