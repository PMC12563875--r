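# ---- end-to-end reproducible pipeline -------------------------------------

#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the simulate -> preprocess -> CSTP ->
#' group statistics -> network -> cross-validation pipeline. All stage seeds
#' are derived deterministically from the single `seed`.
#'
#' @param sim a [sim_config()].
#' @param preprocess list with `lo`, `hi`, `window`, `sfreq_out`, `codes`.
#' @param cstp list with `m_filters`, `k_filters`, `max_iter`, `tol`.
#' @param stats list with `window` (analysis window in ms).
#' @param net list with `config` ([sttcnet_config()]), `prior`
#'   (`NULL` = default [prior_spec()]), and training arguments `epochs`,
#'   `batch_size`, `lr`, `val_frac`.
#' @param cv list with `k` and `methods` (subset of
#'   `c("sttcnet", "cstp_svm", "raw_svm")`).
#' @param seed global integer seed.
#' @param out_dir default output directory for [run_pipeline()].
#' @param stages character vector of stages to run, in pipeline order.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            preprocess = list(lo = 0.1, hi = 30,
                                              window = c(-100, 600),
                                              sfreq_out = 250,
                                              codes = "target"),
                            cstp = list(m_filters = 6, k_filters = 6,
                                        max_iter = 50, tol = 1e-6),
                            stats = list(window = c(250, 500)),
                            net = list(config = sttcnet_config(),
                                       prior = NULL, epochs = 60,
                                       batch_size = 32, lr = 1e-3,
                                       val_frac = 0.2),
                            cv = list(k = 4,
                                      methods = c("sttcnet", "cstp_svm")),
                            seed = 1L, out_dir = "p300_run",
                            stages = c("simulate", "cstp", "groupstats",
                                       "sttcnet", "evaluate")) {
  cfg <- list(sim = sim, preprocess = preprocess, cstp = cstp,
              stats = stats, net = net, cv = cv, seed = as.integer(seed),
              out_dir = out_dir, stages = stages)
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  need <- c("sim", "preprocess", "cstp", "stats", "net", "cv", "seed",
            "out_dir", "stages")
  for (nm in need)
    if (is.null(cfg[[nm]]))
      stop("pipeline config is missing required field: ", nm)
  if (!inherits(cfg$sim, "sim_config")) stop("`sim` must be a sim_config")
  for (nm in c("lo", "hi", "window", "sfreq_out", "codes"))
    if (is.null(cfg$preprocess[[nm]]))
      stop("pipeline config is missing required field: preprocess$", nm)
  if (cfg$preprocess$hi > cfg$preprocess$sfreq_out / 2)
    stop("preprocess low-pass edge exceeds output Nyquist frequency")
  # epoch length must be consistent across stages (mask window inside axis)
  t0 <- cfg$preprocess$window
  mw <- if (!is.null(cfg$net$prior)) cfg$net$prior$mask_window else c(250, 450)
  if (mw[1] < t0[1] || mw[2] > t0[2])
    stop("attention mask window must lie inside the epoch window")
  sw <- cfg$stats$window
  if (sw[1] < t0[1] || sw[2] > t0[2])
    stop("statistics window must lie inside the epoch window")
  invisible(TRUE)
}

#' Read a pipeline configuration from JSON
#'
#' Missing fields take the package defaults; group parameters, topography
#' and noise settings nest under `sim` as in [sim_config()].
#'
#' @param path JSON file path.
#' @return a validated [pipeline_config()].
#' @export
pipeline_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  simargs <- j$sim
  if (!is.null(simargs$group_params))
    simargs$group_params <- lapply(simargs$group_params,
                                   function(g) do.call(group_params, g))
  if (!is.null(simargs$topography))
    simargs$topography <- unlist(simargs$topography)
  sim <- do.call(sim_config, if (is.null(simargs)) list() else simargs)
  args <- list(sim = sim)
  defaults <- list(preprocess = list(lo = 0.1, hi = 30,
                                     window = c(-100, 600), sfreq_out = 250,
                                     codes = "target"),
                   cstp = list(m_filters = 6, k_filters = 6, max_iter = 50,
                               tol = 1e-6),
                   stats = list(window = c(250, 500)),
                   cv = list(k = 4, methods = c("sttcnet", "cstp_svm")))
  for (nm in names(defaults))
    if (!is.null(j[[nm]]))
      args[[nm]] <- utils::modifyList(defaults[[nm]], j[[nm]])
  if (!is.null(j$net)) {
    net <- j$net
    if (!is.null(net$config)) net$config <- do.call(sttcnet_config, net$config)
    default_net <- list(config = sttcnet_config(), prior = NULL, epochs = 60,
                        batch_size = 32, lr = 1e-3, val_frac = 0.2)
    args$net <- utils::modifyList(default_net, net)
  }
  for (nm in c("seed", "out_dir", "stages"))
    if (!is.null(j[[nm]])) args[[nm]] <- j[[nm]]
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort (subject by subject, keeping only epochs), fits the
#' CSTP model and features, computes the channel statistics battery, trains
#' the network, and runs the subject-level cross-validation, writing every
#' artifact plus a manifest (with a config hash and per-file checksums) into
#' `out_dir`. Deterministic for a fixed config: running twice yields
#' identical manifests.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (default `cfg$out_dir`).
#' @param verbose print stage progress.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg, out_dir = cfg$out_dir, verbose = TRUE) {
  validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[p300sttc] ", ...)
  set.seed(cfg$seed)
  stage_seed <- sample.int(1000000L, 8)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  # --- simulate + preprocess (streaming per subject)
  say("simulate + preprocess (", 2 * cfg$sim$n_subjects_per_group,
      " subjects)")
  sim <- cfg$sim
  sim$seed <- stage_seed[1]
  ep <- simulate_epoch_cohort(sim, lo = cfg$preprocess$lo,
                              hi = cfg$preprocess$hi,
                              window = cfg$preprocess$window,
                              sfreq_out = cfg$preprocess$sfreq_out,
                              codes = cfg$preprocess$codes)
  f_ep <- file.path(out_dir, "epochs.rds")
  save_epochs(ep, f_ep); add(f_ep)

  # --- CSTP + features + PCA summaries
  if ("cstp" %in% cfg$stages) {
    say("CSTP (", cfg$cstp$m_filters, " x ", cfg$cstp$k_filters, " filters)")
    cm <- cstp(ep, m_filters = cfg$cstp$m_filters,
               k_filters = cfg$cstp$k_filters,
               max_iter = cfg$cstp$max_iter, tol = cfg$cstp$tol,
               seed = stage_seed[2])
    f_cm <- file.path(out_dir, "cstp_model.rds")
    save_cstp(cm, f_cm, json = file.path(out_dir, "cstp_model.json"))
    add(f_cm); add(file.path(out_dir, "cstp_model.json"))
    ft <- cstp_features(cm, ep)
    f_ft <- file.path(out_dir, "cstp_features.csv")
    utils::write.csv(cbind(ft$meta[c("subject_id", "group")],
                           as.data.frame(ft$features)),
                     f_ft, row.names = FALSE)
    add(f_ft)
    pc_raw <- pca_project(flatten_epochs(ep), 2)
    pc_cstp <- pca_project(ft$features, 2)
    f_pca <- file.path(out_dir, "pca_summary.csv")
    utils::write.csv(data.frame(
      input = c("raw", "cstp"),
      pc1_var = c(pc_raw$explained_variance_ratio[1],
                  pc_cstp$explained_variance_ratio[1]),
      pc2_var = c(pc_raw$explained_variance_ratio[2],
                  pc_cstp$explained_variance_ratio[2])),
      f_pca, row.names = FALSE)
    add(f_pca)
  }

  # --- group statistics
  if ("groupstats" %in% cfg$stages) {
    say("group statistics")
    cs <- channel_stats(ep, window = cfg$stats$window)
    f_cs <- file.path(out_dir, "channel_stats.csv")
    utils::write.csv(as.data.frame(cs), f_cs, row.names = FALSE)
    add(f_cs)
    tv <- topography_values(ep, window = cfg$stats$window)
    f_tv <- file.path(out_dir, "topography.csv")
    utils::write.csv(tv, f_tv, row.names = FALSE)
    add(f_tv)
    pk <- peak_measures(ep, window = cfg$stats$window)
    f_pk <- file.path(out_dir, "peak_measures.csv")
    utils::write.csv(pk, f_pk, row.names = FALSE)
    add(f_pk)
  }

  # --- network fit on the full cohort (training-curve artifact)
  if ("sttcnet" %in% cfg$stages) {
    say("P300-STTCNet fit")
    net <- sttcnet(ep, config = cfg$net$config, prior = cfg$net$prior,
                   epochs = cfg$net$epochs, batch_size = cfg$net$batch_size,
                   lr = cfg$net$lr, val_frac = cfg$net$val_frac,
                   seed = stage_seed[3])
    f_net <- file.path(out_dir, "sttcnet_model.rds")
    save_sttcnet(net, f_net,
                 curve_csv = file.path(out_dir, "training_curve.csv"),
                 json = file.path(out_dir, "sttcnet_model.json"))
    add(f_net); add(file.path(out_dir, "training_curve.csv"))
    add(file.path(out_dir, "sttcnet_model.json"))
  }

  # --- cross-validated evaluation
  if ("evaluate" %in% cfg$stages) {
    for (meth in cfg$cv$methods) {
      say("cross-validation [", meth, "]")
      rep_ <- cv_classify(ep, method = meth, k = cfg$cv$k,
                          seed = stage_seed[4],
                          m_filters = cfg$cstp$m_filters,
                          k_filters = cfg$cstp$k_filters,
                          net_args = list(config = cfg$net$config,
                                          prior = cfg$net$prior,
                                          epochs = cfg$net$epochs,
                                          batch_size = cfg$net$batch_size,
                                          lr = cfg$net$lr,
                                          val_frac = cfg$net$val_frac),
                          verbose = verbose)
      f_cv <- file.path(out_dir, paste0("cv_report_", meth, ".json"))
      save_cv_report(rep_, f_cv,
                     csv = file.path(out_dir, paste0("cv_metrics_", meth,
                                                     ".csv")),
                     confusion_csv = file.path(out_dir,
                                               paste0("confusion_", meth,
                                                      ".csv")))
      add(f_cv); add(file.path(out_dir, paste0("cv_metrics_", meth, ".csv")))
      add(file.path(out_dir, paste0("confusion_", meth, ".csv")))
    }
  }

  # --- manifest with config hash and per-file checksums
  cfg_hashable <- cfg
  cfg_hashable$out_dir <- NULL      # hash the scientific config only
  cfg_json <- jsonlite::toJSON(unclass_deep(cfg_hashable), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(package = "p300sttc",
                   version = as.character(utils::packageVersion("p300sttc")),
                   seed = cfg$seed,
                   config_hash = unname(tools::md5sum(tmp)),
                   stages = cfg$stages,
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f) unname(tools::md5sum(f))))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", length(files), " artifact(s) in ", out_dir)
  invisible(manifest)
}
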