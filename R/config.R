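# Configuration, run manifest and pipeline commands. A single YAML config
# drives the whole pipeline; two built-in profiles reproduce either the
# full-scale study (1000 subjects, 10-fold CV x 5 repeats) or a desk-scale
# run (300 subjects, 2 repeats, coarse grid).

#' Default pipeline configuration
#'
#' Nested configuration list with the exact keys consumed by the pipeline
#' commands. The `full` profile is the full-scale study configuration
#' (n = 1000 subjects, 5 CV repeats, fine grid); the `desk` profile is a
#' coarse single-CPU configuration (n = 300, 2 repeats).
#'
#' @param profile `"desk"` or `"full"`.
#' @return Nested named list.
#' @export
default_config <- function(profile = c("desk", "full")) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    population = list(n_subjects = 300L, seed = 1L,
                      mu_mpa = c(0.01667, 0.1), k_per_day = c(0.2, 1.92),
                      theta_nat = c(1.05, 1.2), rho_kg_m3 = c(1060.2, 1171.8)),
    patch = list(lx_mm = 50, ly_mm = 37.5, h_mm = 3, nx = 40L, ny = 30L),
    expander = list(a_mm = 50, b_mm = 37.5, apex_mm = 23.4),
    protocol = list(hold_days = 7, t0_days = 1e-5, mid_days = 3.5,
                    growth_dt_days = 0.01),
    probe = list(p0_mpa = 0.5, t_pulse_s = 2e-5, r0_mm = 1.0,
                 impact_xy_mm = c(20, 15), recv_xy_mm = c(15, 15),
                 duration_s = 0.0125, cfl = 0.5),
    ann = list(hidden = c(32L, 64L, 32L), max_epochs = 500L,
               batch_size = 32L, learning_rate = 1e-3, patience = 100L,
               val_fraction = 0.05, activation = "tanh", weight_decay = 1e-3,
               noise_sd = 0.05, dct_k = 450L, swa_epochs = 150L,
               swa_lr = 3e-4),
    cv = list(folds = 10L, repeats = 2L, seed = 1L))
  if (profile == "full") {
    cfg$population$n_subjects <- 1000L
    cfg$patch$nx <- 100L; cfg$patch$ny <- 76L
    cfg$cv$repeats <- 5L
  }
  cfg
}

# Recursively merge user values over defaults.
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a YAML configuration over the profile defaults
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param profile Profile whose defaults are used for unspecified keys; a
#'   `profile` key in the file takes precedence.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL, profile = "desk") {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.null(user$profile)) profile <- user$profile
  merge_config(default_config(profile), user)
}

config_objects <- function(cfg) {
  list(
    grid = build_patch(cfg$patch$lx_mm, cfg$patch$ly_mm, cfg$patch$h_mm,
                       cfg$patch$nx, cfg$patch$ny),
    profile = expander_profile(cfg$expander$a_mm, cfg$expander$b_mm,
                               cfg$expander$apex_mm),
    impact = impact_config(cfg$probe$p0_mpa, cfg$probe$t_pulse_s,
                           cfg$probe$r0_mm, cfg$probe$impact_xy_mm,
                           cfg$probe$recv_xy_mm, cfg$probe$duration_s,
                           cfg$probe$cfl),
    pop = population_spec(cfg$population$n_subjects,
                          ranges = list(mu = cfg$population$mu_mpa,
                                        k = cfg$population$k_per_day,
                                        theta_nat = cfg$population$theta_nat,
                                        rho = cfg$population$rho_kg_m3),
                          seed = cfg$population$seed),
    arch = arch_spec(cfg$ann$hidden, cfg$ann$max_epochs, cfg$ann$batch_size,
                     cfg$ann$learning_rate, cfg$ann$patience,
                     cfg$ann$val_fraction, activation = cfg$ann$activation,
                     weight_decay = cfg$ann$weight_decay,
                     noise_sd = cfg$ann$noise_sd, dct_k = cfg$ann$dct_k,
                     swa_epochs = min(cfg$ann$swa_epochs, cfg$ann$max_epochs),
                     swa_lr = cfg$ann$swa_lr, seed = cfg$cv$seed))
}

#' Run manifest with content hashes
#'
#' Records the config snapshot, seeds, package version, timestamp and an MD5
#' content hash for every produced file, so a run can be checked for
#' bit-exact reproducibility.
#'
#' @param cfg Configuration list.
#' @param files Character vector of produced file paths.
#' @param path Output JSON path (directories are created); `NULL` to skip
#'   writing.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(cfg, files, path = NULL) {
  files <- files[file.exists(files)]
  man <- list(
    version = as.character(utils::packageVersion("expansim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    seeds = list(population = cfg$population$seed, cv = cfg$cv$seed),
    artifacts = lapply(stats::setNames(files, basename(files)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  if (!is.null(path)) {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
    return(invisible(man))
  }
  man
}

#' Pipeline commands
#'
#' Thin orchestration over the package functions, mirroring the pipeline
#' stages: `cmd_sample` draws the virtual population and writes the subjects
#' CSV; `cmd_simulate` runs the measurement protocol for every subject and
#' writes the dataset container; `cmd_cv` runs repeated k-fold
#' cross-validation of the surrogate and writes the CV report;  `cmd_train`
#' fits one model on the full dataset and saves a checkpoint; `cmd_report`
#' summarises a CV run (Table-style medians/stds, predicted-vs-true scatter
#' data for a held-out split, and the per-subject extra-area comparison).
#' Each command is deterministic given the config seeds.
#'
#' @param cfg Configuration list from [load_config()] / [default_config()].
#' @param out_dir Run directory for produced artifacts.
#' @param dataset_dir Dataset container directory (produced by
#'   `cmd_simulate`).
#' @param progress Logical; progress messages.
#' @return Paths of produced artifacts (invisibly), or for `cmd_report` the
#'   report list.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmd_sample <- function(cfg, out_dir) {
  obj <- config_objects(cfg)
  subjects <- sample_subjects(obj$pop)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(out_dir, "subjects.csv")
  write_subjects(subjects, csv)
  run_manifest(cfg, csv, file.path(out_dir, "manifest_sample.json"))
  invisible(csv)
}

#' @rdname pipeline
#' @export
cmd_simulate <- function(cfg, out_dir, progress = FALSE) {
  obj <- config_objects(cfg)
  csv <- file.path(out_dir, "subjects.csv")
  if (!file.exists(csv))
    stop("missing subjects manifest '", csv, "'; run cmd_sample first")
  subjects <- read_subjects(csv)
  ds <- build_dataset(subjects, obj$grid, obj$profile, obj$impact,
                      config = cfg, progress = progress)
  dpath <- file.path(out_dir, "dataset")
  write_dataset(ds, dpath)
  run_manifest(cfg, list.files(dpath, full.names = TRUE),
               file.path(out_dir, "manifest_dataset.json"))
  invisible(dpath)
}

#' @rdname pipeline
#' @export
cmd_cv <- function(cfg, out_dir, dataset_dir = file.path(out_dir, "dataset"),
                   progress = FALSE) {
  if (!dir.exists(dataset_dir))
    stop("missing dataset container '", dataset_dir, "'; run cmd_simulate first")
  ds <- read_dataset(dataset_dir)
  obj <- config_objects(cfg)
  report <- cross_validate(ds, obj$arch, folds = cfg$cv$folds,
                           repeats = cfg$cv$repeats, seed = cfg$cv$seed,
                           verbose = progress)
  files <- write_cv_report(report, out_dir)
  run_manifest(cfg, files, file.path(out_dir, "manifest_cv.json"))
  invisible(report)
}

#' @rdname pipeline
#' @export
cmd_train <- function(cfg, out_dir, dataset_dir = file.path(out_dir, "dataset")) {
  if (!dir.exists(dataset_dir))
    stop("missing dataset container '", dataset_dir, "'; run cmd_simulate first")
  ds <- read_dataset(dataset_dir)
  obj <- config_objects(cfg)
  model <- train_ann(ds$features, ds$targets, obj$arch)
  path <- file.path(out_dir, "model.rds")
  saveRDS(model, path)
  run_manifest(cfg, path, file.path(out_dir, "manifest_model.json"))
  invisible(path)
}

#' @rdname pipeline
#' @export
cmd_report <- function(cfg, out_dir, dataset_dir = file.path(out_dir, "dataset")) {
  csv <- file.path(out_dir, "cv_r2.csv")
  if (!file.exists(csv))
    stop("missing CV results '", csv, "'; run cmd_cv first")
  r2 <- utils::read.csv(csv)
  val_cols <- setdiff(names(r2), c("repeat_", "fold"))
  summary <- data.frame(target = val_cols,
                        median_r2 = vapply(r2[val_cols], stats::median, numeric(1)),
                        sd_r2 = vapply(r2[val_cols], stats::sd, numeric(1)))
  report <- list(summary = summary)

  if (dir.exists(dataset_dir)) {
    # held-out illustration split (90/10) + extra-area comparison
    ds <- read_dataset(dataset_dir)
    obj <- config_objects(cfg)
    n <- nrow(ds$features)
    test <- with_seed(cfg$cv$seed, sample.int(n, max(1L, round(n / 10))))
    model <- train_ann(ds$features[-test, , drop = FALSE],
                       ds$targets[-test, , drop = FALSE], obj$arch)
    pred <- predict(model, ds$features[test, , drop = FALSE])
    grid <- obj$grid
    region_area <- grid$lx * grid$ly / 25
    ea <- function(g25) sum(g25 - 1) * region_area
    extra <- data.frame(
      subject_id = ds$manifest$subject_id[test],
      extra_area_true_mm2 = apply(ds$targets[test, 1:25, drop = FALSE], 1, ea),
      extra_area_pred_mm2 = apply(pred[, 1:25, drop = FALSE], 1, ea))
    extra$abs_error_mm2 <- abs(extra$extra_area_pred_mm2 -
                                 extra$extra_area_true_mm2)
    extra$rel_error <- extra$abs_error_mm2 /
      pmax(extra$extra_area_true_mm2, .Machine$double.eps)
    report$scatter <- list(true = ds$targets[test, , drop = FALSE],
                           pred = pred)
    report$extra_area <- extra
    jsonlite::write_json(
      list(summary = summary, extra_area = extra),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  report
}
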