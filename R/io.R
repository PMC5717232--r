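# On-disk formats: a simulated dataset is stored as a plain-text bundle --
# a JSON manifest (dimensions, time axes, attributes), full-precision CSV
# arrays per subject and group, and the TrialInfo table as CSV. Configs are
# YAML or JSON files mirroring sim_config + selection_model.

fmt_num <- function(x) sprintf("%.17g", x)

write_array_csv <- function(x, path) {
  # trials x sensors x time -> (trial*sensor) rows x time columns, exact text
  d <- dim(x)
  m <- matrix(aperm(x, c(2, 1, 3)), nrow = d[1] * d[2])  # sensor fastest
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(m, 1, function(row) paste(fmt_num(row), collapse = ",")),
             con)
}

read_array_csv <- function(path, d) {
  v <- scan(path, what = numeric(), sep = ",", quiet = TRUE)
  m <- matrix(v, nrow = d[2] * d[1], byrow = TRUE)   # rows were lines
  aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Write a simulated dataset to a plain-text bundle
#'
#' Creates `dir/` with `manifest.json` (time axes, sfreq, seed, config,
#' selection model, stimulus onsets), per-subject full-precision CSV arrays
#' (`sub-<s>_localizer.csv`, `sub-<s>_rsvp.csv`), localizer labels, and the
#' combined RSVP TrialInfo table (`trialinfo.csv`).
#'
#' @param ds a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s1 <- ds$subjects[[1]]
  manifest <- list(
    format = "tgdecode-bundle-v1",
    sfreq = ds$config$sfreq,
    seed = ds$config$rng_seed,
    n_subjects = length(ds$subjects),
    localizer = list(dim = dim(s1$localizer$data), times = s1$localizer$times),
    rsvp = list(dim = dim(s1$rsvp$data), times = s1$rsvp$times),
    onsets = as.list(attr(s1$rsvp, "onsets")),
    config = unclass(ds$config),
    model = unclass(ds$model))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  info_all <- do.call(rbind, lapply(ds$subjects, `[[`, "info"))
  write.csv(info_all, file.path(dir, "trialinfo.csv"), row.names = FALSE)
  loc_labels <- do.call(rbind, lapply(ds$subjects, function(s) s$localizer$info))
  write.csv(loc_labels, file.path(dir, "localizer_labels.csv"),
            row.names = FALSE)
  for (s in seq_along(ds$subjects)) {
    write_array_csv(ds$subjects[[s]]$localizer$data,
                    file.path(dir, sprintf("sub-%02d_localizer.csv", s)))
    write_array_csv(ds$subjects[[s]]$rsvp$data,
                    file.path(dir, sprintf("sub-%02d_rsvp.csv", s)))
  }
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir bundle directory.
#' @return a `sim_dataset`-like list with `config`, `model` and `subjects`
#'   (each with `localizer` / `rsvp` epochs and `info`); numeric data
#'   round-trip exactly.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "tgdecode-bundle-v1"))
    stop("not a tgdecode dataset bundle")
  info_all <- read.csv(file.path(dir, "trialinfo.csv"))
  loc_labels <- read.csv(file.path(dir, "localizer_labels.csv"))
  onsets <- unlist(manifest$onsets)
  subjects <- lapply(seq_len(manifest$n_subjects), function(s) {
    loc_dat <- read_array_csv(file.path(dir, sprintf("sub-%02d_localizer.csv", s)),
                              manifest$localizer$dim)
    rsvp_dat <- read_array_csv(file.path(dir, sprintf("sub-%02d_rsvp.csv", s)),
                               manifest$rsvp$dim)
    loc <- epochs(loc_dat, manifest$localizer$times, manifest$sfreq,
                  info = loc_labels[loc_labels$subject == s, , drop = FALSE])
    info <- info_all[info_all$subject == s, , drop = FALSE]
    rownames(info) <- NULL
    rsvp <- epochs(rsvp_dat, manifest$rsvp$times, manifest$sfreq, info = info)
    attr(rsvp, "onsets") <- onsets
    list(localizer = loc, rsvp = rsvp, info = info)
  })
  list(config = manifest$config, model = manifest$model, subjects = subjects,
       seed = manifest$seed)
}

#' Write a simulation/selection configuration file
#'
#' Serializes a simulation config and selection model to YAML (`.yml`,
#' `.yaml`) or JSON (`.json`), chosen by file extension.
#'
#' @param sim a [sim_config()].
#' @param model a [selection_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(sim, model, path) {
  obj <- list(sim = unclass(sim), model = unclass(model))
  # named atomic vectors lose their names in YAML; serialize as maps
  obj$model$lag_modulation <- as.list(obj$model$lag_modulation)
  obj$sim$stage_amplitudes <- as.list(obj$sim$stage_amplitudes)
  obj$sim$stage_windows <- lapply(obj$sim$stage_windows, as.list)
  if (grepl("\\.(yml|yaml)$", path)) {
    yaml::write_yaml(obj, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else stop("config path must end in .yml, .yaml or .json")
  invisible(path)
}

#' Read a configuration file written by [write_config()]
#'
#' @param path YAML or JSON config path.
#' @return list with `sim` (a `sim_config`) and `model` (a
#'   `selection_model`).
#' @export
read_config <- function(path) {
  obj <- if (grepl("\\.(yml|yaml)$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sim$lags <- unlist(obj$sim$lags)
  obj$sim$stage_amplitudes <- unlist(obj$sim$stage_amplitudes)
  obj$sim$stage_windows <- lapply(obj$sim$stage_windows, unlist)
  sim <- do.call(sim_config, obj$sim[setdiff(names(obj$sim), "")])
  m <- obj$model
  model <- selection_model(mode = m$mode, gradual_sigma = m$gradual_sigma,
                           gradual_amplitude = m$gradual_amplitude,
                           gradual_asymmetry = m$gradual_asymmetry,
                           discrete_gain = m$discrete_gain,
                           guess_gains = unlist(m$guess_gains),
                           lag_modulation = unlist(m$lag_modulation),
                           behavior_sigma = m$behavior_sigma,
                           guess_floor = m$guess_floor)
  list(sim = sim, model = model)
}
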