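#' Full experiment configuration
#'
#' Bundles the simulation, selection-model, decoding and statistics options
#' of an end-to-end run. A run is reproducible from the config alone.
#'
#' @param sim a [sim_config()].
#' @param model a [selection_model()].
#' @param n_folds stratified CV folds for localizer decoding.
#' @param anchor_times named training times (ms) extracted from the full
#'   training grid for the statistics layer.
#' @param early_anchor,late_anchor the two contrast anchors (ms) used for
#'   the gradual/discrete signatures.
#' @param test_window per-stimulus window (ms) over which performance is
#'   averaged for condition contrasts.
#' @param position_offsets stimulus offsets relative to the target analyzed
#'   in the position profile.
#' @param lags_for_position lags pooled for the position profile (long lags,
#'   so that all offsets exist in the stream).
#' @param alpha significance threshold.
#' @param seed analysis seed (fold splits, unreported-stimulus draws).
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              model = selection_model(),
                              n_folds = 5,
                              anchor_times = c(120, 170, 220, 270, 320, 370),
                              early_anchor = 170, late_anchor = 370,
                              test_window = c(400, 550),
                              position_offsets = -4:2,
                              lags_for_position = c(7, 9),
                              alpha = 0.05, seed = 1) {
  structure(list(sim = sim, model = model, n_folds = n_folds,
                 anchor_times = anchor_times, early_anchor = early_anchor,
                 late_anchor = late_anchor, test_window = test_window,
                 position_offsets = position_offsets,
                 lags_for_position = lags_for_position, alpha = alpha,
                 seed = seed),
            class = "experiment_config")
}

#' Localizer stage: within-task temporal generalization
#'
#' Simulates (or reuses) the dataset, runs cross-validated temporal
#' generalization per subject on the localizer, and derives the group-level
#' outputs: mean generalization matrix, diagonal timecourse with signed-rank
#' tests against chance (FDR across testing times), and onset/offset of the
#' decodable period, overall and per category.
#'
#' @param cfg an [experiment_config()].
#' @param ds optional pre-simulated `sim_dataset` (simulated from `cfg$sim`
#'   if missing).
#' @return list with `group_matrix`, `train_times`, `test_times`, `diag`
#'   (group diagonal), `diag_stats` (per testing time, FDR-adjusted),
#'   `onset_offset` (overall + per category), `subject_matrices`,
#'   `subject_diags`, `chance`.
#' @export
run_localizer_stage <- function(cfg, ds = NULL) {
  if (is.null(ds)) ds <- simulate_dataset(cfg$sim, cfg$model)
  n_sub <- length(ds$subjects)
  subj <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    loc <- ds$subjects[[s]]$localizer
    gm <- cv_temporal_generalization(loc, n_folds = cfg$n_folds,
                                     seed = cfg$seed + s)
    diag_cat <- sapply(gm$classes, function(cc) {
      idx <- which(loc$info$category == cc)
      dmat <- apply(gm$correct_prob[, , idx, drop = FALSE], c(1, 2), mean)
      dmat[cbind(seq_along(gm$train_times),
                 match(gm$train_times, gm$test_times))]
    })
    subj[[s]] <- list(values = gm$values, diag = gm_diagonal(gm),
                      diag_cat = diag_cat, chance = gm$chance,
                      train_times = gm$train_times,
                      test_times = gm$test_times)
  }
  times <- subj[[1]]$train_times
  group_matrix <- Reduce(`+`, lapply(subj, `[[`, "values")) / n_sub
  diags <- sapply(subj, `[[`, "diag")              # time x subject
  chance <- subj[[1]]$chance
  keep <- times >= 0                                # stats on 0..550 ms
  diag_stats <- do.call(rbind, lapply(which(keep), function(i)
    cbind(test_ms = times[i],
          signed_rank_test(diags[i, ], mu = chance, tail = "greater"))))
  diag_stats <- fdr_family(diag_stats, "localizer_diagonal_testing_times")
  group_diag <- rowMeans(diags)
  oo <- rbind(overall = onset_offset(group_diag[keep], times[keep]))
  for (cc in colnames(subj[[1]]$diag_cat)) {
    dc <- rowMeans(sapply(subj, function(s) s$diag_cat[, cc]))
    oo <- rbind(oo, onset_offset(dc[keep], times[keep]))
    rownames(oo)[nrow(oo)] <- cc
  }
  list(group_matrix = group_matrix, train_times = times,
       test_times = subj[[1]]$test_times, diag = group_diag,
       subject_diags = diags, diag_stats = diag_stats, onset_offset = oo,
       subject_matrices = lapply(subj, `[[`, "values"), chance = chance)
}

#' Transfer stage: localizer classifiers applied to the stream
#'
#' Trains a classifier bank on each subject's full localizer, transfers it
#' to the per-stimulus re-epoched RSVP data, and reduces the result to (i)
#' per-position generalization matrices, (ii) per-trial window means at the
#' anchor training times, and the group-level contrasts of the selection
#' analyses: position profile around the target (long lags), target versus
#' non-target, lag and guess effects, and the gradual/discrete
#' identification signature.
#'
#' @param cfg an [experiment_config()].
#' @param ds optional pre-simulated `sim_dataset`.
#' @param train_times training times for the transferred bank; default the
#'   full localizer grid. Restricting to the anchor times gives the same
#'   window statistics at a fraction of the cost.
#' @return list with `subjects` (per-subject reductions), `position_profile`
#'   + `position_stats`, `profile_spearman`, `target_contrast`,
#'   `guess_table` + `guess_stats` + `guess_trend`, `lag_anova`,
#'   `identification`, axes and `chance`.
#' @export
run_transfer_stage <- function(cfg, ds = NULL, train_times = NULL) {
  if (is.null(ds)) ds <- simulate_dataset(cfg$sim, cfg$model)
  n_sub <- length(ds$subjects)
  anchors <- sort(unique(c(cfg$anchor_times, cfg$early_anchor,
                           cfg$late_anchor)))
  subj <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    sub <- ds$subjects[[s]]
    bank <- train_timepoint_classifiers(sub$localizer,
                                        train_times = train_times)
    pre <- precompute_bank(bank$classifiers)
    ep_list <- epoch_stream(sub$rsvp)
    positions <- as.integer(sub("^pos", "", names(ep_list)))
    test_times <- ep_list[[1]]$times
    n_tr <- nrow(sub$info)
    a_idx <- vapply(anchors, function(t) time_index(bank$train_times, t),
                    integer(1))
    w_idx <- window_index(test_times, cfg$test_window)
    win <- array(NA_real_, c(length(anchors), length(positions), n_tr),
                 dimnames = list(paste0("t", anchors), NULL, NULL))
    pos_values <- vector("list", length(positions))
    names(pos_values) <- names(ep_list)
    for (j in seq_along(positions)) {
      cats <- sub$info[[paste0("cat_pos", positions[j])]]
      cls_idx <- match(as.character(cats), bank$classes)
      cp <- bank_correct_prob(pre, ep_list[[j]], cls_idx)
      pos_values[[j]] <- rowMeans(cp, dims = 2)
      for (a in seq_along(anchors))
        win[a, j, ] <- colMeans(cp[a_idx[a], w_idx, , drop = TRUE])
    }
    psm <- list(positions = positions, train_times = bank$train_times,
                test_times = test_times, chance = 1 / length(bank$classes))
    unrep <- with_seed(cfg$seed * 1000 + s, {
      vapply(seq_len(n_tr), function(t) {
        pool <- setdiff(psm$positions,
                        unlist(sub$info[t, c("guess1", "guess2", "guess3")]))
        pool[sample.int(length(pool), 1L)]
      }, integer(1))
    })
    subj[[s]] <- list(
      pos_values = pos_values,
      positions = psm$positions, win = win, info = sub$info,
      unreported = unrep)
    subj[[s]]$train_times <- psm$train_times
    subj[[s]]$test_times <- psm$test_times
    subj[[s]]$chance <- psm$chance
  }
  chance <- subj[[1]]$chance
  out <- list(subjects = subj, anchors = anchors, chance = chance,
              train_times = subj[[1]]$train_times,
              test_times = subj[[1]]$test_times,
              test_window = cfg$test_window)
  out$position_profile <- position_profile(subj, anchors, cfg)
  out$position_stats <- position_profile_stats(out$position_profile, chance,
                                               cfg)
  out$profile_spearman <- profile_spearman(out$position_profile, cfg)
  out$target_contrast <- target_contrast(subj, anchors, chance, cfg)
  gt <- guess_tables(subj, anchors, cfg)
  out$guess_table <- gt$table
  out$guess_stats <- gt$stats
  out$guess_trend <- gt$trend
  out$lag_anova <- gt$lag_anova
  out$identification <- identify_selection_model(out, cfg)
  out
}

# per-subject mean window performance at each (anchor, offset) for long lags
position_profile <- function(subj, anchors, cfg) {
  offs <- cfg$position_offsets
  res <- expand.grid(anchor = anchors, offset = offs)
  vals <- matrix(NA_real_, nrow(res), length(subj))
  for (s in seq_along(subj)) {
    info <- subj[[s]]$info
    win <- subj[[s]]$win
    for (r in seq_len(nrow(res))) {
      d <- res$offset[r]
      a <- match(res$anchor[r], anchors)
      sel <- which(info$lag %in% cfg$lags_for_position &
                     info$lag + d >= 1 & info$lag + d <= 12)
      pos_idx <- match(info$lag[sel] + d, subj[[s]]$positions)
      vals[r, s] <- mean(win[cbind(a, pos_idx, sel)])
    }
  }
  res$group_mean <- rowMeans(vals)
  attr(res, "subject_values") <- vals
  res
}

position_profile_stats <- function(profile, chance, cfg) {
  vals <- attr(profile, "subject_values")
  stats <- do.call(rbind, lapply(seq_len(nrow(profile)), function(r)
    cbind(anchor = profile$anchor[r], offset = profile$offset[r],
          signed_rank_test(vals[r, ], mu = chance, tail = "greater"))))
  fdr_family(stats, paste0("positions_anchor_", stats$anchor))
}

# Spearman correlation of the window-mean profile with the injected
# attentional gain profile (ground truth available for gradual simulations)
profile_spearman <- function(profile, cfg) {
  if (cfg$model$mode != "gradual") return(NULL)
  gains <- gradual_gain_profile(cfg$model, target_position = 0,
                                positions = cfg$position_offsets)
  anchors <- unique(profile$anchor)
  rho <- vapply(anchors, function(a) {
    sel <- profile$anchor == a
    cor(profile$group_mean[sel], gains, method = "spearman")
  }, numeric(1))
  names(rho) <- anchors
  rho
}

target_contrast <- function(subj, anchors, chance, cfg) {
  lags <- cfg$sim$lags
  res <- expand.grid(anchor = anchors, position = lags)
  tv <- matrix(NA_real_, nrow(res), length(subj))
  nv <- tv
  for (s in seq_along(subj)) {
    info <- subj[[s]]$info
    win <- subj[[s]]$win
    for (r in seq_len(nrow(res))) {
      a <- match(res$anchor[r], anchors)
      j <- match(res$position[r], subj[[s]]$positions)
      tgt <- info$lag == res$position[r]
      tv[r, s] <- mean(win[a, j, tgt])
      nv[r, s] <- mean(win[a, j, !tgt])
    }
  }
  res$target_mean <- rowMeans(tv)
  res$nontarget_mean <- rowMeans(nv)
  stats <- do.call(rbind, lapply(seq_len(nrow(res)), function(r)
    cbind(anchor = res$anchor[r], position = res$position[r],
          signed_rank_test(tv[r, ] - nv[r, ], tail = "two.sided"))))
  stats <- fdr_family(stats, paste0("target_vs_nontarget_anchor_",
                                    stats$anchor))
  list(table = res, stats = stats, target_values = tv,
       nontarget_values = nv)
}

guess_tables <- function(subj, anchors, cfg) {
  classes <- c("guess1", "guess2", "guess3", "unreported")
  rows <- list()
  for (s in seq_along(subj)) {
    info <- subj[[s]]$info
    win <- subj[[s]]$win
    pos_of <- cbind(info$guess1, info$guess2, info$guess3,
                    subj[[s]]$unreported)
    for (a in seq_along(anchors)) for (lg in sort(unique(info$lag))) {
      sel <- which(info$lag == lg)
      for (k in seq_along(classes)) {
        j <- match(pos_of[sel, k], subj[[s]]$positions)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, anchor = anchors[a], lag = lg, guess = classes[k],
          value = mean(win[cbind(a, j, sel)]))
      }
    }
  }
  tab <- do.call(rbind, rows)
  late <- tab[tab$anchor == cfg$late_anchor, ]
  cell <- aggregate(value ~ subject + guess, late, mean)
  chance <- subj[[1]]$chance
  stats <- do.call(rbind, lapply(classes, function(g)
    cbind(guess = g,
          signed_rank_test(cell$value[cell$guess == g], mu = chance,
                           tail = "greater"))))
  stats <- fdr_family(stats, "guess_vs_chance_late_anchor")
  m <- sapply(classes, function(g) cell$value[cell$guess == g][
    order(cell$subject[cell$guess == g])])
  trend <- linear_trend_slope(-m, tail = "greater")  # decreasing over guesses
  trend$mean_slope <- -trend$mean_slope              # report the raw slope
  lag_anova <- art_rm_anova(late, "value", c("lag", "guess"), "subject")
  list(table = tab, stats = stats, trend = trend, lag_anova = lag_anova)
}

#' Identify the generating selection model from the decoding signature
#'
#' Uses the early-versus-late window-mean signature at the target position:
#' gradual selection sustains the early-stage (170 ms) code into the 400-550
#' ms window while leaving no late-anchor elevation, discrete selection does
#' the reverse.
#'
#' @param transfer result of [run_transfer_stage()].
#' @param cfg the matching [experiment_config()].
#' @return list with `label` (`"gradual"` or `"discrete"`), `early_elev`,
#'   `late_elev`.
#' @export
identify_selection_model <- function(transfer, cfg) {
  pr <- transfer$position_profile
  elev <- function(anchor) {
    sel <- pr$anchor == anchor & pr$offset == 0
    pr$group_mean[sel] - transfer$chance
  }
  early <- elev(cfg$early_anchor)
  late <- elev(cfg$late_anchor)
  list(label = if (early > late) "gradual" else "discrete",
       early_elev = early, late_elev = late)
}

#' Run the full pipeline end-to-end
#'
#' Simulation, localizer decoding, transfer contrasts, behavioral tables and
#' activation patterns, plus a run manifest. All outputs are deterministic
#' functions of the config.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional directory; if given, CSV tables and the manifest
#'   are written there.
#' @return object of class `results_bundle`: list with `localizer`,
#'   `transfer`, `behavior`, `patterns`, `manifest`.
#' @export
run_full <- function(cfg, out_dir = NULL) {
  ds <- simulate_dataset(cfg$sim, cfg$model)
  loc <- run_localizer_stage(cfg, ds)
  trf <- run_transfer_stage(cfg, ds)
  info_all <- do.call(rbind, lapply(ds$subjects, `[[`, "info"))
  beh <- list(
    accuracy = blink_accuracy(info_all),
    report = do.call(rbind, lapply(cfg$sim$lags, function(lg)
      do.call(rbind, lapply(1:3, function(g)
        report_distribution(info_all, lg, g))))))
  beh$accuracy_anova <- art_rm_anova(beh$accuracy, "accuracy", "lag",
                                     "subject")
  bank <- train_timepoint_classifiers(ds$subjects[[1]]$localizer,
                                      train_times = cfg$anchor_times)
  pat <- lapply(seq_along(cfg$anchor_times), function(i) {
    ti <- time_index(ds$subjects[[1]]$localizer$times, cfg$anchor_times[i])
    activation_pattern(bank$classifiers[[i]],
                       ds$subjects[[1]]$localizer$data[, , ti])
  })
  names(pat) <- paste0("t", cfg$anchor_times)
  manifest <- list(package_version = as.character(utils::packageVersion("tgdecode")),
                   config_hash = config_hash(cfg), seed = cfg$seed,
                   sim_seed = cfg$sim$rng_seed, model = cfg$model$mode,
                   n_subjects = length(ds$subjects))
  out <- structure(list(localizer = loc, transfer = trf, behavior = beh,
                        patterns = pat, manifest = manifest),
                   class = "results_bundle")
  if (!is.null(out_dir)) export_bundle(out, out_dir)
  out
}

# stable polynomial hash of the serialized configuration (manifest identity)
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483629
  sprintf("%08x", h)
}

export_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$transfer$position_profile,
            file.path(dir, "position_profile.csv"), row.names = FALSE)
  write.csv(bundle$transfer$position_stats,
            file.path(dir, "position_stats.csv"), row.names = FALSE)
  write.csv(bundle$transfer$guess_table, file.path(dir, "guess_table.csv"),
            row.names = FALSE)
  write.csv(bundle$transfer$guess_stats, file.path(dir, "guess_stats.csv"),
            row.names = FALSE)
  write.csv(bundle$behavior$accuracy, file.path(dir, "blink_accuracy.csv"),
            row.names = FALSE)
  write.csv(bundle$behavior$report, file.path(dir, "report_distribution.csv"),
            row.names = FALSE)
  write.csv(bundle$localizer$diag_stats,
            file.path(dir, "localizer_diag_stats.csv"), row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
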