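# End-to-end orchestration: configuration, the full synthetic screen, and
# reproducible run directories.

#' Default screen configuration
#'
#' All tunable parameters of the end-to-end synthetic screen, in one nested
#' list. `screen_config()` returns the defaults; pass overrides as nested
#' lists, or read a YAML file with [read_screen_config()]. Unknown keys are
#' rejected.
#'
#' @param ... nested overrides, e.g. `atlas = list(n_regions = 4)`.
#' @return a validated `screen_config` list.
#' @export
screen_config <- function(...) {
  defaults <- list(
    config_version = 1,
    seed = 1,
    atlas = list(shape = c(4, 16, 16), n_regions = 4,
                 voxel_size = c(40, 10, 10)),
    schedule = list(pre_duration = 120, n_stimuli = 2, interval = 120),
    imaging = list(rate = 20, noise_sd = 2, n_neurons_per_region = 3,
                   signal_amp = 20, duration = NULL),
    connectivity = list(wt_rho = 0.6, n_connected = 2, mut_shift = -0.35),
    compounds = list(drugA = list(correction = 0.9, off_target = 0.05,
                                  efficacy = 0.8, behavior_shift = 0.1),
                     drugB = list(correction = 0.5, off_target = 0.3,
                                  efficacy = 0.5, behavior_shift = 0.3),
                     drugC = list(correction = 0.1, off_target = 0.1,
                                  efficacy = 0.2, behavior_shift = 0.05)),
    groups = list(n_larvae = 3),
    analysis = list(k_range_max = 6, min_frames = 100, active_c = 3,
                    cv_folds = 3),
    selection = list(n_rounds = 2, min_k = 2),
    qa = list(n_surrogates = 100, max_pairs = 2),
    lfp = list(rate = 100, duration = 240, baseline_event_rate = 2.5,
               snr = 6, n_larvae = 3),
    behavior = list(duration = 4, rate = 25, n_larvae = 2))
  validate_config(utils::modifyList(defaults, list(...)), defaults)
}

validate_config <- function(cfg, defaults, path = "") {
  extra <- setdiff(names(cfg), names(defaults))
  if (length(extra))
    stop_fc("unknown config key%s: %s", if (length(extra) > 1) "s" else "",
            paste0(path, extra, collapse = ", "))
  for (k in names(cfg)) {
    if (k == "compounds") next   # free-form compound list
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      validate_config(cfg[[k]], defaults[[k]], paste0(path, k, "."))
  }
  structure(cfg, class = "screen_config")
}

#' Read a screen configuration from YAML
#' @param path YAML file with (a subset of) the [screen_config()] keys.
#' @return a validated `screen_config`.
#' @export
read_screen_config <- function(path) {
  if (!file.exists(path)) stop_fc("config file not found: %s", path)
  do.call(screen_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  s <- yaml::as.yaml(cfg)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

# planted connectivity structures for the screen: wild-type, mutant, and
# per-compound corrected mutants
screen_truth_structures <- function(cfg) {
  R <- cfg$atlas$n_regions
  pr <- area_pairs(R)
  ncon <- min(cfg$connectivity$n_connected, nrow(pr))
  # connected pairs chosen disjoint where possible so row sums stay <= 1
  sel <- integer(0); used <- integer(0)
  for (p in seq_len(nrow(pr))) {
    if (length(sel) == ncon) break
    if (!(pr$i[p] %in% used) && !(pr$j[p] %in% used)) {
      sel <- c(sel, p); used <- c(used, pr$i[p], pr$j[p])
    }
  }
  while (length(sel) < ncon) sel <- c(sel, setdiff(seq_len(nrow(pr)), sel)[1])
  ent <- function(rhos) {
    do.call(rbind, lapply(seq_along(sel), function(q)
      data.frame(i = pr$i[sel[q]], j = pr$j[sel[q]],
                 state = c("pre", "early", "late"),
                 rho = rhos[q])))
  }
  wt_rho <- rep(cfg$connectivity$wt_rho, ncon)
  mut_rho <- pmin(pmax(wt_rho + cfg$connectivity$mut_shift, 0), 0.95)
  comp <- lapply(cfg$compounds, function(cc) {
    r <- mut_rho + cc$correction * (wt_rho - mut_rho)
    r[1] <- min(0.95, r[1] + cc$off_target)   # compound-specific signature
    pmin(pmax(r, 0), 0.95)
  })
  list(pairs = pr[sel, , drop = FALSE],
       wt = plant_connectivity(R, ent(wt_rho)),
       mut = plant_connectivity(R, ent(mut_rho)),
       compounds = lapply(comp, function(r) plant_connectivity(R, ent(r))))
}

process_larva <- function(atlas, truth, schedule, cfg, seed) {
  rec <- simulate_condition_recording(atlas, truth, schedule,
                                      imaging = cfg$imaging, seed = seed)
  mask <- select_timevarying_voxels(rec$volume)
  sv <- build_supervoxels(rec$volume, mask, atlas = atlas,
                          k_range = seq_len(cfg$analysis$k_range_max),
                          cv_folds = cfg$analysis$cv_folds, seed = seed)
  detect_active_supervoxels(sv, c = cfg$analysis$active_c)
}

group_fingerprint <- function(atlas, structure, condition, schedule, cfg,
                              label, seed) {
  svs <- lapply(seq_len(cfg$groups$n_larvae), function(l) {
    truth <- ground_truth(atlas, structure, condition = condition)
    process_larva(atlas, truth, schedule, cfg,
                  seed = substream_seed(seed, paste0(label, l)))
  })
  dur <- if (length(schedule$stimulus_times))
    max(schedule$stimulus_times) + 120 else schedule$pre_duration
  win <- segment_states(schedule, dur)
  fp <- suppressWarnings(
    assemble_fingerprint(svs, atlas, win, group_label = label,
                         min_frames = cfg$analysis$min_frames))
  list(fingerprint = fp, svs = svs)
}

#' Run the full synthetic screen end to end
#'
#' Executes synthetic generation, voxel processing, fingerprinting,
#' clustering and polytherapy selection, stationarity QA, and LFP/behavior
#' scoring, writing every output (CSV/JSON/Newick plus a log) into
#' `out_dir`. Outputs are stamped with the seed and a config hash; rerunning
#' with identical config and seed reproduces them byte for byte.
#'
#' @param config a `screen_config` (or a YAML path).
#' @param out_dir output directory, created if needed.
#' @param seed overrides `config$seed` when given.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_screen <- function(config = screen_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_screen_config(config)
  if (!inherits(config, "screen_config")) config <- do.call(screen_config, config)
  seed <- seed %||% config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  hash <- config_hash(config)
  logline <- function(...) {
    msg <- sprintf(...)
    cat(sprintf("[seed %d | cfg %s] %s\n", seed, hash, msg),
        file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    logline("stage %s: start", name)
    out <- tryCatch(expr, error = function(e)
      stop_fc("stage %s failed: %s", name, conditionMessage(e)))
    logline("stage %s: done", name)
    out
  }
  cat(yaml::as.yaml(config), file = file.path(out_dir, "config.yaml"))

  atlas <- stage("atlas", generate_atlas(
    shape = config$atlas$shape, n_regions = config$atlas$n_regions,
    voxel_size = config$atlas$voxel_size,
    seed = substream_seed(seed, "atlas-stage")))

  sch <- stimulus_schedule(
    pre_duration = config$schedule$pre_duration,
    stimulus_times = config$schedule$pre_duration +
      config$schedule$interval * (seq_len(config$schedule$n_stimuli) - 1))

  strs <- screen_truth_structures(config)
  fp_stage <- stage("fingerprints", {
    fps <- list()
    g <- group_fingerprint(atlas, strs$wt, "wild_type", sch, config,
                           "WT-0h", substream_seed(seed, "WT-0h"))
    fps[["WT-0h"]] <- g$fingerprint
    fps[["Mut-0h"]] <- group_fingerprint(
      atlas, strs$mut, "mutant", sch, config, "Mut-0h",
      substream_seed(seed, "Mut-0h"))$fingerprint
    for (cn in names(strs$compounds))
      fps[[paste0("Mut-4h-", cn)]] <- group_fingerprint(
        atlas, strs$compounds[[cn]], "mutant", sch, config,
        paste0("Mut-4h-", cn), substream_seed(seed, cn))$fingerprint
    write_fingerprint_csv(fps, file.path(out_dir, "fingerprints.csv"),
                          file.path(out_dir, "fingerprints_wide.csv"))
    list(fps = fps, wt_svs = g$svs)
  })
  fps <- fp_stage$fps; wt_svs <- fp_stage$wt_svs

  sel <- stage("clustering", {
    M <- normalize_matrix(fingerprint_matrix(fps))
    tree <- cluster_fingerprints(M, min_k = config$selection$min_k)
    utils::write.csv(data.frame(row = names(tree$assignment),
                                cluster = tree$assignment),
                     file.path(out_dir, "assignments.csv"), row.names = FALSE)
    if (!is.null(tree$hclust)) {
      utils::write.csv(data.frame(merge1 = tree$hclust$merge[, 1],
                                  merge2 = tree$hclust$merge[, 2],
                                  height = tree$hclust$height),
                       file.path(out_dir, "linkage.csv"), row.names = FALSE)
      writeLines(tree_to_newick(tree), file.path(out_dir, "dendrogram.nwk"))
    }
    sel <- select_polytherapy(M, n_rounds = config$selection$n_rounds,
                              min_k = config$selection$min_k)
    write_selection_json(sel, file.path(out_dir, "selection.json"))
    sel
  })

  stage("qa", {
    rep <- stationarity_report(wt_svs[[1]], atlas,
                               n_surrogates = config$qa$n_surrogates,
                               seed = substream_seed(seed, "qa"))
    rep <- utils::head(rep, config$qa$max_pairs)
    utils::write.csv(rep, file.path(out_dir, "stationarity_qa.csv"),
                     row.names = FALSE)
  })

  scores <- stage("scores", {
    lcfg <- config$lfp
    train <- seizure_training_set(rate = lcfg$rate, snr = lcfg$snr,
                                  seed = substream_seed(seed, "train"))
    det <- train_seizure_classifier(train$features, train$labels)
    hits <- sub("^Mut-4h-", "", sel$hits)
    conds <- c(list(untreated = NULL),
               stats::setNames(lapply(hits, identity), hits))
    base_beh <- do.call(rbind, lapply(seq_len(config$behavior$n_larvae),
      function(l) {
        sim <- simulate_behavior(config$behavior$duration,
                                 config$behavior$rate,
                                 motion_program = list(velocity = 30,
                                                       tail_beat = 12,
                                                       lateral_amp = 3,
                                                       start = c(60, 130)),
                                 frame_size = c(260, 260),
                                 seed = substream_seed(seed, paste0("beh0", l)))
        compute_behavioral_features(track_skeleton(sim))
      }))
    rows <- lapply(names(conds), function(cn) {
      eff_pl <- if (cn == "untreated") 0 else
        config$compounds[[cn]]$efficacy
      shift <- if (cn == "untreated") 0 else
        config$compounds[[cn]]$behavior_shift
      pairs <- lapply(seq_len(lcfg$n_larvae), function(l) {
        s0 <- substream_seed(seed, paste0("lfp", cn, l))
        list(baseline = detect_seizures(
               simulate_lfp(lcfg$duration, lcfg$rate,
                            event_rate = lcfg$baseline_event_rate,
                            snr = lcfg$snr, seed = s0), det),
             post = detect_seizures(
               simulate_lfp(lcfg$duration, lcfg$rate,
                            event_rate = lcfg$baseline_event_rate *
                              (1 - eff_pl),
                            snr = lcfg$snr, seed = s0 + 7L), det))
      })
      beh <- do.call(rbind, lapply(seq_len(config$behavior$n_larvae),
        function(l) {
          sim <- simulate_behavior(config$behavior$duration,
                                   config$behavior$rate,
                                   motion_program = list(
                                     velocity = 30 * (1 + shift),
                                     tail_beat = 12, lateral_amp = 3,
                                     start = c(60, 130)),
                                   frame_size = c(260, 260),
                                   seed = substream_seed(seed, paste0("beh", cn, l)))
          compute_behavioral_features(track_skeleton(sim))
        }))
      suppressWarnings(evaluate_condition(
        treatment_condition(cn, 1), pairs, beh, base_beh, det))
    })
    tab <- dose_response_table(rows)
    utils::write.csv(tab, file.path(out_dir, "scores.csv"), row.names = FALSE)
    tab
  })

  logline("run complete")
  invisible(list(atlas = atlas, fingerprints = fps, selection = sel,
                 scores = scores, out_dir = out_dir))
}
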