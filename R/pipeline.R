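#' Pipeline run configuration
#'
#' Nested configuration for a full simulate -> preprocess -> decode ->
#' statistics -> report run. Round-trips losslessly through YAML; every
#' stochastic stage receives a seed derived from `master_seed` and the
#' stage name, which is logged in the manifest.
#'
#' @param sim a [sim_config()] (the demo default is a scaled-down study:
#'   fewer participants, coarser decoding grid and fewer permutations than
#'   the full design, to keep a desk run in minutes).
#' @param n_perm permutations for cluster statistics.
#' @param cluster_alpha cluster-forming alpha.
#' @param decode_step decoding timepoint grid step (ms).
#' @param decode_iterations re-binning iterations.
#' @param stages character vector of enabled stages, in dependency order.
#' @param master_seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(n_participants = 6),
                       n_perm = 200, cluster_alpha = 0.05,
                       decode_step = 100, decode_iterations = 3,
                       stages = c("simulate", "preprocess", "behavior",
                                  "decode", "stats", "report"),
                       master_seed = 1) {
  structure(list(sim = sim, n_perm = n_perm, cluster_alpha = cluster_alpha,
                 decode_step = decode_step,
                 decode_iterations = decode_iterations,
                 stages = stages, master_seed = master_seed),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or the restored `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(lapply(config, function(x)
    if (inherits(x, "sim_config")) unclass(x) else x)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$sim)
  run_config(sim = sim, n_perm = raw$n_perm,
             cluster_alpha = raw$cluster_alpha,
             decode_step = raw$decode_step,
             decode_iterations = raw$decode_iterations,
             stages = raw$stages, master_seed = raw$master_seed)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on synthetic data: simulation,
#' preprocessing (baseline correction, artifact rejection), behavioral
#' statistics, condition- and item-level decoding with empirical chance
#' estimation, cluster permutation inference, and a plain-text report.
#' Writes per-stage outputs, a machine-readable `manifest.json` (stage,
#' seed, outputs, md5 checksums) and `report.txt` under `out_dir`. A rerun
#' with the same config and seed reproduces identical checksums.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  log_stage <- function(stage, seed, outputs, t0) {
    manifest[[stage]] <<- list(
      stage = stage, seed = seed,
      outputs = outputs,
      checksums = as.list(tools::md5sum(outputs)),
      wall_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  }
  report <- character(0)
  montage <- load_montage()
  sims <- NULL; behavior <- NULL
  item_think <- list(); item_pb <- list(); cond_res <- list()
  chance_tbl <- NULL

  run <- function(stage, fn) {
    t0 <- Sys.time()
    out <- tryCatch(fn(t0),
                    error = function(e) stop("pipeline stage '", stage,
                                             "' failed: ",
                                             conditionMessage(e),
                                             call. = FALSE))
    out
  }

  if ("simulate" %in% config$stages) {
    run("simulate", function(t0) {
      cfg <- config$sim
      cfg$seed <- derive_seed(config$master_seed, 1)
      sims <<- lapply(seq_len(cfg$n_participants), function(p)
        simulate_participant(cfg, p, montage = montage))
      behavior <<- simulate_behavior(lapply(sims, `[[`, "truth"), cfg)
      paths <- vapply(seq_along(sims), function(p) {
        write_epochs(sims[[p]]$epochs,
                     file.path(out_dir, sprintf("sub-%02d", p)))
        file.path(out_dir, sprintf("sub-%02d", p), "meta.json")
      }, character(1))
      bpath <- file.path(out_dir, "behavior.csv")
      write_behavior(behavior, bpath)
      log_stage("simulate", cfg$seed, c(paths, bpath), t0)
    })
  }
  if ("preprocess" %in% config$stages) {
    run("preprocess", function(t0) {
      for (p in seq_along(sims)) {
        e <- baseline_correct(sims[[p]]$epochs, c(-500, 0))
        sims[[p]]$epochs <<- reject_artifacts(e, 100)$epochs
      }
      log_stage("preprocess", NA, character(0), t0)
    })
  }
  if ("behavior" %in% config$stages) {
    run("behavior", function(t0) {
      wide <- stats::reshape(behavior[, c("participant", "condition",
                                          "detail")],
                             idvar = "participant",
                             timevar = "condition", direction = "wide")
      an <- rm_anova_gg(as.matrix(wide[, -1]))
      tt <- paired_t_dz(wide$detail.Baseline, wide$detail.NoThink)
      report <<- c(report,
                   sprintf("Detail RM-ANOVA: F(%.2f, %.2f) = %.2f, p = %.4f",
                           an$df_gg[1], an$df_gg[2], an$value, an$p),
                   sprintf("Baseline vs No-Think Detail: t(%d) = %.2f, p = %.4f, dz = %.2f",
                           tt$df, tt$value, tt$p, tt$effect_size))
      log_stage("behavior", NA, character(0), t0)
    })
  }
  if ("decode" %in% config$stages) {
    run("decode", function(t0) {
      ispec <- decode_spec("item_one_vs_all",
                           n_iterations = config$decode_iterations,
                           step = config$decode_step)
      cspec <- decode_spec("condition_pairwise",
                           n_iterations = config$decode_iterations,
                           step = config$decode_step)
      chance_rows <- list()
      for (p in seq_along(sims)) {
        e <- sims[[p]]$epochs
        seedp <- derive_seed(config$master_seed, 2, p)
        think <- select_trials(e, e$trial_table$condition == "Think")
        pb <- select_trials(e,
                            e$trial_table$condition == "PerceptualBaseline")
        ft <- pca_reduce(think); fp <- pca_reduce(pb)
        isp <- ispec; isp$seed <- seedp
        item_think[[p]] <<- decode_timecourse(ft, isp)
        item_pb[[p]] <<- decode_timecourse(fp, isp)
        tp <- select_trials(e, e$trial_table$condition %in%
                              c("Think", "PerceptualBaseline"))
        tp <- subsample_to_match(tp, "Think", "PerceptualBaseline",
                                 seed = seedp)
        fc <- pca_reduce(tp)
        csp <- cspec; csp$seed <- seedp
        cond_res[[p]] <<- decode_timecourse(fc, csp)
        chance_rows[[p]] <- data.frame(
          participant = p,
          item_think = estimate_chance(ft, isp),
          condition_t_pb = estimate_chance(fc, csp))
      }
      chance_tbl <<- do.call(rbind, chance_rows)
      cpath <- file.path(out_dir, "chance_estimates.csv")
      utils::write.csv(chance_tbl, cpath, row.names = FALSE)
      apath <- file.path(out_dir, "item_think_accuracy.csv")
      utils::write.csv(
        data.frame(time = item_think[[1]]$times,
                   t(vapply(item_think, `[[`, numeric(length(
                     item_think[[1]]$times)), "accuracy"))),
        apath, row.names = FALSE)
      report <<- c(report,
                   sprintf("Empirical chance, item decoding (Think): %.2f%%",
                           100 * mean(chance_tbl$item_think)),
                   sprintf("Empirical chance, T-vs-PB decoding: %.2f%%",
                           100 * mean(chance_tbl$condition_t_pb)))
      log_stage("decode", derive_seed(config$master_seed, 2),
                c(cpath, apath), t0)
    })
  }
  if ("stats" %in% config$stages) {
    run("stats", function(t0) {
      seedp <- derive_seed(config$master_seed, 3)
      ct_think <- perm_test_vs_chance(item_think, n_perm = config$n_perm,
                                      cluster_alpha = config$cluster_alpha,
                                      seed = seedp)
      ct_pb <- perm_test_vs_chance(item_pb, n_perm = config$n_perm,
                                   cluster_alpha = config$cluster_alpha,
                                   seed = seedp)
      jp <- file.path(out_dir, "clusters.json")
      jsonlite::write_json(
        list(item_think = ct_think$clusters, item_pb = ct_pb$clusters),
        jp, auto_unbox = TRUE, digits = NA, null = "null")
      nsig <- function(ct) if (is.null(ct$clusters)) 0 else
        sum(ct$clusters$significant)
      report <<- c(report,
                   sprintf("Item decoding vs chance (Think): %d significant cluster(s)",
                           nsig(ct_think)),
                   sprintf("Item decoding vs chance (Perceptual Baseline): %d significant cluster(s)",
                           nsig(ct_pb)))
      log_stage("stats", seedp, jp, t0)
    })
  }
  if ("report" %in% config$stages) {
    run("report", function(t0) {
      rpath <- file.path(out_dir, "report.txt")
      writeLines(c("tntmvpa pipeline report", strrep("-", 40), report),
                 rpath)
      mpath <- file.path(out_dir, "manifest.json")
      log_stage("report", NA, rpath, t0)
      jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                           null = "null")
    })
  }
  invisible(manifest)
}
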