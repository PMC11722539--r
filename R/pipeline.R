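# Config-driven reproducible runs: a JSON run configuration with strict key
# checking, resolved-default materialization, and an end-to-end
# simulate -> quantify -> test pipeline whose artifacts are deterministic in
# (config, seed).

default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "neurofret-run",
    log_level = "info",
    fret = list(
      genotypes = list(wildtype = 1.0, mutant = 0.1),
      n_neurons = 3L,
      scene = list(),             # scene_params() overrides
      peak_window = c(0, 3),
      baseline_window = c(20, 25),
      domain = c(0, 30),
      test_variant = "welch"
    ),
    morphology = list(
      enabled = TRUE,
      n_neurons = 10L,
      n_filopodia = 8L,
      length_range_um = c(0.4, 3),
      min_length_um = 1.0,
      region = NULL
    ),
    intensity = list(
      enabled = TRUE,
      group_means = list(mutant_15 = 10, wt_11 = 12, wt_13 = 60, wt_15 = 110),
      noise_sd = 5,
      n_per_group = 26L,
      neg_group = "mutant_15",
      pos_group = "wt_15",
      timepoint_order = c("11", "13", "15")
    )
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config key(s)%s: %s.",
                  if (nzchar(path)) paste0(" under ", path) else "",
                  paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k %in% c("fret", "morphology", "intensity")) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, if (nzchar(path)) "$", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and resolve a run configuration
#'
#' Reads a JSON run configuration, rejects unknown keys, and materializes
#' every default so the resolved copy written alongside results fully
#' reproduces the run.
#'
#' @param path JSON config path, or `NULL` for the defaults.
#' @param overrides Optional named list applied on top (same key checking).
#' @return The resolved configuration list (class `run_config`).
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg$seed <- check_count(cfg$seed, "seed")
  structure(cfg, class = "run_config")
}

run_log <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]]) {
    message(sprintf("[neurofret %s] %s", level, sprintf(...)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline from a configuration
#'
#' Simulates per-genotype stacks, quantifies every neuron, aggregates group
#' activation and fold changes against the first (reference) genotype, runs
#' the configured two-sample test between the reference and each other
#' genotype (plus a one-way ANOVA when there are three or more genotypes),
#' and optionally simulates/counts morphologies and normalizes an intensity
#' timecourse. Every artifact is written as CSV/JSON under
#' `cfg$output_dir` together with the resolved config and a manifest with
#' the seed and per-file md5 hashes; identical config + seed yields an
#' identical bundle.
#'
#' @param cfg A [read_run_config()] result.
#' @return Invisibly, a list of result tibbles plus the output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  # -- FRET stage -------------------------------------------------------------
  fr <- cfg$fret
  genos <- fr$genotypes
  run_log(cfg, "info", "quantifying %d genotypes x %d neurons",
          length(genos), fr$n_neurons)
  scores <- purrr::imap_dfr(genos, function(amp, label) {
    purrr::map_dfr(seq_len(fr$n_neurons), function(i) {
      sp <- do.call(scene_params, c(
        list(seed = cfg$seed + 1000L * match(label, names(genos)) + i,
             activation_amplitude = amp),
        fr$scene
      ))
      sim <- generate_ratiometric_stack(sp)
      sc <- quantify_stack(sim$stack,
                           peak_window = fr$peak_window,
                           baseline_window = fr$baseline_window,
                           domain = fr$domain,
                           neuron_id = sprintf("%s_%02d", label, i),
                           genotype = label)
      sc$true_auc <- sim$truth$true_auc
      sc
    })
  })
  groups <- aggregate_group(scores)
  ref <- names(genos)[1]
  groups$fold_change_vs_ref <- vapply(groups$label, function(l) {
    fold_change(groups[groups$label == l, ], groups[groups$label == ref, ])
  }, 1)
  tests <- purrr::map(setdiff(names(genos), ref), function(l) {
    t <- ttest_summary(
      summarize_group(scores$auc[scores$genotype == l], l),
      summarize_group(scores$auc[scores$genotype == ref], ref),
      variant = fr$test_variant
    )
    c(tidy(t), list(comparison = paste(l, "vs", ref)))
  })
  if (length(genos) >= 3L) {
    an <- oneway_anova(split(scores$auc, scores$genotype))
    tests <- c(tests, list(c(tidy(an), list(comparison = "all genotypes"))))
  }
  out$scores <- scores
  out$groups <- groups
  out$tests <- tests
  write.csv(scores, file.path(cfg$output_dir, "fret_scores.csv"),
            row.names = FALSE)
  write.csv(groups, file.path(cfg$output_dir, "fret_groups.csv"),
            row.names = FALSE)
  jsonlite::write_json(tests, file.path(cfg$output_dir, "fret_tests.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  # -- morphometry stage ------------------------------------------------------
  if (isTRUE(cfg$morphology$enabled)) {
    mo <- cfg$morphology
    counts <- purrr::map_dfr(seq_len(mo$n_neurons), function(i) {
      sim <- generate_morphology(seed = cfg$seed + 50000L + i,
                                 n_filopodia = mo$n_filopodia,
                                 length_range_um = mo$length_range_um)
      tibble(neuron_id = sprintf("morph_%02d", i),
             filopodia = count_filopodia(sim$morphology,
                                         min_length_um = mo$min_length_um,
                                         region = mo$region),
             planted = sim$truth$planted_filopodia_count)
    })
    out$filopodia <- counts
    write.csv(counts, file.path(cfg$output_dir, "filopodia_counts.csv"),
              row.names = FALSE)
  }

  # -- intensity stage --------------------------------------------------------
  if (isTRUE(cfg$intensity$enabled)) {
    it <- cfg$intensity
    tab <- generate_intensity_table(cfg$seed + 90000L,
                                    unlist(it$group_means),
                                    it$noise_sd, it$n_per_group)$table
    normed <- normalize_two_reference(tab, it$neg_group, it$pos_group)
    summ <- timecourse_summary(normed, timepoint_order = it$timepoint_order)
    out$intensity <- normed
    out$intensity_summary <- summ
    write.csv(normed, file.path(cfg$output_dir, "intensity_normalized.csv"),
              row.names = FALSE)
    write.csv(summ, file.path(cfg$output_dir, "intensity_summary.csv"),
              row.names = FALSE)
  }

  # -- resolved config + manifest --------------------------------------------
  cfg_path <- file.path(cfg$output_dir, "resolved_config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  artifacts <- setdiff(list.files(cfg$output_dir, full.names = TRUE),
                       file.path(cfg$output_dir, "manifest.json"))
  manifest <- list(
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = lapply(stats::setNames(artifacts, basename(artifacts)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out$paths <- c(artifacts, file.path(cfg$output_dir, "manifest.json"))
  invisible(out)
}
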