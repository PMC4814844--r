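#' Run a configured simulate/gate/quantify pipeline
#'
#' Executes a full analysis from a structured configuration (a YAML path
#' or the equivalent named list): optional simulation of wells, gating
#' (from configured thresholds or fitted from control wells), merging,
#' quantification, optional background subtraction, and optional LoD or
#' study-summary stages. All randomness is governed by the configured
#' seed, so the same configuration reproduces byte-identical result
#' tables; a run log captures the configuration, seed and package version.
#'
#' Recognized keys:
#' \describe{
#'   \item{`seed`}{integer master seed (default 1).}
#'   \item{`mode`}{`"quantify"` (default), `"lod"` or `"study"`.}
#'   \item{`droplet_volume_nl`}{droplet volume (default 0.85).}
#'   \item{`model`}{[amplitude_model()] arguments.}
#'   \item{`simulate`}{`n_droplets` plus a `wells` list; each well has
#'     `well_id`, `sample_id` and either rates (`lambda_wt`, `lambda_hdr`,
#'     `lambda_nhej`) or copies plus fractions (`copies_wt`,
#'     `hdr_fraction`, `nhej_fraction`).}
#'   \item{`wells`}{alternatively, a list of amplitude-CSV entries
#'     (`path`, optional `well_id`/`sample_id`).}
#'   \item{`gates`}{`fam_low`/`fam_high`/`hex_low` thresholds, or
#'     `gates_from` with `negative`/`positive` well ids (or CSV paths);
#'     configured thresholds always win over fitting.}
#'   \item{`quantify`}{`merge_by_sample` (default TRUE) and optional
#'     `control_sample` whose frequencies are subtracted as background.}
#'   \item{`lod`}{[run_dilution_series()] arguments (used when
#'     `mode: lod`).}
#'   \item{`study`}{`input` CSV for [summarize_study()] plus optional
#'     `rows`/`cols` for a [tier_matrix()] (used when `mode: study`).}
#' }
#'
#' @param config A YAML path or named list.
#' @param out_dir Output directory for tables and the run log; `NULL`
#'   writes nothing.
#' @return A list with the stage outputs (invisibly when `out_dir` is
#'   set): `wells`, `gates`, `gated`, `results`, `frequencies`, and
#'   mode-specific entries (`lod`, `study`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  seed <- config$seed %||% 1L
  mode <- config$mode %||% "quantify"
  vol <- config$droplet_volume_nl %||% 0.85
  model <- do.call(amplitude_model, config$model %||% list())
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_tbl <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  out <- list(config = config)

  if (mode == "lod") {
    lod_args <- config$lod %||% list()
    lod_args$model <- model
    lod_args$seed <- lod_args$seed %||% seed
    series <- do.call(run_dilution_series, lod_args)
    lod <- lod_by_ci_nonoverlap(series)
    out$lod <- lod
    out$series <- series
    save_tbl(series$points, "dilution_points.csv")
    if (!is.null(out_dir))
      jsonlite::write_json(
        list(spike_class = lod$spike_class,
             lod_fraction = lod$lod_fraction, at_lowest = lod$at_lowest,
             background_ci_high = lod$background_ci_high),
        file.path(out_dir, "lod.json"), auto_unbox = TRUE, digits = NA)
  } else if (mode == "study") {
    st <- config$study %||% stop("mode 'study' needs a study block")
    summary <- summarize_study(st$input)
    out$study <- summary
    save_tbl(summary, "study_summary.csv")
    if (!is.null(st$rows) && !is.null(st$cols)) {
      tm <- tier_matrix(summary, st$rows, st$cols)
      out$tier_matrix <- tm
      if (!is.null(out_dir))
        utils::write.csv(cbind(rownames(tm), tm),
                         file.path(out_dir, "tier_matrix.csv"),
                         row.names = FALSE)
    }
  } else {
    wells <- pipeline_wells(config, model, seed)
    out$wells <- wells
    gates <- pipeline_gates(config, wells, model)
    out$gates <- gates
    gated <- lapply(wells, assign_clusters, gates = gates)
    out$gated <- gated
    save_tbl(do.call(rbind, lapply(gated, function(g)
      cbind(data.frame(well_id = g$well_id, sample_id = g$sample_id),
            as.data.frame(g$counts)))), "cluster_counts.csv")

    qconf <- config$quantify %||% list()
    merge_by_sample <- qconf$merge_by_sample %||% TRUE
    samples <- vapply(gated, `[[`, "", "sample_id")
    groups <- if (merge_by_sample) split(gated, samples)
              else stats::setNames(lapply(gated, list),
                                   vapply(gated, `[[`, "", "well_id"))
    results <- lapply(groups, function(g)
      quantify_classes(merge_wells(lapply(g, `[[`, "counts")),
                       droplet_volume_nl = vol))
    out$results <- results

    freq <- do.call(rbind, lapply(names(results), function(nm)
      data.frame(sample = nm,
                 hdr = results[[nm]]$frequency[["hdr"]],
                 nhej = results[[nm]]$frequency[["nhej"]],
                 wt = results[[nm]]$frequency[["wt"]])))
    ctrl <- qconf$control_sample
    if (!is.null(ctrl)) {
      if (!ctrl %in% freq$sample)
        stop("control_sample '", ctrl, "' not among the samples")
      cf <- freq[freq$sample == ctrl, ]
      edited <- freq$sample != ctrl
      freq$hdr_corrected <- freq$hdr
      freq$nhej_corrected <- freq$nhej
      freq$hdr_corrected[edited] <-
        subtract_background(freq$hdr[edited], cf$hdr)
      freq$nhej_corrected[edited] <-
        subtract_background(freq$nhej[edited], cf$nhej)
    }
    out$frequencies <- freq
    if (!is.null(out_dir)) {
      write_results(results, file.path(out_dir, "results.csv"))
      write_results(results, file.path(out_dir, "results.json"))
      save_tbl(freq, "frequencies.csv")
    }
  }

  if (!is.null(out_dir)) {
    log_lines <- c(
      sprintf("dropedit %s pipeline run",
              as.character(utils::packageVersion("dropedit"))),
      sprintf("time: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
      sprintf("mode: %s", mode), sprintf("seed: %s", seed),
      "config:", yaml::as.yaml(config))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  if (is.null(out_dir)) out else invisible(out)
}

# Build the well list, either by simulation or from amplitude CSVs.
pipeline_wells <- function(config, model, seed) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    specs <- sim$wells %||% stop("simulate block needs a wells list")
    n_droplets <- sim$n_droplets %||% 15000
    wells <- with_rng_seed(seed, {
      seeds <- sample.int(.Machine$integer.max - 1L, length(specs))
      lapply(seq_along(specs), function(i) {
        ws <- specs[[i]]
        mix <- if (!is.null(ws$copies_wt))
          spike_in_mix(ws$copies_wt, ws$hdr_fraction %||% 0,
                       ws$nhej_fraction %||% 0, n_droplets)
        else
          template_mix(ws$lambda_wt %||% 0, ws$lambda_hdr %||% 0,
                       ws$lambda_nhej %||% 0)
        simulate_well(mix, n_droplets, model, seed = seeds[i],
                      well_id = ws$well_id %||% sprintf("W%02d", i),
                      sample_id = ws$sample_id %||% "sample1")
      })
    })
  } else if (!is.null(config$wells)) {
    wells <- lapply(config$wells, function(ws)
      read_amplitude_csv(ws$path, well_id = ws$well_id,
                         sample_id = ws$sample_id))
  } else {
    stop("config needs a 'simulate' block or a 'wells' list of CSVs")
  }
  stats::setNames(wells, vapply(wells, `[[`, "", "well_id"))
}

# Resolve gates: explicit thresholds beat fitting from control wells.
pipeline_gates <- function(config, wells, model) {
  g <- config$gates
  if (!is.null(g) && !is.null(g$fam_low))
    return(gate_config(g$fam_low, g$fam_high, g$hex_low))
  gf <- config$gates_from %||% g$fit_from %||% NULL
  if (is.null(gf))
    stop("supply gate thresholds ('gates') or control wells ",
         "('gates_from' with negative/positive)")
  resolve <- function(ref) {
    if (file.exists(ref)) return(read_amplitude_csv(ref))
    ids <- vapply(wells, `[[`, "", "sample_id")
    hit <- which(ids == ref | names(wells) == ref)
    if (!length(hit)) stop("control well '", ref, "' not found")
    wells[[hit[1]]]
  }
  fit_gates_from_controls(resolve(gf$negative), resolve(gf$positive))
}
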