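# YAML configuration and a small command-line front end.
#
# The config file holds one section per stage, e.g.
#
#   synthetic:
#     slow_wave_freq_hz: 0.15
#     tachy_power_fraction: {baseline: 0.05, feeding: 0.35}
#     saturation_rate_per_hour: 2
#   preprocess:
#     filter_order: 3
#
# Unknown keys raise an error so typos do not silently fall back to
# defaults.

apply_config_section <- function(constructor, section) {
  if (is.null(section)) return(constructor())
  known <- names(formals(constructor))
  bad <- setdiff(names(section), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(known, collapse = ", "), ")")
  }
  sec <- lapply(section, function(v) if (is.list(v)) unlist(v) else v)
  do.call(constructor, sec)
}

#' Read a pipeline configuration file
#'
#' @param path YAML file with optional sections `synthetic`, `artifacts`,
#'   `preprocess`, `bands`, `cnn`, `train`.
#' @return list of constructed parameter objects (defaults where a section
#'   is absent).
#' @export
read_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  list(signal = apply_config_section(signal_params, raw$synthetic),
       artifacts = apply_config_section(artifact_params, raw$artifacts),
       preprocess = apply_config_section(preprocess_config, raw$preprocess),
       bands = apply_config_section(band_spec, raw$bands),
       cnn = apply_config_section(cnn_config, raw$cnn),
       train = apply_config_section(train_config, raw$train))
}

parse_cli_args <- function(argv) {
  opts <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(argv) && !startsWith(argv[i + 1L], "--")) {
        opts[[key]] <- argv[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- TRUE
        i <- i + 1L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(opts = opts, positional = pos)
}

cli_opt <- function(parsed, name, default = NULL, required = FALSE) {
  v <- parsed$opts[[name]]
  if (is.null(v)) {
    if (required) stop("missing required option --", name)
    return(default)
  }
  v
}

#' Command-line entry point
#'
#' Subcommands: `simulate --out-dir DIR [--config FILE] [--seed N]
#' [--duration-s S]`, `preprocess --in FILE --out FILE [--qc-report FILE]
#' [--config FILE]`, `featurize --in DIR --out FILE [--config FILE]`,
#' `evaluate --features FILE --classifier NAME --out DIR [--repeats N]
#' [--seed N]`.  Installed as the `slowwave` executable script.
#'
#' @param argv character vector of arguments (default taken from the
#'   command line).
#' @return exit status, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0L) {
    cat("usage: slowwave <simulate|preprocess|featurize|evaluate> [options]\n")
    return(invisible(1L))
  }
  cmd <- argv[1]
  parsed <- parse_cli_args(argv[-1])
  cfg <- read_config(cli_opt(parsed, "config"))
  switch(cmd,
    simulate = {
      out_dir <- cli_opt(parsed, "out-dir", required = TRUE)
      seed <- as.integer(cli_opt(parsed, "seed", 1L))
      dur <- as.numeric(cli_opt(parsed, "duration-s", 3600))
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      recs <- simulate_study(signal = cfg$signal, artifacts = cfg$artifacts,
                             duration_s = dur, seed = seed)
      for (nm in names(recs)) {
        write_recording_csv(recs[[nm]], file.path(out_dir, paste0(nm, ".csv")))
      }
      cat("wrote", length(recs), "recordings to", out_dir, "\n")
    },
    preprocess = {
      infile <- cli_opt(parsed, "in", required = TRUE)
      outfile <- cli_opt(parsed, "out", required = TRUE)
      rec <- read_recording_csv(infile,
                                condition = cli_opt(parsed, "condition", "baseline"))
      clean <- run_preprocess(rec, cfg$preprocess)
      write_recording_csv(clean, outfile)
      qc_path <- cli_opt(parsed, "qc-report")
      if (!is.null(qc_path)) write_qc_report(list(clean), qc_path)
      cat("retained channels:", paste(clean$retained_channels, collapse = ", "), "\n")
    },
    featurize = {
      in_dir <- cli_opt(parsed, "in", required = TRUE)
      outfile <- cli_opt(parsed, "out", required = TRUE)
      files <- list.files(in_dir, pattern = "\\.csv$", full.names = TRUE)
      if (length(files) == 0L) stop("no recording CSVs in ", in_dir)
      windows <- do.call(c, lapply(files, function(f) {
        cond <- if (grepl("feeding", basename(f))) "feeding" else "baseline"
        rec <- read_recording_csv(f, subject_id = basename(f), condition = cond)
        rec$retained_channels <- rec$channels
        rec$qc <- NULL
        class(rec) <- "clean_recording"
        segment(rec)
      }))
      fm <- featurize_windows(windows, bands = cfg$bands)
      out <- data.frame(subject = fm$subjects, condition = ifelse(fm$labels == 1,
                        "feeding", "baseline"), window_index = fm$window_index)
      out <- cbind(out, as.data.frame(fm$values), label = fm$labels)
      data.table::fwrite(out, outfile)
      cat("wrote", nrow(out), "x", ncol(fm$values), "feature table to",
          outfile, "\n")
    },
    evaluate = {
      feat_file <- cli_opt(parsed, "features", required = TRUE)
      kind <- cli_opt(parsed, "classifier", "svm_rbf")
      out_dir <- cli_opt(parsed, "out", required = TRUE)
      n_rep <- as.integer(cli_opt(parsed, "repeats", 10L))
      seed <- as.integer(cli_opt(parsed, "seed", 1L))
      tab <- data.table::fread(feat_file)
      meta <- c("subject", "condition", "window_index", "label")
      fm <- structure(list(values = as.matrix(tab[, setdiff(names(tab), meta),
                                                  with = FALSE]),
                           feature_names = setdiff(names(tab), meta),
                           labels = tab$label, subjects = tab$subject,
                           window_index = tab$window_index),
                      class = "feature_matrix")
      rep <- repeated_cv(fm, pipeline_spec(kind), n_repeats = n_rep, seed = seed)
      render_reports(stats::setNames(list(rep), kind), out_dir)
      print(rep)
    },
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
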