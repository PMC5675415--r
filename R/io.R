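#' Write a session container to disk
#'
#' The container is a directory holding `metadata.txt` (key-value text),
#' `frames.csv` (the sparse frame stack: frame, row, col, load; a header
#' comment records the grid shape) and, when ground truth is present,
#' `truth.csv`. All files are plain comma-separated UTF-8 text.
#'
#' @param session A `dwb_session` (recording + truth) or a bare
#'   `session_recording`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  recording <- if (inherits(session, "dwb_session")) session$recording
               else session
  truth <- if (inherits(session, "dwb_session")) session$truth else NULL
  stopifnot(inherits(recording, "session_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  g <- recording$geometry
  meta <- c(
    recording$meta,
    list(n_rows = g$n_rows, n_cols = g$n_cols, arena_side = g$arena_side,
         wall_margin = g$wall_margin, frame_rate = g$frame_rate)
  )
  writeLines(
    paste0(names(meta), ": ",
           vapply(meta, function(v) format(v, digits = 15), character(1))),
    file.path(path, "metadata.txt")
  )
  con <- file(file.path(path, "frames.csv"), "w")
  writeLines(sprintf("# grid: %d x %d", g$n_rows, g$n_cols), con)
  utils::write.csv(as.data.frame(recording$cells), con, row.names = FALSE)
  close(con)
  if (!is.null(truth)) {
    utils::write.csv(as.data.frame(truth), file.path(path, "truth.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

parse_kv_file <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  stats::setNames(
    lapply(kv, function(p) {
      v <- p[2]
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    }),
    vapply(kv, `[[`, character(1), 1)
  )
}

#' Read a session container
#'
#' @param path Directory written by [write_session()].
#' @return A `dwb_session` (with `truth = NULL` when the container carries no
#'   ground truth). The grid shape declared in the frames file is validated
#'   against the metadata; mismatches and missing parts are rejected with a
#'   message naming the offending piece.
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "metadata.txt")
  frames_file <- file.path(path, "frames.csv")
  if (!file.exists(meta_file)) stop("missing metadata.txt in ", path)
  if (!file.exists(frames_file)) stop("missing frames.csv in ", path)
  meta <- parse_kv_file(meta_file)
  needed <- c("n_rows", "n_cols", "arena_side", "wall_margin", "frame_rate",
              "n_frames", "body_weight")
  absent <- setdiff(needed, names(meta))
  if (length(absent)) {
    stop("metadata.txt lacks field(s): ", paste(absent, collapse = ", "))
  }
  geometry <- plate_geometry(
    n_rows = meta$n_rows, n_cols = meta$n_cols, arena_side = meta$arena_side,
    wall_margin = meta$wall_margin, frame_rate = meta$frame_rate
  )
  header <- readLines(frames_file, n = 1L)
  gm <- regmatches(header,
                   regexec("# grid: ([0-9]+) x ([0-9]+)", header))[[1]]
  if (length(gm) == 3L) {
    gr <- as.integer(gm[2]); gc <- as.integer(gm[3])
    if (gr != geometry$n_rows || gc != geometry$n_cols) {
      stop("frames.csv declares a ", gr, " x ", gc,
           " grid but metadata.txt says ",
           geometry$n_rows, " x ", geometry$n_cols)
    }
  }
  cells <- data.table::fread(frames_file, skip = 1L)
  n_frames <- as.integer(meta$n_frames)
  if (nrow(cells) && max(cells$frame) > n_frames) {
    stop("frames.csv refers to frame ", max(cells$frame),
         " but metadata.txt declares only ", n_frames, " frames")
  }
  if (nrow(cells) &&
      (max(cells$row) > geometry$n_rows || max(cells$col) > geometry$n_cols)) {
    stop("frames.csv contains cells outside the declared grid")
  }
  data.table::setkeyv(cells, c("frame", "row", "col"))
  geom_keys <- c("n_rows", "n_cols", "arena_side", "wall_margin",
                 "frame_rate")
  recording <- structure(
    list(meta = meta[setdiff(names(meta), geom_keys)], geometry = geometry,
         n_frames = n_frames, cells = cells),
    class = "session_recording"
  )
  truth_file <- file.path(path, "truth.csv")
  truth <- NULL
  if (file.exists(truth_file)) {
    truth <- data.table::fread(truth_file)
    data.table::setattr(truth, "class", c("session_truth", class(truth)))
  }
  structure(list(recording = recording, truth = truth),
            class = "dwb_session")
}

#' Read a per-animal, per-day supplementary measure table
#'
#' Ingests a spreadsheet-like table of analysed measures (one row per animal
#' x day) and splits it into one [measure_matrix()] per metric. Delimited
#' text (`.csv`, `.tsv`, `.txt`) is read natively; `.xls`/`.xlsx` need the
#' `readxl` package.
#'
#' @param path File path.
#' @param mapping List naming the columns: `animal`, `day`, `metrics`
#'   (character vector of metric column names), and optionally `condition`.
#' @param sheet Sheet name/number for spreadsheet files.
#' @return Named list of `measure_matrix`, one per metric. Missing cells are
#'   `NA`.
#' @export
read_supplementary_table <- function(path, mapping, sheet = 1) {
  stopifnot(is.list(mapping), all(c("animal", "day", "metrics") %in%
                                    names(mapping)))
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("xls", "xlsx")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading ", ext, " files requires the readxl package")
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, sep = if (ext == "tsv") "\t" else ",",
                    check.names = FALSE)
  }
  wanted <- c(mapping$animal, mapping$day, mapping$metrics,
              mapping$condition)
  absent <- setdiff(wanted, names(tab))
  if (length(absent)) {
    stop("unmapped column(s): ", paste(absent, collapse = ", "),
         "; available columns: ", paste(names(tab), collapse = ", "))
  }
  days <- unique(as.character(tab[[mapping$day]]))
  animals <- unique(as.character(tab[[mapping$animal]]))
  out <- lapply(mapping$metrics, function(mc) {
    measure_matrix(
      data.frame(animal = tab[[mapping$animal]], day = tab[[mapping$day]],
                 value = as.numeric(tab[[mc]])),
      days = days, animals = animals,
      condition = if (!is.null(mapping$condition))
        paste(unique(tab[[mapping$condition]]), collapse = ",") else NULL
    )
  })
  stats::setNames(out, mapping$metrics)
}

# ---- study configuration -------------------------------------------------

#' Study configuration
#'
#' Bundles every tunable of the longitudinal workflow: which animals, days
#' and conditions to run, the simulator settings, and the detection,
#' assignment, metric and statistics parameters. Two day-schedule presets
#' ship, reflecting the two schedules quoted for the original protocol:
#' `"d17"` (D1, 2, 3, 7, 10, 17, 21) and `"d14"` (D1, 2, 3, 7, 10, 14, 21);
#' both include the D0 baseline.
#'
#' @param animals Character vector of animal ids.
#' @param days Day labels to run (subset of [dwb_day_labels()]), or a preset
#'   name `"d17"`/`"d14"`.
#' @param conditions Subset of `c("normal", "reactivated")`.
#' @param duration,body_weight,noise_sd,tail_belly_load_fraction Simulator
#'   settings (see [sim_config()]).
#' @param activation_threshold,min_cells Detection settings.
#' @param barycenter_method Metric aggregation convention, see [barycenter()].
#' @param alpha Significance level used by the statistics stage.
#' @param seed Single study seed; every session derives its own sub-seed
#'   from it.
#' @param out_dir Output directory for [run_study()] reports.
#' @return A list of class `study_config`.
#' @export
study_config <- function(animals = paste0("rat", sprintf("%02d", 1:9)),
                         days = "d17",
                         conditions = "normal",
                         duration = 300, body_weight = 300, noise_sd = 0.5,
                         tail_belly_load_fraction = 0.02,
                         activation_threshold = 1, min_cells = 1L,
                         barycenter_method = "contact_means",
                         alpha = 0.05, seed = 1L, out_dir = ".") {
  if (length(days) == 1L && days %in% c("d17", "d14")) {
    days <- if (days == "d17") {
      c("D0", "D1", "D2", "D3", "D7", "D10", "D17", "D21")
    } else {
      c("D0", "D1", "D2", "D3", "D7", "D10", "D14", "D21")
    }
  }
  stopifnot(all(days %in% dwb_day_labels()),
            all(conditions %in% c("normal", "reactivated")))
  structure(
    list(animals = animals, days = days, conditions = conditions,
         duration = duration, body_weight = body_weight,
         noise_sd = noise_sd,
         tail_belly_load_fraction = tail_belly_load_fraction,
         activation_threshold = activation_threshold,
         min_cells = as.integer(min_cells),
         barycenter_method = barycenter_method, alpha = alpha,
         seed = as.integer(seed), out_dir = out_dir),
    class = "study_config"
  )
}

#' Write / read a study configuration as key-value text
#'
#' The on-disk form is one `key: value` line per field (vectors
#' comma-separated); it round-trips losslessly and unknown keys are rejected
#' on read.
#'
#' @param config A [study_config()].
#' @param file Path of the text document.
#' @return `write_study_config` returns `file` invisibly;
#'   `read_study_config` returns the `study_config`.
#' @export
write_study_config <- function(config, file) {
  stopifnot(inherits(config, "study_config"))
  vals <- vapply(config, function(v) paste(format(v, digits = 15),
                                           collapse = ","), character(1))
  writeLines(paste0(names(config), ": ", vals), file)
  invisible(file)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(file) {
  kv <- parse_kv_file(file)
  proto <- study_config()
  unknown <- setdiff(names(kv), names(proto))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  args <- lapply(names(kv), function(k) {
    v <- kv[[k]]
    if (is.character(v) && grepl(",", v, fixed = TRUE)) {
      v <- strsplit(v, ",", fixed = TRUE)[[1]]
    }
    if (is.character(proto[[k]])) as.character(v)
    else if (is.integer(proto[[k]])) as.integer(v)
    else as.numeric(v)
  })
  names(args) <- names(kv)
  do.call(study_config, args)
}

# deterministic per-session sub-seed below 2^31
session_seed <- function(study_seed, index) {
  as.integer((as.numeric(study_seed) * 7919 + index * 104729) %% 2147483647L)
}

#' Run a full longitudinal study on synthetic animals
#'
#' Simulates one session per animal x day x condition (each with its own
#' sub-seed derived from the study seed), runs detection, assignment and the
#' metrics stage on each, and computes the per-metric statistics
#' (group summaries and, when at least two complete animals exist,
#' repeated-measures ANOVA with Tukey-Kramer post-hocs). Reports are written
#' to `config$out_dir` as comma-separated text whose header comment carries
#' the MD5 hash of the configuration; re-running with the same config is
#' byte-identical.
#'
#' @param config A [study_config()].
#' @param write_reports Write `metrics.csv` and `stats_<metric>.csv` under
#'   `config$out_dir` (default `TRUE`).
#' @param stat_metrics Metric columns to run the statistics layer on.
#' @return A list of class `study_report`: `metrics` (data.frame, one row per
#'   session), `stats` (per-metric list with `summary`, `anova`, `tukey`),
#'   `config_hash`.
#' @export
run_study <- function(config, write_reports = TRUE,
                      stat_metrics = c("pct_time_on_4", "pct_time_on_2",
                                       "PRP", "PFP")) {
  stopifnot(inherits(config, "study_config"))
  if (length(config$animals) == 0L) stop("empty animal list")
  grid <- expand.grid(animal = config$animals, day = config$days,
                      condition = config$conditions,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- tryCatch({
      phen <- make_phenotype_profile(g$day, g$condition)
      cfg <- sim_config(
        duration = config$duration, body_weight = config$body_weight,
        noise_sd = config$noise_sd,
        tail_belly_load_fraction = config$tail_belly_load_fraction,
        animal_id = g$animal, seed = session_seed(config$seed, i)
      )
      sess <- simulate_session(phen, cfg)
      analyze_session(
        sess, activation_threshold = config$activation_threshold,
        min_cells = config$min_cells,
        barycenter_method = config$barycenter_method
      )$metrics
    }, error = function(e) {
      stop("study failed at session ", g$animal, "/", g$day, "/",
           g$condition, ": ", conditionMessage(e))
    })
    res$score <- score_symptoms(
      make_phenotype_profile(g$day, g$condition)$symptom_set
    )
    rows[[i]] <- res
  }
  metrics <- do.call(rbind, rows)
  # hash the scientific configuration only: where the reports land must not
  # change what they say
  cfg_hashed <- config
  cfg_hashed$out_dir <- "."
  cfg_file <- tempfile(fileext = ".cfg")
  write_study_config(cfg_hashed, cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  stats_out <- list()
  for (metric in stat_metrics) {
    per_cond <- list()
    for (cond in config$conditions) {
      sub <- metrics[metrics$condition == cond, ]
      mm <- measure_matrix(
        data.frame(animal = sub$animal_id, day = sub$day,
                   value = sub[[metric]]),
        days = config$days, animals = config$animals, condition = cond
      )
      res <- list(summary = group_summary(mm))
      n_complete <- sum(stats::complete.cases(mm))
      if (n_complete >= 2L && ncol(mm) >= 2L) {
        res$anova <- rm_anova(mm, alpha = config$alpha)
        res$tukey <- tukey_kramer(mm, alpha = config$alpha)
      }
      per_cond[[cond]] <- res
    }
    stats_out[[metric]] <- per_cond
  }

  if (isTRUE(write_reports)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_csv(metrics, file.path(config$out_dir, "metrics.csv"),
                     config_hash)
    for (metric in names(stats_out)) {
      for (cond in names(stats_out[[metric]])) {
        write_report_csv(
          stats_out[[metric]][[cond]]$summary,
          file.path(config$out_dir,
                    sprintf("stats_%s_%s.csv", metric, cond)),
          config_hash
        )
      }
    }
  }
  structure(list(metrics = metrics, stats = stats_out,
                 config_hash = config_hash, config = config),
            class = "study_report")
}

write_report_csv <- function(df, file, config_hash) {
  con <- file(file, "w")
  writeLines(sprintf("# config: %s", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(file)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "<study_report> %d sessions (%d animals x %d days x %d conditions), config %s\n",
    nrow(x$metrics), length(x$config$animals), length(x$config$days),
    length(x$config$conditions), substr(x$config_hash, 1, 8)
  ))
  invisible(x)
}
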