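# Delimited-text interchange formats. Datetimes are ISO 8601 local clock
# times (the nighttime window 2200-0500 is a clock-time concept, so no UTC
# conversion is ever applied); internally all times are minutes from study
# start, defined as local midnight of the first study day.

DEFAULT_ORIGIN <- "2005-10-24 00:00:00"

parse_clock <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
               "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  out <- as.POSIXct(rep(NA_character_, length(x)), tz = "UTC")
  for (fmt in formats) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

minutes_from_origin <- function(datetime, origin) {
  as.numeric(difftime(parse_clock(datetime), parse_clock(origin),
                      units = "mins"))
}

minutes_to_datetime <- function(time_min, origin) {
  format(parse_clock(origin) + time_min * 60, "%Y-%m-%dT%H:%M:%S")
}

abort_rows <- function(what, rows) {
  if (length(rows)) {
    rlang::abort(paste0(what, " in row(s): ",
                        paste(sort(unique(rows)), collapse = ", ")))
  }
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    rlang::abort(paste0(path, " is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
}

read_delim_chr <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, na = character())
}

#' Read void records
#'
#' Reads a tab-delimited void file with columns `subject_id`, `datetime`
#' (ISO 8601 local time), `volume_L`, and `conc_MEHP`, `conc_MEHHP`,
#' `conc_MEOHP`, `conc_MECPP`. Blank concentration cells mean "not measured"
#' (`NA`); the token `<LOD` marks a censored measurement and sets the
#' corresponding `below_lod_*` flag. Records are returned sorted by subject
#' and time, with `time_min` computed from `origin` (default: local midnight
#' of the earliest date in the file). All malformed rows are reported
#' together, with line numbers.
#'
#' @param path File path.
#' @param origin Study start as `"YYYY-MM-DD HH:MM:SS"`; `NULL` = midnight of
#'   the earliest date present.
#' @return A tibble: `subject_id`, `time_min`, `volume_L`, `conc_*`,
#'   `below_lod_*`, with attribute `origin`.
#' @export
read_voids <- function(path, origin = NULL) {
  conc_cols <- paste0("conc_", METABOLITES)
  df <- read_delim_chr(path)
  require_columns(df, c("subject_id", "datetime", "volume_L", conc_cols), path)

  if (nrow(df) == 0) {
    out <- tibble::tibble(subject_id = character(), time_min = numeric(),
                          volume_L = numeric())
    for (col in conc_cols) {
      out[[col]] <- numeric()
      out[[paste0("below_lod_", sub("conc_", "", col))]] <- logical()
    }
    attr(out, "origin") <- origin
    return(out)
  }
  dt <- suppressWarnings(parse_clock(df$datetime))
  abort_rows("unparseable datetime", which(is.na(dt) & nzchar(df$datetime)))
  abort_rows("missing datetime", which(!nzchar(df$datetime)))
  vol <- suppressWarnings(as.numeric(df$volume_L))
  abort_rows("non-numeric volume_L", which(is.na(vol)))
  abort_rows("non-positive volume_L", which(vol <= 0))

  if (is.null(origin)) {
    origin <- format(min(dt), "%Y-%m-%d 00:00:00")
  }
  out <- tibble::tibble(
    subject_id = df$subject_id,
    time_min = minutes_from_origin(df$datetime, origin),
    volume_L = vol
  )
  for (col in conc_cols) {
    raw <- df[[col]]
    below <- !is.na(raw) & trimws(raw) == "<LOD"
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!below & nzchar(trimws(raw)) & is.na(val))
    abort_rows(paste0("non-numeric ", col), bad)
    val[below] <- NA_real_
    val[!nzchar(trimws(raw))] <- NA_real_
    out[[col]] <- val
    out[[paste0("below_lod_", sub("conc_", "", col))]] <- below
  }
  out <- dplyr::arrange(out, .data$subject_id, .data$time_min)
  attr(out, "origin") <- origin
  out
}

#' Write void records
#'
#' Inverse of [read_voids()]: censored cells are written as `<LOD`, missing
#' cells as blanks. Extra columns (e.g. `true_conc_*`) are dropped.
#'
#' @param voids Tibble with `subject_id`, `time_min`, `volume_L` and
#'   concentration columns.
#' @param path Output path (tab-delimited).
#' @param origin Study-start datetime used to render `time_min`.
#' @return `path`, invisibly.
#' @export
write_voids <- function(voids, path, origin = DEFAULT_ORIGIN) {
  out <- tibble::tibble(
    subject_id = if ("subject_id" %in% names(voids)) voids$subject_id else "s1",
    datetime = minutes_to_datetime(voids$time_min, origin),
    volume_L = voids$volume_L
  )
  for (m in METABOLITES) {
    conc <- voids[[paste0("conc_", m)]]
    flag_col <- paste0("below_lod_", m)
    below <- if (flag_col %in% names(voids)) voids[[flag_col]] else
      rep(FALSE, nrow(voids))
    # %.17g guarantees exact numeric round-trips through the text format
    cell <- ifelse(is.na(conc), "", sprintf("%.17g", conc))
    cell[below] <- "<LOD"
    out[[paste0("conc_", m)]] <- cell
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read dose events
#'
#' Tab-delimited file with columns `subject_id`, `datetime`, `dose_ug_kg`,
#' `spread_min`.
#'
#' @inheritParams read_voids
#' @return A tibble: `subject_id`, `time_min`, `dose_ug_kg`, `spread_min`.
#' @export
read_dose_events <- function(path, origin = DEFAULT_ORIGIN) {
  df <- read_delim_chr(path)
  require_columns(df, c("subject_id", "datetime", "dose_ug_kg", "spread_min"),
                  path)
  dt <- suppressWarnings(parse_clock(df$datetime))
  abort_rows("unparseable datetime", which(is.na(dt)))
  dose <- suppressWarnings(as.numeric(df$dose_ug_kg))
  abort_rows("non-numeric dose_ug_kg", which(is.na(dose)))
  abort_rows("non-positive dose_ug_kg", which(dose <= 0))
  spread <- suppressWarnings(as.numeric(df$spread_min))
  abort_rows("non-numeric spread_min", which(is.na(spread)))
  tibble::tibble(
    subject_id = df$subject_id,
    time_min = minutes_from_origin(df$datetime, origin),
    dose_ug_kg = dose,
    spread_min = spread
  )
}

#' Write dose events
#' @param events Tibble with `subject_id`, `time_min`, `dose_ug_kg`,
#'   `spread_min`.
#' @inheritParams write_voids
#' @return `path`, invisibly.
#' @export
write_dose_events <- function(events, path, origin = DEFAULT_ORIGIN) {
  out <- tibble::tibble(
    subject_id = if ("subject_id" %in% names(events)) events$subject_id else "s1",
    datetime = minutes_to_datetime(events$time_min, origin),
    dose_ug_kg = events$dose_ug_kg,
    spread_min = if ("spread_min" %in% names(events)) events$spread_min else 0
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read diary entries
#'
#' Tab-delimited file with columns `subject_id`, `datetime`, `category`
#' (`food`, `beverage`, `driving`, `other`), `label`.
#'
#' @inheritParams read_voids
#' @return A tibble: `subject_id`, `time_min`, `category`, `label`.
#' @export
read_diary <- function(path, origin = DEFAULT_ORIGIN) {
  df <- read_delim_chr(path)
  require_columns(df, c("subject_id", "datetime", "category", "label"), path)
  dt <- suppressWarnings(parse_clock(df$datetime))
  abort_rows("unparseable datetime", which(is.na(dt)))
  known <- c("food", "beverage", "driving", "other")
  abort_rows("unknown diary category", which(!df$category %in% known))
  tibble::tibble(
    subject_id = df$subject_id,
    time_min = minutes_from_origin(df$datetime, origin),
    category = df$category,
    label = df$label
  )
}

#' Write diary entries
#' @param diary Tibble with `subject_id`, `time_min`, `category`, `label`.
#' @inheritParams write_voids
#' @return `path`, invisibly.
#' @export
write_diary <- function(diary, path, origin = DEFAULT_ORIGIN) {
  out <- tibble::tibble(
    subject_id = if ("subject_id" %in% names(diary)) diary$subject_id else "s1",
    datetime = minutes_to_datetime(diary$time_min, origin),
    category = diary$category,
    label = diary$label
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' The full configuration tree: per-metabolite kinetic constants, the grid
#' step, and the reconstruction (fit) settings. [read_config()] validates a
#' YAML file against this structure (unknown keys are rejected) and fills in
#' the defaults.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  specs <- metabolite_specs()
  mets <- purrr::map(seq_len(nrow(specs)), function(j) {
    list(f = specs$f[j], half_life_hr = log(2) / specs$k_per_hr[j],
         k_a_per_hr = specs$k_a_per_hr[j], g = specs$g[j],
         tau_hr = specs$tau_hr[j])
  })
  names(mets) <- specs$metabolite
  fc <- fit_config()
  list(
    metabolites = mets,
    grid_min = 15,
    seed = 1,
    fit = list(
      weights = as.list(fc$weights),
      search_res_min = fc$search_res_min,
      dose_bounds = fc$dose_bounds,
      n_dose_grid = fc$n_dose_grid,
      prune_threshold = fc$prune_threshold,
      lookahead_hr = fc$lookahead_hr,
      rise_fold = fc$rise_fold,
      rise_increment = fc$rise_increment,
      window_back_min = fc$window_back_min,
      rise_min_metabolites = fc$rise_min_metabolites,
      baseline_floor = fc$baseline_floor,
      start_window = fc$start_window,
      chain_tail_min = fc$chain_tail_min,
      n_refine = fc$n_refine,
      max_events = fc$max_events,
      lod = as.list(fc$lod)
    )
  )
}

check_unknown_keys <- function(user, ref, path = "") {
  if (!is.list(user) || !is.list(ref)) return(invisible(NULL))
  extra <- setdiff(names(user), names(ref))
  if (length(extra)) {
    rlang::abort(paste0("unknown config key(s): ",
                        paste0(path, extra, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      check_unknown_keys(user[[k]], ref[[k]], paste0(path, k, "."))
    }
  }
  invisible(NULL)
}

merge_config <- function(user, ref) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      ref[[k]] <- merge_config(user[[k]], ref[[k]])
    } else {
      ref[[k]] <- user[[k]]
    }
  }
  ref
}

#' Read and validate a YAML configuration file
#'
#' Fails fast on unknown keys (naming them), merges the user's values over
#' [default_config()], and builds the derived objects.
#'
#' @param path YAML file path.
#' @return The merged configuration list, with derived elements `$specs`
#'   (a [metabolite_specs()] tibble) and `$fit_config` (a [fit_config()]).
#' @export
read_config <- function(path) {
  if (!is.character(path) || !nzchar(path) || !file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path))
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  ref <- default_config()
  check_unknown_keys(user, ref)
  cfg <- merge_config(user, ref)
  m <- cfg$metabolites
  cfg$specs <- metabolite_specs(
    f = vapply(m, function(x) x$f, numeric(1)),
    half_life_hr = vapply(m, function(x) x$half_life_hr, numeric(1)),
    k_a_per_hr = vapply(m, function(x) x$k_a_per_hr, numeric(1)),
    g = vapply(m, function(x) x$g, numeric(1)),
    tau_hr = vapply(m, function(x) x$tau_hr, numeric(1))
  )
  f <- cfg$fit
  cfg$fit_config <- fit_config(
    weights = unlist(f$weights),
    search_res_min = f$search_res_min,
    dose_bounds = as.numeric(f$dose_bounds),
    n_dose_grid = f$n_dose_grid,
    prune_threshold = f$prune_threshold,
    lookahead_hr = f$lookahead_hr,
    rise_fold = f$rise_fold,
    rise_increment = f$rise_increment,
    window_back_min = f$window_back_min,
    rise_min_metabolites = f$rise_min_metabolites,
    baseline_floor = f$baseline_floor,
    start_window = f$start_window,
    chain_tail_min = f$chain_tail_min,
    n_refine = f$n_refine,
    max_events = f$max_events,
    lod = unlist(f$lod),
    grid_min = cfg$grid_min
  )
  cfg
}

#' Write a configuration file
#' @param config A configuration list (derived elements are dropped).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config$specs <- NULL
  config$fit_config <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a synthetic cohort to a fixture directory
#'
#' Emits `voids.tsv`, `diary.tsv`, `events.tsv` in the package's interchange
#' formats plus `manifest.json` recording the seed, a hash of the generator
#' configuration, and row counts.
#'
#' @param cohort A `dehp_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param origin Study-start datetime for rendering times.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, origin = DEFAULT_ORIGIN) {
  stopifnot(inherits(cohort, "dehp_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keep <- c("subject_id", "time_min", "volume_L",
            paste0("conc_", METABOLITES), paste0("below_lod_", METABOLITES))
  write_voids(cohort$voids[keep], file.path(dir, "voids.tsv"), origin)
  write_diary(cohort$diary, file.path(dir, "diary.tsv"), origin)
  write_dose_events(cohort$events, file.path(dir, "events.tsv"), origin)
  manifest <- list(
    seed = cohort$seed,
    config_hash = rlang::hash(cohort$config),
    origin = origin,
    n_voids = nrow(cohort$voids),
    n_events = nrow(cohort$events),
    n_subjects = nrow(cohort$subjects)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
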