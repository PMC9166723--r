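#' @title Cohort data model and table input/output
#'
#' @description
#' The package works from two image-derived table kinds, both with units
#' fixed at micrometres and minutes:
#'
#' * **tracks** — one row per cell per frame:
#'   `droplet_id, cell_id, t_min, x_um, y_um[, z_um][, on_spheroid]`.
#'   Tracks without a `z_um` column are flagged as 2D projections and are
#'   refused by 3D-only statistics.
#' * **occupancy** — one row per droplet per frame:
#'   `droplet_id, t_min, n_on, N, frag_flag`, where `n_on` is the number of
#'   CTLs detected on the spheroid and `frag_flag` is 1 on the frame of the
#'   first fragmentation event.  A droplet with no flagged frame is censored
#'   at the end of its recording.
#'
#' @name cohort-io
NULL

#' Construct a validated track table
#'
#' @param df data.frame with columns `droplet_id, cell_id, t_min, x_um,
#'   y_um` and optionally `z_um`, `on_spheroid`.
#' @param delta_t frame interval in minutes; inferred from the data when
#'   `NULL`.
#' @return a `ctl_tracks` data.frame carrying `projected` and `delta_t`
#'   attributes.
#' @export
ctl_tracks <- function(df, delta_t = NULL) {
  req <- c("droplet_id", "cell_id", "t_min", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("track table missing required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  key <- interaction(df$droplet_id, df$cell_id, drop = TRUE)
  steps <- unlist(tapply(df$t_min, key, diff, simplify = FALSE), use.names = FALSE)
  if (length(steps)) {
    if (any(steps <= 0)) stop("non-monotone time within a track")
    dt <- steps[1]
    if (any(abs(steps - dt) > 1e-9))
      stop("mixed frame intervals within the track table")
    if (is.null(delta_t)) delta_t <- dt
    else if (abs(delta_t - dt) > 1e-9)
      stop("stated delta_t disagrees with observed frame spacing")
  }
  structure(df,
            class = c("ctl_tracks", "data.frame"),
            projected = !("z_um" %in% names(df)),
            delta_t = delta_t)
}

#' Is a track table a 2D projection?
#' @param tracks a `ctl_tracks` object.
#' @return logical.
#' @export
is_projected <- function(tracks) isTRUE(attr(tracks, "projected"))

#' @export
print.ctl_tracks <- function(x, ...) {
  cat(sprintf("<ctl_tracks> %d points, %d cells, %d droplets, %s, delta_t = %s min\n",
              nrow(x),
              length(unique(interaction(x$droplet_id, x$cell_id, drop = TRUE))),
              length(unique(x$droplet_id)),
              if (is_projected(x)) "2D-projected" else "3D",
              format(attr(x, "delta_t"))))
  invisible(x)
}

#' Construct one spheroid occupancy series
#'
#' @param droplet_id identifier.
#' @param n_t integer vector of per-frame counts of CTLs on the spheroid
#'   (frame times `0, delta_t, 2*delta_t, ...`); `NA` marks frames with
#'   ambiguous detection.
#' @param delta_t frame interval (min).
#' @param N total number of CTLs in the droplet.
#' @param t_frag time of the first fragmentation event (min), or `NA` if
#'   the droplet was censored at the end of the recording.
#' @param duration observation duration (min); defaults to the time of the
#'   last frame.
#' @param condition label, e.g. `"ova"` or `"wt"`.
#' @param spheroid_area optional projected area (um^2).
#' @return an `occupancy_series` object.
#' @export
occupancy_series <- function(droplet_id, n_t, delta_t, N, t_frag = NA_real_,
                             duration = (length(n_t) - 1) * delta_t,
                             condition = "ova", spheroid_area = NA_real_) {
  if (delta_t <= 0) stop("'delta_t' must be positive")
  if (N < 0) stop("'N' must be non-negative")
  n_t <- as.integer(n_t)
  ok <- !is.na(n_t)
  if (any(n_t[ok] < 0 | n_t[ok] > N))
    stop("occupancy outside [0, N] for droplet ", droplet_id)
  if (!is.na(t_frag) && (t_frag < 0 || t_frag > duration))
    stop("'t_frag' outside [0, duration] for droplet ", droplet_id)
  structure(list(droplet_id = droplet_id, n_t = n_t, delta_t = delta_t,
                 N = as.integer(N), t_frag = t_frag, duration = duration,
                 condition = condition, spheroid_area = spheroid_area),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat(sprintf("<occupancy_series> droplet %s: %d frames, N = %d, %s\n",
              format(x$droplet_id), length(x$n_t), x$N,
              if (is.na(x$t_frag)) sprintf("censored at %g min", x$duration)
              else sprintf("fragmented at %g min", x$t_frag)))
  invisible(x)
}

#' Bundle occupancy series (and optionally tracks) into a cohort
#'
#' @param occupancy list of [occupancy_series()] objects.
#' @param tracks optional `ctl_tracks` table.
#' @param truth optional [sim_config()] that generated the cohort.
#' @return a `ctl_cohort` object.
#' @export
ctl_cohort <- function(occupancy, tracks = NULL, truth = NULL) {
  stopifnot(is.list(occupancy))
  for (s in occupancy)
    if (!inherits(s, "occupancy_series"))
      stop("'occupancy' must be a list of occupancy_series objects")
  dts <- vapply(occupancy, function(s) s$delta_t, numeric(1))
  if (length(dts) && diff(range(dts)) > 1e-9)
    stop("mixed frame intervals within one cohort")
  structure(list(occupancy = occupancy, tracks = tracks, truth = truth),
            class = "ctl_cohort")
}

#' @export
print.ctl_cohort <- function(x, ...) {
  nf <- sum(vapply(x$occupancy, function(s) !is.na(s$t_frag), logical(1)))
  cat(sprintf("<ctl_cohort> %d droplets (%d fragmented), %s tracks%s\n",
              length(x$occupancy), nf,
              if (is.null(x$tracks)) "no" else format(nrow(x$tracks)),
              if (is.null(x$truth)) "" else ", generative truth attached"))
  invisible(x)
}

#' @export
length.ctl_cohort <- function(x) length(x$occupancy)

#' Validate occupancy series against the single-event observation model
#'
#' The rate estimators assume that at most one attachment or detachment
#' happens between consecutive frames.  This audit counts the frames that
#' violate `|n_{t+1} - n_t| <= 1` and the fraction of missing frames per
#' droplet, and marks droplets for exclusion when missingness exceeds
#' `max_missing`.
#'
#' @param cohort a `ctl_cohort` or list of `occupancy_series`.
#' @param max_missing maximum tolerated fraction of missing frames
#'   (default 0.05).
#' @return data.frame with one row per droplet: counts of multi-event
#'   frame pairs, missing frames, and an `excluded` flag.
#' @export
validate_cohort <- function(cohort, max_missing = 0.05) {
  series <- if (inherits(cohort, "ctl_cohort")) cohort$occupancy else cohort
  rows <- lapply(series, function(s) {
    d <- diff(s$n_t)
    data.frame(droplet_id = s$droplet_id,
               frames = length(s$n_t),
               multi_event = sum(abs(d) > 1, na.rm = TRUE),
               missing = sum(is.na(s$n_t)),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$excluded <- rep$missing / rep$frames > max_missing
  rep
}

# ---- CSV round trips ------------------------------------------------------

#' Write / read track tables
#' @param tracks a `ctl_tracks` object.
#' @param path CSV file path.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  ctl_tracks(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read occupancy tables
#'
#' Censoring is encoded structurally: a censored droplet simply has no
#' frame with `frag_flag = 1`, and its duration is the time of its last
#' frame.  No sentinel values are written.
#'
#' @param cohort a `ctl_cohort` or list of `occupancy_series`.
#' @param path CSV file path.
#' @export
write_occupancy <- function(cohort, path) {
  series <- if (inherits(cohort, "ctl_cohort")) cohort$occupancy else cohort
  rows <- lapply(series, function(s) {
    t <- seq_along(s$n_t) - 1
    data.frame(droplet_id = s$droplet_id,
               t_min = t * s$delta_t,
               n_on = s$n_t,
               N = s$N,
               frag_flag = as.integer(!is.na(s$t_frag) &
                                        abs(t * s$delta_t - s$t_frag) < 1e-9),
               condition = s$condition,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy
#' @export
read_occupancy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("droplet_id", "t_min", "n_on", "N", "frag_flag")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("occupancy table missing required column(s): ",
         paste(miss, collapse = ", "))
  series <- lapply(split(df, df$droplet_id), function(d) {
    d <- d[order(d$t_min), ]
    steps <- diff(d$t_min)
    if (any(steps <= 0)) stop("non-monotone time for droplet ", d$droplet_id[1])
    dt <- steps[1]
    if (any(abs(steps - dt) > 1e-9))
      stop("mixed frame intervals for droplet ", d$droplet_id[1])
    fr <- which(d$frag_flag == 1)
    occupancy_series(droplet_id = d$droplet_id[1], n_t = d$n_on,
                     delta_t = dt, N = d$N[1],
                     t_frag = if (length(fr)) d$t_min[min(fr)] else NA_real_,
                     duration = max(d$t_min),
                     condition = if ("condition" %in% names(d)) d$condition[1] else "ova")
  })
  ctl_cohort(unname(series))
}

#' Write / read per-droplet feature tables
#' @param features a `droplet_features` data.frame (see [extract_features()]).
#' @param path CSV file path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("droplet_id", "N", "n_max", "success")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("feature table missing required column(s): ", paste(miss, collapse = ", "))
  df$success <- as.logical(df$success)
  structure(df, class = c("droplet_features", "data.frame"))
}

# ---- results serialization ------------------------------------------------

#' Write a results object as deterministic JSON
#'
#' Every results file embeds the seed and an md5 hash of the configuration
#' that produced it, so that any downstream artifact can be traced to its
#' generative settings.  Serialization is deterministic (sorted keys,
#' unrounded numbers): two runs with the same seed and configuration write
#' byte-identical files.
#'
#' @param results a named list of results.
#' @param path output file.
#' @param seed integer seed that produced `results` (required).
#' @param config optional configuration object to hash into the file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, seed, config = NULL) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("results cannot be written without the seed that produced them")
  if (!is.list(results) || is.null(names(results)) || any(names(results) == ""))
    stop("'results' must be a fully named list")
  sort_rec <- function(x) {
    if (is.list(x) && !is.null(names(x)) && all(names(x) != ""))
      lapply(x[order(names(x))], sort_rec)
    else x
  }
  payload <- list(seed = as.integer(seed),
                  config_hash = config_hash(config),
                  results = sort_rec(results))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(config), collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}
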