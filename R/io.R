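# File formats. Time series travel as tab-separated text with a fixed
# header, '.' decimal and UTF-8; events and results as JSON; simulation
# configuration as YAML. Units are fixed (pN, nm, s), never inferred.

.traj_columns <- c("time_s", "magnet_pos_um", "force_pN", "extension_nm",
                   "cycle", "truth_state")

#' Write a trajectory to TSV
#'
#' Tab-separated, header row
#' \code{time_s  magnet_pos_um  force_pN  extension_nm  cycle  truth_state},
#' '.' decimal, UTF-8. Optionally writes a sidecar metadata JSON
#' (\code{<path>.meta.json}) with the condition, seed and format version.
#'
#' @param trajectory an \code{sm_trajectory} (or compatible data frame).
#' @param path output file path.
#' @param sidecar write the metadata sidecar (default TRUE when the
#'   trajectory carries metadata attributes).
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(trajectory, path,
                             sidecar = !is.null(attr(trajectory, "condition"))) {
  df <- as.data.frame(trajectory)
  for (col in setdiff(.traj_columns, names(df))) {
    df[[col]] <- if (col == "truth_state") NA_character_ else NA_real_
  }
  df <- df[.traj_columns]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (sidecar) {
    meta <- list(
      format_version = "1.0",
      condition = attr(trajectory, "condition"),
      seed = attr(trajectory, "seed")
    )
    jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                         paste0(path, ".meta.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a trajectory from TSV
#'
#' Strict validation: the columns \code{time_s}, \code{force_pN} and
#' \code{extension_nm} must be present; numeric fields must be finite; time
#' must be strictly increasing within each cycle; force must be
#' non-negative. The first offending row is named in the error.
#'
#' @param path TSV file written by [write_trajectory()] or equivalent.
#' @return an \code{sm_trajectory}; sidecar metadata, if present, is attached
#'   as attributes.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("time_s", "force_pN", "extension_nm")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("trajectory file missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$cycle)) df$cycle <- 1L
  for (col in c("time_s", "force_pN", "extension_nm")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-finite value in column '%s' at row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  bad <- which(df$force_pN < 0)
  if (length(bad)) {
    stop(sprintf("negative force at row %d", bad[1]), call. = FALSE)
  }
  for (cyc in unique(df$cycle)) {
    idx <- which(df$cycle == cyc)
    nonmono <- which(diff(df$time_s[idx]) <= 0)
    if (length(nonmono)) {
      stop(sprintf("time not strictly increasing within cycle %s at row %d",
                   cyc, idx[nonmono[1] + 1L]), call. = FALSE)
    }
  }
  meta_path <- paste0(path, ".meta.json")
  extra <- list()
  cond <- NA_character_; seed <- NA_integer_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$condition)) cond <- meta$condition
    if (!is.null(meta$seed)) seed <- meta$seed
  }
  .trajectory(df, cond, seed, extra)
}

#' Write an analysis results document to JSON
#'
#' A self-describing container: schema version, the producing command or
#' function, a parameter echo, and the outputs. Round-trips losslessly
#' through [read_results()].
#'
#' @param outputs named list of results (numbers, vectors, nested lists).
#' @param path output path.
#' @param command name of the producing step.
#' @param params named list echoed verbatim.
#' @param warnings character vector of warnings raised during the run.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(outputs, path, command = "analysis",
                          params = list(), warnings = character(0)) {
  doc <- list(
    schema_version = "1.0",
    command = command,
    params = params,
    outputs = outputs,
    warnings = as.character(warnings)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version)) {
    stop("not a results document: missing schema_version", call. = FALSE)
  }
  doc
}

#' Read a simulation configuration from YAML
#'
#' Sections \code{states}, \code{transitions}, \code{protocol} and
#' \code{noise} are recognised; unknown top-level keys are rejected so typos
#' fail loudly. Returns a condition-style list usable with
#' [simulate_stretch_cycles()] (missing sections fall back to the named
#' preset or package defaults).
#'
#' @param path YAML file.
#' @param base preset name passed to [nucleosome_condition()] used for any
#'   section the file omits (default \code{"h2b"}).
#' @return list with \code{condition} (a \code{sim_condition}),
#'   \code{protocol} (a [ramp_protocol()]) and \code{noise} (a
#'   [noise_model()]).
#' @export
read_sim_config <- function(path, base = "h2b") {
  cfg <- yaml::read_yaml(path)
  known <- c("condition", "states", "transitions", "protocol", "noise",
             "reassemble")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cond <- nucleosome_condition(if (!is.null(cfg$condition)) cfg$condition else base)
  if (!is.null(cfg$states)) {
    cond$states <- do.call(rbind, lapply(cfg$states, function(s) {
      data.frame(name = s$name, tether_contour_nm = s$tether_contour_nm,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(cfg$transitions)) {
    cond$transitions <- do.call(rbind, lapply(cfg$transitions, function(s) {
      data.frame(from = s$from, to = s$to, k0_per_s = s$k0_per_s,
                 x_dagger_nm = s$x_dagger_nm, stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(cfg$reassemble)) cond$reassemble <- isTRUE(cfg$reassemble)
  prot_args <- if (is.null(cfg$protocol)) list() else cfg$protocol
  noise_args <- if (is.null(cfg$noise)) list() else cfg$noise
  list(
    condition = cond,
    protocol = do.call(ramp_protocol, prot_args),
    noise = do.call(noise_model, noise_args)
  )
}
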