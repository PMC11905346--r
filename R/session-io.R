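#' Write / read a session as a plain-text directory
#'
#' A session is serialized as a directory of flat text files: a JSON
#' parameter sidecar (`params.json`), TSV matrices (`f_raw.tsv`,
#' `f_neu.tsv`, `positions.tsv`, `true_effect.tsv`), CSV tables
#' (`labels.csv`, `stim_table.csv`, `tone_table.csv`, `targets.csv`), and
#' per-frame behavior (`behavior.tsv`: run speed and running state). The
#' format is self-describing and diff-able; matrices are written with full
#' double precision.
#'
#' @param session a `pm_session`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly (for `write_session`); a `pm_session` (for
#'   `read_session`).
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "pm_session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- unclass(session$params)
  p$n_frames <- ncol(session$f_raw)
  jsonlite::write_json(p, file.path(path, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  wm <- function(m, f) write.table(format(m, digits = 17, trim = TRUE,
                                          scientific = TRUE),
                                   file.path(path, f), sep = "\t",
                                   row.names = FALSE, col.names = FALSE,
                                   quote = FALSE)
  wm(session$f_raw, "f_raw.tsv")
  wm(session$f_neu, "f_neu.tsv")
  wm(session$positions, "positions.tsv")
  wm(session$true_effect, "true_effect.tsv")
  write.csv(session$labels, file.path(path, "labels.csv"), row.names = FALSE)
  write.csv(session$stim_table, file.path(path, "stim_table.csv"),
            row.names = FALSE)
  write.csv(session$tone_table, file.path(path, "tone_table.csv"),
            row.names = FALSE)
  write.csv(session$targets, file.path(path, "targets.csv"),
            row.names = FALSE)
  beh <- data.frame(run_speed = session$run_speed,
                    run_state = session$ground_truth$run_state)
  write.table(beh, file.path(path, "behavior.tsv"), sep = "\t",
              row.names = FALSE)
  gt <- list(true_bf = session$ground_truth$true_bf,
             latent_loading = session$ground_truth$latent_loading,
             area_tag = session$area_tag)
  jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_session
#' @param path directory previously written by [write_session()].
#' @export
read_session <- function(path) {
  rm_ <- function(f) as.matrix(read.table(file.path(path, f), sep = "\t"))
  p <- jsonlite::read_json(file.path(path, "params.json"), simplifyVector = TRUE)
  class(p) <- "pm_params"
  f_raw <- unname(rm_("f_raw.tsv"))
  f_neu <- unname(rm_("f_neu.tsv"))
  positions <- unname(rm_("positions.tsv"))
  colnames(positions) <- c("x", "y")
  true_effect <- unname(rm_("true_effect.tsv"))
  targets <- read.csv(file.path(path, "targets.csv"))
  rownames(true_effect) <- as.character(targets$target_id)
  beh <- read.table(file.path(path, "behavior.tsv"), header = TRUE, sep = "\t")
  gt <- jsonlite::read_json(file.path(path, "ground_truth.json"),
                            simplifyVector = TRUE)
  structure(list(
    params = p,
    positions = positions,
    labels = read.csv(file.path(path, "labels.csv")),
    f_raw = f_raw, f_neu = f_neu,
    stim_table = read.csv(file.path(path, "stim_table.csv")),
    run_speed = beh$run_speed,
    tone_table = read.csv(file.path(path, "tone_table.csv")),
    area_tag = gt$area_tag,
    targets = targets,
    true_effect = true_effect,
    ground_truth = list(true_bf = gt$true_bf,
                        run_state = beh$run_state,
                        latent_loading = gt$latent_loading)),
    class = "pm_session")
}

#' Validate a session's schema and internal consistency
#'
#' Distinguishes hard failures (missing datasets, shape mismatches,
#' non-monotone onsets, missing positions -- the analysis cannot run) from
#' warnings (e.g. unusually few trials).
#'
#' @param session a `pm_session` or a path written by [write_session()].
#' @return list: `ok` (no hard failures), `errors` (character),
#'   `warnings` (character).
#' @export
validate_session <- function(session) {
  if (is.character(session)) session <- read_session(session)
  errors <- character(0); warns <- character(0)
  need <- c("params", "positions", "labels", "f_raw", "f_neu", "stim_table",
            "run_speed", "tone_table", "true_effect")
  miss <- setdiff(need, names(session))
  if (length(miss) > 0)
    errors <- c(errors, paste("missing dataset(s):", paste(miss, collapse = ", ")))
  if (length(errors) == 0) {
    n <- nrow(session$f_raw)
    if (nrow(session$positions) != n || nrow(session$labels) != n)
      errors <- c(errors, "positions/labels do not match the activity matrix")
    if (!identical(dim(session$f_raw), dim(session$f_neu)))
      errors <- c(errors, "f_raw and f_neu shapes differ")
    bad_pos <- which(!is.finite(rowSums(session$positions)))
    if (length(bad_pos) > 0)
      errors <- c(errors, paste("neuron(s) lacking a position:",
                                paste(bad_pos, collapse = ", ")))
    if (is.unsorted(session$stim_table$onset_frame, strictly = TRUE))
      errors <- c(errors, "stimulation onsets are not strictly increasing")
    if (any(session$run_speed < 0))
      errors <- c(errors, "negative running speed")
    st <- session$stim_table
    for (tid in unique(st$target_id)) {
      o <- st$onset_frame[st$target_id == tid]
      if (is.unsorted(o, strictly = TRUE)) {
        errors <- c(errors, paste("onsets not strictly increasing for target", tid))
        break
      }
    }
    isi_fr <- round(session$params$isi * session$params$frame_rate)
    if (nrow(st) > 1 && any(diff(st$onset_frame) < isi_fr))
      warns <- c(warns, "some interstimulus intervals shorter than isi")
    if (min(table(st$target_id)) < 20)
      warns <- c(warns, "fewer than 20 repeats for some target")
    if (isTRUE(any(session$positions < 0 |
                     session$positions > session$params$fov_size)))
      warns <- c(warns, "positions outside the nominal field of view")
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warns)
}
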