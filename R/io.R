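# Recording and cohort serialization.
#
# HDF5 is the canonical container (a full-scale plant is 15 days x 500 Hz =
# 648M samples; text formats do not scale to that). One group per plant with
# dataset `samples` and attributes `fs`, `plant_id`, `stimulus_time`,
# `symptom_time`. CSV (`time_s,value` plus a commented metadata header) is a
# convenience dialect for small extracts. Both round-trip samples bit-exactly.

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    format_error("the rhdf5 package is required for HDF5 I/O")
}

REC_ATTRS <- c("fs", "plant_id", "stimulus_time", "symptom_time", "t0")

h5_write_group <- function(file, group, rec) {
  rhdf5::h5createGroup(file, group)
  rhdf5::h5write(rec$samples, file, paste0(group, "/samples"))
  fid <- rhdf5::H5Fopen(file)
  gid <- rhdf5::H5Gopen(fid, group)
  for (a in REC_ATTRS) rhdf5::h5writeAttribute(rec[[a]], gid, a)
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
}

h5_read_group <- function(file, group) {
  samples <- as.numeric(rhdf5::h5read(file, paste0(group, "/samples")))
  attrs <- rhdf5::h5readAttributes(file, group)
  for (a in setdiff(REC_ATTRS, "t0"))
    if (is.null(attrs[[a]]))
      format_error(sprintf("HDF5 group %s is missing attribute `%s`",
                           group, a))
  recording(as.character(attrs$plant_id), as.numeric(attrs$fs), samples,
            as.numeric(attrs$stimulus_time), as.numeric(attrs$symptom_time),
            t0 = as.numeric(attrs$t0 %||% 0))
}

#' Write a recording (HDF5 or CSV, by extension)
#'
#' @param rec a [recording()].
#' @param path output path; `.h5`/`.hdf5` selects HDF5, `.csv` the CSV
#'   dialect.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (a in REC_ATTRS)
      writeLines(sprintf("# %s: %s", a,
                         if (is.character(rec[[a]])) rec[[a]]
                         else sprintf("%.17g", rec[[a]])), con)
    t <- rec$t0 + (seq_along(rec$samples) - 1) / rec$fs
    writeLines("time_s,value", con)
    writeLines(sprintf("%.17g,%.17g", t, rec$samples), con)
  } else {
    require_rhdf5()
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    h5_write_group(path, rec$plant_id, rec)
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' Read a recording (HDF5 or CSV, by extension)
#'
#' @param path input path. For HDF5 files holding several plants, pass
#'   `plant_id`; single-group files need no id.
#' @param plant_id optional plant id (HDF5 group).
#' @return A [recording()].
#' @export
read_recording <- function(path, plant_id = NULL) {
  if (!file.exists(path)) format_error(paste("file not found:", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    meta <- list()
    for (h in hdr) {
      kv <- regmatches(h, regexec("^# *([a-z0-9_]+): *(.*)$", h))[[1]]
      if (length(kv) == 3) meta[[kv[2]]] <- kv[3]
    }
    for (a in setdiff(REC_ATTRS, "t0"))
      if (is.null(meta[[a]]))
        format_error(sprintf("CSV header is missing attribute `%s`", a))
    body <- utils::read.csv(text = lines[!grepl("^#", lines)])
    if (!all(c("time_s", "value") %in% names(body)))
      format_error("CSV must have columns time_s,value")
    if (any(diff(body$time_s) <= 0))
      format_error("CSV time column must be strictly increasing")
    recording(meta$plant_id, as.numeric(meta$fs), body$value,
              as.numeric(meta$stimulus_time), as.numeric(meta$symptom_time),
              t0 = as.numeric(meta$t0 %||% 0))
  } else {
    require_rhdf5()
    groups <- rhdf5::h5ls(path, recursive = FALSE)$name
    rhdf5::h5closeAll()
    gid <- plant_id %||% {
      if (length(groups) != 1)
        format_error("file holds several plants; pass `plant_id`")
      groups[1]
    }
    rec <- h5_read_group(path, gid)
    rhdf5::h5closeAll()
    rec
  }
}

#' Write a cohort of recordings to one HDF5 file
#'
#' One group per plant (dataset `samples`, attributes `fs`, `plant_id`,
#' `stimulus_time`, `symptom_time`).
#'
#' @param cohort named list of [recording()]s.
#' @param path output `.h5` path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  require_rhdf5()
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (rec in cohort) h5_write_group(path, rec$plant_id, rec)
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a cohort from an HDF5 file
#' @param path input `.h5` path.
#' @return Named list of [recording()]s (one per stored group).
#' @export
read_cohort <- function(path) {
  require_rhdf5()
  if (!file.exists(path)) format_error(paste("file not found:", path))
  groups <- rhdf5::h5ls(path, recursive = FALSE)$name
  out <- lapply(groups, function(g) h5_read_group(path, g))
  names(out) <- groups
  rhdf5::h5closeAll()
  out
}

#' Write a prediction trace to CSV
#' @param trace a [prediction_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(plant_id = trace$plant_id,
                              start_time_s = trace$start_times,
                              confidence = trace$confidences),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline run records its configuration, seed, package version and
#' stage timings: enough to re-execute the run.
#'
#' @param manifest named list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest$package_version <-
    as.character(utils::packageVersion("phytostress"))
  manifest$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
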