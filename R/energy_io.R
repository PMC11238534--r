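#' Construct an energy trace
#'
#' An `energy_trace` holds the total potential energy time series of one
#' simulated system at one temperature, for one replica. Energies are in
#' kcal/mol, temperature in kelvin.
#'
#' @param system_label Character scalar identifying the system class
#'   (conventionally one of `"holo"`, `"apo"`, `"ligand"`, `"water"`, with
#'   an optional free-form tag such as `"holo_2"`).
#' @param temperature Simulation temperature in kelvin (> 0).
#' @param replica_id Integer replica index.
#' @param energies Numeric vector of total potential energies, kcal/mol,
#'   in frame order. Must be non-empty and finite.
#' @param frame_interval Frame spacing in picoseconds (metadata only).
#' @return An object of class `energy_trace`.
#' @export
energy_trace <- function(system_label, temperature, replica_id, energies,
                         frame_interval = NA_real_) {
  stopifnot(is.character(system_label), length(system_label) == 1L)
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a single positive value in kelvin", call. = FALSE)
  if (length(energies) == 0L)
    stop("energies must be non-empty", call. = FALSE)
  if (!all(is.finite(energies)))
    stop("all energies must be finite", call. = FALSE)
  structure(
    list(system_label = system_label,
         temperature = as.numeric(temperature),
         replica_id = as.integer(replica_id),
         energies = as.numeric(energies),
         frame_interval = frame_interval),
    class = "energy_trace")
}

#' @export
print.energy_trace <- function(x, ...) {
  cat(sprintf("<energy_trace> %s  T = %g K  replica %d  %d frames\n",
              x$system_label, x$temperature, x$replica_id, length(x$energies)))
  invisible(x)
}

#' Read an energy table into energy traces
#'
#' Parses a delimited text file of molecular dynamics energy time series.
#' The file is organised in groups: each group starts with a header block of
#' `# key value` comment lines carrying at least `system`, `temperature_K`
#' and `replica` (optionally `frame_interval_ps`), followed by data rows of
#' `time energy`. The delimiter is auto-detected among comma, tab and
#' whitespace unless given.
#'
#' @param path Path to the file.
#' @param delimiter Optional explicit delimiter (`","`, `"\t"` or `" "`);
#'   by default detected from the first data row.
#' @return A list of [energy_trace()] objects, one per
#'   (system, temperature, replica) group, frame order preserved.
#' @seealso [write_energy_table()] for the inverse operation.
#' @export
read_energy_table <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  traces <- list()
  meta <- list()
  energies <- numeric(0)
  flush_group <- function() {
    if (length(energies) == 0L) return(invisible(NULL))
    for (key in c("system", "temperature_K", "replica")) {
      if (is.null(meta[[key]]))
        stop("schema error: group missing required header '", key, "'",
             call. = FALSE)
    }
    traces[[length(traces) + 1L]] <<- energy_trace(
      system_label = meta$system,
      temperature = as.numeric(meta$temperature_K),
      replica_id = as.integer(meta$replica),
      energies = energies,
      frame_interval = if (is.null(meta$frame_interval_ps)) NA_real_
                       else as.numeric(meta$frame_interval_ps))
    energies <<- numeric(0)
    invisible(NULL)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]
      if (length(kv) >= 2) {
        if (kv[1] == "system" && length(energies) > 0L) flush_group()
        meta[[kv[1]]] <- kv[2]
      }
      next
    }
    sep <- if (!is.null(delimiter)) delimiter
           else if (grepl(",", ln, fixed = TRUE)) ","
           else if (grepl("\t", ln, fixed = TRUE)) "\t"
           else " "
    fields <- strsplit(ln, if (sep == " ") "\\s+" else sep)[[1]]
    fields <- fields[fields != ""]
    if (length(fields) < 2)
      stop(sprintf("parse error at line %d: expected (time, energy), got '%s'",
                   i, lines[i]), call. = FALSE)
    e <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(e))
      stop(sprintf("parse error at line %d: non-numeric energy '%s'",
                   i, fields[2]), call. = FALSE)
    energies <- c(energies, e)
  }
  flush_group()
  if (length(traces) == 0L)
    stop("schema error: no data groups found in ", path, call. = FALSE)
  traces
}

#' Write energy traces to a delimited text table
#'
#' Emits the dialect that [read_energy_table()] reads: per trace a `# key
#' value` header block (system, temperature_K, replica, frame_interval_ps)
#' followed by `time<sep>energy` rows.
#'
#' @param traces A list of [energy_trace()] objects (or a single one).
#' @param path Output file path.
#' @param delimiter Field delimiter for data rows (default tab).
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(traces, path, delimiter = "\t") {
  if (inherits(traces, "energy_trace")) traces <- list(traces)
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in traces) {
    writeLines(c(
      sprintf("# system %s", tr$system_label),
      sprintf("# temperature_K %.10g", tr$temperature),
      sprintf("# replica %d", tr$replica_id)), con)
    if (is.finite(tr$frame_interval))
      writeLines(sprintf("# frame_interval_ps %.10g", tr$frame_interval), con)
    dt <- if (is.finite(tr$frame_interval)) tr$frame_interval else 1
    t <- seq_along(tr$energies) * dt
    writeLines(sprintf("%.10g%s%.17g", t, delimiter, tr$energies), con)
  }
  invisible(path)
}

#' Mean energy of a trace with block-averaged uncertainty
#'
#' Discards an initial equilibration fraction of frames, then splits the
#' retained frames into `block_count` contiguous blocks and reports the
#' overall mean together with the standard error of the block means,
#' `sd(block means)/sqrt(block_count)`. Block averaging gives an uncertainty
#' that is robust to the serial correlation typical of molecular dynamics
#' energy series.
#'
#' @param trace An [energy_trace()].
#' @param equilibration_fraction Fraction in \[0, 1) of initial frames to
#'   discard (default 0: production output is assumed equilibrated).
#' @param block_count Number of blocks (>= 2, default 10).
#' @return A list with `mean_energy`, `sem` (both kcal/mol) and `n_frames`
#'   (retained frames).
#' @export
trace_mean <- function(trace, equilibration_fraction = 0, block_count = 10L) {
  stopifnot(inherits(trace, "energy_trace"))
  if (equilibration_fraction < 0 || equilibration_fraction >= 1)
    stop("equilibration_fraction must be in [0, 1)", call. = FALSE)
  if (block_count < 2L) stop("block_count must be >= 2", call. = FALSE)
  e <- trace$energies
  n_skip <- floor(length(e) * equilibration_fraction)
  e <- e[seq.int(n_skip + 1L, length(e))]
  n <- length(e)
  if (n < block_count)
    stop(sprintf(
      "insufficient data: %d frames remain after equilibration, need >= %d",
      n, block_count), call. = FALSE)
  blk <- split(e, cut(seq_len(n), block_count, labels = FALSE))
  bm <- vapply(blk, mean, numeric(1))
  list(mean_energy = mean(e),
       sem = stats::sd(bm) / sqrt(block_count),
       n_frames = n)
}

#' Aggregate energy traces into a temperature scan
#'
#' Pools all traces of a single system into one mean energy per temperature.
#' Replicas at the same temperature are combined by frame-weighted mean (so
#' pooling replicas is equivalent to concatenating their retained frames);
#' the pooled standard error combines the per-replica block SEMs in
#' frame-weighted quadrature.
#'
#' @param traces List of [energy_trace()] objects sharing one system label.
#' @inheritParams trace_mean
#' @return A `temperature_scan`: list with `system_label` and `points`, a
#'   data.frame with columns `temperature`, `mean_energy`, `sem`, `n_frames`,
#'   sorted by increasing temperature.
#' @export
aggregate_scan <- function(traces, equilibration_fraction = 0,
                           block_count = 10L) {
  if (inherits(traces, "energy_trace")) traces <- list(traces)
  labels <- unique(vapply(traces, `[[`, character(1), "system_label"))
  if (length(labels) != 1L)
    stop("label mismatch: traces span systems ",
         paste(labels, collapse = ", "), call. = FALSE)
  temps <- vapply(traces, `[[`, numeric(1), "temperature")
  sums <- lapply(split(seq_along(traces), temps), function(idx) {
    ms <- lapply(traces[idx], trace_mean,
                 equilibration_fraction = equilibration_fraction,
                 block_count = block_count)
    w <- vapply(ms, `[[`, numeric(1), "n_frames")
    mu <- vapply(ms, `[[`, numeric(1), "mean_energy")
    se <- vapply(ms, `[[`, numeric(1), "sem")
    data.frame(temperature = traces[[idx[1]]]$temperature,
               mean_energy = sum(w * mu) / sum(w),
               sem = sqrt(sum((w / sum(w))^2 * se^2)),
               n_frames = sum(w))
  })
  pts <- do.call(rbind, sums)
  pts <- pts[order(pts$temperature), , drop = FALSE]
  rownames(pts) <- NULL
  if (nrow(pts) >= 2 && any(diff(pts$temperature) <= 0))
    stop("temperatures must be distinct after aggregation", call. = FALSE)
  structure(list(system_label = labels, points = pts),
            class = "temperature_scan")
}

#' @export
print.temperature_scan <- function(x, ...) {
  cat(sprintf("<temperature_scan> %s  %d temperatures\n",
              x$system_label, nrow(x$points)))
  print(x$points, ...)
  invisible(x)
}

#' Write / read a temperature scan as delimited text
#'
#' The scan serialises to a `# system <label>` header plus a tab-separated
#' table with columns `temperature_K`, `mean_energy_kcal_per_mol`,
#' `sem_kcal_per_mol`, `n_frames`. Full double precision is preserved, so a
#' write-then-read round trip reproduces the scan exactly.
#'
#' @param scan A `temperature_scan` from [aggregate_scan()].
#' @param path File path.
#' @return `write_scan()` returns `path` invisibly; `read_scan()` returns a
#'   `temperature_scan`.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "temperature_scan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# system %s", scan$system_label), con)
  writeLines(paste("temperature_K", "mean_energy_kcal_per_mol",
                   "sem_kcal_per_mol", "n_frames", sep = "\t"), con)
  with(scan$points, writeLines(
    sprintf("%.17g\t%.17g\t%.17g\t%d", temperature, mean_energy, sem,
            n_frames), con))
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sys_line <- grep("^#\\s*system\\s", lines, value = TRUE)
  if (length(sys_line) == 0)
    stop("schema error: scan file lacks '# system' header", call. = FALSE)
  label <- strsplit(sub("^#\\s*system\\s+", "", sys_line[1]), "\\s+")[[1]][1]
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#")
  pts <- data.frame(temperature = tab$temperature_K,
                    mean_energy = tab$mean_energy_kcal_per_mol,
                    sem = tab$sem_kcal_per_mol,
                    n_frames = as.integer(tab$n_frames))
  structure(list(system_label = label, points = pts),
            class = "temperature_scan")
}
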