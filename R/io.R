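# Model serialization (JSON, schema 1) and episodic trace text I/O in an
# ATF-like tab-delimited layout: '#'-prefixed metadata header, then a time
# column plus one column per episode.

.kin_to_list <- function(kin) {
  list(alpha0 = kin$alpha0, beta0 = kin$beta0,
       z_alpha_delta = kin$z_alpha_delta, z_beta_delta = kin$z_beta_delta)
}

#' Serialize a channel assembly (with constants) to a JSON model file
#'
#' Versioned schema (`schema: 1`) holding the two subunit parameter sets,
#' the concerted-step rates, conductance, reversal potential, population
#' size and the temperature.
#'
#' @param asm A [channel_assembly()].
#' @param path File path to write; with `path = NULL` the JSON string is
#'   returned instead.
#' @param pc A [physical_constants()] object.
#' @return `path` invisibly (or the JSON string).
#' @export
assembly_to_json <- function(asm, path = NULL, pc = physical_constants()) {
  obj <- list(schema = 1L,
              temperature = pc$temperature,
              common = .kin_to_list(asm$common),
              distinct = .kin_to_list(asm$distinct),
              opening_rate = asm$opening_rate,
              closing_rate = asm$closing_rate,
              single_channel_conductance = asm$single_channel_conductance,
              reversal_potential = asm$reversal_potential,
              n_channels = asm$n_channels)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Read a channel assembly from a JSON model file
#'
#' @param path Path to a file written by [assembly_to_json()] (or a JSON
#'   string).
#' @return A list with `assembly` (a [channel_assembly()]) and `pc`
#'   (a [physical_constants()]).
#' @export
assembly_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$schema) || obj$schema != 1L) {
    stop("unsupported model schema (expected schema: 1)", call. = FALSE)
  }
  mk <- function(k) subunit_kinetics(k$alpha0, k$beta0,
                                     k$z_alpha_delta, k$z_beta_delta)
  list(assembly = channel_assembly(
         common = mk(obj$common), distinct = mk(obj$distinct),
         opening_rate = obj$opening_rate, closing_rate = obj$closing_rate,
         single_channel_conductance = obj$single_channel_conductance,
         reversal_potential = obj$reversal_potential,
         n_channels = obj$n_channels),
       pc = physical_constants(obj$temperature))
}

#' Write episodic current traces as tab-delimited text
#'
#' Layout: '#'-prefixed metadata lines (kind, units, sampling interval,
#' episode labels, shared segment boundaries), a header row, then one time
#' column (ms) and one current column per episode. A JSON sidecar
#' (`<path>.json`) records per-episode segment tables and any extra
#' provenance handed in.
#'
#' @param traces List of `current_trace` objects on a shared time grid.
#' @param path Output file path.
#' @param provenance Optional list stored in the sidecar.
#' @param sidecar Write the JSON sidecar (default TRUE).
#' @return `path` invisibly.
#' @export
write_episodic <- function(traces, path, provenance = list(),
                           sidecar = TRUE) {
  stopifnot(length(traces) >= 1L)
  t0 <- traces[[1L]]$time
  for (tr in traces) {
    if (length(tr$time) != length(t0) || max(abs(tr$time - t0)) > 1e-9) {
      stop("all episodes must share one time grid", call. = FALSE)
    }
  }
  labels <- vapply(traces, function(tr) as.numeric(tr$step_voltage),
                   numeric(1L))
  hdr <- c(
    sprintf("# kind: %s", traces[[1L]]$kind),
    sprintf("# units: %s", traces[[1L]]$units),
    sprintf("# sample_interval_ms: %.17g", t0[2L] - t0[1L]),
    sprintf("# episode_labels: %s", paste(labels, collapse = "\t")))
  mat <- cbind(t0, vapply(traces, function(tr) tr$current,
                          numeric(length(t0))))
  colnames(mat) <- c("time_ms", sprintf("ep_%g", labels))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(mat), collapse = "\t"), con)
  utils::write.table(format(mat, digits = 10, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (sidecar) {
    side <- list(
      kind = traces[[1L]]$kind, units = traces[[1L]]$units,
      episode_labels = labels,
      segments = lapply(traces, function(tr) tr$segments),
      metadata = traces[[1L]]$metadata,
      provenance = provenance)
    writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"),
               paste0(path, ".json"))
  }
  invisible(path)
}

#' Read episodic current traces written by [write_episodic()]
#'
#' @param path Path to the tab-delimited trace file; the JSON sidecar is
#'   picked up automatically when present.
#' @return A list of `current_trace` objects.
#' @export
read_episodic <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(sprintf("^# %s:\\s*", key), "", ln[1L])
  }
  kind <- get_field("kind")
  units <- get_field("units")
  labels <- as.numeric(strsplit(get_field("episode_labels"), "\t")[[1L]])
  body <- lines[!grepl("^#", lines)]
  dat <- utils::read.table(text = body, header = TRUE, sep = "\t")
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::fromJSON(side_path,
                                                         simplifyDataFrame = TRUE)
          else NULL
  lapply(seq_along(labels), function(i) {
    seg <- if (!is.null(side)) as.data.frame(side$segments[[i]]) else NULL
    current_trace(dat[[1L]], dat[[i + 1L]], labels[i],
                  kind = kind, units = units, segments = seg,
                  metadata = if (!is.null(side)) side$metadata else list())
  })
}
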