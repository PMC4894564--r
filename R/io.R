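# Delimited-text readers/writers for cohort tables and raw time series.
# All files are TSV with a leading `# key: value` header block carrying
# metadata (units, seed, acquisition parameters).

write_header <- function(con, meta) {
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]])), con)
  }
}

read_header <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  meta <- list()
  for (m in kv) {
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  meta
}

#' Write a cohort table to delimited text
#'
#' Tab-separated, one row per eye, with a comment header recording the seed
#' and column units.
#'
#' @param cohort A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(
    format = "cohort_table",
    seed = attr(cohort, "seed"),
    units = "age:months last_iop:mmHg E_star:MPa AB:MPa K:per-uL thickness:mm v0:uL"
  ))
  utils::write.table(as.data.frame(cohort), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path File path.
#' @return A `cohort_table` data frame (seed restored from the header).
#' @export
read_cohort <- function(path) {
  meta <- read_header(path)
  out <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!is.null(meta$seed)) attr(out, "seed") <- as.integer(meta$seed)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write an infusion pressure trace to delimited text
#'
#' Two columns (`time_s`, `iop_mmHg`) plus a header block carrying the flow
#' schedule so that the injected volume can be reconstructed on read.
#'
#' @param trace A `pressure_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pressure_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(
    format = "pressure_trace",
    baseline_iop_mmHg = attr(trace, "baseline_iop"),
    sample_rate_Hz = attr(trace, "sample_rate"),
    flow_uL_s = attr(trace, "flow"),
    onset_s = attr(trace, "onset"),
    duration_s = attr(trace, "duration")
  ))
  utils::write.table(
    data.frame(time_s = trace$time, iop_mmHg = trace$iop),
    con, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read an infusion pressure trace written by [write_pressure_trace()]
#'
#' @param path File path.
#' @return A `pressure_trace` data frame with the flow schedule restored.
#' @export
read_pressure_trace <- function(path) {
  meta <- read_header(path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  flow <- as.numeric(meta$flow_uL_s)
  onset <- as.numeric(meta$onset_s)
  duration <- as.numeric(meta$duration_s)
  t_inf <- pmin(pmax(d$time_s - onset, 0), duration)
  out <- data.frame(time = d$time_s, iop = d$iop_mmHg,
                    injected_volume = flow * t_inf)
  attr(out, "baseline_iop") <- as.numeric(meta$baseline_iop_mmHg)
  attr(out, "sample_rate") <- as.numeric(meta$sample_rate_Hz)
  attr(out, "flow") <- flow
  attr(out, "onset") <- onset
  attr(out, "duration") <- duration
  class(out) <- c("pressure_trace", "data.frame")
  out
}

#' Write a DMA stress/strain series to delimited text
#'
#' Three columns (`time_s`, `strain`, `stress_MPa`) with the drive frequency
#' and preload in the header.
#'
#' @param series A `stress_strain_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stress_strain <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_header(con, list(
    format = "stress_strain_series",
    frequency_Hz = attr(series, "frequency"),
    preload_stress_MPa = attr(series, "preload_stress"),
    preload_N = if (is.null(attr(series, "preload_N"))) NA else attr(series, "preload_N"),
    n_cycles = attr(series, "n_cycles"),
    sample_rate_Hz = attr(series, "sample_rate")
  ))
  utils::write.table(
    data.frame(time_s = series$time, strain = series$strain,
               stress_MPa = series$stress),
    con, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a DMA stress/strain series written by [write_stress_strain()]
#'
#' @param path File path.
#' @return A `stress_strain_series` data frame.
#' @export
read_stress_strain <- function(path) {
  meta <- read_header(path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  out <- data.frame(time = d$time_s, strain = d$strain, stress = d$stress_MPa)
  attr(out, "frequency") <- as.numeric(meta$frequency_Hz)
  attr(out, "preload_stress") <- as.numeric(meta$preload_stress_MPa)
  if (!is.null(meta$preload_N) && meta$preload_N != "NA") {
    attr(out, "preload_N") <- as.numeric(meta$preload_N)
  }
  attr(out, "n_cycles") <- as.numeric(meta$n_cycles)
  attr(out, "sample_rate") <- as.numeric(meta$sample_rate_Hz)
  class(out) <- c("stress_strain_series", "data.frame")
  out
}
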