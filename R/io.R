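#' Write a raster to two-column CSV plus a neuron table
#'
#' The spike file has columns `time_ms, neuron_id`; the companion neuron
#' table (written alongside with suffix `_neurons.csv`) has
#' `neuron_id, population`, so silent neurons are preserved.
#'
#' @param raster a [spike_raster()].
#' @param path output CSV path for the spike records.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(raster, path) {
  write.csv(data.frame(time_ms = raster$time, neuron_id = raster$id),
            path, row.names = FALSE, quote = FALSE)
  ntab <- file.path(dirname(path),
                    sub("\\.csv$", "_neurons.csv", basename(path)))
  write.csv(data.frame(neuron_id = seq_along(raster$population),
                       population = raster$population),
            ntab, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a network configuration from YAML
#'
#' The YAML keys are exactly the [network_config()] argument names; absent
#' keys take their defaults.
#'
#' @param path YAML file path.
#' @return a [network_config()].
#' @export
read_network_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  vals <- yaml::read_yaml(path)
  # YAML 1.1 parses a bare `N` key as boolean; map it back to the field name
  names(vals)[names(vals) == "FALSE"] <- "N"
  known <- names(formals(network_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  do.call(network_config, vals)
}

#' Read a generic two-column spike CSV
#'
#' Accepts `time_ms` or `time_s` as the time column (autodetected by
#' header; seconds are converted to ms) and `neuron_id`. If a companion
#' `*_neurons.csv` table exists it supplies population labels; otherwise
#' all neurons are labelled "E".
#'
#' @param path CSV path.
#' @param t_end optional record end, ms (default: last spike time).
#' @return a [spike_raster()].
#' @export
read_raster_csv <- function(path, t_end = NULL) {
  df <- read.csv(path)
  tcol <- intersect(c("time_ms", "time_s", "time"), names(df))[1]
  if (is.na(tcol)) stop("no time column (expected time_ms or time_s)")
  tms <- if (tcol == "time_s") df[[tcol]] * 1000 else df[[tcol]]
  id <- df[["neuron_id"]]
  if (is.null(id)) stop("no neuron_id column")
  ntab <- file.path(dirname(path),
                    sub("\\.csv$", "_neurons.csv", basename(path)))
  pop <- if (file.exists(ntab)) {
    nt <- read.csv(ntab)
    nt$population[order(nt$neuron_id)]
  } else rep("E", max(id))
  spike_raster(tms, id, pop, t_start = 0,
               t_end = if (is.null(t_end)) max(tms) else t_end)
}
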