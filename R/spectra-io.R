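# Plain-text IO for spectra and arrival-time-distribution (ATD) stacks.
#
# Spectrum format: optional "# key=value" header lines, then two whitespace-
# delimited columns (m/z, intensity).  ATD format: "# key=value" headers, a
# first column of arrival times (ms) and one column per collision voltage;
# voltages are taken from a "# voltages=v1,v2,..." header line.

parse_kv_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  kv
}

#' Read a spectrum from two-column delimited text
#'
#' @param path file path.
#' @return a [mass_spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  kv <- parse_kv_header(lines)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  d <- read.table(text = body, col.names = c("mz", "intensity"))
  num <- function(key) if (is.null(kv[[key]])) NA_real_ else as.numeric(kv[[key]])
  mass_spectrum(d$mz, d$intensity,
                collision_voltage = num("collision_voltage"),
                lipid_concentration = num("lipid_concentration"),
                label = if (is.null(kv$label)) "" else kv$label)
}

#' Write a spectrum as two-column delimited text
#'
#' @param spectrum a `mass_spectrum`.
#' @param path file path.
#' @export
write_spectrum <- function(spectrum, path) {
  md <- spectrum$metadata
  hdr <- c(
    if (is.finite(md$collision_voltage))
      sprintf("# collision_voltage=%g", md$collision_voltage),
    if (is.finite(md$lipid_concentration))
      sprintf("# lipid_concentration=%g", md$lipid_concentration),
    if (nzchar(md$label)) sprintf("# label=%s", md$label))
  con <- file(path, "w"); on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  write.table(data.frame(spectrum$mz, spectrum$intensity), con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an arrival-time-distribution stack
#'
#' @param path file path (see the module header for the layout).
#' @return list with `arrival_time` (ms), `voltage` (V), and `intensity`
#'   matrix (rows = arrival times, columns = voltages).
#' @export
read_atd_stack <- function(path) {
  lines <- readLines(path)
  kv <- parse_kv_header(lines)
  if (is.null(kv$voltages)) stop("missing '# voltages=' header")
  voltage <- as.numeric(strsplit(kv$voltages, ",")[[1]])
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  d <- as.matrix(read.table(text = body))
  if (ncol(d) != length(voltage) + 1L)
    stop("column count does not match the voltages header")
  list(arrival_time = d[, 1], voltage = voltage,
       intensity = unname(d[, -1, drop = FALSE]),
       charge = if (is.null(kv$charge)) NA_integer_ else as.integer(kv$charge))
}

#' Write an arrival-time-distribution stack
#'
#' @param atd list as returned by [read_atd_stack()] or [gen_ciu()].
#' @param path file path.
#' @export
write_atd_stack <- function(atd, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# voltages=%s", paste(atd$voltage, collapse = ",")), con)
  if (!is.null(atd$charge) && is.finite(atd$charge))
    writeLines(sprintf("# charge=%d", as.integer(atd$charge)), con)
  write.table(cbind(atd$arrival_time, atd$intensity), con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
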