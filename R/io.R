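# Plain-text containers for cubes and decay curves.
#
# Cube file layout: '#'-prefixed "key: value" header lines (dims, fractions,
# grids, noise, seed) followed by the counts in column-major order (sample
# index fastest), whitespace-separated, full double precision.

fmt_full <- function(x) sprintf("%.17g", x)

#' Write / read a TRES cube as delimited text
#'
#' The container is a single text file: `# key: value` header lines carrying
#' the dimensions, adulteration levels, both axis grids and the noise
#' bookkeeping, followed by the photon counts. The round trip is lossless
#' (counts bit-exact, grids to full double precision).
#'
#' @param cube a [tres_cube()].
#' @param path file path.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns the
#'   [tres_cube()].
#' @export
write_cube <- function(cube, path) {
  d <- dim(cube$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# tresoil-cube: v1",
    sprintf("# dims: %s", paste(d, collapse = " ")),
    sprintf("# fractions: %s", paste(fmt_full(cube$fractions), collapse = " ")),
    sprintf("# emission_nm: %s", paste(fmt_full(cube$emission_nm), collapse = " ")),
    sprintf("# time_ns: %s", paste(fmt_full(cube$time_ns), collapse = " ")),
    sprintf("# noise: %s", cube$noise),
    sprintf("# seed: %s", if (is.null(cube$seed)) "NA" else cube$seed)
  ), con)
  vals <- fmt_full(as.vector(cube$counts))
  writeLines(vapply(split(vals, ceiling(seq_along(vals) / 8)),
                    paste, "", collapse = " "), con)
  invisible(path)
}

read_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
  keys <- vapply(kv, function(m) trimws(m[2]), "")
  vals <- vapply(kv, function(m) trimws(m[3]), "")
  stats::setNames(as.list(vals), keys)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  h <- read_header(lines)
  for (key in c("dims", "fractions", "emission_nm", "time_ns")) {
    if (is.null(h[[key]])) {
      stop_arg("malformed cube file '%s': missing header '%s'", path, key)
    }
  }
  num <- function(key) as.numeric(strsplit(h[[key]], "\\s+")[[1]])
  d <- as.integer(num("dims"))
  body <- lines[!grepl("^#", lines)]
  counts <- as.numeric(unlist(strsplit(trimws(body[nzchar(body)]), "\\s+")))
  if (length(counts) != prod(d)) {
    stop_arg("malformed cube file '%s': expected %d values, found %d",
             path, prod(d), length(counts))
  }
  seed <- h[["seed"]]
  seed <- if (is.null(seed) || seed == "NA") NULL else as.integer(seed)
  tres_cube(array(counts, d), num("fractions"), num("emission_nm"),
            num("time_ns"),
            noise = if (is.null(h[["noise"]])) "none" else h[["noise"]],
            seed = seed)
}

#' Write / read a decay curve or IRF as two-column text
#'
#' Format: '#'-prefixed header lines, then `time_ns counts` pairs, one
#' channel per line.
#'
#' @param curve a [decay_curve()] or [irf()].
#' @param path file path.
#' @param digits decimal places for the counts column (default full
#'   precision).
#' @return `write_decay` returns `path` invisibly; `read_decay` returns a
#'   [decay_curve()]; `read_irf` returns an [irf()].
#' @export
write_decay <- function(curve, path, digits = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tresoil-decay: v1", con)
  if (!is.null(curve$emission_nm) && !is.na(curve$emission_nm)) {
    writeLines(sprintf("# emission_nm: %s", fmt_full(curve$emission_nm)), con)
  }
  writeLines("# columns: time_ns counts", con)
  cts <- if (is.null(digits)) fmt_full(curve$counts) else
    sprintf(paste0("%.", digits, "f"), curve$counts)
  writeLines(paste(fmt_full(curve$time_ns), cts), con)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  lines <- readLines(path)
  h <- read_header(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != 2L)) {
    stop_arg("malformed decay file '%s': expected two columns", path)
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  em <- if (!is.null(h[["emission_nm"]])) as.numeric(h[["emission_nm"]]) else NA_real_
  decay_curve(m[, 1], m[, 2], emission_nm = em)
}

#' @rdname write_decay
#' @export
read_irf <- function(path) {
  d <- read_decay(path)
  irf(d$time_ns, d$counts)
}
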