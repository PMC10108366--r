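# Plain-text file formats. Curves are 2-3 column whitespace-delimited tables
# with a structured metadata header of "# key: value" lines; spectral stacks
# are matrix text with the pulse durations in the header row. There is no
# community standard for TRAST curves; the (tau, G) layout matches common
# correlator exports.

format_meta <- function(meta) {
  vapply(names(meta), function(k) {
    v <- meta[[k]]
    sprintf("# %s: %s", k, paste(format(v, digits = 15), collapse = " "))
  }, character(1))
}

parse_meta <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

#' Write a TRAST or FCS curve to delimited text
#'
#' Two columns (`w_seconds value` for TRAST, `tau_seconds G` for FCS, plus an
#' `sd` column when present), preceded by `# key: value` metadata lines
#' recording wavelength, irradiance, band, duty cycle, normalization pulse
#' duration, and baseline convention.
#'
#' @param curve A `trast_curve` or `fcs_curve` tibble.
#' @param path Output path.
#' @export
write_curve <- function(curve, path) {
  meta <- curve_meta(curve) %||% list()
  df <- tibble::as_tibble(curve)
  cols <- vapply(df, function(col) paste(format(col, digits = 15)),
                 character(nrow(df)))
  body <- apply(as.matrix(cols), 1, paste, collapse = "\t")
  writeLines(c(format_meta(meta),
               paste0("# columns: ", paste(names(df), collapse = " ")),
               body), path)
  invisible(path)
}

#' Read a curve written by [write_curve()]
#'
#' The `type` metadata key decides the returned class (`trast_curve` or
#' `fcs_curve`). FCS data recorded with a zero baseline (`baseline: 0`) are
#' accepted and kept as stored; the baseline convention travels in the
#' metadata.
#'
#' @param path File path.
#' @return A curve tibble with metadata attached.
#' @export
read_curve <- function(path) {
  lines <- readLines(path)
  meta <- parse_meta(lines)
  col_line <- grep("^# columns:", lines, value = TRUE)
  cols <- if (length(col_line) > 0) {
    strsplit(sub("^# columns:\\s*", "", col_line[1]), "\\s+")[[1]]
  } else c("x", "y")
  meta[["columns"]] <- NULL
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  mat <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  df <- tibble::as_tibble(as.data.frame(mat))
  names(df) <- cols[seq_len(ncol(df))]
  type <- meta$type %||% "trast"
  if (identical(type, "fcs")) {
    new_fcs_curve(df[[1]], df[[2]], meta,
                  sd = if (ncol(df) >= 3) df[[3]] else NULL)
  } else {
    out <- new_trast_curve(df[[1]], df[[2]], meta)
    out
  }
}

#' Write / read a spectral stack as matrix text
#'
#' First column `wavelength_nm`; one column per pulse duration with the `w`
#' values (seconds) in the header row. Metadata rides in `# key: value`
#' lines.
#'
#' @param stack A `spectral_stack`.
#' @param path File path.
#' @export
write_stack <- function(stack, path) {
  meta <- attr(stack, "meta") %||% list()
  df <- tibble::as_tibble(stack)
  wide <- tidyr::pivot_wider(df, names_from = "w", values_from = "intensity")
  hdr <- paste(c("wavelength_nm", format(as.numeric(setdiff(names(wide),
                                                            "wavelength")),
                                         digits = 15)), collapse = "\t")
  body <- apply(wide, 1, function(r) paste(format(r, digits = 15),
                                           collapse = "\t"))
  writeLines(c(format_meta(meta), hdr, body), path)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  lines <- readLines(path)
  meta <- parse_meta(lines)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  hdr <- strsplit(body[1], "\t")[[1]]
  ws <- as.numeric(hdr[-1])
  mat <- do.call(rbind, lapply(strsplit(body[-1], "\t"), as.numeric))
  long <- tibble::tibble(
    wavelength = rep(mat[, 1], times = length(ws)),
    w = rep(ws, each = nrow(mat)),
    intensity = as.vector(mat[, -1, drop = FALSE])
  )
  norm <- meta$normalization %||% "none"
  meta$normalization <- NULL
  new_spectral_stack(long, normalization = norm, meta = meta)
}

#' Write / read a TCSPC histogram
#'
#' Two or three columns: `time_s counts [irf]`.
#'
#' @param hist A [decay_histogram()].
#' @param path File path.
#' @export
write_decay <- function(hist, path) {
  df <- tibble::as_tibble(hist)
  body <- apply(df, 1, function(r) paste(format(r, digits = 15),
                                         collapse = "\t"))
  writeLines(c(sprintf("# columns: %s", paste(names(df), collapse = " ")),
               body), path)
  invisible(path)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  mat <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
  decay_histogram(mat[, 1], mat[, 2],
                  irf = if (ncol(mat) >= 3) mat[, 3] else NULL)
}
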