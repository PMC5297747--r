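# Delimited-text IO. All tables are comma-separated UTF-8 with a
# `# key: value` metadata header; units are declared in the header
# (time_unit: s|min; concentration_unit: M|mM|uM|nM) and converted to the
# internal units (M, s) on read.

TIME_UNITS <- c(s = 1, min = 60)
CONC_UNITS <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9)

format_header <- function(meta) {
  meta <- meta[!vapply(meta, is.null, logical(1L))]
  keep <- vapply(meta, function(v)
    is.atomic(v) && length(v) == 1L && !is.na(v), logical(1L))
  vapply(names(meta)[keep], function(k)
    sprintf("# %s: %s", k, format(meta[[k]], digits = 15)), character(1L))
}

parse_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  stats::setNames(as.list(vals), trimws(keys))
}

write_table_with_header <- function(df, path, meta) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(format_header(meta), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an assay dataset as delimited text
#'
#' Writes the object's data columns as CSV preceded by a `#`-prefixed
#' metadata header carrying the dataset type, units, and any generator
#' ground truth, so that every file the package writes is readable by
#' [read_assay_table()].
#'
#' @param x A [progress_curve], [progress_set], [titration_series],
#'   `mm_table`, `stability_profile`, or `trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_assay_table <- function(x, path) UseMethod("write_assay_table")

#' @export
write_assay_table.titration_series <- function(x, path) {
  meta <- c(list(type = "titration"), attr(x, "metadata"))
  write_table_with_header(as.data.frame(x), path, meta)
}

#' @export
write_assay_table.progress_set <- function(x, path) {
  df <- do.call(rbind, lapply(x, function(cv)
    data.frame(time_s = cv$time_s, signal = cv$signal,
               inhibitor_M = attr(cv, "inhibitor_M"))))
  meta <- c(list(type = "progress", time_unit = "s",
                 concentration_unit = "M",
                 substrate_M = attr(x, "substrate_M"),
                 Km_M = attr(x, "Km_M")),
            attr(x, "metadata"))
  write_table_with_header(df, path, meta)
}

#' @export
write_assay_table.progress_curve <- function(x, path) {
  write_assay_table.progress_set(
    progress_set(list(x), substrate_M = attr(x, "substrate_M"),
                 metadata = attr(x, "metadata")), path)
}

#' @export
write_assay_table.mm_table <- function(x, path) {
  meta <- c(list(type = "mm", concentration_unit = "M"),
            attr(x, "metadata"))
  write_table_with_header(as.data.frame(x), path, meta)
}

#' @export
write_assay_table.stability_profile <- function(x, path) {
  md <- attr(x, "metadata")
  md$shape <- NULL  # nested object; not representable as header scalars
  write_table_with_header(as.data.frame(x), path,
                          c(list(type = "stability"), md))
}

#' @export
write_assay_table.trajectory <- function(x, path) {
  write_table_with_header(as.data.frame(x), path,
                          list(type = "trajectory", time_unit = "s",
                               concentration_unit = "M"))
}

read_unit <- function(meta, key, table, default) {
  u <- meta[[key]]
  if (is.null(u)) return(default)
  if (!u %in% names(table))
    stop("unparsable unit in header line '", key, ": ", u, "' (expected ",
         paste(names(table), collapse = ", "), ")")
  table[[u]]
}

check_time_increasing <- function(tm, n_header, by = NULL) {
  idx <- if (is.null(by)) list(seq_along(tm)) else split(seq_along(tm), by)
  for (ix in idx) {
    bad <- which(diff(tm[ix]) <= 0)
    if (length(bad) > 0L)
      stop("non-increasing time column at file line ",
           ix[bad[1L] + 1L] + n_header + 1L)
  }
}

#' Read an assay dataset written as delimited text
#'
#' Parses the `# key: value` metadata header, validates the expected
#' columns for the dataset type, converts declared units to the internal
#' units (M, s), and returns the typed object.
#'
#' @param path CSV file with `#` metadata header.
#' @param type Expected dataset type (`"progress"`, `"titration"`, `"mm"`,
#'   `"stability"`, `"trajectory"`); default: the `type` header key.
#' @return A [progress_set], [titration_series], `mm_table`,
#'   `stability_profile` or `trajectory` according to type.
#' @export
read_assay_table <- function(path, type = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  if (length(hdr) > 0L && !identical(hdr, seq_along(hdr)))
    stop("metadata lines (#) must precede the data")
  meta <- parse_header(lines[hdr])
  n_header <- length(hdr)
  data_lines <- if (n_header > 0L) lines[-seq_len(n_header)] else lines
  df <- utils::read.csv(text = paste(data_lines, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (is.null(type)) type <- meta$type
  if (is.null(type))
    stop("dataset type not given and no 'type' header present")
  need <- switch(type,
    progress   = c("time_s", "signal", "inhibitor_M"),
    titration  = c("ratio", "residual_activity"),
    mm         = c("substrate_M", "rate"),
    stability  = c("condition_type", "condition_value",
                   "residual_activity"),
    trajectory = c("time_s", "E", "EI", "E_inh", "I", "I_clv", "S", "P"),
    stop("unknown dataset type: ", type))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("missing column(s) for type '", type, "': ",
         paste(missing_cols, collapse = ", "),
         " (column-name line ", n_header + 1L, ")")
  tconv <- read_unit(meta, "time_unit", TIME_UNITS, 1)
  cconv <- read_unit(meta, "concentration_unit", CONC_UNITS, 1)
  num_meta <- function(key) {
    v <- suppressWarnings(as.numeric(meta[[key]]))
    if (length(v) == 0L) NULL else v
  }
  if (type == "titration") {
    return(titration_series(df$ratio, df$residual_activity,
                            metadata = meta))
  }
  if (type == "mm") {
    out <- structure(data.frame(substrate_M = df$substrate_M * cconv,
                                rate = df$rate),
                     class = c("mm_table", "data.frame"), metadata = meta)
    return(out)
  }
  if (type == "stability") {
    return(structure(df, class = c("stability_profile", "data.frame"),
                     metadata = meta))
  }
  if (type == "trajectory") {
    check_time_increasing(df$time_s * tconv, n_header)
    df$time_s <- df$time_s * tconv
    return(structure(df, class = c("trajectory", "data.frame")))
  }
  # progress: one or more curves keyed by inhibitor concentration
  df$time_s <- df$time_s * tconv
  df$inhibitor_M <- df$inhibitor_M * cconv
  check_time_increasing(df$time_s, n_header, by = df$inhibitor_M)
  S <- num_meta("substrate_M"); Km <- num_meta("Km_M")
  curves <- lapply(split(df, df$inhibitor_M), function(g)
    progress_curve(g$time_s, g$signal, inhibitor_M = g$inhibitor_M[1L],
                   substrate_M = if (is.null(S)) 0 else S,
                   metadata = meta))
  curves <- curves[order(vapply(curves, attr, numeric(1L), "inhibitor_M"))]
  progress_set(unname(curves),
               substrate_M = if (is.null(S)) 0 else S,
               Km_M = if (is.null(Km)) NA_real_ else Km,
               metadata = meta)
}

#' Write kinetic estimates as delimited text
#'
#' @param estimates A [kinetic_estimate] or list of them.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  if (inherits(estimates, "kinetic_estimate")) estimates <- list(estimates)
  df <- do.call(rbind, lapply(estimates, function(e)
    data.frame(quantity = e$quantity, value = e$value, se = e$se,
               rss = e$rss, n = e$n)))
  write_table_with_header(df, path, list(type = "estimates"))
}
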