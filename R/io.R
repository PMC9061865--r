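# Delimited-text readers and writers for release profiles.
#
# Profile tables are UTF-8 delimited text (comma by default, tab accepted)
# with a mandatory header `time_days, fraction_released, temperature_C`
# and an optional `replicate` column; lines starting with '#' are comments.

#' Read release profiles from a delimited text file
#'
#' Rows are grouped by `temperature_C` (and `replicate`, when present) into
#' one [release_profile()] per group. Malformed rows are reported with
#' their line numbers.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return a list of [release_profile()] objects, ordered by temperature.
#' @export
read_profile <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data in ", path, call. = FALSE)
  header_line <- lines[keep][1L]
  if (is.null(sep)) sep <- if (grepl("\t", header_line)) "\t" else ","
  df <- utils::read.table(text = lines[keep], header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("time_days", "fraction_released", "temperature_C")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  # map data rows back to file line numbers for error reporting
  line_no <- which(keep)[-1L]
  bad <- which(!is.finite(df$time_days) | df$time_days < 0 |
                 !is.finite(df$fraction_released) |
                 df$fraction_released < 0 | df$fraction_released > 1.05)
  if (length(bad) > 0L)
    stop("invalid rows (time < 0 or fraction outside [0, 1.05]) at line(s): ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)

  group_key <- if ("replicate" %in% names(df))
    paste(df$temperature_C, df$replicate, sep = "/") else df$temperature_C
  groups <- split(seq_len(nrow(df)), group_key)
  profiles <- lapply(groups, function(idx) {
    sub <- df[idx, ]
    if (any(diff(sub$time_days) <= 0)) {
      dup <- which(diff(sub$time_days) <= 0)[1L]
      stop("non-increasing times within one profile at line ",
           line_no[idx][dup + 1L], call. = FALSE)
    }
    label <- if ("replicate" %in% names(sub))
      sprintf("%g degC rep %s", sub$temperature_C[1L], sub$replicate[1L])
      else sprintf("%g degC", sub$temperature_C[1L])
    release_profile(sub$time_days, sub$fraction_released,
                    temperature_K = celsius_to_kelvin(sub$temperature_C[1L]),
                    label = label)
  })
  profiles[order(vapply(profiles, function(p) p$temperature_K, numeric(1)))]
}

#' Write release profiles to a delimited text file
#'
#' The inverse of [read_profile()]: a lossless round trip up to numeric
#' formatting (15 significant digits are written).
#'
#' @param profiles a [release_profile()] or list of them.
#' @param path output file path.
#' @param sep field separator (`","` default).
#' @return `path`, invisibly.
#' @export
write_profile <- function(profiles, path, sep = ",") {
  if (inherits(profiles, "release_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(time_days = p$times,
               fraction_released = p$fractions,
               temperature_C = p$temperature_K - 273.15)
  }))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("time_days", "fraction_released", "temperature_C"),
                   collapse = sep), con)
  writeLines(apply(rows, 1L, function(r)
    paste(formatC(r, digits = 15, format = "g"), collapse = sep)), con)
  invisible(path)
}
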