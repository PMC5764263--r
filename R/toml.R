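## Minimal TOML subset reader for run configuration files: [section] and
## [a.b] tables, key = value with strings, numbers, booleans and flat
## arrays, '#' comments. No pre-installed package parses TOML; this covers
## the configuration grammar this pipeline emits and documents.

toml_value <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[.*\\]$", s)) {
    inner <- substr(s, 2, nchar(s) - 1)
    if (trimws(inner) == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, toml_value)))
  }
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (s %in% c("true", "false")) return(s == "true")
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) return(n)
  s
}

#' Read a TOML configuration file (subset)
#'
#' Supports tables (including dotted names), scalar strings/numbers/
#' booleans, flat arrays, and comments — the grammar used by this
#' package's run configurations.
#'
#' @param path File path.
#' @return Nested named list.
#' @export
read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- character(0)
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- strsplit(gsub("^\\[|\\]$", "", ln), ".", fixed = TRUE)[[1]]
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop_config("malformed TOML line: ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- toml_value(substr(ln, eq + 1, nchar(ln)))
    path_keys <- c(section, key)
    out <- toml_assign(out, path_keys, val)
  }
  out
}

toml_assign <- function(lst, keys, value) {
  if (length(keys) == 1L) {
    lst[[keys]] <- value
    return(lst)
  }
  head_key <- keys[1]
  sub <- lst[[head_key]] %||% list()
  lst[[head_key]] <- toml_assign(sub, keys[-1], value)
  lst
}

#' Write a flat two-level list as TOML
#'
#' Inverse of [read_toml()] for configurations of the shape this package
#' uses (top-level scalars plus one level of named sections).
#'
#' @param config Named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toml <- function(config, path) {
  fmt <- function(v) {
    if (is.character(v) && length(v) == 1L) return(sprintf('"%s"', v))
    if (is.logical(v) && length(v) == 1L) return(tolower(as.character(v)))
    if (length(v) > 1L) return(sprintf("[%s]",
      paste(vapply(v, function(x) fmt(x), ""), collapse = ", ")))
    format(v, scientific = FALSE)
  }
  lines <- character(0)
  scalars <- config[!vapply(config, is.list, logical(1))]
  for (k in names(scalars))
    lines <- c(lines, sprintf("%s = %s", k, fmt(scalars[[k]])))
  sections <- config[vapply(config, is.list, logical(1))]
  for (k in names(sections)) {
    lines <- c(lines, "", sprintf("[%s]", k))
    for (kk in names(sections[[k]]))
      lines <- c(lines, sprintf("%s = %s", kk, fmt(sections[[k]][[kk]])))
  }
  writeLines(lines, path)
  invisible(path)
}
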