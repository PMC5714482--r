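#' Read mutant counts from a file or text
#'
#' Counts files hold one experiment: newline- or comma-separated
#' nonnegative integers, with optional header lines starting with `#`
#' carrying `key=value` metadata (`Nt`, `N0`, `epsilon`, `w`, `cv`), e.g.
#'
#' ```
#' #Nt=2.27e8
#' #w=1.47
#' 0, 2, 0, 3
#' ```
#'
#' @param path Path to a counts file, or a character string containing the
#'   counts text itself (anything with a newline or comma, or that is not
#'   an existing file, is treated as literal text).
#' @return A [count_data()] with metadata defaults applied.
#' @examples
#' read_counts("0,2,0,3")
#' read_counts("#Nt=2.27e8\n0\n2")
#' @export
read_counts <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  lines <- if (file.exists(path) && !grepl("[\n,]", path))
    readLines(path, warn = FALSE)
  else strsplit(path, "\n", fixed = TRUE)[[1L]]

  meta <- list(Nt = NA_real_, N0 = 0, epsilon = 1, w = 1, cv = 0)
  counts <- integer(0)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "") next
    if (startsWith(line, "#")) {
      kv <- strsplit(sub("^#\\s*", "", line), "=", fixed = TRUE)[[1L]]
      if (length(kv) == 2L) {
        key <- trimws(kv[1L])
        if (!key %in% names(meta))
          stop(sprintf("line %d: unknown metadata key '%s'", i, key))
        val <- suppressWarnings(as.numeric(trimws(kv[2L])))
        if (is.na(val))
          stop(sprintf("line %d: metadata value for '%s' is not numeric",
                       i, key))
        meta[[key]] <- val
      }
      next
    }
    tokens <- strsplit(line, "[,[:space:]]+")[[1L]]
    tokens <- tokens[tokens != ""]
    vals <- suppressWarnings(as.numeric(tokens))
    if (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))
      stop(sprintf(paste0("line %d: counts must be nonnegative integers ",
                          "(got '%s')"), i, line))
    counts <- c(counts, as.integer(vals))
  }
  if (length(counts) == 0L) stop("no counts found in input")
  count_data(counts, Nt = meta$Nt, N0 = meta$N0, epsilon = meta$epsilon,
             w = meta$w, cv = meta$cv)
}

#' Write mutant counts to a file
#'
#' Inverse of [read_counts()]: non-default metadata go into `#key=value`
#' header lines, counts follow one per line.
#'
#' @param data A [count_data()] object (or a bare counts vector).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile()
#' write_counts(count_data(c(0, 2), Nt = 1e8), f)
#' read_counts(f)
#' @export
write_counts <- function(data, path) {
  meta <- data_meta(data)
  hdr <- character(0)
  if (!is.na(meta$Nt)) hdr <- c(hdr, sprintf("#Nt=%.10g", meta$Nt))
  if (meta$N0 != 0) hdr <- c(hdr, sprintf("#N0=%.10g", meta$N0))
  if (meta$epsilon != 1) hdr <- c(hdr, sprintf("#epsilon=%.10g", meta$epsilon))
  if (meta$w != 1) hdr <- c(hdr, sprintf("#w=%.10g", meta$w))
  if (meta$cv != 0) hdr <- c(hdr, sprintf("#cv=%.10g", meta$cv))
  writeLines(c(hdr, as.character(meta$counts)), path)
  invisible(path)
}
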