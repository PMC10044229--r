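#' Read an annotation label track
#'
#' Parses the three-column tab-separated dialect used by Audacity label
#' tracks: `start_s<TAB>end_s<TAB>label`, one event per row, no header.
#'
#' @param path path to a label track text file
#' @return data.frame with columns `start`, `end` (seconds) and `label`
#' @export
read_label_track <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed label row(s): ", paste(bad, collapse = ", "))
  out <- data.frame(
    start = as.numeric(vapply(parts, `[[`, "", 1L)),
    end   = as.numeric(vapply(parts, `[[`, "", 2L)),
    label = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$start) || anyNA(out$end)) stop("non-numeric interval in label track")
  if (any(out$end < out$start)) stop("label track has end < start")
  out
}

#' Write an annotation label track
#'
#' @param events data.frame with columns `start`, `end`, `label`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_label_track <- function(events, path) {
  stopifnot(all(c("start", "end", "label") %in% names(events)))
  # %.17g keeps doubles exact through a write/parse round trip
  lines <- sprintf("%.17g\t%.17g\t%s", events$start, events$end, events$label)
  writeLines(lines, path)
  invisible(path)
}
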