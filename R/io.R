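#' Read an event file
#'
#' Event files are TSV with comment header lines of the form
#' `#key<TAB>value` (keys: `id`, `voltage_mV`, `filter_fc_Hz`, `dead_time_s`,
#' and `conc_<ligand>_uM` for each ligand), followed by the column header and
#' rows `index`, `class` (0 = shut, 1 = open), `duration_s`, `amplitude_pA`
#' (optional, may be empty). Strict shut/open alternation is not required on
#' input; conditioning ([impose_dead_time()] or `normalize_events`) enforces
#' it.
#'
#' @param path Path to the event file.
#' @return An [event_list()] with the header metadata attached.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (h in lines[hdr]) {
    kv <- strsplit(sub("^#", "", h), "\t", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    key <- kv[1]; val <- kv[2]
    if (key == "id") meta$id <- val
    else if (key == "voltage_mV") meta$voltage <- as.numeric(val)
    else if (key == "filter_fc_Hz") meta$filter_fc <- as.numeric(val)
    else if (key == "dead_time_s") meta$dead_time <- as.numeric(val)
    else if (grepl("^conc_.*_uM$", key)) {
      lig <- sub("^conc_(.*)_uM$", "\\1", key)
      meta$concentrations <- c(meta$concentrations,
                               stats::setNames(as.numeric(val), lig))
    }
  }
  body <- lines[!hdr]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    warning("event file contains no data rows")
    return(event_list(character(0), numeric(0), meta = meta))
  }
  dat <- utils::read.delim(text = body, header = TRUE,
                           colClasses = c("integer", "integer", "character",
                                          "character"))
  if (!all(c("index", "class", "duration_s") %in% names(dat)))
    stop("event file must have columns index, class, duration_s")
  if (!nrow(dat)) {
    warning("event file contains no data rows")
    return(event_list(character(0), numeric(0), meta = meta))
  }
  dur <- suppressWarnings(as.numeric(dat$duration_s))
  bad <- which(!is.finite(dur) | dur <= 0)
  if (length(bad))
    stop("non-numeric or non-positive duration at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  amp <- if ("amplitude_pA" %in% names(dat))
    suppressWarnings(as.numeric(dat$amplitude_pA)) else NULL
  if (!all(dat$class %in% c(0L, 1L)))
    stop("class column must be 0 (shut) or 1 (open)")
  event_list(dat$class, dur, amp, meta = meta)
}

#' Write an event file
#'
#' Inverse of [read_events()]; durations are written with 12 significant
#' digits so a write/read round trip is lossless at event-duration scale.
#'
#' @param events An [event_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_list"))
  m <- attr(events, "meta")
  hdr <- character(0)
  add <- function(key, val) sprintf("#%s\t%s", key, val)
  if (!is.na(m$id %||% NA)) hdr <- c(hdr, add("id", m$id))
  if (isTRUE(is.finite(m$voltage))) hdr <- c(hdr, add("voltage_mV", m$voltage))
  if (isTRUE(is.finite(m$filter_fc)))
    hdr <- c(hdr, add("filter_fc_Hz", m$filter_fc))
  if (isTRUE(is.finite(m$dead_time)))
    hdr <- c(hdr, add("dead_time_s", format(m$dead_time, digits = 12)))
  for (lig in names(m$concentrations))
    hdr <- c(hdr, add(sprintf("conc_%s_uM", lig), m$concentrations[lig]))
  rows <- sprintf("%d\t%d\t%s\t%s",
                  seq_len(nrow(events)),
                  as.integer(events$class == "open"),
                  format(events$duration, digits = 12, scientific = TRUE,
                         trim = TRUE),
                  ifelse(is.na(events$amplitude), "",
                         format(events$amplitude, digits = 8, trim = TRUE)))
  writeLines(c(hdr, "index\tclass\tduration_s\tamplitude_pA", rows), path)
  invisible(path)
}
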