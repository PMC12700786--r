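#' Read Percept-style BrainSense streaming JSON
#'
#' Parses the time-domain streaming subset of the BrainSense JSON schema: a
#' top-level `BrainSenseTimeDomain` array with one object per bipolar LFP
#' channel carrying `Channel`, `Hemisphere`, `SampleRateInHz` and
#' `TimeDomainData`. Optional `ExpectedSamples` and `Gaps` entries describe
#' streaming dropouts; gaps are recorded in `meta$gaps` (seconds and sample
#' counts), never filled into the data. Any other top-level fields are
#' preserved verbatim in `meta$extra`.
#'
#' @param path path to the JSON file.
#' @return A `Recording` with modality `"LFP"`.
#' @export
read_percept_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  chans <- doc$BrainSenseTimeDomain
  if (is.null(chans) || !length(chans))
    stop("not a BrainSense streaming file: missing `BrainSenseTimeDomain`")
  rates <- vapply(chans, function(ch) {
    if (is.null(ch$SampleRateInHz)) stop("channel entry lacks `SampleRateInHz`")
    as.numeric(ch$SampleRateInHz)
  }, numeric(1))
  if (length(unique(rates)) != 1L)
    stop("channels disagree on sampling rate")
  labels <- vapply(chans, function(ch) {
    if (is.null(ch$Channel)) stop("channel entry lacks `Channel`")
    as.character(ch$Channel)
  }, character(1))
  hemis <- vapply(chans, function(ch)
    if (is.null(ch$Hemisphere)) NA_character_ else as.character(ch$Hemisphere),
    character(1))
  series <- lapply(chans, function(ch) {
    x <- as.numeric(unlist(ch$TimeDomainData, use.names = FALSE))
    if (!length(x)) stop("channel entry has empty `TimeDomainData`")
    x
  })
  ns <- lengths(series)
  if (length(unique(ns)) != 1L)
    stop("channels disagree on sample count")
  gaps <- do.call(rbind, lapply(seq_along(chans), function(i) {
    g <- chans[[i]]$Gaps
    if (is.null(g) || !length(g)) return(NULL)
    data.frame(channel = labels[i],
               start_s = vapply(g, function(e) as.numeric(e$StartSeconds), 0),
               samples = vapply(g, function(e) as.integer(e$Samples), 0L))
  }))
  warn <- character()
  for (i in seq_along(chans)) {
    exp_n <- chans[[i]]$ExpectedSamples
    if (!is.null(exp_n)) {
      g <- if (is.null(gaps)) 0L else
        sum(gaps$samples[gaps$channel == labels[i]])
      if (as.integer(exp_n) != ns[i] + g)
        warn <- c(warn, sprintf(
          "channel %s: declared %d samples but found %d (+%d in gap tickets)",
          labels[i], as.integer(exp_n), ns[i], g))
    }
  }
  if (length(warn)) warning(paste(warn, collapse = "; "))
  extra <- doc[setdiff(names(doc), "BrainSenseTimeDomain")]
  new_recording(
    data = do.call(rbind, series), rate = rates[1], channel_labels = labels,
    modality = "LFP",
    meta = list(hemisphere = hemis, gaps = gaps,
                gap_warning = if (length(warn)) warn else NULL,
                extra = extra))
}

#' Write a Percept-style BrainSense streaming JSON file
#'
#' Inverse of [read_percept_json()]; sample values are serialised at full
#' double precision so that a read-back reproduces the data bit-exactly.
#'
#' @param rec an LFP `Recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_percept_json <- function(rec, path) {
  stopifnot(inherits(rec, "Recording"))
  if (rec$modality != "LFP")
    stop("only LFP recordings are written as BrainSense streaming JSON")
  if (ncol(rec$data) == 0L) stop("refusing to write an empty recording")
  gaps <- rec$meta$gaps
  chans <- lapply(seq_len(nrow(rec$data)), function(i) {
    lab <- rec$channel_labels[i]
    g <- if (!is.null(gaps)) gaps[gaps$channel == lab, , drop = FALSE] else NULL
    entry <- list(
      Channel = jsonlite::unbox(lab),
      Hemisphere = jsonlite::unbox(rec$meta$hemisphere[i]),
      SampleRateInHz = jsonlite::unbox(rec$rate),
      TimeDomainData = as.numeric(rec$data[i, ]))
    if (!is.null(g) && nrow(g)) {
      entry$ExpectedSamples <- jsonlite::unbox(ncol(rec$data) + sum(g$samples))
      entry$Gaps <- lapply(seq_len(nrow(g)), function(k)
        list(StartSeconds = jsonlite::unbox(g$start_s[k]),
             Samples = jsonlite::unbox(g$samples[k])))
    } else {
      entry$ExpectedSamples <- jsonlite::unbox(ncol(rec$data))
    }
    entry
  })
  doc <- list(DeviceName = jsonlite::unbox("synthetic BrainSense writer"),
              BrainSenseTimeDomain = chans)
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = FALSE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}
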