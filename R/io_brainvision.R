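#' Read a BrainVision recording
#'
#' Reads the `.vhdr` header, the binary `.eeg` payload and the `.vmrk`
#' marker file of a BrainVision triplet. Both `MULTIPLEXED` and
#' `VECTORIZED` data orientations and both `IEEE_FLOAT_32` and `INT_16`
#' (scaled by the per-channel resolution) binary formats are supported.
#'
#' Marker positions are interpreted as 0-based sample offsets, i.e. a
#' marker at position `p` maps to `p / rate` seconds; the writer uses the
#' same convention so triplets round-trip.
#'
#' @param path_vhdr path to the `.vhdr` header file.
#' @return A list with elements `recording` (an EEG `Recording`) and
#'   `events` (an `EventTable` folded from the marker file).
#' @export
read_brainvision <- function(path_vhdr) {
  if (!file.exists(path_vhdr)) stop("header file not found: ", path_vhdr)
  hdr <- .bv_parse_ini(readLines(path_vhdr, warn = FALSE))
  common <- hdr[["Common Infos"]]
  binary <- hdr[["Binary Infos"]]
  chinfo <- hdr[["Channel Infos"]]
  if (is.null(common) || is.null(common$DataFile))
    stop("malformed .vhdr: missing [Common Infos] DataFile")
  dir <- dirname(path_vhdr)
  eeg_path <- file.path(dir, common$DataFile)
  vmrk_path <- if (!is.null(common$MarkerFile))
    file.path(dir, common$MarkerFile) else NA_character_
  if (!file.exists(eeg_path)) stop("missing data sidecar: ", eeg_path)
  if (!is.na(vmrk_path) && !file.exists(vmrk_path))
    stop("missing marker sidecar: ", vmrk_path)

  n_chan <- as.integer(common$NumberOfChannels)
  rate <- 1e6 / as.numeric(common$SamplingInterval)  # interval is in us
  orientation <- toupper(common$DataOrientation %||% "MULTIPLEXED")
  fmt <- toupper(binary$BinaryFormat %||% "IEEE_FLOAT_32")

  ch <- lapply(seq_len(n_chan), function(i) {
    spec <- chinfo[[paste0("Ch", i)]]
    if (is.null(spec)) stop("header lacks Ch", i, " entry")
    parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
    list(label = parts[1],
         resolution = if (length(parts) >= 3 && nzchar(parts[3]))
           as.numeric(parts[3]) else 1)
  })
  labels <- vapply(ch, `[[`, "", "label")
  resolutions <- vapply(ch, `[[`, 0, "resolution")

  sz <- file.size(eeg_path)
  bytes <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  n_samp <- as.integer(sz / (bytes * n_chan))
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw_vals <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = n_samp * n_chan, size = 4L,
            endian = "little")
  } else if (fmt == "INT_16") {
    readBin(con, "integer", n = n_samp * n_chan, size = 2L, signed = TRUE,
            endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)

  data <- if (orientation == "MULTIPLEXED") {
    matrix(raw_vals, nrow = n_chan, ncol = n_samp)         # sample-major
  } else if (orientation == "VECTORIZED") {
    t(matrix(raw_vals, nrow = n_samp, ncol = n_chan))      # channel-major
  } else stop("unsupported DataOrientation: ", orientation)
  if (fmt == "INT_16") data <- data * resolutions          # column recycling
  rec <- new_recording(data, rate, labels, "EEG",
                       meta = list(source = path_vhdr, format = fmt,
                                   orientation = orientation,
                                   resolution = resolutions))
  events <- if (is.na(vmrk_path)) event_table() else
    .bv_read_vmrk(vmrk_path, rate)
  list(recording = rec, events = events)
}

#' Write a BrainVision triplet
#'
#' Writes `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg`. With
#' `format = "IEEE_FLOAT_32"` the payload stores the data as little-endian
#' float32 (bit-exact round trip for float32-representable values); with
#' `format = "INT_16"` each channel is scaled by a per-channel resolution
#' chosen to cover its range.
#'
#' @param rec an EEG (or SOURCE) `Recording`.
#' @param events an `EventTable` to serialise as markers (may be empty).
#' @param stem output path without extension.
#' @param orientation `"MULTIPLEXED"` or `"VECTORIZED"`.
#' @param format `"IEEE_FLOAT_32"` or `"INT_16"`.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, events = event_table(), stem,
                              orientation = c("MULTIPLEXED", "VECTORIZED"),
                              format = c("IEEE_FLOAT_32", "INT_16")) {
  stopifnot(inherits(rec, "Recording"))
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  base <- basename(stem)
  n_chan <- nrow(rec$data)

  resolutions <- rep(1, n_chan)
  if (format == "INT_16") {
    resolutions <- apply(abs(rec$data), 1, max) / 32000
    resolutions[resolutions == 0] <- 1
  }
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    paste0("DataOrientation=", orientation),
    paste0("NumberOfChannels=", n_chan),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$rate),
    "", "[Binary Infos]",
    paste0("BinaryFormat=", format),
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,%.15g,µV", seq_len(n_chan), rec$channel_labels,
            resolutions))
  writeLines(hdr, paste0(stem, ".vhdr"))

  con <- file(paste0(stem, ".eeg"), "wb")
  vals <- if (orientation == "MULTIPLEXED") rec$data else t(rec$data)
  if (format == "IEEE_FLOAT_32") {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  } else {
    ints <- round(rec$data / resolutions)
    ints <- pmin(pmax(ints, -32768), 32767)
    iv <- if (orientation == "MULTIPLEXED") ints else t(ints)
    writeBin(as.integer(iv), con, size = 2L, endian = "little")
  }
  close(con)

  .bv_write_vmrk(events, paste0(stem, ".vmrk"), paste0(base, ".eeg"),
                 rec$rate)
  invisible(paste0(stem, ".vhdr"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.bv_parse_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && !is.null(section)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

# marker type/description <-> EventTable kind mapping
.bv_kind_to_marker <- c(tic = "Tic", artifact_sync = "Artifact",
                        block_boundary = "Block", movement = "Movement")

.bv_read_vmrk <- function(path, rate) {
  ini <- .bv_parse_ini(readLines(path, warn = FALSE))
  mk <- ini[["Marker Infos"]]
  if (is.null(mk) || !length(mk)) return(event_table())
  rows <- lapply(mk, function(spec) {
    parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
    length(parts) <- max(length(parts), 5L)
    type <- parts[1]
    desc <- parts[2]
    pos <- as.numeric(parts[3])          # 0-based sample offset
    size <- as.numeric(parts[4] %||% "1")
    if (is.na(size)) size <- 1
    kind <- names(.bv_kind_to_marker)[match(type, .bv_kind_to_marker)]
    if (is.na(kind))
      kind <- switch(type, Stimulus = "artifact_sync",
                     `New Segment` = "block_boundary", "block_boundary")
    tic_type <- NA_character_
    condition <- NA_character_
    if (kind == "tic" && !is.na(desc) && nzchar(desc)) {
      bits <- strsplit(desc, ":", fixed = TRUE)[[1]]
      tic_type <- if (length(bits) >= 1) bits[1] else NA_character_
      condition <- if (length(bits) >= 2) bits[2] else NA_character_
    }
    data.frame(onset = pos / rate, offset = (pos + size) / rate,
               kind = kind, tic_type = tic_type, condition = condition,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  event_table(df$onset, df$offset, df$kind, df$tic_type, df$condition)
}

.bv_write_vmrk <- function(events, path, datafile, rate) {
  lines <- c("Brain Vision Data Exchange Marker File, Version 1.0",
             "", "[Common Infos]", "Codepage=UTF-8",
             paste0("DataFile=", datafile),
             "", "[Marker Infos]")
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      e <- events[i, ]
      type <- .bv_kind_to_marker[[e$kind]]
      desc <- if (e$kind == "tic")
        paste(ifelse(is.na(e$tic_type), "", e$tic_type),
              ifelse(is.na(e$condition), "", e$condition), sep = ":") else ""
      pos <- round(e$onset * rate)
      size <- max(1, round((e$offset - e$onset) * rate))
      lines <- c(lines, sprintf("Mk%d=%s,%s,%d,%d,0", i, type, desc,
                                as.integer(pos), as.integer(size)))
    }
  }
  writeLines(lines, path)
}
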