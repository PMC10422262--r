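#' Read and write multichannel recordings as CSV plus sidecar JSON
#'
#' A recording is stored as a plain CSV (one header row of channel names,
#' one column per channel, one row per sample) with a sidecar JSON holding
#' the sampling rate and channel names, e.g.
#' `{"fs": 250, "channels": ["ch1", ...]}`.
#'
#' @param rec An [mmg_recording()].
#' @param csv_path Path of the CSV file.
#' @param json_path Path of the sidecar JSON; defaults to the CSV path with
#'   a `.json` extension.
#' @return `write_recording_csv` returns `csv_path` invisibly;
#'   `read_recording_csv` returns an `mmg_recording`.
#' @export
write_recording_csv <- function(rec, csv_path,
                                json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(is_recording(rec))
  utils::write.csv(as.data.frame(rec$data), csv_path, row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, channels = rec$channel_names),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(csv_path,
                               json_path = sub("\\.csv$", ".json", csv_path)) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  data <- utils::read.csv(csv_path, check.names = FALSE)
  mmg_recording(as.matrix(data), fs = meta$fs,
                channel_names = meta$channels)
}

#' Read and write segment annotations as JSON
#'
#' Annotations are a JSON list of objects
#' `{"start": int, "end": int, "label": str, "condition": str}` with
#' 0-based half-open sample coordinates into the source recording.
#'
#' @param segments List of [mmg_segment()] objects.
#' @param path JSON file path.
#' @return `write_segments_json` returns `path` invisibly;
#'   `read_segments_json` returns a data frame of annotations (use the
#'   source recording to materialize the excerpts).
#' @export
write_segments_json <- function(segments, path) {
  ann <- lapply(segments, function(s)
    list(start = s$start, end = s$end, label = s$label,
         condition = s$condition))
  jsonlite::write_json(ann, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_segments_json
#' @export
read_segments_json <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(ann)
}

#' Cut annotated segments out of a recording
#'
#' @param rec An [mmg_recording()].
#' @param annotations Data frame with `start`, `end`, `label` and
#'   optionally `condition` (0-based half-open sample coordinates), as
#'   returned by [read_segments_json()].
#' @return List of [mmg_segment()] objects.
#' @export
cut_segments <- function(rec, annotations) {
  stopifnot(is_recording(rec))
  lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    if (a$start < 0 || a$end > nrow(rec$data) || a$start >= a$end)
      stop("annotation ", i, " out of bounds")
    mmg_segment(rec$data[(a$start + 1L):a$end, , drop = FALSE], rec$fs,
                a$label, a$start, a$end,
                if ("condition" %in% names(a)) a$condition else NA_character_)
  })
}

#' Feature-matrix CSV round trip
#'
#' The first column (`label`) holds the class labels; the remaining columns
#' are the named features.
#'
#' @param features An `mmg_features` object.
#' @param path CSV file path.
#' @return `write_features_csv` returns `path` invisibly;
#'   `read_features_csv` returns an `mmg_features` object.
#' @export
write_features_csv <- function(features, path) {
  stopifnot(inherits(features, "mmg_features"))
  df <- data.frame(label = features$y, features$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  structure(list(X = X, y = as.character(df$label), names = colnames(X)),
            class = "mmg_features")
}
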