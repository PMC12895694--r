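# Tabular I/O: TSV readers/writers for the package's data objects and a JSON
# run manifest. Numbers are written with 17 significant digits so round trips
# are lossless at double precision.

.write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- out[[j]]
      s <- trimws(formatC(v, digits = 17, format = "g"))
      s[is.na(v)] <- NA
      out[[j]] <- s
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read a pattern dataset as a single TSV
#'
#' Design columns first, then one column per voxel (`v0001`, ...). The
#' simulation parameters are not serialized; decoding needs only the design
#' and the voxel columns.
#'
#' @param dataset A `pattern_dataset`.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `pattern_dataset` (reader).
#' @export
write_pattern_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  .write_tsv(cbind(dataset$design, as.data.frame(dataset$data)), path)
}

#' @rdname write_pattern_dataset
#' @export
read_pattern_dataset <- function(path) {
  df <- .read_tsv(path)
  vox <- grep("^v[0-9]+$", names(df))
  if (!length(vox)) stop("no voxel columns (v0001, ...) found in ", path)
  design <- df[, -vox, drop = FALSE]
  for (col in c("label_2", "represented_item")) {
    if (col %in% names(design)) design[[col]] <- as.numeric(design[[col]])
  }
  structure(list(design = design,
                 data = as.matrix(df[, vox, drop = FALSE]),
                 params = NULL,
                 conditions = unique(design$condition)),
            class = "pattern_dataset")
}

#' Write / read a behavioral dataset TSV
#'
#' Columns: participant, condition, target_deg, response_deg.
#'
#' @param behavior A `behavioral_dataset` data.frame.
#' @param path File path.
#' @export
write_behavioral_dataset <- function(behavior, path) {
  stopifnot(all(c("participant", "condition", "target_deg",
                  "response_deg") %in% names(behavior)))
  .write_tsv(as.data.frame(behavior), path)
}

#' @rdname write_behavioral_dataset
#' @export
read_behavioral_dataset <- function(path) {
  df <- .read_tsv(path)
  class(df) <- c("behavioral_dataset", "data.frame")
  df
}

#' Write / read decoding score tables
#'
#' @param scores A `decoding_scores` data.frame
#'   ([cross_validated_decode()]) or a `generalization_result`
#'   ([temporal_generalization()]).
#' @param path File path.
#' @export
write_decoding_scores <- function(scores, path) {
  .write_tsv(as.data.frame(scores), path)
}

#' @rdname write_decoding_scores
#' @export
read_decoding_scores <- function(path) {
  df <- .read_tsv(path)
  cls <- if (all(c("train_time", "test_time") %in% names(df))) {
    "generalization_result"
  } else "decoding_scores"
  class(df) <- c(cls, "data.frame")
  df
}

#' Write a JSON run manifest
#'
#' Every command-line invocation records its configuration, seed, package
#' version, timestamp and the MD5 digests of its input and output files, so
#' any output can be reproduced from its manifest.
#'
#' @param path Manifest path.
#' @param config Named list with the run configuration.
#' @param seed Master seed of the run.
#' @param inputs,outputs Character vectors of file paths to digest.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, seed, inputs = character(),
                               outputs = character()) {
  digest <- function(files) {
    files <- files[file.exists(files)]
    if (!length(files)) return(NULL)
    md5 <- tools::md5sum(files)
    as.list(stats::setNames(unname(md5), basename(files)))
  }
  manifest <- list(
    schema_version = 1L,
    package = "psvrcap",
    version = as.character(packageVersion("psvrcap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    inputs = digest(inputs),
    outputs = digest(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
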