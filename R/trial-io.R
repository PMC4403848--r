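## On-disk trial format: a plain-text columnar CSV with one row per
## (channel, sample) and a single header comment line declaring the
## sampling rate and TUG distance.  Ground truth travels in a JSON
## sidecar.

.TRIAL_MAGIC <- "# tugseg-trial v1"

#' Write a trial recording to a columnar CSV file
#'
#' Columns: \code{subject_id}, \code{trial_id}, \code{site},
#' \code{quantity}, \code{axis}, \code{sample_index} (0-based),
#' \code{value}.  The first line is a comment declaring the format
#' version, sampling rate and distance.  The file round-trips through
#' \code{\link{readTrial}} losslessly (values to better than 1e-9).
#'
#' @param trial A \linkS4class{TugRecording}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTrial <- function(trial, path) {
  if (!is(trial, "TugRecording")) stop("'trial' must be a TugRecording")
  if (nrow(trial) == 0L) stop("no channels")
  rd <- rowData(trial)
  vals <- assay(trial, "samples")
  n <- ncol(vals)
  dt <- data.table(
    subject_id = subjectId(trial),
    trial_id = trialId(trial),
    site = rep(rd$site, each = n),
    quantity = rep(rd$quantity, each = n),
    axis = rep(rd$axis, each = n),
    sample_index = rep.int(0:(n - 1L), nrow(vals)),
    value = as.vector(t(vals)))
  header <- sprintf("%s rate_hz=%s distance_m=%s", .TRIAL_MAGIC,
                    format(rateHz(trial), digits = 15),
                    format(distanceM(trial), digits = 15))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  close(con); on.exit()
  fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a trial recording written by \code{writeTrial}
#'
#' @param path Path to a trial CSV file.
#' @return A validated \linkS4class{TugRecording}; orientation
#'   quaternions are renormalized on load.  Channels with inconsistent
#'   sample counts (implying mixed sampling rates) raise an error.
#' @export
readTrial <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, .TRIAL_MAGIC))
    stop("not a tugseg trial file (missing header): ", path)
  kv <- regmatches(first, gregexpr("[a-z_]+=[-0-9.eNA]+", first))[[1]]
  meta <- list()
  for (item in kv) {
    parts <- strsplit(item, "=", fixed = TRUE)[[1]]
    meta[[parts[1]]] <- suppressWarnings(as.numeric(parts[2]))
  }
  if (is.null(meta$rate_hz) || is.na(meta$rate_hz) || meta$rate_hz <= 0)
    stop("trial file header lacks a valid rate_hz")
  dt <- fread(path, skip = 1L, header = TRUE)
  need <- c("subject_id", "trial_id", "site", "quantity", "axis",
            "sample_index", "value")
  if (!all(need %in% names(dt)))
    stop("trial file lacks required columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  key <- paste(dt$site, dt$quantity, dt$axis, sep = ".")
  counts <- table(key)
  if (length(unique(counts)) != 1L)
    stop("mixed sample counts across channels (mixed sampling rates?)")
  n <- unname(counts[1])
  ukey <- unique(key)
  values <- matrix(NA_real_, nrow = length(ukey), ncol = n)
  ord <- order(match(key, ukey), dt$sample_index)
  values[] <- matrix(dt$value[ord], nrow = length(ukey), byrow = TRUE)
  parts <- do.call(rbind, strsplit(ukey, ".", fixed = TRUE))
  channels <- data.frame(site = parts[, 1], quantity = parts[, 2],
                         axis = parts[, 3], stringsAsFactors = FALSE)
  TugRecording(values, channels, rate_hz = meta$rate_hz,
               subject_id = as.character(dt$subject_id[1]),
               trial_id = as.character(dt$trial_id[1]),
               distance_m = if (is.null(meta$distance_m)) NA_real_
               else meta$distance_m)
}

#' Write / read ground truth as JSON
#'
#' The label sequence is stored run-length encoded to keep the sidecar
#' small.
#'
#' @param truth A \linkS4class{TugGroundTruth}.
#' @param path File path.
#' @return \code{writeGroundTruth}: invisibly, \code{path};
#'   \code{readGroundTruth}: a \linkS4class{TugGroundTruth}.
#' @export
writeGroundTruth <- function(truth, path) {
  r <- rle(truth@labels)
  obj <- list(rate_hz = truth@rateHz,
              transitions = as.list(truth@transitions),
              segments = truth@segments,
              label_values = r$values, label_lengths = r$lengths)
  write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  obj <- read_json(path, simplifyVector = TRUE)
  tr <- unlist(obj$transitions)
  new("TugGroundTruth",
      segments = as.data.frame(obj$segments),
      transitions = tr[transitionNames()],
      labels = inverse.rle(structure(list(values = obj$label_values,
                                          lengths = obj$label_lengths),
                                     class = "rle")),
      rateHz = obj$rate_hz)
}
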