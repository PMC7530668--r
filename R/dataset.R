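# HDF5 dataset store. Layout (documented constants):
#   /short       float32 [1250 x 12 x R]   2.5-s short blocks, mV
#   /long        float32 [5000 x R]        10-s lead II, mV
#   /labels      uint8   [9 x R]           one-hot labels, ECG_CLASSES order
#   /patient_id  string  [R]
#   /recording_id string [R]
#   /segment_index int32 [R]
#   /window_index  int32 [R]
# Samples are stored as 32-bit floats; reading a store back is
# bit-exact with respect to what is stored.

#' Assemble standard records into an in-memory dataset
#'
#' @param records List of `standard_record` objects (may be empty).
#' @return An `ecg_dataset`: list with arrays `short` (1250 x 12 x R),
#'   `long` (5000 x R), `labels` (9 x R), and provenance vectors.
#' @export
dataset_from_records <- function(records) {
  R <- length(records)
  short <- array(0, c(WIN_SAMPLES, 12L, R))
  long <- matrix(0, SEG_SAMPLES, R)
  labels <- matrix(0L, 9L, R)
  pid <- rid <- character(R); seg <- win <- integer(R)
  for (i in seq_len(R)) {
    r <- records[[i]]
    if (!inherits(r, "standard_record")) stopf("element %d is not a standard_record", i)
    short[, , i] <- t(r$short)
    long[, i] <- r$long
    labels[, i] <- r$labels
    pid[i] <- r$patient_id; rid[i] <- r$recording_id
    seg[i] <- r$segment_index; win[i] <- r$window_index
  }
  structure(list(short = short, long = long, labels = labels,
                 patient_id = pid, recording_id = rid,
                 segment_index = seg, window_index = win, n = R),
            class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  cat(sprintf("<ecg_dataset> %d standard records from %d patients\n",
              x$n, length(unique(x$patient_id))))
  invisible(x)
}

#' Number of records in a dataset
#' @param x An `ecg_dataset`.
#' @param ... Unused.
#' @export
length.ecg_dataset <- function(x) x$n

#' Subset a dataset by record index
#' @param x An `ecg_dataset`.
#' @param i Integer or logical index over records.
#' @export
`[.ecg_dataset` <- function(x, i) {
  structure(list(short = x$short[, , i, drop = FALSE],
                 long = x$long[, i, drop = FALSE],
                 labels = x$labels[, i, drop = FALSE],
                 patient_id = x$patient_id[i], recording_id = x$recording_id[i],
                 segment_index = x$segment_index[i],
                 window_index = x$window_index[i],
                 n = length(x$patient_id[i])),
            class = "ecg_dataset")
}

#' Recover the list-of-records view of a dataset
#' @param ds An `ecg_dataset`.
#' @return List of `standard_record` objects.
#' @export
as_standard_records <- function(ds) {
  stopifnot(inherits(ds, "ecg_dataset"))
  lapply(seq_len(ds$n), function(i) {
    structure(list(short = t(ds$short[, , i]),
                   long = ds$long[, i],
                   labels = setNames(as.integer(ds$labels[, i]), ECG_CLASSES),
                   patient_id = ds$patient_id[i],
                   recording_id = ds$recording_id[i],
                   segment_index = ds$segment_index[i],
                   window_index = ds$window_index[i]),
              class = "standard_record")
  })
}

#' Write a dataset to an HDF5 store
#'
#' Samples are stored as 32-bit floats, labels as 8-bit integers;
#' layout is documented at the top of the module. An existing file at
#' `path` is overwritten.
#'
#' @param ds An `ecg_dataset` or list of `standard_record`s.
#' @param path Output `.h5` file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  if (!inherits(ds, "ecg_dataset")) ds <- dataset_from_records(ds)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5 <- function(name, data, type = NULL, dims = dim(data) %||% length(data)) {
    if (!is.null(type)) {
      rhdf5::h5createDataset(path, name, dims = dims, H5type = type)
      rhdf5::h5write(data, path, name)
    } else rhdf5::h5write(data, path, name)
  }
  # float32 samples: round-trip through float32 so in-memory object
  # matches what a reader will see
  h5("short", ds$short, "H5T_IEEE_F32LE")
  h5("long", ds$long, "H5T_IEEE_F32LE")
  h5("labels", ds$labels, "H5T_STD_U8LE")
  rhdf5::h5write(ds$patient_id, path, "patient_id")
  rhdf5::h5write(ds$recording_id, path, "recording_id")
  rhdf5::h5write(as.integer(ds$segment_index), path, "segment_index")
  rhdf5::h5write(as.integer(ds$window_index), path, "window_index")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a dataset from an HDF5 store
#'
#' @param path Path to a store written by [write_dataset()].
#' @return An `ecg_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  names <- tryCatch(rhdf5::h5ls(path)$name, error = function(e)
    stopf("not a readable HDF5 store: %s", path))
  need <- c("short", "long", "labels", "patient_id", "recording_id",
            "segment_index", "window_index")
  miss <- setdiff(need, names)
  if (length(miss)) stopf("store is missing dataset(s): %s", paste(miss, collapse = ", "))
  g <- function(n) rhdf5::h5read(path, n)
  short <- g("short"); long <- g("long"); labels <- g("labels")
  on.exit(rhdf5::h5closeAll())
  if (length(dim(short)) != 3L || dim(short)[1] != WIN_SAMPLES ||
      dim(short)[2] != 12L)
    stopf("malformed 'short' dataset: dims %s", paste(dim(short), collapse = "x"))
  if (nrow(labels) != 9L) stopf("malformed 'labels' dataset: %d rows", nrow(labels))
  R <- dim(short)[3]
  if (ncol(long) != R || ncol(labels) != R)
    stopf("store dimension mismatch across datasets")
  structure(list(short = short, long = as.matrix(long),
                 labels = matrix(as.integer(labels), 9L, R),
                 patient_id = as.character(g("patient_id")),
                 recording_id = as.character(g("recording_id")),
                 segment_index = as.integer(g("segment_index")),
                 window_index = as.integer(g("window_index")), n = R),
            class = "ecg_dataset")
}
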