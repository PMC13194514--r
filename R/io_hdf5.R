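# On-disk epoch containers.
#
# The native container is a self-describing HDF5 file with a single `data`
# dataset in [trials x channels x samples] order and the sampling metadata
# (`fs`, `cue`, `subject_id`, `t0`) as attributes of that dataset. EEGLAB
# `.set` files saved in the MAT v7.3 dialect (which is HDF5) are supported
# read-only; the classic MAT v5 dialect is not.

#' Save an epoch set to an HDF5 container
#'
#' @param es An [epoch_set()].
#' @param path Destination file path (overwritten if present).
#' @param format Only `"hdf5"` is supported for writing.
#' @return Invisibly, `path`.
#' @export
save_epochs <- function(es, path, format = c("hdf5")) {
  format <- match.arg(format)
  stopifnot(inherits(es, "epoch_set"))
  if (!dir.exists(dirname(path))) {
    stop_contract("cannot write epochs: directory does not exist: %s", dirname(path))
  }
  if (file.exists(path)) file.remove(path)
  h5f <- tryCatch(rhdf5::H5Fcreate(path),
                  error = function(e) stop_contract("cannot create '%s': %s", path,
                                                    conditionMessage(e)))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5writeDataset(es$data, h5f, "data")
  h5d <- rhdf5::H5Dopen(h5f, "data")
  rhdf5::h5writeAttribute(es$fs, h5d, "fs")
  rhdf5::h5writeAttribute(es$cue, h5d, "cue")
  rhdf5::h5writeAttribute(es$subject_id, h5d, "subject_id")
  rhdf5::h5writeAttribute(es$t0, h5d, "t0")
  rhdf5::H5Dclose(h5d)
  invisible(path)
}

#' Load an epoch set from disk
#'
#' Reads either the package's native HDF5 container (written by
#' [save_epochs()]) or an epoched EEGLAB `.set` file in the MAT v7.3
#' (HDF5-based) dialect. Data are returned in
#' `[trials x channels x samples]` order regardless of the on-disk layout.
#'
#' @param path File path.
#' @param format `"hdf5"` or `"eeglab_set"`.
#' @param cue Cue condition to record on the returned object when the file
#'   does not carry one (EEGLAB files); default `"hcue"`.
#' @param subject_id Subject id override for EEGLAB files lacking one.
#' @return An [epoch_set()].
#' @export
load_epochs <- function(path, format = c("hdf5", "eeglab_set"),
                        cue = "hcue", subject_id = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_contract("epoch file not found: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  if (format == "hdf5") {
    data <- rhdf5::h5read(path, "data")
    at <- rhdf5::h5readAttributes(path, "data")
    for (a in c("fs", "cue", "subject_id", "t0")) {
      if (is.null(at[[a]])) stop_contract("HDF5 container misses attribute '%s'", a)
    }
    if (length(dim(data)) != 3L) {
      stop_contract("dataset 'data' is not a 3-d [trials x channels x samples] array")
    }
    return(epoch_set(data, fs = as.numeric(at$fs), cue = as.character(at$cue),
                     subject_id = as.integer(at$subject_id), t0 = as.numeric(at$t0)))
  }
  load_eeglab_set(path, cue = cue, subject_id = subject_id)
}

# EEGLAB .set, MAT v7.3 dialect: workspace variables live under the HDF5
# root; the EEG struct is the group /EEG with fields as datasets. MATLAB's
# EEG.data is [nbchan x pnts x trials]; HDF5 stores dimensions reversed, and
# rhdf5 reverses them again on read, so the array arrives in MATLAB order.
load_eeglab_set <- function(path, cue, subject_id) {
  contents <- tryCatch(rhdf5::h5ls(path), error = function(e) {
    stop_contract(paste0("cannot read '%s' as a MAT v7.3 (HDF5) EEGLAB file: %s. ",
                         "Classic MAT v5 .set files are not supported."),
                  path, conditionMessage(e))
  })
  root <- if (any(contents$group == "/EEG" | contents$name == "EEG")) "/EEG" else "/"
  get_field <- function(name) {
    sel <- contents$group == root & contents$name == name
    if (!any(sel)) stop_contract("EEGLAB file misses field '%s'", name)
    rhdf5::h5read(path, paste(sub("/$", "", root), name, sep = "/"))
  }
  nbchan <- as.integer(get_field("nbchan"))[1L]
  pnts <- as.integer(get_field("pnts"))[1L]
  trials <- as.integer(get_field("trials"))[1L]
  srate <- as.numeric(get_field("srate"))[1L]
  xmin <- as.numeric(get_field("xmin"))[1L]
  data <- get_field("data")
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  perm <- match(c(trials, nbchan, pnts), d)
  if (anyNA(perm) || anyDuplicated(perm[!is.na(perm)])) {
    # ambiguous sizes: assume MATLAB [chan x pnts x trials] order
    perm <- c(3L, 1L, 2L)
  }
  if (prod(d) != as.double(trials) * nbchan * pnts) {
    stop_contract("EEGLAB data dimensions %s disagree with nbchan=%d, pnts=%d, trials=%d",
                  paste(d, collapse = "x"), nbchan, pnts, trials)
  }
  data <- aperm(data, perm)
  epoch_set(data, fs = srate, cue = cue, subject_id = subject_id, t0 = xmin)
}

#' Save a continuous recording to HDF5
#'
#' Stores the `[channels x samples]` data matrix with `fs` as an attribute
#' and the event table under the `events` group.
#'
#' @param x A [continuous_eeg()].
#' @param path Destination file path (overwritten if present).
#' @return Invisibly, `path`.
#' @export
save_continuous <- function(x, path) {
  stopifnot(inherits(x, "continuous_eeg"))
  if (file.exists(path)) file.remove(path)
  h5f <- rhdf5::H5Fcreate(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5writeDataset(x$data, h5f, "data")
  h5d <- rhdf5::H5Dopen(h5f, "data")
  rhdf5::h5writeAttribute(x$fs, h5d, "fs")
  rhdf5::H5Dclose(h5d)
  rhdf5::h5createGroup(h5f, "events")
  rhdf5::h5writeDataset(as.integer(x$events$sample), h5f, "events/sample")
  rhdf5::h5writeDataset(as.character(x$events$cue), h5f, "events/cue")
  invisible(path)
}

#' Load a continuous recording from HDF5
#'
#' @param path File written by [save_continuous()].
#' @return A [continuous_eeg()].
#' @export
load_continuous <- function(path) {
  if (!file.exists(path)) stop_contract("continuous recording not found: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  data <- rhdf5::h5read(path, "data")
  at <- rhdf5::h5readAttributes(path, "data")
  if (is.null(at$fs)) stop_contract("continuous container misses attribute 'fs'")
  events <- data.frame(
    sample = as.integer(rhdf5::h5read(path, "events/sample")),
    cue = as.character(rhdf5::h5read(path, "events/cue"))
  )
  continuous_eeg(data, fs = as.numeric(at$fs), events = events)
}
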