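#' EEG trial of differential-entropy features
#'
#' Bundles one trial's DE feature sequence with its emotion label and
#' subject/session identity. Features are stored as an `L x N x F_de` array:
#' `L` one-second samples, `N` channels, `F_de` frequency bands. DE values
#' are in nats (for a band-limited Gaussian segment, DE = 1/2 log(2*pi*e*s^2)).
#'
#' @param features numeric array `L x N x F_de`, all finite.
#' @param label integer emotion class id (>= 0).
#' @param subject_id,session_id non-empty strings identifying the recording.
#' @param channel_names character vector of length `N`; defaults to
#'   `CH1..CHN`.
#' @return An object of class `trial_features`.
#' @export
trial_features <- function(features, label, subject_id, session_id = "1",
                           channel_names = NULL) {
  features <- as.array(features)
  if (length(dim(features)) != 3L) {
    stop("features must be an L x N x F_de array", call. = FALSE)
  }
  if (dim(features)[1] < 1L) stop("L must be >= 1", call. = FALSE)
  stopifnot_finite(features, "trial features")
  N <- dim(features)[2]
  if (is.null(channel_names)) channel_names <- paste0("CH", seq_len(N))
  if (length(channel_names) != N) {
    stop("channel_names length must equal the number of channels", call. = FALSE)
  }
  label <- as.integer(label)
  if (is.na(label) || label < 0L) stop("label must be an integer >= 0", call. = FALSE)
  if (!nzchar(subject_id)) stop("subject_id must be non-empty", call. = FALSE)
  structure(
    list(features = features, label = label,
         subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         channel_names = as.character(channel_names)),
    class = "trial_features")
}

#' @export
print.trial_features <- function(x, ...) {
  d <- dim(x$features)
  cat(sprintf("<trial_features> subject %s session %s: L=%d, N=%d, F_de=%d, label=%d\n",
              x$subject_id, x$session_id, d[1], d[2], d[3], x$label))
  invisible(x)
}

#' Dataset container for DE-feature trials
#'
#' A list of [trial_features()] sharing channel count and band count, plus
#' class names and band definitions. This is the unit all protocols and the
#' readers/writers operate on.
#'
#' @param trials list of `trial_features` objects (may be empty if
#'   `n_channels` and `n_bands` are given).
#' @param class_names character vector naming the emotion classes; labels
#'   index into it 0-based.
#' @param n_channels,n_bands required when `trials` is empty; otherwise
#'   inferred and checked.
#' @param band_defs optional list of `c(low, high)` Hz pairs, one per band.
#' @return An object of class `eeg_dataset`.
#' @export
eeg_dataset <- function(trials, class_names, n_channels = NULL,
                        n_bands = NULL, band_defs = NULL) {
  if (length(trials) > 0L) {
    dims <- vapply(trials, function(tr) dim(tr$features)[2:3], integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop("all trials must share n_channels and n_bands", call. = FALSE)
    }
    n_channels <- dims[1, 1]
    n_bands <- dims[2, 1]
    if (any(!nzchar(vapply(trials, `[[`, "", "subject_id")))) {
      stop("subject ids must be non-empty", call. = FALSE)
    }
    labs <- vapply(trials, `[[`, 0L, "label")
    if (any(labs >= length(class_names))) {
      stop("trial label outside the dataset class set", call. = FALSE)
    }
  } else if (is.null(n_channels) || is.null(n_bands)) {
    stop("n_channels and n_bands required for an empty dataset", call. = FALSE)
  }
  structure(
    list(trials = trials, n_channels = as.integer(n_channels),
         n_bands = as.integer(n_bands),
         class_names = as.character(class_names),
         band_defs = band_defs),
    class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  subj <- unique(vapply(x$trials, `[[`, "", "subject_id"))
  cat(sprintf("<eeg_dataset> %d trials, %d subjects, N=%d channels, F_de=%d bands, %d classes\n",
              length(x$trials), length(subj), x$n_channels, x$n_bands,
              length(x$class_names)))
  invisible(x)
}

#' Slice a trial into temporal context windows
#'
#' Each model input is the window `X_i = (X_{i-d}, ..., X_i, ..., X_{i+d})`
#' of `T = 2d + 1` consecutive one-second samples centred at sample `i`.
#' A trial of length `L` yields exactly `L - 2d` windows; the trial-level
#' label is copied to every window (stimulus labels are per trial).
#'
#' @param trial a [trial_features()] object.
#' @param d non-negative integer temporal context coefficient.
#' @param domain `"source"` or `"target"` tag carried by each window.
#' @return List of `window_sample` objects ordered by `center_index`
#'   (0-based, in `[d, L-d-1]`).
#' @export
make_windows <- function(trial, d, domain = c("source", "target"),
                         trial_uid = NULL) {
  domain <- match.arg(domain)
  stopifnot(inherits(trial, "trial_features"))
  d <- as.integer(d)
  if (d < 0L) stop("d must be non-negative", call. = FALSE)
  L <- dim(trial$features)[1]
  if (L <= 2L * d) {
    stop(sprintf("trial too short: L=%d samples cannot form T=2d+1 windows with d=%d",
                 L, d), call. = FALSE)
  }
  lapply(seq.int(d, L - d - 1L), function(i) {
    tensor <- trial$features[(i - d + 1L):(i + d + 1L), , , drop = FALSE]
    structure(
      list(tensor = tensor, center_index = i, label = trial$label,
           domain = domain, subject_id = trial$subject_id,
           trial_uid = trial_uid),
      class = "window_sample")
  })
}

#' Window every trial of a dataset
#'
#' @param dataset an [eeg_dataset()].
#' @param d temporal context coefficient.
#' @param domain domain tag applied to all windows.
#' @return Flat list of `window_sample` objects.
#' @export
dataset_windows <- function(dataset, d, domain = "source") {
  unlist(lapply(seq_along(dataset$trials), function(i) {
    make_windows(dataset$trials[[i]], d = d, domain = domain,
                 trial_uid = sprintf("trial%04d", i))
  }), recursive = FALSE)
}

# ---- serialization ----------------------------------------------------------

# Numbers are written with 17 significant digits so that doubles survive the
# text round trip bit-for-bit.
CONTAINER_SCHEMA_VERSION <- 1L

#' Write a dataset container to disk
#'
#' Serializes the container as a single hierarchical JSON file
#' (subject -> session -> trial; per-trial feature array, label, channel
#' names), with numbers at full double precision so the round trip is
#' lossless. A small JSON sidecar `<path>.meta.json` with class names and
#' band definitions is written alongside.
#'
#' @param container an [eeg_dataset()].
#' @param path output file path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_container <- function(container, path) {
  stopifnot(inherits(container, "eeg_dataset"))
  doc <- list(
    schema = "adstgnn-dataset",
    schema_version = CONTAINER_SCHEMA_VERSION,
    n_channels = container$n_channels,
    n_bands = container$n_bands,
    class_names = container$class_names,
    band_defs = container$band_defs,
    trials = lapply(container$trials, function(tr) {
      list(subject_id = tr$subject_id, session_id = tr$session_id,
           label = tr$label, dim = dim(tr$features),
           channel_names = tr$channel_names,
           features = as.numeric(tr$features))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  meta <- list(class_names = container$class_names,
               band_defs = container$band_defs,
               n_channels = container$n_channels,
               n_bands = container$n_bands)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' Read a dataset container written by [write_container()]
#'
#' @param path file path.
#' @return An [eeg_dataset()].
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  for (field in c("schema", "n_channels", "n_bands", "class_names", "trials")) {
    if (is.null(doc[[field]])) {
      stop(sprintf("container schema mismatch: missing field '%s'", field),
           call. = FALSE)
    }
  }
  if (!identical(doc$schema, "adstgnn-dataset")) {
    stop("container schema mismatch: not an adstgnn dataset file", call. = FALSE)
  }
  trials <- lapply(doc$trials, function(tr) {
    for (field in c("subject_id", "label", "dim", "features")) {
      if (is.null(tr[[field]])) {
        stop(sprintf("container schema mismatch: trial missing field '%s'", field),
             call. = FALSE)
      }
    }
    dm <- as.integer(tr$dim)
    if (dm[2] != doc$n_channels || dm[3] != doc$n_bands) {
      stop(sprintf(
        "container schema mismatch: trial dims (%d channels, %d bands) disagree with metadata (%d, %d)",
        dm[2], dm[3], doc$n_channels, doc$n_bands), call. = FALSE)
    }
    trial_features(array(as.numeric(tr$features), dim = dm),
                   label = tr$label, subject_id = tr$subject_id,
                   session_id = tr$session_id %||% "1",
                   channel_names = unlist(tr$channel_names))
  })
  band_defs <- if (is.null(doc$band_defs)) NULL else {
    lapply(doc$band_defs, as.numeric)
  }
  eeg_dataset(trials, class_names = unlist(doc$class_names),
              n_channels = doc$n_channels, n_bands = doc$n_bands,
              band_defs = band_defs)
}
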