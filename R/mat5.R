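# Minimal MAT v5 reader/writer. Covers what the SEED-layout loader needs:
# uncompressed or zlib-compressed numeric arrays (any integer/float storage
# type, read back as double) and character arrays. Writing emits uncompressed
# double arrays only. Little-endian files only (the usual case).

MI_TYPES <- c(INT8 = 1L, UINT8 = 2L, INT16 = 3L, UINT16 = 4L, INT32 = 5L,
              UINT32 = 6L, SINGLE = 7L, DOUBLE = 9L, INT64 = 12L,
              UINT64 = 13L, MATRIX = 14L, COMPRESSED = 15L, UTF8 = 16L)

mi_type_size <- function(type) {
  switch(as.character(type),
         "1" = 1L, "2" = 1L, "3" = 2L, "4" = 2L, "5" = 4L, "6" = 4L,
         "7" = 4L, "9" = 8L, "12" = 8L, "13" = 8L, "16" = 1L,
         stop(sprintf("unsupported MAT data type %d", type), call. = FALSE))
}

read_mi_numeric <- function(raw, type, n) {
  sz <- mi_type_size(type)
  if (type %in% c(7L, 9L)) {
    readBin(raw, "double", n = n, size = sz, endian = "little")
  } else if (type %in% c(12L, 13L)) {
    stop("64-bit integer MAT data is not supported", call. = FALSE)
  } else {
    signed <- type %in% c(1L, 3L, 5L)
    readBin(raw, "integer", n = n, size = sz, signed = signed || sz == 4L,
            endian = "little")
  }
}

# Parses one data element starting at offset `pos` (1-based) in `buf`.
# Returns list(type, data_raw, next_pos).
parse_element <- function(buf, pos) {
  tag <- readBin(buf[pos:(pos + 7L)], "integer", n = 2L, size = 4L,
                 endian = "little")
  type <- tag[1]
  if (type %/% 65536L != 0L) {
    # small data element: upper 16 bits hold byte count, data in tag bytes 5-8
    nbytes <- type %/% 65536L
    type <- type %% 65536L
    data <- buf[(pos + 4L):(pos + 3L + nbytes)]
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  nbytes <- tag[2]
  data <- if (nbytes > 0L) buf[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
  adv <- 8L + nbytes
  if (type != MI_TYPES[["COMPRESSED"]]) adv <- adv + (-nbytes %% 8L)
  list(type = type, data = data, next_pos = pos + adv)
}

parse_matrix <- function(raw_el) {
  p <- 1L
  flags_el <- parse_element(raw_el, p); p <- flags_el$next_pos
  flags <- readBin(flags_el$data, "integer", n = 2L, size = 4L, endian = "little")
  class_id <- flags[1] %% 256L
  dims_el <- parse_element(raw_el, p); p <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) %/% 4L,
                  size = 4L, endian = "little")
  name_el <- parse_element(raw_el, p); p <- name_el$next_pos
  name <- rawToChar(name_el$data)
  data_el <- parse_element(raw_el, p)
  n <- prod(dims)
  if (class_id == 4L) {  # mxCHAR
    vals <- read_mi_numeric(data_el$data, data_el$type, n)
    value <- intToUtf8(vals, multiple = FALSE)
  } else {
    vals <- read_mi_numeric(data_el$data, data_el$type, n)
    value <- array(as.double(vals), dim = dims)
  }
  list(name = name, value = value)
}

#' Read a MAT v5 file (numeric and character arrays)
#'
#' A small self-contained reader for MATLAB level-5 files sufficient for the
#' public SEED "ExtractedFeatures" layout: little-endian files containing
#' numeric arrays (any storage type, returned as double arrays) and character
#' arrays; zlib-compressed elements are supported. Cell arrays, structs,
#' sparse and complex data are not.
#'
#' @param path file path.
#' @return Named list of arrays/strings.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 128L) stop("not a MAT v5 file (truncated header)", call. = FALSE)
  endian <- rawToChar(buf[127:128])
  if (endian != "IM") {
    stop("unsupported MAT file (not little-endian v5)", call. = FALSE)
  }
  pos <- 129L
  out <- list()
  while (pos + 7L <= length(buf)) {
    el <- parse_element(buf, pos)
    pos <- el$next_pos
    payload <- el$data
    type <- el$type
    if (type == MI_TYPES[["COMPRESSED"]]) {
      payload <- memDecompress(payload, type = "gzip")
      inner <- parse_element(payload, 1L)
      type <- inner$type
      payload <- inner$data
    }
    if (type != MI_TYPES[["MATRIX"]]) next
    m <- tryCatch(parse_matrix(payload), error = function(e) NULL)
    if (!is.null(m)) out[[m$name]] <- m$value
  }
  out
}

write_mi_element <- function(con, type, data_raw) {
  writeBin(c(type, length(data_raw)), con, size = 4L, endian = "little")
  writeBin(data_raw, con)
  pad <- -length(data_raw) %% 8L
  if (pad > 0L) writeBin(raw(pad), con)
}

#' Write a MAT v5 file of double arrays
#'
#' Counterpart of [read_mat5()]; writes each element of `vars` (numeric
#' vector/matrix/array) as an uncompressed double array.
#'
#' @param vars named list of numeric arrays.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  stopifnot(length(names(vars)) == length(vars), all(nzchar(names(vars))))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by adstgnn"))
  header <- c(header, raw(116L - length(header)))
  writeBin(header, con)
  writeBin(raw(8L), con)                                   # subsys offset
  writeBin(as.raw(c(0x00, 0x01)), con)                     # version 0x0100
  writeChar("IM", con, eos = NULL)                         # endian indicator
  for (nm in names(vars)) {
    v <- vars[[nm]]
    dims <- dim(v) %||% c(1L, length(v))
    if (length(dims) == 1L) dims <- c(1L, dims)
    body <- rawConnection(raw(0), "wb")
    # array flags: class mxDOUBLE (6)
    flags_raw <- writeBin(c(6L, 0L), raw(), size = 4L, endian = "little")
    write_mi_element(body, MI_TYPES[["UINT32"]], flags_raw)
    dims_raw <- writeBin(as.integer(dims), raw(), size = 4L, endian = "little")
    write_mi_element(body, MI_TYPES[["INT32"]], dims_raw)
    write_mi_element(body, MI_TYPES[["INT8"]], charToRaw(nm))
    data_raw <- writeBin(as.double(v), raw(), size = 8L, endian = "little")
    write_mi_element(body, MI_TYPES[["DOUBLE"]], data_raw)
    payload <- rawConnectionValue(body)
    close(body)
    writeBin(c(MI_TYPES[["MATRIX"]], length(payload)), con, size = 4L,
             endian = "little")
    writeBin(payload, con)
  }
  invisible(path)
}

#' Load a directory in the public SEED precomputed-DE layout
#'
#' Optional convenience loader: a directory of per-subject MAT files, each
#' holding one array per trial named `<feature_prefix><trial>` with shape
#' `N x L x F_de` (SEED: 62 x L x 5), plus a `label.mat` with a `label`
#' vector of per-trial class ids. Labels are shifted so the minimum becomes
#' 0 (SEED uses -1/0/1). Files with a channel count other than 62 are
#' accepted with a warning, taking `N` from the data.
#'
#' @param path directory path.
#' @param feature_prefix trial-array name prefix (default `"de_LDS"`).
#' @param label_file name of the label file inside `path`.
#' @param class_names optional class names; defaults to `class0..classC-1`.
#' @return An [eeg_dataset()].
#' @export
read_seed_layout <- function(path, feature_prefix = "de_LDS",
                             label_file = "label.mat", class_names = NULL) {
  if (!dir.exists(path)) {
    stop(sprintf("no such directory: %s", path), call. = FALSE)
  }
  label_path <- file.path(path, label_file)
  if (!file.exists(label_path)) {
    stop(sprintf("label file not found: %s", label_path), call. = FALSE)
  }
  lab_vars <- read_mat5(label_path)
  if (is.null(lab_vars$label)) {
    stop("label file has no 'label' variable", call. = FALSE)
  }
  labels <- as.integer(round(as.numeric(lab_vars$label)))
  labels <- labels - min(labels)
  files <- setdiff(list.files(path, pattern = "\\.mat$", full.names = FALSE),
                   label_file)
  if (length(files) == 0L) stop("no subject MAT files found", call. = FALSE)
  trials <- list()
  warned_n <- FALSE
  for (f in files) {
    vars <- read_mat5(file.path(path, f))
    keys <- grep(paste0("^", feature_prefix, "[0-9]+$"), names(vars),
                 value = TRUE)
    if (length(keys) == 0L) next
    idx <- as.integer(sub(paste0("^", feature_prefix), "", keys))
    subject <- sub("\\.mat$", "", f)
    for (j in order(idx)) {
      arr <- vars[[keys[j]]]
      if (length(dim(arr)) != 3L) next
      if (dim(arr)[1] != 62L && !warned_n) {
        warning(sprintf("channel count %d differs from the 62-channel SEED montage; using N from data",
                        dim(arr)[1]), call. = FALSE)
        warned_n <- TRUE
      }
      tr_i <- idx[j]
      if (tr_i > length(labels)) {
        stop(sprintf("trial %d has no label (label vector has %d entries)",
                     tr_i, length(labels)), call. = FALSE)
      }
      feats <- aperm(arr, c(2L, 1L, 3L))  # N x L x F -> L x N x F
      trials[[length(trials) + 1L]] <-
        trial_features(feats, label = labels[tr_i], subject_id = subject)
    }
  }
  if (length(trials) == 0L) {
    stop("no trial arrays matching the feature prefix were found", call. = FALSE)
  }
  C <- max(vapply(trials, `[[`, 0L, "label")) + 1L
  if (is.null(class_names)) class_names <- paste0("class", seq_len(C) - 1L)
  eeg_dataset(trials, class_names = class_names)
}
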