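#' @title Minimal MAT v5 container IO
#' @description Reader/writer for the Level-5 MAT container holding the
#'   dataset records. The written dialect stores three top-level numeric
#'   variables per record — `image` (double matrix), `label` (scalar) and
#'   optionally `mask` — uncompressed, little-endian. The reader also
#'   understands files whose record sits inside a `cjdata` struct (the
#'   layout used by the public brain-MRI collection), mapping its
#'   `image` / `label` / `tumorMask` fields onto the package's names and
#'   ignoring unknown fields.
#' @name matio
NULL

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_STRUCT <- 2L; MX_CHAR <- 4L; MX_DOUBLE <- 6L; MX_UINT8 <- 9L

pad8 <- function(n) (8L - n %% 8L) %% 8L

# ---- writing -------------------------------------------------------------

raw_of <- function(writer) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writer(con)
  rawConnectionValue(con)
}

mat_element <- function(type, payload) {
  raw_of(function(con) {
    writeBin(as.integer(c(type, length(payload))), con, size = 4, endian = "little")
    writeBin(payload, con)
    if (pad8(length(payload)) > 0) writeBin(raw(pad8(length(payload))), con)
  })
}

mat_numeric_array <- function(name, values) {
  values <- as.matrix(values)
  flags <- raw_of(function(con) {
    writeBin(as.integer(c(MX_DOUBLE, 0L)), con, size = 4, endian = "little")
  })
  dims <- raw_of(function(con) {
    writeBin(as.integer(dim(values)), con, size = 4, endian = "little")
  })
  data <- raw_of(function(con) {
    writeBin(as.numeric(values), con, size = 8, endian = "little")
  })
  body <- c(
    mat_element(MI_UINT32, flags),
    mat_element(MI_INT32, dims),
    mat_element(MI_INT8, charToRaw(name)),
    mat_element(MI_DOUBLE, data)
  )
  raw_of(function(con) {
    writeBin(as.integer(c(MI_MATRIX, length(body))), con, size = 4, endian = "little")
    writeBin(body, con)
  })
}

write_mat_file <- function(path, vars) {
  header <- charToRaw(sprintf(
    "MATLAB 5.0 MAT-file, Platform: R foxtune, Created on: %s",
    format(Sys.time(), "%Y-%m-%d")))
  header <- c(header, raw(124 - length(header)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(as.integer(256L), con, size = 2, endian = "little")  # version 0x0100
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) {
    writeBin(mat_numeric_array(nm, vars[[nm]]), con)
  }
  invisible(path)
}

# ---- reading -------------------------------------------------------------

# parse one data element starting at offset i (1-based); returns
# list(type, payload_raw, next_i)
read_element <- function(bytes, i) {
  tag1 <- readBin(bytes[i:(i + 3L)], "integer", size = 4, endian = "little")
  small_size <- bitwAnd(bitwShiftR(tag1, 16L), 0xFFFFL)
  type <- bitwAnd(tag1, 0xFFFFL)
  if (small_size > 0L) {  # small element: 4-byte payload slot
    payload <- bytes[(i + 4L):(i + 3L + small_size)]
    return(list(type = type, payload = payload, next_i = i + 8L))
  }
  n <- readBin(bytes[(i + 4L):(i + 7L)], "integer", size = 4, endian = "little")
  payload <- if (n > 0L) bytes[(i + 8L):(i + 7L + n)] else raw(0)
  list(type = type, payload = payload, next_i = i + 8L + n + pad8(n))
}

decode_numeric <- function(type, payload) {
  switch(as.character(type),
    "1" = as.numeric(readBin(payload, "integer", length(payload), 1, signed = TRUE)),
    "2" = as.numeric(readBin(payload, "integer", length(payload), 1, signed = FALSE)),
    "3" = as.numeric(readBin(payload, "integer", length(payload) / 2, 2,
                             signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(payload, "integer", length(payload) / 2, 2,
                             signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(payload, "integer", length(payload) / 4, 4,
                             endian = "little")),
    "6" = as.numeric(readBin(payload, "integer", length(payload) / 4, 4,
                             endian = "little")),
    "7" = readBin(payload, "numeric", length(payload) / 4, 4, endian = "little"),
    "9" = readBin(payload, "numeric", length(payload) / 8, 8, endian = "little"),
    "16" = as.numeric(readBin(payload, "integer", length(payload), 1, signed = FALSE)),
    stop("unsupported MAT data type: ", type, call. = FALSE)
  )
}

# parse a miMATRIX payload into list(name, value) where value is a numeric
# matrix or, for a struct, a named list of numeric matrices
parse_matrix <- function(payload) {
  i <- 1L
  fl <- read_element(payload, i); i <- fl$next_i
  flags_words <- readBin(fl$payload, "integer", 2, 4, endian = "little")
  cls <- bitwAnd(flags_words[1], 0xFFL)
  dm <- read_element(payload, i); i <- dm$next_i
  dims <- readBin(dm$payload, "integer", length(dm$payload) / 4, 4, endian = "little")
  nm <- read_element(payload, i); i <- nm$next_i
  name <- rawToChar(nm$payload[nm$payload != as.raw(0)])
  if (cls == MX_STRUCT) {
    fnl <- read_element(payload, i); i <- fnl$next_i
    field_len <- readBin(fnl$payload, "integer", 1, 4, endian = "little")
    fns <- read_element(payload, i); i <- fns$next_i
    n_fields <- length(fns$payload) / field_len
    field_names <- vapply(seq_len(n_fields), function(f) {
      chunk <- fns$payload[((f - 1L) * field_len + 1L):(f * field_len)]
      rawToChar(chunk[chunk != as.raw(0)])
    }, "")
    fields <- list()
    for (f in seq_len(n_fields)) {
      el <- read_element(payload, i); i <- el$next_i
      if (el$type != MI_MATRIX) stop("malformed struct field", call. = FALSE)
      fields[[field_names[f]]] <- parse_matrix(el$payload)$value
    }
    return(list(name = name, value = fields))
  }
  dt <- read_element(payload, i)
  vals <- if (cls == MX_CHAR) {
    rawToChar(as.raw(decode_numeric(dt$type, dt$payload)))
  } else {
    v <- decode_numeric(dt$type, dt$payload)
    if (length(dims) == 2L) matrix(v, dims[1], dims[2]) else array(v, dims)
  }
  list(name = name, value = vals)
}

read_mat_file <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 128L) stop("not a MAT v5 file: ", path, call. = FALSE)
  i <- 129L
  vars <- list()
  while (i + 7L <= length(bytes)) {
    el <- read_element(bytes, i)
    i <- el$next_i
    if (el$type == MI_COMPRESSED) {
      stop("compressed MAT elements are not supported: ", path, call. = FALSE)
    }
    if (el$type != MI_MATRIX) next
    pm <- parse_matrix(el$payload)
    vars[[pm$name]] <- pm$value
  }
  vars
}

# ---- dataset-level IO ----------------------------------------------------

record_from_vars <- function(vars, path) {
  if (!is.null(vars$cjdata)) {
    inner <- vars$cjdata
    vars <- list(image = inner$image, label = inner$label,
                 mask = inner$tumorMask %||% inner$mask)
  }
  if (is.null(vars$image)) {
    stop("MAT container is missing the `image` field: ", path, call. = FALSE)
  }
  if (is.null(vars$label)) {
    stop("MAT container is missing the `label` field: ", path, call. = FALSE)
  }
  img <- vars$image
  structure(
    list(
      image = matrix(as.integer(round(img)), nrow(img), ncol(img)),
      label = as.integer(vars$label[1]),
      mask = if (is.null(vars$mask)) NULL else vars$mask > 0.5
    ),
    class = "dataset_record"
  )
}

#' Write dataset records as MAT containers
#'
#' One file per record (`record_0001.mat`, ...) holding `image`, `label` and
#' — when present — `mask` as numeric arrays, plus a `manifest.csv` listing
#' filename and label. Integer images round-trip bit-exactly.
#'
#' @param records List of `dataset_record`s (from [generate_dataset()] or
#'   [read_dataset()]).
#' @param path Directory to write into (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(records, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- character(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    files[i] <- sprintf("record_%04d.mat", i)
    vars <- list(image = rec$image, label = matrix(as.numeric(rec$label)))
    if (!is.null(rec$mask)) vars$mask <- rec$mask * 1
    write_mat_file(file.path(path, files[i]), vars)
  }
  manifest <- data.frame(
    filename = files,
    label = vapply(records, function(r) as.integer(r$label), 0L)
  )
  utils::write.csv(manifest, file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a directory of MAT dataset records
#'
#' Reads every `.mat` file (in manifest order when a `manifest.csv` is
#' present, otherwise sorted). A container missing its `image` or `label`
#' field raises a parse error naming the field and file.
#'
#' @param path Directory written by [write_dataset()] or holding compatible
#'   containers.
#' @return A list of `dataset_record`s.
#' @export
read_dataset <- function(path) {
  manifest <- file.path(path, "manifest.csv")
  files <- if (file.exists(manifest)) {
    utils::read.csv(manifest)$filename
  } else {
    sort(list.files(path, pattern = "\\.mat$"))
  }
  lapply(files, function(f) {
    fp <- file.path(path, f)
    record_from_vars(read_mat_file(fp), fp)
  })
}

#' Export dataset records as 8-bit grayscale PNG files
#'
#' @param records List of `dataset_record`s with integer images in
#'   `[0, 255]`.
#' @param path Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_dataset_png <- function(records, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- vapply(seq_along(records), function(i) {
    f <- file.path(path, sprintf("record_%04d_class%d.png",
                                 i, records[[i]]$label))
    png::writePNG(records[[i]]$image / 255, f)
    f
  }, "")
  invisible(files)
}
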