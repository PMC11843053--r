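## WeightSet: the unit exchanged between stations and the aggregation server.
## Values live on the float32 grid (see float32()) so that the on-disk 4-byte
## container is a bit-exact round trip of the in-memory object.

#' Ordered named model parameter arrays with provenance metadata
#'
#' @slot values Ordered named list of numeric vectors/matrices (float32 grid).
#' @slot meta List with `task_id`, `iteration` (0-based), `origin` (station id
#'   or `"SAS"`), `n_train_samples` (local training set size behind these
#'   weights; drives sample-weighted FedAvg).
#' @export
setClass("WeightSet", representation(values = "list", meta = "list"))

setValidity("WeightSet", function(object) {
  msg <- character()
  v <- object@values
  if (!length(v) || is.null(names(v)) || any(!nzchar(names(v))) || anyDuplicated(names(v)))
    msg <- c(msg, "values must be a non-empty uniquely named list")
  if (!all(vapply(v, is.numeric, TRUE))) msg <- c(msg, "all entries must be numeric")
  m <- object@meta
  need <- c("task_id", "iteration", "origin", "n_train_samples")
  if (!all(need %in% names(m))) {
    msg <- c(msg, sprintf("meta must contain %s", paste(need, collapse = ", ")))
  } else {
    if (!isCount(m$iteration, min = 0L)) msg <- c(msg, "meta$iteration must be an integer >= 0")
    if (!isCount(m$n_train_samples, min = 0L)) msg <- c(msg, "meta$n_train_samples must be an integer >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WeightSet
#'
#' Values are quantized onto the float32 grid on construction.
#'
#' @param values Ordered named list of numeric arrays.
#' @param task_id Task identifier (default `""`).
#' @param iteration 0-based federated iteration the weights belong to.
#' @param origin `"SAS"` or a station id.
#' @param n_train_samples Local training-set size behind these weights.
#' @return A [WeightSet-class].
#' @export
weightSet <- function(values, task_id = "", iteration = 0L, origin = "SAS",
                      n_train_samples = 0L) {
  new("WeightSet", values = lapply(values, float32),
      meta = list(task_id = as.character(task_id),
                  iteration = as.integer(iteration),
                  origin = as.character(origin),
                  n_train_samples = as.integer(n_train_samples)))
}

#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))
#' @export
setGeneric("weightMeta", function(x) standardGeneric("weightMeta"))
#' @export
setGeneric("nParams", function(x) standardGeneric("nParams"))
#' @export
setGeneric("weightManifest", function(x) standardGeneric("weightManifest"))

#' @describeIn WeightSet-class Named list of parameter arrays.
#' @param x A `WeightSet`.
#' @export
setMethod("weightValues", "WeightSet", function(x) x@values)
#' @describeIn WeightSet-class Provenance metadata list.
#' @export
setMethod("weightMeta", "WeightSet", function(x) x@meta)
#' @describeIn WeightSet-class Total parameter count.
#' @export
setMethod("nParams", "WeightSet", function(x) sum(vapply(x@values, length, 0L)))
#' @describeIn WeightSet-class Manifest: ordered entry names and shapes.
#' @export
setMethod("weightManifest", "WeightSet", function(x) {
  lapply(stats::setNames(x@values, names(x@values)), function(v) {
    d <- dim(v); if (is.null(d)) length(v) else d
  })
})

#' Do two WeightSets share one manifest (entry order and shapes)?
#'
#' @param a,b [WeightSet-class] objects.
#' @return Logical scalar.
#' @export
manifestsMatch <- function(a, b) {
  ma <- weightManifest(a); mb <- weightManifest(b)
  identical(names(ma), names(mb)) &&
    all(mapply(function(x, y) identical(as.integer(x), as.integer(y)), ma, mb))
}

#' Copy a WeightSet with updated metadata
#'
#' @param w A [WeightSet-class].
#' @param ... Any of `task_id`, `iteration`, `origin`, `n_train_samples`.
#' @return A [WeightSet-class] with the same values.
#' @export
updateWeightMeta <- function(w, ...) {
  upd <- list(...)
  bad <- setdiff(names(upd), c("task_id", "iteration", "origin", "n_train_samples"))
  if (length(bad)) fsStop("configError", sprintf("unknown meta fields: %s", paste(bad, collapse = ", ")))
  meta <- modifyList(w@meta, upd)
  meta$iteration <- as.integer(meta$iteration)
  meta$n_train_samples <- as.integer(meta$n_train_samples)
  new("WeightSet", values = w@values, meta = meta)
}

setMethod("show", "WeightSet", function(object) {
  cat(sprintf("WeightSet: %d entries, %d parameters | task '%s', iteration %d, origin %s, n_train_samples %d\n",
              length(object@values), nParams(object), object@meta$task_id,
              object@meta$iteration, object@meta$origin, object@meta$n_train_samples))
})

## ---- .fweights container ----------------------------------------------
## Layout: 4-byte magic "FWTS" | uint32 LE manifest byte length | manifest
## JSON (UTF-8) | little-endian float32 payload. The manifest records entry
## names, shapes, element counts, byte offsets into the payload, the payload
## byte length and a SHA-256 digest of the payload.

FW_MAGIC <- charToRaw("FWTS")

#' Serialize a WeightSet to a digest-protected container file
#'
#' @param w A [WeightSet-class].
#' @param path Output file path (conventionally `.fweights`).
#' @return Invisibly, `path`.
#' @export
serializeWeights <- function(w, path) {
  validObject(w)
  payload <- writeBin(unlist(lapply(w@values, as.vector), use.names = FALSE),
                      raw(), size = 4L, endian = "little")
  counts <- vapply(w@values, length, 0L)
  offsets <- 4L * c(0L, cumsum(counts))[seq_along(counts)]
  entries <- mapply(function(nm, v, off) {
    d <- dim(v); if (is.null(d)) d <- length(v)
    list(name = nm, shape = as.integer(d), n = length(v), offset = off)
  }, names(w@values), w@values, offsets, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  manifest <- list(format = "fweights", version = 1L, dtype = "float32",
                   meta = w@meta, entries = entries,
                   payload_bytes = length(payload),
                   digest = sha256Hex(payload))
  mjson <- charToRaw(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FW_MAGIC, con)
  writeBin(length(mjson), con, size = 4L, endian = "little")
  writeBin(mjson, con)
  writeBin(payload, con)
  invisible(path)
}

#' Deserialize a WeightSet container file
#'
#' Validates the magic, manifest, payload length and SHA-256 digest before any
#' WeightSet is constructed; a corrupt or truncated file never yields a
#' partial object.
#'
#' @param path File written by [serializeWeights()].
#' @return A [WeightSet-class].
#' @export
deserializeWeights <- function(path) {
  if (!file.exists(path)) fsStop("ioError", sprintf("file not found: %s", path))
  blob <- readBin(path, raw(), n = file.size(path))
  if (length(blob) < 8L || !identical(blob[1:4], FW_MAGIC))
    fsStop("formatError", "not a fweights container (bad magic)")
  mlen <- readBin(blob[5:8], "integer", size = 4L, endian = "little")
  if (mlen <= 0L || 8L + mlen > length(blob))
    fsStop("formatError", "corrupt manifest length")
  manifest <- tryCatch(
    jsonlite::fromJSON(rawToChar(blob[9:(8L + mlen)]), simplifyVector = FALSE),
    error = function(e) fsStop("formatError", sprintf("unreadable manifest: %s", conditionMessage(e))))
  if (!identical(manifest$format, "fweights"))
    fsStop("formatError", "manifest is not a fweights manifest")
  if (!identical(manifest$dtype, "float32"))
    fsStop("formatError", sprintf("unknown dtype tag '%s'", manifest$dtype))
  payload <- blob[-(1:(8L + mlen))]
  if (length(payload) != manifest$payload_bytes)
    fsStop("formatError", sprintf("truncated payload: %d bytes present, %d declared",
                                  length(payload), manifest$payload_bytes))
  if (!identical(sha256Hex(payload), manifest$digest))
    fsStop("integrityError", "payload digest mismatch")
  values <- list()
  for (e in manifest$entries) {
    n <- e$n
    off <- e$offset
    v <- readBin(payload[(off + 1L):(off + 4L * n)], "numeric", size = 4L,
                 n = n, endian = "little")
    shape <- as.integer(unlist(e$shape))
    if (prod(shape) != n)
      fsStop("formatError", sprintf("entry %s: shape/count mismatch", e$name))
    if (length(shape) > 1L) dim(v) <- shape
    values[[e$name]] <- v
  }
  m <- manifest$meta
  weightSet(values, task_id = m$task_id, iteration = m$iteration,
            origin = m$origin, n_train_samples = m$n_train_samples)
}
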