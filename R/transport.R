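## In-memory transport: the reference implementation of the "tracks", the
## secured channels every component talks over. Endpoints (coordinator,
## aggregation server) register named handlers; callers issue requests by
## route. Every message is logged with a recursive payload inventory so a
## test can audit, after a whole federation, exactly what kinds of bytes
## left each station — the data-locality contract made checkable.

## Recursive inventory of a payload: S4 class names, list field names, and
## the size of every numeric leaf.
payloadInventory <- function(x, path = "") {
  out <- list()
  if (isVirtualClass(class(x)) || is.null(x)) return(out)
  if (is(x, "PhantomCase")) {
    return(list(list(path = path, kind = "PhantomCase", n = length(x@image))))
  }
  if (is(x, "WeightSet")) {
    return(list(list(path = path, kind = "WeightSet", n = nParams(x))))
  }
  if (isS4(x)) {
    for (sn in slotNames(class(x)))
      out <- c(out, payloadInventory(slot(x, sn), paste0(path, "@", sn)))
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else sprintf("[[%d]]", i)
      out <- c(out, payloadInventory(x[[i]], paste(path, nm, sep = "$")))
    }
    return(out)
  }
  if (is.numeric(x) || is.logical(x))
    return(list(list(path = path, kind = if (!is.null(dim(x))) "numeric_array" else "numeric",
                     n = length(x))))
  if (is.character(x))
    return(list(list(path = path, kind = "character", n = sum(nchar(x)))))
  list(list(path = path, kind = class(x)[1], n = NA_integer_))
}

#' In-memory transport with message instrumentation
#'
#' @field endpoints Named list of handler functions `(route, payload, from)`.
#' @field log List of message records: `from`, `to`, `route`, `inventory`
#'   (recursive payload inventory), `ok`.
#' @field down Named logical: endpoints currently simulated as unreachable.
#' @export InMemoryTransport
#' @exportClass InMemoryTransport
InMemoryTransport <- setRefClass("InMemoryTransport",
  fields = list(endpoints = "list", log = "list", down = "list"),
  methods = list(
    initialize = function(...) {
      endpoints <<- list(); log <<- list(); down <<- list()
      callSuper(...)
    },
    register = function(name, handler) {
      "Attach an endpoint handler function(route, payload, from)."
      endpoints[[name]] <<- handler
      invisible(NULL)
    },
    setDown = function(name, isDown = TRUE) {
      "Simulate an endpoint outage (used for retry/dropout tests)."
      down[[name]] <<- isDown
      invisible(NULL)
    },
    request = function(from, to, route, payload = list()) {
      "Deliver payload to endpoint `to` on `route`; logs the message and
       rethrows any handler condition to the caller."
      rec <- list(from = from, to = to, route = route,
                  inventory = payloadInventory(payload), ok = NA)
      if (isTRUE(down[[to]])) {
        rec$ok <- FALSE
        log[[length(log) + 1L]] <<- rec
        fsStop("transportUnavailable", sprintf("endpoint '%s' is unreachable", to))
      }
      if (is.null(endpoints[[to]]))
        fsStop("transportUnavailable", sprintf("no endpoint '%s' registered", to))
      res <- tryCatch(endpoints[[to]](route, payload, from), error = function(e) e)
      rec$ok <- !inherits(res, "error")
      log[[length(log) + 1L]] <<- rec
      if (inherits(res, "error")) stop(res)
      res
    },
    show = function() {
      cat(sprintf("InMemoryTransport: %d endpoints, %d messages logged\n",
                  length(endpoints), length(log)))
    }
  )
)

#' Audit a transport log for patient-data leakage
#'
#' Scans every logged message for phantom cases, raw image/mask fields, or
#' anonymous numeric arrays large enough to be an image (>= `pixelLimit`
#' elements) outside a WeightSet. Weight containers and JSON-style control
#' scalars are the only numeric payloads a compliant federation produces.
#'
#' @param transport An [InMemoryTransport] instance.
#' @param pixelLimit Numeric-array size treated as image-like (default 1024).
#' @return List with `ok` (logical) and `violations` (data.frame of offending
#'   message index, path and kind).
#' @export
auditTransportLog <- function(transport, pixelLimit = 1024L) {
  viol <- list()
  for (i in seq_along(transport$log)) {
    for (item in transport$log[[i]]$inventory) {
      bad <- item$kind == "PhantomCase" ||
        grepl("(^|[$@])(image|mask|img|msk)$", item$path) ||
        (item$kind == "numeric_array" && !is.na(item$n) && item$n >= pixelLimit)
      if (bad)
        viol[[length(viol) + 1L]] <- data.frame(
          message = i, path = item$path, kind = item$kind, n = item$n)
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol)
  else data.frame(message = integer(), path = character(), kind = character(), n = integer())
  list(ok = nrow(violations) == 0L, violations = violations)
}
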