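## Per-iteration JSON Web Tokens gating every station <-> aggregation-server
## exchange. Compact JWS serialization (header.payload.signature, base64url)
## signed with HMAC-SHA-256 under a per-task symmetric key. A token is bound
## to (station, task, iteration) and expires, so a token captured at one
## iteration is useless at the next.

#' Claims carried by an iteration token
#'
#' @slot station_id Station the token was minted for.
#' @slot task_id Task identifier.
#' @slot iteration 0-based federated iteration the token is valid for.
#' @slot issued_at,expires_at POSIX timestamps (numeric seconds);
#'   `expires_at > issued_at`.
#' @export
setClass("TokenClaims", representation(
  station_id = "character", task_id = "character", iteration = "integer",
  issued_at = "numeric", expires_at = "numeric"
))

setValidity("TokenClaims", function(object) {
  msg <- character()
  if (!isScalarString(object@station_id)) msg <- c(msg, "station_id must be a non-empty string")
  if (!isScalarString(object@task_id)) msg <- c(msg, "task_id must be a non-empty string")
  if (!isCount(object@iteration, min = 0L)) msg <- c(msg, "iteration must be an integer >= 0")
  if (length(object@expires_at) != 1L || length(object@issued_at) != 1L ||
      object@expires_at <= object@issued_at)
    msg <- c(msg, "expires_at must be strictly after issued_at")
  if (length(msg)) msg else TRUE
})

#' Construct token claims
#'
#' @param station_id Station identifier.
#' @param task_id Task identifier.
#' @param iteration 0-based iteration index.
#' @param issued_at Issue time (numeric POSIX seconds; default now).
#' @param lifetime Token lifetime in seconds (default 7200 — twice a typical
#'   iteration wall time).
#' @param expires_at Explicit expiry; overrides `lifetime`.
#' @return A [TokenClaims-class].
#' @export
tokenClaims <- function(station_id, task_id, iteration,
                        issued_at = as.numeric(Sys.time()),
                        lifetime = 7200, expires_at = issued_at + lifetime) {
  obj <- new("TokenClaims", station_id = as.character(station_id),
             task_id = as.character(task_id), iteration = as.integer(iteration),
             issued_at = as.numeric(issued_at), expires_at = as.numeric(expires_at))
  obj
}

setMethod("show", "TokenClaims", function(object) {
  cat(sprintf("TokenClaims: station %s, task %s, iteration %d, valid %.0f..%.0f\n",
              object@station_id, object@task_id, object@iteration,
              object@issued_at, object@expires_at))
})

tokenRejection <- function(kind, msg) {
  stop(structure(
    class = c(kind, "tokenRejection", "fedsegError", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
}

hs256 <- function(msg, key) {
  as.raw(openssl::sha256(charToRaw(msg), key = key))
}

#' Issue a signed per-iteration token
#'
#' @param claims A [TokenClaims-class].
#' @param signing_key Raw vector or string: the per-task symmetric key shared
#'   between coordinator and aggregation server.
#' @return Compact JWT string `header.payload.signature`.
#' @export
issueIterationToken <- function(claims, signing_key) {
  if (missing(signing_key) || is.null(signing_key) || !length(signing_key))
    fsStop("configError", "signing key is missing")
  v <- validObject(claims, test = TRUE)
  if (!isTRUE(v)) fsStop("claimsError", paste(v, collapse = "; "))
  if (is.character(signing_key)) signing_key <- charToRaw(signing_key)
  header <- b64urlEncode(charToRaw(jsonlite::toJSON(
    list(alg = "HS256", typ = "JWT"), auto_unbox = TRUE)))
  payload <- b64urlEncode(charToRaw(jsonlite::toJSON(list(
    sub = claims@station_id, task = claims@task_id, itr = claims@iteration,
    iat = claims@issued_at, exp = claims@expires_at), auto_unbox = TRUE, digits = NA)))
  signingInput <- paste(header, payload, sep = ".")
  sig <- b64urlEncode(hs256(signingInput, signing_key))
  paste(signingInput, sig, sep = ".")
}

#' Validate a per-iteration token
#'
#' Accepts the token iff (in order) the compact structure parses, the HMAC
#' signature verifies under `signing_key`, the station is on the task roster,
#' the task matches, the iteration matches the aggregator's current
#' iteration, and the token is inside its validity window (with `skew`
#' seconds of clock-skew allowance). Every failure raises a typed rejection
#' (`tokenForgery`, `tokenIntegrity`, `tokenReplay`, `tokenExpiry`, all
#' inheriting `tokenRejection`) and has no side effects.
#'
#' @param token Compact JWT string.
#' @param signing_key Per-task symmetric key (raw or string).
#' @param expected_task Task id the receiving server is running.
#' @param expected_iteration Iteration the server is currently accepting.
#' @param known_stations Character vector of rostered station ids.
#' @param now Validation time (numeric POSIX seconds; default now).
#' @param skew Clock-skew allowance in seconds (default 30).
#' @return The verified [TokenClaims-class].
#' @export
validateIterationToken <- function(token, signing_key, expected_task,
                                   expected_iteration, known_stations,
                                   now = as.numeric(Sys.time()), skew = 30) {
  if (is.character(signing_key)) signing_key <- charToRaw(signing_key)
  if (!isScalarString(token)) tokenRejection("tokenForgery", "malformed token")
  parts <- strsplit(token, ".", fixed = TRUE)[[1]]
  if (length(parts) != 3L) tokenRejection("tokenForgery", "malformed token: expected 3 segments")
  sigOk <- tryCatch({
    expected <- hs256(paste(parts[1], parts[2], sep = "."), signing_key)
    rawEqualConst(b64urlDecode(parts[3]), expected)
  }, error = function(e) FALSE)
  if (!sigOk) tokenRejection("tokenForgery", "signature verification failed")
  payload <- tryCatch(
    jsonlite::fromJSON(rawToChar(b64urlDecode(parts[2])), simplifyVector = TRUE),
    error = function(e) NULL)
  need <- c("sub", "task", "itr", "iat", "exp")
  if (is.null(payload) || !all(need %in% names(payload)))
    tokenRejection("tokenForgery", "undecodable or incomplete claims")
  if (!payload$sub %in% known_stations)
    tokenRejection("tokenIntegrity", sprintf("station '%s' is not a known data node", payload$sub))
  if (!identical(as.character(payload$task), as.character(expected_task)))
    tokenRejection("tokenIntegrity", "token was minted for a different task")
  if (!identical(as.integer(payload$itr), as.integer(expected_iteration)))
    tokenRejection("tokenReplay", sprintf(
      "token is for iteration %s but the server is at iteration %s",
      payload$itr, expected_iteration))
  if (now > as.numeric(payload$exp) + skew)
    tokenRejection("tokenExpiry", "token has expired")
  if (now < as.numeric(payload$iat) - skew)
    tokenRejection("tokenExpiry", "token is not yet valid")
  tokenClaims(payload$sub, payload$task, payload$itr,
              issued_at = as.numeric(payload$iat),
              expires_at = as.numeric(payload$exp))
}

#' Generate a fresh random task signing key
#'
#' @param bytes Key length in bytes (default 32).
#' @return Raw vector.
#' @export
newSigningKey <- function(bytes = 32L) openssl::rand_bytes(bytes)
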