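#' @import methods
#' @importFrom stats rnorm runif
#' @importFrom utils write.csv head modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib fedseg, .registration = TRUE
NULL

## Typed condition helpers -----------------------------------------------
## Every refusal in the package carries a condition class so callers (and
## tests) can distinguish e.g. a token replay from an I/O failure.

fsError <- function(class, msg, ...) {
  structure(
    class = c(class, "fedsegError", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
}

fsStop <- function(class, msg, ...) stop(fsError(class, msg, ...))

#' Evaluate an expression with an isolated, fixed RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the generator (Mersenne-Twister /
#' Inversion / Rejection, pinned explicitly so results do not depend on the
#' session's RNG defaults), evaluates `expr`, and restores the previous state.
#' All stochastic package operations route through this so that a fedseg call
#' never perturbs the user's random stream and is reproducible from its own
#' seed alone.
#'
#' @param seed Non-negative integer seed (< 2^31).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    fsStop("configError", "seed must be a single non-negative number")
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

#' Quantize doubles onto the IEEE-754 float32 grid
#'
#' R stores all numerics as doubles; model weights and phantom intensities are
#' nevertheless defined on the single-precision grid so that the 4-byte weight
#' container and float32 NIfTI files round-trip bit-exactly. Quantization is a
#' round trip through 4-byte binary encoding (round-to-nearest-even, as IEEE
#' demands), and is idempotent.
#'
#' @param x Numeric vector, matrix or array.
#' @return Object of the same shape with every value float32-representable.
#' @export
#' @examples
#' float32(pi) == pi          # FALSE: pi is not float32-representable
#' float32(float32(pi)) == float32(pi)  # idempotent
float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.vector(as.numeric(x)), raw(), size = 4L),
               what = "numeric", size = 4L, n = length(x))
  dim(y) <- d
  y
}

## Deterministic derived seeds (kept < 2^31 - 1). Distinct multipliers keep
## the per-purpose streams apart without a real hash.
deriveSeed <- function(seed, a, b = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(a) * 16807 + as.double(b) + 1) %% 2147483629)
}

#' Seed used for a station's local training at one federated iteration
#'
#' Exposed so that an external reference loop (e.g. a centralized-training
#' comparison) can reproduce exactly the minibatch stream a station uses at a
#' given iteration.
#'
#' @param seed Station base seed.
#' @param iteration 0-based federated iteration index.
#' @return Integer seed.
#' @export
iterationSeed <- function(seed, iteration) deriveSeed(seed, 7L, iteration)

## base64url (RFC 7515) over openssl's base64 -----------------------------
b64urlEncode <- function(raw) {
  gsub("=+$", "", chartr("+/", "-_", openssl::base64_encode(raw)))
}

b64urlDecode <- function(txt) {
  txt <- chartr("-_", "+/", txt)
  pad <- (4L - nchar(txt) %% 4L) %% 4L
  openssl::base64_decode(paste0(txt, strrep("=", pad)))
}

## Constant-time-ish raw comparison: always scans the full vectors.
rawEqualConst <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  sum(as.integer(xor(a, b))) == 0L
}

rawToHex <- function(r) paste(as.character(as.raw(unclass(r))), collapse = "")

sha256Hex <- function(raw) rawToHex(openssl::sha256(raw))

isScalarString <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
isCount <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
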