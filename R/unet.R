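## A small 2D U-Net for binary segmentation, implemented directly on base
## matrix algebra (BLAS) with precomputed gather/scatter index maps:
## 3x3 same-padding convolutions via im2col, ReLU, 2x2 max pooling, nearest
## -neighbour upsampling with a following 3x3 convolution, skip concatenation
## and a sigmoid 1x1 head. Feature maps are (batch*pixels) x channels
## matrices in column-major pixel order; all index geometry is cached per
## (rows, cols, batch). The backward pass is hand-derived and pinned by
## finite-difference tests.

#' U-Net model configuration
#'
#' @slot depth Number of encoder/decoder levels (>= 1).
#' @slot base_filters Channels of the first encoder level (>= 1); channel
#'   counts double per level.
#' @slot input_shape Length-2 integer (rows, cols); each must be divisible by
#'   `2^depth`.
#' @slot learning_rate Adam learning rate (> 0).
#' @slot batch_size Minibatch size (>= 1).
#' @slot loss_name `"dice_loss"` (1 - soft Dice) or `"bce_dice"` (equal blend
#'   of binary cross-entropy and soft Dice).
#' @export
setClass("ModelConfig", representation(
  depth = "integer", base_filters = "integer", input_shape = "integer",
  learning_rate = "numeric", batch_size = "integer", loss_name = "character"
))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!isCount(object@depth)) msg <- c(msg, "depth must be an integer >= 1")
  if (!isCount(object@base_filters)) msg <- c(msg, "base_filters must be an integer >= 1")
  s <- object@input_shape
  if (length(s) != 2L || any(s < 4L)) {
    msg <- c(msg, "input_shape must be two dims >= 4")
  } else if (isCount(object@depth) && any(s %% 2L^object@depth != 0L)) {
    msg <- c(msg, sprintf("input dims (%d x %d) must be divisible by 2^depth = %d",
                          s[1], s[2], 2L^object@depth))
  }
  if (length(object@learning_rate) != 1L || object@learning_rate <= 0)
    msg <- c(msg, "learning_rate must be positive")
  if (!isCount(object@batch_size)) msg <- c(msg, "batch_size must be an integer >= 1")
  if (!object@loss_name %in% c("dice_loss", "bce_dice"))
    msg <- c(msg, "loss_name must be 'dice_loss' or 'bce_dice'")
  if (length(msg)) msg else TRUE
})

#' Construct a ModelConfig
#'
#' Defaults give a depth-2, 8-filter U-Net on 64 x 64 inputs (~33k
#' parameters) — small enough to train on one CPU core in minutes while
#' keeping the standard U-Net topology.
#'
#' @param depth Encoder/decoder levels (default 2).
#' @param base_filters First-level channel count (default 8).
#' @param input_shape Image grid rows x cols (default c(64, 64)).
#' @param learning_rate Adam learning rate (default 5e-4; see the vignette
#'   for why larger rates can drop dice-loss training into an absorbing
#'   all-background state after federated averaging).
#' @param batch_size Minibatch size (default 2).
#' @param loss_name Training loss: `"bce_dice"` (default; an equal blend of
#'   binary cross-entropy and soft Dice, robust to sigmoid saturation) or
#'   `"dice_loss"` (pure soft Dice).
#' @return A [ModelConfig-class].
#' @export
modelConfig <- function(depth = 2, base_filters = 8, input_shape = c(64L, 64L),
                        learning_rate = 5e-4, batch_size = 2,
                        loss_name = "bce_dice") {
  new("ModelConfig", depth = as.integer(depth),
      base_filters = as.integer(base_filters),
      input_shape = as.integer(input_shape),
      learning_rate = as.numeric(learning_rate),
      batch_size = as.integer(batch_size),
      loss_name = as.character(loss_name))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: depth %d, base_filters %d, input %dx%d, lr %g, batch %d, loss %s\n",
              object@depth, object@base_filters, object@input_shape[1],
              object@input_shape[2], object@learning_rate, object@batch_size,
              object@loss_name))
})

## ---- index geometry ----------------------------------------------------

.geomCache <- new.env(parent = emptyenv())

## Gather/scatter maps for one resolution and batch size. Feature matrices
## stack the batch sample-major: row (b-1)*npix + p. A single zero row at the
## bottom of the augmented input serves as padding.
geomFor <- function(H, W, B) {
  key <- sprintf("%d_%d_%d", H, W, B)
  if (!is.null(.geomCache[[key]])) return(.geomCache[[key]])
  npix <- H * W
  yy <- rep(seq_len(H), W)
  xx <- rep(seq_len(W), each = H)
  P0 <- matrix(0L, npix, 9L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    k <- k + 1L
    ny <- yy + dy; nx <- xx + dx
    ok <- ny >= 1L & ny <= H & nx >= 1L & nx <= W
    P0[, k] <- ifelse(ok, (nx - 1L) * H + ny, 0L)
  }
  pad <- B * npix + 1L
  P <- do.call(rbind, lapply(seq_len(B) - 1L, function(b)
    ifelse(P0 == 0L, pad, P0 + b * npix)))
  Pflat <- as.vector(P)

  M <- NULL
  if (H %% 2L == 0L && W %% 2L == 0L) {
    Ho <- H %/% 2L; Wo <- W %/% 2L
    oy <- rep(seq_len(Ho), Wo)
    ox <- rep(seq_len(Wo), each = Ho)
    M0 <- cbind((2L * ox - 2L) * H + (2L * oy - 1L),
                (2L * ox - 2L) * H + 2L * oy,
                (2L * ox - 1L) * H + (2L * oy - 1L),
                (2L * ox - 1L) * H + 2L * oy)
    M <- do.call(rbind, lapply(seq_len(B) - 1L, function(b) M0 + b * npix))
  }

  U <- NULL
  if (H %% 2L == 0L && W %% 2L == 0L) {
    npc <- npix %/% 4L
    U0 <- (((xx + 1L) %/% 2L) - 1L) * (H %/% 2L) + ((yy + 1L) %/% 2L)
    U <- unlist(lapply(seq_len(B) - 1L, function(b) U0 + b * npc))
  }

  g <- list(H = H, W = W, B = B, npix = npix, nAll = B * npix, P = P,
            Pflat = Pflat, M = M, U = U)
  .geomCache[[key]] <- g
  g
}

## ---- layer primitives --------------------------------------------------

## Kernel weight matrices are (9*Cin) x Cout with rows ordered channel-major:
## row (c-1)*9 + k holds input channel c at spatial offset k — the column
## layout produced by the compiled im2col gather.
conv3F <- function(X, Wk, b, g) {
  Xa <- rbind(X, 0)
  cols <- .cppIm2col(Xa, g$P)
  Z <- cols %*% Wk
  Z <- Z + rep(b, each = g$nAll)
  list(Z = Z, cols = cols)
}

conv3B <- function(dZ, cols, Wk, g, Cin) {
  dW <- crossprod(cols, dZ)
  db <- colSums(dZ)
  dcols <- dZ %*% t(Wk)                      # nAll x (9*Cin)
  list(dX = .cppCol2im(dcols, g$P), dW = dW, db = db)
}

poolF <- function(X, g) {
  C <- ncol(X)
  nOut <- nrow(g$M)
  Y <- matrix(0, nOut, C)
  AI <- matrix(0L, nOut, C)
  sq <- seq_len(nOut)
  for (c in seq_len(C)) {
    Vm <- matrix(X[as.vector(g$M), c], nOut, 4L)
    arg <- max.col(Vm, ties.method = "first")
    Y[, c] <- Vm[cbind(sq, arg)]
    AI[, c] <- g$M[cbind(sq, arg)]
  }
  list(Y = Y, AI = AI)
}

poolB <- function(dY, AI, nAllIn) {
  C <- ncol(dY)
  dX <- matrix(0, nAllIn, C)
  for (c in seq_len(C)) dX[AI[, c], c] <- dY[, c]
  dX
}

upF <- function(X, g) X[g$U, , drop = FALSE]

upB <- function(dY, g) rowsum(dY, g$U, reorder = TRUE)

## ---- parameter specs and init ------------------------------------------

## Ordered conv layer specification for a config: name, Cin, Cout, kernel.
unetParamSpecs <- function(depth, base_filters) {
  ch <- base_filters * 2L^(seq_len(depth) - 1L)
  specs <- list()
  add <- function(name, cin, cout, kernel = 9L)
    specs[[length(specs) + 1L]] <<- list(name = name, Cin = as.integer(cin),
                                         Cout = as.integer(cout), kernel = kernel)
  for (i in seq_len(depth)) {
    cin <- if (i == 1L) 1L else ch[i - 1L]
    add(sprintf("enc%d.conv1", i), cin, ch[i])
    add(sprintf("enc%d.conv2", i), ch[i], ch[i])
  }
  add("bott.conv1", ch[depth], 2L * ch[depth])
  add("bott.conv2", 2L * ch[depth], 2L * ch[depth])
  for (i in rev(seq_len(depth))) {
    add(sprintf("dec%d.up", i), 2L * ch[i], ch[i])
    add(sprintf("dec%d.conv1", i), 2L * ch[i], ch[i])
    add(sprintf("dec%d.conv2", i), ch[i], ch[i])
  }
  add("head", base_filters, 1L, kernel = 1L)
  specs
}

## Expected flat manifest (name -> shape) for a config; W entries are
## (kernel*Cin) x Cout matrices, b entries length-Cout vectors.
expectedManifest <- function(config) {
  out <- list()
  for (s in unetParamSpecs(config@depth, config@base_filters)) {
    out[[paste0(s$name, ".W")]] <- c(s$kernel * s$Cin, s$Cout)
    out[[paste0(s$name, ".b")]] <- s$Cout
  }
  out
}

#' Initialize U-Net weights
#'
#' He-normal initialization of all convolution kernels (biases zero),
#' deterministic in `seed`. The result carries `iteration = 0` and
#' `origin = "SAS"`: it is the common starting model the aggregation server
#' broadcasts so that every station begins identically.
#'
#' @param config A [ModelConfig-class].
#' @param seed Integer seed.
#' @param task_id Task identifier recorded in the metadata (default `""`).
#' @return A [WeightSet-class].
#' @export
initWeights <- function(config, seed, task_id = "") {
  validObject(config)
  values <- withSeed(deriveSeed(seed, 3L), {
    out <- list()
    for (s in unetParamSpecs(config@depth, config@base_filters)) {
      fanIn <- s$kernel * s$Cin
      out[[paste0(s$name, ".W")]] <- matrix(rnorm(fanIn * s$Cout, 0, sqrt(2 / fanIn)),
                                            fanIn, s$Cout)
      out[[paste0(s$name, ".b")]] <- numeric(s$Cout)
    }
    out
  })
  weightSet(values, task_id = task_id, iteration = 0L, origin = "SAS",
            n_train_samples = 0L)
}

## Flat WeightSet values -> per-layer list(W=, b=) used by forward/backward.
paramsFromValues <- function(values) {
  layers <- unique(sub("\\.(W|b)$", "", names(values)))
  stats::setNames(lapply(layers, function(l)
    list(W = values[[paste0(l, ".W")]], b = values[[paste0(l, ".b")]])), layers)
}

valuesFromParams <- function(params, templateNames) {
  out <- list()
  for (nm in templateNames) {
    l <- sub("\\.(W|b)$", "", nm)
    out[[nm]] <- if (grepl("\\.W$", nm)) params[[l]]$W else params[[l]]$b
  }
  out
}

## Infer (depth, base_filters) from a flat weight manifest.
archFromValues <- function(values) {
  encs <- grep("^enc([0-9]+)\\.conv1\\.W$", names(values), value = TRUE)
  if (!length(encs)) fsStop("weightCompatError", "weights do not describe a U-Net")
  depth <- max(as.integer(sub("^enc([0-9]+).*$", "\\1", encs)))
  base <- ncol(values[["enc1.conv1.W"]])
  list(depth = depth, base_filters = base)
}

## ---- forward / backward ------------------------------------------------

## X: (B*H*W) x 1 input matrix. Returns probability map p, pre-sigmoid z and
## (optionally) the caches needed for the backward pass.
unetForward <- function(params, X, H, W, B, depth, keepCache = FALSE) {
  gs <- lapply(seq_len(depth + 1L), function(i) geomFor(H %/% 2L^(i - 1L), W %/% 2L^(i - 1L), B))
  cache <- list(enc = vector("list", depth), pool = vector("list", depth),
                up = vector("list", depth), dec = vector("list", depth))
  convRelu <- function(X, layer, g) {
    cf <- conv3F(X, params[[layer]]$W, params[[layer]]$b, g)
    A <- cf$Z * (cf$Z > 0)
    list(A = A, Z = cf$Z, cols = cf$cols)
  }
  cur <- X
  skips <- vector("list", depth)
  for (i in seq_len(depth)) {
    c1 <- convRelu(cur, sprintf("enc%d.conv1", i), gs[[i]])
    c2 <- convRelu(c1$A, sprintf("enc%d.conv2", i), gs[[i]])
    skips[[i]] <- c2$A
    pf <- poolF(c2$A, gs[[i]])
    if (keepCache) {
      cache$enc[[i]] <- list(c1 = c1, c2 = c2)
      cache$pool[[i]] <- pf$AI
    }
    cur <- pf$Y
  }
  b1 <- convRelu(cur, "bott.conv1", gs[[depth + 1L]])
  b2 <- convRelu(b1$A, "bott.conv2", gs[[depth + 1L]])
  if (keepCache) cache$bott <- list(b1 = b1, b2 = b2)
  cur <- b2$A
  for (i in rev(seq_len(depth))) {
    upX <- upF(cur, gs[[i]])
    cu <- convRelu(upX, sprintf("dec%d.up", i), gs[[i]])
    cat <- cbind(skips[[i]], cu$A)
    d1 <- convRelu(cat, sprintf("dec%d.conv1", i), gs[[i]])
    d2 <- convRelu(d1$A, sprintf("dec%d.conv2", i), gs[[i]])
    if (keepCache) {
      cache$up[[i]] <- cu
      cache$dec[[i]] <- list(d1 = d1, d2 = d2)
    }
    cur <- d2$A
  }
  z <- cur %*% params$head$W + rep(params$head$b, each = nrow(cur))
  p <- stats::plogis(z)
  if (keepCache) cache$headIn <- cur
  list(p = p, z = z, cache = if (keepCache) cache else NULL, gs = gs)
}

## dz: gradient of the loss wrt the pre-sigmoid logits z. Walks the network
## in reverse (head, decoder fine-to-coarse, bottleneck, encoder
## coarse-to-fine, adding the skip-connection gradients back in) and returns
## per-layer parameter gradients.
unetBackward <- function(params, fw, dz, depth, base_filters) {
  gs <- fw$gs
  cache <- fw$cache
  ch <- base_filters * 2L^(seq_len(depth) - 1L)
  grads <- list()
  convBack <- function(dA, convCache, layer, g) {
    dZ <- dA * (convCache$Z > 0)
    Cin <- nrow(params[[layer]]$W) %/% 9L
    cb <- conv3B(dZ, convCache$cols, params[[layer]]$W, g, Cin)
    grads[[layer]] <<- list(W = cb$dW, b = cb$db)
    cb$dX
  }
  grads$head <- list(W = crossprod(cache$headIn, dz), b = colSums(dz))
  dcur <- dz %*% t(params$head$W)
  dskip <- vector("list", depth)
  for (i in seq_len(depth)) {
    g <- gs[[i]]
    dcur <- convBack(dcur, cache$dec[[i]]$d2, sprintf("dec%d.conv2", i), g)
    dcat <- convBack(dcur, cache$dec[[i]]$d1, sprintf("dec%d.conv1", i), g)
    cs <- ch[i]
    dskip[[i]] <- dcat[, seq_len(cs), drop = FALSE]
    dupA <- dcat[, -seq_len(cs), drop = FALSE]
    dupX <- convBack(dupA, cache$up[[i]], sprintf("dec%d.up", i), g)
    dcur <- upB(dupX, g)
  }
  gB <- gs[[depth + 1L]]
  dcur <- convBack(dcur, cache$bott$b2, "bott.conv2", gB)
  dcur <- convBack(dcur, cache$bott$b1, "bott.conv1", gB)
  for (i in rev(seq_len(depth))) {
    g <- gs[[i]]
    dA2 <- poolB(dcur, cache$pool[[i]], g$nAll) + dskip[[i]]
    dcur <- convBack(dA2, cache$enc[[i]]$c2, sprintf("enc%d.conv2", i), g)
    dcur <- convBack(dcur, cache$enc[[i]]$c1, sprintf("enc%d.conv1", i), g)
  }
  grads
}
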