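test_that("weight initialization is deterministic and seed-sensitive", {
  cfg <- tinyModelConfig()
  w1 <- initWeights(cfg, 1)
  w2 <- initWeights(cfg, 1)
  w3 <- initWeights(cfg, 2)
  expect_identical(weightValues(w1), weightValues(w2))
  expect_true(any(mapply(function(a, b) any(a != b),
                         weightValues(w1), weightValues(w3))))
  expect_equal(weightMeta(w1)$iteration, 0L)
  expect_equal(weightMeta(w1)$origin, "SAS")
  expect_error(modelConfig(depth = 3, input_shape = c(20L, 20L)))
})

test_that("parameter count equals the closed-form architecture count", {
  ## independent sum: two 3x3 convs per encoder level, two bottleneck convs,
  ## per decoder level an up-conv plus two convs, and a 1x1 sigmoid head;
  ## channels double per level. conv params = k*cin*cout + cout.
  closedForm <- function(depth, base) {
    cv <- function(cin, cout, k = 9) k * cin * cout + cout
    ch <- base * 2^(0:(depth - 1))
    total <- 0
    for (i in 1:depth) {
      cin <- if (i == 1) 1 else ch[i - 1]
      total <- total + cv(cin, ch[i]) + cv(ch[i], ch[i])
    }
    total <- total + cv(ch[depth], 2 * ch[depth]) + cv(2 * ch[depth], 2 * ch[depth])
    for (i in depth:1)
      total <- total + cv(2 * ch[i], ch[i]) + cv(2 * ch[i], ch[i]) + cv(ch[i], ch[i])
    total + cv(base, 1, k = 1)
  }
  expect_equal(nParams(initWeights(modelConfig(), 1)), closedForm(2, 8))
  expect_equal(nParams(initWeights(tinyModelConfig(), 1)), closedForm(2, 4))
  expect_equal(nParams(initWeights(modelConfig(depth = 1, base_filters = 2,
                                               input_shape = c(16L, 16L)), 1)),
               closedForm(1, 2))
})

test_that("backpropagation matches central finite differences", {
  depth <- 2; base <- 2; hw <- 16
  cfg <- modelConfig(depth, base, c(hw, hw), batch_size = 1)
  params <- fedseg:::paramsFromValues(weightValues(initWeights(cfg, 42)))
  ## nudge all parameters off zero so no unit sits exactly on a ReLU kink
  set.seed(11)
  params <- lapply(params, function(pl) list(
    W = pl$W + rnorm(length(pl$W), 0, 0.05),
    b = pl$b + rnorm(length(pl$b), 0, 0.05)))
  X <- matrix(runif(hw * hw), ncol = 1)
  g <- as.numeric(runif(hw * hw) > 0.7)
  for (loss in c("dice_loss", "bce_dice")) {
    lossOf <- function(par) {
      fw <- fedseg:::unetForward(par, X, hw, hw, 1L, depth)
      fedseg:::lossAndGradZ(fw$z, fw$p, g, loss)$loss
    }
    fw <- fedseg:::unetForward(params, X, hw, hw, 1L, depth, keepCache = TRUE)
    lg <- fedseg:::lossAndGradZ(fw$z, fw$p, g, loss)
    grads <- fedseg:::unetBackward(params, fw, matrix(lg$dz, ncol = 1), depth, base)
    h <- 1e-6; worst <- 0
    for (l in names(params)) for (part in c("W", "b")) {
      arr <- params[[l]][[part]]
      for (j in sample(length(arr), min(4, length(arr)))) {
        pp <- params; pp[[l]][[part]][j] <- arr[j] + h
        pm <- params; pm[[l]][[part]][j] <- arr[j] - h
        num <- (lossOf(pp) - lossOf(pm)) / (2 * h)
        ana <- grads[[l]][[part]][j]
        worst <- max(worst, abs(num - ana) / max(1e-7, abs(num) + abs(ana)))
      }
    }
    expect_lt(worst, 1e-3)
  }
})

test_that("local training is deterministic, validated, and learns", {
  cfg <- tinyModelConfig()
  cases <- siteCases(tinyCohort(), "s1", "train")
  w0 <- initWeights(cfg, 3)

  ## steps = 0: weights bit-equal, loss reported missing
  r0 <- trainLocal(w0, cases, cfg, steps = 0, seed = 1)
  expect_identical(weightValues(r0$weights), weightValues(w0))
  expect_true(is.na(r0$mean_train_loss))
  expect_equal(weightMeta(r0$weights)$n_train_samples, length(cases))

  ## deterministic mode: identical inputs, identical outputs
  ra <- trainLocal(w0, cases, cfg, steps = 8, seed = 5)
  rb <- trainLocal(w0, cases, cfg, steps = 8, seed = 5)
  expect_identical(weightValues(ra$weights), weightValues(rb$weights))
  expect_identical(ra$step_losses, rb$step_losses)
  expect_false(identical(weightValues(ra$weights),
                         weightValues(trainLocal(w0, cases, cfg, 8, seed = 6)$weights)))

  ## errors
  expect_error(trainLocal(w0, list(), cfg, steps = 2, seed = 1), class = "dataError")
  wrong <- initWeights(modelConfig(depth = 1, base_filters = 2,
                                   input_shape = c(32L, 32L)), 1)
  expect_error(trainLocal(wrong, cases, cfg, steps = 1, seed = 1),
               class = "weightCompatError")

  ## 200 steps on ~20 easy phantoms: aggregate loss improves and segmentation
  ## beats the untrained model on held-out cases
  trainBig <- unlist(lapply(c("s1", "s2", "s3"), function(s)
    siteCases(tinyCohort(), s, "train")), recursive = FALSE)
  r <- trainLocal(w0, trainBig, cfg, steps = 200, seed = 9)
  expect_lt(mean(tail(r$step_losses, 50)), mean(head(r$step_losses, 50)))

  holdout <- siteCases(tinyCohort(), "s2", "validation")[[1]]
  diceTrained <- diceScore(predictMask(r$weights, caseImage(holdout)), caseMask(holdout))
  diceUntrained <- diceScore(predictMask(w0, caseImage(holdout)), caseMask(holdout))
  expect_gt(diceTrained, diceUntrained)
})

test_that("mask prediction is binary, shape-preserving and threshold-faithful", {
  cfg <- tinyModelConfig()
  w <- initWeights(cfg, 4)
  img <- caseImage(siteCases(tinyCohort(), "s1")[[1]])
  m <- predictMask(w, img)
  expect_identical(dim(m), dim(img))
  expect_true(all(m %in% c(0L, 1L)))

  probs <- predictProbabilities(w, img)
  thr <- min(0.999, (max(probs) + 1) / 2)   # strictly above every probability
  expect_true(all(predictMask(w, img, threshold = thr) == 0L))

  expect_error(predictMask(w, img[1:31, ]), class = "dataError")
  expect_error(predictMask(w, img, threshold = 1.5), class = "configError")
})

test_that("Dice identities and symmetry hold exactly", {
  a <- matrix(0L, 8, 8); a[2:3, 2:3] <- 1L        # |A| = 4
  expect_equal(diceScore(a, a), 1)
  b <- matrix(0L, 8, 8); b[6:7, 6:7] <- 1L        # disjoint, |B| = 4
  expect_equal(diceScore(a, b), 0)
  c2 <- matrix(0L, 8, 8); c2[2:3, 3:4] <- 1L      # |A n C| = 2
  expect_equal(diceScore(a, c2), 0.5)             # 2*2 / (4+4)
  expect_equal(diceScore(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)

  set.seed(21)
  for (i in 1:20) {
    x <- matrix(as.integer(runif(64) > 0.6), 8, 8)
    y <- matrix(as.integer(runif(64) > 0.6), 8, 8)
    expect_identical(diceScore(x, y), diceScore(y, x))
  }
  expect_error(diceScore(a, matrix(0L, 4, 4)), class = "dataError")
  bad <- a; bad[1] <- 2L
  expect_error(diceScore(bad, a), class = "dataError")
})
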