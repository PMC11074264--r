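#' Build a CFNN configuration
#'
#' Defaults reproduce the reference architecture: input length 73, Conv1D
#' 64 filters / kernel 5 (same padding) then 32 filters / kernel 3, max-pool
#' 2 (floor), flatten (width 1152), Gaussian fuzzification with 2 rules,
#' batch normalization, dense 2, centre-of-gravity defuzzification and a
#' softmax head; Adam with learning rate 0.01, batch size 256, 100 epochs.
#'
#' @param inputLen input feature count (default 73; extracted 70-feature
#'   tables are right-padded with zeros when `padFeatures` is `TRUE`).
#' @param conv1Filters,conv1Kernel,conv2Filters,conv2Kernel conv shapes.
#' @param poolSize max-pool width.
#' @param nRules fuzzy rules.
#' @param nClasses output classes (must be 2).
#' @param learningRate,batchSize,epochs Adam schedule.
#' @param aggregation fuzzify aggregation (see [fuzzify()]).
#' @param sigmaMin,eps numerical floors for the fuzzy layers.
#' @param bnMomentum,bnEps batch-norm moving-average momentum and variance
#'   guard.
#' @param clipNorm global gradient-norm clip applied before each Adam step
#'   (`Inf` disables); guards against the transient spikes the
#'   defuzzification denominator can produce early in training.
#' @param padFeatures zero-pad narrower inputs up to `inputLen`.
#' @param seed integer seed for initialization and batch shuffling.
#' @return a validated \linkS4class{CFNNConfig}.
#' @export
cfnnConfig <- function(inputLen = 73L, conv1Filters = 64L, conv1Kernel = 5L,
                       conv2Filters = 32L, conv2Kernel = 3L, poolSize = 2L,
                       nRules = 2L, nClasses = 2L, learningRate = 0.01,
                       batchSize = 256L, epochs = 100L,
                       aggregation = "geometric-mean",
                       sigmaMin = 1e-3, eps = 1e-9,
                       bnMomentum = 0.9, bnEps = 1e-3, clipNorm = 5,
                       padFeatures = TRUE, seed = 42L) {
  new("CFNNConfig",
      inputLen = as.integer(inputLen),
      conv1Filters = as.integer(conv1Filters), conv1Kernel = as.integer(conv1Kernel),
      conv2Filters = as.integer(conv2Filters), conv2Kernel = as.integer(conv2Kernel),
      poolSize = as.integer(poolSize), nRules = as.integer(nRules),
      nClasses = as.integer(nClasses), learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      aggregation = as.character(aggregation), sigmaMin = as.numeric(sigmaMin),
      eps = as.numeric(eps), bnMomentum = as.numeric(bnMomentum),
      bnEps = as.numeric(bnEps), clipNorm = as.numeric(clipNorm),
      padFeatures = as.logical(padFeatures), seed = as.integer(seed))
}

# Derived widths: conv layers use same padding, pool uses floor division.
flattenWidth <- function(cfg) {
  (cfg@inputLen %/% cfg@poolSize) * cfg@conv2Filters
}

glorotUniform <- function(fanIn, fanOut, n) {
  lim <- sqrt(6 / (fanIn + fanOut))
  runif(n, -lim, lim)
}

#' Assemble a CFNN with seeded initial weights
#'
#' Layer sequence: conv1 (ReLU) -> conv2 (ReLU) -> max-pool -> flatten ->
#' fuzzify -> batch-norm -> dense -> defuzzify -> softmax. Convolution and
#' dense weights use Glorot-uniform initialization; fuzzy means are
#' `Normal(0, 1)` (matched to the standardized conv activations), sigmas
#' start at 1 via a softplus reparameterization floored at `sigmaMin`, and
#' defuzzification centres are `Normal(0, 0.1)`. All draws come from the
#' config seed, so identical configs build identical models.
#'
#' @param cfg a \linkS4class{CFNNConfig}.
#' @return an untrained \linkS4class{CFNNModel}.
#' @examples
#' m <- buildModel(cfnnConfig())
#' modelSummary(m)
#' @export
buildModel <- function(cfg = cfnnConfig()) {
  stopIfNot(is(cfg, "CFNNConfig"), "cfg must be a CFNNConfig")
  validObject(cfg)
  D <- flattenWidth(cfg)
  params <- withLocalSeed(cfg@seed, {
    k1 <- cfg@conv1Kernel; f1 <- cfg@conv1Filters
    k2 <- cfg@conv2Kernel; f2 <- cfg@conv2Filters
    rho0 <- softplusInv(1 - cfg@sigmaMin)   # sigma starts at exactly 1
    list(
      conv1W = matrix(glorotUniform(k1, f1, k1 * f1), k1, f1),
      conv1b = numeric(f1),
      conv2W = matrix(glorotUniform(k2 * f1, f2, k2 * f1 * f2), k2 * f1, f2),
      conv2b = numeric(f2),
      fuzzyM = matrix(rnorm(D * cfg@nRules), D, cfg@nRules),
      fuzzyRho = matrix(rho0, D, cfg@nRules),
      bnGamma = rep(1, cfg@nRules),
      bnBeta = rep(0, cfg@nRules),
      denseW = matrix(glorotUniform(cfg@nRules, cfg@nClasses,
                                    cfg@nRules * cfg@nClasses),
                      cfg@nRules, cfg@nClasses),
      denseb = numeric(cfg@nClasses),
      defuzzC = matrix(rnorm(cfg@nClasses * cfg@nClasses, 0, 0.1),
                       cfg@nClasses, cfg@nClasses)
    )
  })
  new("CFNNModel", config = cfg, params = params,
      state = list(bnMean = rep(0, cfg@nRules), bnVar = rep(1, cfg@nRules),
                   mu = NULL, sd = NULL, trained = FALSE),
      history = data.frame(epoch = integer(), loss = numeric(),
                           accuracy = numeric()))
}

# ---- layer primitives -------------------------------------------------------
# All activations are [n x length x channels] arrays handled through im2col
# matrix products so BLAS does the heavy lifting.

im2col <- function(X, k) {
  # X: [n, L, C] -> [n*L, k*C] with same (zero) padding, columns ordered
  # channel-major / offset-minor to match the conv weight layout.
  d <- dim(X); n <- d[1]; L <- d[2]; C <- d[3]
  p <- (k - 1L) %/% 2L
  P <- array(0, c(n, L + 2L * p, C))
  P[, p + seq_len(L), ] <- X
  Y <- matrix(0, n * L, k * C)
  for (u in seq_len(k)) {
    s <- P[, u:(u + L - 1L), , drop = FALSE]
    dim(s) <- c(n * L, C)
    Y[, (seq_len(C) - 1L) * k + u] <- s
  }
  Y
}

col2im <- function(dY, n, L, C, k) {
  # adjoint of im2col: scatter-add [n*L, k*C] back to [n, L, C]
  p <- (k - 1L) %/% 2L
  dP <- array(0, c(n, L + 2L * p, C))
  for (u in seq_len(k)) {
    s <- dY[, (seq_len(C) - 1L) * k + u, drop = FALSE]
    dim(s) <- c(n, L, C)
    dP[, u:(u + L - 1L), ] <- dP[, u:(u + L - 1L), , drop = FALSE] + s
  }
  dP[, p + seq_len(L), , drop = FALSE]
}

convForward <- function(X, W, b, k) {
  d <- dim(X); n <- d[1]; L <- d[2]
  Y <- im2col(X, k)
  out <- Y %*% W
  out <- sweep(out, 2, b, "+")
  dim(out) <- c(n, L, length(b))
  list(out = out, cols = Y)
}

convBackward <- function(dOut, cache, W, k, n, L, C) {
  f <- ncol(W)
  dim(dOut) <- c(n * L, f)
  dW <- crossprod(cache$cols, dOut)
  db <- colSums(dOut)
  dY <- dOut %*% t(W)
  dX <- col2im(dY, n, L, C, k)
  list(dX = dX, dW = dW, db = db)
}

# Batched fuzzification: X [n, D] -> strengths [n, R].
fuzzyForward <- function(X, M, Sigma, aggregation) {
  A <- 1 / (2 * Sigma^2)
  e <- (X * X) %*% A - X %*% (2 * M * A) +
    matrix(colSums(M * M * A), nrow(X), ncol(M), byrow = TRUE)
  e <- pmax(e, 0)   # guards tiny negative round-off
  if (aggregation == "geometric-mean") {
    s <- exp(-e / ncol(X))
    list(s = s, e = e, shiftIdx = NULL)
  } else {
    shiftIdx <- max.col(-e, ties.method = "first")
    emin <- e[cbind(seq_len(nrow(e)), shiftIdx)]
    s <- exp(-(e - emin))
    list(s = s, e = e, shiftIdx = shiftIdx)
  }
}

fuzzyBackward <- function(dS, cache, X, M, Sigma, aggregation) {
  n <- nrow(X); Dd <- ncol(X); R <- ncol(M)
  if (aggregation == "geometric-mean") {
    dE <- -cache$s * dS / Dd
  } else {
    dEdirect <- -cache$s * dS
    dE <- dEdirect
    # dE_jstar additionally receives +sum_r s_r dS_r through the shift
    rowAdd <- rowSums(cache$s * dS)
    idx <- cbind(seq_len(n), cache$shiftIdx)
    dE[idx] <- dE[idx] + rowAdd
  }
  IS2 <- 1 / Sigma^2
  dX <- X * (dE %*% t(IS2)) - dE %*% t(M * IS2)
  colsdE <- colSums(dE)
  XtdE <- crossprod(X, dE)                 # D x R
  dM <- IS2 * (M * matrix(colsdE, Dd, R, byrow = TRUE) - XtdE)
  X2tdE <- crossprod(X * X, dE)
  Q <- X2tdE - 2 * M * XtdE + M * M * matrix(colsdE, Dd, R, byrow = TRUE)
  dSigma <- -Q / Sigma^3
  list(dX = dX, dM = dM, dSigma = dSigma)
}

bnForward <- function(X, gamma, beta, state, training, momentum, epsBN) {
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
    state$bnMean <- momentum * state$bnMean + (1 - momentum) * mu
    state$bnVar <- momentum * state$bnVar + (1 - momentum) * v
  } else {
    mu <- state$bnMean
    v <- state$bnVar
  }
  invStd <- 1 / sqrt(v + epsBN)
  xhat <- sweep(sweep(X, 2, mu), 2, invStd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, invStd = invStd, state = state)
}

bnBackward <- function(dOut, cache, gamma) {
  n <- nrow(dOut)
  dGamma <- colSums(dOut * cache$xhat)
  dBeta <- colSums(dOut)
  dXhat <- sweep(dOut, 2, gamma, "*")
  t1 <- sweep(dXhat, 2, colMeans(dXhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dXhat * cache$xhat), "*")
  dX <- sweep(t1 - t2, 2, cache$invStd, "*")
  list(dX = dX, dGamma = dGamma, dBeta = dBeta)
}

defuzzForward <- function(X, C, eps) {
  Dn <- rowSums(X) + eps
  V <- (X %*% t(C)) / Dn
  list(V = V, Dn = Dn)
}

defuzzBackward <- function(dV, cache, X, C) {
  dX <- (dV %*% C - rowSums(dV * cache$V)) / cache$Dn
  dC <- crossprod(dV / cache$Dn, X)
  list(dX = dX, dC = dC)
}

softmaxRows <- function(V) {
  m <- apply(V, 1, max)
  E <- exp(V - m)
  E / rowSums(E)
}

# Full forward pass. X [n, inputLen]; training toggles batch-norm mode and
# moving-statistic updates. Returns activations needed for backprop.
cfnnForward <- function(model, X, training = FALSE) {
  cfg <- model@config; p <- model@params
  n <- nrow(X); L <- cfg@inputLen
  X3 <- array(X, c(n, L, 1L))
  c1 <- convForward(X3, p$conv1W, p$conv1b, cfg@conv1Kernel)
  a1 <- pmax(c1$out, 0)
  c2 <- convForward(a1, p$conv2W, p$conv2b, cfg@conv2Kernel)
  a2 <- pmax(c2$out, 0)
  Lp <- L %/% cfg@poolSize
  keep <- seq_len(Lp * cfg@poolSize)
  # pool width 2 in the default config; general widths via pairwise max
  pooled <- a2[, seq(1, by = cfg@poolSize, length.out = Lp), , drop = FALSE]
  argmax <- array(1L, dim(pooled))
  if (cfg@poolSize > 1L) {
    for (o in 2:cfg@poolSize) {
      cand <- a2[, seq(o, by = cfg@poolSize, length.out = Lp), , drop = FALSE]
      upd <- cand > pooled
      pooled[upd] <- cand[upd]
      argmax[upd] <- o
    }
  }
  flat <- pooled
  dim(flat) <- c(n, Lp * cfg@conv2Filters)
  Sigma <- softplus(p$fuzzyRho) + cfg@sigmaMin
  fz <- fuzzyForward(flat, p$fuzzyM, Sigma, cfg@aggregation)
  bn <- bnForward(fz$s, p$bnGamma, p$bnBeta, model@state, training,
                  cfg@bnMomentum, cfg@bnEps)
  dnPre <- sweep(bn$out %*% p$denseW, 2, p$denseb, "+")
  dn <- softplus(dnPre)  # defuzzification expects nonnegative activations;
                         # softplus keeps them strictly positive with no dead units
  df <- defuzzForward(dn, p$defuzzC, cfg@eps)
  probs <- softmaxRows(df$V)
  list(probs = probs, caches = list(
    X3 = X3, c1 = c1, a1 = a1, c2 = c2, a2 = a2,
    pooledDim = dim(pooled), argmax = argmax, flat = flat,
    Sigma = Sigma, fz = fz, bn = bn, dnPre = dnPre, dn = dn, df = df),
    state = bn$state)
}

# Backward pass from softmax cross-entropy; Y is one-hot [n, nClasses].
cfnnBackward <- function(model, caches, probs, Y) {
  cfg <- model@config; p <- model@params
  n <- nrow(Y); L <- cfg@inputLen
  g <- list()
  dV <- (probs - Y) / n
  dfz <- defuzzBackward(dV, caches$df, caches$dn, p$defuzzC)
  g$defuzzC <- dfz$dC
  dDense <- dfz$dX * sigmoid(caches$dnPre)
  g$denseW <- crossprod(caches$bn$out, dDense)
  g$denseb <- colSums(dDense)
  dBnOut <- dDense %*% t(p$denseW)
  bnb <- bnBackward(dBnOut, caches$bn, p$bnGamma)
  g$bnGamma <- bnb$dGamma
  g$bnBeta <- bnb$dBeta
  fzb <- fuzzyBackward(bnb$dX, caches$fz, caches$flat, p$fuzzyM,
                       caches$Sigma, cfg@aggregation)
  g$fuzzyM <- fzb$dM
  g$fuzzyRho <- fzb$dSigma * sigmoid(p$fuzzyRho)
  dFlat <- fzb$dX
  Lp <- L %/% cfg@poolSize
  dPooled <- dFlat
  dim(dPooled) <- caches$pooledDim
  dA2 <- array(0, dim(caches$a2))
  for (o in seq_len(cfg@poolSize)) {
    mask <- caches$argmax == o
    slice <- array(0, caches$pooledDim)
    slice[mask] <- dPooled[mask]
    dA2[, seq(o, by = cfg@poolSize, length.out = Lp), ] <- slice
  }
  dA2[caches$a2 <= 0] <- 0
  cb2 <- convBackward(dA2, caches$c2, p$conv2W, cfg@conv2Kernel,
                      n, L, cfg@conv1Filters)
  g$conv2W <- cb2$dW
  g$conv2b <- cb2$db
  dA1 <- cb2$dX
  dA1[caches$a1 <= 0] <- 0
  cb1 <- convBackward(dA1, caches$c1, p$conv1W, cfg@conv1Kernel, n, L, 1L)
  g$conv1W <- cb1$dW
  g$conv1b <- cb1$db
  g
}

# ---- training ---------------------------------------------------------------

oneHot <- function(y, nClasses) {
  Y <- matrix(0, length(y), nClasses)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, opt, lr, clipNorm,
                     beta1 = 0.9, beta2 = 0.999, epsAdam = 1e-7) {
  if (is.finite(clipNorm)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gn > clipNorm)
      grads <- lapply(grads, function(g) g * (clipNorm / gn))
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + epsAdam)
  }
  list(params = params, opt = opt)
}

prepareInput <- function(X, cfg) {
  X <- as.matrix(X)
  if (ncol(X) < cfg@inputLen) {
    stopIfNot(cfg@padFeatures,
              sprintf("input has %d features but the model expects %d (enable padFeatures)",
                      ncol(X), cfg@inputLen))
    X <- cbind(X, matrix(0, nrow(X), cfg@inputLen - ncol(X)))
  }
  stopIfNot(ncol(X) == cfg@inputLen,
            sprintf("input has %d features but the model expects %d",
                    ncol(X), cfg@inputLen))
  X
}

standardizeApply <- function(X, mu, sd) {
  sweep(sweep(X, 2, mu), 2, sd, "/")
}

#' Train a CFNN on a feature matrix
#'
#' Standardizes the training features column-wise (constant columns get unit
#' scale), one-hot encodes the binarized labels of the requested emotion
#' dimension, and minimizes categorical cross-entropy with Adam for exactly
#' `epochs` epochs at the configured learning rate and batch size. Batch
#' shuffling and all initialization derive from the config seed, so the
#' per-epoch history and the final weights are reproducible.
#'
#' @param features a \linkS4class{FeatureMatrix}, or a plain numeric matrix
#'   `[n x features]` if `labels` is given.
#' @param dimension `"valence"` or `"arousal"`.
#' @param cfg a \linkS4class{CFNNConfig}.
#' @param trainIdx indices of the training examples (default: all rows);
#'   use [holdoutSplit()] to build a split.
#' @param labels optional explicit 0/1 labels overriding the feature
#'   matrix's own.
#' @return a trained \linkS4class{CFNNModel} whose `history` slot holds the
#'   per-epoch training loss and accuracy.
#' @export
trainModel <- function(features, dimension = c("valence", "arousal"),
                       cfg = cfnnConfig(), trainIdx = NULL, labels = NULL) {
  dimension <- matchDimension(dimension[1])
  if (is(features, "FeatureMatrix")) {
    X <- featureValues(features)
    y <- if (is.null(labels)) featureLabels(features, dimension) else as.integer(labels)
  } else {
    X <- as.matrix(features)
    stopIfNot(!is.null(labels), "labels are required for plain-matrix input")
    y <- as.integer(labels)
  }
  if (is.null(trainIdx)) trainIdx <- seq_len(nrow(X))
  X <- X[trainIdx, , drop = FALSE]
  y <- y[trainIdx]
  stopIfNot(length(unique(y)) >= 2L,
            "training split must contain both classes")
  stopIfNot(min(table(y)) >= 2L,
            "training split needs >= 2 examples per class")
  X <- prepareInput(X, cfg)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  Xs <- standardizeApply(X, mu, sdv)

  model <- buildModel(cfg)
  model@state$mu <- mu
  model@state$sd <- sdv
  Y <- oneHot(y, cfg@nClasses)
  n <- nrow(Xs)
  opt <- adamInit(model@params)
  hist <- data.frame(epoch = seq_len(cfg@epochs), loss = NA_real_,
                     accuracy = NA_real_)
  withLocalSeed(cfg@seed + 1L, {
    for (ep in seq_len(cfg@epochs)) {
      ord <- sample.int(n)
      bStarts <- seq(1L, n, by = cfg@batchSize)
      epLoss <- 0; epCorrect <- 0L
      for (bs in bStarts) {
        idx <- ord[bs:min(bs + cfg@batchSize - 1L, n)]
        fw <- cfnnForward(model, Xs[idx, , drop = FALSE], training = TRUE)
        model@state$bnMean <- fw$state$bnMean
        model@state$bnVar <- fw$state$bnVar
        pb <- pmax(fw$probs, 1e-12)
        epLoss <- epLoss - sum(log(pb[cbind(seq_along(idx), y[idx] + 1L)]))
        epCorrect <- epCorrect +
          sum(max.col(fw$probs, ties.method = "first") - 1L == y[idx])
        grads <- cfnnBackward(model, fw$caches, fw$probs, Y[idx, , drop = FALSE])
        upd <- adamStep(model@params, grads, opt, cfg@learningRate, cfg@clipNorm)
        model@params <- upd$params
        opt <- upd$opt
      }
      hist$loss[ep] <- epLoss / n
      hist$accuracy[ep] <- epCorrect / n
    }
  })
  model@history <- hist
  # recalibrate the batch-norm moving statistics to the exact training-set
  # statistics under the final weights, so evaluation mode matches training
  # regardless of how few optimizer steps the moving averages saw
  model <- recalibrateBN(model, Xs)
  model@state$trained <- TRUE
  model
}

recalibrateBN <- function(model, Xs, chunkSize = 512L) {
  cfg <- model@config; p <- model@params
  n <- nrow(Xs)
  sums <- numeric(cfg@nRules); sqs <- numeric(cfg@nRules)
  for (bs in seq(1L, n, by = chunkSize)) {
    idx <- bs:min(bs + chunkSize - 1L, n)
    X3 <- array(Xs[idx, , drop = FALSE], c(length(idx), cfg@inputLen, 1L))
    a1 <- pmax(convForward(X3, p$conv1W, p$conv1b, cfg@conv1Kernel)$out, 0)
    a2 <- pmax(convForward(a1, p$conv2W, p$conv2b, cfg@conv2Kernel)$out, 0)
    Lp <- cfg@inputLen %/% cfg@poolSize
    pooled <- a2[, seq(1, by = cfg@poolSize, length.out = Lp), , drop = FALSE]
    if (cfg@poolSize > 1L)
      for (o in 2:cfg@poolSize)
        pooled <- pmax(pooled,
                       a2[, seq(o, by = cfg@poolSize, length.out = Lp), ,
                          drop = FALSE])
    flat <- pooled
    dim(flat) <- c(length(idx), Lp * cfg@conv2Filters)
    Sigma <- softplus(p$fuzzyRho) + cfg@sigmaMin
    s <- fuzzyForward(flat, p$fuzzyM, Sigma, cfg@aggregation)$s
    sums <- sums + colSums(s)
    sqs <- sqs + colSums(s * s)
  }
  mu <- sums / n
  model@state$bnMean <- mu
  model@state$bnVar <- pmax(sqs / n - mu^2, 0)
  model
}

#' Forward pass in evaluation mode
#'
#' Applies the stored feature standardization (when the model has been
#' trained) and returns class probabilities; deterministic, batch-norm uses
#' the moving statistics.
#'
#' @param model a \linkS4class{CFNNModel}.
#' @param X numeric matrix `[n x features]`.
#' @param chunkSize internal batching of the pass (memory control).
#' @return matrix `[n x nClasses]`; rows are nonnegative and sum to 1.
#' @export
forwardPass <- function(model, X, chunkSize = 512L) {
  stopIfNot(is(model, "CFNNModel"), "model must be a CFNNModel")
  X <- prepareInput(as.matrix(X), model@config)
  if (!is.null(model@state$mu))
    X <- standardizeApply(X, model@state$mu, model@state$sd)
  out <- matrix(0, nrow(X), model@config@nClasses)
  for (bs in seq(1L, nrow(X), by = chunkSize)) {
    idx <- bs:min(bs + chunkSize - 1L, nrow(X))
    out[idx, ] <- cfnnForward(model, X[idx, , drop = FALSE],
                              training = FALSE)$probs
  }
  out
}

#' Predict hard 0/1 labels
#'
#' @inheritParams forwardPass
#' @return integer 0/1 vector (argmax of [forwardPass()]).
#' @export
predictClasses <- function(model, X) {
  max.col(forwardPass(model, X), ties.method = "first") - 1L
}

#' @rdname modelSummary
#' @export
setMethod("modelSummary", "CFNNModel", function(model) {
  cfg <- model@config
  L <- cfg@inputLen
  Lp <- L %/% cfg@poolSize
  D <- Lp * cfg@conv2Filters
  shp <- function(...) sprintf("(None, %s)", paste(c(...), collapse = ", "))
  rows <- data.frame(
    layer = c("Conv1D", "Conv1D", "MaxPooling1D", "Flatten", "Fuzzy",
              "BatchNormalization", "Dense", "Defuzzy", "Activation"),
    outputShape = c(shp(L, cfg@conv1Filters), shp(L, cfg@conv2Filters),
                    shp(Lp, cfg@conv2Filters), shp(D), shp(cfg@nRules),
                    shp(cfg@nRules), shp(cfg@nClasses), shp(cfg@nClasses),
                    shp(cfg@nClasses)),
    params = c(
      cfg@conv1Filters * cfg@conv1Kernel * 1L + cfg@conv1Filters,
      cfg@conv2Filters * cfg@conv2Kernel * cfg@conv1Filters + cfg@conv2Filters,
      0L, 0L,
      D * cfg@nRules * 2L,
      4L * cfg@nRules,
      cfg@nRules * cfg@nClasses + cfg@nClasses,
      cfg@nClasses * cfg@nRules,
      0L),
    stringsAsFactors = FALSE)
  # batch-norm: scale/shift trainable, moving mean/variance not
  rows$nonTrainable <- c(0L, 0L, 0L, 0L, 0L, 2L * cfg@nRules, 0L, 0L, 0L)
  nt <- sum(rows$nonTrainable)
  tot <- sum(rows$params)
  new("ModelSummary", rows = rows,
      totals = c(total = tot, trainable = tot - nt, nonTrainable = nt))
})

setMethod("show", "ModelSummary", function(object) {
  r <- object@rows
  cat(sprintf("%-34s %-16s %10s\n", "Layer", "Output shape", "Param #"))
  for (i in seq_len(nrow(r)))
    cat(sprintf("%-34s %-16s %10d\n", r$layer[i], r$outputShape[i], r$params[i]))
  cat(sprintf("Total parameters: %s\n",
              format(object@totals[["total"]], big.mark = ",")))
  cat(sprintf("Trainable parameters: %s\n",
              format(object@totals[["trainable"]], big.mark = ",")))
  cat(sprintf("Non-trainable parameters: %s\n",
              format(object@totals[["nonTrainable"]], big.mark = ",")))
})

setMethod("show", "CFNNModel", function(object) {
  cfg <- object@config
  cat(sprintf("CFNNModel: input %d -> conv(%d,k%d) -> conv(%d,k%d) -> pool(%d) -> fuzzify(%d rules, %s) -> bn -> dense(%d) -> defuzzify -> softmax\n",
              cfg@inputLen, cfg@conv1Filters, cfg@conv1Kernel,
              cfg@conv2Filters, cfg@conv2Kernel, cfg@poolSize, cfg@nRules,
              cfg@aggregation, cfg@nClasses))
  cat(sprintf("  %s; seed %d\n",
              if (object@state$trained)
                sprintf("trained %d epochs (final loss %.4f, acc %.3f)",
                        nrow(object@history),
                        utils::tail(object@history$loss, 1),
                        utils::tail(object@history$accuracy, 1))
              else "untrained", cfg@seed))
})

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing list (config fields, parameter
#' blocks, state, history) written with R serialization; the training
#' history is additionally written as JSON next to the checkpoint when
#' `historyJSON` is `TRUE`.
#'
#' @param model a \linkS4class{CFNNModel}.
#' @param path checkpoint file path.
#' @param historyJSON also write `<path>.history.json`.
#' @return `saveModel` invisibly returns `path`; `loadModel` the model.
#' @export
saveModel <- function(model, path, historyJSON = FALSE) {
  stopIfNot(is(model, "CFNNModel"), "model must be a CFNNModel")
  obj <- list(config = model@config, params = model@params,
              state = model@state, history = model@history)
  saveRDS(obj, path, version = 2L)
  if (historyJSON)
    jsonlite::write_json(model@history, paste0(path, ".history.json"),
                         dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  for (key in c("config", "params", "state", "history"))
    stopIfNot(key %in% names(obj),
              sprintf("malformed checkpoint: missing '%s'", key))
  new("CFNNModel", config = obj$config, params = obj$params,
      state = obj$state, history = obj$history)
}
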