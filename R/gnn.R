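# Twin-tower GIN regressor.
#
# Two independent GIN stacks (one per species of the conjugate pair),
# global average pooling, a learned projection to the pooled width,
# concatenation, dropout, and an MLP head producing the scalar pKa.
# Forward and reverse passes are written directly against BLAS matrix
# ops with sparse adjacency/pooling operators; the reverse pass caches
# every intermediate the gradients need.

#' Construct a twin-tower GIN configuration
#'
#' Defaults: 3 GIN layers of width 64 per tower, pooled tower embeddings
#' projected to 32 so the concatenated MLP input is 64, a 3-layer MLP of
#' width 64, dropout p = 0.5 on the concatenated pooled vector.
#'
#' @param numGinLayers GIN layers per tower.
#' @param ginHiddenDim embedding width of each GIN layer.
#' @param pooledDim per-tower width after the post-pooling projection.
#' @param mlpLayers fully connected layers in the head (the last maps to
#'   the scalar output).
#' @param mlpHiddenDim width of the head's hidden layers.
#' @param dropoutP dropout probability on the concatenated pooled vector
#'   (training mode only).
#' @param shareTowerWeights use one weight set for both towers.
#' @param mlpBatchNorm batch-normalize the MLP head's hidden layers.
#'   On by default: it re-centers the activation statistics the dropout
#'   mask perturbs, keeping training and inference aligned.  Batch norm
#'   is degenerate on single-pair batches, so optimizer sanity checks
#'   turn it off.
#' @param featureSchema the [FeatureSchema] the model consumes.
#' @return a [PairGNNConfig].
#' @export
pairGNNConfig <- function(numGinLayers = 3L, ginHiddenDim = 64L,
                          pooledDim = 32L, mlpLayers = 3L,
                          mlpHiddenDim = 64L, dropoutP = 0.5,
                          shareTowerWeights = FALSE,
                          mlpBatchNorm = TRUE,
                          featureSchema = pkaGraph::featureSchema()) {
  new("PairGNNConfig",
      numGinLayers = as.integer(numGinLayers),
      ginHiddenDim = as.integer(ginHiddenDim),
      pooledDim = as.integer(pooledDim),
      mlpLayers = as.integer(mlpLayers),
      mlpHiddenDim = as.integer(mlpHiddenDim),
      dropoutP = dropoutP,
      shareTowerWeights = shareTowerWeights,
      mlpBatchNorm = mlpBatchNorm,
      featureSchema = featureSchema)
}

.kaiming <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nrow = nin)
}

#' Initialize a twin-tower GIN model
#'
#' Weights use fan-in scaled Gaussian initialization; batch-norm scale/
#' shift start at 1/0 with running statistics at 0/1.  Seed the R RNG
#' before calling for reproducible initialization.
#'
#' @param config a [PairGNNConfig].
#' @return a [PairGNNModel] in `"train"` mode.
#' @export
pairGNN <- function(config = pairGNNConfig()) {
  d0 <- featureDim(config@featureSchema)
  h <- config@ginHiddenDim
  params <- list()
  stats <- list()
  towers <- if (config@shareTowerWeights) "p" else c("p", "d")
  for (t in towers) {
    din <- d0
    for (l in seq_len(config@numGinLayers)) {
      pre <- sprintf("%s.gin%d", t, l)
      params[[paste0(pre, ".W1")]] <- .kaiming(din, h)
      params[[paste0(pre, ".b1")]] <- numeric(h)
      params[[paste0(pre, ".W2")]] <- .kaiming(h, h)
      params[[paste0(pre, ".b2")]] <- numeric(h)
      params[[paste0(pre, ".gamma")]] <- rep(1, h)
      params[[paste0(pre, ".beta")]] <- numeric(h)
      stats[[paste0(pre, ".rm")]] <- numeric(h)
      stats[[paste0(pre, ".rv")]] <- rep(1, h)
      din <- h
    }
    params[[paste0(t, ".proj.W")]] <- .kaiming(h, config@pooledDim)
    params[[paste0(t, ".proj.b")]] <- numeric(config@pooledDim)
  }
  din <- 2L * config@pooledDim
  for (l in seq_len(config@mlpLayers)) {
    dout <- if (l == config@mlpLayers) 1L else config@mlpHiddenDim
    params[[sprintf("mlp%d.W", l)]] <- .kaiming(din, dout)
    params[[sprintf("mlp%d.b", l)]] <- numeric(dout)
    if (l < config@mlpLayers && config@mlpBatchNorm) {
      # hidden layers are batch normalized (pre-activation); this also
      # re-centers the activation statistics the dropout mask perturbs,
      # keeping training- and inference-mode outputs aligned
      params[[sprintf("mlp%d.gamma", l)]] <- rep(1, dout)
      params[[sprintf("mlp%d.beta", l)]] <- numeric(dout)
      stats[[sprintf("mlp%d.rm", l)]] <- numeric(dout)
      stats[[sprintf("mlp%d.rv", l)]] <- rep(1, dout)
    }
    din <- dout
  }
  new("PairGNNModel", config = config,
      weights = list(params = params, bnstats = stats), mode = "train")
}

#' Switch a model between training and inference mode
#'
#' Inference mode disables dropout and uses running batch-norm statistics,
#' making repeated forward passes bit-identical.
#'
#' @param model a [PairGNNModel].
#' @param mode `"train"` or `"infer"`.
#' @return the model with the new mode.
#' @export
setMode <- function(model, mode = c("infer", "train")) {
  model@mode <- match.arg(mode)
  model
}

setMethod("show", "PairGNNModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@weights$params, length, numeric(1)))
  cat(sprintf(
    "PairGNNModel (%s mode): %d GIN layers x %d per tower, pooled %d, %d-layer MLP\n",
    object@mode, cfg@numGinLayers, cfg@ginHiddenDim, cfg@pooledDim,
    cfg@mlpLayers))
  cat(sprintf("  %d trainable parameters, featureDim %d\n",
              np, featureDim(cfg@featureSchema)))
})

# ---- batch assembly ------------------------------------------------------

# Stack one side (protonated/deprotonated graphs) of a pair batch into a
# single block-diagonal graph.  Dense arrays live in a transposed
# (features x nodes) layout; the adjacency is a 0-based directed edge
# list (both directions of every bond) consumed by the compiled kernels;
# pooling segments are the contiguous node runs of each graph.
.stackSide <- function(graphs) {
  ns <- vapply(graphs, function(g) g@numNodes, integer(1))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(cbind, lapply(graphs, function(g) t(g@nodeFeatures)))
  ei <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    e <- graphs[[k]]@edgeIndex
    if (nrow(e) == 0) return(NULL)
    e + offs[k]
  }))
  if (is.null(ei)) ei <- matrix(integer(0), ncol = 2)
  list(X = X, esrc = ei[, 1] - 1L, edst = ei[, 2] - 1L, ns = ns)
}

.assembleBatch <- function(pairs) {
  list(p = .stackSide(lapply(pairs, function(q) q@protonated)),
       d = .stackSide(lapply(pairs, function(q) q@deprotonated)),
       n = length(pairs))
}

# Precomputed store over a fixed pair set: one big (transposed)
# node-feature matrix and edge table per side, so a minibatch is
# assembled by column slicing instead of re-stacking hundreds of small
# matrices every step.
.sideStore <- function(graphs) {
  ns <- vapply(graphs, function(g) g@numNodes, integer(1))
  rowStart <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(cbind, lapply(graphs, function(g) t(g@nodeFeatures)))
  eCount <- vapply(graphs, function(g) nrow(g@edgeIndex), integer(1))
  eStart <- cumsum(c(0L, eCount[-length(eCount)]))
  E <- do.call(rbind, lapply(graphs, function(g) g@edgeIndex))
  list(X = X, ns = ns, rowStart = rowStart, E = E, eCount = eCount,
       eStart = eStart)
}

.pairStore <- function(pairs) {
  list(p = .sideStore(lapply(pairs, function(q) q@protonated)),
       d = .sideStore(lapply(pairs, function(q) q@deprotonated)),
       refs = vapply(pairs, function(q) q@referencePka, numeric(1)),
       n = length(pairs))
}

.storeSideBatch <- function(st, idx) {
  nsb <- st$ns[idx]
  cols <- sequence(nsb) + rep(st$rowStart[idx], nsb)
  offs <- cumsum(c(0L, nsb[-length(nsb)]))
  cnt <- st$eCount[idx]
  if (sum(cnt) > 0) {
    ei <- sequence(cnt) + rep(st$eStart[idx], cnt)
    off <- rep(offs, cnt)
    esrc <- st$E[ei, 1] + off - 1L
    edst <- st$E[ei, 2] + off - 1L
  } else {
    esrc <- edst <- integer(0)
  }
  list(X = st$X[, cols, drop = FALSE], esrc = esrc, edst = edst, ns = nsb)
}

.storeBatch <- function(store, idx) {
  list(p = .storeSideBatch(store$p, idx), d = .storeSideBatch(store$d, idx),
       n = length(idx))
}

# ---- forward / backward --------------------------------------------------

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# Parameter/statistic lists of one tower's GIN stack in kernel order.
.towerLayers <- function(params, stats, cfg, wtower) {
  lapply(seq_len(cfg@numGinLayers), function(l) {
    pre <- sprintf("%s.gin%d", wtower, l)
    list(W1 = params[[paste0(pre, ".W1")]],
         b1 = params[[paste0(pre, ".b1")]],
         W2 = params[[paste0(pre, ".W2")]],
         b2 = params[[paste0(pre, ".b2")]],
         gamma = params[[paste0(pre, ".gamma")]],
         beta = params[[paste0(pre, ".beta")]],
         rm = stats[[paste0(pre, ".rm")]],
         rv = stats[[paste0(pre, ".rv")]])
  })
}

# Forward through one tower (compiled GIN stack + pooling, then the
# learned projection); returns pooled (pooledDim x graphs) and a cache.
.towerForward <- function(params, stats, side, cfg, tower, training) {
  wtower <- if (cfg@shareTowerWeights) "p" else tower
  fw <- towerForwardCpp(side$X, side$esrc, side$edst, side$ns,
                        .towerLayers(params, stats, cfg, wtower),
                        training, .BN_MOMENTUM, .BN_EPS)
  if (training) {
    for (l in seq_len(cfg@numGinLayers)) {
      pre <- sprintf("%s.gin%d", wtower, l)
      stats[[paste0(pre, ".rm")]] <- as.numeric(fw$stats[[l]]$rm)
      stats[[paste0(pre, ".rv")]] <- as.numeric(fw$stats[[l]]$rv)
    }
  }
  pooled <- crossprod(params[[paste0(wtower, ".proj.W")]], fw$pvec) +
    params[[paste0(wtower, ".proj.b")]]
  list(pooled = pooled, caches = fw$caches, pvec = fw$pvec, stats = stats,
       wtower = wtower)
}

.towerBackward <- function(params, side, fwd, dpooled, cfg, grads) {
  wtower <- fwd$wtower
  acc <- function(name, g) {
    grads[[name]] <<- if (is.null(grads[[name]])) g else grads[[name]] + g
  }
  acc(paste0(wtower, ".proj.W"), tcrossprod(fwd$pvec, dpooled))
  acc(paste0(wtower, ".proj.b"), .rowSums(dpooled, nrow(dpooled),
                                          ncol(dpooled)))
  dpvec <- params[[paste0(wtower, ".proj.W")]] %*% dpooled
  lys <- .towerLayers(params, setNames(list(), character(0)), cfg, wtower)
  # rm/rv are not needed by the reverse pass; refill with zeros
  lys <- lapply(lys, function(ly) { ly$rm <- ly$b1 * 0; ly$rv <- ly$b1 * 0; ly })
  bw <- towerBackwardCpp(dpvec, side$esrc, side$edst, side$ns, lys,
                         fwd$caches)
  for (l in seq_len(cfg@numGinLayers)) {
    pre <- sprintf("%s.gin%d", wtower, l)
    g <- bw[[l]]
    acc(paste0(pre, ".W1"), g$W1)
    acc(paste0(pre, ".b1"), as.numeric(g$b1))
    acc(paste0(pre, ".W2"), g$W2)
    acc(paste0(pre, ".b2"), as.numeric(g$b2))
    acc(paste0(pre, ".gamma"), as.numeric(g$gamma))
    acc(paste0(pre, ".beta"), as.numeric(g$beta))
  }
  grads
}

# Full forward: returns predictions and (optionally) the reverse-pass
# cache.  Training-mode batch norm uses batch statistics and updates the
# running ones; dropout draws from the current RNG stream.
.forwardBatch <- function(model, batch, training = FALSE, keepCache = FALSE) {
  cfg <- model@config
  params <- model@weights$params
  stats <- model@weights$bnstats
  fp <- .towerForward(params, stats, batch$p, cfg, "p", training)
  stats <- fp$stats
  fd <- .towerForward(params, stats, batch$d, cfg, "d", training)
  stats <- fd$stats
  C <- rbind(fp$pooled, fd$pooled)
  mask <- NULL
  Cd <- C
  if (training && cfg@dropoutP > 0) {
    mask <- matrix(runif(length(C)) >= cfg@dropoutP, nrow = nrow(C)) /
      (1 - cfg@dropoutP)
    Cd <- C * mask
  }
  H <- Cd
  mlpCache <- vector("list", cfg@mlpLayers)
  for (l in seq_len(cfg@mlpLayers)) {
    lin <- crossprod(params[[sprintf("mlp%d.W", l)]], H) +
      params[[sprintf("mlp%d.b", l)]]
    if (l == cfg@mlpLayers) {
      mlpCache[[l]] <- list(input = H, lin = lin)
      H <- lin
    } else if (!cfg@mlpBatchNorm) {
      mlpCache[[l]] <- list(input = H, lin = lin)
      H <- lin * (lin > 0)
    } else {
      if (training) {
        nr <- nrow(lin); nc <- ncol(lin)
        mu <- .rowMeans(lin, nr, nc)
        va <- pmax(.rowMeans(lin^2, nr, nc) - mu^2, 0)
        stats[[sprintf("mlp%d.rm", l)]] <-
          (1 - .BN_MOMENTUM) * stats[[sprintf("mlp%d.rm", l)]] +
          .BN_MOMENTUM * mu
        stats[[sprintf("mlp%d.rv", l)]] <-
          (1 - .BN_MOMENTUM) * stats[[sprintf("mlp%d.rv", l)]] +
          .BN_MOMENTUM * va
      } else {
        mu <- stats[[sprintf("mlp%d.rm", l)]]
        va <- stats[[sprintf("mlp%d.rv", l)]]
      }
      invstd <- 1 / sqrt(va + .BN_EPS)
      xhat <- (lin - mu) * invstd
      bn <- xhat * params[[sprintf("mlp%d.gamma", l)]] +
        params[[sprintf("mlp%d.beta", l)]]
      mlpCache[[l]] <- list(input = H, lin = lin, xhat = xhat,
                            invstd = invstd, bn = bn)
      H <- bn * (bn > 0)
    }
  }
  out <- list(pred = as.numeric(H), stats = stats)
  if (keepCache)
    out$cache <- list(fp = fp, fd = fd, mask = mask, Cd = Cd,
                      mlpCache = mlpCache, batch = batch)
  out
}

# Reverse pass from d(loss)/d(pred); returns gradients named like params.
.backwardBatch <- function(model, cache, dpred) {
  cfg <- model@config
  params <- model@weights$params
  grads <- list()
  dH <- matrix(dpred, nrow = 1)
  for (l in rev(seq_len(cfg@mlpLayers))) {
    cc <- cache$mlpCache[[l]]
    if (l == cfg@mlpLayers) {
      dlin <- dH
    } else if (!cfg@mlpBatchNorm) {
      dlin <- dH * (cc$lin > 0)
    } else {
      dbn <- dH * (cc$bn > 0)
      dxhat <- dbn * params[[sprintf("mlp%d.gamma", l)]]
      grads[[sprintf("mlp%d.gamma", l)]] <-
        .rowSums(dbn * cc$xhat, nrow(dbn), ncol(dbn))
      grads[[sprintf("mlp%d.beta", l)]] <-
        .rowSums(dbn, nrow(dbn), ncol(dbn))
      n <- ncol(dbn)
      sx <- .rowSums(dxhat, nrow(dxhat), n)
      sxx <- .rowSums(dxhat * cc$xhat, nrow(dxhat), n)
      dlin <- (dxhat - sx / n - cc$xhat * (sxx / n)) * cc$invstd
    }
    grads[[sprintf("mlp%d.W", l)]] <- tcrossprod(cc$input, dlin)
    grads[[sprintf("mlp%d.b", l)]] <- .rowSums(dlin, nrow(dlin), ncol(dlin))
    dH <- params[[sprintf("mlp%d.W", l)]] %*% dlin
  }
  dC <- if (is.null(cache$mask)) dH else dH * cache$mask
  pd <- cfg@pooledDim
  grads <- .towerBackward(params, cache$batch$p, cache$fp,
                          dC[seq_len(pd), , drop = FALSE], cfg, grads)
  grads <- .towerBackward(params, cache$batch$d, cache$fd,
                          dC[pd + seq_len(pd), , drop = FALSE], cfg, grads)
  grads
}

# Fused training step: both towers, projection, dropout, MLP head and
# the MSE reverse pass in one compiled call.  Returns predictions, the
# loss, updated batch-norm statistics and flat-named gradients.
.trainStep <- function(model, batch, refs) {
  cfg <- model@config
  params <- model@weights$params
  stats <- model@weights$bnstats
  shared <- cfg@shareTowerWeights
  wd <- if (shared) "p" else "d"
  pLayers <- .towerLayers(params, stats, cfg, "p")
  dLayers <- .towerLayers(params, stats, cfg, wd)
  mlp <- lapply(seq_len(cfg@mlpLayers), function(l) {
    ly <- list(W = params[[sprintf("mlp%d.W", l)]],
               b = params[[sprintf("mlp%d.b", l)]])
    if (l < cfg@mlpLayers && cfg@mlpBatchNorm) {
      ly$gamma <- params[[sprintf("mlp%d.gamma", l)]]
      ly$beta <- params[[sprintf("mlp%d.beta", l)]]
      ly$rm <- stats[[sprintf("mlp%d.rm", l)]]
      ly$rv <- stats[[sprintf("mlp%d.rv", l)]]
    }
    ly
  })
  mask <- if (cfg@dropoutP > 0) {
    matrix(runif(2L * cfg@pooledDim * batch$n) >= cfg@dropoutP,
           nrow = 2L * cfg@pooledDim) / (1 - cfg@dropoutP)
  } else {
    matrix(numeric(0), nrow = 0, ncol = 0)
  }
  st <- gnnTrainStepCpp(batch$p$X, batch$p$esrc, batch$p$edst, batch$p$ns,
                        batch$d$X, batch$d$esrc, batch$d$edst, batch$d$ns,
                        pLayers, dLayers,
                        params[[paste0("p", ".proj.W")]],
                        params[["p.proj.b"]],
                        params[[paste0(wd, ".proj.W")]],
                        params[[paste0(wd, ".proj.b")]],
                        mlp, mask, refs, shared, .BN_MOMENTUM, .BN_EPS)
  for (l in seq_len(cfg@numGinLayers)) {
    stats[[sprintf("p.gin%d.rm", l)]] <- as.numeric(st$pStats[[l]]$rm)
    stats[[sprintf("p.gin%d.rv", l)]] <- as.numeric(st$pStats[[l]]$rv)
    stats[[sprintf("%s.gin%d.rm", wd, l)]] <- as.numeric(st$dStats[[l]]$rm)
    stats[[sprintf("%s.gin%d.rv", wd, l)]] <- as.numeric(st$dStats[[l]]$rv)
  }
  if (cfg@mlpBatchNorm) {
    for (l in seq_len(cfg@mlpLayers - 1L)) {
      stats[[sprintf("mlp%d.rm", l)]] <- as.numeric(st$mlpStats[[l]]$rm)
      stats[[sprintf("mlp%d.rv", l)]] <- as.numeric(st$mlpStats[[l]]$rv)
    }
  }
  grads <- list()
  addg <- function(name, g) {
    grads[[name]] <<- if (is.null(grads[[name]])) g else grads[[name]] + g
  }
  for (l in seq_len(cfg@numGinLayers)) {
    for (part in c("W1", "b1", "W2", "b2", "gamma", "beta")) {
      gP <- st$pGrads[[l]][[part]]
      gD <- st$dGrads[[l]][[part]]
      if (!grepl("^W", part)) { gP <- as.numeric(gP); gD <- as.numeric(gD) }
      addg(sprintf("p.gin%d.%s", l, part), gP)
      addg(sprintf("%s.gin%d.%s", wd, l, part), gD)
    }
  }
  addg("p.proj.W", st$projWp); addg("p.proj.b", as.numeric(st$projbp))
  addg(paste0(wd, ".proj.W"), st$projWd)
  addg(paste0(wd, ".proj.b"), as.numeric(st$projbd))
  for (l in seq_len(cfg@mlpLayers)) {
    grads[[sprintf("mlp%d.W", l)]] <- st$mlpGrads[[l]]$W
    grads[[sprintf("mlp%d.b", l)]] <- as.numeric(st$mlpGrads[[l]]$b)
    if (l < cfg@mlpLayers && cfg@mlpBatchNorm) {
      grads[[sprintf("mlp%d.gamma", l)]] <-
        as.numeric(st$mlpGrads[[l]]$gamma)
      grads[[sprintf("mlp%d.beta", l)]] <-
        as.numeric(st$mlpGrads[[l]]$beta)
    }
  }
  list(pred = as.numeric(st$pred), loss = st$loss, stats = stats,
       grads = grads)
}

.checkSchema <- function(model, pairs) {
  d <- featureDim(model@config@featureSchema)
  ok <- vapply(pairs, function(q)
    ncol(q@protonated@nodeFeatures) == d &&
      ncol(q@deprotonated@nodeFeatures) == d, logical(1))
  if (!all(ok))
    stop("feature schema mismatch: pair featurized with ",
         ncol(pairs[[which(!ok)[1]]]@protonated@nodeFeatures),
         " features, model expects ", d)
}

#' Predict pKa values for a batch of conjugate pairs
#'
#' Runs the twin-tower forward pass.  In inference mode (the default for a
#' loaded or freshly switched model, see [setMode()]) dropout is off and
#' batch normalization uses running statistics, so results are
#' deterministic and independent of batch composition.
#'
#' @param model a [PairGNNModel].
#' @param pairs list of [ConjugatePair] objects featurized under the
#'   model's schema.
#' @return numeric vector of predicted pKa values, one per pair.
#' @export
predictPka <- function(model, pairs) {
  if (length(pairs) == 0) return(numeric(0))
  if (inherits(pairs, "ConjugatePair")) pairs <- list(pairs)
  .checkSchema(model, pairs)
  .forwardBatch(model, .assembleBatch(pairs), training = FALSE)$pred
}

# ---- checkpointing -------------------------------------------------------

.CHECKPOINT_VERSION <- 1L

.configToList <- function(cfg) {
  list(numGinLayers = cfg@numGinLayers, ginHiddenDim = cfg@ginHiddenDim,
       pooledDim = cfg@pooledDim, mlpLayers = cfg@mlpLayers,
       mlpHiddenDim = cfg@mlpHiddenDim, dropoutP = cfg@dropoutP,
       shareTowerWeights = cfg@shareTowerWeights,
       mlpBatchNorm = cfg@mlpBatchNorm,
       featureSchema = .schemaToList(cfg@featureSchema))
}

.configFromList <- function(x) {
  pairGNNConfig(numGinLayers = x$numGinLayers, ginHiddenDim = x$ginHiddenDim,
                pooledDim = x$pooledDim, mlpLayers = x$mlpLayers,
                mlpHiddenDim = x$mlpHiddenDim, dropoutP = x$dropoutP,
                shareTowerWeights = x$shareTowerWeights,
                mlpBatchNorm = x$mlpBatchNorm,
                featureSchema = .schemaFromList(x$featureSchema))
}

#' Save a model checkpoint
#'
#' Bundles weights, architecture configuration, the frozen feature schema
#' and optional run metadata into a single versioned file.
#'
#' @param model a [PairGNNModel].
#' @param path destination file.
#' @param runRecord optional [RunRecord] stored alongside the weights.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path, runRecord = NULL) {
  payload <- list(format = "pkaGraph-checkpoint",
                  version = .CHECKPOINT_VERSION,
                  config = .configToList(model@config),
                  weights = model@weights,
                  runRecord = if (!is.null(runRecord)) {
                    list(seed = runRecord@seed, history = runRecord@history,
                         bestEpoch = runRecord@bestEpoch,
                         config = runRecord@config)
                  })
  saveRDS(payload, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [saveModel()].
#' @return a [PairGNNModel] in inference mode; the run metadata, if
#'   present, is attached as attribute `"runRecord"`.
#' @export
loadModel <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or unreadable checkpoint at '", path, "': ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(payload) || !identical(payload$format, "pkaGraph-checkpoint"))
    stop("not a pkaGraph checkpoint: '", path, "'")
  if (!identical(payload$version, .CHECKPOINT_VERSION))
    stop("checkpoint version ", payload$version,
         " not supported (expected ", .CHECKPOINT_VERSION, ")")
  model <- new("PairGNNModel", config = .configFromList(payload$config),
               weights = payload$weights, mode = "infer")
  if (!is.null(payload$runRecord))
    attr(model, "runRecord") <- payload$runRecord
  model
}
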