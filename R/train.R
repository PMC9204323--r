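# Training: seeded by-molecule splits, MSE minimization with AdamW,
# plateau LR scheduling, best-checkpoint restoration, fine-tuning with
# pre-training batch mixing, and repeated runs.

#' Construct a training configuration
#'
#' Defaults follow the reference protocol: learning rate 1e-3, 1000
#' epochs, batch size 512 for pre-training and 64 for fine-tuning with a
#' 1024-pair pre-training batch mixed into every fine-tuning step,
#' validation every 5th epoch, plateau schedule (factor 0.5, patience 150
#' epochs, threshold 0.1), 90/10 train/validation split.
#'
#' @param lr initial learning rate.
#' @param batchSize pairs per optimizer step.
#' @param epochs training epochs.
#' @param weightDecay decoupled AdamW weight decay.
#' @param mixBatchSize pre-training pairs mixed into each fine-tuning
#'   batch; 0 disables mixing ("light" profile).
#' @param evalEvery epochs between validation evaluations.
#' @param schedFactor,schedPatience,schedThreshold plateau-scheduler
#'   parameters (see [plateauInit()]).
#' @param schedMode `"absolute"` or `"relative"` plateau threshold.
#' @param splitFraction training share of the by-molecule split.
#' @param seed split and initialization seed.
#' @return a `TrainConfig` (classed list).
#' @export
trainConfig <- function(lr = 1e-3, batchSize = 512L, epochs = 1000L,
                        weightDecay = 1e-4, mixBatchSize = 1024L,
                        evalEvery = 5L, schedFactor = 0.5,
                        schedPatience = 150L, schedThreshold = 0.1,
                        schedMode = "absolute", splitFraction = 0.9,
                        seed = 1L) {
  stopifnot(splitFraction > 0, splitFraction < 1,
            batchSize >= 1, epochs >= 0, evalEvery >= 1,
            schedFactor > 0, schedFactor < 1, mixBatchSize >= 0)
  structure(list(lr = lr, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), weightDecay = weightDecay,
                 mixBatchSize = as.integer(mixBatchSize),
                 evalEvery = as.integer(evalEvery),
                 schedFactor = schedFactor,
                 schedPatience = as.integer(schedPatience),
                 schedThreshold = schedThreshold, schedMode = schedMode,
                 splitFraction = splitFraction, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Seeded by-molecule train/validation split
#'
#' Molecules (not pairs) are partitioned, so all protonation states of
#' one molecule land on the same side.  Identical seeds give identical
#' partitions.
#'
#' @param pairs list of [ConjugatePair] objects.
#' @param fraction training share (default 0.9).
#' @param seed RNG seed for the shuffle.
#' @return list with elements `train` and `validation`.
#' @export
seededSplit <- function(pairs, fraction = 0.9, seed = 1L) {
  if (length(pairs) == 0) stop("empty dataset")
  ids <- vapply(pairs, function(p) p@moleculeId, character(1))
  ids[is.na(ids)] <- paste0(".anon", seq_along(ids)[is.na(ids)])
  mols <- unique(ids)
  nTrain <- round(fraction * length(mols))
  if (nTrain < 1 || nTrain >= length(mols))
    stop("split fraction leaves an empty side (", length(mols),
         " molecules)")
  shuffled <- withr::with_seed(seed, sample(mols))
  trainMols <- shuffled[seq_len(nTrain)]
  list(train = pairs[ids %in% trainMols],
       validation = pairs[!ids %in% trainMols])
}

# Validation metrics in inference mode, evaluated in chunks over a
# precomputed pair store.
.evalStore <- function(model, store, chunk = 512L) {
  model@mode <- "infer"
  preds <- numeric(0)
  for (s in split(seq_len(store$n), ceiling(seq_len(store$n) / chunk)))
    preds <- c(preds, .forwardBatch(model, .storeBatch(store, s))$pred)
  c(mse = mean((preds - store$refs)^2),
    mae = mean(abs(preds - store$refs)))
}

.evalPairs <- function(model, pairs, chunk = 512L) {
  .evalStore(model, .pairStore(pairs), chunk)
}

# Core optimization loop shared by pretrain() and finetune().
.trainLoop <- function(model, trainPairs, valPairs, config,
                       mixPairs = NULL, seed = config$seed) {
  cfg <- config
  store <- .pairStore(c(trainPairs, mixPairs))
  refs <- store$refs
  if (anyNA(refs)) stop("training pairs must carry reference pKa labels")
  valStore <- if (length(valPairs) > 0) .pairStore(valPairs)
  opt <- adamWInit(model@weights$params, lr = cfg$lr,
                   weightDecay = cfg$weightDecay)
  sched <- plateauInit(lr = cfg$lr, factor = cfg$schedFactor,
                       patience = cfg$schedPatience,
                       threshold = cfg$schedThreshold, mode = cfg$schedMode)
  history <- data.frame(epoch = integer(0), val_mse = numeric(0),
                        val_mae = numeric(0), lr = numeric(0))
  batchSizes <- integer(0)
  best <- list(weights = model@weights, mse = Inf, epoch = NA_integer_)
  model@mode <- "train"
  set.seed(seed + 1L)   # optimization stream, distinct from the split
  n <- length(trainPairs)
  for (epoch in seq_len(cfg$epochs)) {
    order_ <- sample(n)
    starts <- seq(1, n, by = cfg$batchSize)
    for (s in starts) {
      idx <- order_[s:min(s + cfg$batchSize - 1, n)]
      if (!is.null(mixPairs) && cfg$mixBatchSize > 0) {
        mi <- sample(length(mixPairs), cfg$mixBatchSize,
                     replace = length(mixPairs) < cfg$mixBatchSize)
        idx <- c(idx, n + mi)
      }
      stepRefs <- refs[idx]
      batchSizes <- c(batchSizes, length(idx))
      batch <- .storeBatch(store, idx)
      st <- .trainStep(model, batch, stepRefs)
      model@weights$bnstats <- st$stats
      if (!is.finite(st$loss))
        stop(structure(class = c("pkaGraph_divergence", "error", "condition"),
                       list(message = sprintf(
                         "training diverged at epoch %d (loss %s)",
                         epoch, st$loss), call = NULL)))
      up <- adamWStep(model@weights$params, st$grads, opt)
      model@weights$params <- up$params
      opt <- up$state
    }
    if (epoch %% cfg$evalEvery == 0 && !is.null(valStore)) {
      ev <- .evalStore(model, valStore)
      history <- rbind(history, data.frame(
        epoch = epoch, val_mse = ev["mse"], val_mae = ev["mae"],
        lr = sched$lr))
      if (ev["mse"] < best$mse) {
        best <- list(weights = model@weights, mse = ev["mse"], epoch = epoch)
      }
      sched <- plateauStep(sched, ev["mse"], epochsElapsed = cfg$evalEvery)
      opt$lr <- sched$lr
    }
  }
  if (!is.na(best$epoch)) model@weights <- best$weights
  model <- setMode(model, "infer")
  rownames(history) <- NULL
  record <- new("RunRecord", seed = as.integer(seed), history = history,
                bestEpoch = as.integer(best$epoch),
                batchSizes = batchSizes,
                config = unclass(cfg))
  list(model = model, record = record)
}

#' Fit a model on an explicit train/validation split
#'
#' Lower-level entry point behind [pretrain()]/[finetune()]: trains on
#' exactly the pairs given, without performing a split.  With an empty
#' validation set no evaluations, scheduling or checkpoint restoration
#' happen (the final weights are returned) — useful for memorization
#' checks and externally managed splits.
#'
#' @param model a [PairGNNModel].
#' @param trainPairs labeled pairs to optimize on.
#' @param valPairs labeled validation pairs (may be empty).
#' @param config a [trainConfig()].
#' @param mixPairs optional pairs sampled into every batch
#'   (`config$mixBatchSize` at a time).
#' @return list with `model` and `record`.
#' @export
fitPairs <- function(model, trainPairs, valPairs = list(),
                     config = trainConfig(), mixPairs = NULL) {
  .trainLoop(model, trainPairs, valPairs, config, mixPairs = mixPairs)
}

#' Pre-train a twin-tower GIN on a labeled pair set
#'
#' Splits the pairs by molecule with the configured seed, minimizes the
#' MSE between predicted and reference pKa with AdamW, evaluates the
#' validation set every `evalEvery` epochs with plateau LR scheduling,
#' and returns the model restored to the best validation checkpoint.
#'
#' @param pairs list of labeled [ConjugatePair] objects.
#' @param config a [trainConfig()].
#' @param model optional pre-built [PairGNNModel]; by default a fresh
#'   model is initialized from the configured seed.
#' @return list with `model` ([PairGNNModel], inference mode) and
#'   `record` ([RunRecord]).
#' @export
pretrain <- function(pairs, config = trainConfig(), model = NULL) {
  sp <- seededSplit(pairs, fraction = config$splitFraction,
                    seed = config$seed)
  if (is.null(model)) {
    set.seed(config$seed)
    schema <- .schemaOfPairs(pairs)
    model <- pairGNN(pairGNNConfig(featureSchema = schema))
  }
  .trainLoop(model, sp$train, sp$validation, config)
}

# Recover the schema dimensionality check source: pairs only carry the
# feature matrices, so the default schema is used unless its width
# disagrees, which predictPka()/forward guards catch later anyway.
.schemaOfPairs <- function(pairs) {
  sch <- featureSchema()
  if (length(pairs) &&
      ncol(pairs[[1]]@protonated@nodeFeatures) != featureDim(sch))
    stop("pairs were featurized under a non-default schema; ",
         "pass a model built with that schema")
  sch
}

#' Fine-tune a pre-trained model on experimental pairs with batch mixing
#'
#' Every optimizer step consumes `batchSize` experimental pairs plus a
#' freshly sampled `mixBatchSize` pre-training batch, with one unweighted
#' MSE over the combined batch; all parameters stay trainable.
#' Validation (checkpoint selection, LR plateau) uses the experimental
#' hold-out only.  Setting `mixBatchSize = 0` ("light" profile) reduces
#' to plain training on the experimental pairs and is the only way to
#' omit `pretrainPairs`.
#'
#' @param model a pre-trained [PairGNNModel].
#' @param experimentalPairs labeled [ConjugatePair] list to fine-tune on.
#' @param pretrainPairs the pre-training pair set mixed into each batch.
#' @param config a [trainConfig()]; fine-tuning defaults are
#'   `batchSize = 64`, `mixBatchSize = 1024`.
#' @return list with `model` and `record`; the record's `batchSizes` log
#'   the combined per-step sizes.
#' @export
finetune <- function(model, experimentalPairs, pretrainPairs = NULL,
                     config = trainConfig(batchSize = 64L)) {
  if (is.null(pretrainPairs) || length(pretrainPairs) == 0) {
    if (config$mixBatchSize > 0)
      stop("batch mixing is enabled (mixBatchSize = ",
           config$mixBatchSize, ") but no pre-training pairs were ",
           "supplied; pass pretrainPairs or set mixBatchSize = 0 ",
           "for the light profile")
    pretrainPairs <- NULL
  }
  sp <- seededSplit(experimentalPairs, fraction = config$splitFraction,
                    seed = config$seed)
  .trainLoop(model, sp$train, sp$validation, config,
             mixPairs = pretrainPairs)
}

#' Repeat training runs with independent recorded seeds
#'
#' Derives one split/initialization seed per repetition from the master
#' seed, runs [pretrain()] (and, when `pretrainPairs` is given,
#' [finetune()] afterwards) for each, and returns the runs in repetition
#' order.  The reference protocol uses 50 repetitions; any count is
#' supported.
#'
#' @param pairs labeled pairs for the (final) training stage.
#' @param config a [trainConfig()] applied to every repetition (its
#'   `seed` is replaced per repetition).
#' @param nRepetitions number of repetitions.
#' @param pretrainPairs optional pre-training set; when given, each
#'   repetition pre-trains on it (with `pretrainConfig`) and then
#'   fine-tunes on `pairs` with batch mixing.
#' @param pretrainConfig configuration for the pre-training stage.
#' @param masterSeed seed from which the per-repetition seeds derive.
#' @return list of per-repetition results (`model`, `record`).
#' @export
repeatRuns <- function(pairs, config = trainConfig(), nRepetitions = 3L,
                       pretrainPairs = NULL,
                       pretrainConfig = trainConfig(),
                       masterSeed = 1L) {
  stopifnot(nRepetitions >= 1)
  seeds <- withr::with_seed(masterSeed,
                            sample.int(.Machine$integer.max - 1L,
                                       nRepetitions))
  lapply(seq_len(nRepetitions), function(i) {
    if (is.null(pretrainPairs)) {
      cfg <- config; cfg$seed <- seeds[i]
      pretrain(pairs, cfg)
    } else {
      pcfg <- pretrainConfig; pcfg$seed <- seeds[i]
      pre <- pretrain(pretrainPairs, pcfg)
      cfg <- config; cfg$seed <- seeds[i]
      finetune(pre$model, pairs, pretrainPairs, cfg)
    }
  })
}

setMethod("show", "RunRecord", function(object) {
  cat(sprintf("RunRecord: seed %d, %d evaluations, best epoch %s\n",
              object@seed, nrow(object@history),
              ifelse(is.na(object@bestEpoch), "<none>", object@bestEpoch)))
  if (nrow(object@history) > 0) {
    b <- object@history[which.min(object@history$val_mse), ]
    cat(sprintf("  best val MSE %.4f (MAE %.4f) at epoch %d\n",
                b$val_mse, b$val_mae, b$epoch))
  }
})
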