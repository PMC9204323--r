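# Adam with decoupled weight decay (AdamW) and the reduce-on-plateau
# learning-rate schedule.

#' Initialize AdamW optimizer state
#'
#' @param params named list of parameter arrays.
#' @param lr initial learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical stabilizer.
#' @param weightDecay decoupled weight-decay coefficient (applied
#'   multiplicatively to the parameters, not through the gradient).
#' @return optimizer state list.
#' @export
adamWInit <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weightDecay = 1e-4) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       weightDecay = weightDecay, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

#' One AdamW update
#'
#' Bias-corrected Adam moments plus decoupled weight decay: decay is not
#' added to the gradient but subtracted directly as `lr * wd * theta`.
#' Batch-norm scale/shift parameters are exempt from decay.
#'
#' @param params named list of parameters.
#' @param grads named list of gradients (same shapes).
#' @param state optimizer state from [adamWInit()].
#' @return list with updated `params` and `state`.
#' @export
adamWStep <- function(params, grads, state) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  noDecay <- grepl("\\.(gamma|beta|b1|b2|b)$", names(params))
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * g
    state$v[[k]] <- state$beta2 * state$v[[k]] + (1 - state$beta2) * g^2
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    upd <- mhat / (sqrt(vhat) + state$eps)
    wd <- if (noDecay[match(k, names(params))]) 0 else state$weightDecay
    params[[k]] <- params[[k]] - state$lr * (upd + wd * params[[k]])
  }
  list(params = params, state = state)
}

#' Initialize a reduce-on-plateau scheduler
#'
#' The learning rate halves (`factor`) whenever the validation metric has
#' not improved by more than `threshold` (absolute, or relative to the
#' best seen) within `patience` epochs.  The patience counter resets on
#' improvement and after each reduction.
#'
#' @param lr initial learning rate.
#' @param factor multiplicative reduction (default 0.5).
#' @param patience epochs without sufficient improvement before reducing
#'   (default 150).
#' @param threshold minimum improvement that resets the counter
#'   (default 0.1).
#' @param mode `"absolute"` (default) or `"relative"` threshold.
#' @return scheduler state list.
#' @export
plateauInit <- function(lr = 1e-3, factor = 0.5, patience = 150,
                        threshold = 0.1, mode = c("absolute", "relative")) {
  list(lr = lr, factor = factor, patience = patience, threshold = threshold,
       mode = match.arg(mode), best = Inf, since = 0L)
}

#' Advance the plateau scheduler by one validation evaluation
#'
#' @param state scheduler state from [plateauInit()].
#' @param metric current validation metric (lower is better).
#' @param epochsElapsed epochs since the previous evaluation (the
#'   evaluation cadence, default 5).
#' @return updated state; `state$lr` is the rate to use next.
#' @export
plateauStep <- function(state, metric, epochsElapsed = 5L) {
  margin <- if (state$mode == "absolute") state$threshold
            else state$threshold * abs(state$best)
  if (metric < state$best - margin) {
    state$best <- metric
    state$since <- 0L
  } else {
    state$since <- state$since + as.integer(epochsElapsed)
    if (state$since >= state$patience) {
      state$lr <- state$lr * state$factor
      state$since <- 0L
    }
  }
  state
}
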