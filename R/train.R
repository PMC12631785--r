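#' @title Training loop
#' @description Binary cross-entropy on the five task heads, minimized
#'   with Adam at learning rate 0.001 (one graph per step by default),
#'   with validation-loss model selection: the returned checkpoint is the
#'   one from the epoch with the lowest validation loss, not the last.
#' @name train_eval
NULL

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param max_epochs training epochs.
#' @param batch_size graphs per optimizer step (gradients averaged).
#' @param patience early-stop patience in epochs without validation
#'   improvement (default Inf: run all epochs).
#' @param seed RNG seed for shuffling and dropout.
#' @param mask_policy `"include_negative"` (default: chains without
#'   positives for a task still contribute negatives to that task's loss)
#'   or `"exclude_taskless"` (mask such task columns out of the loss).
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 30L,
                         batch_size = 1L, patience = Inf, seed = 1L,
                         mask_policy = c("include_negative",
                                         "exclude_taskless")) {
  stopifnot(learning_rate >= 0, max_epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), patience = patience,
                 seed = as.integer(seed),
                 mask_policy = match.arg(mask_policy)),
            class = "train_config")
}

# elementwise walk over two parameter trees
par_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- par_map2(a[[k]], b[[k]], f)
    out
  } else f(a, b)
}

par_map1 <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- par_map1(a[[k]], f)
    out
  } else f(a)
}

adam_init <- function(params) {
  list(m = par_map1(params, function(x) x * 0),
       v = par_map1(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- par_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- par_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- par_map2(state$m, state$v,
                  function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- par_map2(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}

task_mask <- function(labels, policy) {
  mask <- array(1, dim(labels))
  if (policy == "exclude_taskless") {
    empty <- colSums(labels) == 0
    mask[, empty] <- 0
  }
  mask
}

dataset_loss <- function(model, items, policy) {
  tot <- 0; n <- 0
  for (it in items) {
    fw <- egnn_forward(model, it$graph)
    msk <- task_mask(it$labels, policy)
    if (sum(msk) == 0) next
    tot <- tot + bce_loss(fw$probs, it$labels, msk) * sum(msk)
    n <- n + sum(msk)
  }
  if (n == 0) stop("no unmasked labels in dataset")
  tot / n
}

#' Epoch with the lowest validation loss
#' @param val_losses numeric vector of per-epoch validation losses.
#' @return 1-based index of the selected epoch.
#' @export
select_best_epoch <- function(val_losses) which.min(val_losses)

#' Train a model with validation-loss selection
#'
#' Minimizes masked mean BCE with Adam; after every epoch the validation
#' loss is computed and the parameters of the best epoch so far are kept.
#' Fully seeded: repeated runs with the same seed are bit-identical on
#' one machine.
#'
#' @param model an initial `egnn_model`.
#' @param train_items,val_items lists of `list(graph, labels)` pairs.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return list: `model` (parameters from the argmin-validation epoch),
#'   `history` (data.frame epoch/train_loss/val_loss), `best_epoch`.
#' @export
train_model <- function(model, train_items, val_items,
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(length(train_items) > 0, length(val_items) > 0)
  policy <- cfg$mask_policy
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, params = model$params, epoch = 0L)
  with_seed(cfg$seed, function() {
    since_best <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(train_items))
      ep_loss <- 0; ep_n <- 0
      batch_grads <- NULL; in_batch <- 0L
      for (k in ord) {
        it <- train_items[[k]]
        fw <- egnn_forward(model, it$graph, training = TRUE,
                           keep_cache = TRUE)
        msk <- task_mask(it$labels, policy)
        nm <- sum(msk)
        if (nm == 0) next
        loss <- bce_loss(fw$probs, it$labels, msk)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", graph ", k)
        }
        ep_loss <- ep_loss + loss * nm; ep_n <- ep_n + nm
        dlogits <- (fw$probs - it$labels) * msk / nm
        g <- egnn_backward(model, fw$cache, dlogits)
        batch_grads <- if (is.null(batch_grads)) g
                       else par_map2(batch_grads, g, `+`)
        in_batch <- in_batch + 1L
        if (in_batch == cfg$batch_size) {
          if (cfg$batch_size > 1) {
            batch_grads <- par_map1(batch_grads,
                                    function(x) x / cfg$batch_size)
          }
          st <- adam_step(model$params, batch_grads, state,
                          cfg$learning_rate)
          model$params <<- st$params; state <<- st$state
          batch_grads <- NULL; in_batch <- 0L
        }
      }
      if (in_batch > 0) {
        batch_grads <- par_map1(batch_grads, function(x) x / in_batch)
        st <- adam_step(model$params, batch_grads, state, cfg$learning_rate)
        model$params <<- st$params; state <<- st$state
      }
      val <- dataset_loss(model, val_items, policy)
      history[nrow(history) + 1L, ] <<- list(epoch, ep_loss / max(ep_n, 1), val)
      if (verbose) {
        message(sprintf("epoch %d  train %.5f  val %.5f", epoch,
                        ep_loss / max(ep_n, 1), val))
      }
      if (val < best$val) {
        best <<- list(val = val, params = model$params, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= cfg$patience) break
      }
    }
  })
  model$params <- best$params
  stopifnot(best$epoch == select_best_epoch(history$val_loss))
  list(model = model, history = history, best_epoch = best$epoch)
}
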