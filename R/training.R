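#' Label-stratified train / validation / test split with CV folds
#'
#' Partitions the cohort into fixed train / validation / test subsets of the
#' requested sizes (the study design is 145 / 22 / 40 for 207 lesions),
#' stratified by label via largest-remainder allocation so every subset is
#' within one lesion of the cohort's class balance. Cross-validation folds
#' (default 5) partition train + validation, again stratified; the held-out
#' test set never enters a fold.
#'
#' @param labels Character vector (`"benign"`/`"malignant"`) or a
#'   `CohortManifest`.
#' @param sizes Integer length 3: `c(train, val, test)`; must sum to the
#'   cohort size.
#' @param seed Integer seed; the same seed always yields the same plan.
#' @param k Number of CV folds (default 5).
#' @param case_ids Case identifiers (taken from the manifest if given).
#' @return A `SplitPlan`: list with `train_ids`, `val_ids`, `test_ids`,
#'   `fold_assignments` (named fold index per train+val case), `seed`, `k`.
#' @export
make_split <- function(labels, sizes, seed = 1L, k = 5L, case_ids = NULL) {
  if (inherits(labels, "CohortManifest")) {
    case_ids <- labels$case_id
    labels <- labels$label
  }
  n <- length(labels)
  if (is.null(case_ids)) case_ids <- paste0("case_", seq_len(n))
  stopifnot(length(sizes) == 3, all(labels %in% c("benign", "malignant")))
  if (sum(sizes) != n)
    stop("sizes must sum to the cohort size (", n, ")")
  .with_seed(seed, function() {
    subsets <- list(train = character(0), val = character(0),
                    test = character(0))
    # largest-remainder quotas per class x subset
    for (cl in unique(labels)) {
      ids <- sample(case_ids[labels == cl])
      quota_exact <- sizes * length(ids) / n
      quota <- floor(quota_exact)
      rem <- quota_exact - quota
      short <- length(ids) - sum(quota)
      if (short > 0) {
        bump <- order(rem, decreasing = TRUE)[seq_len(short)]
        quota[bump] <- quota[bump] + 1L
      }
      off <- 0L
      for (s in 1:3) {
        take <- ids[seq_len(quota[s]) + off]
        subsets[[s]] <- c(subsets[[s]], take)
        off <- off + quota[s]
      }
    }
    # rebalance if rounding left a subset off-target (classes interact)
    for (s in 1:3) {
      while (length(subsets[[s]]) > sizes[s]) {
        donor <- which(vapply(subsets, length, 1L) <
                         sizes)[1]
        mv <- subsets[[s]][length(subsets[[s]])]
        subsets[[s]] <- setdiff(subsets[[s]], mv)
        subsets[[donor]] <- c(subsets[[donor]], mv)
      }
    }
    dev_ids <- c(subsets$train, subsets$val)
    lab <- setNames(labels, case_ids)
    folds <- integer(0)
    for (cl in unique(labels)) {
      ids <- sample(dev_ids[lab[dev_ids] == cl])
      folds <- c(folds, setNames(rep(seq_len(k), length.out = length(ids)),
                                 ids))
    }
    structure(list(train_ids = subsets$train, val_ids = subsets$val,
                   test_ids = subsets$test,
                   fold_assignments = folds[dev_ids],
                   seed = seed, k = as.integer(k)),
              class = "SplitPlan")
  })
}

#' Default training hyperparameters
#'
#' Adam with cross-entropy loss over the 2-class softmax. The canonical
#' defaults (learning rate 1e-4, batch 4, up to 100 epochs, early stopping
#' on validation AUC with patience 15) suit the full-size network; reduced
#' phantom experiments pass larger learning rates and fewer epochs.
#'
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without validation-AUC
#'   improvement); `Inf` disables early stopping.
#' @param augment_flip Randomly mirror training samples along the first
#'   (left-right) axis; off by default.
#' @param lr_decay,lr_step Multiply the learning rate by `lr_decay` every
#'   `lr_step` epochs (1 = constant).
#' @param min_epochs Burn-in before checkpoint selection starts; guards
#'   against freezing a lucky unconverged epoch on a small validation fold.
#' @param optimizer Optimizer name (only `"adam"` implemented).
#' @export
train_hyperparams <- function(lr = 1e-4, batch_size = 4L, epochs = 100L,
                              patience = 15L, augment_flip = FALSE,
                              lr_decay = 1, lr_step = 10L, min_epochs = 1L,
                              optimizer = "adam") {
  stopifnot(optimizer == "adam")
  list(lr = lr, batch_size = as.integer(batch_size),
       epochs = as.integer(epochs), patience = patience,
       augment_flip = augment_flip, lr_decay = lr_decay,
       lr_step = as.integer(lr_step), min_epochs = as.integer(min_epochs),
       optimizer = optimizer)
}

# stack a list of ModelInputTensors into a (D,H,W,C,N) batch
.stack_tensors <- function(tensors, idx = seq_along(tensors)) {
  d <- dim(tensors[[idx[1]]]$channels)
  x5 <- array(0, c(d, length(idx)))
  for (j in seq_along(idx)) x5[, , , , j] <- tensors[[idx[j]]]$channels
  x5
}

.label_int <- function(labels) ifelse(labels == "malignant", 2L, 1L)

# inference scores (P2, malignant probability) for a set of tensors
.score_tensors <- function(net, tensors, idx, batch = 8L) {
  p2 <- numeric(length(idx))
  for (start in seq(1, length(idx), by = batch)) {
    take <- idx[start:min(start + batch - 1L, length(idx))]
    fw <- net_forward(net, .stack_tensors(tensors, take), training = FALSE)
    p2[start:(start + length(take) - 1L)] <- fw$probs[, 2]
  }
  p2
}

#' Train one network on a fixed train / validation index split
#'
#' Mini-batch Adam on softmax cross-entropy; after every epoch the
#' validation AUC is computed in inference mode and the best-scoring
#' parameters are retained (early stopping). A non-finite loss aborts with
#' a diagnostic.
#'
#' @param tensors List of `ModelInputTensor`s.
#' @param labels Character labels aligned with `tensors`.
#' @param train_idx,val_idx Integer indices into `tensors`.
#' @param config A `NetworkConfig`.
#' @param hyper From [train_hyperparams()].
#' @param seed Seed covering weight init and batch order.
#' @param verbose Print per-epoch loss/AUC lines.
#' @return A `TrainRun`: list with the trained `net`, per-epoch `trace`
#'   (`data.frame`: epoch, loss, val_auc), `best_epoch`, `val_scores`.
#' @export
train_model <- function(tensors, labels, train_idx, val_idx, config,
                        hyper = train_hyperparams(), seed = 1L,
                        verbose = FALSE) {
  y <- .label_int(labels)
  net <- build_network(config, seed = seed)
  opt <- adam_init(net$params)
  best <- list(auc = -Inf, params = net$params, state = net$state,
               epoch = 0L)
  trace <- data.frame(epoch = integer(0), loss = numeric(0),
                      val_auc = numeric(0))
  .with_seed(seed + 1L, function() {
    stall <- 0L
    for (ep in seq_len(hyper$epochs)) {
      lr_ep <- hyper$lr * hyper$lr_decay^((ep - 1L) %/% hyper$lr_step)
      order_idx <- sample(train_idx)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, length(order_idx), by = hyper$batch_size)) {
        take <- order_idx[start:min(start + hyper$batch_size - 1L,
                                    length(order_idx))]
        x5 <- .stack_tensors(tensors, take)
        if (isTRUE(hyper$augment_flip)) {
          d1n <- dim(x5)[1]
          for (b in seq_along(take))
            if (runif(1) < 0.5)
              x5[, , , , b] <- x5[d1n:1, , , , b]
        }
        fw <- net_forward(net, x5, training = TRUE)
        net$state <<- fw$state
        sm <- softmax_ce(fw$logits, y[take])
        if (!is.finite(sm$loss))
          stop("training divergence: non-finite loss at epoch ", ep)
        grads <- net_backward(net, fw$caches, sm$dlogits)
        step <- adam_step(net$params, grads, opt, lr = lr_ep)
        net$params <<- step$params
        opt <<- step$state
        ep_loss <- ep_loss + sm$loss; nb <- nb + 1L
      }
      val_p2 <- .score_tensors(net, tensors, val_idx)
      va <- .auc_rank(val_p2, y[val_idx] == 2L)
      trace <<- rbind(trace, data.frame(epoch = ep, loss = ep_loss / nb,
                                        val_auc = va))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val AUC %.3f", ep,
                        ep_loss / nb, va))
      if (ep < hyper$min_epochs) {
        # burn-in: no checkpointing or stall counting yet
      } else if (va > best$auc + 1e-9) {
        best <<- list(auc = va, params = net$params, state = net$state,
                      epoch = ep)
        stall <- 0L
      } else {
        # on an exact plateau keep the later (more converged) checkpoint:
        # tiny validation folds saturate AUC within a couple of epochs while
        # the scores themselves are still poorly calibrated, and pooled
        # out-of-fold AUC mixes score scales across folds
        if (va >= best$auc - 1e-9)
          best <<- list(auc = best$auc, params = net$params,
                        state = net$state, epoch = ep)
        stall <- stall + 1L
        if (stall >= hyper$patience) break
      }
    }
  })
  net$params <- best$params
  net$state <- best$state
  val_scores <- .score_tensors(net, tensors, val_idx)
  structure(list(net = net, trace = trace, best_epoch = best$epoch,
                 best_val_auc = best$auc, val_scores = val_scores,
                 hyper = hyper, seed = seed),
            class = "TrainRun")
}

#' Five-fold cross-validated training with pooled out-of-fold scores
#'
#' The test subset of the split stays fixed; `k`-fold CV rotates over
#' train + validation. Each fold's model is trained on the other folds and
#' scored on its held-out fold (pooled into one out-of-fold score vector)
#' and on the fixed test set; per-lesion test scores are the mean malignant
#' probability (P2) across fold models.
#'
#' @param tensors Named list of `ModelInputTensor`s (names = case ids) or a
#'   list whose elements carry `case_id`s.
#' @param labels Character labels aligned with `tensors`.
#' @param split A `SplitPlan` from [make_split()].
#' @param config A `NetworkConfig`.
#' @param hyper From [train_hyperparams()].
#' @param seed Base seed; fold f trains with `seed + f`.
#' @param verbose Forwarded to [train_model()].
#' @return List with `runs` (per-fold `TrainRun`s), `oof_scores`
#'   (`data.frame`: case_id, label, fold, P1, P2) and `test_scores`
#'   (`data.frame`: case_id, label, P1, P2).
#' @export
run_cv <- function(tensors, labels, split, config,
                   hyper = train_hyperparams(), seed = 1L, verbose = FALSE) {
  stopifnot(inherits(split, "SplitPlan"))
  ids <- vapply(tensors, function(t) t$case_id, "")
  names(tensors) <- ids
  lab <- setNames(labels, ids)
  folds <- split$fold_assignments
  dev_ids <- names(folds)
  test_ids <- split$test_ids
  if (!all(c(dev_ids, test_ids) %in% ids))
    stop("split references case_ids without tensors")
  runs <- vector("list", split$k)
  oof <- NULL
  test_p2 <- matrix(0, length(test_ids), split$k)
  for (f in seq_len(split$k)) {
    hold_ids <- dev_ids[folds == f]
    fit_ids <- dev_ids[folds != f]
    run <- train_model(tensors, lab[ids],
                       train_idx = match(fit_ids, ids),
                       val_idx = match(hold_ids, ids),
                       config = config, hyper = hyper, seed = seed + f,
                       verbose = verbose)
    runs[[f]] <- run
    oof <- rbind(oof, data.frame(case_id = hold_ids,
                                 label = unname(lab[hold_ids]),
                                 fold = f,
                                 P1 = 1 - run$val_scores,
                                 P2 = run$val_scores))
    if (length(test_ids))
      test_p2[, f] <- .score_tensors(run$net, tensors,
                                     match(test_ids, ids))
  }
  test_scores <- if (length(test_ids))
    data.frame(case_id = test_ids, label = unname(lab[test_ids]),
               P1 = 1 - rowMeans(test_p2), P2 = rowMeans(test_p2))
  list(runs = runs, oof_scores = oof, test_scores = test_scores)
}
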