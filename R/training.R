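# Training: Adam mini-batch loop with best-validation-weight retention,
# end-to-end and branched-frozen strategies, and k-fold cross-validation.

# Generic training loop.  `forward(ix, training)` returns probabilities for
# rows `ix` of the training set; `backward(dz)` backpropagates the
# pre-sigmoid gradient; `val_forward()` returns validation probabilities.
# Retains the weights with the lowest validation loss; stops early after
# `patience` epochs without improvement.
run_training <- function(forward, backward, param_layers,
                         y_train, y_val, val_forward,
                         epochs, batch_size, patience, lr, verbose = FALSE) {
  opt <- adam_new(lr = lr)
  n <- length(y_train)
  best_loss <- Inf
  best_w <- get_weights(param_layers)
  best_epoch <- 0L
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / batch_size)
    tl <- 0
    for (b in seq_len(nb)) {
      ix <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
      p <- forward(ix, TRUE)
      yb <- y_train[ix]
      tl <- tl + bce_loss(yb, p) * length(ix)
      backward(matrix((p - yb) / length(ix), ncol = 1L))
      adam_step(opt, param_layers)
    }
    vp <- val_forward()
    vl <- bce_loss(y_val, vp)
    va <- if (length(unique(y_val)) > 1L) auroc(y_val, vp) else NA_real_
    hist[[ep]] <- data.frame(epoch = ep, train_loss = tl / n,
                             val_loss = vl, val_auroc = va)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  auroc %s",
                      ep, tl / n, vl, format(round(va, 4))))
    if (vl < best_loss) {
      best_loss <- vl
      best_w <- get_weights(param_layers)
      best_epoch <- ep
    } else if (ep - best_epoch >= patience) break
  }
  set_weights(param_layers, best_w)
  list(history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]),
       best_epoch = best_epoch, best_val_loss = best_loss)
}

# Train one branch with a temporary sigmoid head (stage 1 of the branched
# strategy).  Returns the trained branch layers; the temporary head is
# discarded.
train_branch_alone <- function(branch_layers, x_train, y_train, x_val, y_val,
                               in_width, epochs, batch_size, patience, lr,
                               sequence_input, verbose = FALSE) {
  head <- list(layer_dense(in_width, 1L), layer_sigmoid())
  all_layers <- c(branch_layers, head)
  ply <- flatten_param_layers(all_layers)
  take <- if (sequence_input) function(ix) x_train[ix, , drop = FALSE]
          else function(ix) x_train[ix, , drop = FALSE]
  fwd <- function(ix, training) {
    h <- seq_fwd(branch_layers, take(ix), training)
    as.numeric(seq_fwd(head, h, training))
  }
  bwd <- function(dz) {
    dh <- head[[1L]]$bwd(dz)
    seq_bwd(branch_layers, dh)
  }
  vfwd <- function() {
    h <- seq_fwd(branch_layers, x_val, FALSE)
    as.numeric(seq_fwd(head, h, FALSE))
  }
  run_training(fwd, bwd, ply, y_train, y_val, vfwd,
               epochs, batch_size, patience, lr, verbose)
}

#' Fit the hybrid succinylation-site classifier
#'
#' Trains the two-branch network — a learned word-embedding convolutional
#' branch over the 33-residue window and a dense branch over the target-site
#' language-model embedding — with Adam (learning rate 1e-4) under binary
#' cross-entropy loss.  A stratified validation split drives early stopping,
#' and the weights from the best validation-loss epoch are retained.
#'
#' Two training strategies are supported: `"end_to_end"` optimises every
#' weight against the final loss; `"branched"` first trains each branch
#' separately under a temporary sigmoid head, then freezes the branches and
#' trains only the combined head.
#'
#' @param windows Character vector of window strings (or an integer token
#'   matrix from [encode_windows()]).
#' @param plm Numeric matrix (n sites x plm width) of target-site
#'   language-model embeddings.
#' @param labels 0/1 vector of site labels.
#' @param branch Word-branch kind (ignored when `config` is given).
#' @param config A [succnet_config()]; defaults to the published architecture
#'   with `plm_width = ncol(plm)`.
#' @param strategy `"end_to_end"` (default) or `"branched"`.
#' @param epochs Maximum training epochs (default 100).
#' @param batch_size Mini-batch size (default 256).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param validation_fraction Fraction of the data held out (stratified) for
#'   validation when `validation` is not supplied (default 0.1).
#' @param validation Optional list `list(windows =, plm =, labels =)` to use
#'   as the validation set.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param seed Integer seed controlling initialisation, batching, dropout and
#'   the validation split; the fit is deterministic given it.
#' @param verbose Print per-epoch progress.
#' @return Object of class `succnet` with components `model` (the network),
#'   `config`, `history` (per-epoch losses and validation AUROC; for the
#'   branched strategy a list per stage), `fitted.values`, `labels`,
#'   `strategy`, `seed`, `threshold` and `call`.  Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals`, `simulate`,
#'   `plot`, [count_parameters()].
#' @examples
#' syn <- synth_generate(synth_config(n_proteins = 12, sites_per_protein = 4,
#'                                    seed = 7))
#' ds <- balance_undersample(build_site_dataset(syn$proteins, syn$positives), 7)
#' plm <- site_embedding_matrix(syn$embeddings, ds)
#' fit <- succnet(ds$window, plm, ds$label, epochs = 3, seed = 7)
#' head(predict(fit, ds$window, plm))
#' @export
succnet <- function(windows, plm, labels,
                    branch = c("resnet", "conv", "inception"),
                    config = NULL,
                    strategy = c("end_to_end", "branched"),
                    epochs = 100L, batch_size = 256L, patience = 10L,
                    validation_fraction = 0.1, validation = NULL,
                    learning_rate = 1e-4, seed = 1L, verbose = FALSE) {
  strategy <- match.arg(strategy)
  tokens <- encode_windows(windows)
  plm <- as.matrix(plm)
  labels <- as.integer(labels)
  if (nrow(tokens) != nrow(plm) || nrow(tokens) != length(labels))
    stop("windows, plm and labels must agree in length")
  if (anyNA(plm)) stop("plm matrix contains missing values")
  if (is.null(config))
    config <- succnet_config(branch = match.arg(branch), plm_width = ncol(plm))
  if (ncol(plm) != config$plm_width)
    stop("plm width ", ncol(plm), " does not match config plm_width ",
         config$plm_width)
  if (ncol(tokens) != config$window_length)
    stop("window length ", ncol(tokens), " does not match config")

  fit <- with_seed(seed, {
    if (is.null(validation)) {
      idx <- seq_along(labels)
      vix <- sort(unlist(lapply(unique(labels), function(cl) {
        ix <- idx[labels == cl]
        sample(ix, max(1L, round(validation_fraction * length(ix))))
      })))
      tix <- setdiff(idx, vix)
      tr <- list(tokens = tokens[tix, , drop = FALSE],
                 plm = plm[tix, , drop = FALSE], labels = labels[tix])
      va <- list(tokens = tokens[vix, , drop = FALSE],
                 plm = plm[vix, , drop = FALSE], labels = labels[vix])
    } else {
      tr <- list(tokens = tokens, plm = plm, labels = labels)
      va <- list(tokens = encode_windows(validation$windows),
                 plm = as.matrix(validation$plm),
                 labels = as.integer(validation$labels))
    }
    model <- build_hybrid(config)
    if (strategy == "end_to_end") {
      plyrs <- flatten_param_layers(c(model$word, model$mlp, model$head))
      fwd <- function(ix, training)
        net_forward(model, tr$tokens[ix, , drop = FALSE],
                    tr$plm[ix, , drop = FALSE], training)
      bwd <- function(dz) net_backward(model, dz)
      vfwd <- function() net_forward(model, va$tokens, va$plm, FALSE)
      run <- run_training(fwd, bwd, plyrs, tr$labels, va$labels, vfwd,
                          epochs, batch_size, patience, learning_rate, verbose)
      history <- run$history
      stage1_weights <- NULL
    } else {
      run_w <- train_branch_alone(model$word, tr$tokens, tr$labels,
                                  va$tokens, va$labels, config$branch_dense,
                                  epochs, batch_size, patience, learning_rate,
                                  TRUE, verbose)
      run_m <- train_branch_alone(model$mlp, tr$plm, tr$labels,
                                  va$plm, va$labels, config$branch_dense,
                                  epochs, batch_size, patience, learning_rate,
                                  FALSE, verbose)
      branch_layers <- flatten_param_layers(c(model$word, model$mlp))
      for (ly in branch_layers) ly$frozen <- TRUE
      stage1_weights <- get_weights(branch_layers)
      head_layers <- flatten_param_layers(model$head)
      fwd <- function(ix, training)
        net_forward(model, tr$tokens[ix, , drop = FALSE],
                    tr$plm[ix, , drop = FALSE], training,
                    train_word = FALSE, train_mlp = FALSE)
      bwd <- function(dz) net_backward(model, dz, skip_word = TRUE, skip_mlp = TRUE)
      vfwd <- function() net_forward(model, va$tokens, va$plm, FALSE)
      run_h <- run_training(fwd, bwd, c(branch_layers, head_layers),
                            tr$labels, va$labels, vfwd,
                            epochs, batch_size, patience, learning_rate, verbose)
      history <- list(word = run_w$history, mlp = run_m$history,
                      head = run_h$history)
    }
    fitted_all <- net_forward(model, tokens, plm, FALSE)
    list(model = model, history = history, fitted = fitted_all,
         stage1_weights = stage1_weights)
  })

  structure(
    list(model = fit$model, config = config, history = fit$history,
         fitted.values = fit$fitted, labels = labels,
         strategy = strategy, seed = seed, threshold = 0.5,
         stage1_weights = fit$stage1_weights, call = match.call()),
    class = "succnet"
  )
}

#' Predict succinylation probabilities
#'
#' @param object A fitted [succnet()] model.
#' @param windows Window strings or token matrix.
#' @param plm Matrix of target-site language-model embeddings.
#' @param type `"response"` for probabilities, `"class"` for 0/1 calls at
#'   `threshold`.
#' @param threshold Decision threshold for `type = "class"`.
#' @param ... Unused.
#' @return Numeric vector of probabilities, or integer 0/1 vector.
#' @export
predict.succnet <- function(object, windows, plm,
                            type = c("response", "class"),
                            threshold = object$threshold, ...) {
  type <- match.arg(type)
  tokens <- encode_windows(windows)
  plm <- as.matrix(plm)
  if (ncol(plm) != object$config$plm_width)
    stop("plm width ", ncol(plm), " does not match the fitted model (",
         object$config$plm_width, ")")
  p <- net_forward(object$model, tokens, plm, FALSE)
  if (type == "response") p else as.integer(p >= threshold)
}

#' @export
print.succnet <- function(x, ...) {
  cat("Hybrid succinylation-site classifier (", x$config$branch,
      " word branch + MLP), ", count_parameters(x),
      " parameters, ", x$strategy, " training\n", sep = "")
  if (is.data.frame(x$history))
    cat("epochs run:", nrow(x$history), " best val loss:",
        format(min(x$history$val_loss), digits = 4), "\n")
  invisible(x)
}

#' @export
summary.succnet <- function(object, ...) {
  h <- if (is.data.frame(object$history)) object$history else object$history$head
  out <- list(
    branch = object$config$branch,
    strategy = object$strategy,
    n_parameters = count_parameters(object),
    epochs = nrow(h),
    best_val_loss = min(h$val_loss),
    best_val_auroc = if (all(is.na(h$val_auroc))) NA_real_ else
      max(h$val_auroc, na.rm = TRUE),
    train_metrics = compute_metrics(object$labels, object$fitted.values)
  )
  class(out) <- "summary.succnet"
  out
}

#' @export
print.summary.succnet <- function(x, ...) {
  cat("Hybrid site classifier —", x$branch, "branch,", x$strategy, "\n")
  cat("parameters:", x$n_parameters, " epochs:", x$epochs,
      " best val loss:", format(x$best_val_loss, digits = 4),
      " best val AUROC:", format(x$best_val_auroc, digits = 4), "\n")
  cat("training-set metrics:\n")
  print(x$train_metrics)
  invisible(x)
}

#' @export
coef.succnet <- function(object, ...) {
  plyrs <- flatten_param_layers(c(object$model$word, object$model$mlp,
                                  object$model$head))
  out <- list()
  nms <- character(0)
  for (ly in plyrs) for (nm in names(ly$par)) {
    out <- c(out, list(ly$par[[nm]]))
    nms <- c(nms, paste(ly$kind, nm, sep = "."))
  }
  names(out) <- make.unique(nms, sep = "_")
  out
}

#' @export
fitted.succnet <- function(object, ...) object$fitted.values

#' @export
residuals.succnet <- function(object, ...) object$labels - object$fitted.values

#' @export
simulate.succnet <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$fitted.values
  sims <- with_seed(seed, {
    as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  })
  names(sims) <- paste0("sim_", seq_len(nsim))
  sims
}

#' @export
plot.succnet <- function(x, ...) {
  h <- if (is.data.frame(x$history)) x$history else x$history$head
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Partitions the sites into `k` stratified folds (disjoint, exhaustive,
#' class-balanced within one record per class), trains a model on each
#' training complement and evaluates the full metric panel on the held-out
#' fold.
#'
#' @inheritParams succnet
#' @param k Number of folds (default 10); must not exceed either class count.
#' @param ... Further arguments passed to [succnet()] (e.g. `epochs`,
#'   `batch_size`, `config`).
#' @return List with `folds` (assignment vector), `reports` (per-fold
#'   [compute_metrics()] objects) and `summary` (data frame of per-metric
#'   mean and sd across folds).
#' @export
kfold_cv <- function(windows, plm, labels, k = 10L, seed = 1L, ...) {
  labels <- as.integer(labels)
  fold <- stratified_folds(labels, k, seed)
  tokens <- encode_windows(windows)
  plm <- as.matrix(plm)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tix <- which(fold != f)
    vix <- which(fold == f)
    fit <- succnet(tokens[tix, , drop = FALSE], plm[tix, , drop = FALSE],
                   labels[tix], seed = seed_fanout(seed, paste0("fold", f)),
                   ...)
    p <- predict(fit, tokens[vix, , drop = FALSE], plm[vix, , drop = FALSE])
    reports[[f]] <- compute_metrics(labels[vix], p)
  }
  mnames <- c("accuracy", "precision", "recall", "specificity",
              "f1", "mcc", "auroc", "auprc")
  vals <- sapply(mnames, function(m)
    vapply(reports, function(r) r[[m]], numeric(1)))
  list(
    folds = fold,
    reports = reports,
    summary = data.frame(metric = mnames,
                         mean = colMeans(vals),
                         sd = apply(vals, 2, stats::sd),
                         row.names = NULL)
  )
}

#' Save / load a model checkpoint
#'
#' A checkpoint holds the architecture configuration and the weight arrays;
#' loading rebuilds the network and restores the weights.
#'
#' @param object A fitted [succnet()] model.
#' @param path Checkpoint path.
#' @return `write_checkpoint`: `path` invisibly; `read_checkpoint`: a
#'   `succnet` object (history and fitted values as saved).
#' @export
write_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "succnet"))
  plyrs <- flatten_param_layers(c(object$model$word, object$model$mlp,
                                  object$model$head))
  saveRDS(list(config = unclass(object$config), weights = get_weights(plyrs),
               history = object$history, strategy = object$strategy,
               seed = object$seed, threshold = object$threshold,
               labels = object$labels, fitted = object$fitted.values),
          path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  config <- structure(ck$config, class = "succnet_config")
  model <- with_seed(0L, build_hybrid(config))
  plyrs <- flatten_param_layers(c(model$word, model$mlp, model$head))
  set_weights(plyrs, ck$weights)
  structure(
    list(model = model, config = config, history = ck$history,
         fitted.values = ck$fitted, labels = ck$labels,
         strategy = ck$strategy, seed = ck$seed, threshold = ck$threshold,
         stage1_weights = NULL, call = quote(read_checkpoint())),
    class = "succnet"
  )
}
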