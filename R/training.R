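# End-to-end training of the unrolled network: Adam on the mean-squared
# reconstruction loss, with measurements simulated on the fly (y = A x per
# batch), deterministic shuffling under a seed, per-epoch checkpoints and
# optional validation PSNR on held-out images.

#' Training configuration
#'
#' Defaults target full-scale runs: Adam with learning rate 1e-4 for 200
#' epochs over Xavier-initialized parameters, batch size 64, moment
#' constants (0.9, 0.999).  Desk-scale experiments typically raise the
#' learning rate and shrink everything else.
#'
#' @param learning_rate Adam step size
#' @param epochs number of passes over the training set
#' @param batch_size minibatch size
#' @param seed integer seed controlling initialization and shuffling
#' @param beta1,beta2,eps Adam moment/stabilization constants
#' @param checkpoint_dir directory for per-epoch checkpoints (`NULL` = none)
#' @return a `train_config` list
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 200L, batch_size = 64L,
                         seed = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         checkpoint_dir = NULL) {
  if (learning_rate < 0) stop("learning rate must be nonnegative")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Read a training configuration from a YAML file
#'
#' The file may set any argument of [train_config()] (e.g. `learning_rate`,
#' `epochs`, `batch_size`, `seed`); unknown keys are rejected.
#'
#' @param path YAML file path
#' @return a `train_config`
#' @export
read_train_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("package `yaml` required")
  vals <- yaml::read_yaml(path)
  known <- names(formals(train_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop(sprintf("unknown training config key(s): %s", paste(bad, collapse = ", ")))
  do.call(train_config, vals)
}

# recursive elementwise ops over nested parameter/gradient lists
.tree_map2 <- function(a, b, f) {
  out <- a
  for (nm in names(a)) {
    if (is.list(a[[nm]])) out[[nm]] <- .tree_map2(a[[nm]], b[[nm]], f)
    else out[[nm]] <- f(a[[nm]], b[[nm]])
  }
  out
}

.tree_zero <- function(a) {
  out <- a
  for (nm in names(a)) {
    if (is.list(a[[nm]])) out[[nm]] <- .tree_zero(a[[nm]])
    else out[[nm]] <- a[[nm]] * 0
  }
  out
}

.adam_init <- function(phases) {
  list(m = lapply(phases, .zero_phase_grads),
       v = lapply(phases, .zero_phase_grads),
       t = 0L)
}

.adam_step <- function(phases, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (k in seq_along(phases)) {
    state$m[[k]] <- .tree_map2(state$m[[k]], grads[[k]],
                               function(m, g) b1 * m + (1 - b1) * g)
    state$v[[k]] <- .tree_map2(state$v[[k]], grads[[k]],
                               function(v, g) b2 * v + (1 - b2) * g^2)
    upd <- .tree_map2(state$m[[k]], state$v[[k]],
                      function(m, v) cfg$learning_rate * (m / bc1) /
                        (sqrt(v / bc2) + cfg$eps))
    phases[[k]] <- .tree_map2(phases[[k]], upd, function(p, u) p - u)
  }
  list(phases = phases, state = state)
}

#' Train an EPGN / NL-EPGN network on paired patches
#'
#' Measurements are simulated on the fly as `y = A x` for every minibatch.
#' Shuffling is deterministic given `config$seed`, so a run can be replayed
#' exactly; with `checkpoint_dir` set, parameters and optimizer state are
#' written each epoch and training can resume mid-run via `resume_from`.
#'
#' @param net an `epgn_network` (freshly initialized or loaded)
#' @param patches (n, N) matrix of vectorised training images in [0, 1]
#' @param op a `sensing_operator` on n pixels
#' @param config a [train_config()]
#' @param shape image shape `c(H, W)` when not inferable from `op`
#' @param val_patches optional (n, Nv) matrix; per-epoch mean validation PSNR
#'   of direct network reconstructions is recorded when supplied
#' @param resume_from path to a checkpoint written by a previous call with
#'   the same data and config; training restarts from the epoch after it
#' @return list with `net` (trained network), `history` (data.frame with
#'   `epoch`, `loss`, and `val_psnr` when applicable)
#' @export
epgn_train <- function(net, patches, op, config, shape = NULL,
                       val_patches = NULL, resume_from = NULL) {
  stopifnot(inherits(net, "epgn_network"), inherits(config, "train_config"))
  N <- ncol(patches)
  if (N < 1) stop("empty training set")
  state <- .adam_init(net$phases)
  start_epoch <- 1L
  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from)
    net <- ck$net
    state <- ck$extra$adam
    start_epoch <- ck$extra$epoch + 1L
  }
  losses <- rep(NA_real_, config$epochs)
  val <- rep(NA_real_, config$epochs)
  if (!is.null(resume_from) && !is.null(ck$extra$losses)) {
    done <- seq_len(ck$extra$epoch)
    losses[done] <- ck$extra$losses[done]
    val[done] <- ck$extra$val[done]
  }
  last_good <- net
  for (ep in seq(start_epoch, length.out = max(0L, config$epochs - start_epoch + 1L))) {
    set.seed(config$seed + ep)          # replayable epoch shuffling
    ord <- sample.int(N)
    nb <- ceiling(N / config$batch_size)
    ep_loss <- 0; seen <- 0
    for (ib in seq_len(nb)) {
      idx <- ord[((ib - 1L) * config$batch_size + 1L):min(ib * config$batch_size, N)]
      Xb <- patches[, idx, drop = FALSE]
      Yb <- op_forward(op, Xb)
      lg <- .loss_and_grads(net, op, Yb, Xb, shape = shape)
      if (!is.finite(lg$loss))
        stop("non-finite training loss; last good parameters retained in the returned checkpoint")
      upd <- .adam_step(net$phases, lg$grads, state, config)
      net$phases <- upd$phases
      state <- upd$state
      ep_loss <- ep_loss + lg$loss * length(idx)
      seen <- seen + length(idx)
    }
    losses[ep] <- ep_loss / seen
    if (!is.null(val_patches)) {
      rec <- .network_fw(net, op, op_forward(op, val_patches), shape = shape)$x
      val[ep] <- mean(vapply(seq_len(ncol(val_patches)), function(j)
        psnr(rec[, j], val_patches[, j]), numeric(1)))
    }
    last_good <- net
    if (!is.null(config$checkpoint_dir)) {
      dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      save_checkpoint(net, file.path(config$checkpoint_dir,
                                     sprintf("epoch_%04d.rds", ep)),
                      extra = list(adam = state, epoch = ep,
                                   losses = losses, val = val))
    }
  }
  history <- data.frame(epoch = seq_len(config$epochs), loss = losses)
  if (!is.null(val_patches)) history$val_psnr <- val
  list(net = last_good, history = history)
}
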