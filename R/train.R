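#' Training configuration
#'
#' Mirrors the training protocol of the model: mini-batches of 10 samples,
#' Adam, up to 400 epochs with early stopping on validation loss at a
#' patience of 100 epochs. The two physical coefficients share the network
#' learning rate by default: each competes with the response network for
#' overlapping residual signal, and a faster coefficient transiently absorbs
#' response it does not own (see the methods vignette). `alpha` stays
#' nonnegative by projection after each update.
#'
#' @param batch_size Mini-batch size (default 10).
#' @param max_epochs Maximum epochs (default 400).
#' @param patience Early-stopping patience in epochs (default 100); must
#'   not exceed `max_epochs`.
#' @param learning_rate Adam step size for the network weights.
#' @param pde_learning_rate Adam step size for `alpha` and `beta` (default:
#'   same as the weights).
#' @param seed Seed for weight initialization and batch shuffling.
#' @param deterministic Kept for API symmetry; all computation in this
#'   implementation is deterministic given `seed`.
#' @param init_alpha,init_beta Initial coefficient values (`alpha` through
#'   softplus, so it stays positive during optimization).
#' @return Object of class `training_config`.
#' @export
training_config <- function(batch_size = 10, max_epochs = 400,
                            patience = 100, learning_rate = 1e-3,
                            pde_learning_rate = learning_rate, seed = 0,
                            deterministic = TRUE, scalar_warmup_epochs = 15,
                            init_alpha = 0.01, init_beta = 0) {
  if (batch_size < 1) stop("training_config: batch_size must be >= 1")
  if (patience > max_epochs)
    stop("training_config: patience must be <= max_epochs")
  if (learning_rate <= 0 || pde_learning_rate <= 0)
    stop("training_config: learning rates must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 pde_learning_rate = pde_learning_rate,
                 seed = as.integer(seed),
                 deterministic = isTRUE(deterministic),
                 scalar_warmup_epochs = as.integer(scalar_warmup_epochs),
                 init_alpha = init_alpha, init_beta = init_beta),
            class = "training_config")
}

# stack list of cases into normalized (H, W, N) arrays
stack_cases <- function(cases, ns, need_post = TRUE) {
  g <- cases[[1]]$pre$grid
  N <- length(cases)
  pre <- array(0, c(g$n_rows, g$n_cols, N))
  dose <- array(0, c(g$n_rows, g$n_cols, N))
  post <- if (need_post) array(0, c(g$n_rows, g$n_cols, N)) else NULL
  for (k in seq_len(N)) {
    ck <- cases[[k]]
    if (!same_grid(ck$pre$grid, g)) stop("train: cases on different grids")
    pre[, , k] <- ck$pre$values / ns$suv_scale
    dose[, , k] <- ck$dose$values / ns$dose_scale
    if (need_post) {
      if (is.null(ck$post)) stop("train: case ", ck$case_id, " has no post image")
      post[, , k] <- ck$post$values / ns$suv_scale
    }
  }
  list(pre = pre, dose = dose, post = post, grid = g)
}

lap_batch <- function(U3, boundary) {
  out <- U3
  for (b in seq_len(dim(U3)[3]))
    out[, , b] <- discrete_laplacian(U3[, , b], boundary)
  out
}

lap_adjoint_batch <- function(G3, boundary) {
  out <- G3
  for (b in seq_len(dim(G3)[3]))
    out[, , b] <- laplacian_adjoint(G3[, , b], boundary)
  out
}

# forward + backward through the unrolled graph for one batch.
# Returns loss, weight grads, and scalar grads (d a_raw, d beta).
unrolled_batch_grad <- function(net, alpha, beta, pde, pre, dose, post,
                                boundary = "replicate") {
  h <- pde$h; Nt <- pde$n_steps
  d <- dim(pre); H <- d[1]; W <- d[2]; B <- d[3]
  U <- pre
  Us <- vector("list", Nt); laps <- vector("list", Nt)
  caches <- vector("list", Nt)
  running <- net$running
  length(running) <- Nt
  for (n in seq_len(Nt)) {
    laps[[n]] <- lap_batch(U, boundary)
    Us[[n]] <- U
    psi <- array(dose * U, c(H, W, 1L, B))
    fw <- net_forward(psi, net, training = TRUE, step = n)
    running[[n]] <- fw$running
    caches[[n]] <- fw$cache
    U <- U + h * (alpha * laps[[n]]) + h * (beta * U) +
      h * array(fw$out, c(H, W, B))
  }
  if (any(!is.finite(U))) stop("train: non-finite loss (divergence)")
  resid <- U - post
  loss <- sum(resid^2) / B
  g <- 2 * resid / B
  grads <- zero_grads(net)
  da <- 0; db <- 0
  for (n in rev(seq_len(Nt))) {
    da <- da + h * sum(g * laps[[n]])
    db <- db + h * sum(g * Us[[n]])
    nb <- net_backward(array(h * g, c(H, W, 1L, B)), net, caches[[n]], grads)
    grads <- nb$grads
    dpsi <- array(nb$dpsi, c(H, W, B))
    g <- g + h * alpha * lap_adjoint_batch(g, boundary) + h * beta * g +
      dose * dpsi
  }
  list(loss = loss, grads = grads,
       d_alpha = da, d_beta = db, running = running)
}

# validation loss (inference mode), chunked to bound memory
val_loss_eval <- function(net, alpha, beta, pde, data, boundary = "replicate",
                          chunk = 10L) {
  h <- pde$h; Nt <- pde$n_steps
  N <- dim(data$pre)[3]
  tot <- 0
  for (s in seq(1, N, by = chunk)) {
    idx <- s:min(s + chunk - 1L, N)
    U <- data$pre[, , idx, drop = FALSE]
    Dn <- data$dose[, , idx, drop = FALSE]
    d <- dim(U)
    for (n in seq_len(Nt)) {
      lap <- lap_batch(U, boundary)
      psi <- array(Dn * U, c(d[1], d[2], 1L, d[3]))
      out <- net_forward(psi, net, training = FALSE, step = n)$out
      U <- U + h * (alpha * lap) + h * (beta * U) +
        h * array(out, c(d[1], d[2], d[3]))
    }
    tot <- tot + sum((U - data$post[, , idx, drop = FALSE])^2)
  }
  tot / N
}

adam_init <- function(par) lapply(par, function(p)
  if (is.list(p)) lapply(p, function(a) a * 0) else p * 0)

adam_update <- function(par, grad, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  for (nm in names(par)) for (f in names(par[[nm]])) {
    gr <- grad[[nm]][[f]]
    m[[nm]][[f]] <- b1 * m[[nm]][[f]] + (1 - b1) * gr
    v[[nm]][[f]] <- b2 * v[[nm]][[f]] + (1 - b2) * gr^2
    mh <- m[[nm]][[f]] / (1 - b1^t)
    vh <- v[[nm]][[f]] / (1 - b2^t)
    par[[nm]][[f]] <- par[[nm]][[f]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, m = m, v = v)
}

#' Train the unrolled model on paired cases
#'
#' Jointly minimizes the [l2_loss()] over the network weights and the two
#' physical coefficients by Adam on mini-batches, with early stopping on
#' validation loss. Returns the weights of the best validation epoch.
#' All randomness (weight init, batch shuffling) derives from
#' `tcfg$seed`, so two runs with one seed produce identical histories.
#'
#' @param cases Training cases (each must carry a post image).
#' @param val_cases Non-empty validation cases.
#' @param net_cfg A [response_net_config()].
#' @param pde An [rd_params()] fixing `n_steps` and `total_time`.
#' @param tcfg A [training_config()].
#' @param normalization Input scaling constants (see [rd_model()]).
#' @param boundary Laplacian boundary rule.
#' @param resume Optional `rd_model` checkpoint to continue training from
#'   (epoch numbering continues where it left off).
#' @param verbose Print a line every 10 epochs.
#' @return An [rd_model()] with `history` (epochs, train/validation loss),
#'   `initial_val_loss` (validation loss of the untrained model), and
#'   `best_epoch`.
#' @export
train <- function(cases, val_cases, net_cfg = response_net_config(),
                  pde = rd_params(), tcfg = training_config(),
                  normalization = list(suv_scale = 10, dose_scale = 20),
                  boundary = "replicate", resume = NULL, verbose = FALSE) {
  if (length(val_cases) == 0L) stop("train: val_cases must be non-empty")
  tr <- stack_cases(cases, normalization)
  va <- stack_cases(val_cases, normalization)
  if (!is.null(resume)) {
    net <- resume$net
    alpha <- resume$alpha_hat
    beta <- resume$beta_hat
    opt <- resume$optimizer_state
    history <- resume$history
    epoch0 <- if (nrow(history)) max(history$epoch) else 0L
    initial_val <- resume$initial_val_loss
    set.seed(tcfg$seed + epoch0)
  } else {
    net <- build_response_net(net_cfg, seed = tcfg$seed)
    alpha <- tcfg$init_alpha
    beta <- tcfg$init_beta
    opt <- NULL
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    epoch0 <- 0L
    initial_val <- val_loss_eval(net, alpha, beta, pde, va, boundary)
    set.seed(tcfg$seed)
  }
  if (is.null(opt)) {
    opt <- list(m = adam_init(net$params), v = adam_init(net$params),
                ms = c(a = 0, b = 0), vs = c(a = 0, b = 0), t = 0L)
  }
  N <- dim(tr$pre)[3]
  best <- list(val = Inf, net = net, alpha = alpha, beta = beta,
               epoch = epoch0)
  if (nrow(history)) {
    best$val <- min(history$val_loss)
    best$epoch <- history$epoch[which.min(history$val_loss)]
  }
  since_best <- 0L
  for (epoch in (epoch0 + 1L):tcfg$max_epochs) {
    if (epoch0 >= tcfg$max_epochs) break
    perm <- sample.int(N)
    ep_loss <- 0
    for (s in seq(1, N, by = tcfg$batch_size)) {
      idx <- perm[s:min(s + tcfg$batch_size - 1L, N)]
      bg <- unrolled_batch_grad(net, alpha, beta, pde,
                                tr$pre[, , idx, drop = FALSE],
                                tr$dose[, , idx, drop = FALSE],
                                tr$post[, , idx, drop = FALSE], boundary)
      net$running <- bg$running
      ep_loss <- ep_loss + bg$loss * length(idx)
      opt$t <- opt$t + 1L
      up <- adam_update(net$params, bg$grads, opt$m, opt$v,
                        tcfg$learning_rate, opt$t)
      net$params <- up$par; opt$m <- up$m; opt$v <- up$v
      # stage-wise fitting: the physical scalars stay frozen during warm-up
      # (a lone scalar with a consistent gradient outruns the network under
      # Adam and absorbs response signal it cannot own), then learn at
      # pde_learning_rate; alpha is kept nonnegative by projection
      if (epoch > tcfg$scalar_warmup_epochs) {
        gs <- c(a = bg$d_alpha, b = bg$d_beta)
        opt$ms <- 0.9 * opt$ms + 0.1 * gs
        opt$vs <- 0.999 * opt$vs + 0.001 * gs^2
        step <- tcfg$pde_learning_rate *
          (opt$ms / (1 - 0.9^opt$t)) / (sqrt(opt$vs / (1 - 0.999^opt$t)) + 1e-8)
        alpha <- max(alpha - step[["a"]], 0)
        beta <- beta - step[["b"]]
      }
    }
    vl <- val_loss_eval(net, alpha, beta, pde, va, boundary)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / N,
                                         val_loss = vl))
    if (verbose && epoch %% 10 == 0)
      message(sprintf("epoch %d: train %.5g val %.5g alpha %.4g beta %.4g",
                      epoch, ep_loss / N, vl, alpha, beta))
    if (vl < best$val) {
      best <- list(val = vl, net = net, alpha = alpha, beta = beta,
                   epoch = epoch)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= tcfg$patience) break
    }
  }
  rd_model(net = best$net, alpha_hat = unname(best$alpha),
           beta_hat = unname(best$beta),
           pde = pde, normalization = normalization, history = history,
           initial_val_loss = initial_val, best_epoch = best$epoch,
           training_config = tcfg, optimizer_state = opt,
           boundary = boundary)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized file plus a human-readable JSON
#' sidecar (`<path>.json`) with the configuration, normalization,
#' coefficients, and training history.
#'
#' @param model An `rd_model`.
#' @param path Checkpoint file path.
#' @return `path` (invisibly) for `save_checkpoint`; the `rd_model` for
#'   `load_checkpoint`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  side <- list(alpha_hat = model$alpha_hat, beta_hat = model$beta_hat,
               pde = unclass(model$pde),
               normalization = model$normalization,
               net_config = if (!is.null(model$net)) unclass(model$net$config),
               best_epoch = model$best_epoch,
               history = model$history)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("load_checkpoint: no checkpoint at ", path)
  m <- readRDS(path)
  if (!inherits(m, "rd_model")) stop("load_checkpoint: not an rd_model")
  m
}
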