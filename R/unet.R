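#' U-Net architecture configuration
#'
#' A symmetric encoder-decoder segmentation network with skip connections
#' at every resolution level. Each level applies two 3x3 convolutions,
#' each followed by an instance-normalization layer and a ReLU; channel
#' counts double at every pooling. `residual_blocks` switches every
#' double-convolution block to a residual block (identity/1x1-projection
#' shortcut), giving the residual variant of the network.
#'
#' @param input_size square input side length in pixels; must be divisible
#'   by `2^depth`. 256 is the full-scale profile; 128 with
#'   `base_channels = 16` is the reduced desk profile used for tests.
#' @param depth number of encoder levels (poolings); the bottleneck sits at
#'   `input_size / 2^depth` pixels.
#' @param base_channels channels of the first level (>= 4); doubled per
#'   level.
#' @param normalization `"instance"` (per-image, per-channel; the variant
#'   used here) or `"none"`.
#' @param residual_blocks logical: use residual double-conv blocks.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(input_size = 256L, depth = 4L, base_channels = 32L,
                        normalization = c("instance", "none"),
                        residual_blocks = FALSE) {
  normalization <- match.arg(normalization)
  stop_if(input_size %% 2^depth != 0,
          "input_size (%d) must be divisible by 2^depth (%d)",
          input_size, 2^depth)
  stop_if(base_channels < 4, "base_channels must be >= 4")
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 normalization = normalization,
                 residual_blocks = isTRUE(residual_blocks)),
            class = "unet_config")
}

#' Desk-scale U-Net profile
#'
#' A reduced configuration (128x128 inputs, 16 base channels, depth 3)
#' that trains in minutes on one CPU while exercising the identical code
#' path as the full-scale 256x256 network.
#'
#' @param residual_blocks logical, as in [unet_config()].
#' @return A `unet_config`.
#' @export
unet_desk_profile <- function(residual_blocks = FALSE) {
  unet_config(input_size = 128L, depth = 3L, base_channels = 16L,
              residual_blocks = residual_blocks)
}

#' Training configuration
#'
#' Adam optimization of the Dice loss with a reduce-on-plateau learning
#' rate schedule and early stopping: the learning rate is multiplied by
#' `lr_decay_factor` when the validation loss has not improved for
#' `plateau_patience` epochs, and training stops after
#' `early_stop_patience` epochs without improvement (or at `max_epochs`).
#' Cross-validation folds are formed at the exam level: all slices of one
#' exam stay in the same fold.
#'
#' @param initial_lr initial learning rate.
#' @param plateau_patience epochs of stagnant validation loss before the
#'   learning rate decays.
#' @param lr_decay_factor multiplicative decay (in (0, 1)).
#' @param early_stop_patience epochs of stagnant validation loss before
#'   training stops.
#' @param max_epochs epoch budget.
#' @param k_folds number of cross-validation folds (>= 2).
#' @param loss `"dice"`, `"focal"` or `"tversky"`.
#' @param batch_size images per optimizer step.
#' @param seed integer seed controlling weight init, fold assignment,
#'   shuffling and augmentation.
#' @param augment logical: apply random geometric augmentation
#'   ([augment_pair()]) to training frames.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.001, plateau_patience = 5L,
                         lr_decay_factor = 0.1, early_stop_patience = 16L,
                         max_epochs = 200L, k_folds = 5L,
                         loss = c("dice", "focal", "tversky"),
                         batch_size = 8L, seed = 1L, augment = FALSE) {
  loss <- match.arg(loss)
  stop_if(k_folds < 2, "k_folds must be >= 2")
  stop_if(!(lr_decay_factor > 0 && lr_decay_factor < 1),
          "lr_decay_factor must be in (0, 1)")
  stop_if(plateau_patience < 1 || early_stop_patience < 1,
          "patience values must be >= 1")
  structure(list(initial_lr = initial_lr,
                 plateau_patience = as.integer(plateau_patience),
                 lr_decay_factor = lr_decay_factor,
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 k_folds = as.integer(k_folds), loss = loss,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = isTRUE(augment)),
            class = "train_config")
}

# ---- Parameter initialization ---------------------------------------------

conv_init <- function(cin, cout, k) {
  list(w = matrix(stats::rnorm(k * k * cin * cout, 0,
                               sqrt(2 / (k * k * cin))), k * k * cin, cout),
       b = numeric(cout))
}

norm_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))

block_init <- function(cin, cout, residual) {
  p <- list(conv1 = conv_init(cin, cout, 3L), n1 = norm_init(cout),
            conv2 = conv_init(cout, cout, 3L), n2 = norm_init(cout))
  if (residual && cin != cout) p$proj <- conv_init(cin, cout, 1L)
  p
}

#' Build an (untrained) U-Net model
#'
#' Initializes all convolution weights with He (Kaiming) normal
#' initialization under the given seed; identical seeds give identical
#' initial weights.
#'
#' @param config a [unet_config()].
#' @param seed integer seed for the weight initialization.
#' @return An object of class `unet_model` with fields `config`, `params`,
#'   `fold_history` (NULL until trained).
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  d <- config$depth; base <- config$base_channels; res <- config$residual_blocks
  ch <- base * 2^(0:d)  # ch[l] = channels at encoder level l; ch[d+1] bottleneck
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (l in seq_len(d)) {
      p[[paste0("enc", l)]] <- block_init(cin, ch[l], res)
      cin <- ch[l]
    }
    p$bot <- block_init(ch[d], ch[d + 1], res)
    for (l in rev(seq_len(d))) {
      p[[paste0("dec", l, "_up")]] <- conv_init(ch[l + 1], ch[l], 3L)
      p[[paste0("dec", l, "_upn")]] <- norm_init(ch[l])
      p[[paste0("dec", l)]] <- block_init(2L * ch[l], ch[l], res)
    }
    p$final <- conv_init(ch[1], 1L, 1L)
    p
  })
  structure(list(config = config, params = params, fold_history = NULL,
                 train_config = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model: input %d, depth %d, base %d, %s norm%s%s>\n",
              x$config$input_size, x$config$depth, x$config$base_channels,
              x$config$normalization,
              if (x$config$residual_blocks) ", residual" else "",
              if (is.null(x$fold_history)) ", untrained" else ", trained"))
  invisible(x)
}

# ---- Layer forward/backward ------------------------------------------------

IN_EPS <- 1e-5

in_fw <- function(x, p, enabled) {
  d <- dim(x)
  if (!enabled) return(list(y = x, cache = NULL))
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  istd <- 1 / sqrt(colMeans(xc^2) + IN_EPS)
  xhat <- xc * rep(istd, each = n)
  y <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
  list(y = array(y, d), cache = list(xhat = xhat, istd = istd, dim = d))
}

in_bw <- function(gout, p, cache) {
  if (is.null(cache)) return(list(gx = gout, ggamma = NULL, gbeta = NULL))
  d <- cache$dim
  n <- d[1] * d[2]
  g <- matrix(gout, n, d[3])
  ggamma <- colSums(g * cache$xhat)
  gbeta <- colSums(g)
  gxhat <- g * rep(p$gamma, each = n)
  m1 <- colMeans(gxhat)
  m2 <- colMeans(gxhat * cache$xhat)
  gx <- (gxhat - rep(m1, each = n) - cache$xhat * rep(m2, each = n)) *
    rep(cache$istd, each = n)
  list(gx = array(gx, d), ggamma = ggamma, gbeta = gbeta)
}

block_fw <- function(x, p, norm_on, residual) {
  c1 <- .conv2d_fw(x, p$conv1$w, p$conv1$b, 3L)
  n1 <- in_fw(c1, p$n1, norm_on)
  r1 <- pmax(n1$y, 0)
  c2 <- .conv2d_fw(r1, p$conv2$w, p$conv2$b, 3L)
  n2 <- in_fw(c2, p$n2, norm_on)
  pre <- n2$y
  if (residual) {
    sc <- if (!is.null(p$proj)) .conv2d_fw(x, p$proj$w, p$proj$b, 1L) else x
    pre <- pre + sc
  }
  y <- pmax(pre, 0)
  list(y = y, cache = list(x = x, n1 = n1$cache, r1 = r1, n2 = n2$cache,
                           pre = pre))
}

block_bw <- function(gout, p, cache, norm_on, residual, need_gx = TRUE) {
  g <- gout * (cache$pre > 0)
  grads <- list()
  gsc <- NULL
  if (residual) {
    if (!is.null(p$proj)) {
      bwp <- .conv2d_bw(cache$x, p$proj$w, g, 1L)
      grads$proj <- list(w = bwp$gw, b = bwp$gb)
      gsc <- if (need_gx) bwp$gx else NULL
    } else gsc <- if (need_gx) g else NULL
  }
  b2 <- in_bw(g, p$n2, cache$n2)
  grads$n2 <- list(gamma = b2$ggamma, beta = b2$gbeta)
  bw2 <- .conv2d_bw(cache$r1, p$conv2$w, b2$gx, 3L, TRUE)
  grads$conv2 <- list(w = bw2$gw, b = bw2$gb)
  g1 <- bw2$gx * (cache$r1 > 0)
  b1 <- in_bw(g1, p$n1, cache$n1)
  grads$n1 <- list(gamma = b1$ggamma, beta = b1$gbeta)
  bw1 <- .conv2d_bw(cache$x, p$conv1$w, b1$gx, 3L, need_gx)
  grads$conv1 <- list(w = bw1$gw, b = bw1$gb)
  gx <- NULL
  if (need_gx) {
    gx <- bw1$gx
    if (!is.null(gsc)) gx <- gx + gsc
  }
  list(gx = gx, grads = grads)
}

# Full forward pass; x is an [H, W] matrix. Returns the sigmoid probability
# map and (optionally) the caches needed for backpropagation.
unet_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$config; p <- model$params
  d <- cfg$depth
  norm_on <- cfg$normalization == "instance"
  res <- cfg$residual_blocks
  h <- array(x, c(dim(x), 1L))
  caches <- list(); skips <- list(); pools <- list()
  for (l in seq_len(d)) {
    bf <- block_fw(h, p[[paste0("enc", l)]], norm_on, res)
    skips[[l]] <- bf$y
    caches[[paste0("enc", l)]] <- bf$cache
    mp <- .maxpool2_fw(bf$y)
    pools[[l]] <- mp$idx
    h <- mp$out
  }
  bf <- block_fw(h, p$bot, norm_on, res)
  caches$bot <- bf$cache
  h <- bf$y
  for (l in rev(seq_len(d))) {
    up <- .upsample2_fw(h)
    cu <- .conv2d_fw(up, p[[paste0("dec", l, "_up")]]$w,
                     p[[paste0("dec", l, "_up")]]$b, 3L)
    nu <- in_fw(cu, p[[paste0("dec", l, "_upn")]], norm_on)
    ru <- pmax(nu$y, 0)
    cat_in <- abind3(skips[[l]], ru)
    bf <- block_fw(cat_in, p[[paste0("dec", l)]], norm_on, res)
    caches[[paste0("dec", l)]] <- list(up_x = up, nu = nu$cache, ru = ru,
                                       block = bf$cache,
                                       skip_ch = dim(skips[[l]])[3])
    h <- bf$y
  }
  logits <- .conv2d_fw(h, p$final$w, p$final$b, 1L)[, , 1]
  prob <- 1 / (1 + exp(-logits))
  out <- list(prob = prob)
  if (want_cache) {
    caches$final_in <- h
    caches$pools <- pools
    out$cache <- caches
  }
  out
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# Backward pass from the gradient of the loss w.r.t. the probability map.
# Returns the flat gradient tree matching model$params.
unet_backward <- function(model, prob, cache, gprob) {
  cfg <- model$config; p <- model$params
  d <- cfg$depth
  norm_on <- cfg$normalization == "instance"
  res <- cfg$residual_blocks
  glogits <- gprob * prob * (1 - prob)
  g <- array(glogits, c(dim(glogits), 1L))
  grads <- list()
  bwf <- .conv2d_bw(cache$final_in, p$final$w, g, 1L, TRUE)
  grads$final <- list(w = bwf$gw, b = bwf$gb)
  g <- bwf$gx
  gskips <- vector("list", d)
  for (l in seq_len(d)) {
    cc <- cache[[paste0("dec", l)]]
    bb <- block_bw(g, p[[paste0("dec", l)]], cc$block, norm_on, res)
    grads[[paste0("dec", l)]] <- bb$grads
    nsk <- cc$skip_ch
    gskips[[l]] <- bb$gx[, , seq_len(nsk), drop = FALSE]
    gru <- bb$gx[, , nsk + seq_len(dim(bb$gx)[3] - nsk), drop = FALSE]
    gnu <- gru * (cc$ru > 0)
    bun <- in_bw(gnu, p[[paste0("dec", l, "_upn")]], cc$nu)
    grads[[paste0("dec", l, "_upn")]] <- list(gamma = bun$ggamma,
                                              beta = bun$gbeta)
    bcu <- .conv2d_bw(cc$up_x, p[[paste0("dec", l, "_up")]]$w, bun$gx, 3L,
                      TRUE)
    grads[[paste0("dec", l, "_up")]] <- list(w = bcu$gw, b = bcu$gb)
    g <- .upsample2_bw(bcu$gx)
  }
  bb <- block_bw(g, p$bot, cache$bot, norm_on, res)
  grads$bot <- bb$grads
  g <- bb$gx
  for (l in rev(seq_len(d))) {
    sz <- dim(cache[[paste0("enc", l)]]$pre)
    g <- .maxpool2_bw(g, cache$pools[[l]], sz[1], sz[2])
    g <- g + gskips[[l]]
    bb <- block_bw(g, p[[paste0("enc", l)]], cache[[paste0("enc", l)]],
                   norm_on, res, need_gx = (l > 1L))
    grads[[paste0("enc", l)]] <- bb$grads
    g <- bb$gx
  }
  grads
}

# ---- Losses ----------------------------------------------------------------

#' Soft Dice loss
#'
#' `1 - 2 * sum(p*g) / (sum(p) + sum(g) + eps)` between a probability map
#' and a binary mask. On hard (0/1) predictions this equals one minus the
#' Dice coefficient computed from TP/FP/FN counts, up to the smoothing
#' constant that keeps the loss defined on empty masks.
#'
#' @param prob 2D probability map in `[0, 1]`.
#' @param mask 2D binary matrix of the same shape.
#' @param smooth smoothing constant added to the denominator.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(prob, mask, smooth = 1e-6) {
  stop_if(!identical(dim(prob), dim(mask)), "shapes differ")
  1 - 2 * sum(prob * mask) / (sum(prob) + sum(mask) + smooth)
}

# loss + gradient wrt prob, for training
loss_grad <- function(prob, mask, kind, smooth = 1e-6) {
  if (kind == "dice") {
    I <- sum(prob * mask); S <- sum(prob) + sum(mask) + smooth
    list(loss = 1 - 2 * I / S, grad = -(2 * mask * S - 2 * I) / S^2)
  } else if (kind == "focal") {
    gam <- 2; eps <- 1e-7
    p <- pmin(pmax(prob, eps), 1 - eps)
    lpos <- -(1 - p)^gam * log(p)
    lneg <- -p^gam * log(1 - p)
    n <- length(p)
    gpos <- (1 - p)^(gam - 1) * (gam * log(p) * p - (1 - p)) / p
    gneg <- p^(gam - 1) * (p - gam * log(1 - p) * (1 - p)) / (1 - p)
    list(loss = sum(mask * lpos + (1 - mask) * lneg) / n,
         grad = (mask * gpos + (1 - mask) * gneg) / n)
  } else {  # tversky, alpha weights FP, beta weights FN
    al <- 0.3; be <- 0.7
    I <- sum(prob * mask)
    FP <- sum(prob * (1 - mask)); FN <- sum((1 - prob) * mask)
    den <- I + al * FP + be * FN + smooth
    gI <- mask; gFP <- 1 - mask; gFN <- -mask
    gden <- gI + al * gFP + be * gFN
    list(loss = 1 - I / den, grad = -(gI * den - I * gden) / den^2)
  }
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  zeros <- rapply(params, function(a) a * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

acc_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  rapply2(acc, g, `+`)
}

rapply2 <- function(a, b, f) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- rapply2(a[[nm]], b[[nm]], f)
    a
  } else f(a, b)
}

scale_grads <- function(g, s) rapply(g, function(a) a * s, how = "replace")

# ---- Training --------------------------------------------------------------

# Learning-rate scheduler + early-stopping state machine, factored out so
# its contract is testable without running the optimizer. Feed it the
# validation loss once per epoch.
scheduler_init <- function(cfg) {
  list(lr = cfg$initial_lr, best = Inf, best_epoch = 0L, epoch = 0L,
       stall = 0L, plateau_stall = 0L, stop = FALSE, cfg = cfg)
}

scheduler_step <- function(st, val_loss) {
  st$epoch <- st$epoch + 1L
  if (val_loss < st$best - 1e-9) {
    st$best <- val_loss; st$best_epoch <- st$epoch
    st$stall <- 0L; st$plateau_stall <- 0L
  } else {
    st$stall <- st$stall + 1L
    st$plateau_stall <- st$plateau_stall + 1L
    if (st$plateau_stall >= st$cfg$plateau_patience) {
      st$lr <- st$lr * st$cfg$lr_decay_factor
      st$plateau_stall <- 0L
    }
    if (st$stall >= st$cfg$early_stop_patience) st$stop <- TRUE
  }
  st
}

# One optimization pass over a set of frames (list of list(x=, y=)).
# Returns updated params/state and the mean training loss.
train_epoch <- function(model, frames, opt, lr, loss_kind, batch_size,
                        augment, aug_seed) {
  ord <- sample.int(length(frames))
  total <- 0
  bacc <- NULL; bn <- 0
  for (i in seq_along(ord)) {
    fr <- frames[[ord[i]]]
    x <- fr$x; y <- fr$y
    if (augment) {
      ap <- augment_pair(x, y, seed = aug_seed * 1e4 + i)
      x <- ap$frame; y <- ap$mask
    }
    fwd <- unet_forward(model, x, want_cache = TRUE)
    lg <- loss_grad(fwd$prob, y, loss_kind)
    total <- total + lg$loss
    g <- unet_backward(model, fwd$prob, fwd$cache, lg$grad)
    bacc <- acc_grads(bacc, g); bn <- bn + 1
    if (bn == batch_size || i == length(ord)) {
      step <- adam_step(model$params, scale_grads(bacc, 1 / bn), opt, lr)
      model$params <- step$params
      opt <- step$state
      bacc <- NULL; bn <- 0
    }
  }
  list(model = model, opt = opt, loss = total / length(frames))
}

eval_loss <- function(model, frames, loss_kind) {
  mean(vapply(frames, function(fr) {
    loss_grad(unet_forward(model, fr$x)$prob, fr$y, loss_kind)$loss
  }, 0))
}

exam_frames <- function(ex) {
  nt <- dim(ex$cine$frames)[1]
  lapply(seq_len(nt), function(t)
    list(x = ex$cine$frames[t, , ], y = ex$masks$frames[t, , ]))
}

# Core single-split training loop with scheduling; returns trained params,
# history data.frame and the stopping epoch.
fit_split <- function(model, train_frames, val_frames, cfg, fold_id = 0L,
                      verbose = FALSE) {
  opt <- adam_state(model$params)
  st <- scheduler_init(cfg)
  best_params <- model$params
  hist <- list()
  for (ep in seq_len(cfg$max_epochs)) {
    te <- train_epoch(model, train_frames, opt, st$lr, cfg$loss,
                      cfg$batch_size, cfg$augment, cfg$seed + ep)
    model <- te$model; opt <- te$opt
    vl <- if (length(val_frames)) eval_loss(model, val_frames, cfg$loss)
    else te$loss
    prev_best <- st$best
    st <- scheduler_step(st, vl)
    if (vl < prev_best) best_params <- model$params
    hist[[ep]] <- data.frame(fold = fold_id, epoch = ep, lr = st$lr,
                             train_loss = te$loss, val_loss = vl)
    if (verbose)
      message(sprintf("fold %d epoch %3d lr %.2g train %.4f val %.4f",
                      fold_id, ep, st$lr, te$loss, vl))
    if (st$stop) break
  }
  model$params <- best_params
  list(model = model, history = do.call(rbind, hist),
       best_epoch = st$best_epoch)
}

#' Train a U-Net on paired cine/mask exams
#'
#' Runs exam-level K-fold cross-validation (every exam's slices confined
#' to a single fold) with Adam, reduce-on-plateau learning rate and early
#' stopping, then retrains on all exams for the median best-epoch count
#' found across folds. With `cross_validate = FALSE` a single held-out
#' validation exam set drives the schedule instead, which is the fast path
#' for large phantom corpora.
#'
#' @param exams list of exams, each a `list(cine = cine_sequence, masks =
#'   mask_sequence)` with frames already preprocessed to the model input
#'   size and `[0, 1]` intensity range.
#' @param config a [unet_config()].
#' @param cfg a [train_config()].
#' @param cross_validate logical: run the full K-fold protocol (default)
#'   or a single split with `holdout` validation exams.
#' @param holdout number of exams used as the validation set when
#'   `cross_validate = FALSE`.
#' @param verbose print per-epoch progress.
#' @return A trained `unet_model`; `fold_history` holds the per-fold
#'   epoch/lr/loss curves and the exam-to-fold assignment.
#' @export
train_unet <- function(exams, config = unet_config(), cfg = train_config(),
                       cross_validate = TRUE, holdout = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "unet_config"), inherits(cfg, "train_config"))
  n_ex <- length(exams)
  ids <- vapply(exams, function(e) e$cine$exam_id, "")
  stop_if(anyDuplicated(ids) > 0, "exam_ids must be unique")
  for (e in exams)
    stop_if(sum(e$masks$frames) == 0, "exam '%s' has empty masks throughout",
            e$cine$exam_id)
  frames_by_exam <- lapply(exams, exam_frames)

  if (cross_validate) {
    stop_if(n_ex < cfg$k_folds, "need at least k_folds = %d exams, got %d",
            cfg$k_folds, n_ex)
    fold_of <- with_seed(cfg$seed,
                         sample(rep_len(seq_len(cfg$k_folds), n_ex)))
    hist <- list(); best_eps <- integer(0)
    for (k in seq_len(cfg$k_folds)) {
      model <- build_unet(config, seed = cfg$seed)
      tr <- unlist(frames_by_exam[fold_of != k], recursive = FALSE)
      va <- unlist(frames_by_exam[fold_of == k], recursive = FALSE)
      fit <- fit_split(model, tr, va, cfg, fold_id = k, verbose = verbose)
      hist[[k]] <- fit$history
      best_eps <- c(best_eps, max(1L, fit$best_epoch))
    }
    final_epochs <- max(1L, round(stats::median(best_eps)))
    cfg_final <- cfg
    cfg_final$max_epochs <- final_epochs
    model <- build_unet(config, seed = cfg$seed)
    all_frames <- unlist(frames_by_exam, recursive = FALSE)
    fit <- fit_split(model, all_frames, list(), cfg_final, fold_id = 0L,
                     verbose = verbose)
    model <- fit$model
    model$fold_history <- list(
      folds = data.frame(exam_id = ids, fold = fold_of),
      history = rbind(do.call(rbind, hist), fit$history),
      final_epochs = final_epochs)
  } else {
    stop_if(n_ex < holdout + 1, "need more exams than holdout")
    idx <- with_seed(cfg$seed, sample.int(n_ex))
    va_ids <- idx[seq_len(holdout)]
    tr <- unlist(frames_by_exam[-va_ids], recursive = FALSE)
    va <- unlist(frames_by_exam[va_ids], recursive = FALSE)
    model <- build_unet(config, seed = cfg$seed)
    fit <- fit_split(model, tr, va, cfg, fold_id = 1L, verbose = verbose)
    model <- fit$model
    model$fold_history <- list(
      folds = data.frame(exam_id = ids,
                         fold = ifelse(seq_len(n_ex) %in% va_ids, 1L, 0L)),
      history = fit$history, final_epochs = fit$best_epoch)
  }
  model$train_config <- cfg
  model
}

#' Segment a cine sequence with a trained model
#'
#' Runs the network frame by frame, thresholds the sigmoid probability map
#' at 0.5, keeps only the largest 4-connected component (there is a single
#' target vessel per frame) and fills interior holes (the lumen is simply
#' connected; flow-artifact dropouts must not punch holes into the area
#' count). An all-background prediction yields a valid empty mask.
#'
#' @param model a trained `unet_model`.
#' @param sequence a `cine_sequence` preprocessed to the model input size.
#' @param threshold probability threshold.
#' @param fill_holes logical: fill interior background components.
#' @return A `mask_sequence`.
#' @export
predict_mask <- function(model, sequence, threshold = 0.5,
                         fill_holes = TRUE) {
  stopifnot(inherits(model, "unet_model"), inherits(sequence, "cine_sequence"))
  d <- dim(sequence$frames)
  stop_if(d[2] %% 2^model$config$depth != 0 || d[3] %% 2^model$config$depth != 0,
          "frame size %dx%d incompatible with model depth %d",
          d[2], d[3], model$config$depth)
  out <- array(0L, d)
  for (t in seq_len(d[1])) {
    prob <- unet_forward(model, sequence$frames[t, , ])$prob
    m <- largest_component(prob > threshold)
    if (fill_holes) m <- fill_mask_holes(m)
    out[t, , ] <- m
  }
  mask_sequence(out, sequence$pixel_spacing, exam_id = sequence$exam_id)
}

#' Fill interior holes of a binary mask
#'
#' Background components not connected to the image border are relabelled
#' as foreground.
#'
#' @param mask binary matrix.
#' @return Binary integer matrix with holes filled.
#' @export
fill_mask_holes <- function(mask) {
  m <- matrix(as.integer(mask > 0.5), nrow(mask), ncol(mask))
  bg <- .label_components(1L - m)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  matrix(as.integer(m == 1L | !(bg %in% border_labels) & bg > 0),
         nrow(m), ncol(m))
}

#' Keep the largest 4-connected component of a binary mask
#' @param mask binary matrix.
#' @return Binary integer matrix with only the largest component (all
#'   zeros when the input is empty).
#' @export
largest_component <- function(mask) {
  m <- matrix(as.integer(mask > 0.5), nrow(mask), ncol(mask))
  if (sum(m) == 0) return(m)
  lab <- .label_components(m)
  sizes <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(sizes)), nrow(m), ncol(m))
}

# ---- Checkpointing ---------------------------------------------------------

#' Save a model checkpoint
#'
#' Weights are serialized to RDS; a JSON sidecar carries the architecture
#' and training configuration for inspection. `load_model` restores a
#' model whose predictions are bit-identical to the saved one.
#'
#' @param model a `unet_model`; @param path checkpoint path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  side <- list(unet_config = unclass(model$config))
  if (!is.null(model$train_config))
    side$train_config <- unclass(model$train_config)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path checkpoint path.
#' @return A `unet_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_model"))
  model
}

#' Write a training log as CSV
#' @param model a trained `unet_model`; @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(model, path) {
  stop_if(is.null(model$fold_history), "model has no training history")
  utils::write.csv(model$fold_history$history, path, row.names = FALSE)
  invisible(path)
}
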