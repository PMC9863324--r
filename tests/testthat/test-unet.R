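test_that("configuration invariants are enforced", {
  expect_error(unet_config(input_size = 100, depth = 3), "divisible")
  expect_error(unet_config(base_channels = 2), "base_channels")
  cfg <- unet_config(input_size = 256, depth = 4)
  expect_equal(cfg$input_size / 2^cfg$depth, 16)  # bottleneck spatial size
  expect_error(train_config(k_folds = 1), "k_folds")
  expect_error(train_config(lr_decay_factor = 1.5), "decay_factor")
})

test_that("forward pass maps a frame to a probability map of the same size", {
  cfg <- unet_config(input_size = 32, depth = 2, base_channels = 4)
  model <- build_unet(cfg, seed = 1)
  x <- matrix(runif(32 * 32), 32, 32)
  p <- aortaflex:::unet_forward(model, x)$prob
  expect_identical(dim(p), c(32L, 32L))
  expect_true(all(p > 0 & p < 1))
  model2 <- build_unet(cfg, seed = 1)
  expect_identical(model$params, model2$params)  # seeded init
  model3 <- build_unet(cfg, seed = 2)
  expect_false(identical(model$params, model3$params))
})

test_that("soft Dice loss agrees with hard-count Dice on binary masks", {
  a <- matrix(0, 20, 20); a[1:10, 1:10] <- 1
  b <- matrix(0, 20, 20); b[6:15, 1:10] <- 1
  expect_equal(dice_loss(a, a), 0, tolerance = 1e-5)
  d <- matrix(0, 20, 20); d[15:20, 15:20] <- 1
  expect_equal(dice_loss(a, d), 1, tolerance = 1e-5)
  expect_equal(dice_loss(a, b), 0.5, tolerance = 1e-5)
  expect_equal(dice_loss(a, b), 1 - dice_coefficient(a, b), tolerance = 1e-5)
  set.seed(3)
  for (i in 1:10) {
    p <- random_mask(15, 0.4); g <- random_mask(15, 0.4)
    expect_equal(dice_loss(p, g), 1 - dice_coefficient(p, g),
                 tolerance = 1e-4)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- unet_config(input_size = 16, depth = 2, base_channels = 4,
                     residual_blocks = TRUE)
  model <- build_unet(cfg, seed = 2)
  set.seed(4)
  x <- matrix(runif(256), 16, 16)
  y <- matrix(rbinom(256, 1, 0.3), 16, 16)
  fwd <- aortaflex:::unet_forward(model, x, want_cache = TRUE)
  for (loss in c("dice", "focal", "tversky")) {
    lg <- aortaflex:::loss_grad(fwd$prob, y, loss)
    gr <- aortaflex:::unet_backward(model, fwd$prob, fwd$cache, lg$grad)
    lossfn <- function(m)
      aortaflex:::loss_grad(aortaflex:::unet_forward(m, x)$prob, y, loss)$loss
    base <- lg$loss
    eps <- 1e-6
    checks <- list(
      list(c("enc2", "conv1", "w"), 5), list(c("bot", "conv2", "w"), 17),
      list(c("dec1", "n1", "gamma"), 2), list(c("final", "w"), 1),
      list(c("enc1", "proj", "w"), 3))
    for (ch in checks) {
      path <- ch[[1]]; idx <- ch[[2]]
      m2 <- model
      m2$params[[path]][idx] <- m2$params[[path]][idx] + eps
      fd <- (lossfn(m2) - base) / eps
      expect_equal(gr[[path]][idx], fd, tolerance = 1e-3)
    }
  }
})

test_that("scheduler decays the learning rate and stops on stagnation", {
  cfg <- train_config(initial_lr = 0.001, plateau_patience = 5,
                      lr_decay_factor = 0.1, early_stop_patience = 16)
  st <- aortaflex:::scheduler_init(cfg)
  # strictly improving validation loss: no decay, no stop
  for (v in seq(1, 0.1, length.out = 20)) st <- aortaflex:::scheduler_step(st, v)
  expect_equal(st$lr, 0.001)
  expect_false(st$stop)
  # stagnation: decay by 0.1 after exactly 5 flat epochs
  st <- aortaflex:::scheduler_init(cfg)
  st <- aortaflex:::scheduler_step(st, 0.5)
  for (i in 1:4) st <- aortaflex:::scheduler_step(st, 0.5)
  expect_equal(st$lr, 0.001)
  st <- aortaflex:::scheduler_step(st, 0.5)              # 5th stagnant epoch
  expect_equal(st$lr, 0.001 * 0.1, tolerance = 1e-12)
  # early stop after 16 stagnant epochs
  st <- aortaflex:::scheduler_init(cfg)
  st <- aortaflex:::scheduler_step(st, 0.5)
  for (i in 1:15) {
    st <- aortaflex:::scheduler_step(st, 0.5)
    expect_false(st$stop)
  }
  st <- aortaflex:::scheduler_step(st, 0.5)
  expect_true(st$stop)
})

test_that("exam-level folds never split an exam", {
  exams <- lapply(1:5, function(i) small_exam(input = 32, n_frames = 2,
                                              seed = i))
  exams <- lapply(seq_along(exams), function(i) {
    e <- exams[[i]]
    e$cine$exam_id <- e$masks$exam_id <- sprintf("ex%02d", i)
    e
  })
  cfg <- train_config(max_epochs = 1L, k_folds = 5L, batch_size = 2L,
                      seed = 3L)
  model <- train_unet(exams, unet_config(input_size = 32, depth = 2,
                                         base_channels = 4), cfg)
  folds <- model$fold_history$folds
  expect_equal(sort(unique(folds$fold)), 1:5)
  expect_equal(anyDuplicated(folds$exam_id), 0L)
  # k=5 with 5 exams: every fold's validation set is exactly one exam
  expect_equal(unname(table(folds$fold)), rep(1L, 5), ignore_attr = TRUE)
  expect_error(train_unet(exams[1:3], unet_config(input_size = 32, depth = 2,
                                                  base_channels = 4), cfg),
               "k_folds")
})

test_that("checkpoints round-trip with bit-identical predictions", {
  cfg <- unet_config(input_size = 32, depth = 2, base_channels = 4)
  model <- build_unet(cfg, seed = 9)
  ph <- small_exam(input = 32, n_frames = 2, seed = 2)
  before <- predict_mask(model, ph$cine)
  tmp <- tempfile(fileext = ".rds")
  save_model(model, tmp)
  expect_true(file.exists(paste0(tmp, ".json")))
  back <- load_model(tmp)
  expect_identical(back$params, model$params)
  after <- predict_mask(back, ph$cine)
  expect_identical(after$frames, before$frames)
})

test_that("prediction keeps only the largest component and allows empty masks", {
  m <- matrix(0, 32, 32)
  m[5:20, 5:20] <- 1        # 256 px blob
  m[28:30, 28:30] <- 1      # 9 px blob
  keep <- largest_component(m)
  expect_equal(sum(keep), 256)
  expect_equal(sum(keep[28:30, 28:30]), 0)
  expect_equal(sum(largest_component(matrix(0, 8, 8))), 0)
  cfg <- unet_config(input_size = 32, depth = 2, base_channels = 4)
  model <- build_unet(cfg, seed = 1)
  zero <- cine_sequence(array(0, c(1, 32, 32)), 1)
  expect_s3_class(predict_mask(model, zero), "mask_sequence")
  odd <- cine_sequence(array(0, c(1, 30, 30)), 1)
  expect_error(predict_mask(model, odd), "incompatible")
})

test_that("a short training run reduces the Dice loss", {
  exams <- lapply(1:4, function(i) {
    e <- small_exam(input = 32, n_frames = 2, seed = 10 + i)
    e$cine$exam_id <- e$masks$exam_id <- sprintf("t%02d", i)
    e
  })
  cfg <- train_config(initial_lr = 0.003, max_epochs = 10L, batch_size = 2L,
                      seed = 1L)
  model <- train_unet(exams, unet_config(input_size = 32, depth = 2,
                                         base_channels = 8), cfg,
                      cross_validate = FALSE, holdout = 1L)
  h <- model$fold_history$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("interior holes are filled but border-connected background is kept", {
  m <- matrix(0L, 12, 12); m[3:10, 3:10] <- 1L
  holey <- m; holey[6:7, 6:7] <- 0L
  expect_identical(fill_mask_holes(holey), m)
  bay <- m; bay[3:6, 10] <- 0L; bay[3:5, 9] <- 0L  # inlet open to border?
  # the notch touches the mask edge column but not the image border: filled
  expect_true(all(fill_mask_holes(m) == m))
  expect_equal(sum(fill_mask_holes(matrix(0L, 5, 5))), 0)
})
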