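# Training recipe: schedule, augmentation, optimizer loop.

test_that("learning-rate schedule hits the recipe's anchor points", {
  cfg <- train_config()  # 100 epochs, 5 warm-up, peak 5e-5
  expect_identical(lr_at(0, cfg), 0)
  expect_equal(lr_at(0.05, cfg), 5e-5)            # end of warm-up, epoch 5/100
  expect_equal(lr_at(0.05 + 0.95 / 2, cfg), 2.5e-5)  # cosine midpoint
  expect_equal(lr_at(1, cfg), 0, tolerance = 1e-20)
  expect_true(all(diff(lr_at(seq(0, 0.05, by = 0.01), cfg)) > 0))  # monotone ramp
  expect_true(all(diff(lr_at(seq(0.05, 1, by = 0.05), cfg)) < 0))  # monotone decay
  expect_error(train_config(epochs = 5, warmup_epochs = 5), "warmup")
  expect_error(lr_at(1.2, cfg), "within")
})

test_that("augmentation contracts: output shape, flip involution, degenerate identity", {
  set.seed(41)
  img <- array(runif(48 * 40 * 3), c(48, 40, 3))
  cfg <- train_config(image_size = 32)
  out <- augment(img, cfg)
  expect_equal(dim(out), c(32L, 32L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  # horizontal flip applied twice restores the original
  flip <- function(x) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  expect_identical(flip(flip(img)), img)
  # with crop scale 1, no flip and no jitter, augment is exactly the resize
  cfg0 <- train_config(image_size = 32, crop_scale = c(1, 1), hflip_prob = 0,
                       jitter = 0)
  sq <- array(runif(40 * 40 * 3), c(40, 40, 3))
  expect_identical(augment(sq, cfg0), resize_image(sq, 32))
  # seeded stream reproduces the pipeline
  set.seed(7); a <- augment(img, cfg)
  set.seed(7); b <- augment(img, cfg)
  expect_identical(a, b)
})

test_that("resize is identity at matching size and preserves constant images", {
  img <- array(0.25, c(16, 16, 3))
  expect_identical(resize_image(img, 16), img)
  up <- resize_image(img, 33)
  expect_equal(up, array(0.25, c(33, 33, 3)), tolerance = 1e-12)
})

test_that("Adam takes a step against the gradient with bias correction", {
  st <- fundusnet:::adam_init(3)
  theta <- c(1, -1, 0.5)
  g <- c(0.1, -0.2, 0)
  out <- fundusnet:::adam_step(st, theta, g, lr = 0.1, beta1 = 0.9, beta2 = 0.999)
  # first step moves by exactly lr * sign(g) up to eps
  expect_equal(out$theta, theta - 0.1 * sign(g), tolerance = 1e-6)
})

test_that("a tiny model overfits a 32-image memorization set", {
  td <- file.path(tempdir(), "overfit")
  mp <- generate_dataset(32, out_dir = td, seed = 51, image_size = 64)
  rec <- load_manifest(mp)
  plan <- fundusnet:::split_plan(train = rec, val = rec, test = rec)
  cfg <- train_config(epochs = 50, warmup_epochs = 5, peak_lr = 3e-3,
                      image_size = 64, batch_size = 32,
                      crop_scale = c(1, 1), hflip_prob = 0, jitter = 0, seed = 52)
  model <- assemble_model(backbone_config("nf_resnet", 26, 0.125, 64),
                          list(r = 4), seed = 53)
  fit <- train_model(model, plan, cfg)
  expect_lt(min(fit$history$train_loss), 0.1)
  # bookkeeping contracts
  expect_equal(nrow(fit$history), cfg$epochs)
  expect_equal(fit$history$lr,
               lr_at(seq_len(cfg$epochs) / cfg$epochs, cfg))
  # best checkpoint = highest val accuracy, earliest on ties
  best <- fit$history$epoch[which.max(fit$history$val_acc)]
  expect_equal(fit$best_epoch, best)
  # the checkpoint reproduces its recorded validation accuracy
  ev <- evaluate_model(fit, plan$val)
  expect_equal(ev$metrics$accuracy, fit$best_val_acc, tolerance = 1e-12)
  unlink(td, recursive = TRUE)
})

test_that("training is reproducible from the seed", {
  td <- file.path(tempdir(), "repro")
  mp <- generate_dataset(24, out_dir = td, seed = 54, image_size = 32)
  rec <- load_manifest(mp)
  plan <- fundusnet:::split_plan(train = rec[1:16, ], val = rec[17:24, ],
                                 test = rec[17:24, ])
  cfg <- train_config(epochs = 2, warmup_epochs = 1, peak_lr = 1e-3,
                      image_size = 32, batch_size = 8, seed = 55)
  run <- function() {
    m <- assemble_model(backbone_config("nf_resnet", 26, 0.0625, 32),
                        list(r = 4), seed = 56)
    train_model(m, plan, cfg)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_error(train_model(assemble_model(backbone_config("nf_resnet", 26, 0.0625, 32),
                                          NULL, seed = 1),
                           fundusnet:::split_plan(rec[0, ], rec, rec), cfg),
               "nonempty")
  unlink(td, recursive = TRUE)
})
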