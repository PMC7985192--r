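# Sampling scheme, alternating updates, optimizer hygiene, checkpointing.

demo_like_stack <- function(seed = 1L, side = 32L) {
  opt <- optics_model(pixel_size = 0.1)
  ph <- generate_bead_phantom(8, c(side / 10, side / 10, 2), seed = seed,
                              margin = 0.5)
  raw <- render_stack(ph, seq(0, 2, by = 0.25), opt, noise = TRUE, seed = seed)
  normalize_stack(raw)$stack
}

test_that("sampled examples have exactly equidistant inputs and in-range targets", {
  st <- demo_like_stack(2)
  cfg <- train_config(M = 3, delta_z = 0.5, crop = 32, steps = 1, seed = 1)
  set.seed(5)
  for (i in 1:25) {
    ex <- sample_training_example(st, cfg)
    expect_equal(diff(ex$input_z), c(0.5, 0.5))
    expect_gte(ex$target$z, 0); expect_lte(ex$target$z, 2)
    expect_equal(length(ex$sequence$entries), 3L)
    # DPM values consistent with target minus input
    for (e in ex$sequence$entries)
      expect_equal(e$dpm$value, ex$target$z - e$plane$z)
  }
  ex1 <- sample_training_example(st, cfg, seed = 42)
  ex2 <- sample_training_example(st, cfg, seed = 42)
  expect_identical(ex1, ex2)
  # delta_z off the grid is rejected
  bad <- train_config(M = 3, delta_z = 0.3, crop = 32, steps = 1)
  expect_error(sample_training_example(st, bad), "not a multiple")
  too_wide <- train_config(M = 9, delta_z = 0.5, crop = 32, steps = 1)
  expect_error(sample_training_example(st, too_wide), "too small")
})

test_that("target draws cover the stack range uniformly (KS oracle)", {
  st <- demo_like_stack(3)
  cfg <- train_config(M = 2, delta_z = 0.5, crop = 32, steps = 1)
  set.seed(7)
  zs <- vapply(1:1000, function(i)
    sample_training_example(st, cfg)$target$z, 0)
  # discrete-uniform draw over 9 grid planes, compared against U(0, 2) with
  # half-step continuity correction via the empirical CDF at the grid
  ks <- suppressWarnings(stats::ks.test(zs + runif(1000, -0.125, 0.125),
                                        "punif", -0.125, 2.125))
  expect_gt(ks$p.value, 0.01)
})

test_that("a zero learning rate leaves parameters bitwise unchanged", {
  st <- demo_like_stack(4)
  cfg <- train_config(M = 2, delta_z = 0.5, crop = 32, steps = 1,
                      learning_rate = 1e-30, batch = 1, seed = 1)
  gen <- tiny_gen(K = 2, base = 2)
  opt <- vrefocus:::adam_init(gen$params)
  w <- loss_weights(msssim_levels = 1)
  set.seed(1)
  batch <- list(sample_training_example(st, cfg))
  res <- train_step(gen, NULL, batch, w, opt, NULL, cfg)
  # with lr ~ 0 every trainable parameter is numerically unchanged
  la <- vrefocus:::tree_leaves(res$gen$params)
  lb <- vrefocus:::tree_leaves(gen$params)
  for (nm in names(la))
    if (!grepl("rmean|rvar", nm))
      expect_lt(max(abs(la[[nm]] - lb[[nm]])), 1e-25)
})

test_that("gan off leaves the discriminator untouched; gan on updates it", {
  st <- demo_like_stack(5)
  gen <- tiny_gen(K = 2, base = 2)
  disc <- tiny_disc(n_blocks = 3, base = 2)
  w <- loss_weights(msssim_levels = 1)
  cfg_off <- train_config(M = 2, delta_z = 0.5, crop = 32, steps = 1,
                          learning_rate = 1e-3, batch = 1, gan_enabled = FALSE)
  cfg_on <- train_config(M = 2, delta_z = 0.5, crop = 32, steps = 1,
                         learning_rate = 1e-3, batch = 1, gan_enabled = TRUE)
  opt <- vrefocus:::adam_init(gen$params)
  dopt <- vrefocus:::adam_init(disc$params)
  set.seed(2)
  batch <- list(sample_training_example(st, cfg_off))
  r_off <- train_step(gen, disc, batch, w, opt, dopt, cfg_off)
  expect_identical(r_off$disc$params, disc$params)
  expect_true(is.na(r_off$record$d_loss))
  r_on <- train_step(gen, disc, batch, w, opt, dopt, cfg_on)
  expect_false(identical(r_on$disc$params, disc$params))
  expect_true(is.finite(r_on$record$d_loss))
  expect_true(is.finite(r_on$record$adv))
})

test_that("repeated steps on one fixed example drive the loss down", {
  st <- demo_like_stack(6)
  cfg <- train_config(M = 2, delta_z = 0.5, crop = 32, steps = 1,
                      learning_rate = 1e-3, batch = 1, seed = 3)
  gen <- tiny_gen(K = 2, base = 4, seed = 8)
  opt <- vrefocus:::adam_init(gen$params)
  w <- loss_weights(msssim_levels = 1)
  batch <- list(sample_training_example(st, cfg, seed = 11))
  losses <- numeric(60)
  for (s in 1:60) {
    r <- train_step(gen, NULL, batch, w, opt, NULL, cfg)
    gen <- r$gen; opt <- r$gen_opt
    losses[s] <- r$record$total
  }
  expect_lt(mean(tail(losses, 10)), 0.5 * mean(head(losses, 10)))
})

test_that("fit_refocus runs, validates on held-out stacks and checkpoints", {
  stacks <- lapply(1:3, function(i) demo_like_stack(i))
  cfg <- train_config(M = 2, delta_z = 0.5, crop = 32, steps = 6,
                      learning_rate = 1e-3, batch = 1, seed = 2,
                      validation_fraction = 0.34, val_every = 3)
  fit <- fit_refocus(stacks, cfg, gen_config(K = 2, base_channels = 2),
                     weights = loss_weights(msssim_levels = 1))
  expect_s3_class(fit, "vz_fit")
  expect_equal(nrow(fit$log), 6L)
  expect_true(all(c("total", "berhu", "msssim") %in% names(fit$log)))
  expect_gte(nrow(fit$val_log), 1L)
  # checkpoint round-trip preserves forward outputs exactly
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(fit, path)
  back <- load_checkpoint(path)
  fr <- tiny_frames(2)
  expect_identical(generator_forward(back, fr),
                   generator_forward(fit$model, fr))
  expect_error(fit_refocus(list(), cfg, gen_config(K = 2)), "no training")
})

test_that("training is reproducible given seed, config and data", {
  stacks <- lapply(1:2, function(i) demo_like_stack(i))
  cfg <- train_config(M = 2, delta_z = 0.5, crop = 32, steps = 4,
                      learning_rate = 1e-3, batch = 1, seed = 7,
                      validation_fraction = 0)
  run <- function() fit_refocus(stacks, cfg, gen_config(K = 2, base_channels = 2),
                                weights = loss_weights(msssim_levels = 1))
  f1 <- run(); f2 <- run()
  expect_identical(f1$log, f2$log)
  expect_identical(f1$model$params, f2$model$params)
})
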