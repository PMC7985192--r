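# Training: draw M planes at exact spacing delta_z plus a uniformly chosen
# target plane from a normalized stack, assemble the (image, DPM) sequence,
# and alternate generator / discriminator Adam updates (1:1).  With the GAN
# term disabled only alpha * BerHu + beta * (1 - MSSSIM) is optimized and the
# discriminator is never touched.

#' Training configuration
#'
#' @param M input planes per sequence (>= 1).
#' @param delta_z axial spacing of the input planes (um); must be an integer
#'   multiple of the stack's z step.
#' @param crop lateral crop in pixels applied identically to inputs and
#'   target (default 256).
#' @param learning_rate Adam step size (default 1e-5, suited to long runs;
#'   small desk-scale demonstrations use a larger value).
#' @param steps optimizer steps.
#' @param batch examples per step (default 4).
#' @param ordering sequence ordering fed to [assemble_sequence].
#' @param seed integer seed controlling sampling and initialization.
#' @param gan_enabled logical; include the adversarial term and train the
#'   discriminator.
#' @param validation_fraction fraction of stacks held out for validation.
#' @param val_every validation period in steps.
#' @return a list of class `train_config`.
#' @export
train_config <- function(M = 3L, delta_z = 6, crop = 256L,
                         learning_rate = 1e-5, steps = 1000L, batch = 4L,
                         ordering = c("by_z", "by_abs_dz_desc", "random"),
                         seed = 1L, gan_enabled = FALSE,
                         validation_fraction = 0.2, val_every = 50L) {
  ordering <- match.arg(ordering)
  check_number(M, "M", positive = TRUE)
  check_number(delta_z, "delta_z", positive = TRUE)
  check_number(learning_rate, "learning_rate", positive = TRUE)
  structure(list(M = as.integer(M), delta_z = delta_z, crop = as.integer(crop),
                 learning_rate = learning_rate, steps = as.integer(steps),
                 batch = as.integer(batch), ordering = ordering,
                 seed = as.integer(seed), gan_enabled = isTRUE(gan_enabled),
                 validation_fraction = validation_fraction,
                 val_every = as.integer(val_every)),
            class = "train_config")
}

#' Sample one training example from a stack
#'
#' Picks a random start plane such that M planes at exact spacing `delta_z`
#' fit on the stack's grid, a target plane uniformly over the full stack
#' range (including extrapolation beyond the outermost inputs), and one
#' lateral crop applied to all planes.
#'
#' @param stack a (normalized) [image_stack] on a uniform z grid.
#' @param cfg a [train_config].
#' @param seed optional seed; by default the caller's RNG stream is used.
#' @param scale_constant DPM normalizer passed to [assemble_sequence].
#' @return list with `sequence` (an `input_sequence`), `target` (the
#'   ground-truth [image_plane]) and `input_z`.
#' @export
sample_training_example <- function(stack, cfg, seed = NULL,
                                    scale_constant = 10) {
  draw <- function() {
    zg <- stack$z_grid
    n <- length(zg)
    if (n < 2L) stopf("stack has too few planes")
    zstep <- diff(zg)
    if (max(zstep) - min(zstep) > 1e-9)
      stopf("stack z grid must be uniform")
    zstep <- zstep[1L]
    kk <- cfg$delta_z / zstep
    if (abs(kk - round(kk)) > 1e-9)
      stopf("delta_z = %g is not a multiple of the stack z step %g",
            cfg$delta_z, zstep)
    kk <- as.integer(round(kk))
    span <- (cfg$M - 1L) * kk
    if (span >= n)
      stopf("stack range (%g um) too small for M = %d planes at delta_z = %g",
            zg[n] - zg[1L], cfg$M, cfg$delta_z)
    start <- sample.int(n - span, 1L)
    in_idx <- start + (0:(cfg$M - 1L)) * kk
    t_idx <- sample.int(n, 1L)
    d <- dim(stack$planes[[1L]]$pixels)
    if (cfg$crop > min(d)) stopf("crop %d exceeds stack dims %d x %d",
                                 cfg$crop, d[1L], d[2L])
    r0 <- if (d[1L] > cfg$crop) sample.int(d[1L] - cfg$crop + 1L, 1L) else 1L
    c0 <- if (d[2L] > cfg$crop) sample.int(d[2L] - cfg$crop + 1L, 1L) else 1L
    rows <- r0:(r0 + cfg$crop - 1L); cols <- c0:(c0 + cfg$crop - 1L)
    planes <- lapply(in_idx, function(i)
      image_plane(stack$planes[[i]]$pixels[rows, cols, drop = FALSE], zg[i]))
    ord <- if (cfg$ordering == "random") "given" else cfg$ordering
    if (cfg$ordering == "random") planes <- planes[sample.int(cfg$M)]
    seqn <- assemble_sequence(planes, zg[t_idx], order = ord,
                              scale_constant = scale_constant)
    target <- image_plane(stack$planes[[t_idx]]$pixels[rows, cols, drop = FALSE],
                          zg[t_idx])
    list(sequence = seqn, target = target, input_z = zg[in_idx])
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# gradient of the generator objective wrt the predicted image, plus the loss
# record; optionally includes the adversarial path through the discriminator
gen_objective_grad <- function(y_hat, y, weights, disc = NULL) {
  lb <- berhu(y_hat, y, weights$berhu_c, reduction = "mean")
  gb <- berhu_grad(y_hat, y, weights$berhu_c, reduction = "mean")
  ms <- msssim_(y_hat, y, weights$msssim_levels, weights$data_range, grad = TRUE)
  dy <- weights$alpha * gb - weights$beta * ms$grad
  la <- 0; score <- NA_real_
  if (!is.null(disc)) {
    fw <- disc_forward_(disc, y_hat, keep_cache = TRUE)
    score <- fw$score
    la <- (score - 1)^2
    bw <- disc_backward_(disc, fw$cache, weights$gamma * 2 * (score - 1))
    dy <- dy + bw$dinput
  }
  total <- weights$alpha * lb + weights$beta * (1 - ms$value) +
    weights$gamma * la
  list(dy = dy,
       record = list(total = total, berhu = lb, msssim = ms$value,
                     adv = la, d_score = score))
}

#' One alternating generator / discriminator update
#'
#' @param gen a `vz_generator`.
#' @param disc a `vz_discriminator` (may be `NULL` when the GAN term is off).
#' @param batch list of examples from [sample_training_example].
#' @param weights a [loss_weights].
#' @param gen_opt,disc_opt Adam states from [adam_init] on the respective
#'   parameter trees.
#' @param cfg a [train_config] (learning rate, `gan_enabled`).
#' @return list with updated `gen`, `disc`, `gen_opt`, `disc_opt` and a
#'   one-row data frame `record` of all loss components (batch means).
#' @export
train_step <- function(gen, disc, batch, weights, gen_opt, disc_opt, cfg) {
  if (length(batch) == 0L) stopf("empty batch")
  G <- NULL
  recs <- NULL
  y_hats <- vector("list", length(batch))
  use_gan <- cfg$gan_enabled && !is.null(disc)
  for (i in seq_along(batch)) {
    ex <- batch[[i]]
    fw <- gen_forward_(gen, sequence_frames(ex$sequence), train = TRUE)
    gen <- fw$model
    y_hats[[i]] <- fw$out
    og <- gen_objective_grad(fw$out, ex$target$pixels, weights,
                             disc = if (use_gan) disc)
    if (!is.finite(og$record$total))
      stopf("non-finite generator loss at batch item %d (berhu=%g msssim=%g adv=%g)",
            i, og$record$berhu, og$record$msssim, og$record$adv)
    gi <- gen_backward_(gen, fw$cache, og$dy)
    G <- if (is.null(G)) gi else tree_map2(`+`, G, gi)
    recs <- rbind(recs, as.data.frame(og$record))
  }
  G <- tree_map(function(x) x / length(batch), G)
  up <- adam_update(gen$params, G, gen_opt, cfg$learning_rate)
  gen$params <- up$params
  gen_opt <- up$state
  d_loss <- NA_real_
  if (use_gan) {
    DG <- NULL
    dl <- 0
    for (i in seq_along(batch)) {
      ff <- disc_forward_(disc, y_hats[[i]], keep_cache = TRUE)
      fr <- disc_forward_(disc, batch[[i]]$target$pixels, keep_cache = TRUE)
      dl <- dl + discriminator_loss(ff$score, fr$score)
      bf <- disc_backward_(disc, ff$cache, ff$score)
      br <- disc_backward_(disc, fr$cache, fr$score - 1)
      di <- tree_map2(`+`, bf$grads, br$grads)
      DG <- if (is.null(DG)) di else tree_map2(`+`, DG, di)
    }
    DG <- tree_map(function(x) x / length(batch), DG)
    ud <- adam_update(disc$params, DG, disc_opt, cfg$learning_rate)
    disc$params <- ud$params
    disc_opt <- ud$state
    d_loss <- dl / length(batch)
  }
  record <- data.frame(total = mean(recs$total), berhu = mean(recs$berhu),
                       msssim = mean(recs$msssim), adv = mean(recs$adv),
                       d_loss = d_loss)
  list(gen = gen, disc = disc, gen_opt = gen_opt, disc_opt = disc_opt,
       record = record)
}

#' Train a generator on a set of stacks
#'
#' Runs the sampling scheme and the alternating update loop, periodically
#' evaluating the non-adversarial fidelity loss on held-out validation
#' examples; the best-validation and final weights are both returned.
#' Validation stacks never contribute gradient updates.
#'
#' @param stacks list of normalized [image_stack] objects.
#' @param cfg a [train_config].
#' @param gen_cfg a [gen_config].
#' @param weights a [loss_weights].
#' @param disc_cfg optional [disc_config] (required when `cfg$gan_enabled`).
#' @param verbose print progress every `val_every` steps.
#' @return an object of class `vz_fit`: fields `model` (final), `best_model`,
#'   `discriminator`, `log` (per-step loss components), `val_log`, `cfg`,
#'   `gen_cfg`, `weights`.
#' @export
fit_refocus <- function(stacks, cfg, gen_cfg, weights = loss_weights(),
                        disc_cfg = NULL, verbose = FALSE) {
  if (length(stacks) == 0L) stopf("no training stacks supplied")
  n_val <- round(cfg$validation_fraction * length(stacks))
  n_val <- min(max(n_val, 0L), length(stacks) - 1L)
  val_stacks <- if (n_val > 0L) stacks[seq(length(stacks) - n_val + 1L, length(stacks))]
  train_stacks <- if (n_val > 0L) stacks[seq_len(length(stacks) - n_val)] else stacks
  gen <- init_generator(gen_cfg, seed = cfg$seed)
  disc <- NULL; disc_opt <- NULL
  if (cfg$gan_enabled) {
    if (is.null(disc_cfg)) disc_cfg <- disc_config()
    disc <- init_discriminator(disc_cfg, seed = cfg$seed + 1L)
    disc_opt <- adam_init(disc$params)
  }
  gen_opt <- adam_init(gen$params)
  sc <- gen_cfg$scale_constant
  val_examples <- NULL
  if (!is.null(val_stacks)) {
    val_examples <- with_seed(derive_seed(cfg$seed, "val-examples"), {
      lapply(seq_len(min(8L, 2L * length(val_stacks))), function(i)
        sample_training_example(val_stacks[[1L + (i - 1L) %% length(val_stacks)]],
                                cfg, scale_constant = sc))
    })
  }
  log <- NULL; val_log <- NULL
  best <- list(loss = Inf, params = gen$params)
  with_seed(derive_seed(cfg$seed, "train-loop"), {
    for (step in seq_len(cfg$steps)) {
      batch <- lapply(seq_len(cfg$batch), function(i)
        sample_training_example(train_stacks[[sample.int(length(train_stacks), 1L)]],
                                cfg, scale_constant = sc))
      st <- train_step(gen, disc, batch, weights, gen_opt, disc_opt, cfg)
      gen <- st$gen; disc <- st$disc; gen_opt <- st$gen_opt; disc_opt <- st$disc_opt
      log <- rbind(log, cbind(step = step, st$record))
      if (!is.null(val_examples) &&
          (step %% cfg$val_every == 0L || step == cfg$steps)) {
        vl <- mean(vapply(val_examples, function(ex) {
          out <- gen_forward_(gen, sequence_frames(ex$sequence))$out
          weights$alpha * berhu(out, ex$target$pixels, weights$berhu_c, "mean") +
            weights$beta * (1 - msssim(out, ex$target$pixels,
                                       weights$msssim_levels, weights$data_range))
        }, 0))
        val_log <- rbind(val_log, data.frame(step = step, val_loss = vl))
        if (vl < best$loss) best <- list(loss = vl, params = gen$params)
        if (verbose)
          message(sprintf("step %d: train %.4f, val %.4f", step,
                          st$record$total, vl))
      }
    }
  })
  best_model <- gen
  best_model$params <- best$params
  structure(list(model = gen, best_model = best_model, discriminator = disc,
                 log = log, val_log = val_log, cfg = cfg, gen_cfg = gen_cfg,
                 weights = weights),
            class = "vz_fit")
}

#' Save model weights and configuration to a checkpoint
#'
#' A single RDS file holding the parameter tree plus a JSON sidecar with the
#' architecture and (optionally) training metadata; [load_checkpoint] restores
#' a bit-identical model.
#'
#' @param model a `vz_generator` or a `vz_fit` (whose final model is saved).
#' @param path checkpoint file path (e.g. `model.ckpt`).
#' @param metadata optional list stored in the JSON sidecar.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, metadata = NULL) {
  if (inherits(model, "vz_fit")) model <- model$model
  stopifnot(inherits(model, "vz_generator"))
  saveRDS(list(config = unclass(model$config), params = model$params), path)
  jsonlite::write_json(list(config = unclass(model$config),
                            n_parameters = count_parameters(model),
                            metadata = metadata),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a generator checkpoint
#'
#' @param path file written by [save_checkpoint].
#' @return a `vz_generator`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(gen_config, obj$config[c("K", "base_channels",
                                          "input_channels", "scale_constant")])
  structure(list(config = cfg, params = obj$params), class = "vz_generator")
}
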