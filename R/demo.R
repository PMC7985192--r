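# Desk-scale study conditions: a bead-phantom emulation of sparse wide-field
# z-scanning that every end-to-end check runs on.  The geometry mirrors the
# sparse-scan regime (M = 3 equidistant inputs spanning the volume, targets on
# a fine 0.2 um grid over the full axial extent, objective DOF 0.4 um) scaled
# to a 64 x 64 x 3.6 um phantom so that training and evaluation complete on a
# single CPU.

#' Optics used by the desk-scale demonstration
#'
#' 63x/1.4NA-class parameters: 0.1 um pixels, in-focus PSF sigma 0.2 um
#' (FWHM 0.47 um) and DOF 0.4 um, with moderate shot and read noise.
#' @return an [optics_model].
#' @export
demo_optics <- function() optics_model()

#' Demonstration geometry and training recipe
#'
#' @return list with the phantom extent, z grid, input-plane positions,
#'   training spacing `delta_z`, crop, architecture and loss settings.
#' @export
demo_recipe <- function() {
  list(extent = c(6.4, 6.4, 3.6),
       z_grid = seq(0, 3.6, by = 0.2),
       input_z = c(0.6, 1.8, 3.0),
       delta_z = 1.2,
       n_beads = 25L,
       crop = 64L,
       M = 3L,
       K = 3L,
       base_channels = 8L,
       learning_rate = 1e-3,
       batch = 2L,
       steps = 400L,
       msssim_levels = 3L)
}

#' Generate one normalized demonstration stack
#'
#' A random bead phantom rendered with noise on the fine z grid, then passed
#' through the EDF / triangle-threshold normalization pipeline.
#'
#' @param seed integer seed (distinct seeds give independent phantoms).
#' @param n_beads bead count (default from [demo_recipe]).
#' @return list with `stack` (normalized [image_stack]), `raw`, `phantom`,
#'   `factors`.
#' @export
demo_stack <- function(seed, n_beads = demo_recipe()$n_beads) {
  rc <- demo_recipe()
  optics <- demo_optics()
  ph <- generate_bead_phantom(n_beads, rc$extent, intensity_range = c(0.5, 1),
                              seed = seed, margin = 0.8)
  raw <- render_stack(ph, rc$z_grid, optics, noise = TRUE, seed = seed)
  nm <- normalize_stack(raw)
  list(stack = nm$stack, raw = raw, phantom = ph, factors = nm$factors)
}

#' Train the desk-scale demonstration model
#'
#' Trains the recurrent generator on synthetic bead stacks under the
#' demonstration recipe (K = 3 scales, 8 stem channels, M = 3 inputs at
#' delta_z = 1.2 um, 64 x 64 crops, no adversarial term).
#'
#' @param seed integer seed for data generation, initialization and sampling.
#' @param steps optimizer steps (default from [demo_recipe]).
#' @param n_stacks training + validation stacks (default 10).
#' @param verbose print validation progress.
#' @return the `vz_fit` object from [fit_refocus].
#' @export
train_demo_model <- function(seed = 1L, steps = demo_recipe()$steps,
                             n_stacks = 10L, verbose = FALSE) {
  rc <- demo_recipe()
  stacks <- lapply(seq_len(n_stacks), function(i)
    demo_stack(derive_seed(seed, paste0("demo-stack", i)))$stack)
  cfg <- train_config(M = rc$M, delta_z = rc$delta_z, crop = rc$crop,
                      learning_rate = rc$learning_rate, steps = steps,
                      batch = rc$batch, ordering = "by_z", seed = seed,
                      gan_enabled = FALSE, validation_fraction = 0.2,
                      val_every = 50L)
  gcfg <- gen_config(K = rc$K, base_channels = rc$base_channels)
  w <- loss_weights(msssim_levels = rc$msssim_levels)
  fit_refocus(stacks, cfg, gcfg, weights = w, verbose = verbose)
}

#' Mid-gap evaluation against the nearest-input baseline
#'
#' On held-out phantoms, reconstructs target planes lying at least
#' `min_gap` um from every input plane and compares the model's PSNR with the
#' nearest-input-plane baseline (the sparse-scan practitioner's alternative:
#' use the closest acquired image as-is).
#'
#' @param model a `vz_generator`.
#' @param seed seed for the held-out phantoms (disjoint from training seeds
#'   by tag derivation).
#' @param n_planes number of evaluated target planes (default 20).
#' @param min_gap minimum |z_target - z_input| in um (default 0.4, one DOF).
#' @return data frame with one row per plane: `stack`, `z`, `psnr_model`,
#'   `psnr_baseline`.
#' @export
evaluate_midgap <- function(model, seed = 999L, n_planes = 20L,
                            min_gap = 0.4) {
  rc <- demo_recipe()
  out <- NULL
  s <- 0L
  while (is.null(out) || nrow(out) < n_planes) {
    s <- s + 1L
    ds <- demo_stack(derive_seed(seed, paste0("eval-stack", s)))
    stack <- ds$stack
    idx_in <- vapply(rc$input_z, function(z) which.min(abs(stack$z_grid - z)), 0L)
    inputs <- stack$planes[idx_in]
    mid <- which(vapply(stack$z_grid, function(z)
      min(abs(z - rc$input_z)) >= min_gap - 1e-9, TRUE))
    for (i in mid) {
      gt <- stack$planes[[i]]
      pred <- infer_plane(model, inputs, stack$z_grid[i])
      nearest <- inputs[[which.min(abs(rc$input_z - stack$z_grid[i]))]]
      out <- rbind(out, data.frame(stack = s, z = stack$z_grid[i],
                                   psnr_model = psnr(pred, gt),
                                   psnr_baseline = psnr(nearest, gt)))
      if (nrow(out) >= n_planes) break
    }
  }
  out[seq_len(n_planes), ]
}
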