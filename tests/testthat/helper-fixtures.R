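# Shared fixtures: small phantom specs, a tiny cached GAN run, and the
# memoised desk-scale study used by the acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

fixture_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L), voxel_spacing = c(1.9, 1.9), ...)
}

# tiny training run: 6 pairs, 32x32, width 4, 3 epochs (seconds)
tiny_gan_run <- function() {
  if (!is.null(.fixture_cache$tiny)) return(.fixture_cache$tiny)
  cases <- make_cohort(3L, 3L, 0L, fixture_spec(), seed = 42L)
  xs <- ys <- list()
  for (i in seq_along(cases)) {
    z <- fit_adc(cases[[i]]$clean_dwi)
    bi <- which(cases[[i]]$degraded_dwi$b_values == 1000)
    xs[[i]] <- normalize_intensity(cases[[i]]$degraded_dwi$data[bi, , ])
    ys[[i]] <- pmin(pmax(z$data / 4e-3, 0), 1)
  }
  recog <- build_recognizer(recognition_spec(base_width = 4L),
                            image_size = 32L, seed = 7L)
  state <- train_gan(xs, ys, recog,
                     gen_spec = generator_spec(base_width = 4L,
                                               n_residual_blocks = 2L),
                     disc_spec = discriminator_spec(base_width = 4L),
                     config = train_config(epochs = 3L, batch_size = 3L,
                                           seed = 5L, image_size = 32L))
  .fixture_cache$tiny <- list(state = state, xs = xs, ys = ys, cases = cases,
                              recog = recog)
  .fixture_cache$tiny
}

micro_study_config <- function(seed, out_dir = NULL) {
  study_config("desk", seed = seed, out_dir = out_dir,
               n_train = 8L, n_test = 4L, n_volunteer = 2L,
               image_size = 48L, epochs = 2L, cls_epochs = 2L,
               gen_width = 8L, disc_width = 8L, recog_width = 4L)
}

# the seeded desk-scale study shared by the acceptance blocks (minutes)
desk_study <- function() {
  if (is.null(.fixture_cache$desk))
    .fixture_cache$desk <- run_study(study_config("desk", seed = 1L),
                                     verbose = FALSE)
  .fixture_cache$desk
}

num_grad <- function(f, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
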