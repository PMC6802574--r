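# Shared fixture datasets, generated once per test session in a tempdir.
# The seeds and sizes here are the pinned study conditions used by the
# integration and acceptance tests; they are fixed, not tuned per test.
.fx <- new.env(parent = emptyenv())

fx_easy <- function() {
  if (is.null(.fx$easy)) {
    dir <- file.path(tempdir(), "deepident_fx_easy")
    .fx$easy <- generate_image_dataset(
      fixture_spec(n_categories = 4, images_per_category = 12,
                   images_per_specimen = 4, seed = 7), dir)
  }
  .fx$easy
}

fx_hard <- function() {
  if (is.null(.fx$hard)) {
    dir <- file.path(tempdir(), "deepident_fx_hard")
    .fx$hard <- generate_image_dataset(
      fixture_spec(n_categories = 4, images_per_category = 16,
                   images_per_specimen = 4, difficulty = "hard", seed = 19),
      dir)
  }
  .fx$hard
}

fx_cache_dir <- function() {
  dir <- file.path(tempdir(), "deepident_fx_cache")
  dir.create(dir, showWarnings = FALSE)
  dir
}

# Pipeline settings shared by the integration tests: 64-px inputs match the
# fixture image scale and keep forward passes cheap.
fx_base_config <- function(manifest, ...) {
  args <- list(manifest = manifest, image_size = 64, level = 1,
               folds = 10, fold_seed = 11, cache_dir = fx_cache_dir())
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

# Independent brute-force window pooling: plain loops, no shared code with
# the implementation under test.
brute_pool <- function(fm, n, mode) {
  d <- dim(fm)
  win <- d[1] %/% n
  out <- array(0, c(n, n, d[3]))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (f in seq_len(d[3])) {
        w <- fm[(i - 1) * win + seq_len(win), (j - 1) * win + seq_len(win), f]
        out[i, j, f] <- if (mode == "average") mean(w) else max(w)
      }
    }
  }
  out
}

random_volume <- function(side, depth) {
  array(stats::rnorm(side * side * depth), c(side, side, depth))
}
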