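# Shared fixtures, built in code and cached for the duration of the run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

ref_fixture <- function() cached("ref", chart_reference())

# a clean default scene, reused by many tests
scene_fixture <- function(seed = 5) {
  cached(paste0("scene", seed), render_scene(scene_spec(seed = seed)))
}

# a trained segmenter on two clean scenes
segmenter_fixture <- function() {
  cached("segmenter", {
    tr <- lapply(1:2, function(i) render_scene(scene_spec(seed = 10 + i)))
    train_segmenter(lapply(tr, `[[`, "image"),
                    lapply(tr, function(s) s$truth$plant_mask), seed = 7)
  })
}

# the 60-scene distorted benchmark: per-scene chart fits and R2 comparisons
benchmark_fixture <- function(n = 60, seed = 0) {
  cached(paste0("bench", n, "_", seed), {
    ref <- ref_fixture()
    set.seed(seed)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      scene_seed <- seed * 1000L + i
      sc <- render_scene(scene_spec(seed = scene_seed))
      d <- random_illumination()
      img <- apply_illumination(sc$image, d)
      g <- detect_chart(img, scales = 1, rotations = c(0, 180))
      obs <- extract_tile_values(img, g)
      fit <- fit_correction_model(obs, ref)
      cmp <- compare_fits(obs, ref)
      out[[i]] <- list(fit = fit, cmp = cmp)
    }
    out
  })
}
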