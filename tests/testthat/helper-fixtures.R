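# Shared fixtures: a miniature oocyte scene keeps the suite fast while
# exercising the same machinery as the full-scale defaults. Expensive runs
# are generated once and cached for the whole suite.

mini_params <- function(seed = 4, noise = FALSE, ...) {
  defaults <- list(
    oocyte_diameter = 150, gv_diameter = 37, n_yolk = 25, n_cg = 60,
    yolk_radius_range = c(5, 9), cg_radius_range = c(2, 3.5),
    n_frames = 30, gvbd_time = 300, n_rab11 = 40,
    noise_model = if (noise) list(photon_rate = 200, read_sigma = 2)
                  else list(photon_rate = 0, read_sigma = 0),
    psf_sigma = if (noise) 1 else 0,
    seed = seed
  )
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

# mini scene tuned for wave/drift velocimetry: dense, long-lived asters
wave_params <- function(seed = 7, noise = TRUE, ...) {
  mini_params(seed = seed, noise = noise,
              aster_density_peak = 120, aster_sigma = 4,
              aster_lifetime = 40, ...)
}

wave_run <- function()
  cached("run_wave", generate_timelapse(wave_params()))

aster_clean_run <- function()
  cached("run_aster_clean",
         generate_timelapse(wave_params(noise = FALSE, n_frames = 24)))

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

mini_run_clean <- function()
  cached("run_clean", generate_timelapse(mini_params()))

mini_run_noisy <- function()
  cached("run_noisy", generate_timelapse(mini_params(seed = 4, noise = TRUE)))

mini_scene_clean <- function()
  cached("scene_clean", init_scene(mini_params()))

# channels of one frame as the named list segment_granules() expects
frame_channels <- function(tl, f,
                           which = c("ooplasm", "lysotracker", "kplus",
                                     "rab11", "microtubule")) {
  out <- lapply(which, function(ch) tl_frame(tl, f, ch))
  names(out) <- which
  out
}

# segment all yolk label frames of a run (cached per run key)
mini_yolk_labels <- function(run, key) {
  cached(paste0("yolk_labels_", key), {
    tl <- run$timelapse
    mask <- segment_oocyte(tl_frame(tl, 1, "ooplasm"), tl$pixel_size)
    lapply(seq_len(dim(tl$frames)[1]), function(f)
      segment_granules(list(lysotracker = tl_frame(tl, f, "lysotracker")),
                       "yolk", tl$pixel_size, oocyte_mask = mask,
                       frame_index = f))
  })
}
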