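# shared fixtures, built in code at test time

# single-marker class spec with full positivity (diameters unconstrained)
flat_spec <- function(k = 0.0070, n_max = 500, level = 1,
                      total_n_max = 2000, total_k = 0.01) {
  class_spec("fixture", size_dist_lnorm(),
             list(marker_profile("CD63", rep(level, 13), k = k,
                                 n_max = n_max)),
             total_n_max = total_n_max, total_k = total_k)
}

# dataset with no class separation: five classes, identical flat profiles
flat_five_class_dataset <- function(seed = 1, replicates = 4,
                                    duration = 300) {
  markers <- c("CD63", "EpCAM", "HER2", "PSMA", "PTK7")
  dist <- size_dist_lnorm()
  mk_spec <- function(lab) {
    profiles <- lapply(markers, function(m)
      marker_profile(m, rep(0.2, 13), k = 0.005, n_max = 400))
    class_spec(lab, dist, profiles, total_n_max = 2000, total_k = 0.01)
  }
  classes <- paste0("class", 1:5)
  withr::with_seed(seed, {
    events <- list()
    samples <- data.frame(sample_id = character(0), class_label = character(0))
    for (cl in classes) {
      spec <- mk_spec(cl)
      for (r in seq_len(replicates)) {
        sid <- sprintf("%s_%02d", cl, r)
        samples <- rbind(samples,
                         data.frame(sample_id = sid, class_label = cl))
        for (m in markers)
          events[[length(events) + 1L]] <-
            simulate_marker_run(spec, m, duration, sample_id = sid)$events
        events[[length(events) + 1L]] <-
          simulate_total_run(spec, duration, sample_id = sid)$events
      }
    }
    structure(list(events = do.call(rbind, events), samples = samples,
                   markers = markers, duration = duration),
              class = "evp_dataset")
  })
}

# render a stack with well-separated landings at a given differential-domain
# SNR (peak differential amplitude over differential noise SD)
render_detection_fixture <- function(n_events = 20, snr = 10, n_avg = 10,
                                     fps = 10, noise_sd = 1, seed = 7,
                                     frame = 256) {
  sd_diff <- noise_sd * sqrt(2 / n_avg)
  amp <- snr * sd_diff * n_avg
  g <- round(seq(30, frame - 30, length.out = 5))
  gx <- rep(g, length(g))[seq_len(n_events)]
  gy <- rep(g, each = length(g))[seq_len(n_events)]
  tt <- seq(1.5, 9.1, length.out = n_events)
  ev <- data.frame(time_s = tt, x_px = gx, y_px = gy, intensity = amp)
  r <- render_image_stack(ev, c(frame, frame), fps = fps,
                          noise_sd = noise_sd, duration = 11, seed = seed)
  list(events = ev, stack = r$stack, landing_frames = r$landing_frames,
       amp = amp, n_avg = n_avg)
}
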