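# Small head geometry used throughout the unit tests: big enough for the
# 11 mm pooling kernel and a multi-mL lesion, small enough to keep each
# stage below a second.
small_spec <- function(...) {
  phantom_spec(dim = c(72, 88, 64), brain_radii_mm = c(30, 38, 25),
               ventricle_radii_mm = c(4, 9, 5),
               ventricle_center_mm = c(7, 6, 1), ...)
}

small_lesion_spec <- function(uptake = 15, noise_sd = 0, seed = 7, ...) {
  small_spec(lesion_center_mm = c(-15, -8, 0), lesion_radii_mm = c(9, 10, 8),
             uptake_percent = uptake, noise_sd = noise_sd, seed = seed, ...)
}

# cache expensive shared fixtures across tests within a run
.fixture_env <- new.env(parent = emptyenv())

small_template <- function() {
  if (is.null(.fixture_env$tmpl))
    .fixture_env$tmpl <- default_template(small_spec())
  .fixture_env$tmpl
}

# manually assembled lesion candidate, for exercising lesion_report with a
# known mask
as_lesion_candidate <- function(mask, side) {
  structure(list(mask = mask, side = side, otsu_threshold = NA_real_,
                 threshold = NA_real_, component_count = 1L),
            class = "lesion_candidate")
}
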