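# Shared fixtures: a small phantom configuration that keeps the study's
# physical geometry (6 mm field, per-layer FAZ, sector NPA) on a coarser
# 200-px grid (30 um/px) so test cases generate in about a second.
small_phantom_config <- function(seed = 7, ...) {
  args <- list(
    grid_size = 200, pixel_pitch_um = 30,
    motion = affine_from_params(rotation_deg = 1, scale = 1.005,
                                tx = 3, ty = -2, center = c(100.5, 100.5)),
    seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(phantom_config, args)
}

small_phantom_case <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7, ...) {
    key <- paste0("s", seed, "_", length(list(...)))
    if (length(list(...)) == 0 && !is.null(cache[[key]])) return(cache[[key]])
    case <- generate_phantom_case(small_phantom_config(seed = seed, ...))
    if (length(list(...)) == 0) cache[[key]] <- case
    case
  }
})

random_mask <- function(n, p = 0.4) matrix(runif(n * n) < p, n, n)
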