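# Shared fixtures: all synthetic, generated in code.

std_input <- function() make_input_function()
std_schedule <- function() dynamic_schedule_45min()

# Lesion-typical and liver-typical kinetics (reported medians).
lesion_params <- function(vb = 0.05) kinetic_params(0.2, 0.5, 0.07, vb = vb)
liver_params <- function(vb = 0.12) kinetic_params(0.37, 0.5, 0.0211, vb = vb)

# Additive Gaussian noise with variance proportional to C / frame duration.
# s = 0.3 is the VOI-level default (voxel-level 1.5 reduced by averaging over
# a ~20-voxel lesion).
noisy_tac <- function(params, input, schedule, s = 0.3, seed = 1,
                      model = "2TC-3k") {
  tac <- model_tac(params, model, input, schedule)
  set.seed(seed)
  v <- tac$values +
    rnorm(schedule$n, 0, s * sqrt(pmax(tac$values, 0) / schedule$duration))
  time_activity_curve(schedule, v)
}

# Small fast phantom (16 x 16 x 8, one lesion) for geometry-level tests.
small_spec <- function(noise_scale = 0, seed = 1L,
                       lesions = data.frame(label = 3, cx = 7, cy = 8, cz = 4,
                                            r_mm = 8, K1 = 0.2, k2 = 0.5,
                                            k3 = 0.07, k4 = 0, vb = 0.05),
                       liver_k4 = 0) {
  phantom_spec(
    dim = c(16, 16, 8),
    liver = list(x = 2:12, y = 2:14, z = 2:7,
                 K1 = 0.37, k2 = 0.5, k3 = 0.0211, k4 = liver_k4, vb = 0.12),
    aorta = list(cx = 14, cy = 8, r_mm = 4, z = 2:7),
    lesions = lesions,
    noise_scale = noise_scale, seed = seed)
}

rel_dev <- function(a, b) max(abs(a - b)) / max(abs(b))
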