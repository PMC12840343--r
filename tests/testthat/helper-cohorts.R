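# Shared synthetic worlds for the test suite. The 32^3 / 1 mm "small world"
# uses a center sd of 2 mm and an edema radius of 4.5 +/- 0.6 mm (3 sd
# truncation => max extent 6.3 mm), so lesions always fit the grid.

small_world_spec <- function(seed, groups = c(A = 10L, B = 10L),
                             effect = NULL, ...) {
  synthetic_cohort_spec(
    grid_shape = c(32L, 32L, 32L), voxel_size = c(1, 1, 1),
    groups = groups, center_cov = diag(c(2, 2, 2)^2),
    radius_model = list(necrosis = c(mean = 1.8, sd = 0.3),
                        core = c(mean = 3, sd = 0.4),
                        edema = c(mean = 4.5, sd = 0.6)),
    effect = effect, master_seed = seed, ...)
}

# planted spatial predilection: 80% of group A centers re-drawn inside a
# 5 mm ball offset 6 mm to the right
planted_effect_spec <- function(seed, n = 60L) {
  small_world_spec(seed, groups = c(A = n, B = n),
                   effect = list(group = "A",
                                 boost = list(center = c(6, 0, 0),
                                              radius = 5, prob = 0.8)))
}

group_masks <- function(gen, group, compartment = "whole_tumor") {
  lapply(gen$volumes[gen$cohort$subtype == group], derive_compartment,
         compartment = compartment)
}

dice <- function(a, b) 2 * length(intersect(a, b)) / (length(a) + length(b))

# Independent Fisher oracle: enumerate the full hypergeometric support with
# choose() ratios (no dhyper, no fisher.test) and apply the
# point-probability rule.
fisher_oracle <- function(a, b, n1, n2) {
  m <- a + b
  k <- max(0, m - n2):min(n1, m)
  probs <- choose(n1, k) * choose(n2, m - k) / choose(n1 + n2, m)
  min(1, sum(probs[probs <= probs[match(a, k)] * (1 + 1e-7)]))
}
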