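## Shared small fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## a perturbed (non-IAM) water model with a fixed seed
perturbed_water <- function() fixture("pwater", function() {
  sample_ground_truth(synthetic_spec("water", seed = 42))
})

## small Friedel-unique reflection set for refinement tests
small_hkl_case <- function(gname = "water", seed = 11, bumps = FALSE)
  fixture(paste0("case_", gname, "_", seed, "_", bumps), function()
    generate_case(synthetic_spec(gname, seed = seed, nonrepresentable = bumps),
                  a = 8, s_max = 0.7, friedel_unique = TRUE))

## centered cubic grid around a geometry
centered_grid <- function(geom, n = 32, pad = 6) {
  span <- apply(geom$pos, 2, range)
  edge <- max(span[2, ] - span[1, ]) + 2 * pad
  grid_spec_centered(geom, edge / (n - 1), n)
}

expect_close <- function(object, expected, tol = 1e-10) {
  expect_lt(max(abs(object - expected)), tol)
}
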