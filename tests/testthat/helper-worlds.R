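# shared fixtures: small synthetic worlds, built in code at test time

small_world <- function(seed = 42, years = 2010:2011, n_crops = 3,
                        grid = 32, coarse_factor = 8, ...) {
  make_world(world_config(grid_height = grid, grid_width = grid,
                          coarse_factor = coarse_factor, n_nuts1 = 2,
                          nuts2_per_nuts1 = 2, n_crops = n_crops,
                          years = years, seed = seed, ...))
}

# maximum relative deviation, guarding tiny denominators
max_rel_err <- function(got, want, floor = 1e-12) {
  max(abs(got - want) / pmax(abs(want), floor), na.rm = TRUE)
}

# a 2x2-region world where one NUTS1 reports at NUTS1 level
expect_stack_equal <- function(got, want, tol = 1e-9) {
  for (cc in names(want$layers))
    expect_lt(max_rel_err(got$layers[[cc]], want$layers[[cc]]), tol)
}
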