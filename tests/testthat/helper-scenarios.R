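# Shared fixtures: small grids and memoized scenario runs so expensive
# simulations are built once per test session.

tiny_grid <- function(n_fast = 128, n_slow = 64)
  grid_params(n_fast = n_fast, n_slow = n_slow,
              fast_window = n_fast * (124e-9 / 4096))

# clean-frame wrapper around a bare matrix
as_clean <- function(m, grid = NULL)
  structure(list(data = m, grid = grid, stage_tag = character()),
            class = "uwb_clean_frame")

as_smoothed <- function(m, grid = NULL, block = 7L)
  structure(list(data = m, grid = grid, block = block,
                 stage_tag = character()),
            class = "uwb_smoothed_frame")

# memoized expensive fixtures
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# one reduced-scale subject scenario run through the whole chain
reduced_subject_run <- function() {
  fixture("reduced_subject_run", function() {
    sc <- scenario_subject(seed = 7, reduced = TRUE)
    rep <- suppressMessages(run_pipeline(sc$frame))
    list(sc = sc, rep = rep)
  })
}

reduced_empty_run <- function() {
  fixture("reduced_empty_run", function() {
    sc <- scenario_empty(seed = 7, reduced = TRUE)
    rep <- suppressMessages(run_pipeline(sc$frame))
    list(sc = sc, rep = rep)
  })
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)) / max(abs(expected), .Machine$double.eps),
            tol)
}
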