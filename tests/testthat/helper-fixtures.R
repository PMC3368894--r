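# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

tiny_refs <- function() cached("tiny_refs", generate_reference_set(4, n_res = 30, seed = 11))

tiny_kb <- function() cached("tiny_kb", build_knowledge_base(
  tiny_refs(), synthetic_filter_matrix(), strict_interior = FALSE))

tiny_complex <- function() cached("tiny_complex",
                                  generate_toy_complex(n_res = 24, seed = 5))

# a small labelled and featurized chain used by several modules
tiny_prep <- function() cached("tiny_prep", {
  cfg <- ppi_config(strict_interior = FALSE, sasa_points = 480)
  tc <- tiny_complex()
  suppressWarnings(prepare_protein(tc$unbound$A, tiny_kb(), tc$complexed,
                                   cfg))
})

# the full desk-scale planted-interface experiment (minutes); built once
cached_scenario <- function() cached("scenario",
                                     end_to_end_scenario(seed = 1,
                                                         null_control = TRUE))

# deterministic rotation used by invariance tests
fixed_rotation <- function() {
  th <- 0.7; ph <- 0.3
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  Rz %*% Rx
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
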