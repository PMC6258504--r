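# Shared expensive fixtures, computed once per test session.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# deterministic wild-type runs (the classification references)
wt_1d <- function() cached("wt_1d", integrate_deterministic(domain_1d()))

wt_2d <- function() cached("wt_2d", run_2d(seed = 1L))

wt_series <- function() cached("wt_series", generate_outline_series())
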