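# Shared fixtures, built lazily once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_phantom <- function() {
  fixture("default_phantom", build_phantom(phantom_config()))
}

default_m5tt <- function() {
  fixture("default_m5tt", {
    ph <- default_phantom()
    amend_to_m5tt(ph$t5, ph$hippocampus_mask, ph$config$inferior_axis)
  })
}

two_bundle_config <- function() {
  phantom_config(bundles = list(
    bundle_spec(101L, "L_A", "head", medial = TRUE, density = 2),
    bundle_spec(102L, "L_B", "tail", medial = TRUE, density = 1)))
}

two_bundle_phantom <- function() {
  fixture("two_bundle_phantom", build_phantom(two_bundle_config()))
}

# small pipeline run shared by non-acceptance tests
small_run <- function() {
  fixture("small_run",
          run_pipeline(default_phantom(), n_whole = 3000, n_hippo = 1500,
                       seed = 11))
}

# random tractogram with k short streamlines inside the default grid
random_tractogram <- function(k, grid, n_pts = 3, seed = 99) {
  set.seed(seed)
  strs <- lapply(seq_len(k), function(i) {
    start <- runif(3, 5, 25)
    step <- matrix(rnorm(3 * (n_pts - 1), sd = 2), ncol = 3)
    pts <- rbind(start, start + apply(step, 2, cumsum))
    pts
  })
  tg <- list(streamlines = strs, grid = grid, params = NULL)
  class(tg) <- "tractogram"
  tg
}
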