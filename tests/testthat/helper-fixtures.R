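# Shared fixtures, built once per test run.

# deterministic random valid caps for property tests
random_caps <- function(n, seed = 101) {
  withr::with_seed(seed, {
    R <- exp(runif(n, log(10), log(500)))
    h <- runif(n, 1e-3, 2) * R
    data.frame(R = R, h = pmin(h, 2 * R))
  })
}

# rendered synthetic cap topograph, leveled, with the seed point at center
cap_fixture <- function(R = 100, h = 40, mesh = NULL, ridge_height = 2,
                        r_tip = 2, noise_sd = 0.1, n_pixels = 300,
                        seed = 1) {
  cap <- spherical_cap(R = R, h = h)
  tr <- synthetic_truth(cap, mesh, ridge_height = ridge_height,
                        r_tip = r_tip, noise_sd = noise_sd,
                        pixel_size = 2, n_pixels = n_pixels, seed = seed)
  topo <- level_background(render_topograph(tr))
  list(cap = cap, truth = tr, topo = topo,
       center = c((n_pixels - 1), (n_pixels - 1)))  # nm at 2 nm/px
}

# the 19-hexagon flat honeycomb rendered as a topograph (cached)
honeycomb_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mesh <- hex_patch_mesh(rings = 2, edge = 18)
      tr <- synthetic_truth(cap = NULL, mesh = mesh, seed = 1)
      topo <- level_background(render_topograph(tr))
      cache <<- list(mesh = mesh, truth = tr, topo = topo)
    }
    cache
  }
})
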