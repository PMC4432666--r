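# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# Noiseless three-bundle phantom: generative tensors, eigensystem, FA map
# and whole-volume FACT streamlines.
noiseless_phantom <- function(fa_target = 0.45) {
  fixture(sprintf("phantom_%.3f", fa_target), function() {
    geom <- default_geometry()
    bundles <- bundle_fixtures(geom)
    ras <- rasterize_tensor_field(bundles, geom,
                                  eigenvalues_for_fa(fa_target))
    eig <- tensor_eigensystem(ras$tensors, geom = geom)
    fa <- fa_map(eig)
    sl <- fact_track(eig, fa)
    list(geom = geom, bundles = bundles, ras = ras, eig = eig, fa = fa,
         streamlines = sl)
  })
}

# Hand-built straight synthetic bundle: n parallel streamlines along +x
# from x0 to x1 (mm), spread over a small y-z disc, npts points each.
synthetic_straight_bundle <- function(geom, x0, x1, n = 20L, npts = 60L,
                                      y0 = NULL, z0 = NULL, spread = 2) {
  fov <- geom$dim * geom$voxel_size
  y0 <- y0 %||% (fov[2] / 2)
  z0 <- z0 %||% (fov[3] / 2)
  offs <- seq(-spread, spread, length.out = max(n, 2))[seq_len(n)]
  sls <- lapply(seq_len(n), function(i) {
    cbind(seq(x0, x1, length.out = npts), y0 + offs[i], z0)
  })
  structure(list(streamlines = sls, seed_label = 1L, target_label = 2L,
                 n_fibers = n, geom = geom, name = "synthetic"),
            class = "bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FA closed form, written out independently of the package implementation
fa_reference <- function(l) {
  lbar <- mean(l)
  sqrt(3 / 2) * sqrt(sum((l - lbar)^2)) / sqrt(sum(l^2))
}

extdata <- function(f) system.file("extdata", f, package = "tractwise")
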