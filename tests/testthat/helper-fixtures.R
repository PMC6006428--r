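## Shared fixture builders.  Everything is generated in code; sizes are
## kept small so the whole suite stays desk-scale.

random_map <- function(n = 16, voxel = 2, seed = 1, origin = c(0, 0, 0)) {
  set.seed(seed)
  density_map(array(rnorm(n^3), c(n, n, n)), voxel, origin)
}

## A C8 ring of `copies` posed subunits at z = 0 on one grid.
ring_spec <- function(copies = 8, radius = 30, z = 0, phase = 0,
                      label = "Y") {
  architecture_spec(list(
    list(label = label, ring = "R1", copies = copies, radius = radius,
         z = z, phase = phase)))
}

## Noise-free rendered ring phantom plus its ground truth.
ring_phantom <- function(spec, subunits = NULL, voxel = 4, box = 128,
                         res = 6) {
  if (is.null(subunits)) subunits <- default_subunits()
  asm <- build_assembly(spec, subunits)
  list(map = render_density(asm$model, voxel, box, res),
       gt = asm$ground_truth)
}

## Smooth single-subunit map for transform/alignment tests.
y_map <- function(voxel = 3, box = 72, res = 6) {
  render_density(make_subunit("Y", "Y"), voxel, box, res)
}

expect_map_equal <- function(a, b, tol = 1e-9) {
  expect_equal(dim(a$values), dim(b$values))
  expect_lt(max(abs(a$values - b$values)), tol)
}

map_cc <- function(a, b) {
  stats::cor(as.numeric(a$values), as.numeric(b$values))
}

## nearest-truth distance for each accepted placement / each truth
nearest_dist <- function(xy, gt) {
  vapply(seq_len(nrow(xy)), function(i)
    min(sqrt((gt$tx - xy$tx[i])^2 + (gt$ty - xy$ty[i])^2 +
             (gt$tz - xy$tz[i])^2)), 0)
}
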