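# Fixture builders shared across the suite. Everything is generated in
# code, seeded, and small enough to keep the full run fast.

random_volume <- function(shape = c(8L, 8L, 8L), labels = 0:2,
                          spacing = c(1, 1, 1), seed = 1L,
                          source_id = "rand") {
  set.seed(seed)
  label_volume(array(sample(labels, prod(shape), replace = TRUE), shape),
               spacing = spacing, source_id = source_id)
}

# Axis-aligned cube mask of side `side` with its lowest corner at `corner`,
# carrying `label` on an otherwise-background grid.
cube_volume <- function(shape = c(12L, 12L, 12L), corner = c(3L, 3L, 3L),
                        side = 3L, label = 1L, spacing = c(1, 1, 1)) {
  v <- array(0L, shape)
  idx <- lapply(corner, function(c0) c0:(c0 + side - 1L))
  v[idx[[1]], idx[[2]], idx[[3]]] <- label
  label_volume(v, spacing = spacing)
}

small_phantom_spec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(32L, 32L, 24L), spacing = c(1.5, 1.5, 3),
         kidney_centers = list(c(9, 16, 12), c(23, 16, 12)),
         kidney_axes = list(c(5, 7, 6), c(5, 7, 6)),
         tumor_center = c(23, 20, 14), tumor_radius = 4),
    list(...))
  do.call(phantom_spec, args)
}
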