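# Shared in-code fixtures: analytic tubes, arcs and small phantoms.

# solid circular cylinder along the given axis, value `value` inside
make_cylinder <- function(dim, radius, axis = 3L, value = 100,
                          centre = NULL, extent = NULL) {
  a <- array(0, dim)
  plane <- setdiff(1:3, axis)
  if (is.null(centre)) centre <- (dim[plane] + 1) / 2
  if (is.null(extent)) extent <- c(1L, dim[axis])
  idx <- expand.grid(i = seq_len(dim[plane[1]]), j = seq_len(dim[plane[2]]))
  inside <- (idx$i - centre[1])^2 + (idx$j - centre[2])^2 <= radius^2
  sl <- matrix(0, dim[plane[1]], dim[plane[2]])
  sl[cbind(idx$i[inside], idx$j[inside])] <- value
  for (k in seq(extent[1], extent[2])) {
    if (axis == 1L) a[k, , ] <- sl
    else if (axis == 2L) a[, k, ] <- sl
    else a[, , k] <- sl
  }
  a
}

# one-voxel path along axis 3 at (z0, y0), x in xs
make_path_mask <- function(dim, z0, y0, xs) {
  m <- array(FALSE, dim)
  m[z0, y0, xs] <- TRUE
  m
}

# small noisy phantom reused across tests (cached per session)
tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_phantom(phantom_spec(shape = c(48, 64, 64),
                                              stage = "normal", seed = 21))
    cache
  }
})

expect_same_mask <- function(a, b) {
  expect_identical(array(as.logical(a), dim(a)), array(as.logical(b), dim(b)))
}
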