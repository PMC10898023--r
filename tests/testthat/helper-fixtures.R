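# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

# a small desk-scale cohort reused by several test files
small_cohort <- function() {
  memo("small_cohort", function() {
    generate_cohort(cohort_spec(n_subjects = 24, seed = 404),
                    desk_phantom_spec())
  })
}

# tiny 32-px phantoms for fast training smoke tests (depth-3 network)
tiny_seg_data <- function(n = 16, seed = 7) {
  spec <- phantom_spec(image_size = 32L, cortical_thickness = 1,
                       vertebra_axes = c(0.3, 0.22), center_jitter = 0.01)
  imgs <- vector("list", n)
  msks <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_subject(spec, 100 + 10 * (i %% 5), 100, seed = seed + i)
    imgs[[i]] <- s$l1_slice
    msks[[i]] <- s$l1_mask
  }
  list(images = imgs, masks = msks, spec = spec)
}

# moment-matched sample: exact mean m and sd s
exact_sample <- function(n, m, s, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  m + s * (z - mean(z)) / stats::sd(z)
}

# naive O(n^2) DeLong structural components (double loop)
naive_delong <- function(scores, y) {
  xs <- scores[y == 1]
  ys <- scores[y == 0]
  m <- length(xs)
  n0 <- length(ys)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(xs, function(a) mean(psi(a, ys)), 1.0)
  v01 <- vapply(ys, function(b) mean(psi(xs, b)), 1.0)
  list(auc = mean(v10), v10 = v10, v01 = v01,
       var = stats::var(v10) / m + stats::var(v01) / n0)
}
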