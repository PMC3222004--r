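# Small in-code fixtures shared across test files.

# a uniform-HU volume with an all-true mask
uniformVolume <- function(hu = -700, dim = c(10, 10, 10),
                          spacing = c(10, 10, 10)) {
  CTVolume(array(hu, dim), spacing = spacing)
}

fullMask <- function(dim = c(10, 10, 10)) {
  LungMask(array(TRUE, dim))
}

# quick small phantom spec that fits its grid
smallSpec <- function(...) {
  phantomSpec(dim = c(48, 48, 32), spacing = c(4, 4, 6),
              lungVolumeMl = 2000, ...)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
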