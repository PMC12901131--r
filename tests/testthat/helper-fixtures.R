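# Shared fixtures, built lazily once per test session. The full stimulus
# set takes ~20 s to render, so every test file that needs it goes through
# cached_full_set().
.fixture_cache <- new.env(parent = emptyenv())

cached_full_set <- function(seed = 1L) {
  key <- paste0("set", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_full_set(seed = seed)
  .fixture_cache[[key]]
}

cached_session <- function(seed = 1L) {
  key <- paste0("session", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- assemble_session(seed = seed)
  .fixture_cache[[key]]
}

# small scene for pipeline tests (full geometry, procedural source)
cached_scene <- function() {
  if (is.null(.fixture_cache$scene)) {
    src <- make_naturalistic_fixtures(1, seed = 42L)[[1]]
    .fixture_cache$scene <- prep_scene(src)
  }
  .fixture_cache$scene
}

# radially averaged log-log spectral slope over mid frequencies
spectral_slope <- function(values) {
  n <- nrow(values)
  A <- Mod(stats::fft(values - mean(values)))
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  fx <- matrix(rep(f, each = n), n, n)
  fy <- matrix(rep(f, times = n), n, n)
  rad <- sqrt(fx^2 + fy^2)
  lo <- 4; hi <- n / 8
  keep <- rad >= lo & rad <= hi
  bins <- cut(log(rad[keep]), 30)
  mlog_a <- tapply(log(A[keep]), bins, mean)
  mlog_f <- tapply(log(rad[keep]), bins, mean)
  unname(stats::coef(stats::lm(mlog_a ~ mlog_f))[2])
}
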