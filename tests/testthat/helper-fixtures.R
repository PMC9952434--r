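# Shared fixtures, built in code (one cache per test file).

quiet_analyze <- function(...) suppressWarnings(analyze_recording(...))

fixture <- local({
  cache <- list()
  function(name) {
    if (is.null(cache[[name]])) {
      cache[[name]] <<- switch(
        name,
        # noise-free, no ectopics: ground truth exactly recoverable
        clean = generate_recording(
          tachogram_spec(duration = 60, seed = 11, ectopic_rate = 0),
          morphology_spec(noise_sd = 0)),
        # study-condition defaults, 120 s
        default = generate_recording(tachogram_spec(seed = 12)),
        stop("unknown fixture: ", name)
      )
    }
    cache[[name]]
  }
})

# Brute-force PRSA oracles: naive loops, independent of the implementation.
brute_anchors_increment <- function(x, L) {
  n <- length(x)
  out <- integer(0)
  for (i in 2:n) {
    if (x[i] > x[i - 1] && i - L >= 1 && i + L - 1 <= n) out <- c(out, i)
  }
  out
}

brute_anchors_averaged <- function(x, M, L) {
  n <- length(x)
  out <- integer(0)
  for (i in seq_len(n)) {
    if (i - M < 1 || i + M - 1 > n || i - L < 1 || i + L - 1 > n) next
    if (mean(x[i:(i + M - 1)]) > mean(x[(i - M):(i - 1)])) out <- c(out, i)
  }
  out
}

brute_prsa_curve <- function(x, anchors, L) {
  vapply(seq(-L, L - 1), function(k) mean(x[anchors + k]), numeric(1))
}
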