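# Construct an NRAD directly from a numeric vector (normalized and sorted),
# bypassing the resampling pipeline, for tests of the downstream tools.
make_nrad <- function(a, label = "x") {
  a <- sort(a / sum(a), decreasing = TRUE)
  radnorm:::new_nrad(a, length(a), a, a, 0L, NULL, label)
}
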