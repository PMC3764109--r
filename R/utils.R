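# Derive independent substream seeds from the current RNG state (or from a
# master seed when given). Keeps every derived seed inside 32-bit range.
derive_seeds <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, n)
}
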