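# Shared small fixtures, built once per test run.

# coarse deterministic map used by several structural tests
coarse_det_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- sweep_deterministic(0.05)
    cache
  }
})

# leaf/parent bookkeeping for conservation checks
children_of <- function(nodes) {
  split(seq_len(nrow(nodes)), factor(nodes$parent_id, levels = nodes$node_id))
}

# sum of daughter contents minus parent content, for every divided node
division_residuals <- function(tree) {
  nodes <- tree$nodes
  kids <- children_of(nodes)
  divided <- which(nodes$divided)
  vapply(divided, function(i) {
    sum(nodes$content[kids[[i]]]) - nodes$content[i]
  }, double(1))
}
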