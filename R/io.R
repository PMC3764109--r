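#' Serialise a lineage tree to Newick
#'
#' Writes the rooted binary lineage tree as a Newick string. Leaf labels
#' carry the final content of each quiescent cell (fraction for the
#' deterministic engine, molecule count otherwise), internal node labels
#' carry the generation at which the cell was born, every branch has length
#' 1 (one synchronous generation), and the children of each division are
#' ordered large-daughter-first.
#'
#' @param tree A [lineage_tree][grow_lineage].
#' @param digits Significant digits for fractional leaf contents.
#' @return A single Newick string (terminated by `;`).
#' @examples
#' export_newick(grow_lineage(0.3, 0.5))
#' @export
export_newick <- function(tree, digits = 6L) {
  stopifnot(inherits(tree, "lineage_tree"))
  nodes <- tree$nodes
  fmt <- function(x) {
    if (tree$engine == "deterministic") sprintf("%.*g", digits, x)
    else sprintf("%d", as.integer(x))
  }
  kids <- split(nodes$node_id, factor(nodes$parent_id, levels = nodes$node_id))
  build <- function(i) {
    ch <- kids[[i]]
    if (length(ch) == 0L) {
      return(fmt(nodes$content[i]))
    }
    ch <- ch[order(nodes$content[ch], decreasing = TRUE)] # large daughter first
    paste0("(", build(ch[1L]), ":1,", build(ch[2L]), ":1)g", nodes$generation[i])
  }
  paste0(build(1L), ";")
}

#' Write a lineage tree to a Newick file
#'
#' @inheritParams export_newick
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6L) {
  writeLines(export_newick(tree, digits = digits), path)
  invisible(path)
}

#' Convert a lineage tree to an ape `phylo` object
#'
#' @param x A [lineage_tree][grow_lineage].
#' @param ... Unused.
#' @return An object of class `phylo` (tip labels are final contents).
#' @export
as.phylo.lineage_tree <- function(x, ...) {
  ape::read.tree(text = export_newick(x))
}

#' @importFrom ape as.phylo
#' @export
ape::as.phylo

#' Write sweep/census results to CSV
#'
#' Thin wrapper over [readr::write_csv()]; identical inputs (including seed)
#' produce byte-identical files.
#'
#' @param x A tibble result (deterministic map, stochastic sweep, census,
#'   histogram, robustness curve, ...).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the settings of a simulation campaign into a serialisable object;
#' a run is reproducible from (config, seed) alone.
#'
#' @param engine `"deterministic"`, `"stochastic"` or `"perturbed"`.
#' @param mesh Grid mesh size.
#' @param n0 Founder molecule count (or vector, for censuses).
#' @param reps Replicates per grid pair.
#' @param seed Master seed.
#' @param sigma_p,sigma_phi Perturbation widths (fraction of mean).
#' @param max_iter,max_cells Growth caps.
#' @param out_dir Output directory for exports.
#' @return A list of class `run_config`.
#' @export
run_config <- function(engine = "deterministic", mesh = 0.0025, n0 = 10000L,
                       reps = 100L, seed = 1L, sigma_p = 0, sigma_phi = 0,
                       max_iter = 1e5, max_cells = 1e6, out_dir = ".") {
  structure(
    list(engine = engine, mesh = mesh, n0 = n0, reps = reps, seed = seed,
         sigma_p = sigma_p, sigma_phi = sigma_phi,
         max_iter = max_iter, max_cells = max_cells, out_dir = out_dir),
    class = "run_config"
  )
}

#' Read/write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a JSON sidecar recording run metadata
#'
#' @inheritParams write_run_config
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  meta <- c(unclass(config),
            list(package = "hourglass",
                 version = as.character(utils::packageVersion("hourglass"))))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
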