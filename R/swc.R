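#' Neuron morphology container (SWC semantics)
#'
#' A rooted tree of 3D nodes: columns `id`, `type`, `x`, `y`, `z`,
#' `radius`, `parent` (coordinates in micrometers, parent `-1` for the
#' root). The root is the soma. Parents must precede children and the
#' structure must be acyclic with a single root.
#'
#' @param nodes data.frame with the SWC columns.
#' @return object of class `neuron_tree`.
#' @export
neuron_tree <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(all(need %in% names(nodes)))
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  idx <- match(nodes$parent, nodes$id)
  bad <- is.na(idx) & nodes$parent != -1
  if (any(bad)) stop("parent ids must reference existing nodes")
  if (any(which(!is.na(idx)) <= idx[!is.na(idx)])) {
    stop("parents must precede children")
  }
  structure(list(nodes = nodes, soma_id = nodes$id[roots]),
            class = "neuron_tree")
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree> %d nodes, %d tips\n", nrow(x$nodes),
              sum(!x$nodes$id %in% x$nodes$parent)))
  invisible(x)
}

#' Read / write SWC morphology files
#'
#' Standard whitespace-separated SWC text
#' (`id type x y z radius parent`, `#` comments).
#'
#' @param tree a [neuron_tree()].
#' @param path file path.
#' @return `write_swc` returns `path` invisibly; `read_swc` a
#'   `neuron_tree`.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC morphology", con)
  utils::write.table(tree$nodes, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  nodes <- utils::read.table(path, comment.char = "#",
                             col.names = c("id", "type", "x", "y", "z",
                                           "radius", "parent"))
  neuron_tree(nodes)
}

#' Generate a random neuron morphology
#'
#' Grows a piecewise-straight rooted tree from a soma at the origin: each
#' branch extends `branch_len_steps` segments of `step_um` in a straight
#' line whose direction is drawn at the branch point; after growing, a
#' branch bifurcates while branch events remain (processed breadth-first).
#' With `n_branch_events = 0` the result is a single straight radial cable
#' of `branch_len_steps * step_um` micrometers.
#'
#' @param n_branch_events number of bifurcations (>= 0).
#' @param step_um segment length in micrometers.
#' @param seed integer seed.
#' @param branch_len_steps segments per branch.
#' @return a [neuron_tree()].
#' @export
generate_neuron_tree <- function(n_branch_events, step_um = 10, seed = 1L,
                                 branch_len_steps = 10L) {
  stopifnot(n_branch_events >= 0, step_um > 0, branch_len_steps >= 1)
  with_seed(seed, {
    rand_dir <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2))
    }
    nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                        radius = 5, parent = -1L)
    next_id <- 2L
    events_left <- n_branch_events
    # queue entries: (attachment node id, direction)
    queue <- list(list(at = 1L, dir = rand_dir()))
    while (length(queue) > 0L) {
      br <- queue[[1L]]
      queue <- queue[-1L]
      at <- br$at
      p0 <- as.numeric(nodes[match(at, nodes$id), c("x", "y", "z")])
      for (s in seq_len(branch_len_steps)) {
        p0 <- p0 + step_um * br$dir
        nodes <- rbind(nodes, data.frame(id = next_id, type = 3L,
                                         x = p0[1], y = p0[2], z = p0[3],
                                         radius = 0.5, parent = at))
        at <- next_id
        next_id <- next_id + 1L
      }
      if (events_left > 0L) {
        events_left <- events_left - 1L
        queue <- c(queue, list(list(at = at, dir = rand_dir()),
                               list(at = at, dir = rand_dir())))
      }
    }
    neuron_tree(nodes)
  })
}
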