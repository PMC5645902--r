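#' Grow the interaction-discovery regression tree
#'
#' Recursive binary splitting of the episodes on the 29 binary parameters,
#' used to surface candidate interactions for the improved linear model. At
#' each node the splitter is the parameter with the largest absolute
#' difference between the child mean scores, among splits that leave both
#' children with at least `min_node_size` episodes (ties broken by the larger
#' within-node error reduction, then by parameter order). A node is not split
#' when no admissible split exists or when its best split would raise the
#' overall tree R-squared (one minus the leaf error sum over the root total
#' sum of squares) by `delta_r2` or less.
#'
#' @param flags Tibble with the 29 binary parameter columns.
#' @param y Numeric score vector, one per row.
#' @param min_node_size Minimum episodes per child node (default 50).
#' @param delta_r2 Minimum overall R-squared gain required to accept a split
#'   (default 0.01).
#' @param weighted If `TRUE`, the split criterion weights the squared child
#'   mean difference by the child sizes (variance-reduction reading); the
#'   default uses the unweighted absolute mean difference.
#' @return An object of class `dhsi_tree`: a tibble of nodes (`id, parent,
#'   depth, n, mean_y, split_parameter, is_leaf, r_squared`) where
#'   `r_squared` is the cumulative tree R-squared when the node's split was
#'   accepted.
#' @export
#' @examples
#' cfg <- dhsi_sim_config(seed = 5)
#' m <- generate_parameter_matrix(400, cfg)
#' y <- 50 + 30 * m$X1 * m$Y7 + rnorm(400)
#' grow_interaction_tree(m, y)
grow_interaction_tree <- function(flags, y, min_node_size = 50,
                                  delta_r2 = 0.01, weighted = FALSE) {
  ids <- dhsi_parameter_ids()
  stopifnot(all(ids %in% names(flags)), length(y) == nrow(flags))
  X <- as.matrix(flags[ids])
  n <- length(y)
  sst <- sum((y - mean(y))^2)

  nodes <- tibble::tibble(
    id = integer(), parent = integer(), depth = integer(), n = integer(),
    mean_y = numeric(), split_parameter = character(), is_leaf = logical(),
    r_squared = numeric()
  )
  env <- new.env()
  env$nodes <- nodes
  env$next_id <- 1L
  env$leaf_sse <- 0   # SSE of finalized leaves
  env$r2 <- 0

  node_sse <- function(idx) sum((y[idx] - mean(y[idx]))^2)

  best_split <- function(idx) {
    best <- NULL
    for (j in seq_along(ids)) {
      xj <- X[idx, j]
      n1 <- sum(xj == 1)
      n0 <- length(idx) - n1
      if (n1 < min_node_size || n0 < min_node_size) next
      i1 <- idx[xj == 1]
      i0 <- idx[xj == 0]
      gap <- abs(mean(y[i1]) - mean(y[i0]))
      sse_red <- node_sse(idx) - node_sse(i1) - node_sse(i0)
      crit <- if (weighted) gap^2 * n1 * n0 / length(idx) else gap
      if (is.null(best) || crit > best$crit + 1e-12 ||
          (abs(crit - best$crit) <= 1e-12 && sse_red > best$sse_red + 1e-12)) {
        best <- list(j = j, crit = crit, sse_red = sse_red, i1 = i1, i0 = i0)
      }
    }
    best
  }

  grow <- function(idx, parent, depth) {
    id <- env$next_id
    env$next_id <- id + 1L
    row <- tibble::tibble(
      id = id, parent = parent, depth = depth, n = length(idx),
      mean_y = mean(y[idx]), split_parameter = NA_character_,
      is_leaf = TRUE, r_squared = env$r2
    )
    env$nodes <- dplyr::bind_rows(env$nodes, row)
    split <- if (sst > 0) best_split(idx) else NULL
    accept <- !is.null(split) && split$sse_red / sst > delta_r2
    if (!accept) {
      env$leaf_sse <- env$leaf_sse + node_sse(idx)
      return(invisible(NULL))
    }
    env$r2 <- env$r2 + split$sse_red / sst
    env$nodes$split_parameter[env$nodes$id == id] <- ids[split$j]
    env$nodes$is_leaf[env$nodes$id == id] <- FALSE
    env$nodes$r_squared[env$nodes$id == id] <- env$r2
    grow(split$i0, id, depth + 1L)
    grow(split$i1, id, depth + 1L)
    invisible(NULL)
  }

  grow(seq_len(n), NA_integer_, 0L)
  structure(list(nodes = env$nodes, sst = sst, n = n,
                 min_node_size = min_node_size, delta_r2 = delta_r2),
            class = "dhsi_tree")
}

#' @export
print.dhsi_tree <- function(x, ...) {
  n_leaves <- sum(x$nodes$is_leaf)
  cat(sprintf("Interaction-discovery tree: %d nodes (%d leaves), final R-squared %.4f\n",
              nrow(x$nodes), n_leaves, max(x$nodes$r_squared)))
  invisible(x)
}

#' Candidate interaction pairs from a grown tree
#'
#' Walks every root-to-leaf path and emits each unordered pair of distinct
#' splitting parameters that appear together on a path (ancestor-descendant
#' pairs, which subsume direct parent-child pairs), deduplicated across
#' paths. With `mode = "parent_child"` only directly nested splitter pairs
#' are emitted.
#'
#' @param tree A `dhsi_tree` from [grow_interaction_tree()].
#' @param mode `"ancestor"` (default) or `"parent_child"`.
#' @return A list of length-2 character vectors (sorted pairs); empty for a
#'   root-only tree.
#' @export
derive_interactions <- function(tree, mode = c("ancestor", "parent_child")) {
  mode <- match.arg(mode)
  nd <- tree$nodes
  internal <- nd[!nd$is_leaf, ]
  if (nrow(internal) == 0) return(list())
  pairs <- character(0)
  if (mode == "parent_child") {
    for (k in seq_len(nrow(internal))) {
      p <- internal$parent[k]
      if (is.na(p)) next
      psplit <- nd$split_parameter[nd$id == p]
      if (!is.na(psplit) && psplit != internal$split_parameter[k]) {
        pairs <- c(pairs, paste(sort(c(psplit, internal$split_parameter[k])),
                                collapse = ":"))
      }
    }
  } else {
    path_splits <- function(id) {
      out <- character(0)
      while (!is.na(id)) {
        s <- nd$split_parameter[nd$id == id]
        if (!is.na(s)) out <- c(s, out)
        id <- nd$parent[nd$id == id]
      }
      out
    }
    for (leaf in nd$id[nd$is_leaf]) {
      sp <- unique(path_splits(nd$parent[nd$id == leaf]))
      if (length(sp) >= 2) {
        cmb <- utils::combn(sort(sp), 2)
        pairs <- c(pairs, apply(cmb, 2, paste, collapse = ":"))
      }
    }
  }
  pairs <- unique(pairs)
  purrr::map(pairs, ~ strsplit(.x, ":", fixed = TRUE)[[1]])
}
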