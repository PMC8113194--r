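node_to_list <- function(node) {
  out <- list(class = node$class)
  if (!is.null(node$counts)) out$counts <- as.list(node$counts)
  if (!is_leaf(node)) {
    out$feature <- node$feature
    out$threshold <- node$threshold
    if (!is.null(node$decrease)) out$decrease <- node$decrease
    out$children <- list(node_to_list(node$left), node_to_list(node$right))
  }
  out
}

node_from_list <- function(x, classes) {
  counts <- if (!is.null(x$counts)) {
    stats::setNames(as.integer(unlist(x$counts)), names(x$counts))
  }
  node <- if (!is.null(counts)) {
    new_leaf(counts, names(counts))
  } else {
    structure(list(n = NA_integer_, counts = NULL, class = x$class,
                   impurity = NA_real_, feature = NULL, threshold = NULL,
                   decrease = NULL, left = NULL, right = NULL),
              class = "cart_node")
  }
  if (!is.null(x$class)) node$class <- x$class
  if (!is.null(x$feature)) {
    if (length(x$children) != 2L)
      stop_input("internal node on '%s' must have exactly two children",
                 x$feature)
    node$feature <- x$feature
    node$threshold <- x$threshold
    if (!is.null(x$decrease)) node$decrease <- x$decrease
    node$left <- node_from_list(x$children[[1]], classes)
    node$right <- node_from_list(x$children[[2]], classes)
  }
  node
}

#' Serialize a tree to JSON and back
#'
#' The JSON schema stores, per node, the split `feature` and `threshold`
#' (internal nodes), per-class training `counts` where known, the
#' predicted `class`, and a two-element `children` array; tree-level
#' metadata (`features`, `classes`, `n`, `params`) rides alongside the
#' root. A tree written and re-read compares equal node for node.
#'
#' @param tree A `cart_tree`.
#' @param file Path to write; `NULL` returns the JSON string.
#' @return `tree_to_json` returns `file` (or the JSON string) invisibly;
#'   `tree_from_json` returns the reconstructed `cart_tree`.
#' @export
tree_to_json <- function(tree, file = NULL) {
  if (!inherits(tree, "cart_tree")) stop_input("tree must be a cart_tree")
  payload <- list(features = tree$features, classes = tree$classes,
                  n = tree$n, params = tree$params,
                  root = node_to_list(tree$root))
  if (is.null(file)) {
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                            null = "null", na = "null"))
  }
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(file)
}

#' @rdname tree_to_json
#' @param x JSON string or path to a JSON file.
#' @export
tree_from_json <- function(x) {
  payload <- if (length(x) == 1L && !grepl("[{]", x) && file.exists(x)) {
    jsonlite::read_json(x)
  } else {
    jsonlite::parse_json(paste(x, collapse = "\n"))
  }
  if (is.null(payload$root) || is.null(payload$classes))
    stop_input("tree JSON must contain 'root' and 'classes'")
  structure(list(
    root = node_from_list(payload$root, unlist(payload$classes)),
    features = unlist(payload$features),
    classes = unlist(payload$classes),
    n = if (!is.null(payload$n)) as.integer(payload$n) else NA_integer_,
    params = payload$params
  ), class = "cart_tree")
}

render_node <- function(node, indent, lines) {
  pad <- strrep("  ", indent)
  counts <- if (!is.null(node$counts)) {
    sprintf(" [%s]", paste(sprintf("%s=%d", names(node$counts), node$counts),
                           collapse = " "))
  } else ""
  if (is_leaf(node)) {
    c(lines, sprintf("%s* %s%s", pad, node$class, counts))
  } else {
    lines <- c(lines, sprintf("%s%s <= %g ?%s", pad,
                              node$feature, node$threshold, counts))
    lines <- render_node(node$left, indent + 1L, lines)
    render_node(node$right, indent + 1L, lines)
  }
}

#' Text rendering of a tree
#'
#' One line per node, indented by depth: internal nodes show
#' `feature <= threshold ?` (left child = condition true), leaves show the
#' predicted class; per-class counts are appended where known.
#'
#' @param tree A `cart_tree`.
#' @return Character vector of lines, invisibly also printed by
#'   `print.cart_tree`.
#' @export
render_tree <- function(tree) {
  render_node(tree$root, 0L, character(0))
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("Classification tree: %d leaves, classes: %s\n",
              n_leaves(x), paste(x$classes, collapse = ", ")))
  cat(render_tree(x), sep = "\n")
  invisible(x)
}

#' @export
print.prune_path <- function(x, ...) {
  cat(sprintf("Cost-complexity pruning path (%d subtrees, root error %d/%d)\n",
              nrow(x$table), x$root_error, x$n))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' DOT (Graphviz) export of a tree
#'
#' @param tree A `cart_tree`.
#' @param file Path to write; `NULL` returns the DOT source as a string.
#' @return The DOT source, invisibly when written to a file.
#' @export
tree_to_dot <- function(tree, file = NULL) {
  id <- 0L
  lines <- c("digraph cart {", "  node [shape=box];")
  emit <- function(node) {
    id <<- id + 1L
    me <- id
    label <- if (is_leaf(node)) {
      node$class
    } else {
      sprintf("%s <= %g", node$feature, node$threshold)
    }
    if (!is.null(node$counts))
      label <- paste0(label, "\\n", paste(node$counts, collapse = "/"))
    lines <<- c(lines, sprintf("  n%d [label=\"%s\"];", me, label))
    if (!is_leaf(node)) {
      lid <- emit(node$left)
      rid <- emit(node$right)
      lines <<- c(lines,
                  sprintf("  n%d -> n%d [label=\"yes\"];", me, lid),
                  sprintf("  n%d -> n%d [label=\"no\"];", me, rid))
    }
    me
  }
  emit(tree$root)
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (is.null(file)) return(dot)
  writeLines(dot, file)
  invisible(dot)
}
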