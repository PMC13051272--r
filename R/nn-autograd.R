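# Minimal tape-based reverse-mode automatic differentiation over plain R
# arrays. Every operator records a node on a per-graph tape; ag_backward()
# walks the tape in reverse creation order, which is a valid topological
# order because nodes can only depend on previously created nodes.

.ag <- new.env(parent = emptyenv())
.ag$tape <- list()
.ag$n <- 0L

ag_reset <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

.ag_record <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[n]] <- node
  .ag$n <- n
  node
}

#' @noRd
ag_node <- function(value, parents = list(), backward = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$backward <- backward
  node$grad <- NULL
  class(node) <- "ag_node"
  .ag_record(node)
}

# Leaf holding trainable weights; lives outside any tape so it survives
# graph resets and accumulates gradients across a batch.
ag_param <- function(value) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- list()
  node$backward <- NULL
  node$grad <- NULL
  class(node) <- "ag_node"
  node
}

ag_is_node <- function(x) inherits(x, "ag_node")

# Wrap a constant (no gradient tracked).
ag_const <- function(x) if (ag_is_node(x)) x else ag_param(x)

ag_value <- function(x) if (ag_is_node(x)) x$value else x

.ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

ag_backward <- function(loss) {
  stopifnot(ag_is_node(loss), length(loss$value) == 1L)
  loss$grad <- 1
  if (.ag$n == 0L) return(invisible(NULL))
  for (i in seq(.ag$n, 1L)) {
    node <- .ag$tape[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node$grad)
    for (j in seq_along(node$parents)) {
      if (!is.null(gs[[j]])) .ag_accum(node$parents[[j]], gs[[j]])
    }
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
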