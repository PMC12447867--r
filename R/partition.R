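# Partition = assignment of every node to exactly one module label,
# represented as a vector of labels named by node id.

#' Create a partition
#'
#' @param ids node identifiers (bodyIds).
#' @param labels module labels, one per id (coerced to character).
#' @return Named character vector of class `partition` (names are node ids).
#' @export
partition <- function(ids, labels) {
  if (length(ids) != length(labels)) {
    stop("ids and labels must have equal length", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate node ids in partition", call. = FALSE)
  p <- stats::setNames(as.character(labels), as.character(ids))
  class(p) <- "partition"
  p
}

#' Coerce to a partition
#'
#' Accepts a `partition`, a named vector, or a two-column data.frame
#' (node id, module label).
#' @param x object to coerce.
#' @return A [partition()].
#' @export
as_partition <- function(x) {
  if (inherits(x, "partition")) return(x)
  if (is.data.frame(x)) {
    if (ncol(x) < 2) stop("partition table needs two columns", call. = FALSE)
    return(partition(x[[1]], x[[2]]))
  }
  if (!is.null(names(x))) return(partition(names(x), unname(x)))
  stop("cannot coerce to partition: need names or a two-column table",
       call. = FALSE)
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", length(x), " nodes in ", length(unique(unclass(x))),
      " modules\n", sep = "")
  invisible(x)
}

#' List the node sets of each module
#' @param p a [partition()].
#' @return Named list: module label -> character vector of node ids.
#' @export
partition_communities <- function(p) {
  p <- as_partition(p)
  split(names(p), unclass(p))
}

#' Read / write partition tables
#'
#' Two-column CSV (`bodyId`, `module`), the interchange format shared by the
#' clustering, comparison, and profile stages.
#' @param path file path.
#' @return `read_partition` returns a [partition()].
#' @export
read_partition <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  partition(d[[1]], d[[2]])
}

#' @rdname read_partition
#' @param p a [partition()].
#' @export
write_partition <- function(p, path) {
  p <- as_partition(p)
  utils::write.csv(data.frame(bodyId = names(p), module = unclass(p)),
                   path, row.names = FALSE)
  invisible(p)
}

# canonical form: labels renumbered by order of first appearance over
# id-sorted nodes; used for duplicate detection in the ensemble
canonical_membership <- function(p) {
  p <- as_partition(p)
  p <- p[order(names(p))]
  v <- unclass(p)
  match(v, unique(v))
}

canonical_key <- function(p) paste(canonical_membership(p), collapse = ",")
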