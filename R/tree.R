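#' Parse a Newick string into a phylogeny
#'
#' Thin validated wrapper around the ape Newick parser. The tree must be
#' rooted with branch lengths on every edge, have at least two uniquely
#' labelled tips, and end in a semicolon.
#'
#' @param text a Newick string, or the path of a file containing one.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("expected a single Newick string or file path", call. = FALSE)
  }
  is_file <- !grepl("\\(", text) && file.exists(text)
  if (!is_file) {
    if (!grepl(";\\s*$", text)) {
      stop("Newick parse error: missing terminating semicolon", call. = FALSE)
    }
    n_open <- lengths(regmatches(text, gregexpr("\\(", text)))
    n_close <- lengths(regmatches(text, gregexpr("\\)", text)))
    if (n_open != n_close) {
      stop("Newick parse error: unbalanced parentheses (", n_open,
           " open vs ", n_close, " close)", call. = FALSE)
    }
  }
  tree <- tryCatch(
    if (is_file) ape::read.tree(file = text) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(tree)) stop("Newick parse error: unparseable input",
                          call. = FALSE)
  validate_phylogeny(tree)
  tree
}

#' Serialize a phylogeny to Newick
#'
#' @param tree an [ape::phylo] object.
#' @param file optional output path; if `NULL` the string is returned.
#' @return the Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylogeny(tree)
  s <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks unique tip labels, >= 2 tips, presence of branch lengths and their
#' non-negativity. Called by every tree-consuming entry point.
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (length(tree$tip.label) < 2L) stop("tree needs >= 2 tips", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("branch lengths must be finite and non-negative", call. = FALSE)
  }
  invisible(tree)
}

#' Brownian variance-covariance matrix of a phylogeny
#'
#' Under Brownian trait evolution the covariance of two tips equals the total
#' branch length shared by their root-to-tip paths, i.e. the depth of their
#' most recent common ancestor; the diagonal holds each tip's root-to-tip
#' distance. Built directly from node depths and the MRCA table.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return an n x n symmetric positive semi-definite matrix with tip labels
#'   as dimnames, rows/columns in `tree$tip.label` order.
#' @export
vcv_from_tree <- function(tree) {
  validate_phylogeny(tree)
  depth <- ape::node.depth.edgelength(tree)   # root-to-node distances
  M <- ape::mrca(tree)                        # tip x tip MRCA node ids
  V <- matrix(depth[M], nrow = nrow(M), dimnames = dimnames(M))
  # exact symmetry for downstream factorizations
  (V + t(V)) / 2
}

#' Pagel lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies every off-diagonal entry of `V` by `lambda`, leaving the
#' diagonal untouched. `lambda = 1` is strict Brownian motion; `lambda = 0`
#' removes all phylogenetic covariance (a star phylogeny).
#'
#' @param V phylogenetic covariance matrix from [vcv_from_tree()].
#' @param lambda value in [0, 1].
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

#' Align a trait vector or trait table to a tree
#'
#' Prunes the tree to the species present in both the tree and the trait
#' data, reorders the traits to tip order, and reports dropped species
#' explicitly. Matching is strict and case-sensitive: labels that would match
#' another label ignoring case are treated as an error, never silently
#' dropped.
#'
#' @param x a named numeric vector, or a data.frame with a `species_id` (or
#'   `species`) column.
#' @param tree an [ape::phylo] object.
#' @param quiet suppress the dropped-species message.
#' @return list with `tree` (pruned), `x` (reordered vector or data.frame),
#'   `dropped_from_tree`, `dropped_from_data`.
#' @export
align_traits_to_tree <- function(x, tree, quiet = FALSE) {
  validate_phylogeny(tree)
  labels <- if (is.data.frame(x)) {
    key <- intersect(c("species_id", "species"), names(x))[1]
    if (is.na(key)) stop("trait table needs a species_id column",
                         call. = FALSE)
    as.character(x[[key]])
  } else {
    if (is.null(names(x))) stop("trait vector must be named by species",
                                call. = FALSE)
    names(x)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate species labels in trait data", call. = FALSE)
  }
  keep <- intersect(tree$tip.label, labels)
  if (length(keep) == 0L) {
    stop("no species labels shared between tree and trait data",
         call. = FALSE)
  }
  # case-insensitive near-misses are an error, not a silent drop
  miss_data <- setdiff(labels, keep)
  miss_tree <- setdiff(tree$tip.label, keep)
  near <- intersect(tolower(miss_data), tolower(miss_tree))
  if (length(near) > 0L) {
    stop("case-mismatched species labels between tree and trait data: ",
         paste(miss_data[tolower(miss_data) %in% near], collapse = ", "),
         call. = FALSE)
  }
  pruned <- if (length(miss_tree) > 0L) {
    ape::drop.tip(tree, miss_tree)
  } else tree
  if (!quiet && (length(miss_tree) > 0L || length(miss_data) > 0L)) {
    message("align_traits_to_tree: dropped ", length(miss_tree),
            " tip(s) [", paste(miss_tree, collapse = ", "), "] and ",
            length(miss_data), " data row(s) [",
            paste(miss_data, collapse = ", "), "]")
  }
  ord <- pruned$tip.label
  x_out <- if (is.data.frame(x)) {
    x[match(ord, labels), , drop = FALSE]
  } else {
    x[ord]
  }
  list(tree = pruned, x = x_out,
       dropped_from_tree = miss_tree, dropped_from_data = miss_data)
}
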