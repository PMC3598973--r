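#' Read a phylogeny from a Newick string or file
#'
#' Parses a rooted, branch-length-annotated Newick tree (branch lengths in
#' million years) and validates it: exactly one root, unique tip labels, a
#' branch length on every non-root edge, and no negative branch lengths.
#' Zero-length internal edges are tolerated with a warning (they arise from
#' arbitrarily resolved polytomies).
#'
#' @param text a Newick string, or the path of a file containing one tree.
#' @param quiet suppress the tip-count message.
#' @return an [ape::phylo] object.
#' @seealso [write_newick()], [read_nexus_tree()]
#' @export
read_newick <- function(text, quiet = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("(", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  .check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed tree: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed tree: parser returned no tree", call. = FALSE)
  validate_phylogeny(tree)
  if (!quiet) message("read tree with ", ape::Ntip(tree), " tips")
  tree
}

# Character-level scan so parse failures can name a position, which
# ape::read.tree does not do.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed tree: unbalanced ')' at character ", i, call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("malformed tree: ", depth, " unclosed '(' by character ",
         length(chars), call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("malformed tree: missing terminating ';' at character ",
         length(chars), call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks that `tree` is a rooted `phylo` object with exactly one root,
#' unique tip labels, a branch length on every edge, and no negative branch
#' lengths. Zero-length edges trigger a warning rather than an error.
#'
#' @param tree an [ape::phylo] object.
#' @return `tree`, invisibly; errors describe the violated invariant.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("missing branch lengths: every non-root edge needs a length",
         call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("missing branch lengths on ", sum(is.na(tree$edge.length)),
         " edge(s)", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  n <- ape::Ntip(tree)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(root) != 1L) {
    stop("tree must have exactly one root, found ", length(root), call. = FALSE)
  }
  if (any(tree$edge.length == 0)) {
    warning("tree contains zero-length branches", call. = FALSE)
  }
  invisible(tree)
}

#' Write a phylogeny as a Newick string or file
#'
#' @param tree an [ape::phylo] object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  validate_phylogeny(suppressWarnings(tree))
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Read a tree from a NEXUS file
#'
#' Thin wrapper over [ape::read.nexus()] applying the same validation as
#' [read_newick()].
#'
#' @param path NEXUS file path.
#' @return an [ape::phylo] object (the first tree, if several).
#' @export
read_nexus_tree <- function(path) {
  trees <- ape::read.nexus(path)
  tree <- if (inherits(trees, "multiPhylo")) trees[[1]] else trees
  validate_phylogeny(tree)
  message("read NEXUS tree with ", ape::Ntip(tree), " tips")
  tree
}

#' Read a species trait table from CSV
#'
#' Expected columns: `species` (unique), and any of `membrane_length` (mm),
#' `turns` (quarter-turn units), `mass` (g), `echolocation_type`,
#' `call_min`, `call_peak`, `call_max` (kHz). Numeric columns must be
#' positive where present.
#'
#' @param path CSV path.
#' @param quiet suppress the row-count message.
#' @return a data.frame with one row per species.
#' @export
read_trait_table <- function(path, quiet = FALSE) {
  traits <- read.csv(path, stringsAsFactors = FALSE)
  validate_trait_table(traits)
  if (!quiet) message("read trait table with ", nrow(traits), " species")
  traits
}

#' Validate a species trait table
#'
#' @param traits a data.frame with a `species` column.
#' @return `traits`, invisibly.
#' @export
validate_trait_table <- function(traits) {
  if (!is.data.frame(traits) || !"species" %in% names(traits)) {
    stop("trait table must be a data.frame with a 'species' column",
         call. = FALSE)
  }
  if (anyDuplicated(traits$species)) {
    stop("trait table has duplicated species", call. = FALSE)
  }
  num_cols <- intersect(
    c("membrane_length", "turns", "mass", "call_min", "call_peak", "call_max"),
    names(traits))
  for (cl in num_cols) {
    v <- traits[[cl]]
    bad <- !is.na(v) & (!is.finite(v) | v <= 0)
    if (any(bad)) {
      stop("column '", cl, "' must be finite and positive (",
           sum(bad), " offending rows)", call. = FALSE)
    }
  }
  invisible(traits)
}

#' Prune a tree and trait table to their shared species
#'
#' Keeps the intersection of tip labels and trait species, collapsing the
#' degree-2 nodes created by pruning (child and parent branch lengths are
#' summed, so patristic distances among retained tips are preserved), and
#' reorders trait rows to tip order.
#'
#' @param tree an [ape::phylo] object.
#' @param traits a data.frame with a `species` column.
#' @param quiet suppress count messages.
#' @return a list with elements `tree` and `traits`.
#' @export
prune_and_match <- function(tree, traits, quiet = FALSE) {
  validate_phylogeny(suppressWarnings(tree))
  validate_trait_table(traits)
  shared <- intersect(tree$tip.label, traits$species)
  if (length(shared) == 0L) {
    stop("no overlap between tree tips [",
         paste(head(tree$tip.label, 10), collapse = ", "),
         "] and trait species [",
         paste(head(traits$species, 10), collapse = ", "), "]", call. = FALSE)
  }
  drop_tips <- setdiff(tree$tip.label, shared)
  drop_rows <- setdiff(traits$species, shared)
  if (length(drop_tips)) {
    if (!quiet) message("dropping ", length(drop_tips), " tips without traits")
    tree <- ape::keep.tip(tree, shared)
  }
  if (length(drop_rows)) {
    warning("dropping ", length(drop_rows),
            " trait rows absent from the tree: ",
            paste(head(drop_rows, 10), collapse = ", "), call. = FALSE)
  }
  traits <- traits[match(tree$tip.label, traits$species), , drop = FALSE]
  rownames(traits) <- NULL
  if (!quiet) message("matched ", length(shared), " species")
  list(tree = tree, traits = traits)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip path lengths must agree within `rel_tol` of their mean.
#'
#' @param tree an [ape::phylo] object.
#' @param rel_tol relative tolerance on tip depths (default `1e-6`).
#' @return logical scalar.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  depths <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  m <- mean(depths)
  if (m == 0) return(TRUE)
  all(abs(depths - m) <= rel_tol * m)
}

#' Root-to-node path lengths
#'
#' @param tree an [ape::phylo] object.
#' @return numeric vector of depths indexed by node id (tips first, then
#'   internal nodes in `ape` numbering).
#' @export
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(n_node)
  po <- ape::reorder.phylo(tree, "postorder")
  # reversed postorder visits parents before children
  for (i in rev(seq_len(nrow(po$edge)))) {
    depth[po$edge[i, 2]] <- depth[po$edge[i, 1]] + po$edge.length[i]
  }
  depth
}
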