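#' Phylogenetic correlation matrix from a tree
#'
#' Builds the species-by-species correlation matrix of shared evolutionary
#' history under a Brownian model: `A[i, j]` is the shared root-to-tip path
#' length of species i and j divided by the total tree depth, with a unit
#' diagonal. Polytomies are resolved to bifurcations by seeded
#' randomization (the seed is required and echoed back, because results at
#' coarse taxonomic levels are sensitive to the randomized bifurcation).
#' Absent branch lengths are assigned by Grafen's depth-based rule (node
#' height proportional to the number of descendant tips), which yields an
#' ultrametric tree; trees with branch lengths that are not ultrametric
#' have their terminal edges extended so every tip reaches the maximum
#' root-to-tip depth.
#'
#' @param tree an [ape::phylo] object or path to a newick file.
#' @param species character vector of species to include; names are
#'   normalized by trimming whitespace, replacing spaces with underscores
#'   and lower-casing before matching tips.
#' @param seed integer seed for polytomy randomization (required).
#' @return A list of class `phylo_correlation`: `A` (correlation matrix in
#'   the order of `species`), `species`, `seed`, `tree` (the processed
#'   tree).
#' @export
tree_to_correlation <- function(tree, species, seed) {
  if (missing(seed)) stop("polytomy randomization 'seed' is required",
                          call. = FALSE)
  if (is.character(tree) && length(tree) == 1) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  norm <- function(x) tolower(gsub("\\s+", "_", trimws(x)))
  tips <- norm(tree$tip.label)
  want <- norm(species)
  missing_sp <- species[!want %in% tips]
  if (length(missing_sp))
    stop("species missing from tree: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  tree$tip.label <- tips
  drop <- setdiff(tips, want)
  if (length(drop)) tree <- ape::drop.tip(tree, drop)
  if (!ape::is.binary(tree)) {
    set.seed(seed)
    tree <- ape::multi2di(tree, random = TRUE)
  }
  if (is.null(tree$edge.length)) {
    tree <- ape::compute.brlen(tree, method = "Grafen")
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > 1e-8 * max(depths)) {
    # extend terminal edges so the tree is ultrametric
    need <- max(depths) - depths
    term <- match(seq_along(tree$tip.label), tree$edge[, 2])
    tree$edge.length[term] <- tree$edge.length[term] + need
  }
  V <- ape::vcv(tree, corr = TRUE)
  ord <- match(want, rownames(V))
  A <- V[ord, ord, drop = FALSE]
  dimnames(A) <- list(species, species)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  structure(list(A = A, species = species, seed = seed, tree = tree),
            class = "phylo_correlation")
}
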