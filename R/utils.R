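# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Replace a tip label in a Newick string by an (unquoted) replacement,
# anchored so that e.g. "S1" never matches inside "S10".  Labels used by the
# simulators are alphanumeric plus "|._-"; escape for safety anyway.
sub_tip_label <- function(newick, label, replacement) {
  pat <- paste0("(?<=[(,])", gsub("([][{}()*+?.\\^$|\\\\])", "\\\\\\1", label),
                "(?=[:,)])")
  out <- gsub(pat, replacement, newick, perl = TRUE)
  if (identical(out, newick))
    stop("tip label '", label, "' not found in Newick string")
  out
}

# All tip indices below a node of a phylo object (node may itself be a tip).
tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    ch <- phy$edge[phy$edge[, 1L] == nd, 2L]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  sort(out)
}

# Children of an internal node.
node_children <- function(phy, node) phy$edge[phy$edge[, 1L] == node, 2L]

# Ages (time before present) of all nodes of a rooted tree with branch
# lengths; tips of an ultrametric tree get age ~0.
node_ages <- function(phy) {
  depth <- ape::node.depth.edgelength(phy)
  max(depth) - depth
}

`%||%` <- function(a, b) if (is.null(a)) b else a
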