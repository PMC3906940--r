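#' Read a rooted phylogeny from Newick
#'
#' Thin validating wrapper around [ape::read.tree()]. Trees are the universal
#' substrate of the package: gene trees of WGD paralogues, dated species
#' trees, and simulated birth-death trees, with branch lengths in Myr (or any
#' consistent unit). Branch lengths are required on all edges (the root edge
#' is optional); internal node labels (e.g. support values) are preserved.
#'
#' @param x a Newick string, or the path of a file containing one tree.
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x) && !grepl("\\(", x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  txt <- trimws(txt)
  if (!nzchar(txt)) stop("empty Newick input")
  .check_balanced(txt)
  ## single-tip dialect: "A:1;" (ape cannot represent a 1-tip tree usefully)
  if (!grepl("\\(", txt)) {
    m <- regmatches(txt, regexec("^([^():,;[:space:]]+)(:([0-9.eE+-]+))?;$", txt))[[1L]]
    if (length(m) == 0L) stop("Newick parse error at character 1: not a tree")
    phy <- structure(list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = if (nzchar(m[3L])) as.numeric(m[4L]) else 0,
      tip.label = m[2L], Nnode = 1L), class = "phylo")
    return(phy)
  }
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error: unreadable tree")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("all edges must carry branch lengths")
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  phy
}

.check_balanced <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error at character ", i,
                           ": unmatched ')'")
    }
  }
  if (depth != 0L) stop("Newick parse error at character ", nchar(txt),
                        ": ", depth, " unclosed '('")
  if (!grepl(";\\s*$", txt)) stop("Newick parse error at character ",
                                  nchar(txt), ": missing terminal ';'")
  invisible(TRUE)
}

#' Write a phylogeny as Newick
#'
#' Branch lengths are printed with enough significant digits (>= 10) that a
#' read/write round trip reproduces topology and lengths to better than 1e-9.
#' A single-tip tree is written in the `"A:0;"` dialect.
#'
#' @param tree a `"phylo"` object.
#' @param file optional path; the default returns the string.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 1L) {
    s <- paste0(tree$tip.label, ":",
                format(tree$edge.length %||% 0, digits = 12), ";")
  } else {
    s <- ape::write.tree(tree, digits = 12)
  }
  if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
  s
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip path lengths must agree within `tol` times the tree
#' height. Dated trees exported by external programs typically carry small
#' rounding noise, hence the relative-tolerance default.
#'
#' @param tree a rooted `"phylo"` with branch lengths.
#' @param tol relative tolerance (default `1e-6`).
#' @return `TRUE` or `FALSE`.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) return(TRUE)
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(depth) - min(depth)) <= tol * max(depth)
}

#' Branching times of an ultrametric tree
#'
#' Extracts the sorted node ages \eqn{x_1 \ge x_2 \ge \dots \ge x_{n-1}}
#' (Ma before present, \eqn{x_1} the root age) together with the derived
#' internode intervals \eqn{g_k} (duration spent with exactly `k` lineages,
#' `k = 2..n`), the cumulative sums \eqn{T_i = \sum_{k=2}^{i} k g_k} and the
#' total \eqn{T = T_n}. These are the sufficient statistics of the gamma
#' constant-rates test and of the survival models.
#'
#' @param tree ultrametric, binary, rooted `"phylo"` with >= 3 tips.
#' @param tol ultrametricity tolerance passed to [is_ultrametric()].
#' @return an object of class `"branching_times"`: a list with elements
#'   `n`, `times`, `g` (named `"2"..as.character(n)`), `Ti`, `total`.
#' @export
branching_times <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 3L) stop("branching_times() requires >= 3 tips")
  if (!ape::is.binary(tree)) stop("tree contains polytomies; resolve first")
  if (!is_ultrametric(tree, tol)) stop("tree is not ultrametric within tol = ", tol)
  ages <- node_ages(tree)
  times <- sort(ages[(n + 1L):(n + tree$Nnode)], decreasing = TRUE)
  g <- c(-diff(times), times[n - 1L])           # g_2 .. g_n
  names(g) <- as.character(2:n)
  Ti <- cumsum((2:n) * g)
  names(Ti) <- as.character(2:n)
  structure(list(n = n, times = unname(times), g = g, Ti = Ti,
                 total = unname(Ti[n - 1L])),
            class = "branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat("Branching times: n =", x$n, "tips, root age =",
      format(x$times[1L], digits = 6), "\n")
  cat("  total lineage-time T =", format(x$total, digits = 6), "\n")
  invisible(x)
}
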