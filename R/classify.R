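#' Taxon map for WGD gene trees
#'
#' Maps each gene-tree tip to its species and subfamily. Outgroup tips carry
#' subfamily `"outgroup"`; all other tips are ingroup (salmonid) sequences.
#' Tip labels of the form `"Species|P1"` produced by
#' [simulate_wgd_gene_tree()] can be mapped automatically with
#' [taxon_map_from_tips()].
#'
#' @param tip gene-tree tip labels.
#' @param species species each tip belongs to.
#' @param subfamily subfamily of each species (e.g. `"Salmoninae"`,
#'   `"Thymallinae"`, `"Coregoninae"`) or `"outgroup"`.
#' @param paralog optional known paralogue tag per tip.
#' @return a `data.frame` of class `"taxon_map"`.
#' @export
taxon_map <- function(tip, species, subfamily, paralog = NA_character_) {
  df <- data.frame(tip = as.character(tip), species = as.character(species),
                   subfamily = as.character(subfamily),
                   paralog = as.character(paralog))
  if (anyDuplicated(df$tip)) stop("duplicate tips in taxon map")
  if (!any(df$subfamily == "outgroup")) stop("taxon map needs >= 1 outgroup tip")
  structure(df, class = c("taxon_map", "data.frame"))
}

#' Build a taxon map from `"Species|P"` tip labels
#'
#' @param tips gene-tree tip labels; the part before `"|"` is the species.
#' @param subfamilies named character vector mapping species to subfamily
#'   (`"outgroup"` for outgroup species).
#' @return a `"taxon_map"`.
#' @export
taxon_map_from_tips <- function(tips, subfamilies) {
  sp <- sub("\\|.*$", "", tips)
  par <- ifelse(grepl("\\|", tips), sub("^.*\\|", "", tips), NA_character_)
  miss <- setdiff(sp, names(subfamilies))
  if (length(miss)) stop("species without subfamily: ", paste(miss, collapse = ", "))
  taxon_map(tips, sp, unname(subfamilies[sp]), par)
}

#' Classify a WGD paralogue gene tree by diploidization-resolution outcome
#'
#' Screens a gene tree of WGD paralogue sequences against the topology
#' expected when diploidization resolution (DR) completed in the common
#' ancestor of the ingroup lineages, the only configuration in which the
#' paralogue split is a clean, datable event shared by all lineages:
#'
#' 1. the tree is (re)rooted on the outgroup; the ingroup must be
#'    monophyletic, else `"ambiguous"`;
#' 2. the ingroup crown must split into two paralogous clades in which no
#'    species appears twice; if instead some species' two copies are sister
#'    tips the pattern indicates unresolved tetrasomic inheritance with
#'    concerted evolution (`"unresolved_tetrasomic"`); if every crown
#'    lineage contains a private, mirrored paralogue split the DR was
#'    lineage-specific (`"lineage_specific"`); anything else is
#'    `"ambiguous"`;
#' 3. both paralogous clades must contain every subfamily present in the
#'    dataset, else `"ambiguous"`;
#' 4. if `min_support` is given, the support annotation (internal node
#'    label) of the paralogue-split node must reach it; a missing annotation
#'    yields `"ambiguous"`.
#'
#' Only `"resolved_ancestral"` trees are kept for downstream concatenation
#' and molecular-clock dating (`keep = TRUE`).
#'
#' @param gene_tree a rooted or rootable `"phylo"`.
#' @param map a [taxon_map()] covering every tip.
#' @param min_support optional support threshold in the units of the input
#'   tree's node labels.
#' @return an object of class `"dr_classification"`: list with elements
#'   `scenario`, `keep`, `support` (paralogue-split support or `NA`) and
#'   `diagnostics` (named logical/character vector per criterion).
#' @export
classify_diploidization <- function(gene_tree, map, min_support = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(map, "taxon_map"))
  tips <- gene_tree$tip.label
  unmapped <- setdiff(tips, map$tip)
  if (length(unmapped)) stop("unmapped tips: ", paste(unmapped, collapse = ", "))
  m <- map[match(tips, map$tip), ]
  out_tips <- tips[m$subfamily == "outgroup"]
  if (length(out_tips) == 0L) stop("no outgroup tips in this gene tree")
  ing_tips <- setdiff(tips, out_tips)
  if (length(unique(m$species[m$subfamily != "outgroup"])) < 2L)
    stop("fewer than 2 ingroup species")
  subfams <- unique(m$subfamily[m$subfamily != "outgroup"])

  diag <- c(outgroup_root = FALSE, ingroup_monophyly = FALSE,
            two_paralog_clades = FALSE, subfamily_representation = FALSE,
            support_ok = NA)
  res <- function(scenario, support = NA_real_) {
    structure(list(scenario = scenario,
                   keep = identical(scenario, "resolved_ancestral"),
                   support = support, diagnostics = diag),
              class = "dr_classification")
  }

  ## 1. root on the outgroup branch
  tr <- tryCatch({
    t2 <- ape::unroot(gene_tree)
    ape::root(t2, outgroup = out_tips, resolve.root = TRUE)
  }, error = function(e) NULL)
  if (is.null(tr)) return(res("ambiguous"))
  diag["outgroup_root"] <- TRUE
  if (!ape::is.monophyletic(tr, ing_tips)) return(res("ambiguous"))
  diag["ingroup_monophyly"] <- TRUE

  sp_of <- stats::setNames(m$species, m$tip)
  crown <- ape::getMRCA(tr, ing_tips)
  kids <- node_children(tr, crown)
  clade_tips <- lapply(kids, function(k) tr$tip.label[tips_under(tr, k)])
  dup_free <- vapply(clade_tips, function(tt) !anyDuplicated(sp_of[tt]), logical(1L))

  if (length(kids) == 2L && all(dup_free) &&
      all(lengths(clade_tips) >= 2L)) {
    diag["two_paralog_clades"] <- TRUE
    sf <- lapply(clade_tips, function(tt)
      unique(m$subfamily[match(tt, m$tip)]))
    if (all(vapply(sf, function(s) all(subfams %in% s), logical(1L)))) {
      diag["subfamily_representation"] <- TRUE
      sup <- .node_support(tr, crown)
      if (!is.null(min_support)) {
        diag["support_ok"] <- isTRUE(sup >= min_support)
        if (!isTRUE(sup >= min_support)) return(res("ambiguous", sup))
      }
      return(res("resolved_ancestral", sup))
    }
    return(res("ambiguous"))
  }

  ## not a clean ancestral paralogue split: tetrasomic vs lineage-specific
  cherries <- .species_cherries(tr, ing_tips, sp_of)
  if (length(cherries)) return(res("unresolved_tetrasomic"))
  if (length(kids) == 2L &&
      all(vapply(seq_along(kids), function(i)
        .is_private_paralog_split(tr, kids[i], sp_of), logical(1L))))
    return(res("lineage_specific"))
  res("ambiguous")
}

# Support value (numeric node label) of an internal node, NA if absent.
.node_support <- function(tr, node) {
  nl <- tr$node.label
  if (is.null(nl)) return(NA_real_)
  lab <- nl[node - length(tr$tip.label)]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) return(NA_real_)
  suppressWarnings(as.numeric(lab))
}

# Species whose two ingroup copies are sister tips.
.species_cherries <- function(tr, ing_tips, sp_of) {
  idx <- match(ing_tips, tr$tip.label)
  par <- tr$edge[match(idx, tr$edge[, 2L]), 1L]
  out <- character(0)
  for (sp in unique(sp_of[ing_tips])) {
    k <- idx[sp_of[ing_tips] == sp]
    if (length(k) == 2L && par[match(k[1L], idx)] == par[match(k[2L], idx)])
      out <- c(out, sp)
  }
  out
}

# Does clade `node` consist of each of its species exactly twice, split at
# its top into two mirrored, duplication-free subclades?
.is_private_paralog_split <- function(tr, node, sp_of) {
  tt <- tr$tip.label[tips_under(tr, node)]
  spp <- sp_of[tt]
  if (!all(table(spp) == 2L)) return(FALSE)
  if (node <= length(tr$tip.label)) return(FALSE)
  ch <- node_children(tr, node)
  if (length(ch) != 2L) return(FALSE)
  s1 <- sp_of[tr$tip.label[tips_under(tr, ch[1L])]]
  s2 <- sp_of[tr$tip.label[tips_under(tr, ch[2L])]]
  !anyDuplicated(s1) && !anyDuplicated(s2) && setequal(s1, s2)
}

#' @export
print.dr_classification <- function(x, ...) {
  cat("DR classification:", x$scenario,
      if (x$keep) "(kept)" else "(discarded)", "\n")
  if (!is.na(x$support)) cat("  paralogue-split support:", x$support, "\n")
  invisible(x)
}

#' Classify a batch of gene trees
#'
#' @param gene_trees list of `"phylo"` gene trees.
#' @param maps a single [taxon_map()] shared by all trees, or a list of maps.
#' @param min_support optional support threshold, see
#'   [classify_diploidization()].
#' @return a `data.frame` with one row per tree (`scenario`, `keep`,
#'   `support`).
#' @export
classify_batch <- function(gene_trees, maps, min_support = NULL) {
  one_map <- inherits(maps, "taxon_map")
  rows <- lapply(seq_along(gene_trees), function(i) {
    cl <- classify_diploidization(gene_trees[[i]],
                                  if (one_map) maps else maps[[i]],
                                  min_support)
    data.frame(tree = i, scenario = cl$scenario, keep = cl$keep,
               support = cl$support)
  })
  do.call(rbind, rows)
}
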