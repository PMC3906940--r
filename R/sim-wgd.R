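#' Specification of a WGD gene-tree scenario
#'
#' Describes how the duplicated loci produced by a whole-genome duplication
#' (WGD) resolved into independently evolving paralogues (diploidization
#' resolution, DR) relative to speciation:
#'
#' * `"a_species_only"` - a single-copy locus: the gene tree is the species
#'   tree (no WGD signal).
#' * `"b_ancestral_DR"` - DR completed in the common ancestor: two paralogue
#'   clades, each mirroring the species tree, diverging at the (single) DR
#'   age.
#' * `"c_lineage_specific_DR"` - DR happened independently in each daughter
#'   lineage of the first speciation, at its own age: paralogue divergence
#'   nests within lineages.
#' * `"d_unresolved_tetrasomic"` - as (c), but at least one lineage never
#'   resolved: tetrasomic inheritance with gene conversion homogenises its
#'   copies, so a species' paralogue pair coalesces near the present and its
#'   sequence variants cluster together.
#'
#' @param scenario one of the four scenario codes above (may be abbreviated
#'   to `"a"`, `"b"`, `"c"`, `"d"`).
#' @param wgd_depth age of the WGD (Ma); must predate the ingroup crown and
#'   postdate the outgroup split.
#' @param dr_depths DR age(s) in Ma: a single value for scenario b; one value
#'   per crown lineage for scenarios c/d.
#' @param conversion_strength in `[0, 1]`: degree of concerted-evolution
#'   homogenisation in unresolved lineages (scenario d); the realised
#'   within-species paralogue divergence is `(1 - conversion_strength) *
#'   dr_depth` for that lineage.
#' @param unresolved indices (1-based, into the crown lineages) of lineages
#'   that never resolve (scenario d); default: lineage 1.
#' @return an object of class `"wgd_scenario"`.
#' @export
wgd_scenario <- function(scenario = c("b_ancestral_DR", "a_species_only",
                                      "c_lineage_specific_DR",
                                      "d_unresolved_tetrasomic"),
                         wgd_depth, dr_depths = NULL,
                         conversion_strength = 1, unresolved = 1L) {
  scenario <- match.arg(scenario)
  if (missing(wgd_depth) || !is.finite(wgd_depth) || wgd_depth <= 0)
    stop("'wgd_depth' must be a positive age in Ma")
  if (scenario != "a_species_only") {
    if (is.null(dr_depths) || any(!is.finite(dr_depths)) || any(dr_depths <= 0))
      stop("'dr_depths' must be positive ages in Ma")
    if (any(dr_depths > wgd_depth))
      stop("DR cannot predate the WGD: dr_depths must be <= wgd_depth")
  }
  if (conversion_strength < 0 || conversion_strength > 1)
    stop("'conversion_strength' must be in [0, 1]")
  structure(list(scenario = scenario, wgd_depth = wgd_depth,
                 dr_depths = dr_depths,
                 conversion_strength = conversion_strength,
                 unresolved = as.integer(unresolved)),
            class = "wgd_scenario")
}

# Newick of a subtree (no trailing ";"), with tips tagged "Tip|P1" etc.
.sub_newick <- function(phy, tag = NULL) {
  if (!is.null(tag)) phy$tip.label <- paste0(phy$tip.label, "|", tag)
  sub(";$", "", write_newick(phy))
}

# Subtree of `phy` spanned by `tips`: list(tips, clade phylo or NULL for a
# single tip, crown age).
.clade_of <- function(phy, tips) {
  if (length(tips) == 1L) list(tips = tips, clade = NULL, crown = 0)
  else {
    cl <- ape::keep.tip(phy, tips)
    list(tips = tips, clade = cl, crown = max(node_ages(cl)))
  }
}

# Newick (no ";") of a lineage, tips tagged with a paralogue suffix.
.lineage_newick <- function(L, tag) {
  if (is.null(L$clade)) paste0(L$tips, "|", tag)
  else .sub_newick(L$clade, tag)
}

#' Simulate a WGD paralogue gene tree under a diploidization scenario
#'
#' Builds the gene tree implied by an ultrametric species tree and a
#' [wgd_scenario()]: paralogue copies of every ingroup species (tips labelled
#' `"Species|P1"` / `"Species|P2"`), diverging at the scenario's DR age(s),
#' with the outgroup species attached exactly as in the species tree (single
#' copy, splitting before the duplication node). Scenario geometry is
#' deterministic given its ages; `seed` is accepted for interface symmetry
#' with the stochastic simulators.
#'
#' @param species_tree ultrametric rooted `"phylo"` containing ingroup and
#'   outgroup tips.
#' @param outgroups character vector of outgroup tip labels (>= 1); the
#'   remaining tips form the (monophyletic) ingroup.
#' @param spec a [wgd_scenario()].
#' @param seed unused (deterministic); kept for a uniform simulator surface.
#' @return the gene tree as a `"phylo"`.
#' @export
simulate_wgd_gene_tree <- function(species_tree, outgroups, spec, seed = NULL) {
  stopifnot(inherits(species_tree, "phylo"), inherits(spec, "wgd_scenario"))
  if (!is_ultrametric(species_tree)) stop("species tree must be ultrametric")
  tips <- species_tree$tip.label
  if (!all(outgroups %in% tips)) stop("unknown outgroup tips")
  ingroup <- setdiff(tips, outgroups)
  if (length(ingroup) < 2L) stop("need >= 2 ingroup species")
  if (!ape::is.monophyletic(species_tree, ingroup))
    stop("ingroup is not monophyletic in the species tree")
  if (spec$scenario == "a_species_only") return(species_tree)

  ing <- ape::keep.tip(species_tree, ingroup)
  h <- max(node_ages(ing))                       # ingroup crown age
  ## backbone: outgroup structure + one placeholder tip for the ingroup
  backbone <- ape::keep.tip(species_tree, c(outgroups, ingroup[1L]))
  ptip <- which(backbone$tip.label == ingroup[1L])
  backbone$tip.label[ptip] <- "INGROUP_PLACEHOLDER"
  pedge <- which(backbone$edge[, 2L] == ptip)
  attach_age <- backbone$edge.length[pedge]      # outgroup split age
  if (spec$wgd_depth <= h)
    stop("wgd_depth must predate the ingroup crown age (", signif(h, 6), " Ma)")
  if (spec$wgd_depth >= attach_age)
    stop("wgd_depth must postdate the outgroup split (",
         signif(attach_age, 6), " Ma)")

  graft <- function(sub_nwk, crown_age) {
    if (crown_age >= attach_age)
      stop("scenario ages inconsistent with the outgroup split age")
    bb <- backbone
    bb$edge.length[pedge] <- attach_age - crown_age
    s <- sub_tip_label(write_newick(bb), "INGROUP_PLACEHOLDER", sub_nwk)
    read_newick(s)
  }

  if (spec$scenario == "b_ancestral_DR") {
    d <- spec$dr_depths[1L]
    if (d <= h) stop("scenario b needs a DR age older than the first speciation")
    sub <- paste0("(", .sub_newick(ing, "P1"), ":", format(d - h, digits = 12),
                  ",", .sub_newick(ing, "P2"), ":", format(d - h, digits = 12), ")")
    return(graft(sub, d))
  }

  ## scenarios c and d: per-lineage resolution below the ingroup crown
  crown <- length(ingroup) + 1L                  # ingroup root node id
  kids <- node_children(ing, crown)
  lineages <- lapply(kids, function(k) .clade_of(ing, ing$tip.label[tips_under(ing, k)]))
  d_lin <- rep_len(spec$dr_depths, length(kids))
  unres <- if (spec$scenario == "d_unresolved_tetrasomic") spec$unresolved else integer(0)
  if (spec$scenario == "d_unresolved_tetrasomic" && length(unres) == 0L)
    stop("scenario d needs at least one unresolved lineage")

  cherry <- function(lab, age) {
    paste0("(", lab, "|P1:", format(age, digits = 12), ",",
           lab, "|P2:", format(age, digits = 12), ")")
  }
  lin_nwk <- vapply(seq_along(kids), function(i) {
    L <- lineages[[i]]; d <- d_lin[i]
    if (d >= h) stop("lineage DR ages must be younger than the first speciation")
    if (d <= L$crown)
      stop("lineage DR age must predate the lineage crown (lineage ", i, ")")
    if (i %in% unres) {
      ## tetrasomy + gene conversion: per-species paralogue cherries at
      ## (1 - conversion_strength) * dr, clamped inside each terminal branch
      a <- (1 - spec$conversion_strength) * d
      if (is.null(L$clade))
        return(paste0(cherry(L$tips, a), ":", format(h - a, digits = 12)))
      cl <- L$clade
      term <- match(seq_along(cl$tip.label), cl$edge[, 2L])
      repl <- vector("list", length(cl$tip.label))
      for (j in seq_along(cl$tip.label)) {
        parent_age <- cl$edge.length[term[j]]  # ultrametric: tip edge = parent age
        aj <- min(a, 0.9 * parent_age)
        repl[[j]] <- c(sprintf("CHERRY%03d", j), cherry(cl$tip.label[j], aj))
        cl$edge.length[term[j]] <- parent_age - aj
        cl$tip.label[j] <- sprintf("CHERRY%03d", j)
      }
      out <- write_newick(cl)
      for (r in repl) out <- sub_tip_label(out, r[1L], r[2L])
      paste0(sub(";$", "", out), ":", format(h - L$crown, digits = 12))
    } else {
      paste0("(", .lineage_newick(L, "P1"), ":", format(d - L$crown, digits = 12),
             ",", .lineage_newick(L, "P2"), ":", format(d - L$crown, digits = 12),
             "):", format(h - d, digits = 12))
    }
  }, character(1L))
  graft(paste0("(", paste(lin_nwk, collapse = ","), ")"), h)
}
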