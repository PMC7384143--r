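#' Simulate a dated phylogeny with tunable trait signal
#'
#' Simulates an ultrametric birth-death tree (branch lengths in Myr) over
#' `n_species` tips and a continuous trait mixing a Brownian-motion
#' component with i.i.d. noise:
#' trait = w * BM* + (1 - w) * eps, where BM* is the Brownian simulation
#' standardised to unit variance, eps is standard normal, and
#' w = `signal_weight`. w = 1 gives pure Brownian evolution (Blomberg's K
#' with expectation ~1); w = 0 gives phylogenetically random traits.
#'
#' @param scenario a [leaf_scenario()] (uses n_species, birth, death,
#'   signal_weight).
#' @param seed integer seed; the same seed yields an identical Newick
#'   string.
#' @param n_tips optional override of the number of tips.
#' @return list with `tree` (ape "phylo", ultrametric), `trait` (named
#'   vector over tips) and `signal_weight`.
#' @export
make_phylogeny <- function(scenario, seed = scenario$seed, n_tips = NULL) {
  validate_scenario(scenario)
  n <- if (is.null(n_tips)) scenario$n_species else as.integer(n_tips)
  if (n < 3L) stop("need at least 3 taxa for a meaningful phylogeny")
  set.seed(seed)
  tree <- ape::rphylo(n, birth = scenario$birth, death = scenario$death)
  bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  bm_std <- (bm - mean(bm)) / sd(bm)
  eps <- rnorm(n)
  w <- scenario$signal_weight
  trait <- w * bm_std + (1 - w) * eps
  names(trait) <- tree$tip.label
  list(tree = tree, trait = trait, signal_weight = w)
}

#' Cut a dated tree into clades at a given age and read stem ages
#'
#' Clades ("genera" or "families" depending on the cut age) are the maximal
#' subtrees whose crown lies below `cut_age` Myr: every edge spanning
#' `cut_age` defines one clade containing the tips below it. The clade's
#' stem age is the age of the node at the older end of that edge (for an
#' edge hanging off the root, the root age). With `crown = TRUE`, the crown
#' age (age of the clade's own root node, or the tip itself for monotypic
#' clades) is reported instead.
#'
#' @param tree ultrametric ape "phylo" with branch lengths in Myr.
#' @param cut_age age (Myr before present) at which to delimit clades.
#' @param prefix label prefix for clade names.
#' @param crown report crown ages instead of stem ages.
#' @return list with `map` (data.frame species, clade) and `ages`
#'   (data.frame clade, age).
#' @export
clade_table <- function(tree, cut_age, prefix = "clade", crown = FALSE) {
  depth <- ape::node.depth.edgelength(tree)   # distance from root
  H <- max(depth)
  age <- H - depth                            # age before present
  ntip <- length(tree$tip.label)

  # tips below each node, by post-order accumulation over the edge list
  po <- ape::reorder.phylo(tree, "postorder")
  tips_below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }

  root <- ntip + 1L
  edges <- tree$edge
  cross <- which(age[edges[, 1]] > cut_age & age[edges[, 2]] <= cut_age)
  map <- data.frame(species = character(0), clade = character(0),
                    stringsAsFactors = FALSE)
  ages <- data.frame(clade = character(0), age = numeric(0),
                     stringsAsFactors = FALSE)
  for (k in seq_along(cross)) {
    e <- cross[k]
    nd <- edges[e, 2]
    tips <- tips_below[[nd]]
    cl <- sprintf("%s%03d", prefix, k)
    a <- if (crown) age[nd] else age[edges[e, 1]]
    map <- rbind(map, data.frame(species = tree$tip.label[tips], clade = cl,
                                 stringsAsFactors = FALSE))
    ages <- rbind(ages, data.frame(clade = cl, age = a,
                                   stringsAsFactors = FALSE))
  }
  # whole tree younger than the cut: a single clade at the root
  if (!length(cross)) {
    map <- data.frame(species = tree$tip.label, clade = paste0(prefix, "001"),
                      stringsAsFactors = FALSE)
    ages <- data.frame(clade = paste0(prefix, "001"), age = age[root],
                       stringsAsFactors = FALSE)
  }
  list(map = map, ages = ages)
}
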