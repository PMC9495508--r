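# Synthetic benchmark generator: random and structured species trees,
# gene trees made discordant by random NNI moves (a structural stand-in
# for incomplete lineage sorting), and gap-free alignments evolved under
# the Jukes-Cantor model. Everything is deterministic given the config
# seed, so all other modules are testable without external datasets.

#' Simulation configuration
#'
#' @param n_leaves number of species (>= 4).
#' @param tree_shape `"birth_death"` (random topology by uniform
#'   coalescent-style joining), `"balanced"` (perfectly height-balanced,
#'   unit edges) or `"caterpillar"`.
#' @param mean_branch_length mean of the i.i.d. exponential branch lengths
#'   (substitutions/site; default 0.1, a typical single-gene scale).
#'   Ignored for the unit-edge balanced shape.
#' @param seq_length alignment length L (default 500).
#' @param nni_moves number of random NNI moves separating the gene tree
#'   from the species tree (default 0 = concordant).
#' @param query_fraction fraction of leaves held out as queries by
#'   [make_benchmark()] (default 0.05).
#' @param seed RNG seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_leaves = 16L,
                              tree_shape = c("birth_death", "balanced", "caterpillar"),
                              mean_branch_length = 0.1, seq_length = 500L,
                              nni_moves = 0L, query_fraction = 0.05,
                              seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_leaves >= 4, mean_branch_length > 0, seq_length >= 1,
            nni_moves >= 0, query_fraction > 0, query_fraction < 1)
  structure(list(n_leaves = as.integer(n_leaves), tree_shape = tree_shape,
                 mean_branch_length = mean_branch_length,
                 seq_length = as.integer(seq_length),
                 nni_moves = as.integer(nni_moves),
                 query_fraction = query_fraction, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Random binary tree
#'
#' Builds a rooted binary topology by uniformly joining random pairs of
#' lineages (coalescent-style) and assigns i.i.d. exponential branch
#' lengths with the configured mean. Leaf labels are `t1 ... tn`.
#'
#' @param cfg a [simulation_config()] (fields `n_leaves`,
#'   `mean_branch_length`, `seed` are used).
#' @return an `ape::phylo`.
#' @export
random_binary_tree <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  .with_seed(.derive_seed(cfg$seed, 1L), {
    frags <- paste0("t", seq_len(cfg$n_leaves))
    while (length(frags) > 1) {
      pick <- sample.int(length(frags), 2L)
      lens <- stats::rexp(2, rate = 1 / cfg$mean_branch_length)
      joined <- sprintf("(%s:%.10g,%s:%.10g)",
                        frags[pick[1]], lens[1], frags[pick[2]], lens[2])
      frags <- c(frags[-pick], joined)
    }
    ape::read.tree(text = paste0(frags, ";"))
  })
}

#' Perfectly height-balanced binary tree with unit edges
#'
#' `2^depth` leaves, every branch of length 1; every leaf at distance
#' `depth` from the root and the closest leaf pairs at distance 2. The
#' canonical hard case for Euclidean tree embedding: its leaf count grows
#' exponentially in the diameter.
#'
#' @param depth tree height r (>= 1).
#' @return an `ape::phylo` with `2^depth` leaves labeled `t1 ...`.
#' @export
balanced_tree <- function(depth) {
  stopifnot(depth >= 1)
  build <- function(lo, hi, d) {
    if (d == 0) return(paste0("t", lo))
    mid <- (lo + hi + 1) %/% 2
    sprintf("(%s:1,%s:1)", build(lo, mid - 1, d - 1), build(mid, hi, d - 1))
  }
  ape::read.tree(text = paste0(build(1, 2^depth, depth), ";"))
}

#' Caterpillar (ladder) tree
#'
#' @param n_leaves number of leaves.
#' @param edge_length branch length for every edge (default 1).
#' @return an `ape::phylo`.
#' @export
caterpillar_tree <- function(n_leaves, edge_length = 1) {
  stopifnot(n_leaves >= 4)
  s <- sprintf("(t1:%g,t2:%g)", edge_length, edge_length)
  for (i in 3:n_leaves)
    s <- sprintf("(%s:%g,t%d:%g)", s, edge_length, i, edge_length)
  ape::read.tree(text = paste0(s, ";"))
}

#' Perturb a species tree into a discordant gene tree
#'
#' Applies `nni_moves` random nearest-neighbor interchanges on internal
#' edges of the unrooted tree (branch lengths are kept), so the normalized
#' RF distance to the
#' input is at most `2 * nni_moves / (2 (n - 3))`. A controllable,
#' structural stand-in for gene-tree discordance; it does not model the
#' population-genetic process that generates it.
#'
#' @param species_tree a binary `ape::phylo`.
#' @param nni_moves number of NNI moves (>= 0).
#' @param seed RNG seed.
#' @return the perturbed (unrooted) tree; with `nni_moves = 0` the input
#'   is returned unchanged.
#' @export
perturb_gene_tree <- function(species_tree, nni_moves, seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"), nni_moves >= 0)
  if (nni_moves == 0) return(species_tree)
  .with_seed(.derive_seed(seed, 2L),
             phangorn::rNNI(ape::unroot(species_tree), moves = nni_moves, n = 1))
}

#' Simulate a gap-free alignment under the Jukes-Cantor model
#'
#' The root sequence is uniform over A, C, G, T; along each branch of
#' length `t` (expected substitutions per site) a site is unchanged with
#' probability `1/4 + 3/4 exp(-4t/3)` and otherwise uniformly one of the
#' other three bases. Simulation is delegated to `phangorn::simSeq` under
#' the equal-rates model, which implements exactly this process.
#'
#' @param tree an `ape::phylo` with branch lengths in expected
#'   substitutions per site.
#' @param L alignment length.
#' @param seed RNG seed.
#' @return an [alignment()] with ids = the tree's leaf labels.
#' @export
simulate_jc_alignment <- function(tree, L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), L >= 1)
  m <- .with_seed(.derive_seed(seed, 3L),
                  as.character(phangorn::simSeq(tree, l = L, type = "DNA")))
  seqs <- toupper(apply(m, 1, paste, collapse = ""))
  alignment(seqs[tree$tip.label])
}

#' Jukes-Cantor distance from an observed mismatch fraction
#'
#' `-3/4 log(1 - 4/3 p)` for mismatch fraction `p < 3/4`; `Inf` beyond
#' saturation.
#'
#' @param p_mismatch observed fraction of mismatching sites.
#' @return the JC distance estimate (vectorized).
#' @export
jc_distance <- function(p_mismatch) {
  ifelse(p_mismatch >= 0.75, Inf, -0.75 * log(1 - 4 / 3 * p_mismatch))
}

#' Generate a complete synthetic benchmark
#'
#' The full fixture: a species tree (the backbone and the source of
#' ground-truth distances), a gene tree obtained from it by random NNI
#' moves, an alignment evolved on the gene tree under Jukes-Cantor, and a
#' random query split. If `out_dir` is given, writes
#' `species.nwk`, `gene.nwk`, `alignment.fasta`, `queries.txt` and a
#' `manifest.json` recording the configuration; re-running with the same
#' config reproduces the files byte-identically.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir optional output directory.
#' @return a list: `species_tree`, `gene_tree`, `alignment`, `backbone`
#'   (species tree with queries pruned), `queries`, `cfg`.
#' @export
make_benchmark <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  species <- switch(cfg$tree_shape,
    birth_death = random_binary_tree(cfg),
    balanced = balanced_tree(max(2L, as.integer(round(log2(cfg$n_leaves))))),
    caterpillar = caterpillar_tree(cfg$n_leaves, cfg$mean_branch_length))
  gene <- perturb_gene_tree(species, cfg$nni_moves, cfg$seed)
  aln <- simulate_jc_alignment(gene, cfg$seq_length, cfg$seed)
  split <- random_query_split(species, cfg$query_fraction,
                              .derive_seed(cfg$seed, 4L))
  out <- list(species_tree = species, gene_tree = gene, alignment = aln,
              backbone = split$backbone, queries = split$queries, cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_newick(species, file.path(out_dir, "species.nwk"))
    write_newick(gene, file.path(out_dir, "gene.nwk"))
    write_alignment(aln, file.path(out_dir, "alignment.fasta"))
    writeLines(split$queries, file.path(out_dir, "queries.txt"))
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
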