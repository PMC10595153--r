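# Fragment-pair enumeration: every acyclic single bond of a molecule is a
# breakable ("fragile") bond; deleting one yields the molecule's two connected
# components as a fragment pair. All breakable bonds are enumerated
# deterministically in bond-index order, and the model later averages over all
# resulting pairs.

#' Enumerate breakable bonds
#'
#' A bond is breakable when its order is single (not aromatic) and it is not
#' part of any ring. Bonds to terminal heavy atoms are breakable and yield
#' one-atom fragments.
#'
#' @param g A `mol_graph`.
#' @return A data frame with columns `bond` (index into `g$bonds`), `u`, `v`
#'   (1-based endpoint atom indices, `u < v`), in bond-index order.
#' @examples
#' \donttest{
#' nrow(breakable_bonds(smiles_to_graph("CC")))        # 1
#' nrow(breakable_bonds(smiles_to_graph("c1ccccc1")))  # 0
#' }
#' @export
breakable_bonds <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  keep <- g$bond_order == "single" & !g$bond_ring
  data.frame(bond = which(keep),
             u = g$bonds[keep, "u"],
             v = g$bonds[keep, "v"])
}

# induced subgraph on a sorted atom index set, inheriting features verbatim
induced_subgraph_mol <- function(g, atoms) {
  atoms <- sort(atoms)
  remap <- match(seq_len(g$n_atoms), atoms)
  keep_bond <- g$bonds[, "u"] %in% atoms & g$bonds[, "v"] %in% atoms
  bonds <- cbind(u = remap[g$bonds[keep_bond, "u"]],
                 v = remap[g$bonds[keep_bond, "v"]])
  structure(list(
    smiles = NA_character_, canonical = NA_character_,
    n_atoms = length(atoms),
    elements = g$elements[atoms],
    atom_features = g$atom_features[atoms, , drop = FALSE],
    bonds = bonds,
    bond_order = g$bond_order[keep_bond],
    bond_ring = g$bond_ring[keep_bond],
    bond_features = g$bond_features[keep_bond, , drop = FALSE],
    atom_info = g$atom_info[atoms, , drop = FALSE],
    bond_info = g$bond_info[keep_bond, , drop = FALSE]),
    class = "mol_graph")
}

#' Split a molecule at one breakable bond
#'
#' Deletes the bond and returns the two connected components as independent
#' graphs. Atom and bond features are copied verbatim from the parent; no cap
#' atoms are added and nothing is re-featurized, so the split is purely
#' graph-topological.
#'
#' @param g A connected `mol_graph`.
#' @param bond_index Index (into `g$bonds`) of a bond listed by
#'   [breakable_bonds()].
#' @return A `fragment_pair`: list with `frag1`, `frag2` (`mol_graph`s; `frag1`
#'   contains the smaller endpoint `u`), `bond_index`, `endpoints`, and the
#'   atom maps `map1`, `map2` (fragment atom index -> parent atom index).
#' @export
split_on_bond <- function(g, bond_index) {
  bb <- breakable_bonds(g)
  if (!bond_index %in% bb$bond)
    stop(sprintf("bond %d is not a breakable (acyclic single) bond",
                 bond_index), call. = FALSE)
  u <- unname(g$bonds[bond_index, "u"])
  v <- unname(g$bonds[bond_index, "v"])
  rest <- g$bonds[-bond_index, , drop = FALSE]
  ig <- igraph::graph_from_edgelist(rest, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, g$n_atoms - igraph::vcount(ig)))
  comp <- igraph::components(ig)$membership
  if (max(comp) != 2)
    stop("molecule is not connected; cannot form a fragment pair",
         call. = FALSE)
  atoms1 <- which(comp == comp[u])
  atoms2 <- which(comp == comp[v])
  structure(list(frag1 = induced_subgraph_mol(g, atoms1),
                 frag2 = induced_subgraph_mol(g, atoms2),
                 bond_index = bond_index,
                 endpoints = c(u = u, v = v),
                 map1 = sort(atoms1), map2 = sort(atoms2)),
            class = "fragment_pair")
}

#' Enumerate all fragment pairs of a molecule
#'
#' One pair per breakable bond, in bond-index order; the pair count `m` feeds
#' the model's average over pairs. Molecules with no breakable bond (single
#' atoms, pure ring systems) return an empty list and are handled downstream
#' by the whole-molecule path.
#'
#' @param g A `mol_graph`.
#' @return List of `fragment_pair` objects (possibly empty). Disconnected
#'   inputs (multi-component SMILES) return an empty list: a one-bond cut
#'   cannot partition them into two fragments, so they take the
#'   whole-molecule path like ring systems do.
#' @examples
#' \donttest{
#' length(fragment_pairs(smiles_to_graph("CCO")))       # 2
#' length(fragment_pairs(smiles_to_graph("c1ccccc1")))  # 0
#' }
#' @export
fragment_pairs <- function(g) {
  if (!is_connected_mol(g)) return(list())
  bb <- breakable_bonds(g)
  lapply(bb$bond, function(b) split_on_bond(g, b))
}

is_connected_mol <- function(g) {
  if (g$n_atoms <= 1) return(TRUE)
  ig <- igraph::make_empty_graph(g$n_atoms, directed = FALSE)
  if (nrow(g$bonds) > 0) ig <- igraph::add_edges(ig, t(g$bonds))
  igraph::components(ig)$no == 1
}

#' @export
print.fragment_pair <- function(x, ...) {
  cat(sprintf("<fragment_pair> broken bond %d (%d-%d): %d + %d atoms\n",
              x$bond_index, x$endpoints["u"], x$endpoints["v"],
              x$frag1$n_atoms, x$frag2$n_atoms))
  invisible(x)
}
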