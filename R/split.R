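# Dataset partitioning: seeded random splits and deterministic Bemis-Murcko
# scaffold splits.

#' Split specification
#'
#' @param mode `"random"` or `"scaffold"`.
#' @param ratios Train/validation/test fractions; positive, summing to 1.
#' @param seed Shuffle seed (random mode only; scaffold splits are
#'   deterministic).
#' @return A `split_spec` list.
#' @export
split_spec <- function(mode = c("random", "scaffold"),
                       ratios = c(0.8, 0.1, 0.1), seed = 1) {
  mode <- match.arg(mode)
  if (length(ratios) != 3 || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must be three positive fractions summing to 1",
         call. = FALSE)
  structure(list(mode = mode, ratios = ratios, seed = as.integer(seed)),
            class = "split_spec")
}

split_sizes <- function(n, ratios) {
  nv <- floor(ratios[2] * n)
  nt <- floor(ratios[3] * n)
  c(train = n - nv - nt, val = nv, test = nt)
}

#' Random train/validation/test split
#'
#' Validation and test sizes are the floors of their fractions; the remainder
#' goes to the training set. The shuffle is driven solely by `spec$seed`
#' (R's Mersenne-Twister `sample()`), so a given seed reproduces the same
#' partition on every platform.
#'
#' @param x Number of records, or a data frame / list whose length is used.
#' @param spec A [split_spec()] with `mode = "random"`.
#' @return List of integer index vectors `train`, `val`, `test`: disjoint,
#'   covering `1..n`.
#' @export
random_split <- function(x, spec = split_spec("random")) {
  stopifnot(inherits(spec, "split_spec"), spec$mode == "random")
  n <- if (is.numeric(x) && length(x) == 1) as.integer(x)
       else if (is.data.frame(x)) nrow(x) else length(x)
  if (n < 3) stop("need at least 3 records to split", call. = FALSE)
  sz <- split_sizes(n, spec$ratios)
  perm <- with_local_seed(spec$seed, sample.int(n))
  list(train = sort(perm[seq_len(sz["train"])]),
       val = sort(perm[sz["train"] + seq_len(sz["val"])]),
       test = sort(perm[sz["train"] + sz["val"] + seq_len(sz["test"])]))
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The ring-and-linker framework obtained by iteratively pruning terminal
#' (degree-1) atoms; acyclic molecules have an empty scaffold. The returned
#' key is the canonical SMILES of the framework, so two molecules share a key
#' exactly when they share a framework.
#'
#' @param g A `mol_graph`.
#' @return Character scaffold key (`""` for acyclic molecules).
#' @export
murcko_scaffold <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  atoms <- seq_len(g$n_atoms)
  bonds <- g$bonds
  repeat {
    deg <- tabulate(c(bonds[, "u"], bonds[, "v"]), nbins = g$n_atoms)
    drop <- intersect(atoms, which(deg == 1))
    if (length(drop) == 0 || length(atoms) == 0) break
    atoms <- setdiff(atoms, drop)
    keep <- bonds[, "u"] %in% atoms & bonds[, "v"] %in% atoms
    bonds <- bonds[keep, , drop = FALSE]
  }
  atoms <- setdiff(atoms, which(tabulate(c(bonds[, "u"], bonds[, "v"]),
                                         nbins = g$n_atoms) == 0))
  if (length(atoms) == 0) return("")
  sub <- induced_subgraph_mol(g, atoms)
  # stereo annotations play no role in framework identity
  sub$atom_info$chiral <- FALSE
  if (nrow(sub$bond_info) > 0) sub$bond_info$stereo <- "none"
  s <- write_smiles(sub)
  key <- canonical_smiles(s)
  if (is.na(key)) s else key
}

#' Scaffold train/validation/test split
#'
#' Molecules are grouped by Bemis-Murcko scaffold; whole groups are assigned,
#' largest first, to the partition currently furthest below its target count
#' (ties resolved train, then validation, then test). Acyclic molecules form
#' one shared empty-scaffold group that is assigned to the training set first.
#' The procedure is deterministic: no randomness is involved.
#'
#' @param x Character vector of SMILES, a data frame with a `smiles` column,
#'   or a list of `mol_graph` objects.
#' @param spec A [split_spec()] with `mode = "scaffold"`.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
scaffold_split <- function(x, spec = split_spec("scaffold")) {
  stopifnot(inherits(spec, "split_spec"), spec$mode == "scaffold")
  graphs <- if (is.character(x)) parse_smiles(x)
            else if (is.data.frame(x)) parse_smiles(x$smiles)
            else x
  n <- length(graphs)
  if (n < 3) stop("need at least 3 records to split", call. = FALSE)
  keys <- vapply(graphs, murcko_scaffold, "")
  groups <- split(seq_len(n), keys)
  target <- split_sizes(n, spec$ratios)
  sizes <- c(train = 0L, val = 0L, test = 0L)
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  if ("" %in% names(groups)) {
    out$train <- groups[["" ]]
    sizes["train"] <- length(groups[[""]])
    groups[[""]] <- NULL
  }
  if (length(groups) > 0) {
    first_seen <- vapply(groups, min, 0L)
    ord <- order(-lengths(groups), first_seen)
    for (gi in ord) {
      deficit <- target - sizes
      dest <- names(deficit)[which.max(deficit)]  # ties: train, val, test
      out[[dest]] <- c(out[[dest]], groups[[gi]])
      sizes[dest] <- sizes[dest] + length(groups[[gi]])
    }
  }
  list(train = sort(out$train), val = sort(out$val), test = sort(out$test))
}
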