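# Graph -> SMILES writer.
#
# Used for two things: generating alternative SMILES writings of a molecule
# (invariance testing) and serializing scaffold subgraphs for canonical
# scaffold keys. It covers the structures this package produces -- standard
# valences, optional aromatic rings, charges -- and refuses molecules whose
# stereo annotations it would lose.

smiles_atom_token <- function(g, i) {
  info <- g$atom_info[i, ]
  sym <- info$element
  arom_ok <- tolower(sym) %in% c("b", "c", "n", "o", "p", "s")
  needs_bracket <- info$charge != 0 || info$radicals > 0 ||
    !(sym %in% ORGANIC_SUBSET) || (info$aromatic && !arom_ok) ||
    (info$aromatic && sym == "N" && info$n_h > 0)
  shown <- if (info$aromatic && arom_ok) tolower(sym) else sym
  if (!needs_bracket) return(shown)
  h <- if (info$n_h == 0) "" else if (info$n_h == 1) "H"
       else paste0("H", info$n_h)
  q <- if (info$charge == 0) ""
       else if (info$charge == 1) "+"
       else if (info$charge == -1) "-"
       else if (info$charge > 1) paste0("+", info$charge)
       else paste0("-", abs(info$charge))
  paste0("[", shown, h, q, "]")
}

smiles_bond_token <- function(g, b) {
  switch(g$bond_order[b],
         single = {
           uu <- g$bonds[b, "u"]; vv <- g$bonds[b, "v"]
           if (g$atom_info$aromatic[uu] && g$atom_info$aromatic[vv]) "-" else ""
         },
         double = "=",
         triple = "#",
         aromatic = "")
}

#' Write a molecular graph as SMILES
#'
#' Depth-first traversal with ring closures. With `seed = NULL` the traversal
#' is deterministic (start at atom 1, neighbours in index order); with a seed,
#' the start atom and neighbour order are shuffled, producing an alternative
#' valid writing of the same molecule. Molecules carrying tetrahedral or
#' double-bond stereo annotations are refused (the writer does not emit them).
#'
#' @param g A `mol_graph`.
#' @param seed Optional integer for a randomized writing.
#' @return A SMILES string.
#' @export
write_smiles <- function(g, seed = NULL) {
  stopifnot(inherits(g, "mol_graph"))
  if (any(g$atom_info$chiral) ||
      (nrow(g$bond_info) > 0 && any(g$bond_info$stereo != "none")))
    stop("write_smiles does not emit stereo annotations", call. = FALSE)
  n <- g$n_atoms
  nb <- nrow(g$bonds)
  adj <- vector("list", n)
  for (b in seq_len(nb)) {
    u <- g$bonds[b, "u"]; v <- g$bonds[b, "v"]
    adj[[u]] <- rbind(adj[[u]], c(v, b))
    adj[[v]] <- rbind(adj[[v]], c(u, b))
  }
  emit <- function() {
    order_of <- function(k) {
      if (is.null(seed)) seq_len(k) else sample.int(k)
    }
    starts <- if (is.null(seed)) seq_len(n) else sample.int(n)
    visited <- logical(n)
    used <- logical(nb)
    children <- vector("list", n)
    ring_tok <- vector("list", n)   # ring-closure tokens per atom, in order
    digit <- 0L
    dfs1 <- function(u) {
      visited[u] <<- TRUE
      nbrs <- adj[[u]]
      if (!is.null(nbrs)) {
        for (r in order_of(nrow(nbrs))) {
          w <- nbrs[r, 1]; b <- nbrs[r, 2]
          if (used[b]) next
          used[b] <<- TRUE
          if (!visited[w]) {
            children[[u]] <<- rbind(children[[u]], c(w, b))
            dfs1(w)
          } else {
            digit <<- digit + 1L
            d <- if (digit <= 9) as.character(digit)
                 else paste0("%", digit)
            tok <- paste0(smiles_bond_token(g, b), d)
            ring_tok[[w]] <<- c(ring_tok[[w]], tok)
            ring_tok[[u]] <<- c(ring_tok[[u]], tok)
          }
        }
      }
    }
    write1 <- function(u) {
      out <- paste0(smiles_atom_token(g, u),
                    paste(ring_tok[[u]], collapse = ""))
      ch <- children[[u]]
      if (!is.null(ch)) {
        k <- nrow(ch)
        for (r in seq_len(k)) {
          sub <- paste0(smiles_bond_token(g, ch[r, 2]), write1(ch[r, 1]))
          out <- if (r < k) paste0(out, "(", sub, ")")
                 else paste0(out, sub)
        }
      }
      out
    }
    parts <- character(0)
    for (s in starts) {
      if (!visited[s]) {
        dfs1(s)
        parts <- c(parts, write1(s))
      }
    }
    paste(parts, collapse = ".")
  }
  if (is.null(seed)) emit() else with_local_seed(seed, emit())
}

#' Rewrite a SMILES string as an equivalent alternative writing
#'
#' Produces a different-looking SMILES for the same molecule (random traversal
#' order) and verifies, via canonical SMILES, that the rewriting preserves the
#' structure. Useful for testing that predictions are invariant to how a
#' molecule happens to be written.
#'
#' @param x A SMILES string or a `mol_graph`.
#' @param seed Integer controlling the traversal shuffle.
#' @return A SMILES string equivalent to the input.
#' @examples
#' \donttest{
#' rewrite_smiles("CCO", seed = 7)  # e.g. "OCC" or "C(O)C"
#' }
#' @export
rewrite_smiles <- function(x, seed = 1) {
  g <- if (inherits(x, "mol_graph")) x else smiles_to_graph(x)
  s <- write_smiles(g, seed = seed)
  chk <- canonical_smiles(s)
  if (is.na(chk) || is.na(g$canonical) || chk != g$canonical)
    stop(sprintf("internal error: rewriting '%s' produced non-equivalent '%s'",
                 g$smiles, s), call. = FALSE)
  s
}
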