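# SMILES -> molecular graph construction.
#
# OpenBabel (via ChemmineOB::convertFormat) supplies the chemistry: validity,
# canonical SMILES, kekulized bond orders, aromaticity perception (MOL2/SYBYL
# atom typing), implicit hydrogen counts, formal charges and generated 2D
# coordinates (used to resolve double-bond geometry). A small tokenizer scans
# the input string for what the converted formats do not preserve: strict
# structural validity (OpenBabel silently repairs some malformed inputs) and
# input-order atom annotations (tetrahedral @/@@ tags, directional / \ bonds).

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

# --- tokenizer ---------------------------------------------------------------

# Scans a SMILES string into heavy atoms (in order of appearance) and written
# bonds. Stops with a validity error on malformed input. Hydrogens written as
# standalone [H] atoms are kept and rejected later by the element vocabulary.
tokenize_smiles <- function(s) {
  fail <- function(msg) stop(sprintf("invalid SMILES '%s': %s", s, msg),
                             call. = FALSE)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_       # atom awaiting a bond to the next atom
  pending <- ""             # bond symbol read since the previous atom
  stack <- integer(0)       # branch stack
  ring <- list()            # open ring-closure digits -> list(atom, sym)
  i <- 1L
  add_atom <- function(symbol, aromatic, chiral_tag) {
    atoms[[length(atoms) + 1L]] <<- list(symbol = symbol, aromatic = aromatic,
                                         chiral = chiral_tag)
    idx <- length(atoms)
    if (!is.na(prev)) {
      sym <- pending
      if (sym == "") sym <- if (aromatic && atoms[[prev]]$aromatic) ":" else "-"
      bonds[[length(bonds) + 1L]] <<- list(u = prev, v = idx, sym = sym)
    }
    prev <<- idx
    pending <<- ""
    idx
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unterminated bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0) fail(sprintf("cannot read bracket atom [%s]", body))
      sym <- m[3]
      if (sym == "*") fail("wildcard atoms are not supported")
      aromatic <- sym == tolower(sym) && sym %in% c("b", "c", "n", "o", "p",
                                                    "s", "as", "se", "te")
      symbol <- if (aromatic) paste0(toupper(substr(sym, 1, 1)),
                                     substring(sym, 2)) else sym
      chiral_tag <- if (m[4] == "@") "anticlockwise"
                    else if (m[4] == "@@") "clockwise" else NA_character_
      add_atom(symbol, aromatic, chiral_tag)
      i <- j + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, NA_character_)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, NA_character_)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE, NA_character_)
        i <- i + 1L
      } else {
        fail(sprintf("unexpected symbol '%s' (bracket required?)", ch))
      }
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~", "$")) {
      if (ch %in% c("~", "$")) fail(sprintf("unsupported bond symbol '%s'", ch))
      if (pending != "") fail("two consecutive bond symbols")
      pending <- ch
      i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (is.na(prev)) fail("ring-closure digit before any atom")
      if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9][0-9]$",
                                 paste0(chars[i + 1L], chars[i + 2L])))
          fail("malformed %nn ring closure")
        key <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        key <- ch
        i <- i + 1L
      }
      if (is.null(ring[[key]])) {
        ring[[key]] <- list(atom = prev, sym = pending)
      } else {
        op <- ring[[key]]
        sym <- if (pending != "") pending else op$sym
        if (op$sym != "" && pending != "" && op$sym != pending &&
            !all(c(op$sym, pending) %in% c("/", "\\")))
          fail(sprintf("conflicting ring-closure bond symbols for ring %s", key))
        if (op$atom == prev) fail("ring closure bonds an atom to itself")
        if (sym == "") sym <- if (atoms[[prev]]$aromatic &&
                                  atoms[[op$atom]]$aromatic) ":" else "-"
        bonds[[length(bonds) + 1L]] <- list(u = op$atom, v = prev, sym = sym)
        ring[[key]] <- NULL
      }
      pending <- ""
    } else if (ch == "(") {
      if (is.na(prev)) fail("branch opened before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) fail("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- ""
      i <- i + 1L
    } else if (ch %in% c(" ", "\t")) {
      break  # trailing title field
    } else {
      fail(sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(stack) > 0) fail("unclosed branch '('")
  if (length(ring) > 0)
    fail(sprintf("unmatched ring-closure digit(s): %s",
                 paste(names(ring), collapse = ", ")))
  if (pending != "") fail("dangling bond symbol at end of input")
  if (length(atoms) == 0) fail("no atoms")
  list(
    atoms = data.frame(
      symbol = vapply(atoms, `[[`, "", "symbol"),
      aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
      chiral = vapply(atoms, `[[`, "", "chiral"),
      stringsAsFactors = FALSE),
    bonds = if (length(bonds) == 0)
      data.frame(u = integer(0), v = integer(0), sym = character(0))
    else data.frame(
      u = vapply(bonds, `[[`, 0L, "u"),
      v = vapply(bonds, `[[`, 0L, "v"),
      sym = vapply(bonds, `[[`, "", "sym"),
      stringsAsFactors = FALSE)
  )
}

# --- OpenBabel plumbing ------------------------------------------------------

ob_convert <- function(to, smiles, ids, options = NULL) {
  src <- paste0(paste0(smiles, "\t", ids, collapse = "\n"), "\n")
  if (is.null(options))
    suppressWarnings(ChemmineOB::convertFormat("SMI", to, src))
  else
    suppressWarnings(ChemmineOB::convertFormat("SMI", to, src,
                                               options = options))
}

# Minimal reader for the V2000 blocks OpenBabel emits (ChemmineR's SDF
# container does not expose M CHG / parity / wedge fields, which are needed).
read_v2000_blocks <- function(text) {
  blocks <- strsplit(text, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  out <- list()
  for (b in blocks) {
    lines <- strsplit(b, "\n")[[1]]
    if (lines[1] == "") lines <- lines[-1]
    title <- trimws(lines[1])
    counts <- lines[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    atoms <- lines[5:(4 + na)]
    af <- strsplit(trimws(atoms), "[[:space:]]+")
    coords <- t(vapply(af, function(x) as.numeric(x[1:2]), numeric(2)))
    elem <- vapply(af, `[[`, "", 4)
    bonds <- if (nb > 0) {
      bl <- lines[(5 + na):(4 + na + nb)]
      t(vapply(bl, function(l) {
        as.integer(c(substr(l, 1, 3), substr(l, 4, 6), substr(l, 7, 9)))
      }, integer(3), USE.NAMES = FALSE))
    } else matrix(integer(0), 0, 3)
    charges <- integer(na)
    rest <- lines[-seq_len(4 + na + nb)]
    for (l in grep("^M  CHG", rest, value = TRUE)) {
      f <- as.integer(strsplit(trimws(substring(l, 7)), "[[:space:]]+")[[1]])
      k <- f[1]
      for (p in seq_len(k)) charges[f[2 * p]] <- f[2 * p + 1]
    }
    out[[title]] <- list(elements = elem, coords = coords, bonds = bonds,
                         charges = charges)
  }
  out
}

read_mol2_blocks <- function(text) {
  blocks <- strsplit(text, "@<TRIPOS>MOLECULE")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  out <- list()
  for (b in blocks) {
    lines <- strsplit(b, "\n")[[1]]
    lines <- lines[nzchar(lines) | seq_along(lines) <= 2]
    title <- trimws(lines[2])
    ai <- grep("^@<TRIPOS>ATOM", lines)
    bi <- grep("^@<TRIPOS>BOND", lines)
    if (length(ai) == 0) next
    at <- lines[(ai + 1L):length(lines)]
    stop_at <- grep("^@<TRIPOS>", at)
    if (length(stop_at)) at <- at[seq_len(stop_at[1] - 1L)]
    at <- at[nzchar(trimws(at))]
    af <- strsplit(trimws(at), "[[:space:]]+")
    types <- vapply(af, `[[`, "", 6)
    btypes <- character(0)
    bidx <- matrix(integer(0), 0, 2)
    if (length(bi) && bi < length(lines)) {
      rest <- lines[(bi + 1L):length(lines)]
      stop_at <- grep("^@<TRIPOS>", rest)
      if (length(stop_at)) rest <- rest[seq_len(stop_at[1] - 1L)]
      rest <- rest[nzchar(trimws(rest))]
      if (length(rest)) {
        bf <- strsplit(trimws(rest), "[[:space:]]+")
        bidx <- t(vapply(bf, function(x) as.integer(x[2:3]), integer(2)))
        btypes <- vapply(bf, `[[`, "", 4)
      }
    }
    out[[title]] <- list(types = types, bond_idx = bidx, bond_types = btypes)
  }
  out
}

# SYBYL atom type -> hybridization slot
sybyl_hybridization <- function(type) {
  suffix <- sub("^[A-Za-z]+\\.?", "", type)
  switch(suffix,
         "1" = "sp",
         "2" = , "ar" = , "am" = , "co2" = , "pl3" = "sp2",
         "3" = , "4" = , "O" = , "o" = , "O2" = , "o2" = "sp3",
         "other")
}

DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
                     Cl = 1, As = 3, Se = 2, Br = 1, Te = 2, I = 1, At = 1)

# Radical electrons as the valence deficit against the charge-adjusted default
# valence; only computed for C/N/O where the octet rule makes it meaningful.
radical_electrons <- function(element, charge, bonded_valence) {
  if (!element %in% c("C", "N", "O")) return(0L)
  allowed <- switch(element,
                    C = 4 - abs(charge),
                    N = 3 + charge,
                    O = 2 + charge)
  max(0L, as.integer(allowed - bonded_valence))
}

# --- graph assembly ----------------------------------------------------------

#' Convert SMILES strings into molecular graphs
#'
#' Parses SMILES with OpenBabel, checks validity and the 15-element vocabulary,
#' and builds heavy-atom graphs with per-atom (length-40) and per-bond
#' (length-10) feature vectors. Hydrogens are implicit: they enter only through
#' the attached-hydrogen count block.
#'
#' @param smiles Character vector of SMILES strings.
#' @param cfg A [feature_config()].
#' @param strict If `TRUE` (default) any unparseable or out-of-vocabulary
#'   input raises an error naming it; if `FALSE` such entries yield `NULL`
#'   elements with a warning.
#' @return A list of `mol_graph` objects (see [smiles_to_graph()] for the
#'   fields), one per input, named by the inputs.
#' @export
parse_smiles <- function(smiles, cfg = feature_config(), strict = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  out <- vector("list", length(smiles))
  names(out) <- smiles
  report <- function(msg) {
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  toks <- vector("list", length(smiles))
  ok <- logical(length(smiles))
  for (k in seq_along(smiles)) {
    t <- tryCatch(tokenize_smiles(smiles[k]), error = function(e) e)
    if (inherits(t, "error")) report(conditionMessage(t))
    else {
      bad <- setdiff(unique(t$atoms$symbol), cfg$elements)
      if (length(bad) > 0)
        report(sprintf(
          "unsupported element%s %s in SMILES '%s' (allowed: %s)",
          if (length(bad) > 1) "s" else "", paste(bad, collapse = ", "),
          smiles[k], paste(cfg$elements, collapse = " ")))
      else {
        toks[[k]] <- t
        ok[k] <- TRUE
      }
    }
  }
  if (!any(ok)) return(out)
  idx <- which(ok)
  ids <- paste0("m", idx)
  smi <- smiles[idx]
  can_lines <- strsplit(ob_convert("CAN", smi, ids), "\n")[[1]]
  can_lines <- can_lines[nzchar(trimws(can_lines))]
  can_smiles <- sub("[\t ].*$", "", can_lines)
  names(can_smiles) <- sub("^.*[\t ]", "", can_lines)
  sdf <- read_v2000_blocks(ob_convert("SDF", smi, ids,
    options = data.frame(names = "gen2D", args = "", stringsAsFactors = FALSE)))
  sdfh <- read_v2000_blocks(ob_convert("SDF", smi, ids,
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)))
  mol2 <- read_mol2_blocks(ob_convert("MOL2", smi, ids))
  for (j in seq_along(idx)) {
    k <- idx[j]
    id <- ids[j]
    if (is.null(sdf[[id]]) || is.null(mol2[[id]]) || is.null(sdfh[[id]]) ||
        !(id %in% names(can_smiles)) || !nzchar(can_smiles[[id]])) {
      report(sprintf("invalid SMILES '%s': rejected by OpenBabel", smiles[k]))
      next
    }
    g <- tryCatch(
      assemble_graph(smiles[k], toks[[k]], sdf[[id]], sdfh[[id]], mol2[[id]],
                     can_smiles[[id]], cfg),
      error = function(e) e)
    if (inherits(g, "error")) report(conditionMessage(g)) else out[[k]] <- g
  }
  out
}

#' Convert one SMILES string into a molecular graph
#'
#' @param smiles A single SMILES string.
#' @param cfg A [feature_config()].
#' @return A `mol_graph` object: a list with `smiles`, `canonical` (OpenBabel
#'   canonical SMILES), `n_atoms`, `elements`, `atom_features` (`n_atoms` x 40
#'   matrix), `bonds` (two-column matrix of 1-based atom indices, `u < v`),
#'   `bond_order` (`single`/`double`/`triple`/`aromatic`), `bond_ring`
#'   (logical), `bond_features` (`n_bonds` x 10 matrix), and the per-atom /
#'   per-bond annotation frames `atom_info` and `bond_info`.
#' @examples
#' \donttest{
#' g <- smiles_to_graph("CCO")
#' g$n_atoms          # 3
#' nrow(g$bonds)      # 2
#' }
#' @export
smiles_to_graph <- function(smiles, cfg = feature_config()) {
  stopifnot(length(smiles) == 1)
  parse_smiles(smiles, cfg, strict = TRUE)[[1]]
}

assemble_graph <- function(smiles, tok, sdf, sdfh, mol2, canonical, cfg) {
  n <- length(sdf$elements)
  if (n != nrow(tok$atoms) ||
      !all(sdf$elements == tok$atoms$symbol))
    stop(sprintf("invalid SMILES '%s': atom order mismatch between readers",
                 smiles), call. = FALSE)
  bad <- setdiff(unique(sdf$elements), cfg$elements)
  if (length(bad) > 0)
    stop(sprintf("unsupported element%s %s in SMILES '%s'",
                 if (length(bad) > 1) "s" else "",
                 paste(bad, collapse = ", "), smiles), call. = FALSE)
  bonds <- sdf$bonds
  nb <- nrow(bonds)
  u <- pmin(bonds[, 1], bonds[, 2])
  v <- pmax(bonds[, 1], bonds[, 2])
  if (nb > 0 && anyDuplicated(paste(u, v)))
    stop(sprintf("invalid SMILES '%s': duplicate bond", smiles), call. = FALSE)
  kek_order <- bonds[, 3]

  # ring membership: a bond is in a ring iff it is not a bridge
  ring <- logical(nb)
  if (nb > 0) {
    ig <- igraph::graph_from_edgelist(cbind(u, v), directed = FALSE)
    br <- igraph::bridges(ig)
    ring <- !(seq_len(nb) %in% as.integer(br))
  }

  # aromaticity from SYBYL typing: 'ar' bonds that sit in a ring
  aromatic_bond <- logical(nb)
  if (nb > 0 && length(mol2$bond_types) > 0) {
    m_u <- pmin(mol2$bond_idx[, 1], mol2$bond_idx[, 2])
    m_v <- pmax(mol2$bond_idx[, 1], mol2$bond_idx[, 2])
    key <- paste(u, v)
    mkey <- paste(m_u, m_v)
    ar <- mol2$bond_types[match(key, mkey)] == "ar"
    ar[is.na(ar)] <- FALSE
    aromatic_bond <- ar & ring
  }
  aromatic_atom <- logical(n)
  if (nb > 0) {
    aromatic_atom[unique(c(u[aromatic_bond], v[aromatic_bond]))] <- TRUE
  }

  degree <- tabulate(c(u, v), nbins = n)

  # hydrogens: count H neighbours in the hydrogen-added conversion
  hn <- sdfh
  if (length(hn$elements) < n ||
      !all(hn$elements[seq_len(n)] == sdf$elements))
    stop(sprintf("invalid SMILES '%s': hydrogen-added atom order mismatch",
                 smiles), call. = FALSE)
  n_h <- integer(n)
  bonded_val <- numeric(n)  # kekulized valence incl. H, for radical detection
  if (nrow(hn$bonds) > 0) {
    for (r in seq_len(nrow(hn$bonds))) {
      a <- hn$bonds[r, 1]; b <- hn$bonds[r, 2]; o <- hn$bonds[r, 3]
      if (a <= n) bonded_val[a] <- bonded_val[a] + o
      if (b <= n) bonded_val[b] <- bonded_val[b] + o
      if (a <= n && b > n) n_h[a] <- n_h[a] + 1L
      if (b <= n && a > n) n_h[b] <- n_h[b] + 1L
    }
  }

  hyb <- vapply(mol2$types, sybyl_hybridization, "", USE.NAMES = FALSE)
  if (length(hyb) != n)
    stop(sprintf("invalid SMILES '%s': SYBYL typing mismatch", smiles),
         call. = FALSE)

  charges <- sdf$charges
  radicals <- vapply(seq_len(n), function(i)
    radical_electrons(sdf$elements[i], charges[i], bonded_val[i]), 0L)

  chiral_tag <- tok$atoms$chiral
  chiral <- !is.na(chiral_tag) & chiral_tag != ""

  order_chr <- ifelse(aromatic_bond, "aromatic",
                      c("single", "double", "triple")[pmin(kek_order, 3L)])

  # conjugation: aromatic bonds, or bonds whose both ends carry pi density
  # beyond the bond itself (an external multiple/aromatic bond, or a neutral
  # N/O/S lone pair)
  conj <- logical(nb)
  if (nb > 0) {
    multi <- order_chr %in% c("double", "triple", "aromatic")
    has_multi <- logical(n)
    for (r in seq_len(nb)) if (multi[r]) {
      has_multi[u[r]] <- TRUE; has_multi[v[r]] <- TRUE
    }
    ext_pi <- function(x, r) {
      if (sdf$elements[x] %in% c("N", "O", "S") && charges[x] <= 0) return(TRUE)
      any(multi & seq_len(nb) != r & (u == x | v == x))
    }
    for (r in seq_len(nb)) {
      conj[r] <- aromatic_bond[r] || (ext_pi(u[r], r) && ext_pi(v[r], r))
    }
  }

  stereo <- assign_bond_stereo(tok, sdf, u, v, order_chr, ring, n, nb)

  atom_info <- data.frame(
    element = sdf$elements, degree = degree, charge = charges,
    radicals = radicals, hybridization = hyb, aromatic = aromatic_atom,
    n_h = n_h, chiral = chiral,
    chirality = ifelse(chiral, chiral_tag, NA_character_),
    stringsAsFactors = FALSE)
  bond_info <- data.frame(
    order = order_chr, conjugated = conj, ring = ring, stereo = stereo,
    stringsAsFactors = FALSE)

  X <- matrix(0, n, cfg$atom_width,
              dimnames = list(NULL, atom_feature_names(cfg)))
  for (i in seq_len(n)) X[i, ] <- featurize_atom(as.list(atom_info[i, ]), cfg)
  Xe <- matrix(0, nb, cfg$bond_width,
               dimnames = list(NULL, bond_feature_names(cfg)))
  for (r in seq_len(nb)) Xe[r, ] <- featurize_bond(as.list(bond_info[r, ]), cfg)

  structure(list(
    smiles = smiles, canonical = canonical, n_atoms = n,
    elements = sdf$elements, atom_features = X,
    bonds = cbind(u = u, v = v), bond_order = order_chr, bond_ring = ring,
    bond_features = Xe, atom_info = atom_info, bond_info = bond_info),
    class = "mol_graph")
}

# Double-bond geometry from generated 2D coordinates, only for double bonds
# whose both ends carry a written directional (/ or \) single bond. Substituent
# on the same side of the double-bond axis -> Z, opposite -> E.
assign_bond_stereo <- function(tok, sdf, u, v, order_chr, ring, n, nb) {
  stereo <- rep("none", nb)
  if (nb == 0) return(stereo)
  tb <- tok$bonds
  has_dir <- logical(n)
  if (nrow(tb) > 0) {
    d <- tb$sym %in% c("/", "\\")
    has_dir[unique(c(tb$u[d], tb$v[d]))] <- TRUE
  }
  if (!any(has_dir)) return(stereo)
  coords <- sdf$coords
  for (r in seq_len(nb)) {
    if (order_chr[r] != "double" || ring[r]) next
    a <- u[r]; b <- v[r]
    if (!(has_dir[a] && has_dir[b])) next
    na_ <- setdiff(c(u[u == a | v == a], v[u == a | v == a]), c(a, b))
    nb_ <- setdiff(c(u[u == b | v == b], v[u == b | v == b]), c(a, b))
    if (length(na_) == 0 || length(nb_) == 0) next
    ax <- coords[b, ] - coords[a, ]
    side <- function(p, origin) {
      d <- p - origin
      sign(ax[1] * d[2] - ax[2] * d[1])
    }
    s1 <- side(coords[na_[1], ], coords[a, ])
    s2 <- side(coords[nb_[1], ], coords[b, ])
    if (s1 == 0 || s2 == 0) next
    stereo[r] <- if (s1 == s2) "Z" else "E"
  }
  stereo
}

#' Canonical SMILES
#'
#' OpenBabel canonical SMILES, used for duplicate detection during cleaning:
#' two SMILES writings of the same structure map to the same canonical string.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES; `NA` for inputs OpenBabel
#'   rejects.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  ids <- paste0("m", seq_along(smiles))
  can <- ob_convert("CAN", smiles, ids)
  lines <- strsplit(can, "\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  got_id <- sub("^.*[\t ]", "", lines)
  got_smi <- sub("[\t ].*$", "", lines)
  out <- got_smi[match(ids, got_id)]
  out[out == ""] <- NA_character_
  out
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s\n", x$smiles))
  cat(sprintf("  atoms: %d  bonds: %d  (aromatic bonds: %d, ring bonds: %d)\n",
              x$n_atoms, nrow(x$bonds), sum(x$bond_order == "aromatic"),
              sum(x$bond_ring)))
  invisible(x)
}

#' Write molecular graphs as JSON lines
#'
#' One molecule per line: atoms, bonds and their feature vectors; a debugging
#' dump of the in-memory representation.
#'
#' @param graphs List of `mol_graph` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
graphs_to_jsonl <- function(graphs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in graphs) {
    rec <- list(smiles = g$smiles, canonical = g$canonical,
                n_atoms = g$n_atoms, elements = g$elements,
                bonds = unname(g$bonds), bond_order = g$bond_order,
                atom_features = unname(g$atom_features),
                bond_features = unname(g$bond_features))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
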