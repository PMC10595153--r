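# Atom/bond one-hot featurization.
#
# Atom vector (40 = 15 + 8 + 1 + 1 + 6 + 1 + 5 + 1 + 2):
#   element one-hot | heavy degree one-hot | formal charge | radical electrons |
#   hybridization one-hot | aromatic flag | attached-H one-hot | chiral flag |
#   tetrahedral parity one-hot (all-zero for achiral atoms)
# Bond vector (10 = 4 + 1 + 1 + 4):
#   bond type one-hot | conjugation flag | ring flag | stereo one-hot

#' Featurization configuration
#'
#' Returns the vocabularies and block layout used to turn atoms and bonds into
#' fixed-width numeric feature vectors. The element vocabulary is the 15-symbol
#' set `B, C, N, O, F, Si, P, S, Cl, As, Se, Br, Te, I, At`; molecules containing
#' any other element are rejected. Eight one-hot slots are allocated for heavy-atom
#' degrees 0--7 and five for attached-hydrogen counts 0--4. The chirality-type
#' block has two slots for the two tetrahedral parity classes (`@` and `@@`) and
#' is all-zero for achiral atoms; there is no "none" slot.
#'
#' @return A list with components `elements`, `degree_slots`,
#'   `hybridizations`, `hydrogen_slots`, `chirality_types`, `bond_types`,
#'   `stereo_types`, the derived widths `atom_width` (40) and `bond_width` (10),
#'   and `descriptor`, a canonical string identifying the layout (stored in
#'   checkpoints and compared on load).
#' @examples
#' cfg <- feature_config()
#' cfg$atom_width  # 40
#' cfg$bond_width  # 10
#' @export
feature_config <- function() {
  cfg <- list(
    elements = c("B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "As",
                 "Se", "Br", "Te", "I", "At"),
    degree_slots = 8L,
    hybridizations = c("sp", "sp2", "sp3", "sp3d", "sp3d2", "other"),
    hydrogen_slots = 5L,
    chirality_types = c("anticlockwise", "clockwise"),
    bond_types = c("single", "double", "triple", "aromatic"),
    stereo_types = c("Z", "none", "E", "any")
  )
  cfg$atom_width <- length(cfg$elements) + cfg$degree_slots + 1L + 1L +
    length(cfg$hybridizations) + 1L + cfg$hydrogen_slots + 1L +
    length(cfg$chirality_types)
  cfg$bond_width <- length(cfg$bond_types) + 1L + 1L + length(cfg$stereo_types)
  cfg$descriptor <- paste(
    "v1",
    paste(cfg$elements, collapse = ","),
    cfg$degree_slots,
    paste(cfg$hybridizations, collapse = ","),
    cfg$hydrogen_slots,
    paste(cfg$chirality_types, collapse = ","),
    paste(cfg$bond_types, collapse = ","),
    paste(cfg$stereo_types, collapse = ","),
    sep = "|"
  )
  class(cfg) <- "feature_config"
  cfg
}

onehot <- function(value, vocab, what, hot_ok = TRUE) {
  v <- numeric(length(vocab))
  i <- match(value, vocab)
  if (is.na(i)) {
    if (hot_ok) stop(sprintf("value '%s' not in %s vocabulary", value, what),
                     call. = FALSE)
    return(v)
  }
  v[i] <- 1
  v
}

#' Encode one atom as a length-40 feature vector
#'
#' @param atom A list describing the atom in its molecular context:
#'   `element` (symbol), `degree` (heavy-atom degree, 0--7), `charge` (formal
#'   charge, signed integer), `radicals` (radical electron count), `hybridization`
#'   (one of `sp, sp2, sp3, sp3d, sp3d2, other`), `aromatic` (logical), `n_h`
#'   (attached hydrogens, 0--4), `chiral` (logical), `chirality`
#'   (`"anticlockwise"`, `"clockwise"`, or `NA` when achiral).
#' @param cfg A [feature_config()].
#' @return Numeric vector of length `cfg$atom_width`.
#' @examples
#' # the carbon of methane: degree 0, four hydrogens
#' v <- featurize_atom(list(element = "C", degree = 0, charge = 0, radicals = 0,
#'                          hybridization = "sp3", aromatic = FALSE, n_h = 4,
#'                          chiral = FALSE, chirality = NA))
#' which(v[1:15] == 1)  # element slot 2 (C)
#' @export
featurize_atom <- function(atom, cfg = feature_config()) {
  if (!atom$element %in% cfg$elements)
    stop(sprintf("unsupported element '%s' (allowed: %s)", atom$element,
                 paste(cfg$elements, collapse = " ")), call. = FALSE)
  if (atom$degree < 0 || atom$degree >= cfg$degree_slots)
    stop(sprintf("heavy-atom degree %d exceeds the %d encoding slots",
                 atom$degree, cfg$degree_slots), call. = FALSE)
  if (atom$n_h < 0 || atom$n_h >= cfg$hydrogen_slots)
    stop(sprintf("hydrogen count %d exceeds the %d encoding slots",
                 atom$n_h, cfg$hydrogen_slots), call. = FALSE)
  deg <- numeric(cfg$degree_slots); deg[atom$degree + 1L] <- 1
  hyd <- numeric(cfg$hydrogen_slots); hyd[atom$n_h + 1L] <- 1
  chir <- if (isTRUE(atom$chiral) && !is.na(atom$chirality))
    onehot(atom$chirality, cfg$chirality_types, "chirality type")
  else numeric(length(cfg$chirality_types))
  c(onehot(atom$element, cfg$elements, "element"),
    deg,
    atom$charge,
    atom$radicals,
    onehot(atom$hybridization, cfg$hybridizations, "hybridization"),
    as.numeric(isTRUE(atom$aromatic)),
    hyd,
    as.numeric(isTRUE(atom$chiral)),
    chir)
}

#' Encode one bond as a length-10 feature vector
#'
#' @param bond A list with `order` (`single`, `double`, `triple`, `aromatic`),
#'   `conjugated` (logical), `ring` (logical), and `stereo` (`"Z"`, `"none"`,
#'   `"E"`, or `"any"`).
#' @param cfg A [feature_config()].
#' @return Numeric vector of length `cfg$bond_width`.
#' @examples
#' featurize_bond(list(order = "single", conjugated = FALSE, ring = FALSE,
#'                     stereo = "none"))
#' @export
featurize_bond <- function(bond, cfg = feature_config()) {
  c(onehot(bond$order, cfg$bond_types, "bond type"),
    as.numeric(isTRUE(bond$conjugated)),
    as.numeric(isTRUE(bond$ring)),
    onehot(bond$stereo, cfg$stereo_types, "bond stereo"))
}

# Column labels for the atom feature matrix (debugging / JSON dumps).
atom_feature_names <- function(cfg = feature_config()) {
  c(paste0("el_", cfg$elements),
    paste0("deg_", seq_len(cfg$degree_slots) - 1L),
    "charge", "radicals",
    paste0("hyb_", cfg$hybridizations),
    "aromatic",
    paste0("nH_", seq_len(cfg$hydrogen_slots) - 1L),
    "chiral",
    paste0("chir_", cfg$chirality_types))
}

bond_feature_names <- function(cfg = feature_config()) {
  c(paste0("type_", cfg$bond_types), "conjugated", "ring",
    paste0("stereo_", cfg$stereo_types))
}
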